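# Shared fixtures: tiny genotype matrices, trees, and an exhaustive Fitch
# oracle independent of the package's bottom-up/top-down implementation.

make_gm <- function(states, ref = NULL, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(ncol(states)) * 10L
  if (is.null(ref)) ref <- rep("A", ncol(states))
  colnames(states) <- as.character(positions)
  structure(list(states = states, positions = positions, ref = ref),
            class = "genotype_matrix")
}

# Minimum changes for one site by brute force over all 4^(internal nodes)
# ancestral labelings of a rooted tree.
oracle_fitch_site <- function(tree, tip_states) {
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- c(tip_states[tree$tip.label], rep(NA, nint))
  grids <- rep(list(bases), nint)
  best <- Inf
  grid <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  for (g in seq_len(nrow(grid))) {
    states[ntip + seq_len(nint)] <- unlist(grid[g, ])
    chg <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, chg)
  }
  best
}

# Brute-force rho: mean over descendant tips of summed edge lengths.
oracle_rho <- function(tree, node) {
  ntip <- length(tree$tip.label)
  tips <- if (node <= ntip) node else {
    po <- ape::reorder.phylo(tree, "postorder")$edge
    keep <- rep(FALSE, ntip + tree$Nnode); keep[node] <- TRUE
    for (k in rev(seq_len(nrow(po)))) if (keep[po[k, 1]]) keep[po[k, 2]] <- TRUE
    which(keep[seq_len(ntip)])
  }
  if (node <= ntip) return(0)
  d <- ape::dist.nodes(tree)
  mean(d[node, tips])
}

random_gm <- function(n_tips, n_sites, seed) {
  set.seed(seed)
  states <- matrix(sample(c("A", "C", "G", "T"), n_tips * n_sites, TRUE),
                   n_tips, n_sites,
                   dimnames = list(paste0("t", seq_len(n_tips)), NULL))
  make_gm(states, ref = states[1, ])
}

mini_truth <- local({
  cache <- NULL
  function(seed = 11) {
    if (!is.null(cache) && cache$config$seed == seed) return(cache)
    cfg <- sim_config(layout = "mini", n_tips = 10,
                      ancient_tips = c(anc_old = 45000, anc_mid = 7205),
                      seed = seed)
    lay <- msymut:::mini_layout()
    set.seed(seed)
    ref <- simulate_reference(max(lay$bins$end) + 10)
    tr <- simulate_genealogy(cfg)
    out <- simulate_mutations(tr, lay, ref, cfg)
    out$layout <- lay
    cache <<- out
    out
  }
})
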