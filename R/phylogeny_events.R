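# Base encoding for Fitch sets: A=1, C=2, G=4, T=8; missing = 15 (free).
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)

encode_states <- function(states) {
  m <- matrix(15L, nrow(states), ncol(states), dimnames = dimnames(states))
  for (b in names(.base_bits)) m[states == b] <- .base_bits[[b]]
  m
}

decode_bit <- function(bits) names(.base_bits)[match(bits, .base_bits)]

# Lowest set bit of each element (deterministic representative of a set).
lowest_bit <- function(x) bitwAnd(x, bitwAnd(bitwNot(x), x - 1L) + 1L)

popcount4 <- function(x) {
  bitwAnd(x, 1L) + bitwAnd(bitwShiftR(x, 1L), 1L) +
    bitwAnd(bitwShiftR(x, 2L), 1L) + bitwAnd(bitwShiftR(x, 3L), 1L)
}

# Bottom-up Fitch pass. Returns list(sets = node x site int matrix,
# score = per-site minimum change counts). Works on rooted trees with
# arbitrary (>=2) multifurcations by sequential folding of children.
fitch_down <- function(tree, enc) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nsite <- ncol(enc)
  sets <- matrix(15L, nnode, nsite)
  sets[seq_len(ntip), ] <- enc[tree$tip.label, , drop = FALSE]
  score <- integer(nsite)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  cur_parent <- -1L
  acc <- NULL
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    if (p != cur_parent) {
      if (cur_parent > 0) sets[cur_parent, ] <- acc
      cur_parent <- p
      acc <- sets[ch, ]
    } else {
      inter <- bitwAnd(acc, sets[ch, ])
      un <- bitwOr(acc, sets[ch, ])
      changed <- inter == 0L
      score <- score + changed
      acc <- ifelse(changed, un, inter)
    }
  }
  if (cur_parent > 0) sets[cur_parent, ] <- acc
  list(sets = sets, score = score)
}

#' Minimum-change (Fitch) parsimony score of a tree
#'
#' @param tree A rooted or unrooted `phylo` tree whose tips are the samples
#'   of `gm` (an unrooted tree is scored via an arbitrary rooting; the score
#'   is rooting-invariant).
#' @param gm A `genotype_matrix`.
#' @return Total parsimony score (integer).
#' @export
fitch_score <- function(tree, gm) {
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, tree$tip.label[1], resolve.root = TRUE)
  enc <- encode_states(gm$states)
  sum(fitch_down(tree, enc)$score)
}

#' Assign mutation events to tree branches by Fitch parsimony
#'
#' For every variable site a bottom-up/top-down Fitch pass yields a
#' minimum-mutation ancestral labeling; each state change becomes a
#' mutation event on the branch where it occurs. Where several
#' minimum-change labelings exist the reconstruction prefers, at the root,
#' the reference allele (ancestral context) and otherwise a fixed
#' alphabetical representative, pushing changes rootward; such events are
#' flagged `ambiguous`. Sites struck more than once are reported as
#' recurrent (same derived allele) or double-hit (different derived
#' alleles).
#'
#' @param tree A rooted `phylo` whose tip labels are the samples of `gm`.
#' @param gm A `genotype_matrix`.
#' @return A list of class `fitch_assignment`: `events` (data.frame `pos`,
#'   `edge`, `ancestral`, `derived`, `ambiguous`), `tree` (input tree with
#'   `edge.length` set to per-branch event counts), `score` (per-site
#'   change counts), `multi_hit` (data.frame `pos`, `n_events`, `kind`).
#' @export
fitch_assign <- function(tree, gm) {
  if (!ape::is.rooted(tree)) stop("fitch_assign needs a rooted tree; see root_tree()")
  if (!setequal(tree$tip.label, rownames(gm$states)))
    stop("tree tips and matrix samples differ")
  enc <- encode_states(gm$states)
  nsite <- ncol(enc)
  ntip <- length(tree$tip.label)
  down <- fitch_down(tree, enc)
  sets <- down$sets
  root <- ntip + 1L
  refbits <- .base_bits[gm$ref]
  refbits[is.na(refbits)] <- 0L
  # root state: reference allele when compatible, else lowest bit
  rootset <- sets[root, ]
  root_has_ref <- bitwAnd(rootset, refbits) != 0L
  final <- matrix(0L, nrow(sets), nsite)
  final[root, ] <- ifelse(root_has_ref, refbits, lowest_bit(rootset))
  root_amb <- popcount4(rootset) > 1L
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]  # preorder
  ev <- vector("list", nrow(pre))
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1]; ch <- pre[k, 2]
    keep <- bitwAnd(final[p, ], sets[ch, ]) != 0L
    final[ch, ] <- ifelse(keep, final[p, ], lowest_bit(sets[ch, ]))
    chg <- which(!keep)
    if (length(chg)) {
      ei <- which(tree$edge[, 1] == p & tree$edge[, 2] == ch)
      ev[[k]] <- data.frame(
        pos = gm$positions[chg],
        site = chg,
        edge = ei,
        ancestral = decode_bit(final[p, chg]),
        derived = decode_bit(final[ch, chg]),
        ambiguous = popcount4(sets[ch, chg]) > 1L | root_amb[chg],
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev)
  if (is.null(events))
    events <- data.frame(pos = integer(), site = integer(), edge = integer(),
                         ancestral = character(), derived = character(),
                         ambiguous = logical())
  rownames(events) <- NULL
  stopifnot(nrow(events) == sum(down$score))
  counts <- tabulate(events$edge, nbins = nrow(tree$edge))
  tree$edge.length <- counts
  nev <- table(events$pos)
  multi <- nev[nev >= 2]
  multi_hit <- data.frame(pos = as.integer(names(multi)),
                          n_events = as.integer(multi),
                          stringsAsFactors = FALSE)
  if (nrow(multi_hit)) {
    multi_hit$kind <- vapply(multi_hit$pos, function(p) {
      d <- events$derived[events$pos == p]
      if (length(unique(d)) == 1) "recurrent" else "double_hit"
    }, "")
  } else multi_hit$kind <- character(0)
  structure(list(events = events, tree = tree, score = down$score,
                 multi_hit = multi_hit),
            class = "fitch_assignment")
}

#' @export
print.fitch_assignment <- function(x, ...) {
  cat("fitch_assignment:", nrow(x$events), "events at",
      length(unique(x$events$pos)), "positions;",
      nrow(x$multi_hit), "multi-hit site(s)\n")
  invisible(x)
}

#' Detect hyper-recurrent positions
#'
#' Positions struck by more than `max_events` independent events; these are
#' candidate genotyping artefacts to feed back into the variant blacklist
#' (the study removed positions recurrent on 4-6 branches but retained
#' double-event positions).
#'
#' @param assignment A [fitch_assign()] result.
#' @param max_events Maximum tolerated events per position (default 3).
#' @return Integer vector of positions.
#' @export
detect_hyper_recurrent <- function(assignment, max_events = 3L) {
  mh <- assignment$multi_hit
  mh$pos[mh$n_events > max_events]
}

#' Mean mutational distance from a node to its descendant tips (rho)
#'
#' @param tree A rooted `phylo` with `edge.length` = per-branch event
#'   counts.
#' @param node Node number (tip or internal); default all nodes.
#' @return Numeric rho per requested node.
#' @export
rho <- function(tree, node = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ntips_below <- c(rep(1, ntip), numeric(tree$Nnode))
  pathsum <- numeric(nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  len <- po$edge.length
  if (is.null(len)) stop("tree has no event counts; run fitch_assign first")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
    pathsum[p] <- pathsum[p] + pathsum[ch] + ntips_below[ch] * len[k]
  }
  r <- pathsum / ntips_below
  if (is.null(node)) r else r[node]
}

#' Root a tree for event assignment
#'
#' Roots on a given outgroup tip, or by default at the midpoint of the
#' longest tip-to-tip path measured in event counts (obtained from a
#' provisional Fitch pass under an arbitrary rooting).
#'
#' @param tree An unrooted (or rooted) `phylo`.
#' @param gm The `genotype_matrix` (needed for midpoint rooting).
#' @param outgroup Optional tip label.
#' @return A rooted `phylo`.
#' @export
root_tree <- function(tree, gm = NULL, outgroup = NULL) {
  if (!is.null(outgroup))
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  if (is.null(gm)) stop("midpoint rooting needs the genotype matrix")
  prov <- ape::root(tree, tree$tip.label[1], resolve.root = TRUE)
  prov <- fitch_assign(prov, gm)$tree
  phangorn::midpoint(prov)
}

#' Heuristic maximum-parsimony tree search
#'
#' Builds a neighbor-joining start tree on Hamming distances and improves it
#' by steepest-descent nearest-neighbor-interchange under the Fitch score.
#' Deterministic given the seed (used only to break exact ties in the
#' distance matrix by an infinitesimal jitter).
#'
#' @param gm A `genotype_matrix` with at least 3 samples.
#' @param seed Integer seed.
#' @param max_rounds NNI improvement rounds cap.
#' @return An unrooted `phylo`; attribute `parsimony_score` holds the final
#'   Fitch score.
#' @export
build_parsimony_tree <- function(gm, seed = 1L, max_rounds = 50L) {
  n <- nrow(gm$states)
  if (n < 3) stop("need at least 3 samples")
  if (ncol(gm$states) == 0) {
    warning("no variable sites; returning a star tree")
    tr <- ape::stree(n, type = "star")
    tr$tip.label <- rownames(gm$states)
    attr(tr, "parsimony_score") <- 0L
    return(tr)
  }
  set.seed(seed)
  D <- hamming_distance(gm$states)
  D <- D + matrix(stats::runif(n * n, 0, 1e-9), n, n)  # tie-break jitter
  D <- (D + t(D)) / 2; diag(D) <- 0
  tree <- ape::nj(stats::as.dist(D))
  best <- fitch_score(tree, gm)
  for (round in seq_len(max_rounds)) {
    neighbors <- tryCatch(phangorn::nni(tree), error = function(e) list())
    if (!length(neighbors)) break
    scores <- vapply(neighbors, fitch_score, 0L, gm = gm)
    if (min(scores) >= best) break
    tree <- neighbors[[which.min(scores)]]
    best <- min(scores)
  }
  attr(tree, "parsimony_score") <- best
  tree
}

#' Pairwise Hamming distances between haploid sequences
#'
#' @param states Character matrix samples x sites; `N`/`NA` ignored
#'   pairwise.
#' @return A numeric distance matrix (counts of differing sites).
#' @export
hamming_distance <- function(states) {
  n <- nrow(states)
  D <- matrix(0, n, n, dimnames = list(rownames(states), rownames(states)))
  obs <- !is.na(states) & states != "N"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- obs[i, ] & obs[j, ]
    D[i, j] <- D[j, i] <- sum(states[i, ok] != states[j, ok])
  }
  D
}

#' Section configuration for time-window branch classes
#'
#' @param terminal_max_events Terminal branches with at most this many
#'   events are "very recent" (default 10, roughly the last 9.3 ky).
#' @param recent_max_rho Branches coalescing at nodes with rho at most this
#'   are "recent" (default 20).
#' @param deep_min_age Branches below the deep root whose lower node is at
#'   least this old are "deep" (default 68,000 years).
#' @param deep_root_tips Tip labels whose MRCA is the deep root node
#'   (the A0-T node in the study); NULL = tree root.
#' @param excluded_tips Tip labels of clades excluded from sectioning
#'   (e.g. the single-representative A00 lineage).
#' @return An object of class `section_config`.
#' @export
section_config <- function(terminal_max_events = 10L, recent_max_rho = 20,
                           deep_min_age = 68000, deep_root_tips = NULL,
                           excluded_tips = NULL) {
  stopifnot(terminal_max_events > 0, recent_max_rho > 0, deep_min_age > 0)
  structure(list(terminal_max_events = terminal_max_events,
                 recent_max_rho = recent_max_rho,
                 deep_min_age = deep_min_age,
                 deep_root_tips = deep_root_tips,
                 excluded_tips = excluded_tips),
            class = "section_config")
}

#' Classify branches into time windows
#'
#' Branches are labelled `very_recent` (terminal, few events), `recent`
#' (coalescing at shallow nodes by rho), `deep` (old branches below the
#' configured deep root, requiring dated nodes) or `intermediate`;
#' excluded clades get `NA`.
#'
#' @param tree Rooted `phylo` with event-count branch lengths.
#' @param config A [section_config()].
#' @param node_ages Numeric vector of node ages in years (from
#'   [date_nodes()]); required unless `deep_min_age` is `Inf`.
#' @return Character vector over `tree$edge` rows.
#' @export
section_branches <- function(tree, config = section_config(), node_ages = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(node_ages)) {
    if (is.finite(config$deep_min_age))
      stop("deep sectioning needs dated nodes; run fit_strict_clock()/date_nodes()")
    node_ages <- rep(0, ntip + tree$Nnode)
  }
  r <- rho(tree)
  lab <- rep("intermediate", nrow(tree$edge))
  child <- tree$edge[, 2]
  parent <- tree$edge[, 1]
  terminal <- child <= ntip
  lab[terminal & tree$edge.length <= config$terminal_max_events] <- "very_recent"
  recent <- r[parent] <= config$recent_max_rho & lab != "very_recent"
  lab[recent] <- "recent"
  deep_root <- if (is.null(config$deep_root_tips)) ntip + 1L
               else ape::getMRCA(tree, config$deep_root_tips)
  in_deep <- descendant_nodes(tree, deep_root)
  deep <- child %in% in_deep & node_ages[child] >= config$deep_min_age &
    lab == "intermediate"
  lab[deep] <- "deep"
  if (!is.null(config$excluded_tips)) {
    for (tipset in list(config$excluded_tips)) {
      tips <- match(tipset, tree$tip.label)
      excl <- if (length(tips) == 1) tips
              else descendant_nodes(tree, ape::getMRCA(tree, tipset))
      lab[child %in% excl] <- NA
    }
  }
  lab
}

# All nodes (incl. `node`) in the clade below `node`.
descendant_nodes <- function(tree, node) {
  po <- ape::reorder.phylo(tree, "postorder")$edge
  keep <- rep(FALSE, length(tree$tip.label) + tree$Nnode)
  keep[node] <- TRUE
  for (k in rev(seq_len(nrow(po)))) if (keep[po[k, 1]]) keep[po[k, 2]] <- TRUE
  which(keep)
}

#' Extract a clade by defining mutation or tip set
#'
#' @param tree Rooted `phylo` with events assigned.
#' @param assignment The [fitch_assign()] result for `tree` (needed when
#'   extracting by `defining_site`).
#' @param defining_site 1-based position whose event defines the clade.
#' @param tips Alternatively, tip labels whose MRCA clade is returned.
#' @return A list: `tips` (labels in the clade) and `edge` (the subtending
#'   branch index, or NA when defined by MRCA).
#' @export
extract_clade <- function(tree, assignment = NULL, defining_site = NULL,
                          tips = NULL) {
  ntip <- length(tree$tip.label)
  if (!is.null(defining_site)) {
    if (is.null(assignment)) stop("need the fitch_assign result")
    eds <- assignment$events$edge[assignment$events$pos == defining_site]
    if (length(eds) == 0) stop("no event at position ", defining_site)
    if (length(eds) > 1)
      stop("position ", defining_site, " maps to multiple branches: ",
           paste(eds, collapse = ", "))
    node <- tree$edge[eds, 2]
    nodes <- descendant_nodes(tree, node)
    return(list(tips = tree$tip.label[nodes[nodes <= ntip]], edge = eds))
  }
  if (is.null(tips)) stop("give defining_site or tips")
  if (length(tips) == 1) return(list(tips = tips, edge = which(tree$edge[, 2] == match(tips, tree$tip.label))))
  node <- ape::getMRCA(tree, tips)
  nodes <- descendant_nodes(tree, node)
  list(tips = tree$tip.label[nodes[nodes <= ntip]],
       edge = if (any(tree$edge[, 2] == node)) which(tree$edge[, 2] == node) else NA_integer_)
}
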