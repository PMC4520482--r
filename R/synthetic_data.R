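#' Simulation configuration
#'
#' Defaults mirror the study design: 104 modern haploid samples plus two
#' ancient calibration tips (45,000 and 7,205 years old), ~1.5 Mb of
#' baited fragments in 19 bins with the published effective sizes, a mean
#' substitution rate of 0.716e-9 /site/year, 12-fold CpG hypermutability
#' and transition/transversion ratios of 12.7 (CpG) and 1.5 (non-CpG).
#' `base_rate` is the mean per-site rate over the region; per-site rates
#' are proportional to `per_bin_multipliers` and `cpg_factor` and rescaled
#' so their mean equals `base_rate`.
#'
#' The default genealogy is a serial-sampling coalescent with exponential
#' growth (haploid effective size `n0` today, growth `growth` per year
#' backwards in time, generation time `gen_time` years), calibrated so the
#' mean root depth is about 291 ky at the default sample size.
#'
#' @param n_tips Number of modern tips.
#' @param ancient_tips Named numeric vector of ancient tip ages (years).
#' @param base_rate Mean substitutions/site/year.
#' @param per_bin_multipliers Per-bin rate factors (recycled to the number
#'   of bins; default all 1).
#' @param cpg_factor Fold rate increase at CpG positions (default 12).
#' @param tstv_cpg,tstv_noncpg Transition/transversion ratios by context.
#' @param n0,growth,gen_time Coalescent parameters.
#' @param layout "study" (Table-1-sized 19 bins, ~1.5 Mb) or "mini"
#'   (10 tips, 5 bins, ~50 kb) for fast runs.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 104L,
                       ancient_tips = c(ancient_45k = 45000, ancient_7k = 7205),
                       base_rate = 0.716e-9,
                       per_bin_multipliers = 1,
                       cpg_factor = 12,
                       tstv_cpg = 12.7,
                       tstv_noncpg = 1.5,
                       n0 = 4850L,
                       growth = 0,
                       gen_time = 30,
                       layout = c("study", "mini"),
                       seed = 1L) {
  layout <- match.arg(layout)
  if (layout == "mini") n_tips <- min(n_tips, 10L)
  stopifnot(all(per_bin_multipliers > 0), cpg_factor > 0,
            tstv_cpg > 0, tstv_noncpg > 0, n0 > 0, gen_time > 0)
  structure(list(n_tips = as.integer(n_tips), ancient_tips = ancient_tips,
                 base_rate = base_rate,
                 per_bin_multipliers = per_bin_multipliers,
                 cpg_factor = cpg_factor, tstv_cpg = tstv_cpg,
                 tstv_noncpg = tstv_noncpg, n0 = n0, growth = growth,
                 gen_time = gen_time, layout = layout, seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic fragment manifest shaped like the published bin table
#'
#' Builds a stand-in fragment manifest (the real 5,274-fragment list is not
#' published): each bin contributes its published number of fragments whose
#' lengths sum exactly to its effectively sequenced bases. With
#' `compact = TRUE` fragments are laid densely (10 bp gaps) on a synthetic
#' coordinate system so a full reference sequence stays small; with
#' `compact = FALSE` the published genomic spans are used.
#'
#' @param bin_table A bin table as from [msy_bin_table()].
#' @param compact Use compact synthetic coordinates (default TRUE).
#' @param gap Gap between consecutive fragments in compact mode.
#' @return List: `fragments` (manifest data.frame, 0-based half-open),
#'   `bins` (bin data.frame with `bin`, `region`, `start`, `end`,
#'   `effective_bases`).
#' @export
synthetic_fragments_from_bins <- function(bin_table = msy_bin_table(),
                                          compact = TRUE, gap = 10L) {
  frags <- list(); binrows <- list()
  cursor <- 0L
  for (i in seq_len(nrow(bin_table))) {
    nf <- bin_table$n_fragments[i]
    eff <- bin_table$effective_bases[i]
    len <- rep(eff %/% nf, nf)
    len[seq_len(eff %% nf)] <- len[seq_len(eff %% nf)] + 1L
    if (compact) {
      starts <- cursor + cumsum(c(0L, len[-nf] + gap))
    } else {
      span_start <- bin_table$initial_pos[i] - 1L
      span <- bin_table$final_pos[i] - span_start
      slack <- span - eff
      g <- if (nf > 1) slack %/% nf else 0L
      starts <- span_start + cumsum(c(0L, len[-nf] + g))
    }
    ends <- starts + len
    frags[[i]] <- data.frame(chrom = "chrY", start = starts, end = ends,
                             region = bin_table$region[i],
                             effective_bases = len, stringsAsFactors = FALSE)
    binrows[[i]] <- data.frame(bin = bin_table$bin[i],
                               region = bin_table$region[i],
                               start = starts[1], end = ends[nf],
                               n_fragments = nf, effective_bases = eff,
                               stringsAsFactors = FALSE)
    if (compact) cursor <- ends[nf] + gap
  }
  list(fragments = do.call(rbind, frags), bins = do.call(rbind, binrows))
}

# Miniature layout: 5 bins of ~10 kb, 20 fragments each.
mini_layout <- function(n_bins = 5L, bin_eff = 10000L, n_frag = 20L, gap = 10L) {
  bt <- data.frame(region = LETTERS[seq_len(n_bins)], bin = seq_len(n_bins),
                   initial_pos = NA, final_pos = NA, genomic_span = NA,
                   n_fragments = n_frag, effective_bases = bin_eff)
  synthetic_fragments_from_bins(bt, compact = TRUE, gap = gap)
}

#' Generate a reference sequence with CpG suppression
#'
#' Uniform random sequence in which the G following a C is resampled so
#' that the fraction of positions residing in CpG dinucleotides comes out
#' near the target (default ~1.1%, as observed over the study's
#' fragments). Uses the current RNG state.
#'
#' @param length Sequence length.
#' @param cpg_positions_frac Target fraction of positions in CpGs.
#' @return A character string.
#' @export
simulate_reference <- function(length, cpg_positions_frac = 0.0108) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, length, replace = TRUE)
  q <- cpg_positions_frac / 2 / 0.25   # target P(G | previous C)
  cg <- which(s[-length(s)] == "C" & s[-1] == "G")
  repl <- cg[stats::runif(length(cg)) > q / 0.25]
  # A/T replacements cannot form new CpGs with either neighbour
  if (length(repl))
    s[repl + 1L] <- sample(c("A", "T"), length(repl), replace = TRUE)
  paste(s, collapse = "")
}

#' Simulate a dated genealogy with serial sampling
#'
#' Coalescent for haploid lineages with exponential population growth
#' (backward-in-time intensity k(k-1)/2 * exp(growth * t) / (n0 *
#' gen_time) per year) in which ancient tips join the process at their
#' sampling ages. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A rooted `phylo` with branch lengths in years; attributes
#'   `node_ages` (years before present per node) and `tip_dates`.
#' @export
simulate_genealogy <- function(config = sim_config()) {
  set.seed(config$seed)
  n_mod <- config$n_tips
  anc <- config$ancient_tips
  if (n_mod + length(anc) < 2) stop("need at least 2 tips")
  labels <- c(sprintf("S%03d", seq_len(n_mod)), names(anc))
  tip_age <- c(rep(0, n_mod), unname(anc))
  n <- length(labels)
  # active lineages: list of (node id, newick subtree string, node age)
  pend <- order(tip_age)             # activation order
  active_id <- integer(0); active_nwk <- character(0); active_age <- numeric(0)
  t <- 0
  next_pend <- 1L
  rate_const <- function(k) k * (k - 1) / (2 * config$n0 * config$gen_time)
  draw_wait <- function(k, t0) {
    if (k < 2) return(Inf)
    C <- rate_const(k); g <- config$growth
    E <- stats::rexp(1)
    if (g == 0) E / C else log1p(g * E * exp(-g * t0) / C) / g
  }
  repeat {
    # activate tips sampled at or before current time
    while (next_pend <= n && tip_age[pend[next_pend]] <= t) {
      i <- pend[next_pend]
      active_id <- c(active_id, i)
      active_nwk <- c(active_nwk, labels[i])
      active_age <- c(active_age, tip_age[i])
      next_pend <- next_pend + 1L
    }
    if (next_pend > n && length(active_nwk) == 1) break
    w <- draw_wait(length(active_id), t)
    t_next_act <- if (next_pend <= n) tip_age[pend[next_pend]] else Inf
    if (t + w >= t_next_act) { t <- t_next_act; next }
    t <- t + w
    pick <- sample(length(active_id), 2)
    i <- pick[1]; j <- pick[2]
    nwk <- sprintf("(%s:%.8f,%s:%.8f)", active_nwk[i], t - active_age[i],
                   active_nwk[j], t - active_age[j])
    active_nwk <- c(active_nwk[-pick], nwk)
    active_id <- c(active_id[-pick], -1L)
    active_age <- c(active_age[-pick], t)
  }
  tree <- ape::read.tree(text = paste0(active_nwk, ";"))
  depth <- node_depths(tree)
  root_age <- depth[match(labels[1], tree$tip.label)] + tip_age[1]
  attr(tree, "node_ages") <- root_age - depth
  attr(tree, "tip_dates") <- stats::setNames(tip_age, labels)
  tree
}

# Depth (path length from root) per node, using edge lengths.
node_depths <- function(tree) {
  depth <- numeric(length(tree$tip.label) + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in rev(seq_len(nrow(po$edge))))
    depth[po$edge[k, 2]] <- depth[po$edge[k, 1]] + po$edge.length[k]
  depth
}

#' Simulate mutations on a dated genealogy
#'
#' Events arise per branch as Poisson(duration * mean rate * sites), with
#' positions drawn proportionally to per-position weights: the bin
#' multiplier times `cpg_factor` at reference CpG positions, rescaled so
#' the mean per-site rate equals `base_rate`. Derived alleles follow the
#' context's transition/transversion ratio conditional on the lineage's
#' current base, so repeat draws at one position naturally create
#' recurrent and back mutations (no infinite-sites assumption).
#'
#' @param tree Dated genealogy from [simulate_genealogy()] (branch lengths
#'   in years).
#' @param layout List with `fragments` and `bins` (see
#'   [synthetic_fragments_from_bins()]).
#' @param reference Reference string covering the layout.
#' @param config A [sim_config()].
#' @return A list of class `sim_truth`: `events` (pos, edge, ancestral,
#'   derived, bin, is_cpg, type), `matrix` (a `genotype_matrix` of final
#'   tip states at variable positions), `tree` (with per-branch true event
#'   counts as `edge.length`), `dated_tree` (input), `bin_counts`,
#'   `config`, `positions_per_bin`.
#' @export
simulate_mutations <- function(tree, layout, reference, config = sim_config()) {
  set.seed(config$seed + 1L)
  refstr <- as_ref_string(reference)
  pw <- position_weights(layout, refstr, config)
  pos <- pw$pos; bin_of <- pw$bin; is_cpg <- pw$is_cpg; w <- pw$w
  L <- length(pos)
  lambda_site_year <- config$base_rate * L        # region-wide events/year
  durations <- tree$edge.length
  n_ev <- stats::rpois(length(durations), durations * lambda_site_year)
  total <- sum(n_ev)
  ev_edge <- rep(seq_along(durations), n_ev)
  ev_idx <- if (total > 0) sample.int(L, total, replace = TRUE, prob = w) else integer(0)
  # order events root-to-tip so nested recurrences see the current base
  po <- ape::reorder.phylo(tree, "postorder")
  edge_rank <- integer(nrow(tree$edge))
  r <- 1L
  for (k in rev(seq_len(nrow(po$edge)))) {
    ei <- which(tree$edge[, 1] == po$edge[k, 1] & tree$edge[, 2] == po$edge[k, 2])
    edge_rank[ei] <- r; r <- r + 1L
  }
  ord <- order(edge_rank[ev_edge])
  ev_edge <- ev_edge[ord]; ev_idx <- ev_idx[ord]
  ts_frac <- function(cpg) {
    r <- ifelse(cpg, config$tstv_cpg, config$tstv_noncpg)
    r / (1 + r)
  }
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  ntip <- length(tree$tip.label)
  # DFS propagation of mutated-position states
  events_by_edge <- split(seq_along(ev_edge), ev_edge)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  anc_al <- der_al <- character(length(ev_edge))
  tip_states <- vector("list", ntip)
  walk <- function(node, state) {
    for (ei in kids[[as.character(node)]]) {
      st <- state
      for (e in events_by_edge[[as.character(ei)]]) {
        p <- ev_idx[e]
        key <- as.character(pos[p])
        cur <- if (!is.null(st[[key]])) st[[key]]
               else substring(refstr, pos[p], pos[p])
        if (stats::runif(1) < ts_frac(is_cpg[p])) {
          der <- transit[[cur]]
        } else {
          der <- sample(setdiff(setdiff(c("A", "C", "G", "T"), cur),
                                transit[[cur]]), 1)
        }
        anc_al[e] <<- cur; der_al[e] <<- der
        st[[key]] <- der
      }
      ch <- tree$edge[ei, 2]
      if (ch <= ntip) tip_states[[ch]] <<- st else walk(ch, st)
    }
  }
  root <- ntip + 1L
  if (total > 0 || TRUE) walk(root, list())
  events <- data.frame(pos = pos[ev_idx], edge = ev_edge,
                       ancestral = anc_al, derived = der_al,
                       bin = bin_of[ev_idx], is_cpg = is_cpg[ev_idx],
                       stringsAsFactors = FALSE)
  events$type <- if (nrow(events)) classify_substitution(events$ancestral, events$derived) else character(0)
  # final tip states -> genotype matrix at variable positions
  mut_pos <- sort(unique(events$pos))
  ref_mut <- if (length(mut_pos)) substring(refstr, mut_pos, mut_pos) else character(0)
  states <- matrix(ref_mut,
                   nrow = ntip, ncol = length(mut_pos), byrow = TRUE,
                   dimnames = list(tree$tip.label, as.character(mut_pos)))
  for (i in seq_len(ntip)) {
    st <- tip_states[[i]]
    if (length(st))
      states[i, match(as.integer(names(st)), mut_pos)] <- unlist(st)
  }
  variable <- apply(states, 2, function(col) length(unique(col)) >= 2)
  gm <- structure(list(states = states[, variable, drop = FALSE],
                       positions = mut_pos[variable],
                       ref = ref_mut[variable]),
                  class = "genotype_matrix")
  count_tree <- tree
  count_tree$edge.length <- tabulate(events$edge, nbins = nrow(tree$edge))
  bin_counts <- as.integer(table(factor(events$bin, levels = layout$bins$bin)))
  structure(list(events = events, matrix = gm, tree = count_tree,
                 dated_tree = tree, bin_counts = bin_counts,
                 positions_per_bin = as.integer(table(factor(bin_of, levels = layout$bins$bin))),
                 cpg_positions_per_bin = as.integer(tapply(is_cpg, factor(bin_of, levels = layout$bins$bin), sum)),
                 config = config, reference = refstr, layout = layout),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$events), "events on",
      length(x$dated_tree$tip.label), "tips;",
      ncol(x$matrix$states), "variable sites\n")
  invisible(x)
}

# Per-position sampling weights of the mutation process: bin multiplier
# times cpg_factor at reference CpG positions.
position_weights <- function(layout, reference, config) {
  refstr <- as_ref_string(reference)
  frags <- layout$fragments
  pos <- unlist(lapply(seq_len(nrow(frags)),
                       function(k) (frags$start[k] + 1L):frags$end[k]))
  bin_of <- assign_bins(pos, layout$bins)
  is_cpg <- cpg_status(pos, refstr)
  mult <- rep_len(config$per_bin_multipliers, nrow(layout$bins))
  w <- mult[match(bin_of, layout$bins$bin)] * ifelse(is_cpg, config$cpg_factor, 1)
  list(pos = pos, bin = bin_of, is_cpg = is_cpg, w = w)
}

#' Draw mutation positions from the simulator's placement law
#'
#' Samples `n` event positions with the per-position weights used by
#' [simulate_mutations()] (bin multipliers, CpG upweighting), without
#' generating a genealogy. Useful for large-sample checks of the placement
#' law itself. Uses the current RNG state.
#'
#' @param n Number of events to draw.
#' @param layout,reference,config As in [simulate_mutations()].
#' @return Data.frame `pos`, `bin`, `is_cpg`.
#' @export
simulate_event_positions <- function(n, layout, reference, config = sim_config()) {
  pw <- position_weights(layout, reference, config)
  idx <- sample.int(length(pw$pos), n, replace = TRUE, prob = pw$w)
  data.frame(pos = pw$pos[idx], bin = pw$bin[idx], is_cpg = pw$is_cpg[idx])
}

#' Fast marginal simulation of per-bin event counts
#'
#' Draws per-bin counts from the same law that [simulate_mutations()]
#' induces marginally: a Poisson total split multinomially with per-bin
#' probabilities proportional to multiplier * (non-CpG bases + cpg_factor
#' * CpG bases). Used for calibration/power experiments where positions
#' and alleles are not needed.
#'
#' @param expected_total Expected total number of events.
#' @param noncpg_bases,cpg_bases Per-bin base counts.
#' @param multipliers Per-bin rate factors.
#' @param cpg_factor CpG fold.
#' @param n_rep Number of replicate draws.
#' @return An `n_rep` x bins integer matrix.
#' @export
simulate_bin_counts <- function(expected_total, noncpg_bases, cpg_bases,
                                multipliers = 1, cpg_factor = 12, n_rep = 1L) {
  w <- rep_len(multipliers, length(noncpg_bases)) *
    (noncpg_bases + cpg_factor * cpg_bases)
  totals <- stats::rpois(n_rep, expected_total)
  out <- matrix(0L, n_rep, length(w))
  for (r in seq_len(n_rep))
    out[r, ] <- as.integer(stats::rmultinom(1, totals[r], w / sum(w)))
  out
}

#' Write a simulated dataset as analysis-ready fixture files
#'
#' Emits per-sample VCFs (with GT, FT and AD fields populated so the
#' variant filters are exercised), the fragment manifest (BED-like), the
#' reference FASTA, a tip-date TSV and a truth JSON. Byte-identical across
#' runs for a given truth object.
#'
#' @param truth A [simulate_mutations()] result.
#' @param dir Output directory (created; must not already contain the
#'   files).
#' @param depth_modern,depth_ancient Constant allele depths written to AD.
#' @return Invisibly, the named list of paths written.
#' @export
emit_fixture <- function(truth, dir, depth_modern = 20L, depth_ancient = 6L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- truth$matrix
  ancient <- names(truth$config$ancient_tips)
  paths <- list()
  for (s in rownames(gm$states)) {
    path <- file.path(dir, paste0(s, ".vcf"))
    if (file.exists(path)) stop("fixture path collision: ", path)
    is_anc <- s %in% ancient
    sel <- which(gm$states[s, ] != gm$ref & gm$states[s, ] != "N")
    ad <- if (is_anc) sprintf("%d,%d", 1L, depth_ancient)
          else sprintf("%d,%d", 0L, depth_modern)
    lines <- c("##fileformat=VCFv4.2",
               "##contig=<ID=chrY>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Sample filter\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", s),
               if (length(sel)) sprintf("chrY\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:FT:AD\t1:PASS:%s",
                                        gm$positions[sel], gm$ref[sel],
                                        gm$states[s, sel], ad))
    writeLines(lines, path)
    paths[[s]] <- path
  }
  bed <- file.path(dir, "fragments.bed")
  utils::write.table(truth$layout$fragments[, c("chrom", "start", "end", "region")],
                     bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrY = truth$reference)), fasta)
  tips <- file.path(dir, "tip_dates.tsv")
  td <- attr(truth$dated_tree, "tip_dates")
  utils::write.table(data.frame(sample_id = names(td), age_years = unname(td)),
                     tips, sep = "\t", quote = FALSE, row.names = FALSE)
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    config = truth$config[c("n_tips", "base_rate", "cpg_factor",
                            "tstv_cpg", "tstv_noncpg", "seed")],
    n_events = nrow(truth$events),
    bin_counts = truth$bin_counts,
    events = truth$events), tj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(fragments = bed, reference = fasta,
                          tip_dates = tips, truth = tj)))
}
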