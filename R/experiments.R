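#' Study-scale simulation experiments
#'
#' Canned experiments at the scale of the study design (104 modern tips,
#' two ancient tips, 1.5 Mb in 19 bins), used to validate the estimators:
#' strict-clock rate recovery, the null behaviour and power of the per-bin
#' proportionality chi-square, and recovery of the CpG hypermutability
#' factor. All draw their randomness from the supplied seed.
#'
#' `study_layout()` returns the shared synthetic layout and reference:
#' fragments shaped like the published bin table plus a CpG-suppressed
#' random reference (~1.1% of positions in CpGs).
#'
#' @param seed Integer seed.
#' @return For `study_layout`: list `layout`, `reference`, `cpg_per_bin`.
#' @export
study_layout <- function(seed = 99L) {
  lay <- synthetic_fragments_from_bins()
  set.seed(seed)
  ref <- simulate_reference(max(lay$bins$end) + 10L)
  cpg <- vapply(seq_len(nrow(lay$bins)), function(b) {
    sel <- lay$fragments$start >= lay$bins$start[b] &
      lay$fragments$end <= lay$bins$end[b]
    count_cpg_positions(lay$fragments[sel, , drop = FALSE], ref)
  }, 0L)
  list(layout = lay, reference = ref, cpg_per_bin = cpg)
}

#' @rdname study_layout
#' @param n_rep Number of simulation replicates.
#' @param n_boot Bootstrap replicates per clock fit.
#' @param true_rate Generating substitution rate.
#' @return For `clock_recovery_experiment`: data.frame per replicate
#'   (`rate`, `lower`, `upper`, `n_events`, `covered`) with attributes
#'   `mean_rate`, `coverage`.
#' @export
clock_recovery_experiment <- function(n_rep = 20L, n_boot = 300L,
                                      true_rate = 0.716e-9, seed = 1L) {
  sl <- study_layout(seed + 1000L)
  L <- sum(sl$layout$fragments$effective_bases)
  out <- data.frame(rate = numeric(n_rep), lower = NA_real_,
                    upper = NA_real_, n_events = integer(n_rep))
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(base_rate = true_rate, seed = seed + i)
    tr <- simulate_genealogy(cfg)
    truth <- simulate_mutations(tr, sl$layout, sl$reference, cfg)
    fit <- fit_strict_clock(truth$tree, attr(tr, "tip_dates"), L,
                            n_boot = n_boot, seed = seed + i)
    out$rate[i] <- fit$rate
    out$lower[i] <- fit$interval[1]; out$upper[i] <- fit$interval[2]
    out$n_events[i] <- nrow(truth$events)
  }
  out$covered <- out$lower <= true_rate & out$upper >= true_rate
  attr(out, "mean_rate") <- mean(out$rate)
  attr(out, "coverage") <- mean(out$covered)
  attr(out, "true_rate") <- true_rate
  out
}

#' @rdname study_layout
#' @param expected_total Expected events per replicate (study scale: 3,390).
#' @param multipliers Per-bin rate multipliers of the generating process.
#' @param alpha Test level.
#' @return For `chi2_rejection_experiment`: the rejection rate of the
#'   per-bin proportionality chi-square (weights = effective bases,
#'   excluding bin 2) over `n_rep` simulated event sets.
#' @export
chi2_rejection_experiment <- function(n_rep = 500L, expected_total = 3390,
                                      multipliers = 1, alpha = 0.05,
                                      seed = 1L) {
  sl <- study_layout(seed + 2000L)
  bins <- sl$layout$bins
  set.seed(seed)
  cnt <- simulate_bin_counts(expected_total,
                             bins$effective_bases - sl$cpg_per_bin,
                             sl$cpg_per_bin,
                             multipliers = multipliers,
                             cpg_factor = 12, n_rep = n_rep)
  rej <- apply(cnt, 1, function(o)
    chi2_proportionality(o, bins$effective_bases, bin_ids = bins$bin)$p < alpha)
  mean(rej)
}

#' @rdname study_layout
#' @param n 1e6 by default: number of event positions drawn.
#' @param cpg_factor Generating CpG fold.
#' @return For `cpg_fold_experiment`: the observed CpG/non-CpG density
#'   ratio among `n` simulated event placements.
#' @export
cpg_fold_experiment <- function(n = 1e6, cpg_factor = 12, seed = 1L) {
  sl <- study_layout(seed + 3000L)
  cfg <- sim_config(cpg_factor = cpg_factor, seed = seed)
  set.seed(seed)
  ev <- simulate_event_positions(n, sl$layout, sl$reference, cfg)
  C <- sum(sl$cpg_per_bin)
  L <- sum(sl$layout$fragments$effective_bases)
  (sum(ev$is_cpg) / C) / (sum(!ev$is_cpg) / (L - C))
}
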