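#' Cross-tabulate labelled mutation events by bin and stratum
#'
#' Produces a per-bin count table with columns for all events, CpG and
#' non-CpG subsets, each split into transitions and transversions, plus one
#' column per extra stratum (e.g. haplogroup membership or time window).
#' Overlapping strata (a nested haplogroup inside a larger one) each count
#' their events fully.
#'
#' @param events Labelled events ([classify_events()]); columns `bin`,
#'   `is_cpg`, `type`, optionally more.
#' @param bins Bin data.frame (`bin`, `effective_bases`, optionally
#'   `cpg_positions`).
#' @param strata Optional named list of logical vectors over events (one
#'   entry per stratum) to tabulate as extra columns.
#' @return A data.frame, one row per bin, with counting columns `all_abs`,
#'   `all_tr`, `all_tv`, `cpg_abs`, `cpg_tr`, `cpg_tv`, `noncpg_abs`,
#'   `noncpg_tr`, `noncpg_tv` and one `<stratum>_abs` per extra stratum.
#' @export
tabulate_events <- function(events, bins, strata = NULL) {
  need <- c("bin", "is_cpg", "type")
  if (!all(need %in% names(events)))
    stop("events lack labels: ", paste(setdiff(need, names(events)), collapse = ", "))
  cnt <- function(sel) as.integer(table(factor(events$bin[sel], levels = bins$bin)))
  tr <- events$type == "transition"
  out <- data.frame(
    bin = bins$bin, region = bins$region,
    effective_bases = bins$effective_bases,
    all_abs = cnt(TRUE), all_tr = cnt(tr), all_tv = cnt(!tr),
    cpg_abs = cnt(events$is_cpg),
    cpg_tr = cnt(events$is_cpg & tr), cpg_tv = cnt(events$is_cpg & !tr),
    noncpg_abs = cnt(!events$is_cpg),
    noncpg_tr = cnt(!events$is_cpg & tr), noncpg_tv = cnt(!events$is_cpg & !tr),
    stringsAsFactors = FALSE)
  if ("cpg_positions" %in% names(bins)) out$cpg_positions <- bins$cpg_positions
  for (nm in names(strata)) out[[paste0(nm, "_abs")]] <- cnt(strata[[nm]])
  out
}

#' Mutation density per 100 kb
#'
#' @param count Event counts.
#' @param bases Denominator in bases (effectively sequenced bases, or CpG
#'   positions for CpG densities).
#' @return `count / bases * 100000`.
#' @export
mutation_density <- function(count, bases) {
  if (any(bases <= 0)) stop("density denominator must be positive")
  count / bases * 1e5
}

#' Chi-square test of proportionality of counts to sequence amount
#'
#' Tests whether per-bin event counts are proportional to per-bin weights
#' (by default the effectively sequenced bases): expected_i = total *
#' w_i / sum(w), X^2 = sum (obs - exp)^2 / exp on bins - 1 degrees of
#' freedom. The small bin 2 is excluded by default, as in all the study's
#' per-bin tests (the 5-region aggregation uses all 19 bins).
#'
#' @param counts Integer counts per bin.
#' @param weights Positive weights per bin (same length).
#' @param bin_ids Bin identifiers (defaults to seq_along).
#' @param exclude_bins Bin ids dropped before testing (default 2).
#' @return List of class `msy_chi2`: `chi2`, `df`, `p`, `contributions`,
#'   `expected`, `included_bins`.
#' @export
chi2_proportionality <- function(counts, weights, bin_ids = seq_along(counts),
                                 exclude_bins = 2L) {
  keep <- !(bin_ids %in% exclude_bins)
  counts <- counts[keep]; weights <- weights[keep]
  if (length(counts) < 2) stop("need at least 2 included bins")
  if (any(weights <= 0)) stop("weights must be positive")
  expected <- sum(counts) * weights / sum(weights)
  if (any(expected < 1))
    warning("expected count below 1 in ", sum(expected < 1), " bin(s)")
  contrib <- (counts - expected)^2 / expected
  chi2 <- sum(contrib)
  df <- length(counts) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 contributions = contrib, expected = expected,
                 included_bins = bin_ids[keep]),
            class = "msy_chi2")
}

#' @export
print.msy_chi2 <- function(x, ...) {
  cat(sprintf("chi2 = %.2f, df = %d, p = %.3g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Fold factors, Ts/Tv ratios and coefficients of variation
#'
#' Summary ratio statistics of a count table: the CpG/non-CpG density fold
#' (CpG events per CpG position vs non-CpG events per non-CpG base),
#' transition/transversion ratios per stratum, and coefficients of
#' variation (sample sd / mean) of per-bin densities over the included
#' bins.
#'
#' @param table A [tabulate_events()]-style table with `cpg_positions`.
#' @param exclude_bins Bins dropped from CV computations (default 2).
#' @return Named list: `cpg_density`, `noncpg_density`, `cpg_fold`,
#'   `tstv_all`, `tstv_cpg`, `tstv_noncpg`, `cv_noncpg_tr`, `cv_noncpg_tv`.
#' @export
ratio_stats <- function(table, exclude_bins = 2L) {
  if (!"cpg_positions" %in% names(table))
    stop("table lacks cpg_positions; supply bins with CpG counts")
  cpg_d <- mutation_density(sum(table$cpg_abs), sum(table$cpg_positions))
  noncpg_d <- mutation_density(sum(table$noncpg_abs),
                               sum(table$effective_bases) - sum(table$cpg_positions))
  keep <- !(table$bin %in% exclude_bins)
  cv <- function(x) stats::sd(x) / mean(x)
  tstv <- function(tr, tv) if (sum(tv) == 0) NA_real_ else sum(tr) / sum(tv)
  list(cpg_density = cpg_d, noncpg_density = noncpg_d,
       cpg_fold = cpg_d / noncpg_d,
       tstv_all = tstv(table$all_tr, table$all_tv),
       tstv_cpg = tstv(table$cpg_tr, table$cpg_tv),
       tstv_noncpg = tstv(table$noncpg_tr, table$noncpg_tv),
       cv_noncpg_tr = cv(mutation_density(table$noncpg_tr[keep],
                                          table$effective_bases[keep])),
       cv_noncpg_tv = cv(mutation_density(table$noncpg_tv[keep],
                                          table$effective_bases[keep])))
}

#' Pearson correlation between per-bin quantities
#'
#' @param x,y Per-bin values.
#' @param bin_ids Bin identifiers.
#' @param exclude_bins Bins dropped (default 2).
#' @return List `r`, `p` (two-sided, t distribution on n - 2 df), `n`.
#' @export
correlate_bins <- function(x, y, bin_ids = seq_along(x), exclude_bins = 2L) {
  keep <- !(bin_ids %in% exclude_bins)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Regress per-bin mutation density on genomic features
#'
#' Ordinary least squares of density on a feature matrix, either with all
#' predictors (`full`) or with bidirectional stepwise selection on
#' partial-coefficient p-values (entry 0.05, stay 0.10), the selection
#' style contemporary with the study. Collinear predictors (aliased in the
#' fit) are dropped with a warning.
#'
#' @param density Per-bin response.
#' @param features Data.frame of per-bin predictors.
#' @param mode "full" or "stepwise".
#' @param bin_ids,exclude_bins Bin filter as elsewhere (default drops bin 2).
#' @param p_enter,p_stay Stepwise thresholds.
#' @return List of class `msy_regression`: `fit` (the `lm`), `selected`,
#'   `multiple_R`, `p_overall`, `fitted` (per included bin), `included_bins`.
#' @export
regress_density <- function(density, features, mode = c("full", "stepwise"),
                            bin_ids = seq_along(density), exclude_bins = 2L,
                            p_enter = 0.05, p_stay = 0.10) {
  mode <- match.arg(mode)
  keep <- !(bin_ids %in% exclude_bins)
  y <- density[keep]
  X <- features[keep, , drop = FALSE]
  dat <- data.frame(.y = y, X, check.names = TRUE)
  preds <- setdiff(names(dat), ".y")
  if (mode == "full") {
    if (length(y) <= length(preds)) stop("more predictors than bins")
    fit <- stats::lm(.y ~ ., data = dat)
    if (any(is.na(stats::coef(fit)))) {
      drop <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      warning("collinear predictor(s) dropped: ", paste(drop, collapse = ", "))
    }
    selected <- preds
  } else {
    selected <- character(0)
    repeat {
      changed <- FALSE
      # entry step: best candidate below p_enter
      cand <- setdiff(preds, selected)
      if (length(cand)) {
        pv <- vapply(cand, function(v) {
          f <- stats::lm(stats::reformulate(c(selected, v), ".y"), data = dat)
          ctab <- summary(f)$coefficients
          if (v %in% rownames(ctab)) ctab[v, 4] else 1
        }, 0)
        if (min(pv) < p_enter) {
          selected <- c(selected, cand[which.min(pv)])
          changed <- TRUE
        }
      }
      # removal step: worst included above p_stay
      if (length(selected)) {
        f <- stats::lm(stats::reformulate(selected, ".y"), data = dat)
        ctab <- summary(f)$coefficients
        pv <- ctab[intersect(selected, rownames(ctab)), 4]
        if (length(pv) && max(pv) > p_stay) {
          selected <- setdiff(selected, names(pv)[which.max(pv)])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    fit <- stats::lm(
      if (length(selected)) stats::reformulate(selected, ".y") else .y ~ 1,
      data = dat)
  }
  sm <- summary(fit)
  p_overall <- if (!is.null(sm$fstatistic))
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE) else NA_real_
  structure(list(fit = fit, selected = selected,
                 multiple_R = sqrt(sm$r.squared),
                 p_overall = unname(p_overall),
                 fitted = stats::fitted(fit),
                 included_bins = bin_ids[keep]),
            class = "msy_regression")
}

#' @export
print.msy_regression <- function(x, ...) {
  cat(sprintf("multiple R = %.3f, p = %.3g; predictors: %s\n",
              x$multiple_R, x$p_overall,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(intercept only)"))
  invisible(x)
}
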