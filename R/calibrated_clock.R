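#' Root-to-tip mutation counts
#'
#' @param tree Rooted `phylo` with `edge.length` = per-branch event counts.
#' @return Named numeric vector of summed counts from the root to each tip.
#' @export
root_to_tip_counts <- function(tree) {
  if (!ape::is.rooted(tree)) stop("root_to_tip_counts needs a rooted tree")
  if (is.null(tree$edge.length)) stop("tree has no event counts")
  ntip <- length(tree$tip.label)
  depth <- numeric(ntip + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(pre$edge)))
  for (k in ord)
    depth[pre$edge[k, 2]] <- depth[pre$edge[k, 1]] + pre$edge.length[k]
  stats::setNames(depth[seq_len(ntip)], tree$tip.label)
}

# tips x edges incidence: tip i descends from edge e.
tip_edge_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  inc <- matrix(FALSE, ntip, nrow(tree$edge))
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    tips <- below[[ch]]
    below[[p]] <- c(below[[p]], tips)
    ei <- which(tree$edge[, 1] == p & tree$edge[, 2] == ch)
    inc[tips, ei] <- TRUE
  }
  inc
}

#' Tip-calibrated strict-clock substitution rate
#'
#' Least-squares fit of per-tip root-to-tip mutation counts against tip
#' sampling ages under a strict clock: E[count_i] = mu * L * (T_root -
#' age_i), so the regression of counts on age has slope -mu * L. At least
#' one dated (ancient) tip is required; with all tips contemporary the
#' rate is unidentifiable. The 95% interval comes from a nonparametric
#' bootstrap over mutation events (sites), resampling each event's
#' multiplicity and refitting.
#'
#' @param tree Rooted `phylo` with event-count branch lengths.
#' @param tip_dates Named numeric vector of ages in years before present
#'   (names = tip labels; tips absent from the vector get age 0).
#' @param sequence_length Number of sites surveyed (the effective bases).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return Object of class `clock_fit`: `rate` (substitutions/site/year),
#'   `interval` (95% percentile), `t_root` (years), `sequence_length`,
#'   `boot_rates`.
#' @export
fit_strict_clock <- function(tree, tip_dates, sequence_length,
                             n_boot = 1000L, seed = 1L) {
  counts <- root_to_tip_counts(tree)
  ages <- stats::setNames(rep(0, length(counts)), names(counts))
  common <- intersect(names(tip_dates), names(ages))
  ages[common] <- tip_dates[common]
  if (length(counts) < 2) stop("need at least 2 tips")
  if (length(unique(ages)) < 2)
    stop("all tips contemporary: rate unidentifiable without a dated tip")
  solve_mu <- function(cts) {
    fit <- stats::lm(cts ~ ages)
    mu <- -unname(stats::coef(fit)[2]) / sequence_length
    c(mu = mu, t_root = unname(stats::coef(fit)[1]) / (mu * sequence_length))
  }
  est <- solve_mu(counts)
  if (!is.finite(est["mu"]) || est["mu"] <= 0)
    warning("non-positive rate estimate; check tip dates and counts")
  inc <- tip_edge_incidence(tree)
  edge_counts <- tree$edge.length
  nev <- sum(edge_counts)
  boot <- rep(NA_real_, n_boot)
  if (nev > 0 && n_boot > 0) {
    # expand edges into events; resample event multiplicities jointly
    ev_edge <- rep(seq_along(edge_counts), edge_counts)
    inc_ev <- inc[, ev_edge, drop = FALSE] * 1
    set.seed(seed)
    W <- stats::rmultinom(n_boot, nev, rep(1 / nev, nev))
    boot_counts <- inc_ev %*% W   # tips x n_boot
    for (b in seq_len(n_boot)) boot[b] <- solve_mu(boot_counts[, b])["mu"]
  }
  structure(list(rate = unname(est["mu"]),
                 t_root = unname(est["t_root"]),
                 interval = if (all(is.na(boot))) c(NA_real_, NA_real_)
                            else unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
                 sequence_length = sequence_length,
                 boot_rates = boot,
                 ages = ages, counts = counts),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("strict-clock rate: %.3g /site/year (95%% CI %.3g-%.3g), root %.0f y\n",
              x$rate, x$interval[1], x$interval[2], x$t_root))
  invisible(x)
}

#' Convert branch event counts to node ages
#'
#' The age of a node is the mean over its descendant tips of
#' (mutations from node to tip) / (mu * L) + tip sampling age (the rho
#' statistic converted by the fitted clock, tip dates offsetting ancient
#' tips). A bottom-up pass enforces age monotonicity (a parent is at least
#' as old as its children). Intervals propagate the bootstrap rate draws.
#'
#' @param tree Rooted `phylo` with event-count branch lengths.
#' @param fit A [fit_strict_clock()] result.
#' @param tip_dates Ages of dated tips (as in [fit_strict_clock()]).
#' @return Data.frame over nodes: `node`, `age`, `lower`, `upper` (95%).
#' @export
date_nodes <- function(tree, fit, tip_dates = NULL) {
  if (fit$rate <= 0) stop("non-positive rate")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ages_tips <- stats::setNames(rep(0, ntip), tree$tip.label)
  if (!is.null(tip_dates)) {
    common <- intersect(names(tip_dates), names(ages_tips))
    ages_tips[common] <- tip_dates[common]
  }
  po <- ape::reorder.phylo(tree, "postorder")
  age_for_mu <- function(mu) {
    muL <- mu * fit$sequence_length
    ntips_below <- c(rep(1, ntip), numeric(tree$Nnode))
    agesum <- c(ages_tips, numeric(tree$Nnode))  # sum over tips of count/muL + age
    for (k in seq_len(nrow(po$edge))) {
      p <- po$edge[k, 1]; ch <- po$edge[k, 2]
      ntips_below[p] <- ntips_below[p] + ntips_below[ch]
      agesum[p] <- agesum[p] + agesum[ch] + ntips_below[ch] * po$edge.length[k] / muL
    }
    age <- agesum / ntips_below
    # monotonicity: parent at least as old as children
    for (k in seq_len(nrow(po$edge)))
      age[po$edge[k, 1]] <- max(age[po$edge[k, 1]], age[po$edge[k, 2]])
    age
  }
  age <- age_for_mu(fit$rate)
  lo <- hi <- rep(NA_real_, nnode)
  br <- fit$boot_rates[is.finite(fit$boot_rates) & fit$boot_rates > 0]
  if (length(br) >= 20) {
    qs <- stats::quantile(br, c(0.025, 0.975))
    a_hi <- age_for_mu(qs[[1]])  # lower rate -> older ages
    a_lo <- age_for_mu(qs[[2]])
    lo <- pmin(a_lo, a_hi); hi <- pmax(a_lo, a_hi)
  }
  data.frame(node = seq_len(nnode), age = age, lower = lo, upper = hi)
}
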