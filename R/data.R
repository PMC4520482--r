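#' Published per-bin summaries of the 1.5 Mb MSY target region
#'
#' The study region comprises 1,495,512 effectively sequenced bases in 5,274
#' baited fragments across five X-degenerate regions (A-E) of the human Y
#' chromosome (GRCh37), partitioned into 19 bins of roughly 80 kb of
#' effectively sequenced bases each. `msy_bin_table()` returns the per-bin
#' manifest: coordinates, fragment counts, effective bases, gene overlap,
#' CpG position counts and the BG02 embryonic-stem-cell replication-timing
#' score. `msy_event_table()` returns the per-bin mutation-event counts for
#' the whole tree, split by CpG context and transition/transversion type.
#'
#' @return A data.frame with one row per bin.
#' @export
msy_bin_table <- function() {
  read.delim(system.file("extdata", "msy_bins.tsv", package = "msymut"),
             stringsAsFactors = FALSE)
}

#' @rdname msy_bin_table
#' @export
msy_event_table <- function() {
  read.delim(system.file("extdata", "msy_events_by_bin.tsv", package = "msymut"),
             stringsAsFactors = FALSE)
}

#' Per-bin mutation counts by haplogroup and by time window
#'
#' Counts of mutation events assigned to branches of selected haplogroups
#' (A00, A0, A1, A2'3, B, DE, CF, R1; R1 is nested within CF) and to four
#' time windows of the tree: deep African branches, branches of intermediate
#' antiquity, recent branches (coalescing at nodes with rho <= 20) and very
#' recent terminal branches (<= 10 mutations).
#'
#' @return A data.frame with one row per bin.
#' @export
msy_haplogroup_table <- function() {
  read.delim(system.file("extdata", "msy_events_by_haplogroup.tsv",
                         package = "msymut"), stringsAsFactors = FALSE)
}

#' @rdname msy_haplogroup_table
#' @export
msy_window_table <- function() {
  read.delim(system.file("extdata", "msy_events_by_window.tsv",
                         package = "msymut"), stringsAsFactors = FALSE)
}

#' Scalar constants of the study design
#'
#' Quantities of the published experiment that are not per-bin: the number
#' of variable positions underlying the 3,390 events, the exonic sequence
#' represented in the baited fragments together with the coding variants
#' found there, the total CpG positions in the reference over the fragments,
#' and the sampling ages of the two ancient calibration specimens.
#'
#' @return A named list.
#' @export
msy_study_constants <- function() {
  list(
    variable_sites    = 3373L,
    total_events      = 3390L,
    multi_hit_sites   = 17L,   # 11 recurrent + 6 double-hit
    coding_variants   = 76L,
    coding_bases      = 33377L,
    cpg_bases         = 16094L,
    effective_bases   = 1495512L,
    n_fragments       = 5274L,
    n_modern          = 104L,
    ancient_ages      = c(ust_ishim = 45000, loschbour = 7205),
    published_rate    = 0.716e-9,       # substitutions / site / year
    published_rate_ci = c(0.619e-9, 0.815e-9),
    root_age          = 291000          # years, point estimate
  )
}
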