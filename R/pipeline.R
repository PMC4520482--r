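#' Run the full analysis pipeline on fixture files
#'
#' Orchestrates filter -> genotype matrix -> parsimony tree -> Fitch
#' assignment -> classification -> per-bin tabulation -> proportionality
#' tests -> tip-calibrated clock, writing all artifacts (TSV, Newick,
#' JSON) plus a run log into `out_dir`. Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param vcf_paths Named character vector of per-sample VCF paths.
#' @param fragments_path Fragment manifest (BED-like).
#' @param reference_path Reference FASTA.
#' @param tip_dates_path Optional tip-date TSV (`sample_id`, `age_years`);
#'   when given, the clock stage runs.
#' @param out_dir Output directory.
#' @param ancient_samples Sample ids filtered by the ancient-depth rule.
#' @param filter_cfg A [filter_config()].
#' @param bins Optional precomputed bin data.frame; default
#'   [partition_fragments()] at 80 kb.
#' @param seed Root seed for tree search and bootstrap.
#' @param n_boot Clock bootstrap replicates.
#' @return Invisibly, a list with the main in-memory results (`matrix`,
#'   `tree`, `assignment`, `events`, `table`, `chi2`, `clock`).
#' @export
run_pipeline <- function(vcf_paths, fragments_path, reference_path,
                         tip_dates_path = NULL, out_dir,
                         ancient_samples = character(0),
                         filter_cfg = filter_config(site_blacklist = numeric(0),
                                                    site_whitelist = numeric(0)),
                         bins = NULL, seed = 1L, n_boot = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(stage, msg)
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  cat(sprintf("pipeline seed=%d, %d samples\n", seed, length(vcf_paths)),
      file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  frags <- stage("fragments", load_fragments(fragments_path))
  reference <- stage("reference",
                     as_ref_string(Biostrings::readDNAStringSet(reference_path)))
  recs <- stage("filter", {
    all <- lapply(seq_along(vcf_paths), function(i) {
      r <- read_sample_vcf(vcf_paths[[i]], sample_id = names(vcf_paths)[i])
      if (names(vcf_paths)[i] %in% ancient_samples)
        filter_ancient_calls(r, filter_cfg)
      else filter_modern_calls(r, filter_cfg)
    })
    do.call(rbind, all)
  })
  logf("filter", sprintf("%d records retained", nrow(recs)))
  gm <- stage("matrix", build_matrix(recs, frags, reference,
                                     samples = names(vcf_paths)))
  write_matrix_tsv(gm, file.path(out_dir, "genotype_matrix.tsv"))
  logf("matrix", sprintf("%d variable sites", ncol(gm$states)))
  if (is.null(bins)) bins <- stage("bins", partition_fragments(frags))
  utils::write.table(bins, file.path(out_dir, "bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tree <- stage("tree", build_parsimony_tree(gm, seed = seed))
  rooted <- stage("root", root_tree(tree, gm))
  asg <- stage("assign", fitch_assign(rooted, gm))
  ape::write.tree(asg$tree, file.path(out_dir, "tree_events.nwk"))
  events <- stage("classify", classify_events(asg$events, reference, bins))
  utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logf("assign", sprintf("%d events at %d positions (%d multi-hit)",
                         nrow(events), length(unique(events$pos)),
                         nrow(asg$multi_hit)))
  bins$cpg_positions <- vapply(seq_len(nrow(bins)), function(b) {
    sel <- frags$start >= bins$start[b] & frags$end <= bins$end[b]
    count_cpg_positions(frags[sel, , drop = FALSE], reference)
  }, 0L)
  tab <- stage("tabulate", tabulate_events(events, bins))
  chi2 <- stage("chi2", chi2_proportionality(tab$all_abs, tab$effective_bases,
                                             bin_ids = tab$bin,
                                             exclude_bins = integer(0)))
  render_count_table(tab, file.path(out_dir, "count_table.tsv"), chi2 = chi2)
  logf("chi2", sprintf("chi2=%.2f df=%d p=%.3g", chi2$chi2, chi2$df, chi2$p))
  clock <- NULL
  if (!is.null(tip_dates_path)) {
    td <- utils::read.delim(tip_dates_path, stringsAsFactors = FALSE)
    dates <- stats::setNames(td$age_years, td$sample_id)
    if (any(dates > 0)) {
      clock <- stage("clock", fit_strict_clock(asg$tree, dates,
                                               sum(frags$effective_bases),
                                               n_boot = n_boot, seed = seed))
      ages <- if (clock$rate > 0)
        stage("dates", date_nodes(asg$tree, clock, dates)) else NULL
      if (is.null(ages))
        logf("dates", "skipped: rate estimate not positive")
      jsonlite::write_json(list(rate = clock$rate, interval = clock$interval,
                                t_root = clock$t_root,
                                node_ages = ages),
                           file.path(out_dir, "clock.json"),
                           auto_unbox = TRUE, digits = NA)
      logf("clock", sprintf("rate=%.3g", clock$rate))
    }
  }
  invisible(list(matrix = gm, tree = rooted, assignment = asg,
                 events = events, bins = bins, table = tab, chi2 = chi2,
                 clock = clock))
}

#' Render a per-bin count table with totals and chi-square footer
#'
#' Publication-style TSV: one row per bin with absolute counts and
#' densities per 100 kb (1 decimal place for display), a totals row, and
#' footer rows with the proportionality chi-square, df and p.
#'
#' @param table A [tabulate_events()] table.
#' @param path Output TSV path.
#' @param chi2 Optional [chi2_proportionality()] result for the footer.
#' @return Invisibly, `path`.
#' @export
render_count_table <- function(table, path, chi2 = NULL) {
  dens <- function(cnt) sprintf("%.1f", mutation_density(cnt, table$effective_bases))
  out <- data.frame(bin = table$bin, region = table$region,
                    effective_bases = table$effective_bases,
                    all_abs = table$all_abs, all_per100kb = dens(table$all_abs),
                    tr = table$all_tr, tv = table$all_tv,
                    cpg_abs = table$cpg_abs, noncpg_abs = table$noncpg_abs,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("Total\t\t%d\t%d\t\t%d\t%d\t%d\t%d\n",
              sum(table$effective_bases), sum(table$all_abs),
              sum(table$all_tr), sum(table$all_tv),
              sum(table$cpg_abs), sum(table$noncpg_abs)), file = con)
  if (!is.null(chi2))
    cat(sprintf("chi2 (%d d.f.)\t%.1f\nP\t%.3g\n", chi2$df, chi2$chi2, chi2$p),
        file = con)
  invisible(path)
}
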