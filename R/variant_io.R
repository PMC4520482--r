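#' Load a baited-fragment manifest
#'
#' Fragment manifests are BED-like: tab-separated `chrom, start, end, region`
#' with 0-based half-open coordinates. Fragments are the capture targets
#' whose lengths sum to the effectively sequenced bases of the experiment.
#'
#' @param path Path to the manifest file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `region`,
#'   `effective_bases`, sorted as in the file. Attribute `total_bases` holds
#'   the summed fragment lengths.
#' @export
load_fragments <- function(path) {
  cols <- c("chrom", "start", "end", "region")
  if (file.size(path) == 0) {
    frags <- data.frame(chrom = character(), start = integer(),
                        end = integer(), region = character(),
                        effective_bases = integer())
    attr(frags, "total_bases") <- 0L
    return(frags)
  }
  frags <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(frags) < 4) stop("fragment manifest needs 4 columns (chrom, start, end, region)")
  frags <- frags[, 1:4]
  names(frags) <- cols
  if (!is.numeric(frags$start) || !is.numeric(frags$end))
    stop("fragment coordinates must be numeric")
  if (any(frags$end <= frags$start)) stop("fragment with end <= start")
  for (r in unique(frags$region)) {
    f <- frags[frags$region == r, ]
    if (is.unsorted(f$start, strictly = TRUE))
      stop("fragments not sorted within region ", r)
    if (any(f$start[-1] < f$end[-nrow(f)]))
      stop("overlapping fragments within region ", r)
  }
  frags$effective_bases <- as.integer(frags$end - frags$start)
  attr(frags, "total_bases") <- sum(frags$effective_bases)
  frags
}

#' Variant filtering configuration
#'
#' Modern (genotyping-platform) calls are dropped when their FT filter token
#' is in the reject set or their alternative-allele depth is below
#' `min_alt_depth`. Ancient (low-coverage) calls are retained only when the
#' alternative-allele depth strictly exceeds the reference-allele depth.
#' A site blacklist removes hyper-recurrent positions regardless of quality;
#' a whitelist protects positions from depth/FT-based removal.
#'
#' @param min_alt_depth Minimum alternative allele depth for modern calls
#'   (default 3, i.e. depth <= 2 is discarded).
#' @param reject_filter Filter tokens that invalidate a modern call.
#' @param site_blacklist Positions always removed. Defaults to the three
#'   hyper-recurrent positions removed in the study.
#' @param site_whitelist Positions never removed by quality filters.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_alt_depth = 3L,
                          reject_filter = "VQLow",
                          site_blacklist = c(6670461, 8417317, 19044813),
                          site_whitelist = c(19319427, 19431990)) {
  if (length(intersect(site_blacklist, site_whitelist)))
    stop("site blacklist and whitelist overlap")
  structure(list(min_alt_depth = as.integer(min_alt_depth),
                 reject_filter = reject_filter,
                 site_blacklist = site_blacklist,
                 site_whitelist = site_whitelist),
            class = "filter_config")
}

#' Filter variant calls from a modern sample
#'
#' @param records A data.frame of per-sample variant records with columns
#'   `pos`, `ref`, `alt`, `filter`, `ad_alt` (and optionally `ad_ref`,
#'   `sample_id`).
#' @param config A [filter_config()].
#' @return The retained records.
#' @export
filter_modern_calls <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(records) == 0) return(records)
  miss <- is.na(records$ad_alt)
  if (any(miss)) {
    warning(sum(miss), " record(s) lack an allele depth; dropped")
  }
  white <- records$pos %in% config$site_whitelist
  keep <- !miss &
    !(records$filter %in% config$reject_filter) &
    records$ad_alt >= config$min_alt_depth
  keep <- (keep | white) & !(records$pos %in% config$site_blacklist)
  records[keep, , drop = FALSE]
}

#' Filter variant calls from an ancient sample
#'
#' Retains a call only when the alternative-allele depth strictly exceeds
#' the reference-allele depth, the rule used for the low-coverage ancient
#' genomes; blacklisted positions are removed as for modern samples.
#'
#' @inheritParams filter_modern_calls
#' @export
filter_ancient_calls <- function(records, config = filter_config()) {
  if (nrow(records) == 0) return(records)
  if (any(is.na(records$ad_ref)) || any(is.na(records$ad_alt)))
    stop("ancient records must carry both reference and alternative depths")
  keep <- records$ad_alt > records$ad_ref &
    !(records$pos %in% config$site_blacklist)
  records[keep, , drop = FALSE]
}

#' Read one sample's variant records from a VCF file
#'
#' Extracts single-nucleotide substitutions (POS, REF, ALT, FILTER or FT,
#' AD) as a flat record table; multi-allelic rows are split into bi-allelic
#' records. Non-SNV alleles are dropped.
#'
#' @param path Path to a VCF 4.x file for a single sample.
#' @param sample_id Sample identifier; defaults to the VCF sample column.
#' @return A data.frame of records as used by [filter_modern_calls()].
#' @export
read_sample_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    sample_id <- colnames(v@gt)[2]
    if (is.null(sample_id)) sample_id <- "sample"
  }
  if (nrow(fix) == 0) {
    return(data.frame(sample_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      filter = character(), ad_ref = integer(),
                      ad_alt = integer()))
  }
  ft <- tryCatch(vcfR::extract.gt(v, element = "FT")[, 1],
                 error = function(e) rep(NA_character_, nrow(fix)))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD")[, 1],
                 error = function(e) rep(NA_character_, nrow(fix)))
  filt <- ifelse(!is.na(ft), ft, fix$FILTER)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    depths <- if (!is.na(ad[i])) as.integer(strsplit(ad[i], ",")[[1]]) else NA_integer_
    for (j in seq_along(alts)) {
      if (!fix$REF[i] %in% c("A", "C", "G", "T")) next
      if (!alts[j] %in% c("A", "C", "G", "T")) next
      out[[i]] <- rbind(out[[i]], data.frame(
        sample_id = sample_id,
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        filter = if (is.na(filt[i])) "PASS" else filt[i],
        ad_ref = if (all(is.na(depths))) NA_integer_ else depths[1],
        ad_alt = if (all(is.na(depths))) NA_integer_ else depths[j + 1],
        stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(sample_id = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      filter = character(), ad_ref = integer(),
                                      ad_alt = integer())
  rownames(out) <- NULL
  out
}

# Coerce a reference to a single uppercase character string.
as_ref_string <- function(reference) {
  if (inherits(reference, "DNAStringSet")) reference <- reference[[1]]
  if (inherits(reference, "DNAString")) return(as.character(reference))
  if (is.character(reference) && length(reference) == 1) return(toupper(reference))
  stop("reference must be a DNAString(Set) or a single character string")
}

#' Build the haploid genotype matrix
#'
#' Combines filtered per-sample records into a samples-by-sites matrix of
#' haploid allele calls. Sites outside the baited fragments are removed; a
#' sample without a record at a retained site carries the reference state
#' (the input datasets report variants only); monomorphic columns are
#' dropped so every retained site is variable.
#'
#' @param records Filtered records for all samples (column `sample_id`).
#' @param fragments Fragment manifest from [load_fragments()] (0-based
#'   half-open); record positions are 1-based.
#' @param reference Reference sequence (`DNAStringSet`/`DNAString` or a
#'   character string) covering all positions.
#' @param samples Sample ids to include; defaults to those present in
#'   `records`. Samples with no surviving records still get a (reference)
#'   row when listed here.
#' @return An object of class `genotype_matrix`: a list with `states`
#'   (character matrix, samples x sites), `positions` (1-based) and `ref`
#'   (reference allele per site).
#' @export
build_matrix <- function(records, fragments, reference,
                         samples = unique(records$sample_id)) {
  refstr <- as_ref_string(reference)
  inside <- rep(FALSE, nrow(records))
  if (nrow(records)) {
    # fragments half-open 0-based; pos 1-based => inside iff start < pos <= end
    for (k in seq_len(nrow(fragments))) {
      inside <- inside | (records$pos > fragments$start[k] &
                          records$pos <= fragments$end[k])
    }
  }
  records <- records[inside, , drop = FALSE]
  dup <- paste(records$sample_id, records$pos)
  if (anyDuplicated(dup)) {
    d <- records[duplicated(dup) | duplicated(dup, fromLast = TRUE), ]
    conf <- tapply(d$alt, paste(d$sample_id, d$pos), function(a) length(unique(a)) > 1)
    if (any(conf))
      stop("conflicting alleles for ", names(conf)[which(conf)[1]])
    records <- records[!duplicated(dup), , drop = FALSE]
  }
  positions <- sort(unique(records$pos))
  refal <- if (length(positions)) substring(refstr, positions, positions)
           else character(0)
  states <- matrix(rep(refal, each = length(samples)),
                   nrow = length(samples), ncol = length(positions),
                   dimnames = list(samples, as.character(positions)))
  if (nrow(records)) {
    idx <- cbind(match(records$sample_id, samples),
                 match(records$pos, positions))
    states[idx] <- records$alt
  }
  variable <- apply(states, 2, function(col) {
    length(unique(col[!is.na(col) & col != "N"])) >= 2
  })
  states <- states[, variable, drop = FALSE]
  structure(list(states = states,
                 positions = positions[variable],
                 ref = refal[variable]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$states), "samples x",
      ncol(x$states), "variable sites\n")
  invisible(x)
}

#' Export a genotype matrix as TSV
#'
#' @param x A `genotype_matrix`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(sample = rownames(x$states), x$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
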