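#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) changes are
#' transitions; all others are transversions. Vectorized.
#'
#' @param ancestral,derived Single bases in A, C, G, T.
#' @return Character vector, "transition" or "transversion".
#' @export
classify_substitution <- function(ancestral, derived) {
  ok <- ancestral %in% c("A", "C", "G", "T") & derived %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("non-ACGT allele in substitution")
  if (any(ancestral == derived)) stop("ancestral and derived alleles identical")
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(ancestral) == purine(derived), "transition", "transversion")
}

#' CpG status of positions from the reference context
#'
#' A position is CpG when the reference carries C there followed by G, or G
#' there preceded by C. The reference (ancestral) context is used; flanking
#' polymorphism is ignored. Flanking `N` (or a sequence edge) gives non-CpG.
#'
#' @param pos 1-based positions.
#' @param reference Reference sequence.
#' @return Logical vector.
#' @export
cpg_status <- function(pos, reference) {
  refstr <- as_ref_string(reference)
  L <- nchar(refstr)
  if (any(pos < 1 | pos > L)) stop("position outside reference")
  base <- substring(refstr, pos, pos)
  nxt <- ifelse(pos < L, substring(refstr, pos + 1L, pos + 1L), "")
  prv <- ifelse(pos > 1L, substring(refstr, pos - 1L, pos - 1L), "")
  (base == "C" & nxt == "G") | (base == "G" & prv == "C")
}

#' Label mutation events with bin, CpG context and substitution type
#'
#' @param events Event data.frame with columns `pos`, `ancestral`,
#'   `derived` (as from [fitch_assign()]).
#' @param reference Reference sequence.
#' @param bins Bin data.frame.
#' @return `events` with added columns `bin`, `is_cpg`,
#'   `type` ("transition"/"transversion").
#' @export
classify_events <- function(events, reference, bins) {
  if (nrow(events) == 0) {
    events$bin <- integer(0); events$is_cpg <- logical(0)
    events$type <- character(0)
    return(events)
  }
  events$bin <- assign_bins(events$pos, bins)
  events$is_cpg <- cpg_status(events$pos, reference)
  events$type <- classify_substitution(events$ancestral, events$derived)
  events
}
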