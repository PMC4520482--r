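#' Partition fragments into bins of approximately equal effective size
#'
#' Within each region, consecutive fragments are grouped into
#' `k = round(region total / target_effective)` bins (at least one), choosing
#' the consecutive partition that minimizes the maximum deviation of any
#' bin's effective size from the region mean. Regions smaller than the
#' target form a single bin.
#'
#' @param fragments Fragment manifest ([load_fragments()]).
#' @param target_effective Target effectively sequenced bases per bin
#'   (default 80,000).
#' @return A data.frame with one row per bin: `bin`, `region`, `start`,
#'   `end` (genomic span bounds, 0-based half-open), `n_fragments`,
#'   `effective_bases`, plus a `fragment_bin` attribute giving each
#'   fragment's bin id.
#' @export
partition_fragments <- function(fragments, target_effective = 80000) {
  regions <- unique(fragments$region)
  bins <- list()
  frag_bin <- integer(nrow(fragments))
  next_id <- 1L
  for (r in regions) {
    sel <- which(fragments$region == r)
    if (!length(sel)) next
    sizes <- fragments$effective_bases[sel]
    total <- sum(sizes)
    k <- max(1L, as.integer(round(total / target_effective)))
    k <- min(k, length(sel))
    grp <- best_consecutive_partition(sizes, k)
    for (g in seq_len(k)) {
      idx <- sel[grp == g]
      bins[[length(bins) + 1L]] <- data.frame(
        bin = next_id, region = r,
        start = fragments$start[idx[1]],
        end = fragments$end[idx[length(idx)]],
        n_fragments = length(idx),
        effective_bases = sum(fragments$effective_bases[idx]),
        stringsAsFactors = FALSE)
      frag_bin[idx] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- do.call(rbind, bins)
  attr(out, "fragment_bin") <- frag_bin
  out
}

# Split `sizes` into k consecutive groups minimizing the maximum |group sum -
# mean group sum|. Dynamic programme over (item, groups used); determinate
# tie-break: earliest split.
best_consecutive_partition <- function(sizes, k) {
  n <- length(sizes)
  if (k >= n) return(seq_len(n))
  if (k == 1) return(rep(1L, n))
  target <- sum(sizes) / k
  cs <- c(0, cumsum(sizes))
  dev <- function(i, j) abs(cs[j + 1] - cs[i] - target)  # group = items i..j
  # best[j, g]: minimal max-deviation covering items 1..j with g groups
  best <- matrix(Inf, n, k)
  cut <- matrix(0L, n, k)
  for (j in 1:n) best[j, 1] <- dev(1, j)
  for (g in 2:k) {
    for (j in g:n) {
      for (i in g:j) {  # last group = items i..j
        cand <- max(best[i - 1, g - 1], dev(i, j))
        if (cand < best[j, g]) {
          best[j, g] <- cand
          cut[j, g] <- i
        }
      }
    }
  }
  grp <- integer(n)
  j <- n
  for (g in k:1) {
    i <- if (g == 1) 1L else cut[j, g]
    grp[i:j] <- g
    j <- i - 1L
  }
  grp
}

#' Form bins from externally specified boundaries
#'
#' Reproduces a published binning exactly: each fragment is assigned to the
#' bin whose `[initial_pos, final_pos]` span (1-based inclusive) contains
#' it. A fragment straddling a boundary is an error.
#'
#' @param fragments Fragment manifest (0-based half-open coordinates).
#' @param boundaries A data.frame with columns `bin`, `region`,
#'   `initial_pos`, `final_pos` (1-based inclusive).
#' @return A bin data.frame as from [partition_fragments()].
#' @export
bins_from_boundaries <- function(fragments, boundaries) {
  frag_bin <- rep(NA_integer_, nrow(fragments))
  for (b in seq_len(nrow(boundaries))) {
    lo <- boundaries$initial_pos[b] - 1L  # to 0-based half-open
    hi <- boundaries$final_pos[b]
    starts_in <- fragments$start >= lo & fragments$start < hi
    ends_in <- fragments$end > lo & fragments$end <= hi
    if (any(starts_in != ends_in))
      stop("fragment straddles boundary of bin ", boundaries$bin[b])
    frag_bin[starts_in] <- boundaries$bin[b]
  }
  if (anyNA(frag_bin)) stop(sum(is.na(frag_bin)), " fragment(s) fall in no bin")
  out <- do.call(rbind, lapply(seq_len(nrow(boundaries)), function(b) {
    idx <- which(frag_bin == boundaries$bin[b])
    if (!length(idx)) return(NULL)
    data.frame(bin = boundaries$bin[b], region = boundaries$region[b],
               start = min(fragments$start[idx]),
               end = max(fragments$end[idx]),
               n_fragments = length(idx),
               effective_bases = sum(fragments$effective_bases[idx]),
               stringsAsFactors = FALSE)
  }))
  attr(out, "fragment_bin") <- frag_bin
  out
}

#' Count CpG positions within sequenced fragments
#'
#' A position counts when it is the C or the G of a 5'-CG-3' dinucleotide in
#' the reference (both members of one CpG count as two positions), with the
#' dinucleotide context taken from the full reference but only positions
#' inside the given fragments counted. `N` bases never form CpGs.
#'
#' @param fragments Fragment rows restricted to the bin of interest
#'   (0-based half-open).
#' @param reference Reference sequence.
#' @return Integer count of CpG positions.
#' @export
count_cpg_positions <- function(fragments, reference) {
  refstr <- as_ref_string(reference)
  n <- 0L
  L <- nchar(refstr)
  for (k in seq_len(nrow(fragments))) {
    pos <- (fragments$start[k] + 1L):fragments$end[k]  # 1-based
    base <- substring(refstr, pos, pos)
    nxt <- ifelse(pos < L, substring(refstr, pos + 1L, pos + 1L), "")
    prv <- ifelse(pos > 1L, substring(refstr, pos - 1L, pos - 1L), "")
    n <- n + sum((base == "C" & nxt == "G") | (base == "G" & prv == "C"))
  }
  as.integer(n)
}

#' Attach genomic-feature summaries to a bin
#'
#' Computes basewise overlap percentages of annotation tracks over the
#' sequenced fragments of a bin (e.g. genes, transcribed regions, ESTs) and
#' over the whole genomic span (e.g. simple repeats), plus the unweighted
#' mean of a positional score track (replication timing) over the bin span.
#'
#' @param bin One row of a bin data.frame.
#' @param fragments Fragment rows belonging to the bin.
#' @param tracks Named list of interval data.frames (`start`, `end`,
#'   0-based half-open) for overlap percentages.
#' @param span_tracks Named list of tracks measured over the genomic span
#'   instead of the sequenced fragments.
#' @param score_tracks Named list of data.frames (`pos`, `score`): values
#'   whose position falls in the bin span are averaged.
#' @return A named list of feature values (percentages in 0-100).
#' @export
aggregate_features <- function(bin, fragments, tracks = list(),
                               span_tracks = list(), score_tracks = list()) {
  ovl_bases <- function(intervals, qs, qe) {
    if (!nrow(intervals)) return(0)
    sum(pmax(0, pmin(intervals$end, qe) - pmax(intervals$start, qs)))
  }
  out <- list()
  eff <- sum(fragments$effective_bases)
  for (nm in names(tracks)) {
    tr <- merge_intervals(tracks[[nm]])
    b <- 0
    for (k in seq_len(nrow(fragments)))
      b <- b + ovl_bases(tr, fragments$start[k], fragments$end[k])
    out[[paste0(nm, "_pct")]] <- 100 * b / eff
  }
  span <- bin$end - bin$start
  for (nm in names(span_tracks)) {
    tr <- merge_intervals(span_tracks[[nm]])
    out[[paste0(nm, "_span_pct")]] <- 100 * ovl_bases(tr, bin$start, bin$end) / span
  }
  for (nm in names(score_tracks)) {
    sc <- score_tracks[[nm]]
    inside <- sc$pos > bin$start & sc$pos <= bin$end
    out[[paste0(nm, "_score")]] <- if (any(inside)) mean(sc$score[inside]) else NA_real_
  }
  out
}

merge_intervals <- function(x) {
  if (!nrow(x)) return(x)
  x <- x[order(x$start), , drop = FALSE]
  out_s <- x$start[1]; out_e <- x$end[1]
  ss <- c(); ee <- c()
  for (i in seq_len(nrow(x))[-1]) {
    if (x$start[i] <= out_e) out_e <- max(out_e, x$end[i])
    else { ss <- c(ss, out_s); ee <- c(ee, out_e); out_s <- x$start[i]; out_e <- x$end[i] }
  }
  data.frame(start = c(ss, out_s), end = c(ee, out_e))
}

#' Assign event positions to bins
#'
#' @param pos 1-based positions.
#' @param bins Bin data.frame (`start`, `end` 0-based half-open, `bin`).
#' @return Integer bin id per position; error if any position falls in no
#'   bin span.
#' @export
assign_bins <- function(pos, bins) {
  out <- rep(NA_integer_, length(pos))
  for (b in seq_len(nrow(bins))) {
    sel <- pos > bins$start[b] & pos <= bins$end[b]
    out[sel] <- bins$bin[b]
  }
  if (anyNA(out))
    stop("position(s) outside all bins: ", paste(utils::head(pos[is.na(out)]), collapse = ", "))
  out
}
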