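# Coverage profiles and ab initio "hard domain" detection.
#
# A region whose alignment coverage sits well below the rest of the chain
# is under-represented in the full-length MSA; re-searching it on its own
# typically recovers more homologs. Such regions are flagged as hard
# domains: maximal runs of >= min_len consecutive positions whose coverage
# is strictly below the median coverage of the chain.

#' Domain segment on the query sequence
#'
#' @param start,end 1-based inclusive bounds
#' @param kind `"hard"` (detected under-covered region) or `"full"`
#'   (the whole chain)
#' @return object of class `domain_segment`
#' @export
domain_segment <- function(start, end, kind = c("hard", "full")) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop(sprintf("invalid segment [%s, %s]", start, end))
  }
  structure(list(start = start, end = end, kind = kind),
            class = "domain_segment")
}

#' @export
print.domain_segment <- function(x, ...) {
  cat(sprintf("<domain_segment> [%d, %d] (%s, %d residues)\n",
              x$start, x$end, x$kind, x$end - x$start + 1L))
  invisible(x)
}

segment_length <- function(seg) seg$end - seg$start + 1L

#' Per-column alignment coverage profile
#'
#' Counts, for each query position, the number of alignment rows with a
#' non-gap character in that column, and records the median of those
#' counts as the cutoff used by [parse_hard_domains()]. The query covers
#' every position, so every count is at least 1. For an even number of
#' columns the median is the mean of the two central order statistics.
#'
#' @param x an [msa]
#' @return object of class `coverage_profile`: list with integer vector
#'   `counts` (length L) and scalar `cutoff`
#' @export
coverage_profile <- function(x) {
  stopifnot(inherits(x, "msa"))
  m <- msa_char_matrix(x)
  counts <- as.integer(rowSums(m != "-" & m != "."))
  structure(list(counts = counts, cutoff = stats::median(counts)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> L = %d, coverage %d-%d, median cutoff %.1f\n",
              length(x$counts), min(x$counts), max(x$counts), x$cutoff))
  invisible(x)
}

#' Detect hard domains as long below-median coverage runs
#'
#' Scans the coverage profile for maximal runs of consecutive positions
#' whose count is strictly below the cutoff (the median coverage) and
#' reports each run of at least `min_len` residues as a hard domain.
#' Positions tied with the median never qualify, so a flat profile yields
#' no domains. With `bridge > 0`, below-cutoff runs separated by at most
#' `bridge` above-cutoff positions are merged before the length test;
#' the default keeps runs strict.
#'
#' @param profile a [coverage_profile]
#' @param min_len minimum run length in residues, default 30
#' @param bridge maximum above-cutoff gap to bridge between runs,
#'   default 0 (no bridging)
#' @return list of [domain_segment]s of kind `"hard"`, in ascending
#'   order; empty list when no run qualifies
#' @export
parse_hard_domains <- function(profile, min_len = 30L, bridge = 0L) {
  stopifnot(inherits(profile, "coverage_profile"))
  min_len <- as.integer(min_len)
  if (min_len < 1L) stop("min_len must be >= 1")
  below <- profile$counts < profile$cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (bridge > 0L && nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (k in 2L:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap <= bridge) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  lapply(seq_len(nrow(runs)), function(k) {
    domain_segment(runs$start[k], runs$end[k], kind = "hard")
  })
}

#' Build the per-segment prediction work list
#'
#' The full-length alignment predicts the full-length contact map; each
#' hard domain gets its own alignment and map which is later merged back
#' with [merge_domain_map()]. The plan is simply the full-length segment
#' followed by the hard segments in ascending order.
#'
#' @param segments list of hard [domain_segment]s (may be empty)
#' @param L chain length
#' @return list of [domain_segment]s: `[1, L]` of kind `"full"` first,
#'   then the hard segments
#' @export
plan_domain_prediction <- function(segments, L) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  segments <- segments[order(vapply(segments, `[[`, integer(1L), "start"))]
  prev_end <- 0L
  for (seg in segments) {
    if (!inherits(seg, "domain_segment")) stop("segments must be domain_segment objects")
    if (seg$end > L || seg$start < 1L) {
      stop(sprintf("segment [%d, %d] outside [1, %d]", seg$start, seg$end, L))
    }
    if (seg$start <= prev_end) stop("hard segments overlap")
    prev_end <- seg$end
  }
  c(list(domain_segment(1L, L, kind = "full")), segments)
}
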