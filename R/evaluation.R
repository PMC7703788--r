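# CASP-convention scoring of predicted contact maps against native
# distance matrices.

#' Sequence-separation range classes
#'
#' CASP bands residue pairs by sequence separation |i - j|: short range
#' 6-11, medium range 12-23, long range >= 24. Pairs closer than 6
#' residues are never assessed.
#'
#' @param name `"short"`, `"medium"` or `"long"`
#' @return object of class `range_class` with `min_sep` and `max_sep`
#' @export
range_class <- function(name = c("long", "medium", "short")) {
  name <- match.arg(name)
  bounds <- switch(name,
    short  = c(6L, 11L),
    medium = c(12L, 23L),
    long   = c(24L, .Machine$integer.max)
  )
  structure(list(name = name, min_sep = bounds[1L], max_sep = bounds[2L]),
            class = "range_class")
}

as_range <- function(range) {
  if (inherits(range, "range_class")) range else range_class(range)
}

#' Rank residue pairs of a map within a separation band
#'
#' Returns the pairs `i < j` whose separation falls in the band, sorted
#' by predicted probability. Because top-k precision is sensitive to
#' order at tied scores, the tie-break is fully deterministic:
#' probability descending, then separation descending, then `i`
#' ascending (then `j` ascending).
#'
#' @param map a [contact_map]
#' @param range a [range_class] or its name
#' @return data frame with columns `i`, `j`, `sep`, `prob`, best first
#' @export
rank_pairs <- function(map, range = "long") {
  stopifnot(inherits(map, "contact_map"))
  rng <- as_range(range)
  idx <- which(upper.tri(map$prob), arr.ind = TRUE)
  sep <- idx[, 2L] - idx[, 1L]
  keep <- sep >= rng$min_sep & sep <= rng$max_sep
  d <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L], sep = sep[keep],
                  prob = map$prob[idx[keep, , drop = FALSE]])
  d <- d[order(-d$prob, -d$sep, d$i, d$j), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Ranked band pairs annotated with native distance and truth; drops
# unassessable pairs (missing native distance), per CASP convention.
# With predicted_only, pairs scored 0 are treated as not submitted and
# excluded from the ranking (the CASP habit of listing only confident
# pairs); a map with no positive pair in the band falls back to the full
# tie-broken list so a null predictor is still assessable.
assessable_ranked <- function(pred, native, range, contact_threshold = 8.0,
                              predicted_only = FALSE) {
  stopifnot(inherits(pred, "contact_map"), inherits(native, "distance_matrix"))
  if (pred$L != native$L) stop("prediction and native structure differ in length")
  d <- rank_pairs(pred, range)
  if (predicted_only && any(d$prob > 0)) d <- d[d$prob > 0, , drop = FALSE]
  d$dist <- native$dist[cbind(d$i, d$j)]
  d <- d[!is.na(d$dist), , drop = FALSE]
  d$true <- d$dist < contact_threshold
  d
}

topk_count <- function(L, fraction) max(1L, as.integer(floor(L * fraction)))

#' Precision of the top-ranked predicted contacts
#'
#' Takes the `k = floor(L * fraction)` highest-probability pairs in the
#' band (at least 1) and reports `100 * TP / k`, where a true positive
#' has native Cbeta distance strictly below `contact_threshold`. Pairs
#' with missing native distances are skipped and replaced by the next
#' ranked pairs. Pairs scored exactly 0 count as not predicted and never
#' enter the top list (unless the map predicts nothing at all, in which
#' case the full tie-broken band list is assessed). With fewer than `k`
#' assessable pairs the denominator is the number actually assessed;
#' with none, `NA`.
#'
#' @param pred predicted [contact_map]
#' @param native native [distance_matrix]
#' @param fraction top-list size as a fraction of L (e.g. 1/5 for top
#'   L/5); ignored when `k` is given
#' @param range a [range_class] or its name
#' @param k absolute top-list size, overriding `fraction`
#' @param contact_threshold contact definition in Angstrom, default 8.0
#' @param filter_one_per_residue apply [one_per_residue_filter()] to the
#'   ranked list before taking the top k
#' @return precision in percent
#' @export
precision_topk <- function(pred, native, fraction = 1 / 5, range = "long",
                           k = NULL, contact_threshold = 8.0,
                           filter_one_per_residue = FALSE) {
  d <- assessable_ranked(pred, native, range, contact_threshold,
                         predicted_only = TRUE)
  if (filter_one_per_residue) d <- one_per_residue_filter(d)
  if (is.null(k)) k <- topk_count(pred$L, fraction)
  if (k < 1L || nrow(d) == 0L) return(NA_real_)
  top <- utils::head(d, k)
  100 * sum(top$true) / nrow(top)
}

#' Coverage of native contacts by the top-ranked predictions
#'
#' `100 * TP / N` where `TP` counts true positives among the top `k`
#' ranked pairs and `N` is the number of native contacts in the band.
#'
#' @inheritParams precision_topk
#' @param k top-list size (absolute); `k = 0` gives 0
#' @return coverage in percent, `NA` when the band has no native contact
#' @export
coverage_stat <- function(pred, native, k, range = "long",
                          contact_threshold = 8.0) {
  all_pairs <- assessable_ranked(pred, native, range, contact_threshold)
  n_native <- sum(all_pairs$true)
  if (n_native == 0L) return(NA_real_)
  if (k < 1L) return(0)
  d <- assessable_ranked(pred, native, range, contact_threshold,
                         predicted_only = TRUE)
  100 * sum(utils::head(d, k)$true) / n_native
}

#' ROC AUC of contact probabilities within a band
#'
#' Area under the ROC curve of the predicted probabilities against the
#' binary native contact labels, over all assessable pairs in the band.
#' Computed via the rank-sum (Mann-Whitney) identity with mid-ranks at
#' ties, which equals the trapezoidal area under the empirical ROC.
#'
#' @inheritParams precision_topk
#' @return AUC in \[0, 1\]; `NA` when the band lacks a positive or a
#'   negative pair
#' @export
roc_auc <- function(pred, native, range = "long", contact_threshold = 8.0) {
  d <- assessable_ranked(pred, native, range, contact_threshold)
  n1 <- sum(d$true); n0 <- sum(!d$true)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(d$prob)                     # mid-ranks at ties
  (sum(r[d$true]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean native distance of false-positive predictions
#'
#' Among the top `k` ranked pairs, averages the native distance of those
#' that are not true contacts. Large values mean the predictor's errors
#' are far from the contact shell rather than near misses.
#'
#' @inheritParams precision_topk
#' @param k top-list size; defaults to `floor(L / 5)`
#' @return mean false-positive distance in Angstrom, `NA` when the top
#'   list has no false positive
#' @export
mean_fp_distance <- function(pred, native, k = NULL, range = "long",
                             contact_threshold = 8.0) {
  d <- assessable_ranked(pred, native, range, contact_threshold,
                         predicted_only = TRUE)
  if (is.null(k)) k <- topk_count(pred$L, 1 / 5)
  top <- utils::head(d, k)
  fp <- top$dist[!top$true]
  if (length(fp) == 0L) return(NA_real_)
  mean(fp)
}

#' Restrict a map or distance matrix to a domain
#'
#' Slices the square submatrix over the segment so only pairs with both
#' residues inside the domain are assessed. Sequence separation between
#' two positions inside the domain is the same before and after slicing,
#' so range bands still reflect full-chain separations.
#'
#' @param x a [contact_map] or [distance_matrix]
#' @param segment a [domain_segment] or `c(start, end)`
#' @return object of the same class over the segment
#' @export
restrict_to_domain <- function(x, segment) {
  if (inherits(x, "contact_map")) {
    seg <- as_segment_bounds(segment, x$L)
    block <- seg[1L]:seg[2L]
    out <- contact_map(x$prob[block, block], threshold = x$threshold)
    if (!is.null(attr(x, "assessable"))) {
      attr(out, "assessable") <- attr(x, "assessable")[block, block]
    }
    out
  } else if (inherits(x, "distance_matrix")) {
    seg <- as_segment_bounds(segment, x$L)
    block <- seg[1L]:seg[2L]
    distance_matrix(x$dist[block, block], source = x$source)
  } else {
    stop("restrict_to_domain expects a contact_map or distance_matrix")
  }
}

#' Keep at most one contact per residue
#'
#' Greedy scan of a ranked pair list: a pair is kept only if neither of
#' its residues has already appeared in a kept pair. Spreads the top
#' predictions across the chain instead of piling them onto a few
#' residues.
#'
#' @param ranked data frame with columns `i` and `j`, best pair first
#'   (as from [rank_pairs()])
#' @return the filtered data frame, original order preserved
#' @export
one_per_residue_filter <- function(ranked) {
  stopifnot(is.data.frame(ranked), all(c("i", "j") %in% names(ranked)))
  if (nrow(ranked) == 0L) return(ranked)
  used <- logical(max(ranked$i, ranked$j))
  keep <- logical(nrow(ranked))
  for (r in seq_len(nrow(ranked))) {
    i <- ranked$i[r]; j <- ranked$j[r]
    if (!used[i] && !used[j]) {
      keep[r] <- TRUE
      used[i] <- TRUE
      used[j] <- TRUE
    }
  }
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full CASP-style evaluation of a predicted contact map
#'
#' Convenience wrapper computing ranked precision at several top-list
#' fractions for each requested range band, plus AUC, coverage and mean
#' false-positive distance.
#'
#' @inheritParams precision_topk
#' @param ranges character vector of band names
#' @param fractions named numeric vector of top-list fractions of L
#' @param segment optional domain restriction applied to both inputs
#' @return list with `precision` (data frame: range, fraction label, k,
#'   precision), `auc`, `coverage` and `mean_fp_distance` (one row per
#'   range)
#' @export
evaluate_contacts <- function(pred, native, ranges = c("long", "medium", "short"),
                              fractions = c("L/5" = 1 / 5, "L/2" = 1 / 2, "L" = 1),
                              segment = NULL, contact_threshold = 8.0,
                              filter_one_per_residue = FALSE) {
  if (!is.null(segment)) {
    pred <- restrict_to_domain(pred, segment)
    native <- restrict_to_domain(native, segment)
  }
  prec <- do.call(rbind, lapply(ranges, function(rg) {
    data.frame(
      range = rg,
      fraction = names(fractions),
      k = vapply(fractions, function(f) topk_count(pred$L, f), integer(1L)),
      precision = vapply(fractions, function(f) {
        precision_topk(pred, native, fraction = f, range = rg,
                       contact_threshold = contact_threshold,
                       filter_one_per_residue = filter_one_per_residue)
      }, numeric(1L)),
      row.names = NULL
    )
  }))
  per_range <- data.frame(
    range = ranges,
    auc = vapply(ranges, function(rg) {
      roc_auc(pred, native, range = rg, contact_threshold = contact_threshold)
    }, numeric(1L)),
    coverage = vapply(ranges, function(rg) {
      coverage_stat(pred, native, k = topk_count(pred$L, 1 / 5), range = rg,
                    contact_threshold = contact_threshold)
    }, numeric(1L)),
    mean_fp_distance = vapply(ranges, function(rg) {
      mean_fp_distance(pred, native, range = rg,
                       contact_threshold = contact_threshold)
    }, numeric(1L)),
    row.names = NULL
  )
  list(precision = prec, by_range = per_range)
}
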