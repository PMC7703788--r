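# Contact maps, distance matrices, RR I/O, domain integration and the
# multi-threshold distance-distribution algebra.

#' Contact probability map
#'
#' An `L x L` symmetric matrix of contact probabilities at a named
#' Cbeta-Cbeta distance threshold. The diagonal is zero and all entries
#' lie in \[0, 1\].
#'
#' @param prob square numeric matrix of probabilities
#' @param threshold distance threshold in Angstrom the map refers to,
#'   default 8.0
#' @return object of class `contact_map`
#' @export
contact_map <- function(prob, threshold = 8.0) {
  prob <- as.matrix(prob)
  if (nrow(prob) != ncol(prob)) stop("contact map must be square")
  if (anyNA(prob) || min(prob) < 0 || max(prob) > 1) {
    stop("contact probabilities must lie in [0, 1]")
  }
  if (max(abs(prob - t(prob))) > 1e-9) stop("contact map must be symmetric")
  diag(prob) <- 0
  dimnames(prob) <- NULL
  structure(list(prob = prob, L = nrow(prob), threshold = as.numeric(threshold)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> L = %d at %.1f A, %d pairs with p > 0\n",
              x$L, x$threshold, sum(x$prob[upper.tri(x$prob)] > 0)))
  invisible(x)
}

#' Inter-residue distance matrix
#'
#' Symmetric `L x L` Cbeta-Cbeta distances in Angstrom; `NA` marks a pair
#' that cannot be assessed (e.g. unresolved residues).
#'
#' @param dist square numeric matrix of distances; off-diagonal entries
#'   must be positive where present
#' @param source `"structure"` or `"synthetic"`
#' @return object of class `distance_matrix`
#' @export
distance_matrix <- function(dist, source = c("structure", "synthetic")) {
  source <- match.arg(source)
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  off <- dist[upper.tri(dist)]
  if (any(off <= 0, na.rm = TRUE)) stop("off-diagonal distances must be positive")
  ok <- !is.na(dist) & !is.na(t(dist))
  if (max(abs((dist - t(dist))[ok])) > 1e-6) stop("distance matrix must be symmetric")
  diag(dist) <- 0
  dimnames(dist) <- NULL
  structure(list(dist = dist, L = nrow(dist), source = source),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> L = %d (%s), %d unassessable pairs\n",
              x$L, x$source, sum(is.na(x$dist[upper.tri(x$dist)]))))
  invisible(x)
}

#' Distance matrix from a Cbeta coordinate table
#'
#' Builds all pairwise Euclidean distances from per-residue coordinates.
#' The table is expected to carry representative side-chain positions
#' (Cbeta; by CASP convention Calpha stands in for glycine). Residues
#' missing from the table become `NA` rows/columns.
#'
#' @param coords data frame or matrix with columns `resnum, x, y, z`
#' @param L chain length; defaults to `max(resnum)`
#' @param source passed to [distance_matrix()]
#' @return a [distance_matrix]
#' @export
distance_matrix_from_coords <- function(coords, L = NULL,
                                        source = c("structure", "synthetic")) {
  coords <- as.data.frame(coords)
  if (ncol(coords) < 4L) stop("coordinate table needs columns resnum, x, y, z")
  names(coords)[1:4] <- c("resnum", "x", "y", "z")
  resnum <- as.integer(coords$resnum)
  if (anyDuplicated(resnum)) stop("duplicate residue numbers in coordinate table")
  if (is.null(L)) L <- max(resnum)
  if (any(resnum < 1L | resnum > L)) stop("residue numbers outside [1, L]")
  d <- matrix(NA_real_, L, L)
  d[resnum, resnum] <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  diag(d) <- 0
  distance_matrix(d, source = match.arg(source))
}

#' Read a contact map from RR or square-matrix text
#'
#' The CASP RR exchange format lists one pair per line as
#' `i j d1 d2 p` (or the shorter `i j p`), with 1-based `i < j` and
#' probability `p`; header lines (`PFRMAT`, `TARGET`, `MODEL`, ...) and a
#' plain sequence line are tolerated and skipped. Pairs not listed get
#' probability 0, following the CASP habit of submitting only confident
#' pairs. The matrix format is `L` whitespace-separated rows of an
#' already-square symmetric matrix.
#'
#' @param path file path
#' @param format `"rr"` or `"matrix"`
#' @param L chain length; required for RR, checked for matrix input when
#'   given
#' @param threshold distance threshold the map refers to, default 8.0
#' @return a [contact_map]
#' @export
read_contact_map <- function(path, format = c("rr", "matrix"), L = NULL,
                             threshold = 8.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "matrix") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    if (!is.null(L) && nrow(m) != L) {
      stop(sprintf("matrix is %d x %d but L = %d was given", nrow(m), ncol(m), L))
    }
    return(contact_map(m, threshold = threshold))
  }
  if (is.null(L)) stop("L is required to read RR format")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(PFRMAT|TARGET|AUTHOR|REMARK|METHOD|MODEL|END)", lines) &
    !grepl("^[A-Za-z]+$", lines)   # bare sequence line
  prob <- matrix(0, L, L)
  for (line in lines[keep]) {
    tok <- strsplit(line, "\\s+")[[1L]]
    if (!length(tok) %in% c(3L, 5L)) {
      stop("malformed RR line (expected 'i j p' or 'i j d1 d2 p'): ", line)
    }
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) stop("non-numeric RR line: ", line)
    i <- as.integer(v[1L]); j <- as.integer(v[2L]); p <- v[length(v)]
    if (i >= j) stop(sprintf("RR requires i < j, got %d >= %d", i, j))
    if (i < 1L || j > L) stop(sprintf("RR pair (%d, %d) outside [1, %d]", i, j, L))
    if (p < 0 || p > 1) stop(sprintf("RR probability %g outside [0, 1]", p))
    prob[i, j] <- p
    prob[j, i] <- p
  }
  contact_map(prob, threshold = threshold)
}

#' Write a contact map as CASP RR text
#'
#' Emits the 5-column dialect `i j 0 <threshold> p` for every pair with
#' positive probability, probabilities printed to 6 decimal places.
#'
#' @param x a [contact_map]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_contact_map <- function(x, path) {
  stopifnot(inherits(x, "contact_map"))
  idx <- which(upper.tri(x$prob) & x$prob > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- sprintf("%d %d 0 %g %.6f", idx[, 1L], idx[, 2L],
                   x$threshold, x$prob[idx])
  writeLines(lines, path)
  invisible(path)
}

#' Integrate a domain-level map into the full-length map
#'
#' For every residue pair with both partners inside the segment, the
#' full-length probability is replaced by the domain-level one whenever
#' the latter is larger -- an elementwise maximum over the segment block.
#' Entries with either partner outside the segment are unchanged, so the
#' merge never decreases any probability.
#'
#' @param full full-length [contact_map]
#' @param domain domain-level [contact_map] whose `L` equals the segment
#'   length
#' @param segment a [domain_segment] or `c(start, end)` on the full chain
#' @return a [contact_map] of the full chain's size
#' @export
merge_domain_map <- function(full, domain, segment) {
  stopifnot(inherits(full, "contact_map"), inherits(domain, "contact_map"))
  seg <- as_segment_bounds(segment, full$L)
  len <- seg[2L] - seg[1L] + 1L
  if (domain$L != len) {
    stop(sprintf("domain map is %d x %d but segment [%d, %d] spans %d residues",
                 domain$L, domain$L, seg[1L], seg[2L], len))
  }
  if (!isTRUE(all.equal(full$threshold, domain$threshold))) {
    stop("full and domain maps are at different distance thresholds")
  }
  prob <- full$prob
  block <- seg[1L]:seg[2L]
  prob[block, block] <- pmax(prob[block, block], domain$prob)
  contact_map(prob, threshold = full$threshold)
}

#' Binary contact map from a native distance matrix
#'
#' A residue pair is in contact when its Cbeta-Cbeta distance is strictly
#' below the threshold (8.0 A by the CASP definition). Pairs with missing
#' distances get probability 0 and are flagged in the `assessable`
#' attribute so evaluation can skip them.
#'
#' @param dm a [distance_matrix]
#' @param threshold contact threshold in Angstrom, default 8.0
#' @return a binary [contact_map] with logical attribute `assessable`
#' @export
contacts_from_distance <- function(dm, threshold = 8.0) {
  stopifnot(inherits(dm, "distance_matrix"))
  assessable <- !is.na(dm$dist)
  prob <- ifelse(assessable & dm$dist < threshold, 1, 0)
  out <- contact_map(prob, threshold = threshold)
  attr(out, "assessable") <- assessable
  out
}

#' Stack of contact maps at increasing distance thresholds
#'
#' Five per-threshold maps (6, 7.5, 8, 8.5, 10 A by default) viewed
#' jointly give, for each residue pair, the predicted probability that
#' its distance falls below each threshold -- a discretised distance
#' distribution.
#'
#' @param maps list of [contact_map]s with strictly increasing thresholds
#'   and a common `L`
#' @return object of class `threshold_stack`
#' @export
threshold_stack <- function(maps) {
  if (length(maps) < 2L) stop("a threshold stack needs at least two maps")
  if (!all(vapply(maps, inherits, logical(1L), "contact_map"))) {
    stop("all stack elements must be contact_map objects")
  }
  Ls <- vapply(maps, `[[`, numeric(1L), "L")
  if (length(unique(Ls)) != 1L) stop("all maps in a stack must share L")
  th <- vapply(maps, `[[`, numeric(1L), "threshold")
  if (any(diff(th) <= 0)) stop("thresholds must be strictly increasing")
  structure(list(maps = maps, thresholds = th, L = Ls[1L]),
            class = "threshold_stack")
}

#' @export
print.threshold_stack <- function(x, ...) {
  cat(sprintf("<threshold_stack> L = %d at %s A\n",
              x$L, paste(x$thresholds, collapse = ", ")))
  invisible(x)
}

#' Default stage-one threshold set
#'
#' @return the five distance thresholds, in Angstrom, at which stage-one
#'   maps are predicted: 6, 7.5, 8, 8.5 and 10
#' @export
stage1_thresholds <- function() c(6.0, 7.5, 8.0, 8.5, 10.0)

#' Enforce monotonicity across thresholds
#'
#' Independently predicted per-threshold probabilities need not be a
#' valid cumulative distribution: P(d < 6) can exceed P(d < 7.5). The
#' projection takes, for each pair, the running maximum across increasing
#' thresholds, the smallest pointwise change that restores monotone
#' non-decreasing probabilities. Idempotent; never decreases an entry.
#'
#' @param stack a [threshold_stack]
#' @return a monotone [threshold_stack]
#' @export
monotone_project <- function(stack) {
  stopifnot(inherits(stack, "threshold_stack"))
  maps <- stack$maps
  for (k in seq_along(maps)[-1L]) {
    maps[[k]] <- contact_map(pmax(maps[[k]]$prob, maps[[k - 1L]]$prob),
                             threshold = maps[[k]]$threshold)
  }
  threshold_stack(maps)
}

is_monotone_stack <- function(stack, tol = 1e-9) {
  probs <- lapply(stack$maps, `[[`, "prob")
  for (k in seq_along(probs)[-1L]) {
    if (min(probs[[k]] - probs[[k - 1L]]) < -tol) return(FALSE)
  }
  TRUE
}

#' Per-pair distance distribution over threshold intervals
#'
#' Converts a monotone threshold stack (a discrete CDF at each pair) into
#' probabilities of the distance falling in each interval between
#' consecutive thresholds, plus the open tail beyond the largest
#' threshold. For the default thresholds the intervals are (0, 6\],
#' (6, 7.5\], (7.5, 8\], (8, 8.5\], (8.5, 10\] and (10, Inf). Each
#' pair's interval probabilities are non-negative and sum to 1, and their
#' cumulative sum recovers the CDF.
#'
#' @param stack a monotone [threshold_stack] (apply [monotone_project()]
#'   first)
#' @return numeric array of dim `c(L, L, n_intervals)` with dimnames on
#'   the third margin labelling the intervals
#' @export
interval_distribution <- function(stack) {
  stopifnot(inherits(stack, "threshold_stack"))
  if (!is_monotone_stack(stack)) {
    stop("stack is not monotone across thresholds; apply monotone_project() first")
  }
  probs <- lapply(stack$maps, `[[`, "prob")
  n <- length(probs)
  L <- stack$L
  out <- array(0, dim = c(L, L, n + 1L))
  out[, , 1L] <- probs[[1L]]
  for (k in seq_len(n - 1L)) out[, , k + 1L] <- probs[[k + 1L]] - probs[[k]]
  out[, , n + 1L] <- 1 - probs[[n]]
  lab <- c(0, stack$thresholds, Inf)
  dimnames(out) <- list(NULL, NULL,
                        sprintf("(%g,%g]", lab[-length(lab)], lab[-1L]))
  out
}
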