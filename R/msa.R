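# MSA container, alignment I/O, identity weighting and Neff.

GAP_CHARS <- c("-", ".")

#' Construct a query-anchored multiple sequence alignment
#'
#' An `msa` holds a query sequence and the aligned homolog rows over the
#' same `L` columns. The query itself is always row 1, so every alignment
#' has at least one row. Row characters are upper-cased on construction;
#' `-` and `.` are treated as gap characters throughout the package.
#'
#' @param rows character vector of aligned sequences, all of equal length.
#'   Row 1 must be the query and may not contain gaps.
#' @param row_ids character vector of row identifiers, same length as
#'   `rows`. Defaults to `seq_1 ... seq_N`.
#' @return An object of class `msa` with elements `query_id`, `query_seq`,
#'   `rows`, `row_ids`, and attributes `N` (rows) and `L` (columns).
#' @examples
#' aln <- msa(c("ACDEFG", "AC--FG", "ACDEFG"))
#' msa_dim(aln)
#' @export
msa <- function(rows, row_ids = NULL) {
  if (length(rows) < 1L) stop("an MSA needs at least one row (the query)")
  rows <- toupper(as.character(rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("row %d has length %d, expected %d", bad, widths[bad], widths[1L]))
  }
  if (widths[1L] < 1L) stop("alignment has zero columns")
  if (is.null(row_ids)) row_ids <- paste0("seq_", seq_along(rows))
  if (length(row_ids) != length(rows)) stop("row_ids length must match rows")
  if (grepl("[-.]", rows[1L])) stop("the query row (row 1) must not contain gaps")
  out <- list(
    query_id  = row_ids[1L],
    query_seq = rows[1L],
    rows      = rows,
    row_ids   = as.character(row_ids)
  )
  structure(out, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  d <- msa_dim(x)
  cat(sprintf("<msa> query '%s': %d sequences x %d columns\n",
              x$query_id, d[["N"]], d[["L"]]))
  invisible(x)
}

#' Alignment dimensions
#'
#' @param x an `msa`
#' @return named integer vector with `N` (number of rows, query included)
#'   and `L` (number of columns = query length).
#' @export
msa_dim <- function(x) {
  stopifnot(inherits(x, "msa"))
  c(N = length(x$rows), L = nchar(x$rows[1L]))
}

# rows -> L x N character matrix (columns are alignment rows)
msa_char_matrix <- function(x) {
  vapply(strsplit(x$rows, "", fixed = TRUE), identity,
         character(nchar(x$rows[1L])))
}

#' Read an alignment from FASTA or A3M
#'
#' Aligned FASTA requires all records to have identical length. In the A3M
#' dialect lowercase letters mark insertion states relative to the query;
#' they are removed (together with `.` placeholders) to restore
#' query-anchored columns before the equal-length check.
#'
#' @param path file path
#' @param dialect `"aligned-fasta"` or `"a3m"`
#' @return an [msa] with the first record as the query
#' @export
read_msa <- function(path, dialect = c("aligned-fasta", "a3m")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not FASTA: first non-blank line must start with '>'")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1L), collapse = "")
  if (length(seqs) != length(ids)) stop("record with header but no sequence in ", path)
  if (dialect == "a3m") {
    # lowercase = insertion relative to the query; '.' pads some writers emit
    seqs <- gsub("[a-z.]", "", seqs)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("alignment rows disagree in length: row %d ('%s') has %d columns, expected %d",
                 bad, ids[bad], widths[bad], widths[1L]))
  }
  msa(unname(seqs), row_ids = ids)
}

#' Write an alignment as aligned FASTA
#'
#' @param x an [msa]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  writeLines(rbind(paste0(">", x$row_ids), x$rows), path)
  invisible(path)
}

#' Pairwise sequence identity between two aligned rows
#'
#' Identity is the number of columns where both rows carry the same
#' residue, divided by a denominator chosen by `denominator`:
#' `"nongap_union"` (default) counts columns where at least one row is
#' non-gap, so a gap aligned against a residue counts as a mismatch and
#' gap-vs-gap columns are ignored; `"alignment_length"` divides by the
#' full number of columns. `X` is an unknown residue and matches nothing,
#' not even another `X`. Comparison is case-insensitive.
#'
#' @param a,b aligned rows (strings of equal length)
#' @param denominator `"nongap_union"` or `"alignment_length"`
#' @return identity fraction in \[0, 1\]
#' @examples
#' pairwise_identity("ACDE", "AC--")  # 0.5
#' pairwise_identity("A-DE", "A-DF")  # 2/3
#' @export
pairwise_identity <- function(a, b, denominator = c("nongap_union", "alignment_length")) {
  denominator <- match.arg(denominator)
  if (nchar(a) != nchar(b)) stop("rows have different lengths")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  gap_a <- ca %in% GAP_CHARS
  gap_b <- cb %in% GAP_CHARS
  match <- !gap_a & !gap_b & ca == cb & ca != "X"
  denom <- if (denominator == "nongap_union") sum(!(gap_a & gap_b)) else length(ca)
  if (denom == 0L) stop("identity undefined: both rows are entirely gaps")
  sum(match) / denom
}

#' Redundancy weights for every alignment row
#'
#' Row `i` gets weight equal to the number of rows (itself included) whose
#' pairwise identity with it is at least `threshold`. Each off-diagonal
#' contribution is binary, so the weight is a neighbour count and is
#' always at least 1.
#'
#' @param x an [msa]
#' @param threshold identity threshold, default 0.62
#' @param denominator identity denominator mode, see [pairwise_identity()]
#' @return object of class `sequence_weights`: integer vector of weights
#'   with the threshold stored as attribute `threshold`
#' @export
sequence_weights <- function(x, threshold = 0.62,
                             denominator = c("nongap_union", "alignment_length")) {
  stopifnot(inherits(x, "msa"))
  denominator <- match.arg(denominator)
  m <- msa_char_matrix(x)             # L x N
  n <- ncol(m)
  gap <- m == "-" | m == "."
  resid <- !gap & m != "X"            # columns eligible to match
  w <- rep(1L, n)
  if (n > 1L) {
    full_len <- denominator == "alignment_length"
    for (i in seq_len(n - 1L)) {
      mi <- m[, i]; gi <- gap[, i]; ri <- resid[, i]
      for (j in (i + 1L):n) {
        hits <- sum(ri & resid[, j] & mi == m[, j])
        den <- if (full_len) nrow(m) else sum(!(gi & gap[, j]))
        if (den == 0L) stop("identity undefined between all-gap rows ", i, " and ", j)
        if (hits / den >= threshold) {
          w[i] <- w[i] + 1L
          w[j] <- w[j] + 1L
        }
      }
    }
  }
  structure(w, threshold = threshold, class = "sequence_weights")
}

#' Effective number of sequences (Neff)
#'
#' Neff summarises alignment depth after discounting redundancy: each row
#' contributes the reciprocal of its weight, where the weight counts rows
#' within `threshold` identity of it (itself included),
#' \deqn{N_{eff} = \sum_{i=1}^{N} 1 / weight_i.}
#' An alignment of N identical rows has Neff = 1; N mutually dissimilar
#' rows give Neff = N; B mutually dissimilar blocks of identical rows give
#' Neff = B.
#'
#' @inheritParams sequence_weights
#' @return Neff, a real number in \[1, N\]
#' @examples
#' compute_neff(msa(rep("ACDEFGHIKL", 5))) # 1
#' @export
compute_neff <- function(x, threshold = 0.62,
                         denominator = c("nongap_union", "alignment_length")) {
  w <- sequence_weights(x, threshold = threshold, denominator = denominator)
  sum(1 / as.numeric(w))
}

#' Extract the alignment of a domain from a full-length alignment
#'
#' Slices the segment's columns out of every row. Rows left entirely
#' gapped inside the segment carry no signal for the domain and are
#' dropped; the query row never contains gaps so it is always retained.
#'
#' @param x an [msa]
#' @param segment a [domain_segment] or numeric `c(start, end)`
#'   (1-based, inclusive)
#' @return an [msa] over the segment's columns
#' @export
extract_domain_msa <- function(x, segment) {
  stopifnot(inherits(x, "msa"))
  seg <- as_segment_bounds(segment, nchar(x$rows[1L]))
  sliced <- substr(x$rows, seg[1L], seg[2L])
  all_gap <- !grepl("[^-.]", sliced)
  if (all_gap[1L]) stop("query row is all gaps in the segment (invalid MSA)")
  msa(sliced[!all_gap], row_ids = x$row_ids[!all_gap])
}

#' Neff of a domain within a full-length alignment
#'
#' Extracts the domain columns with [extract_domain_msa()], then applies
#' [compute_neff()] to the sliced alignment.
#'
#' @inheritParams extract_domain_msa
#' @inheritParams sequence_weights
#' @return domain-level Neff
#' @export
domain_neff <- function(x, segment, threshold = 0.62,
                        denominator = c("nongap_union", "alignment_length")) {
  compute_neff(extract_domain_msa(x, segment),
               threshold = threshold, denominator = denominator)
}

# Accept a domain_segment or a length-2 numeric; validate against L.
as_segment_bounds <- function(segment, L) {
  if (inherits(segment, "domain_segment")) {
    seg <- c(segment$start, segment$end)
  } else {
    seg <- as.integer(segment)
    if (length(seg) != 2L || anyNA(seg)) stop("segment must be c(start, end)")
  }
  if (seg[1L] < 1L || seg[2L] > L || seg[1L] > seg[2L]) {
    stop(sprintf("segment [%d, %d] out of bounds for L = %d", seg[1L], seg[2L], L))
  }
  seg
}
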