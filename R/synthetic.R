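# Synthetic fixtures: MSAs with engineered redundancy blocks and coverage
# dips, toy 3D chains, and noisy predicted maps derived from a truth map.
# Every generator is a pure function of its recipe: the seed is mandatory
# and the caller's RNG state is left untouched.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Run expr under a local RNG seeded with `seed`, restoring global state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory for synthetic generators")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Recipe for a synthetic MSA
#'
#' Describes an alignment as a set of redundancy blocks plus engineered
#' coverage dips. Each block is a family of rows copied from a block
#' consensus with a per-position mutation rate; with mutation rate 0 the
#' block collapses to one effective sequence. When the mutation rate is
#' 0, block consensi are drawn from disjoint sub-alphabets so cross-block
#' identity is 0 and the alignment's Neff equals the number of blocks.
#' A coverage dip gaps a stated fraction of rows over a column interval,
#' carving the below-median coverage runs the domain parser detects. The
#' query (row 1) is the first row of the first block and is never gapped.
#'
#' @param L alignment length (columns)
#' @param blocks data frame with columns `size` (rows per block) and
#'   `mutation` (per-position mutation rate in \[0, 1\])
#' @param dips optional data frame with columns `start`, `end`, `frac`:
#'   in columns `start:end`, `round(frac * N)` non-query rows are gapped
#' @param seed mandatory RNG seed
#' @return object of class `msa_recipe`
#' @export
msa_recipe <- function(L, blocks, dips = NULL, seed) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  blocks <- as.data.frame(blocks)
  if (!all(c("size", "mutation") %in% names(blocks))) {
    stop("blocks needs columns size and mutation")
  }
  if (any(blocks$size < 1L)) stop("block sizes must be >= 1")
  if (any(blocks$mutation < 0 | blocks$mutation > 1)) {
    stop("mutation rates must lie in [0, 1]")
  }
  if (!is.null(dips)) {
    dips <- as.data.frame(dips)
    if (!all(c("start", "end", "frac") %in% names(dips))) {
      stop("dips needs columns start, end, frac")
    }
    if (any(dips$start < 1L | dips$end > L | dips$start > dips$end)) {
      stop("dip intervals must lie within [1, L]")
    }
    if (any(dips$frac < 0 | dips$frac > 1)) stop("dip fractions must lie in [0, 1]")
  }
  structure(list(L = L, blocks = blocks, dips = dips, seed = as.integer(seed)),
            class = "msa_recipe")
}

#' Generate a synthetic MSA from a recipe
#'
#' @param recipe an [msa_recipe]
#' @return an [msa]; deterministic given the recipe's seed
#' @export
gen_msa <- function(recipe) {
  stopifnot(inherits(recipe, "msa_recipe"))
  with_local_seed(recipe$seed, {
    L <- recipe$L
    nb <- nrow(recipe$blocks)
    # Disjoint sub-alphabets guarantee cross-block identity 0 for
    # mutation-free blocks; 20 letters cap the number of blocks.
    if (nb > length(AA20)) stop("at most ", length(AA20), " blocks supported")
    chunk <- split(AA20, rep(seq_len(nb), length.out = length(AA20)))
    rows <- character(0)
    for (b in seq_len(nb)) {
      consensus <- sample(chunk[[b]], L, replace = TRUE)
      size <- recipe$blocks$size[b]
      mu <- recipe$blocks$mutation[b]
      for (r in seq_len(size)) {
        row <- consensus
        if (mu > 0) {
          flip <- stats::runif(L) < mu
          row[flip] <- sample(AA20, sum(flip), replace = TRUE)
        }
        rows <- c(rows, paste(row, collapse = ""))
      }
    }
    n <- length(rows)
    if (!is.null(recipe$dips)) {
      row_chars <- strsplit(rows, "", fixed = TRUE)
      for (k in seq_len(nrow(recipe$dips))) {
        d <- recipe$dips[k, ]
        n_gap <- min(round(d$frac * n), n - 1L)   # query is never gapped
        victims <- sample(2:n, n_gap)
        for (v in victims) row_chars[[v]][d$start:d$end] <- "-"
      }
      rows <- vapply(row_chars, paste, character(1L), collapse = "")
    }
    msa(rows, row_ids = c("query", paste0("hom_", seq_len(n - 1L))))
  })
}

#' Recipe for a toy 3D chain
#'
#' @param L number of residues
#' @param mode `"helix-like"` (ideal helical trace, constant geometry) or
#'   `"random-walk"` (self-avoiding walk with fixed step)
#' @param step consecutive-residue distance in Angstrom, default 3.8
#'   (the Calpha-Calpha virtual bond)
#' @param clash minimum allowed distance between non-adjacent residues,
#'   default 3.0; must be below `step`
#' @param confine radius in Angstrom of a sphere (centred at the first
#'   residue) the random walk must stay inside, emulating the packing of
#'   a globular fold so that medium- and long-range contacts arise.
#'   Default `3.8 * L^(1/3)`, roughly globular protein density; `Inf`
#'   disables confinement. Ignored in helix-like mode.
#' @param seed mandatory RNG seed
#' @return object of class `chain_recipe`
#' @export
chain_recipe <- function(L, mode = c("helix-like", "random-walk"),
                         step = 3.8, clash = 3.0, confine = NULL, seed) {
  mode <- match.arg(mode)
  L <- as.integer(L)
  if (L < 2L) stop("a chain needs at least 2 residues")
  if (clash >= step) stop("clash distance must be smaller than the step length")
  if (is.null(confine)) confine <- 3.8 * L^(1 / 3)
  if (confine <= step) stop("confinement radius must exceed the step length")
  structure(list(L = L, mode = mode, step = as.numeric(step),
                 clash = as.numeric(clash), confine = as.numeric(confine),
                 seed = as.integer(seed)),
            class = "chain_recipe")
}

#' Generate a toy 3D chain and its distance matrix
#'
#' The helix-like mode traces an ideal helix (2.3 A radius, 100 degree
#' turn per residue, rise chosen to match `step`), giving constant
#' consecutive-residue distances and a dense short-range contact
#' pattern. The random-walk mode grows a self-avoiding walk: each step
#' has length `step` in a uniformly random direction and is rejected if
#' any non-adjacent pair comes closer than `clash`.
#'
#' @param recipe a [chain_recipe]
#' @param max_tries rejection-sampling budget per residue (random walk)
#' @return list with `coords` (`L x 3` matrix) and `dm` (a
#'   [distance_matrix] with source `"synthetic"`); deterministic given
#'   the seed
#' @export
gen_chain <- function(recipe, max_tries = 200L) {
  stopifnot(inherits(recipe, "chain_recipe"))
  with_local_seed(recipe$seed, {
    L <- recipe$L
    if (recipe$mode == "helix-like") {
      radius <- 2.3
      turn <- 100 * pi / 180
      # chord in the xy-plane per residue; rise fills out the step length
      chord <- 2 * radius * sin(turn / 2)
      if (chord >= recipe$step) stop("step too short for the helical geometry")
      rise <- sqrt(recipe$step^2 - chord^2)
      t <- (seq_len(L) - 1L)
      coords <- cbind(radius * cos(t * turn), radius * sin(t * turn), t * rise)
    } else {
      coords <- matrix(NA_real_, L, 3L)
      coords[1L, ] <- 0
      for (r in 2L:L) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          # uniform direction on the sphere
          v <- stats::rnorm(3L)
          v <- v / sqrt(sum(v^2))
          cand <- coords[r - 1L, ] + recipe$step * v
          if (sqrt(sum(cand^2)) > recipe$confine) next
          if (r > 2L) {
            d2 <- rowSums((coords[seq_len(r - 2L), , drop = FALSE] -
                             matrix(cand, r - 2L, 3L, byrow = TRUE))^2)
            if (min(d2) < recipe$clash^2) next
          }
          coords[r, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) stop("self-avoiding walk stuck at residue ", r,
                          "; loosen clash or increase max_tries")
      }
    }
    dimnames(coords) <- NULL
    dm <- distance_matrix(as.matrix(stats::dist(coords)), source = "synthetic")
    list(coords = coords, dm = dm)
  })
}

#' Generate a noisy predicted map from a truth map
#'
#' Emulates a probabilistic predictor: each pair's score is
#' `clip(tp_signal * truth + e, 0, 1)` with independent Gaussian noise
#' `e ~ N(0, noise_sd)` on the upper triangle, then symmetrised. Larger
#' `tp_signal / noise_sd` separates true from false pairs more cleanly
#' and raises the expected AUC; `tp_signal = 0` gives scores independent
#' of the truth (AUC about 0.5).
#'
#' @param truth a binary [contact_map]
#' @param tp_signal score offset added to true contacts
#' @param noise_sd standard deviation of the Gaussian noise
#' @param seed mandatory RNG seed
#' @return a [contact_map] of noisy scores at the truth's threshold
#' @export
gen_predictions <- function(truth, tp_signal = 0.8, noise_sd = 0.2, seed) {
  stopifnot(inherits(truth, "contact_map"))
  with_local_seed(seed, {
    L <- truth$L
    up <- upper.tri(truth$prob)
    score <- matrix(0, L, L)
    score[up] <- pmin(pmax(tp_signal * truth$prob[up] +
                             stats::rnorm(sum(up), 0, noise_sd), 0), 1)
    score <- score + t(score)
    contact_map(score, threshold = truth$threshold)
  })
}
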