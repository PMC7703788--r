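# Independent brute-force oracles and fixture builders. These
# deliberately re-derive quantities with the most literal code possible,
# sharing nothing with the package implementation.

# Literal per-character identity: matches / columns-with-any-residue.
oracle_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  hits <- 0L
  denom <- 0L
  for (p in seq_along(ca)) {
    ga <- ca[p] %in% c("-", ".")
    gb <- cb[p] %in% c("-", ".")
    if (ga && gb) next
    denom <- denom + 1L
    if (!ga && !gb && ca[p] == cb[p] && ca[p] != "X") hits <- hits + 1L
  }
  hits / denom
}

# O(N^2) double loop over all ordered pairs.
oracle_weights <- function(rows, threshold = 0.62) {
  n <- length(rows)
  w <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (oracle_identity(rows[i], rows[j]) >= threshold) w[i] <- w[i] + 1L
    }
  }
  w
}

oracle_neff <- function(rows, threshold = 0.62) sum(1 / oracle_weights(rows, threshold))

# Enumerate every maximal run of positions strictly below the cutoff by
# scanning each candidate start position.
oracle_runs <- function(counts, cutoff, min_len) {
  below <- counts < cutoff
  runs <- list()
  p <- 1L
  while (p <= length(counts)) {
    if (below[p] && (p == 1L || !below[p - 1L])) {
      q <- p
      while (q < length(counts) && below[q + 1L]) q <- q + 1L
      if (q - p + 1L >= min_len) runs[[length(runs) + 1L]] <- c(p, q)
      p <- q + 1L
    } else {
      p <- p + 1L
    }
  }
  runs
}

# Random gappy alignment rows (query row gap-free).
random_msa_rows <- function(n, L, gap_prob = 0.15) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rows <- character(n)
  rows[1] <- paste(sample(aa, L, replace = TRUE), collapse = "")
  base <- strsplit(rows[1], "")[[1]]
  for (r in seq_len(n)[-1]) {
    row <- ifelse(runif(L) < 0.5, base, sample(aa, L, replace = TRUE))
    row[runif(L) < gap_prob] <- "-"
    rows[r] <- paste(row, collapse = "")
  }
  rows
}

# Small deterministic native + prediction pair for evaluation tests.
eval_fixture <- function(L = 60, seed = 11, tp_signal = 0.8, noise_sd = 0.2) {
  chain <- gen_chain(chain_recipe(L, "random-walk", seed = seed))
  truth <- contacts_from_distance(chain$dm)
  pred <- gen_predictions(truth, tp_signal = tp_signal, noise_sd = noise_sd,
                          seed = seed + 1000L)
  list(dm = chain$dm, truth = truth, pred = pred)
}

random_contact_map <- function(L, threshold = 8.0) {
  m <- matrix(0, L, L)
  up <- upper.tri(m)
  m[up] <- runif(sum(up))
  m <- m + t(m)
  diag(m) <- 0
  contact_map(m, threshold = threshold)
}
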