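# CASP-convention scoring: ranking, precision, coverage, AUC, mean
# false-positive distance, domain restriction, one-per-residue filter.

test_that("separation bands follow the CASP definition", {
  long <- range_class("long")
  expect_equal(long$min_sep, 24L)
  med <- range_class("medium")
  expect_equal(c(med$min_sep, med$max_sep), c(12L, 23L))
  sh <- range_class("short")
  expect_equal(c(sh$min_sep, sh$max_sep), c(6L, 11L))
})

test_that("pair ranking sorts by probability with a deterministic tie-break", {
  p <- matrix(0, 40, 40)
  p[1, 30] <- p[30, 1] <- 0.9
  p[2, 35] <- p[35, 2] <- 0.5
  p[3, 30] <- p[30, 3] <- 0.5    # same prob as (2,35), smaller separation
  m <- contact_map(p)
  r <- rank_pairs(m, "long")
  expect_equal(r$i[1:3], c(1, 2, 3))
  expect_equal(r$j[1:3], c(30, 35, 30))
  # ties broken by separation desc then i asc: (2,35) sep 33 before (3,30) sep 27
  expect_true(all(diff(r$prob) <= 0))

  # order equals a brute-force sort oracle on a random map
  set.seed(4)
  m <- random_contact_map(30)
  r <- rank_pairs(m, "medium")
  idx <- which(upper.tri(m$prob), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  keep <- sep >= 12 & sep <= 23
  oracle <- data.frame(i = idx[keep, 1], j = idx[keep, 2], sep = sep[keep],
                       prob = m$prob[idx[keep, , drop = FALSE]])
  oracle <- oracle[order(-oracle$prob, -oracle$sep, oracle$i, oracle$j), ]
  expect_equal(r$i, oracle$i)
  expect_equal(r$j, oracle$j)
})

test_that("a perfect prediction scores 100% precision at every fraction and range", {
  for (seed in c(3, 9, 27)) {
    fix <- eval_fixture(L = 60, seed = seed, noise_sd = 0)
    truth <- fix$truth
    for (rg in c("long", "medium", "short")) {
      for (f in c(1 / 5, 1 / 2, 1, 2)) {
        p <- precision_topk(truth, fix$dm, fraction = f, range = rg)
        if (!is.na(p)) expect_equal(p, 100)
      }
    }
  }
})

test_that("hand-placed top-4 list with 3 true and 1 false gives 75%", {
  d <- matrix(30, 10, 10); diag(d) <- 0
  # true long-range contacts at native distance 5
  for (pr in list(c(1, 8), c(2, 9), c(3, 10))) {
    d[pr[1], pr[2]] <- d[pr[2], pr[1]] <- 5
  }
  dm <- distance_matrix(d, source = "synthetic")
  p <- matrix(0, 10, 10)
  probs <- list(c(1, 8, 0.9), c(2, 9, 0.8), c(3, 10, 0.7), c(1, 9, 0.6))
  for (x in probs) p[x[1], x[2]] <- p[x[2], x[1]] <- x[3]
  pred <- contact_map(p)
  # short range here means separation 6-11: all four pairs qualify
  expect_equal(precision_topk(pred, dm, k = 4, range = "short"), 75)
})

test_that("precision is invariant under strictly monotone score transforms", {
  fix <- eval_fixture(L = 50, seed = 5)
  for (rg in c("long", "short")) {
    base <- precision_topk(fix$pred, fix$dm, 1 / 5, rg)
    sq <- contact_map(fix$pred$prob^2, threshold = 8)
    expect_equal(precision_topk(sq, fix$dm, 1 / 5, rg), base)
  }
})

test_that("unassessable native pairs are skipped and replaced by next-ranked", {
  fix <- eval_fixture(L = 50, seed = 6, noise_sd = 0)
  dm <- fix$dm
  # knock out the native distances of the two top-ranked long-range pairs
  r <- rank_pairs(fix$truth, "long")
  d2 <- dm$dist
  for (k in 1:2) d2[r$i[k], r$j[k]] <- d2[r$j[k], r$i[k]] <- NA
  dm2 <- distance_matrix(d2, source = "synthetic")
  p <- precision_topk(fix$truth, dm2, k = 5, range = "long")
  expect_equal(p, 100)   # still perfect: NAs skipped, not counted wrong
})

test_that("coverage is TP over native contacts and non-decreasing in k", {
  fix <- eval_fixture(L = 60, seed = 7, noise_sd = 0)
  n_native <- sum(rank_pairs(fix$truth, "long")$prob > 0)
  expect_gte(n_native, 3)
  expect_equal(coverage_stat(fix$truth, fix$dm, k = n_native, range = "long"), 100)
  expect_equal(coverage_stat(fix$truth, fix$dm, k = 0, range = "long"), 0)
  noisy <- eval_fixture(L = 60, seed = 7, noise_sd = 0.3)$pred
  prev <- -1
  for (k in c(1, 5, 10, 20, 50, 200)) {
    cov <- coverage_stat(noisy, fix$dm, k = k, range = "long")
    expect_gte(cov, prev)
    prev <- cov
  }
})

test_that("AUC matches the Mann-Whitney rank statistic and pROC", {
  set.seed(12)
  for (rep in 1:10) {
    fix <- eval_fixture(L = 40, seed = rep, noise_sd = 0.35)
    d <- rank_pairs(fix$pred, "long")
    d$true <- fix$dm$dist[cbind(d$i, d$j)] < 8
    expect_gt(sum(d$true), 0)
    expect_gt(sum(!d$true), 0)
    got <- roc_auc(fix$pred, fix$dm, "long")
    # Wilcoxon rank-sum oracle
    w <- wilcox.test(d$prob[d$true], d$prob[!d$true], exact = FALSE)
    expect_equal(got, unname(w$statistic) / (sum(d$true) * sum(!d$true)))
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(got,
                   as.numeric(pROC::auc(pROC::roc(d$true, d$prob, quiet = TRUE))))
    }
  }
})

test_that("AUC is 1 for perfect separation and ~0.5 for label-free scores", {
  fix <- eval_fixture(L = 60, seed = 14, noise_sd = 0)
  expect_equal(roc_auc(fix$truth, fix$dm, "long"), 1)
  # average over repeated label-independent scores
  aucs <- vapply(1:50, function(s) {
    pr <- gen_predictions(fix$truth, tp_signal = 0, noise_sd = 0.3,
                          seed = 5000 + s)
    roc_auc(pr, fix$dm, "long")
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.05)
  # degenerate labels give NA
  far <- distance_matrix(matrix(50, 30, 30) - diag(50, 30), source = "synthetic")
  expect_true(is.na(roc_auc(random_contact_map(30), far, "long")))
})

test_that("mean false-positive distance averages native distances of errors", {
  d <- matrix(30, 40, 40); diag(d) <- 0
  d[1, 30] <- d[30, 1] <- 5       # true contact
  d[2, 31] <- d[31, 2] <- 14.1    # a false positive at 14.1 A
  dm <- distance_matrix(d, source = "synthetic")
  p <- matrix(0, 40, 40)
  p[1, 30] <- p[30, 1] <- 0.9
  p[2, 31] <- p[31, 2] <- 0.8
  pred <- contact_map(p)
  expect_equal(mean_fp_distance(pred, dm, k = 2, range = "long"), 14.1)
  # all-true top list has no FP
  expect_true(is.na(mean_fp_distance(pred, dm, k = 1, range = "long")))
  # brute-force check on a noisy fixture
  fix <- eval_fixture(L = 50, seed = 18, noise_sd = 0.4)
  k <- 10
  r <- rank_pairs(fix$pred, "long")
  r <- r[r$prob > 0, ]
  r$dist <- fix$dm$dist[cbind(r$i, r$j)]
  top <- head(r[!is.na(r$dist), ], k)
  fp <- top$dist[top$dist >= 8]
  expect_gt(length(fp), 0)
  expect_equal(mean_fp_distance(fix$pred, fix$dm, k = k, range = "long"),
               mean(fp))
})

test_that("domain restriction slices both map and native consistently", {
  fix <- eval_fixture(L = 60, seed = 20, noise_sd = 0)
  # full-length segment is the identity
  same <- restrict_to_domain(fix$pred, c(1, 60))
  expect_equal(same$prob, fix$pred$prob)
  sub_pred <- restrict_to_domain(fix$pred, c(11, 50))
  sub_dm <- restrict_to_domain(fix$dm, c(11, 50))
  expect_equal(sub_pred$L, 40)
  expect_equal(sub_pred$prob[1, 5], fix$pred$prob[11, 15])
  expect_equal(sub_dm$dist[1, 5], fix$dm$dist[11, 15])
  # perfect prediction stays perfect under restriction
  expect_equal(precision_topk(restrict_to_domain(fix$truth, c(11, 50)), sub_dm,
                              fraction = 1, range = "short"), 100)
  expect_error(restrict_to_domain(fix$pred, c(50, 70)), "out of bounds")
})

test_that("one-per-residue filtering keeps the greedy maximal list", {
  ranked <- data.frame(i = c(1, 1, 2, 5), j = c(30, 40, 31, 6),
                       prob = c(0.9, 0.8, 0.7, 0.6))
  kept <- one_per_residue_filter(ranked)
  expect_equal(kept$i, c(1, 2, 5))
  expect_equal(kept$j, c(30, 31, 6))     # (1,40) dropped: residue 1 used
  # disjoint pairs pass through unchanged
  disjoint <- data.frame(i = c(1, 3, 5), j = c(20, 22, 24), prob = c(0.9, 0.8, 0.7))
  expect_equal(one_per_residue_filter(disjoint), disjoint)
  # greedy oracle on a random ranked list
  set.seed(9)
  r <- rank_pairs(random_contact_map(30), "long")
  kept <- one_per_residue_filter(r)
  seen <- integer(0)
  want <- logical(nrow(r))
  for (k in seq_len(nrow(r))) {
    if (!(r$i[k] %in% seen) && !(r$j[k] %in% seen)) {
      want[k] <- TRUE
      seen <- c(seen, r$i[k], r$j[k])
    }
  }
  expect_equal(kept$i, r$i[want])
  expect_equal(kept$j, r$j[want])
})

test_that("evaluate_contacts assembles the per-range summary", {
  fix <- eval_fixture(L = 60, seed = 23, noise_sd = 0.25)
  res <- evaluate_contacts(fix$pred, fix$dm)
  expect_equal(nrow(res$precision), 9)    # 3 ranges x 3 fractions
  expect_true(all(res$precision$precision >= 0 & res$precision$precision <= 100,
                  na.rm = TRUE))
  expect_true(all(res$by_range$auc >= 0 & res$by_range$auc <= 1, na.rm = TRUE))
  expect_equal(res$precision$k[res$precision$fraction == "L/5"][1], 12L)
  # domain-restricted evaluation runs on the sliced pair set
  res_dom <- evaluate_contacts(fix$pred, fix$dm, segment = c(11, 50))
  expect_equal(res_dom$precision$k[res_dom$precision$fraction == "L"][1], 40L)
})
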