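test_that("roc_auc handles extremes, the null, and matches pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  set.seed(1)
  big <- runif(4000)
  expect_equal(roc_auc(big, rbinom(4000, 1, 0.5)), 0.5, tolerance = 0.03)
  for (i in 1:40) {
    n <- 50L
    scores <- if (i %% 2 == 0) round(runif(n), 1) else runif(n)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    expect_equal(roc_auc(scores, y), oracle_auc(scores, y), tolerance = 1e-12)
    # complement symmetry under score negation
    expect_equal(roc_auc(scores, y) + roc_auc(-scores, y), 1,
                 tolerance = 1e-12)
    # order permutation invariance
    p <- sample.int(n)
    expect_equal(roc_auc(scores[p], y[p]), roc_auc(scores, y))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("threshold metrics reproduce the confusion table and AUPR oracle", {
  # TP=9 FP=1 FN=1 TN=9 at threshold 0.5
  scores <- c(rep(0.9, 9), 0.1, rep(0.8, 1), rep(0.2, 9))
  y <- c(rep(1, 10), rep(0, 10))
  pm <- pr_metrics(scores, y, 0.5)
  expect_equal(pm$precision, 0.9)
  expect_equal(pm$recall, 0.9)
  expect_equal(pm$acc, 0.9)
  # everything called positive -> recall 1
  pm2 <- pr_metrics(scores, y, 0)
  expect_equal(pm2$recall, 1)
  # no predicted positives -> precision 0 with warning
  expect_warning(pm3 <- pr_metrics(scores, y, 1.5), "precision")
  expect_equal(pm3$precision, 0)
  set.seed(2)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    scores <- if (i %% 2 == 0) round(runif(n), 1) else runif(n)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    pm <- pr_metrics(scores, y, 0.5)
    expect_equal(pm$aupr, oracle_ap(scores, y), tolerance = 1e-12)
  }
})

test_that("DeLong's test is exact for identical scores and agrees with pROC", {
  set.seed(3)
  y <- rbinom(100, 1, 0.5)
  s <- runif(100)
  same <- delong_test(s, s, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  skip_if_not_installed("pROC")
  for (i in 1:10) {
    n <- 80L
    y <- c(rep(1, 40), rep(0, 40))
    a <- runif(n) + 0.4 * y
    b <- runif(n) + 0.2 * y
    got <- delong_test(a, b, y)
    # pin the comparison direction: roc()'s "auto" flips curves with AUC < 0.5
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                          pROC::roc(y, b, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-8)
    expect_equal(abs(got$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
    expect_equal(got$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney comparison matches the known exact case and enumeration", {
  res <- compare_strategies(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  # identical groups: maximal p
  res_same <- compare_strategies(c(1, 2, 3), c(1, 2, 3))
  expect_gte(res_same$p, 0.99)
  # full-enumeration oracle on small tie-free groups
  set.seed(4)
  for (i in 1:8) {
    a <- runif(sample(3:5, 1))
    b <- runif(sample(3:5, 1))
    expect_equal(compare_strategies(a, b)$p, oracle_mw_exact_p(a, b),
                 tolerance = 1e-12)
  }
  # rank-based: invariant to monotone transforms
  a <- c(0.61, 0.64, 0.70, 0.72)
  b <- c(0.55, 0.59, 0.63, 0.69)
  expect_equal(compare_strategies(a, b)$p,
               compare_strategies(exp(a), exp(b))$p)
  expect_error(compare_strategies(numeric(0), 1), "non-empty")
})

test_that("repeated re-partitioned evaluation is seeded and reduces correctly", {
  d <- fx_clf_data()
  train_fn <- function(train, val, seed) {
    structure(list(threshold = 0.5), class = "stub_fit")
  }
  score_fn <- function(fit, w) w$kin_ipd[, 11] / max(w$kin_ipd[, 11])
  plan1 <- bootstrap_plan(n_rounds = 1L, seed = 5L)
  r1 <- bootstrap_evaluate(d$train, d$test, plan1, train_fn, score_fn)
  expect_equal(nrow(r1$rounds), 1L)
  expect_equal(r1$mean$auc, r1$rounds$auc[1])

  plan <- bootstrap_plan(n_rounds = 5L, seed = 6L)
  ra <- bootstrap_evaluate(d$train, d$test, plan, train_fn, score_fn)
  rb <- bootstrap_evaluate(d$train, d$test, plan, train_fn, score_fn)
  expect_identical(ra$rounds, rb$rounds)
  expect_gte(ra$mean$auc, min(ra$rounds$auc))
  expect_lte(ra$mean$auc, max(ra$rounds$auc))
  # failing rounds are reported, not fatal, as long as one succeeds
  flaky <- local({
    k <- 0L
    function(train, val, seed) {
      k <<- k + 1L
      if (k == 1L) stop("synthetic failure")
      structure(list(threshold = 0.5), class = "stub_fit")
    }
  })
  rf <- bootstrap_evaluate(d$train, d$test, bootstrap_plan(3L, seed = 7L),
                           flaky, score_fn)
  expect_equal(nrow(rf$rounds), 2L)
  expect_match(rf$failures, "round 1")
})

test_that("eval_report collects threshold-free and thresholded metrics", {
  set.seed(8)
  y <- rbinom(60, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- runif(60) + 0.5 * y
  rep <- eval_report(s, y, 0.6)
  expect_true(all(c("auc", "acc", "precision", "recall", "aupr",
                    "threshold", "n_pos", "n_neg") %in% names(rep)))
  expect_equal(rep$n_pos + rep$n_neg, 60L)
  expect_true(all(unlist(rep[c("auc", "acc", "precision", "recall", "aupr")]) >= 0 &
                    unlist(rep[c("auc", "acc", "precision", "recall", "aupr")]) <= 1))
  # label strings are accepted
  rep2 <- eval_report(s, ifelse(y == 1, "methylated", "unmethylated"), 0.6)
  expect_equal(rep2$auc, rep$auc)
})
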