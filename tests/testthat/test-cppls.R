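test_that("power 0.5 with a single response reproduces NIPALS PLS first
           weights (equivalence oracle)", {
  set.seed(42)
  n <- 30; p <- 25
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("M%02d", 1:p)))
  y <- factor(rep(c("A", "B"), length.out = n))
  fit <- fit_cppls(X, y, n_components = 3, power_grid = 0.5)
  W_ref <- nipals_pls_weights(X, as.numeric(y == "B"), n_components = 3)
  for (a in 1:3) {
    cs <- abs(sum(fit$loading_weights[, a] * W_ref[, a]))
    expect_gt(cs, 1 - 1e-10)
  }
})

test_that("the informative molecule dominates the first loading weight", {
  d <- make_separable_X(n = 30, m = 15, n_inf = 1, delta = 3, seed = 7)
  fit <- fit_cppls(d$X, d$y, n_components = 1)
  expect_identical(unname(which.max(abs(fit$loading_weights[, 1]))), 1L)
  fit05 <- fit_cppls(d$X, d$y, n_components = 1, power_grid = 0.5)
  expect_identical(unname(which.max(abs(fit05$loading_weights[, 1]))), 1L)
})

test_that("scores are mutually orthogonal and weights unit norm", {
  set.seed(5)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- factor(rep(c("A", "B", "C"), length.out = 25))
  fit <- fit_cppls(X, y, n_components = 4)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(unname(colSums(fit$loading_weights^2)), rep(1, 4),
               tolerance = 1e-12)
  expect_true(all(fit$powers > 0 & fit$powers < 1))
})

test_that("fit_cppls validates inputs", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_cppls(X, rep("A", 10), 1), "2 classes")
  expect_error(fit_cppls(X, rep(c("A", "B"), 5), n_components = 12),
               "n_components too large")
  expect_error(fit_cppls(X, rep(c("A", "B"), 5), 1, power_grid = c(0, 0.5)),
               "strictly inside")
})

test_that("vip normalization: mean squared VIP is exactly 1; one-molecule
           model has VIP 1", {
  d <- make_separable_X(n = 24, m = 12, n_inf = 3, seed = 3)
  fit <- fit_cppls(d$X, d$y, n_components = 3)
  vip <- vip_scores(fit)
  expect_equal(mean(vip$vip^2), 1, tolerance = 1e-12)
  fit1 <- fit_cppls(d$X[, 1, drop = FALSE], d$y, n_components = 1)
  expect_equal(vip_scores(fit1)$vip, 1, tolerance = 1e-12)
})

test_that("informative molecules carry the top VIP scores", {
  d <- make_separable_X(n = 40, m = 30, n_inf = 3, delta = 2.5, seed = 11)
  fit <- fit_cppls(d$X, d$y, n_components = 2)
  vip <- vip_scores(fit)
  expect_true(all(c("M001", "M002", "M003") %in% vip$molecule[1:4]))
})

test_that("loocv on perfectly separated groups is perfect; metrics
           arithmetic is exact", {
  d <- make_separable_X(n = 20, m = 10, n_inf = 4, delta = 6, seed = 2)
  rep_ <- loocv_evaluate(d$X, d$y, n_components = 2)
  expect_equal(rep_$balanced_accuracy, c(1, 1))
  expect_equal(rep_$auc, c(1, 1))
  expect_equal(rep_$balanced_accuracy,
               (rep_$sensitivity + rep_$specificity) / 2)
})

test_that("printed sensitivity/specificity reproduce printed balanced
           accuracy (performance-table arithmetic)", {
  tab <- read.delim(system.file("extdata", "table2_metrics.tsv",
                                package = "ipmnomics"))
  ba <- balanced_accuracy(tab$sensitivity, tab$specificity)
  # agreement at the printed 3-decimal precision (one row is 0.8375,
  # printed 0.837: half a unit in the last printed digit)
  expect_true(all(abs(ba - tab$balanced_accuracy) <= 5e-4 + 1e-12))
  # the LGD-vs-All plasma row exactly: 1.000 / 0.812 -> 0.906
  expect_equal(balanced_accuracy(1.000, 0.812), 0.906)
})

test_that("held-out auc equals the brute-force Mann-Whitney count", {
  set.seed(9)
  scores <- c(rnorm(12), rnorm(11) + 0.5)
  scores[3] <- scores[15]                      # force a tie
  pos <- rep(c(FALSE, TRUE), c(12, 11))
  expect_identical(auc_score(scores, pos), auc_bruteforce(scores, pos))
  d <- make_separable_X(n = 24, m = 8, n_inf = 2, delta = 1, seed = 13)
  rep_ <- loocv_evaluate(d$X, d$y, n_components = 2)
  post <- attr(rep_, "posterior")
  expect_equal(rep_$auc[rep_$task == "B vs All"],
               auc_bruteforce(post[, "B"], d$y == "B"))
})

test_that("permuted labels give chance-level balanced accuracy", {
  set.seed(31)
  d <- make_separable_X(n = 40, m = 25, n_inf = 5, delta = 2, seed = 5)
  y_perm <- sample(d$y)
  rep_ <- loocv_evaluate(d$X, y_perm, n_components = 2)
  ba <- mean(rep_$balanced_accuracy)
  expect_gte(ba, 0.35)
  expect_lte(ba, 0.65)
})

test_that("recursive elimination drops floor(0.05 m) >= 1 per step with a
           strictly decreasing trace", {
  d <- make_separable_X(n = 24, m = 20, n_inf = 3, delta = 2, seed = 17)
  elim <- recursive_elimination(d$X, d$y, drop_fraction = 0.05,
                                n_components = 2)
  expect_identical(diff(elim$trace$n_retained), rep(-1L, nrow(elim$trace) - 1))
  expect_gte(min(elim$trace$n_retained), 2 + 1)
  expect_true(all(elim$selected %in% colnames(d$X)))
  # selected step is the trace argmax
  expect_identical(elim$trace$balanced_accuracy[elim$best_step],
                   max(elim$trace$balanced_accuracy))
})

test_that("elimination keeps informative molecules and beats the
           no-selection baseline", {
  d <- make_separable_X(n = 36, m = 40, n_inf = 4, delta = 2, seed = 23)
  elim <- recursive_elimination(d$X, d$y, n_components = 2)
  kept_inf <- sum(sprintf("M%03d", 1:4) %in% elim$selected)
  expect_gte(kept_inf, 3)
  baseline <- elim$trace$balanced_accuracy[1]
  expect_gte(max(elim$trace$balanced_accuracy), baseline)
})

test_that("vip ties at the drop boundary break toward alphabetically-last
           IDs", {
  # two identical molecules -> identical VIP; the alphabetically-last
  # one must drop first
  set.seed(29)
  X <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(NULL, c("MA", "MB", "MZ1", "MZ2")))
  X[, "MZ2"] <- X[, "MZ1"]
  y <- factor(rep(c("A", "B"), 10))
  fit <- fit_cppls(X, y, n_components = 1)
  vip <- vip_scores(fit)
  expect_equal(vip$vip[vip$molecule == "MZ1"],
               vip$vip[vip$molecule == "MZ2"], tolerance = 1e-10)
  elim <- recursive_elimination(X, y, drop_fraction = 0.05,
                                n_components = 1)
  d1 <- elim$vip$dropped_at_step[elim$vip$molecule == "MZ1"]
  d2 <- elim$vip$dropped_at_step[elim$vip$molecule == "MZ2"]
  if (!is.na(d1) && !is.na(d2)) expect_gte(d1, d2)
})
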