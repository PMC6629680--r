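# a small preprocessed cohort reused across model tests
fit_small_cohort <- function(m = 30, n_per = 12, eff = NULL, gage = NULL,
                             sigma = 0.4, seed = 31, fit_seed = 41,
                             n_draws = 1200, n_chains = 2, warmup = 400) {
  groups <- c("SCN", "LGD")
  if (is.null(eff))
    eff <- matrix(0, m, 2, dimnames = list(NULL, groups))
  cov_eff <- list(age = if (is.null(gage)) rep(0, m) else gage,
                  bmi = rep(0, m))
  sp <- cohort_spec(n_per_group = stats::setNames(rep(n_per, 2), groups),
                    m_molecules = m, effect_table = eff,
                    covariate_effects = cov_eff, sigma = sigma,
                    missingness = list(q_cens = 0, steepness = Inf),
                    seed = seed)
  sc <- simulate_cohort(sp)
  pre <- qrilc_impute(log_transform(sc$concentrations), seed = seed + 1)
  fit <- suppressWarnings(fit_hier_model(
    pre, sc$clinical, n_draws = n_draws, n_chains = n_chains,
    warmup = warmup, seed = fit_seed))
  list(fit = fit, cohort = sc, pre = pre)
}

test_that("sum-to-zero constraints hold exactly in every retained draw", {
  r <- fit_small_cohort(m = 12, n_per = 8, n_draws = 400, warmup = 200)
  fit <- r$fit
  expect_lt(max(abs(rowSums(fit$phi))), 1e-10)
  expect_lt(max(abs(rowSums(fit$lambda))), 1e-10)
  expect_lt(max(abs(apply(fit$eta, c(1, 3), sum))), 1e-10)
  # scales positive in every draw
  expect_true(all(fit$sigma > 0) && all(fit$zeta > 0) &&
                all(fit$alpha > 0) && all(fit$beta > 0))
})

test_that("null cohort: eta posterior means within 3 posterior sds of 0,
           and sigma is recovered", {
  r <- fit_small_cohort(m = 40, n_per = 20, sigma = 0.5,
                        n_draws = 1600, warmup = 400)
  fit <- r$fit
  eta_mat <- matrix(fit$eta, nrow = fit$n_draws)
  z <- abs(colMeans(eta_mat)) / matrixStats::colSds(eta_mat)
  expect_true(all(z < 3))
  expect_lt(abs(mean(fit$sigma) - 0.5), 0.05)
})

test_that("molecule-varying covariate effects are recovered", {
  # NOTE: an age effect *constant* across molecules is confounded with
  # the sample effects phi and is not identifiable; only the
  # molecule-varying part of gamma is.  Truth is therefore mean-zero
  # across molecules.
  set.seed(17)
  m <- 40
  gage <- rnorm(m, 0, 0.03)
  gage <- gage - mean(gage)
  r <- fit_small_cohort(m = m, n_per = 18, gage = gage, sigma = 0.4,
                        n_draws = 1600, warmup = 400)
  fit <- r$fit
  sd_age <- fit$cov_scale[["age"]]
  truth_scaled <- gage * sd_age            # model fits scaled covariates
  gmat <- matrix(fit$gamma[, "age", ], nrow = fit$n_draws)
  lo <- matrixStats::colQuantiles(gmat, probs = 0.025)
  hi <- matrixStats::colQuantiles(gmat, probs = 0.975)
  covered <- mean(truth_scaled >= lo & truth_scaled <= hi)
  expect_gte(covered, 0.9)
  # and the fitted slopes track the truth
  expect_gt(cor(colMeans(gmat), truth_scaled), 0.8)
})

test_that("fits are deterministic given the seed", {
  r1 <- fit_small_cohort(m = 8, n_per = 6, n_draws = 200, warmup = 100)
  r2 <- fit_small_cohort(m = 8, n_per = 6, n_draws = 200, warmup = 100)
  expect_identical(r1$fit$theta, r2$fit$theta)
  expect_identical(r1$fit$eta, r2$fit$eta)
  expect_identical(r1$fit$sigma, r2$fit$sigma)
})

test_that("fold_changes validates inputs and honors its contracts", {
  r <- fit_small_cohort(m = 10, n_per = 6, n_draws = 300, warmup = 150)
  fit <- r$fit
  expect_error(fold_changes(fit, "SCN", "SCN"), "different")
  expect_error(fold_changes(fit, "SCN", "HGD"), "unknown group")
  fc <- fold_changes(fit, "LGD", "SCN")
  expect_true(all(fc$lo95 <= fc$fc & fc$fc <= fc$hi95))
  expect_identical(fc$significant, fc$lo95 > 1 | fc$hi95 < 1)
  # antisymmetry holds exactly per draw ...
  lfc <- fit$eta[, "LGD", ] - fit$eta[, "SCN", ]
  expect_equal(exp(lfc), 1 / exp(-lfc), tolerance = 1e-14)
  # ... and at the summary level up to quantile interpolation
  fc_rev <- fold_changes(fit, "SCN", "LGD")
  expect_equal(fc$fc, 1 / fc_rev$fc, tolerance = 1e-3)
  expect_equal(fc$lo95, 1 / fc_rev$hi95, tolerance = 1e-3)
  expect_equal(fc$hi95, 1 / fc_rev$lo95, tolerance = 1e-3)
})

test_that("identical eta draws give fold change exactly 1, not significant", {
  r <- fit_small_cohort(m = 6, n_per = 6, n_draws = 200, warmup = 100)
  fit <- r$fit
  fit$eta[, "LGD", ] <- fit$eta[, "SCN", ]   # force eta_g == eta_h
  fc <- fold_changes(fit, "LGD", "SCN")
  expect_equal(fc$fc, rep(1, 6))
  expect_equal(fc$lo95, rep(1, 6))
  expect_equal(fc$hi95, rep(1, 6))
  expect_false(any(fc$significant))
})

test_that("log-2 contrast is recovered within [1.7, 2.3] at n = 30/group,
           m = 100", {
  groups <- c("SCN", "LGD", "HGD")
  eff <- make_effect_table(100, groups, n_inf = 10, bg = 0.25, seed = 3)
  sp <- cohort_spec(n_per_group = c(SCN = 30, LGD = 30, HGD = 30),
                    m_molecules = 100, effect_table = eff, sigma = 0.5,
                    missingness = list(q_cens = 0, steepness = Inf),
                    seed = 19)
  sc <- simulate_cohort(sp)
  pre <- qrilc_impute(log_transform(sc$concentrations), seed = 20)
  fit <- suppressWarnings(fit_hier_model(pre, sc$clinical, n_draws = 2000,
                                         n_chains = 2, warmup = 500,
                                         seed = 23))
  fc <- fold_changes(fit, "LGD", "SCN")
  expect_gt(median(fc$fc[1:10]), 1.7)
  expect_lt(median(fc$fc[1:10]), 2.3)
})

test_that("merge_groups relabels, reduces k, and validates", {
  cl <- clinical_table(data.frame(
    sample_id = paste0("s", 1:8),
    group = factor(rep(c("SCN", "LGD", "HGD", "Cancer"), 2),
                   levels = c("SCN", "LGD", "HGD", "Cancer")),
    fluid = "cyst", age = 60, bmi = 25))
  m1 <- merge_groups(cl, c("HGD", "Cancer"), "HGD/Cancer")
  expect_identical(levels(m1$group), c("SCN", "LGD", "HGD/Cancer"))
  expect_identical(sum(m1$group == "HGD/Cancer"), 4L)
  m2 <- merge_groups(cl, c("LGD", "HGD", "Cancer"), "IPMN")
  expect_identical(levels(m2$group), c("SCN", "IPMN"))
  # single-label merge is identity relabeling
  m3 <- merge_groups(cl, "SCN", "Serous")
  expect_identical(sum(m3$group == "Serous"), 2L)
  expect_error(merge_groups(cl, c("HGD", "Cancer"), "SCN"), "collides")
  expect_error(merge_groups(cl, "NOPE", "X"), "unknown group")
})

test_that("adjust_matrix standardizes and reduces covariate-driven structure", {
  set.seed(33)
  m <- 30
  gage <- rnorm(m, 0, 0.05); gage <- gage - mean(gage)
  r <- fit_small_cohort(m = m, n_per = 15, gage = gage,
                        n_draws = 800, warmup = 300)
  adj <- adjust_matrix(r$pre, r$cohort$clinical, r$fit)
  expect_equal(unname(colMeans(adj)), rep(0, m), tolerance = 1e-12)
  expect_equal(unname(apply(adj, 2, sd)), rep(1, m), tolerance = 1e-12)
  expect_error(adjust_matrix(r$pre, r$cohort$clinical, r$fit,
                             covariates = "statin"), "not in the fitted")

  # age-driven structure: correlation with age shrinks after adjustment
  raw_std <- scale(t(r$pre$values))
  age <- r$cohort$clinical$age
  cor_raw <- mean(abs(cor(raw_std, age)))
  cor_adj <- mean(abs(cor(adj, age)))
  expect_lt(cor_adj, cor_raw)
})

test_that("zero gamma posterior makes adjustment pure z-scoring", {
  r <- fit_small_cohort(m = 8, n_per = 6, n_draws = 200, warmup = 100)
  fit <- r$fit
  fit$gamma[] <- 0
  adj <- adjust_matrix(r$pre, r$cohort$clinical, fit)
  expect_equal(unclass(adj), unclass(scale(t(r$pre$values))),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("posterior_summary covers every parameter block", {
  r <- fit_small_cohort(m = 5, n_per = 6, n_draws = 200, warmup = 100)
  ps <- posterior_summary(r$fit)
  expect_true(all(c("theta", "sigma", "alpha", "beta") %in% ps$parameter))
  expect_identical(nrow(ps), 4L + 2L + 2L * 5L + 2L * 5L)
  expect_true(all(ps$lo95 <= ps$median & ps$median <= ps$hi95))
})
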