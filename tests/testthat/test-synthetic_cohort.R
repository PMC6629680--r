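test_that("degenerate noise gives exp(theta + lambda_j) exactly", {
  m <- 5
  sp <- cohort_spec(n_per_group = c(SCN = 3, LGD = 3), m_molecules = m,
                    sigma = 1e-12, hyper_sds = c(alpha = 0, beta = 0),
                    theta = 1.0,
                    missingness = list(q_cens = 0, steepness = Inf),
                    seed = 4)
  sc <- simulate_cohort(sp)
  # all eta, gamma zero; alpha = beta = 0 -> every sample of a molecule
  # equals exp(theta)
  expect_equal(unname(unclass(sc$concentrations)),
               matrix(exp(1.0), m, 6), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("log-2 contrast recovers ratio 2 empirically at n = 500/group", {
  m <- 3
  eff <- matrix(c(-log(2) / 2, log(2) / 2), m, 2, byrow = TRUE,
                dimnames = list(NULL, c("SCN", "LGD")))
  sp <- cohort_spec(n_per_group = c(SCN = 500, LGD = 500), m_molecules = m,
                    effect_table = eff, sigma = 0.3,
                    hyper_sds = c(alpha = 0, beta = 0),
                    missingness = list(q_cens = 0, steepness = Inf),
                    seed = 11)
  sc <- simulate_cohort(sp)
  g <- sc$clinical$group
  y <- log(unclass(sc$concentrations))
  # ratio of geometric group means on the natural scale
  ratio <- exp(rowMeans(y[, g == "LGD"]) - rowMeans(y[, g == "SCN"]))
  expect_true(all(abs(ratio - 2) < 2 * 0.1))   # Monte-Carlo error at n = 500
})

test_that("same spec and seed give identical cohorts; different seed differs", {
  sp <- cohort_spec(n_per_group = c(SCN = 4, LGD = 4), m_molecules = 10,
                    seed = 99)
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(unclass(a$concentrations), unclass(b$concentrations))
  expect_identical(a$clinical, b$clinical)
  sp2 <- cohort_spec(n_per_group = c(SCN = 4, LGD = 4), m_molecules = 10,
                     seed = 100)
  expect_false(identical(unclass(a$concentrations),
                         unclass(simulate_cohort(sp2)$concentrations)))
})

test_that("spec validation rejects bad inputs", {
  expect_error(cohort_spec(n_per_group = c(SCN = 5), m_molecules = 10,
                           sigma = -1, seed = 1), "sigma")
  eff <- matrix(1, 10, 2, dimnames = list(NULL, c("SCN", "LGD")))
  expect_error(cohort_spec(n_per_group = c(SCN = 5, LGD = 5),
                           m_molecules = 10, effect_table = eff, seed = 1),
               "sum to zero")
  expect_error(cohort_spec(n_per_group = c(SCN = 5, LGD = 5),
                           m_molecules = 10,
                           effect_table = matrix(0, 3, 2), seed = 1),
               "effect_table must be")
  expect_error(cohort_spec(n_per_group = c(SCN = 5, LGD = 5),
                           m_molecules = 10,
                           missingness = list(q_cens = 0.7), seed = 1),
               "q_cens")
  expect_error(cohort_spec(n_per_group = c(SCN = 5, LGD = 5),
                           m_molecules = 10), "seed")
})

test_that("clinical covariates respect the printed per-group ranges", {
  sp <- cohort_spec(n_per_group = c(SCN = 30, LGD = 30, HGD = 30,
                                    Cancer = 30),
                    m_molecules = 5, fluid = "cyst", seed = 21)
  cl <- simulate_cohort(sp)$clinical
  rg <- clinical_ranges$cyst
  for (g in rg$group) {
    r <- rg[rg$group == g, ]
    ages <- cl$age[cl$group == g]
    bmis <- cl$bmi[cl$group == g]
    expect_true(all(ages >= r$age_min & ages <= r$age_max))
    expect_true(all(bmis >= r$bmi_min & bmis <= r$bmi_max))
    expect_true(all(cl$ca19_9[cl$group == g] >= r$ca19_9_min - 1e-9))
  }
})

test_that("apply_censoring: q_cens = 0 leaves nothing missing", {
  set.seed(1)
  x <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("M", 1:5),
                                                paste0("S", 1:10)))
  out <- apply_censoring(x, q_cens = 0, seed = 1)
  expect_false(anyNA(out$values))
  expect_false(any(out$mask))
})

test_that("hard-threshold censoring removes exactly floor(q*n) smallest", {
  set.seed(2)
  n <- 17
  x <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("M", 1:5),
                                                  paste0("S", 1:n)))
  out <- apply_censoring(x, q_cens = 0.2, steepness = Inf, seed = 1)
  k_exp <- floor(0.2 * n)
  for (j in 1:5) {
    miss <- is.na(out$values[j, ])
    expect_identical(sum(miss), as.integer(k_exp))
    # all missing below all observed
    expect_lt(max(x[j, miss]), min(x[j, !miss]))
    # and below the recorded threshold
    expect_true(all(x[j, miss] < out$thresholds[j]))
  }
})

test_that("finite steepness censors only below the threshold", {
  set.seed(3)
  x <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(paste0("M", 1:4),
                                                    paste0("S", 1:40)))
  out <- apply_censoring(x, q_cens = 0.3, steepness = 2, seed = 5)
  for (j in 1:4) {
    miss <- is.na(out$values[j, ])
    if (any(miss))
      expect_true(all(x[j, miss] < out$thresholds[j]))
    expect_lte(sum(miss), floor(0.3 * 40))
  }
})

test_that("cohort missingness is MNAR by construction", {
  sp <- cohort_spec(n_per_group = c(SCN = 10, LGD = 10), m_molecules = 30,
                    missingness = list(q_cens = 0.2, steepness = Inf),
                    seed = 7)
  sc <- simulate_cohort(sp)
  mask <- is.na(unclass(sc$concentrations))
  expect_identical(mask, sc$truth$missing_mask)
  for (j in which(rowSums(mask) > 0)) {
    expect_true(all(sc$truth$log_complete[j, mask[j, ]] <
                      sc$truth$thresholds[j]))
  }
})

test_that("write_cohort produces readable CSVs and truth JSON", {
  dir <- withr::local_tempdir()
  sp <- cohort_spec(n_per_group = c(SCN = 4, LGD = 4), m_molecules = 6,
                    seed = 13)
  sc <- simulate_cohort(sp)
  write_cohort(sc, dir)
  back <- read_concentration_csv(file.path(dir, "concentrations.csv"))
  expect_equal(dim(back), dim(sc$concentrations))
  cl <- read_clinical_csv(file.path(dir, "clinical.csv"))
  expect_identical(as.character(cl$group), as.character(sc$clinical$group))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$seed, 13L)
})
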