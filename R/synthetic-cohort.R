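#' Printed clinical ranges used by the cohort generator
#'
#' Group-level medians/ranges of the pancreas-resection cohort the
#' generator emulates: per-fluid group sizes, age and BMI min-max, the
#' fraction of female patients, statin use and diabetes prevalence, and
#' ranges for the circulating markers CA19-9 (kE/L), albumin (g/L) and
#' bilirubin (umol/L).  Values below a reporting limit ("<1", "<3") enter
#' as half the limit.
#'
#' @format a list with one element per fluid ("cyst", "plasma"), each a
#'   data.frame with one row per diagnosis group.
#' @export
clinical_ranges <- list(
  cyst = data.frame(
    group     = c("SCN", "LGD", "HGD", "Cancer"),
    n         = c(5, 8, 7, 11),
    age_min   = c(34, 56, 66, 46),  age_max  = c(58, 81, 75, 83),
    bmi_min   = c(24.1, 21.8, 23.4, 20.2),
    bmi_max   = c(32.0, 36.6, 28.3, 29.7),
    female    = c(1.00, 0.50, 0.429, 0.273),
    statin    = c(0.20, 0.125, 0.143, 0.0909),
    diabetes  = c(0.00, 0.125, 0.429, 0.364),
    ca19_9_min = c(6.8, 6.4, 0.5, 0.5), ca19_9_max = c(62, 182, 115, 1040),
    albumin_min = c(33, 26, 22, 19),    albumin_max = c(39, 38, 39, 38),
    bilirubin_min = c(3, 1.5, 1.5, 5),  bilirubin_max = c(18, 13, 315, 150),
    stringsAsFactors = FALSE),
  plasma = data.frame(
    group     = c("SCN", "LGD", "HGD", "Cancer"),
    n         = c(5, 5, 6, 5),
    age_min   = c(34, 56, 66, 65),  age_max  = c(68, 76, 75, 83),
    bmi_min   = c(24.1, 24.8, 21.5, 24.1),
    bmi_max   = c(31.0, 36.6, 28.3, 32.9),
    female    = c(1.00, 0.20, 0.333, 0.40),
    statin    = c(0.20, 0.00, 0.167, 0.40),
    diabetes  = c(0.00, 0.20, 0.167, 0.20),
    ca19_9_min = c(7.9, 6.4, 0.5, 46),  ca19_9_max = c(62, 182, 115, 480),
    albumin_min = c(33, 36, 22, 28),    albumin_max = c(39, 39, 39, 34),
    bilirubin_min = c(3, 4, 4, 12),     bilirubin_max = c(7, 13, 315, 119),
    stringsAsFactors = FALSE)
)

# default molecule-class mix: TAG-dominated lipidome plus the two
# metabolite blocks measured by the targeted platform
default_class_composition <- function(m) {
  prop <- c(TAG = 0.25, PC = 0.12, FFA = 0.10, PE = 0.08, CER = 0.07,
            SM = 0.06, CE = 0.05, DAG = 0.05, LPC = 0.04, LPE = 0.03,
            `amino acid` = 0.10, `organic acid` = 0.05)
  cnt <- floor(prop * m)
  rem <- m - sum(cnt)
  if (rem > 0) {
    frac <- prop * m - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt[cnt > 0]
}

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the generative model: on the log-umol/L
#' scale, the observed log-concentration of molecule j in sample i of
#' group g is
#' \deqn{y_{gij} = \theta + \phi_i + \lambda_j + \eta_{gj}
#'   + \gamma_{1j} age_i + \gamma_{2j} bmi_i + \epsilon_{gij}}
#' with \eqn{\epsilon ~ N(0, \sigma^2)}, sample effects
#' \eqn{\phi_i ~ N(0, \alpha^2)} and molecule effects
#' \eqn{\lambda_j ~ N(0, \beta^2)}.  Concentrations are `exp(y)`;
#' low values are then censored to `NA` (see [apply_censoring()]).
#'
#' @param n_per_group named integer vector of samples per diagnosis group;
#'   default: the cyst-fluid group sizes of the emulated cohort.
#' @param m_molecules number of molecules.
#' @param class_composition named integer vector, class -> molecule count;
#'   must sum to `m_molecules`.
#' @param effect_table m x k matrix of true group-by-molecule effects
#'   eta_gj (columns = groups); every row must sum to zero.
#' @param covariate_effects list with numeric vectors `age` and `bmi`
#'   (length m): per-molecule slopes gamma_1j, gamma_2j per unit of the
#'   (uncentered) covariate.
#' @param theta grand mean on the log scale.
#' @param sigma residual sd on the log scale.
#' @param hyper_sds named numeric vector `c(alpha=, beta=)`: sds of the
#'   sample and molecule effects.
#' @param missingness list with `q_cens` (censoring quantile, in
#'   \[0, 0.5\]) and `steepness` (`Inf` = hard threshold).
#' @param fluid `"cyst"` or `"plasma"`; selects the clinical ranges used
#'   to draw covariates.
#' @param seed integer seed; mandatory, the generator is deterministic
#'   given the seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(SCN = 5, LGD = 8, HGD = 7, Cancer = 11),
                        m_molecules = 200,
                        class_composition = NULL,
                        effect_table = NULL,
                        covariate_effects = NULL,
                        theta = 1.0,
                        sigma = 0.5,
                        hyper_sds = c(alpha = 0.3, beta = 1.0),
                        missingness = list(q_cens = 0.1, steepness = Inf),
                        fluid = c("cyst", "plasma"),
                        seed) {
  fluid <- match.arg(fluid)
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for simulate_cohort()")
  if (is.null(names(n_per_group)))
    stop("n_per_group must be a named vector of group sizes")
  if (any(n_per_group < 1) || m_molecules < 1)
    stop("all counts must be >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  if (any(hyper_sds < 0)) stop("hyper_sds must be >= 0")
  k <- length(n_per_group)
  m <- m_molecules
  if (is.null(class_composition))
    class_composition <- default_class_composition(m)
  if (sum(class_composition) != m)
    stop("class_composition must sum to m_molecules")
  if (is.null(effect_table))
    effect_table <- matrix(0, m, k, dimnames = list(NULL, names(n_per_group)))
  effect_table <- as.matrix(effect_table)
  if (!all(dim(effect_table) == c(m, k)))
    stop("effect_table must be m_molecules x n_groups (",
         m, " x ", k, "), got ", nrow(effect_table), " x ", ncol(effect_table))
  if (max(abs(rowSums(effect_table))) > 1e-8)
    stop("each row of effect_table must sum to zero across groups")
  if (is.null(colnames(effect_table)))
    colnames(effect_table) <- names(n_per_group)
  if (is.null(covariate_effects))
    covariate_effects <- list(age = rep(0, m), bmi = rep(0, m))
  if (length(covariate_effects$age) != m || length(covariate_effects$bmi) != m)
    stop("covariate_effects$age and $bmi must have length m_molecules")
  q <- missingness$q_cens
  if (is.null(q) || q < 0 || q > 0.5)
    stop("missingness$q_cens must be in [0, 0.5]")
  if (is.null(missingness$steepness)) missingness$steepness <- Inf
  structure(list(n_per_group = n_per_group, m_molecules = m,
                 class_composition = class_composition,
                 effect_table = effect_table,
                 covariate_effects = covariate_effects,
                 theta = theta, sigma = sigma, hyper_sds = hyper_sds,
                 missingness = missingness, fluid = fluid,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw one clinical table from the printed per-group ranges
simulate_clinical <- function(spec) {
  rg <- clinical_ranges[[spec$fluid]]
  rows <- lapply(seq_along(spec$n_per_group), function(gidx) {
    g <- names(spec$n_per_group)[gidx]
    n_g <- spec$n_per_group[gidx]
    # unknown labels (merged / custom groups) fall back to cohort-wide ranges
    r <- rg[match(g, rg$group), ]
    if (is.na(r$n[1])) {
      r <- data.frame(age_min = min(rg$age_min), age_max = max(rg$age_max),
                      bmi_min = min(rg$bmi_min), bmi_max = max(rg$bmi_max),
                      female = mean(rg$female), statin = mean(rg$statin),
                      diabetes = mean(rg$diabetes),
                      ca19_9_min = min(rg$ca19_9_min),
                      ca19_9_max = max(rg$ca19_9_max),
                      albumin_min = min(rg$albumin_min),
                      albumin_max = max(rg$albumin_max),
                      bilirubin_min = min(rg$bilirubin_min),
                      bilirubin_max = max(rg$bilirubin_max))
    }
    data.frame(
      group = g,
      age = round(stats::runif(n_g, r$age_min, r$age_max), 1),
      bmi = round(stats::runif(n_g, r$bmi_min, r$bmi_max), 2),
      sex = ifelse(stats::runif(n_g) < r$female, "F", "M"),
      statin = stats::runif(n_g) < r$statin,
      diabetes = stats::runif(n_g) < r$diabetes,
      # markers span orders of magnitude -> log-uniform within the range
      ca19_9 = exp(stats::runif(n_g, log(r$ca19_9_min), log(r$ca19_9_max))),
      albumin = stats::runif(n_g, r$albumin_min, r$albumin_max),
      bilirubin = exp(stats::runif(n_g, log(r$bilirubin_min),
                                   log(r$bilirubin_max))),
      stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, rows)
  cl$sample_id <- sprintf("S%03d", seq_len(nrow(cl)))
  cl$fluid <- spec$fluid
  cl$group <- factor(cl$group, levels = names(spec$n_per_group))
  clinical_table(cl[, c("sample_id", "group", "fluid", "age", "bmi", "sex",
                        "statin", "diabetes", "ca19_9", "albumin",
                        "bilirubin")])
}

#' Simulate a synthetic cyst-fluid / plasma cohort
#'
#' Runs the hierarchical lognormal model forward (see [cohort_spec()]) and
#' applies left-censored missingness, producing a concentration matrix,
#' a clinical table drawn from the printed per-group ranges, and the
#' ground truth needed for parameter-recovery tests.
#'
#' @param spec a [cohort_spec()]
#' @return an object of class `synthetic_cohort`: list with
#'   `concentrations` (a [conc_matrix()] in umol/L with `NA` for censored
#'   entries), `clinical` (a [clinical_table()]) and `truth` (the spec,
#'   the complete pre-censoring log matrix, the drawn sample/molecule
#'   effects and the per-molecule censoring thresholds).
#' @examples
#' sc <- simulate_cohort(cohort_spec(m_molecules = 20, seed = 1))
#' sc$concentrations
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  k <- length(spec$n_per_group)
  m <- spec$m_molecules
  n <- sum(spec$n_per_group)

  clinical <- simulate_clinical(spec)
  gi <- as.integer(clinical$group)

  phi <- stats::rnorm(n, 0, spec$hyper_sds[["alpha"]])
  lambda <- stats::rnorm(m, 0, spec$hyper_sds[["beta"]])
  eta <- t(spec$effect_table)                       # k x m
  g1 <- spec$covariate_effects$age
  g2 <- spec$covariate_effects$bmi

  mol_ids <- sprintf("M%03d", seq_len(m))
  classes <- rep(names(spec$class_composition), spec$class_composition)

  # complete log-concentration matrix, molecules x samples
  mu <- matrix(spec$theta, m, n) + lambda +
    matrix(phi, m, n, byrow = TRUE) +
    t(eta[gi, , drop = FALSE]) +
    outer(g1, clinical$age) + outer(g2, clinical$bmi)
  y <- mu + matrix(stats::rnorm(m * n, 0, spec$sigma), m, n)
  dimnames(y) <- list(mol_ids, clinical$sample_id)

  cens <- apply_censoring(y, q_cens = spec$missingness$q_cens,
                          steepness = spec$missingness$steepness,
                          seed = spec$seed + 1L)
  conc <- conc_matrix(exp(cens$values), mol_class = classes)

  structure(list(
    concentrations = conc,
    clinical = clinical,
    truth = list(spec = spec, log_complete = y, phi = phi, lambda = lambda,
                 eta = eta, thresholds = cens$thresholds,
                 missing_mask = cens$mask)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  print(x$concentrations)
  print(table(x$clinical$group))
  invisible(x)
}

#' Left-censor a complete log-concentration matrix
#'
#' Emulates the missing-not-at-random pattern of targeted MS data: per
#' molecule, only values in the lowest `q_cens` fraction are eligible for
#' censoring; each eligible value is removed with probability given by a
#' monotone decreasing function of its distance to the censoring
#' threshold.  With `steepness = Inf` the threshold is hard and exactly
#' `floor(q_cens * n)` values per molecule go missing.
#'
#' @param complete numeric matrix (molecules x samples), complete, log scale.
#' @param q_cens censoring quantile in \[0, 0.5\].
#' @param steepness positive scalar or `Inf`; logistic steepness of the
#'   censoring probability below the threshold.
#' @param seed integer seed.
#' @return list with `values` (matrix with `NA`s), `mask` (logical matrix,
#'   `TRUE` = censored) and `thresholds` (per-molecule censoring
#'   threshold on the input scale).
#' @export
apply_censoring <- function(complete, q_cens, steepness = Inf, seed) {
  if (q_cens < 0 || q_cens > 0.5)
    stop("q_cens must be in [0, 0.5]")
  complete <- as.matrix(complete)
  if (anyNA(complete)) stop("input matrix must be complete")
  set.seed(as.integer(seed))
  n <- ncol(complete)
  k_cens <- floor(q_cens * n)
  mask <- matrix(FALSE, nrow(complete), n, dimnames = dimnames(complete))
  thr <- rep(NA_real_, nrow(complete))
  if (k_cens >= 1) {
    for (j in seq_len(nrow(complete))) {
      x <- complete[j, ]
      ord <- order(x)                  # ties broken by position: deterministic
      low <- ord[seq_len(k_cens)]
      thr[j] <- x[ord[k_cens + 1L]]    # smallest retained value
      if (is.infinite(steepness)) {
        mask[j, low] <- TRUE
      } else {
        s <- stats::sd(x)
        if (s == 0) s <- 1
        p <- stats::plogis(steepness * (thr[j] - x[low]) / s)
        mask[j, low] <- stats::runif(k_cens) < p
      }
    }
  }
  values <- complete
  values[mask] <- NA_real_
  list(values = values, mask = mask, thresholds = thr)
}

#' Write a synthetic cohort to disk
#'
#' Writes the concentration matrix and clinical table in the package CSV
#' dialect plus a `truth.json` with the generator parameters (for
#' recovery tests).  The complete pre-censoring log matrix is written as
#' `log_complete.csv`.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_concentration_csv(cohort$concentrations,
                          file.path(dir, "concentrations.csv"))
  write_clinical_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  utils::write.csv(cohort$truth$log_complete,
                   file.path(dir, "log_complete.csv"))
  tr <- cohort$truth$spec
  truth <- list(n_per_group = as.list(tr$n_per_group),
                m_molecules = tr$m_molecules,
                theta = tr$theta, sigma = tr$sigma,
                hyper_sds = as.list(tr$hyper_sds),
                effect_table = tr$effect_table,
                covariate_effects = tr$covariate_effects,
                q_cens = tr$missingness$q_cens,
                steepness = tr$missingness$steepness,
                fluid = tr$fluid, seed = tr$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
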