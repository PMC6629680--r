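#' Log-transform a concentration matrix
#'
#' Concentrations are assumed lognormal, so the natural log is the
#' preliminary normalization before any modeling.  Missing entries stay
#' missing.
#'
#' @param raw a [conc_matrix()] on the natural scale; all observed values
#'   must be strictly positive.
#' @return a [conc_matrix()] on the log scale.
#' @export
log_transform <- function(raw) {
  check_conc_matrix(raw)
  if (is_log_scale(raw))
    stop("matrix is already on the log scale")
  bad <- which(!is.na(raw) & unclass(raw) <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonpositive concentration for molecule '%s', sample '%s'",
                 rownames(raw)[bad[1, 1]], colnames(raw)[bad[1, 2]]))
  conc_matrix(log(unclass(raw)), mol_class = mol_class(raw), log_scale = TRUE)
}

#' Filter molecules by the modified 80 percent rule
#'
#' A molecule is discarded only if its fraction of missing values exceeds
#' 0.8 in *every* clinical group; one group with 80 percent or fewer
#' missing is enough to keep it.  The comparison is strict
#' (fraction > 0.8), so a molecule at exactly 0.8 everywhere is retained.
#'
#' @param mat a [conc_matrix()] (either scale; the rule only looks at the
#'   missingness pattern).
#' @param clinical a [clinical_table()] covering every sample of `mat`.
#' @param threshold missingness threshold (default 0.8).
#' @return list with `retained` (a `conc_matrix`), `dropped` (data.frame
#'   of molecule and reason) and `report` (per-molecule per-group missing
#'   fractions and the decision).
#' @export
modified_80_rule <- function(mat, clinical, threshold = 0.8) {
  check_conc_matrix(mat)
  cl <- align_clinical(clinical, colnames(mat))
  groups <- levels(cl$group)
  frac <- sapply(groups, function(g) {
    rowMeans(is.na(unclass(mat)[, cl$group == g, drop = FALSE]))
  })
  frac <- matrix(frac, nrow = nrow(mat),
                 dimnames = list(rownames(mat), groups))
  drop <- rowSums(frac > threshold) == length(groups)
  report <- data.frame(molecule = rownames(mat), frac,
                       decision = ifelse(drop, "dropped", "retained"),
                       check.names = FALSE, row.names = NULL)
  dropped <- data.frame(
    molecule = rownames(mat)[drop],
    reason = sprintf("missing fraction > %.2f in all %d groups",
                     threshold, length(groups))[rep(1, sum(drop))],
    row.names = NULL)
  list(retained = cm_subset(mat, rows = !drop), dropped = dropped,
       report = report)
}

# estimate (mean, sd) of the complete lognormal from left-truncated
# observations: regress observed order statistics against the standard
# normal quantiles of their plotting positions within the full
# distribution (missing fraction assumed entirely left of the observed)
qrilc_fit_one <- function(obs, n_total) {
  n_obs <- length(obs)
  pi_miss <- 1 - n_obs / n_total
  p <- pi_miss + (1 - pi_miss) * (seq_len(n_obs) - 0.5) / n_obs
  q <- stats::qnorm(p)
  fit <- stats::lm.fit(cbind(1, q), sort(obs))
  mu <- fit$coefficients[1]
  s <- fit$coefficients[2]
  if (!is.finite(s) || s <= 0) s <- max(stats::sd(obs), 1e-8)
  c(mean = unname(mu), sd = unname(s))
}

#' QRILC-style imputation of left-censored values
#'
#' Per molecule, the mean and sd of the complete log-scale distribution
#' are estimated by quantile regression of the observed order statistics
#' against standard-normal quantiles (robust to left truncation), and
#' missing entries are drawn from that normal truncated above at the
#' molecule's minimum observed value, so every imputed value lies
#' strictly below everything observed for that molecule.
#'
#' @param mat a [conc_matrix()] on the log scale, already filtered by
#'   [modified_80_rule()]; every molecule needs at least 3 observed
#'   values.
#' @param seed integer seed; imputation is deterministic given the seed.
#' @return an object of class `preprocessed_matrix`: list with `values`
#'   (complete molecules x samples log matrix), `imputed_mask`,
#'   `mol_class`, `per_molecule_min_observed` and `qrilc_params`
#'   (estimated mean/sd per molecule).
#' @export
qrilc_impute <- function(mat, seed) {
  check_conc_matrix(mat)
  if (!is_log_scale(mat))
    stop("qrilc_impute expects a log-scale matrix; run log_transform() first")
  if (missing(seed)) stop("a seed is mandatory for qrilc_impute()")
  n_obs <- rowSums(!is.na(mat))
  if (any(n_obs < 3))
    stop("molecule(s) with fewer than 3 observed values: ",
         paste(utils::head(rownames(mat)[n_obs < 3], 5), collapse = ", "),
         " -- apply stricter filtering first")
  set.seed(as.integer(seed))
  vals <- matrix(as.numeric(mat), nrow(mat), ncol(mat),
                 dimnames = dimnames(mat))
  mask <- is.na(vals)
  n_total <- ncol(vals)
  min_obs <- apply(vals, 1, min, na.rm = TRUE)
  params <- matrix(NA_real_, nrow(vals), 2,
                   dimnames = list(rownames(vals), c("mean", "sd")))
  for (j in seq_len(nrow(vals))) {
    obs <- vals[j, !mask[j, ]]
    est <- qrilc_fit_one(obs, n_total)
    params[j, ] <- est
    k <- sum(mask[j, ])
    if (k > 0) {
      # draws are assigned in sample-ID order so the result is
      # equivariant under column permutations
      idx <- which(mask[j, ])
      idx <- idx[order(colnames(vals)[idx])]
      vals[j, idx] <- truncnorm::rtruncnorm(
        k, a = -Inf, b = min_obs[j], mean = est["mean"], sd = est["sd"])
    }
  }
  structure(list(values = vals, imputed_mask = mask,
                 mol_class = mol_class(mat),
                 per_molecule_min_observed = min_obs,
                 qrilc_params = params),
            class = "preprocessed_matrix")
}

#' @export
print.preprocessed_matrix <- function(x, ...) {
  cat(sprintf("<preprocessed_matrix> %d molecules x %d samples, %d imputed (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$imputed_mask),
              100 * mean(x$imputed_mask)))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' Log transform, modified 80 percent rule, QRILC imputation -- in the
#' stated order.  A matrix with no missing values passes through with no
#' value changed.
#'
#' @param raw a natural-scale [conc_matrix()]
#' @param clinical a [clinical_table()]
#' @param seed integer seed for the imputation draw
#' @param threshold missingness threshold of the filter
#' @return a `preprocessed_matrix` (see [qrilc_impute()]) with the filter
#'   report attached as `filter_report` and dropped molecules as
#'   `dropped_molecules`.
#' @export
preprocess <- function(raw, clinical, seed, threshold = 0.8) {
  lg <- log_transform(raw)
  flt <- modified_80_rule(lg, clinical, threshold = threshold)
  pre <- qrilc_impute(flt$retained, seed = seed)
  pre$filter_report <- flt$report
  pre$dropped_molecules <- flt$dropped
  pre
}
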