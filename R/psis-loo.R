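# Pareto-smoothed importance sampling LOO (Vehtari, Gelman & Gabry) --
# implemented from the published algorithm: generalized Pareto fit to the
# upper tail of the importance ratios by the Zhang--Stephens profile
# posterior, tail replaced by expected GPD order statistics.

# Zhang & Stephens (2009) style GPD fit to exceedances x > 0.
# Returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bk <- 3
  ngrid <- 30 + floor(sqrt(n))
  jj <- seq_len(ngrid)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(ngrid / (jj - 0.5))) / (prior_bk * xstar)
  kt <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l <- n * (log(-theta / kt) - kt - 1)
  w <- exp(l - max(l)); w <- w / sum(w)
  theta_hat <- sum(theta * w)
  khat <- mean(log1p(-theta_hat * x))
  sigma <- -khat / theta_hat
  # weakly informative regularization of khat (as in the published
  # algorithm) stabilizes small tails
  khat <- (n * khat + 10 * 0.5) / (n + 10)
  c(k = khat, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, khat = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exc <= 0)) return(list(lw = lw, khat = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  p <- (seq_len(M) - 0.5) / M
  smoothed <- log(qgpd(p, fit["k"], fit["sigma"]) + exp(cutoff))
  # keep tail order, cap at the observed maximum
  smoothed <- pmin(smoothed, 0)
  lw[tail_idx[order(lw[tail_idx])]] <- smoothed
  list(lw = lw - logsumexp(lw), khat = unname(fit["k"]))
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# pointwise log-likelihood draws for one molecule: S x n matrix
loglik_molecule <- function(draws, j, Y, Xc, gi) {
  S <- draws$n_draws
  n <- nrow(Y)
  mu <- draws$theta + draws$phi +
    matrix(draws$lambda[, j], S, n) +
    draws$eta[, gi, j]
  V <- length(draws$covariates)
  if (V > 0)
    for (v in seq_len(V))
      mu <- mu + outer(draws$gamma[, v, j], Xc[, v])
  stats::dnorm(matrix(Y[, j], S, n, byrow = TRUE), mu, draws$sigma, log = TRUE)
}

#' Expected log pointwise predictive density (PSIS-LOO or WAIC)
#'
#' Computes the out-of-sample pointwise predictive accuracy of a fitted
#' hierarchical model: either by Pareto-smoothed importance-sampling
#' leave-one-out cross-validation (default) or by WAIC.
#'
#' @param draws a `posterior_draws`
#' @param pre the `preprocessed_matrix` the model was fit to
#' @param clinical the matching [clinical_table()]
#' @param method `"psis_loo"` or `"waic"`
#' @return list with `elpd`, `se`, `pointwise` (n x m matrix of
#'   per-observation contributions) and for PSIS-LOO the vector of Pareto
#'   `khat` diagnostics.
#' @export
elpd_score <- function(draws, pre, clinical,
                       method = c("psis_loo", "waic")) {
  method <- match.arg(method)
  stopifnot(inherits(draws, "posterior_draws"))
  vals <- if (inherits(pre, "preprocessed_matrix")) pre$values else as.matrix(pre)
  cl <- align_clinical(clinical, colnames(vals))
  Y <- t(vals)
  gi <- match(as.character(cl$group), draws$groups)
  V <- length(draws$covariates)
  if (V > 0) {
    Xraw <- as.matrix(cl[, draws$covariates, drop = FALSE])
    Xc <- sweep(sweep(Xraw, 2, draws$cov_center), 2, draws$cov_scale, "/")
  } else Xc <- matrix(0, nrow(Y), 0)
  n <- nrow(Y); m <- ncol(Y)
  pointwise <- matrix(NA_real_, n, m)
  khat <- if (method == "psis_loo") matrix(NA_real_, n, m) else NULL
  for (j in seq_len(m)) {
    ll <- loglik_molecule(draws, j, Y, Xc, gi)     # S x n
    for (i in seq_len(n)) {
      if (method == "waic") {
        lpd <- logsumexp(ll[, i]) - log(nrow(ll))
        pointwise[i, j] <- lpd - stats::var(ll[, i])
      } else {
        sm <- psis_smooth(-ll[, i])
        pointwise[i, j] <- logsumexp(sm$lw + ll[, i])
        khat[i, j] <- sm$khat
      }
    }
  }
  elpd <- sum(pointwise)
  se <- sqrt(length(pointwise) * stats::var(as.vector(pointwise)))
  out <- list(elpd = elpd, se = se, pointwise = pointwise, method = method)
  if (!is.null(khat)) out$khat <- as.vector(khat)
  out
}

#' Select model covariates by out-of-sample predictive accuracy
#'
#' Fits the hierarchical model once per candidate covariate set and
#' scores each fit by its expected log pointwise predictive density
#' (PSIS-LOO by default, WAIC optionally).  The highest-scoring set is
#' returned.
#'
#' @param pre a `preprocessed_matrix`
#' @param clinical a [clinical_table()]
#' @param candidate_sets list of character vectors (use `character(0)`
#'   for the covariate-free model); every name must be a numeric clinical
#'   column.
#' @param n_draws,n_chains,warmup sampler settings per candidate fit
#'   (kept modest by default; selection needs relative, not absolute,
#'   precision).
#' @param seed integer seed
#' @param method `"psis_loo"` (default) or `"waic"`
#' @return list with `chosen` (character vector), `scores` (data.frame of
#'   set label, elpd, se) and `fits` (the posterior draws per candidate).
#' @export
select_covariates <- function(pre, clinical, candidate_sets,
                              n_draws = 2000, n_chains = 2, warmup = 500,
                              seed, method = c("psis_loo", "waic")) {
  method <- match.arg(method)
  if (missing(seed)) stop("a seed is mandatory for select_covariates()")
  if (!length(candidate_sets)) stop("no candidate sets given")
  for (cs in candidate_sets) {
    unknown <- setdiff(cs, names(clinical))
    if (length(unknown))
      stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  }
  labels <- vapply(candidate_sets, function(cs)
    if (!length(cs)) "(none)" else paste(cs, collapse = "+"), character(1))
  groups <- levels(droplevels(align_clinical(
    clinical, colnames(if (inherits(pre, "preprocessed_matrix"))
      pre$values else pre))$group))
  scores <- data.frame(set = labels, elpd = NA_real_, se = NA_real_)
  fits <- vector("list", length(candidate_sets))
  for (ii in seq_along(candidate_sets)) {
    sp <- model_spec(groups, covariates = candidate_sets[[ii]])
    fit <- suppressWarnings(fit_hier_model(
      pre, clinical, sp, n_draws = n_draws, n_chains = n_chains,
      warmup = warmup, seed = seed + ii))
    sc <- elpd_score(fit, pre, clinical, method = method)
    scores$elpd[ii] <- sc$elpd
    scores$se[ii] <- sc$se
    fits[[ii]] <- fit
  }
  best <- which.max(scores$elpd)
  list(chosen = candidate_sets[[best]], scores = scores, fits = fits)
}
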