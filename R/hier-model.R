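#' Model specification for the hierarchical mixed model
#'
#' The observed log-concentration of molecule j in sample i of group g is
#' modeled as
#' \deqn{y_{gij} | \mu_{gij}, \sigma \sim N(\mu_{gij}, \sigma^2)}
#' \deqn{\mu_{gij} = \theta + \phi_i + \lambda_j + \eta_{gj}
#'   + \sum_v \gamma_{vj} x_{vi}}
#' with weakly informative priors: \eqn{\theta ~ t(3, 0, 10)},
#' \eqn{\phi_i ~ N(0, \alpha^2)}, \eqn{\lambda_j ~ N(0, \beta^2)},
#' \eqn{\eta_{gj} ~ N(0, \zeta_g^2)}, \eqn{\gamma_{vj} ~ N(0, \omega_v^2)},
#' and half-t(3, 0, 10) on every scale (\eqn{\sigma, \alpha, \beta,
#' \omega_v, \zeta_g}).  Coefficients sharing a discrete category are
#' constrained to sum to zero (\eqn{\sum_i \phi_i = 0},
#' \eqn{\sum_j \lambda_j = 0}, \eqn{\sum_g \eta_{gj} = 0} per molecule)
#' to make the model identifiable.
#'
#' @param groups ordered character vector of group labels (k >= 2).
#' @param covariates character vector of continuous covariate names
#'   (columns of the clinical table); default `c("age", "bmi")`.  They are
#'   mean-centered and sd-scaled internally before fitting.
#' @param prior_scale scale of the t / half-t priors (default 10).
#' @param prior_df degrees of freedom of the t / half-t priors (default 3).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(groups, covariates = c("age", "bmi"),
                       prior_scale = 10, prior_df = 3) {
  if (length(groups) < 2) stop("need k >= 2 groups")
  structure(list(groups = as.character(groups),
                 covariates = as.character(covariates),
                 prior_scale = prior_scale, prior_df = prior_df),
            class = "model_spec")
}

# inverse-gamma draw (shape/rate parametrization)
rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape, rate = rate)

# Gibbs update (via slice sampling) of one group scale zeta_g^2.
#
# The group-by-molecule effects have the Gaussian prior conditioned on
# the per-molecule zero-sum hyperplane, whose normalizing constant
# depends on the scales: each molecule contributes a factor
# (sum_h zeta_h^2)^{1/2}.  The conditional density of u = zeta_g^2 is
# therefore
#   u^{-(nu+m)/2 - 1} (u + C)^{m/2} exp(-(nu/a + SS/2)/u),
# with C the sum of the other groups' squared scales -- not inverse
# gamma, so it is sampled exactly with a stepping-out slice sampler on
# log u (Neal 2003).
update_zeta2 <- function(u, C, SS, m, nu, a) {
  rate_p <- nu / a + SS / 2
  logf <- function(x)                      # density of x = log u, du terms in
    -(nu + m) / 2 * x + (m / 2) * log(exp(x) + C) - rate_p * exp(-x)
  x0 <- log(u)
  y <- logf(x0) - stats::rexp(1)
  w <- 1
  lo <- x0 - w * stats::runif(1); hi <- lo + w
  for (s in 1:50) { if (logf(lo) < y) break; lo <- lo - w }
  for (s in 1:50) { if (logf(hi) < y) break; hi <- hi + w }
  for (s in 1:100) {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) >= y) return(exp(x1))
    if (x1 < x0) lo <- x1 else hi <- x1
  }
  u
}

#' Fit the Bayesian hierarchical linear mixed model
#'
#' Gibbs sampler for the model in [model_spec()].  Every full conditional
#' is available in closed form: the Student-t prior on the grand mean and
#' the half-t priors on the scales are handled through their
#' inverse-gamma scale-mixture representations, and the sum-to-zero
#' constraints are imposed exactly in every draw by sampling each
#' Gaussian block conditional on its zero-sum hyperplane
#' (variance-weighted projection of the unconstrained conditional draw).
#'
#' @param pre a `preprocessed_matrix` (complete log-scale values), or a
#'   plain complete molecules x samples matrix.
#' @param clinical a [clinical_table()] covering all samples.
#' @param spec a [model_spec()]; defaults to the group levels found in
#'   `clinical` with covariates age and bmi.
#' @param n_draws total retained posterior draws across chains
#'   (default 20000).
#' @param n_chains number of chains (default 4).
#' @param warmup burn-in iterations per chain (default 1000).
#' @param seed integer seed (mandatory).
#' @return an object of class `posterior_draws`: retained draws of all
#'   parameters, the chain index per draw, group/molecule/covariate
#'   labels, covariate centering constants, and a `convergence` table of
#'   split R-hat and effective sample size.  A warning is raised (and
#'   recorded in `$convergence_warning`) if any monitored R-hat
#'   exceeds 1.05.
#' @export
fit_hier_model <- function(pre, clinical, spec = NULL,
                           n_draws = 20000, n_chains = 4, warmup = 1000,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory for fit_hier_model()")
  vals <- if (inherits(pre, "preprocessed_matrix")) pre$values else as.matrix(pre)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("model input must be complete and finite; preprocess first")
  cl <- align_clinical(clinical, colnames(vals))
  if (is.null(spec))
    spec <- model_spec(levels(cl$group))
  if (!setequal(levels(cl$group), spec$groups))
    stop("clinical groups do not match model_spec groups")
  Y <- t(vals)                                   # samples x molecules
  n <- nrow(Y); m <- ncol(Y); N <- n * m
  gf <- factor(as.character(cl$group), levels = spec$groups)
  gi <- as.integer(gf)
  k <- length(spec$groups)
  n_g <- as.numeric(table(gf))
  if (any(n_g == 0)) stop("empty group: ",
                          paste(spec$groups[n_g == 0], collapse = ", "))
  V <- length(spec$covariates)
  if (V > 0) {
    missing_cov <- setdiff(spec$covariates, names(cl))
    if (length(missing_cov))
      stop("covariate(s) not in clinical table: ",
           paste(missing_cov, collapse = ", "))
    Xraw <- as.matrix(cl[, spec$covariates, drop = FALSE])
    if (!is.numeric(Xraw)) stop("covariates must be numeric")
    if (anyNA(Xraw)) stop("missing covariate values")
    cov_center <- colMeans(Xraw)
    cov_scale <- apply(Xraw, 2, stats::sd)
    cov_scale[cov_scale == 0] <- 1
    Xc <- sweep(sweep(Xraw, 2, cov_center), 2, cov_scale, "/")
  } else {
    Xc <- matrix(0, n, 0); cov_center <- numeric(0); cov_scale <- numeric(0)
  }

  nu <- spec$prior_df; A2 <- spec$prior_scale^2
  per_chain <- ceiling(n_draws / n_chains)
  S_tot <- per_chain * n_chains

  # storage
  d_theta <- numeric(S_tot); d_sigma <- numeric(S_tot)
  d_alpha <- numeric(S_tot); d_beta <- numeric(S_tot)
  d_omega <- matrix(NA_real_, S_tot, max(V, 1))
  d_zeta <- matrix(NA_real_, S_tot, k)
  d_phi <- matrix(NA_real_, S_tot, n)
  d_lambda <- matrix(NA_real_, S_tot, m)
  d_eta <- array(NA_real_, c(S_tot, k, m))
  d_gamma <- array(NA_real_, c(S_tot, max(V, 1), m))
  chain_id <- rep(seq_len(n_chains), each = per_chain)

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, n_chains)

  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    # init from data moments, jittered per chain
    theta <- mean(Y) + stats::rnorm(1, 0, 0.1)
    lambda <- colMeans(Y) - mean(Y)
    phi <- rowMeans(Y) - mean(Y)
    eta <- matrix(0, k, m)
    gamma <- matrix(0, max(V, 1), m)
    sigma2 <- stats::var(as.vector(Y - mean(Y))) * exp(stats::rnorm(1, 0, 0.2))
    alpha2 <- max(stats::var(phi), 1e-4)
    beta2 <- max(stats::var(lambda), 1e-4)
    zeta2 <- rep(0.25, k); omega2 <- rep(0.25, max(V, 1))
    V_theta <- A2
    a_sigma <- a_alpha <- a_beta <- 1
    a_zeta <- rep(1, k); a_omega <- rep(1, max(V, 1))

    R <- Y - theta - phi - matrix(lambda, n, m, byrow = TRUE) -
      eta[gi, , drop = FALSE]
    if (V > 0) R <- R - Xc %*% gamma[seq_len(V), , drop = FALSE]

    for (it in seq_len(warmup + per_chain)) {
      ## theta (t prior via normal/inverse-gamma mixture)
      R <- R + theta
      prec <- N / sigma2 + 1 / V_theta
      theta <- stats::rnorm(1, (sum(R) / sigma2) / prec, sqrt(1 / prec))
      R <- R - theta
      V_theta <- rinvgamma1((nu + 1) / 2, (nu * A2 + theta^2) / 2)

      ## phi (equal conditional variances -> centering is the exact
      ## zero-sum conditional draw)
      R <- R + phi
      v <- 1 / (m / sigma2 + 1 / alpha2)
      z <- stats::rnorm(n, v * rowSums(R) / sigma2, sqrt(v))
      phi <- z - mean(z)
      R <- R - phi

      ## lambda
      R <- R + matrix(lambda, n, m, byrow = TRUE)
      v <- 1 / (n / sigma2 + 1 / beta2)
      z <- stats::rnorm(m, v * colSums(R) / sigma2, sqrt(v))
      lambda <- z - mean(z)
      R <- R - matrix(lambda, n, m, byrow = TRUE)

      ## eta: per-group conditional variances differ, so the zero-sum
      ## conditional is the weighted projection z - v * sum(z) / sum(v)
      R <- R + eta[gi, , drop = FALSE]
      Sgj <- rowsum(R, gi, reorder = TRUE)             # k x m
      v_g <- 1 / (n_g / sigma2 + 1 / zeta2)            # k
      Z <- v_g * Sgj / sigma2 +
        matrix(stats::rnorm(k * m), k, m) * sqrt(v_g)
      eta <- Z - (v_g / sum(v_g)) %o% colSums(Z)
      R <- R - eta[gi, , drop = FALSE]

      ## gamma_v
      if (V > 0) {
        for (vv in seq_len(V)) {
          xv <- Xc[, vv]
          R <- R + outer(xv, gamma[vv, ])
          prec <- sum(xv^2) / sigma2 + 1 / omega2[vv]
          mu_g <- (crossprod(xv, R)[1, ] / sigma2) / prec
          gamma[vv, ] <- stats::rnorm(m, mu_g, sqrt(1 / prec))
          R <- R - outer(xv, gamma[vv, ])
        }
      }

      ## scales (half-t via double inverse-gamma); shapes account for the
      ## degrees of freedom removed by each sum-to-zero constraint
      sigma2 <- rinvgamma1((nu + N) / 2, nu / a_sigma + sum(R^2) / 2)
      a_sigma <- rinvgamma1((nu + 1) / 2, nu / sigma2 + 1 / A2)

      alpha2 <- rinvgamma1((nu + n - 1) / 2, nu / a_alpha + sum(phi^2) / 2)
      a_alpha <- rinvgamma1((nu + 1) / 2, nu / alpha2 + 1 / A2)

      beta2 <- rinvgamma1((nu + m - 1) / 2, nu / a_beta + sum(lambda^2) / 2)
      a_beta <- rinvgamma1((nu + 1) / 2, nu / beta2 + 1 / A2)

      for (g in seq_len(k)) {
        zeta2[g] <- update_zeta2(zeta2[g], sum(zeta2[-g]), sum(eta[g, ]^2),
                                 m, nu, a_zeta[g])
        a_zeta[g] <- rinvgamma1((nu + 1) / 2, nu / zeta2[g] + 1 / A2)
      }
      if (V > 0) {
        for (vv in seq_len(V)) {
          omega2[vv] <- rinvgamma1((nu + m) / 2,
                                   nu / a_omega[vv] + sum(gamma[vv, ]^2) / 2)
          a_omega[vv] <- rinvgamma1((nu + 1) / 2, nu / omega2[vv] + 1 / A2)
        }
      }

      if (it > warmup) {
        s <- (ch - 1) * per_chain + (it - warmup)
        d_theta[s] <- theta; d_sigma[s] <- sqrt(sigma2)
        d_alpha[s] <- sqrt(alpha2); d_beta[s] <- sqrt(beta2)
        d_omega[s, ] <- sqrt(omega2); d_zeta[s, ] <- sqrt(zeta2)
        d_phi[s, ] <- phi; d_lambda[s, ] <- lambda
        d_eta[s, , ] <- eta; d_gamma[s, , ] <- gamma
      }
    }
  }

  molecules <- colnames(Y)
  dimnames(d_eta) <- list(NULL, spec$groups, molecules)
  dimnames(d_gamma) <- list(NULL,
                            if (V > 0) spec$covariates else "none", molecules)
  colnames(d_zeta) <- spec$groups
  colnames(d_omega) <- if (V > 0) spec$covariates else "none"
  colnames(d_phi) <- rownames(Y)
  colnames(d_lambda) <- molecules

  draws <- structure(list(
    theta = d_theta, sigma = d_sigma, alpha = d_alpha, beta = d_beta,
    omega = d_omega[, seq_len(max(V, 1)), drop = FALSE],
    zeta = d_zeta, phi = d_phi, lambda = d_lambda,
    eta = d_eta, gamma = d_gamma,
    n_draws = S_tot, n_chains = n_chains, chain_id = chain_id,
    groups = spec$groups, molecules = molecules,
    mol_class = if (inherits(pre, "preprocessed_matrix")) pre$mol_class else NULL,
    covariates = if (V > 0) spec$covariates else character(0),
    cov_center = cov_center, cov_scale = cov_scale,
    group_index = gi, spec = spec, seed = as.integer(seed)),
    class = "posterior_draws")

  draws$convergence <- convergence_table(draws)
  bad <- draws$convergence$rhat > 1.05
  if (any(bad, na.rm = TRUE)) {
    msg <- sprintf("convergence warning: %d parameter(s) with split R-hat > 1.05 (max %.3f)",
                   sum(bad, na.rm = TRUE), max(draws$convergence$rhat, na.rm = TRUE))
    draws$convergence_warning <- msg
    warning(msg)
  }
  draws
}

# split R-hat (Gelman et al.) for a draws matrix S x P with chain ids
split_rhat <- function(x, chain_id) {
  x <- as.matrix(x)
  chains <- unique(chain_id)
  halves <- list()
  for (c0 in chains) {
    xs <- x[chain_id == c0, , drop = FALSE]
    h <- floor(nrow(xs) / 2)
    halves <- c(halves, list(xs[seq_len(h), , drop = FALSE],
                             xs[h + seq_len(h), , drop = FALSE]))
  }
  M <- length(halves); nh <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) matrixStats::colVars(h))
  means <- matrix(means, ncol = M); vars <- matrix(vars, ncol = M)
  B <- nh * matrixStats::rowVars(means)
  W <- rowMeans(vars)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

# crude but dependable ESS: initial positive sequence estimator on the
# pooled within-chain autocorrelations
ess_basic <- function(x, chain_id, max_lag = 100) {
  x <- as.numeric(x)
  chains <- unique(chain_id)
  n_tot <- length(x)
  rho_sum <- 0
  nc <- length(chains)
  acfs <- sapply(chains, function(c0) {
    xs <- x[chain_id == c0]
    stats::acf(xs, lag.max = min(max_lag, length(xs) - 1),
               plot = FALSE)$acf[-1]
  })
  rho <- rowMeans(matrix(acfs, ncol = nc))
  s <- 0
  for (l in seq_along(rho)) {
    if (rho[l] < 0.01) break
    s <- s + rho[l]
  }
  n_tot / (1 + 2 * s)
}

# R-hat / ESS for the grand mean, all scales, and every eta (the
# parameters fold changes are built from)
convergence_table <- function(draws) {
  k <- length(draws$groups); m <- length(draws$molecules)
  eta_mat <- matrix(draws$eta, nrow = draws$n_draws)
  scal <- cbind(theta = draws$theta, sigma = draws$sigma,
                alpha = draws$alpha, beta = draws$beta,
                draws$zeta)
  nm <- c("theta", "sigma", "alpha", "beta",
          paste0("zeta[", draws$groups, "]"),
          paste0("eta[", rep(draws$groups, m), ",",
                 rep(draws$molecules, each = k), "]"))
  all_mat <- cbind(scal, eta_mat)
  rhat <- split_rhat(all_mat, draws$chain_id)
  # ESS is expensive; report it for the scalar block plus a fixed-size
  # sample of eta columns
  ess <- rep(NA_real_, ncol(all_mat))
  idx <- seq_len(ncol(scal))
  extra <- ncol(scal) + unique(round(seq(1, k * m, length.out = min(20, k * m))))
  for (i in union(idx, extra))
    ess[i] <- ess_basic(all_mat[, i], draws$chain_id)
  data.frame(parameter = nm, rhat = rhat, ess = ess, row.names = NULL)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws (%d chains), %d groups x %d molecules, %d covariate(s)\n",
              x$n_draws, x$n_chains, length(x$groups), length(x$molecules),
              length(x$covariates)))
  cat(sprintf("max split R-hat: %.3f\n", max(x$convergence$rhat, na.rm = TRUE)))
  invisible(x)
}
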