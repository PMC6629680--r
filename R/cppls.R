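# Canonical powered partial least squares (CPPLS) for discriminant
# analysis.  Loading weights blend per-variable standard deviations and
# variable-response correlations through a power p in (0, 1):
#   w0[, q] = sign(C[, q]) * (|C[, q]|/max|C|)^(p/(1-p)) * (S/maxS)^((1-p)/p)
# and the candidate weight matrix is collapsed to a single direction by
# the first canonical covariate between X %*% W0 and the dummy response
# space.  p = 0.5 makes both exponents one, recovering the ordinary PLS2
# weight X'Y up to the canonical combination.

# first canonical correlation between Z (n x a) and Y (n x q), plus the
# Z-side coefficient vector; both inputs are column-centered
first_canonical <- function(Z, Y) {
  qz <- qr(Z); qy <- qr(Y)
  dz <- qz$rank; dy <- qy$rank
  if (dz == 0 || dy == 0) stop("rank-0 matrix in canonical correlation")
  Qz <- qr.Q(qz)[, seq_len(dz), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(dy), drop = FALSE]
  sv <- svd(crossprod(Qz, Qy), nu = dz, nv = 0)
  r <- min(max(sv$d[1], 0), 1)
  a <- backsolve(qr.R(qz)[seq_len(dz), seq_len(dz), drop = FALSE],
                 sv$u[, 1, drop = FALSE])
  coef <- numeric(ncol(Z))
  coef[qz$pivot[seq_len(dz)]] <- a
  list(r = r, coef = coef)
}

# powered candidate weights for power p given prepared C (signed
# correlations), S (sds), both already scaled to max 1
powered_w0 <- function(Cn, Sn, sng, p) {
  if (p <= 0 || p >= 1) stop("power must be in (0, 1)")
  (sng * Cn^(p / (1 - p))) * Sn^((1 - p) / p)
}

# one CPPLS component on centered X (n x p) and centered responses
# Y (n x q); returns unit-norm loading weight, chosen power, canonical corr
cppls_component <- function(X, Y, power_grid) {
  n <- nrow(X)
  S <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))    # population sd
  degenerate <- S == 0
  S[degenerate] <- 1
  Xs <- sweep(X, 2, colMeans(X))
  Ys <- sweep(Y, 2, colMeans(Y))
  sy <- sqrt(colMeans(Ys^2)); sy[sy == 0] <- 1
  C <- crossprod(Xs, Ys) / (n * tcrossprod(S, sy))
  C[degenerate, ] <- 0
  S[degenerate] <- 0
  sng <- sign(C)
  Cn <- abs(C) / max(abs(C), 1e-300)
  Sn <- S / max(S, 1e-300)

  if (length(power_grid) == 1 && power_grid == 0.5) {
    W0 <- crossprod(X, Y)              # plain PLS2 candidate weights
    cc <- first_canonical(X %*% W0, Y)
    w <- W0 %*% cc$coef
    return(list(w = w / sqrt(sum(w^2)), power = 0.5, cc = cc$r))
  }

  best <- list(cc = -Inf)
  for (p in power_grid) {
    W0 <- powered_w0(Cn, Sn, sng, p)
    if (all(abs(W0) < 1e-300)) next
    cc <- tryCatch(first_canonical(X %*% W0, Y), error = function(e) NULL)
    if (is.null(cc)) next
    if (cc$r > best$cc) {
      w <- W0 %*% cc$coef
      best <- list(w = w, power = p, cc = cc$r)
    }
  }
  if (!is.finite(best$cc)) stop("no usable power in power_grid")
  list(w = best$w / sqrt(sum(best$w^2)), power = best$power, cc = best$cc)
}

#' Fit a CPPLS-DA model
#'
#' Canonical powered partial least squares with dummy-coded class
#' responses, followed by linear discriminant analysis on the component
#' scores (the conventional classifier companion; its class posterior
#' probabilities serve as continuous scores for ROC analysis).
#'
#' @param X samples x molecules numeric matrix (typically an
#'   `adjusted_matrix`).
#' @param y class labels (factor or character), >= 2 classes present.
#' @param n_components number of latent components; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param power_grid candidate powers in (0, 1); the power maximizing the
#'   canonical correlation between the X-score and the response space is
#'   chosen per component.  `c(0.5)` reduces to ordinary PLS2 weights.
#' @return an object of class `cppls_model` with loading weights, scores,
#'   loadings, Y-loadings, chosen powers, explained Y-variance per
#'   component, and the LDA fit on the scores.
#' @export
fit_cppls <- function(X, y, n_components = 2,
                      power_grid = seq(0.05, 0.95, by = 0.05)) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("y must contain at least 2 classes")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components too large: must be <= min(n - 1, m)")
  if (any(power_grid <= 0 | power_grid >= 1))
    stop("powers must lie strictly inside (0, 1)")
  Ydum <- stats::model.matrix(~ y - 1)
  colnames(Ydum) <- levels(y)
  Xmeans <- colMeans(X)
  Xc <- sweep(X, 2, Xmeans)
  Yc <- sweep(Ydum, 2, colMeans(Ydum))

  p <- ncol(X); a_max <- n_components
  W <- matrix(0, p, a_max); P <- matrix(0, p, a_max)
  TT <- matrix(0, nrow(X), a_max); Q <- matrix(0, ncol(Ydum), a_max)
  pow <- numeric(a_max); ccs <- numeric(a_max); tsqs <- numeric(a_max)
  Xd <- Xc
  for (a in seq_len(a_max)) {
    comp <- cppls_component(Xd, Yc, power_grid)
    w <- comp$w
    t_a <- Xd %*% w
    tsq <- sum(t_a^2)
    if (tsq < 1e-12) stop("degenerate component ", a, ": X exhausted")
    p_a <- crossprod(Xd, t_a) / tsq
    q_a <- crossprod(Yc, t_a) / tsq
    Xd <- Xd - tcrossprod(t_a, p_a)
    W[, a] <- w; P[, a] <- p_a; TT[, a] <- t_a; Q[, a] <- q_a
    pow[a] <- comp$power; ccs[a] <- comp$cc; tsqs[a] <- tsq
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Q) <- levels(y)
  # variance of Y explained per component (for VIP)
  ss_y <- colSums(Q^2) * tsqs
  lda_fit <- MASS::lda(TT, grouping = y)
  structure(list(loading_weights = W, loadings = P, scores = TT,
                 Yloadings = Q, powers = pow, canonical_corr = ccs,
                 tsqs = tsqs, ss_y = ss_y, Xmeans = Xmeans,
                 projection = W %*% solve(crossprod(P, W)),
                 labels = y, lda = lda_fit, n_components = a_max,
                 power_grid = power_grid),
            class = "cppls_model")
}

#' @export
print.cppls_model <- function(x, ...) {
  cat(sprintf("<cppls_model> %d components, %d molecules, classes: %s\n",
              x$n_components, nrow(x$loading_weights),
              paste(levels(x$labels), collapse = "/")))
  cat("powers:", paste(sprintf("%.2f", x$powers), collapse = " "), "\n")
  invisible(x)
}

#' Predict classes and class posteriors from a CPPLS-DA model
#'
#' @param object a `cppls_model`
#' @param newdata samples x molecules matrix with the same molecules the
#'   model was fit on
#' @param ... unused
#' @return list with `class` (factor) and `posterior` (matrix of class
#'   posterior probabilities from the LDA on the scores)
#' @export
predict.cppls_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$Xmeans))
  scores <- sweep(newdata, 2, object$Xmeans) %*% object$projection
  pr <- stats::predict(object$lda, scores)
  post <- pr$posterior
  # classes absent from the training fold get posterior 0
  all_lev <- levels(object$labels)
  if (!all(all_lev %in% colnames(post))) {
    full <- matrix(0, nrow(post), length(all_lev),
                   dimnames = list(NULL, all_lev))
    full[, colnames(post)] <- post
    post <- full
  }
  list(class = factor(as.character(pr$class), levels = all_lev),
       posterior = post)
}

#' Variable importance in projection
#'
#' Standard multi-component VIP:
#' \deqn{VIP_j = \sqrt{m \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' where \eqn{SS_a} is the variance of the dummy response explained by
#' component a.  The scores are normalized so that the mean squared VIP
#' over molecules is exactly one.
#'
#' @param model a fitted `cppls_model`
#' @return a `vip_ranking`: data.frame with `molecule`, `vip`, `rank`
#'   (1 = most important)
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "cppls_model"))
  ss <- model$ss_y
  if (all(ss <= 0)) stop("zero explained variance in all components")
  W2 <- model$loading_weights^2          # columns already unit norm
  m <- nrow(W2)
  vip <- sqrt(m * as.vector(W2 %*% ss) / sum(ss))
  out <- data.frame(molecule = rownames(model$loading_weights), vip = vip,
                    row.names = NULL)
  out$rank <- rank(-out$vip, ties.method = "first")
  structure(out[order(out$rank), ], class = c("vip_ranking", "data.frame"))
}
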