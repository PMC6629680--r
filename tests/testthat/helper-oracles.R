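# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (brute force / textbook formulas)
# and must stay independent of the package implementation it checks.

# --- NIPALS PLS2: textbook first-weight iteration, used as the oracle
#     for the CPPLS power = 0.5 equivalence -------------------------------
nipals_pls_weights <- function(X, Y, n_components = 1, tol = 1e-12,
                               maxit = 5000) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  W <- matrix(0, ncol(X), n_components)
  for (a in seq_len(n_components)) {
    u <- Y[, 1]
    w_old <- rep(Inf, ncol(X))
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)
      w <- w / sqrt(sum(w^2))
      t_ <- X %*% w
      q <- crossprod(Y, t_) / sum(t_^2)
      u <- Y %*% q / sum(q^2)
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    t_ <- X %*% w
    p <- crossprod(X, t_) / sum(t_^2)
    X <- X - tcrossprod(t_, p)
    Y <- Y - tcrossprod(t_, crossprod(Y, t_) / sum(t_^2))
    W[, a] <- w
  }
  W
}

# --- brute-force AUC: count over all positive/negative pairs ------------
auc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# --- adjusted Rand index (textbook contingency formula) -----------------
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# --- small deterministic concentration fixtures -------------------------
toy_conc <- function(m = 4, n = 6, seed = 1, classes = "TAG") {
  set.seed(seed)
  vals <- matrix(exp(rnorm(m * n)), m, n,
                 dimnames = list(sprintf("M%02d", 1:m),
                                 sprintf("S%02d", 1:n)))
  conc_matrix(vals, mol_class = classes)
}

toy_clinical <- function(n = 6, groups = c("SCN", "LGD"), seed = 1) {
  set.seed(seed)
  clinical_table(data.frame(
    sample_id = sprintf("S%02d", 1:n),
    group = factor(rep(groups, length.out = n), levels = groups),
    fluid = "cyst",
    age = round(runif(n, 40, 80), 1),
    bmi = round(runif(n, 21, 34), 1),
    ca19_9 = exp(runif(n, 1, 5)),
    albumin = runif(n, 20, 40),
    bilirubin = exp(runif(n, 1, 4))))
}

# a cohort with an effect table carrying a log-2 contrast between the
# first two groups for the first `n_inf` molecules, and background group
# effects drawn from the model (scale `bg`), rows centered
make_effect_table <- function(m, groups, n_inf, bg = 0.25, seed = 1,
                              contrast = log(2)) {
  set.seed(seed)
  k <- length(groups)
  eff <- matrix(rnorm(m * k, 0, bg), m, k, dimnames = list(NULL, groups))
  eff <- eff - rowMeans(eff)
  if (n_inf > 0) {
    a <- contrast / 2
    row <- c(-a, a, rep(0, k - 2))
    eff[seq_len(n_inf), ] <- matrix(row - mean(row), n_inf, k, byrow = TRUE)
  }
  eff
}

# separable two-group matrix for classification tests: `n_inf` molecules
# shifted by `delta` in group B, the rest pure noise
make_separable_X <- function(n = 40, m = 20, n_inf = 5, delta = 2,
                             seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("S%02d", 1:n),
                              sprintf("M%03d", 1:m)))
  X[y == "B", seq_len(n_inf)] <- X[y == "B", seq_len(n_inf)] + delta
  list(X = X, y = y)
}
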