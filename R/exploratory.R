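#' Principal component projection of the adjusted matrix
#'
#' SVD-based PCA of the (already standardized) samples x molecules
#' matrix.  Sign convention: within each component the loading with the
#' largest magnitude is made positive, so projections are reproducible
#' across platforms.
#'
#' @param adj samples x molecules matrix (typically an
#'   `adjusted_matrix`: per-molecule mean 0, sd 1)
#' @param n_components number of components to return (default 2)
#' @return a `pca_result`: list with `scores` (samples x components),
#'   `loadings` (molecules x components, orthonormal) and `explained`
#'   (fractions of total variance, non-increasing, all components)
#' @export
pca_project <- function(adj, n_components = 2) {
  X <- as.matrix(adj)
  if (n_components > nrow(X))
    stop("fewer samples than requested components")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(nc), drop = FALSE]
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  for (a in seq_len(nc)) {
    imax <- which.max(abs(load[, a]))
    if (load[imax, a] < 0) {
      load[, a] <- -load[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = load, explained = expl),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
                    collapse = " ")))
  invisible(x)
}

#' Ward / Euclidean clustering orders for heatmap rendering
#'
#' Agglomerative clustering with Ward's method on Euclidean distances,
#' in both the sample and the molecule dimension; returns the leaf
#' orders and the dendrograms.
#'
#' @param adj samples x molecules matrix, complete and finite
#' @return list with `sample_order`, `molecule_order` (integer leaf
#'   orders), `sample_hclust`, `molecule_hclust`
#' @export
ward_cluster_order <- function(adj) {
  X <- as.matrix(adj)
  if (any(!is.finite(X))) stop("non-finite entries in matrix")
  hs <- stats::hclust(stats::dist(X), method = "ward.D2")
  hm <- stats::hclust(stats::dist(t(X)), method = "ward.D2")
  list(sample_order = hs$order, molecule_order = hm$order,
       sample_hclust = hs, molecule_hclust = hm)
}

#' Pearson screen against clinical blood markers
#'
#' Correlates every molecule with each clinical marker (by default
#' CA19-9, albumin, bilirubin), adjusts the p-values across the full
#' molecule x marker grid (Benjamini--Hochberg), and flags hits with
#' |r| above the threshold and adjusted p at or below `alpha`.  The
#' absolute value is used because negative correlations are findings
#' too.
#'
#' @param adj samples x molecules matrix (adjusted log-scale data)
#' @param clinical a [clinical_table()] with the marker columns
#' @param markers marker column names (default CA19-9 / albumin /
#'   bilirubin); each needs >= 5 non-missing values.  Constant markers
#'   are excluded with a warning.
#' @param r_threshold absolute correlation threshold (default 0.6)
#' @param alpha adjusted-p threshold (default 0.05)
#' @param adjust p-adjustment method (default `"BH"`)
#' @return data.frame with `molecule`, `class`, `marker`, `r`, `p`, `q`,
#'   `direction` ("positive"/"negative") and `hit`
#' @export
marker_correlations <- function(adj, clinical,
                                markers = c("ca19_9", "albumin", "bilirubin"),
                                r_threshold = 0.6, alpha = 0.05,
                                adjust = "BH") {
  X <- as.matrix(adj)
  cl <- align_clinical(clinical, rownames(X))
  mcls <- attr(adj, "mol_class")
  keep <- character(0)
  for (mk in markers) {
    if (!mk %in% names(cl)) stop("marker '", mk, "' not in clinical table")
    v <- cl[[mk]]
    if (sum(!is.na(v)) < 5)
      stop("marker '", mk, "' has fewer than 5 non-missing values")
    if (stats::sd(v, na.rm = TRUE) == 0) {
      warning("marker '", mk, "' is constant; excluded from the screen")
      next
    }
    keep <- c(keep, mk)
  }
  rows <- list()
  for (mk in keep) {
    v <- cl[[mk]]
    for (j in seq_len(ncol(X))) {
      ok <- !is.na(v) & !is.na(X[, j])
      ct <- stats::cor.test(X[ok, j], v[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        molecule = colnames(X)[j],
        class = if (is.null(mcls)) NA_character_
                else unname(mcls[colnames(X)[j]]),
        marker = mk, r = unname(ct$estimate), p = ct$p.value,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = adjust)
  out$direction <- ifelse(out$r >= 0, "positive", "negative")
  out$hit <- abs(out$r) > r_threshold & out$q <= alpha
  out
}
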