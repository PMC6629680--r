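#' Posterior fold changes between two groups
#'
#' The fold change of molecule j between groups g and h is
#' \eqn{e^{\eta_{gj} - \eta_{hj}}}, computed within each posterior draw
#' and summarized by the posterior median and the equal-tailed 95 percent
#' credibility interval.  A molecule is flagged significant when the
#' interval does not contain the null value of one.
#'
#' @param draws a `posterior_draws` from [fit_hier_model()]
#' @param g,h group labels (must differ)
#' @param prob interval mass (default 0.95)
#' @return a `fold_change_table`: data.frame with columns `molecule`,
#'   `class`, `fc`, `lo95`, `hi95`, `significant`, plus attributes
#'   `groups` (c(g, h)) and `n_draws`.
#' @export
fold_changes <- function(draws, g, h, prob = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (identical(g, h)) stop("g and h must be different groups")
  for (lab in c(g, h))
    if (!lab %in% draws$groups)
      stop("unknown group label '", lab, "'")
  lfc <- draws$eta[, g, , drop = TRUE] - draws$eta[, h, , drop = TRUE]
  lfc <- matrix(lfc, nrow = draws$n_draws)        # draws x molecules
  fc <- exp(lfc)
  a <- (1 - prob) / 2
  qs <- matrixStats::colQuantiles(fc, probs = c(a, 0.5, 1 - a))
  out <- data.frame(molecule = draws$molecules,
                    class = if (is.null(draws$mol_class)) NA_character_
                            else unname(draws$mol_class[draws$molecules]),
                    fc = qs[, 2], lo95 = qs[, 1], hi95 = qs[, 3],
                    row.names = NULL)
  out$significant <- out$lo95 > 1 | out$hi95 < 1
  structure(out, groups = c(g, h), n_draws = draws$n_draws,
            class = c("fold_change_table", "data.frame"))
}

#' Adjust the matrix for confounders and standardize
#'
#' Subtracts the posterior-mean covariate effects (plug-in adjustment)
#' from each log concentration and then standardizes every molecule to
#' mean zero and unit variance across samples.  The result is the input
#' for visualization, PCA, clustering and classification.
#'
#' @param pre a `preprocessed_matrix`
#' @param clinical a [clinical_table()]
#' @param draws a `posterior_draws` whose model included the covariates
#'   to adjust for
#' @param covariates covariates to remove; default: all covariates in the
#'   fitted model
#' @return an `adjusted_matrix`: samples x molecules numeric matrix
#'   (analysis orientation) with attribute `mol_class`.
#' @export
adjust_matrix <- function(pre, clinical, draws,
                          covariates = draws$covariates) {
  stopifnot(inherits(draws, "posterior_draws"))
  vals <- if (inherits(pre, "preprocessed_matrix")) pre$values else as.matrix(pre)
  cl <- align_clinical(clinical, colnames(vals))
  missing_cov <- setdiff(covariates, draws$covariates)
  if (length(missing_cov))
    stop("covariate(s) not in the fitted model: ",
         paste(missing_cov, collapse = ", "))
  Y <- t(vals)                                    # samples x molecules
  for (v in covariates) {
    x <- (cl[[v]] - draws$cov_center[[v]]) / draws$cov_scale[[v]]
    gbar <- colMeans(matrix(draws$gamma[, v, ], nrow = draws$n_draws))
    Y <- Y - outer(x, gbar)
  }
  Y <- scale(Y)                                   # per molecule: mean 0, sd 1
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  structure(Y, mol_class = if (inherits(pre, "preprocessed_matrix"))
    pre$mol_class else NULL, class = c("adjusted_matrix", "matrix", "array"))
}

#' @export
print.adjusted_matrix <- function(x, ...) {
  cat(sprintf("<adjusted_matrix> %d samples x %d molecules (confounder-adjusted, standardized)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Write a fold-change table as TSV
#'
#' Columns: molecule, class, fc, lo95, hi95, significant.
#'
#' @param fc a `fold_change_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fold_changes <- function(fc, path) {
  utils::write.table(as.data.frame(fc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
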