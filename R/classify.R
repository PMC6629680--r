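#' Binary classification metrics
#'
#' Sensitivity = true positive rate, specificity = true negative rate,
#' balanced accuracy = (sensitivity + specificity) / 2, and AUC computed
#' as the Mann--Whitney statistic over all positive/negative score pairs
#' (ties count one half).
#'
#' @param sensitivity,specificity numeric in \[0, 1\]
#' @return balanced accuracy, exactly `(sensitivity + specificity) / 2`
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  (sensitivity + specificity) / 2
}

#' @rdname balanced_accuracy
#' @param scores numeric vector of continuous classifier scores (higher =
#'   more positive)
#' @param positive logical vector: is each sample a true positive?
#' @export
auc_score <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  pos <- scores[positive]; neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# confusion-derived one-vs-rest metrics for one positive class
ovr_metrics <- function(pred, truth, positive) {
  is_pos <- truth == positive
  pred_pos <- pred == positive
  sens <- if (any(is_pos)) mean(pred_pos[is_pos]) else NA_real_
  spec <- if (any(!is_pos)) mean(!pred_pos[!is_pos]) else NA_real_
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = balanced_accuracy(sens, spec))
}

#' Leave-one-out cross-validated CPPLS-DA performance
#'
#' For each sample the model is refit on the remaining n - 1 samples and
#' the held-out sample is predicted (class label and class posterior
#' probabilities).  Held-out predictions are aggregated into one-vs-rest
#' sensitivity, specificity, balanced accuracy, and AUC (from the
#' held-out posteriors) per class.  Deterministic: no randomness is
#' involved.
#'
#' If a training fold loses an entire class, that fold's prediction falls
#' back to the training-fold majority class (prior-frequency rule) and a
#' warning is logged.
#'
#' @param X samples x molecules matrix
#' @param y class labels
#' @param n_components number of CPPLS components
#' @param power_grid candidate powers (see [fit_cppls()])
#' @return a `classification_report`: data.frame with one row per class
#'   (`task` = "<class> vs All"), columns `auc`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`; held-out predictions attached as
#'   attributes `predicted` and `posterior`.
#' @export
loocv_evaluate <- function(X, y, n_components = 2,
                           power_grid = seq(0.05, 0.95, by = 0.05)) {
  X <- as.matrix(X); y <- droplevels(factor(y))
  n <- nrow(X); k <- nlevels(y)
  if (n < k + 2) stop("need at least k + 2 samples for LOO-CV")
  lev <- levels(y)
  post <- matrix(NA_real_, n, k, dimnames = list(NULL, lev))
  pred <- character(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) {
      warning("training fold ", i, " lost all but one class; ",
              "falling back to the majority-class rule")
      tab <- table(y[-i])
      pred[i] <- names(tab)[which.max(tab)]
      post[i, ] <- as.numeric(tab[lev] / sum(tab))
      next
    }
    ncomp_i <- min(n_components, n - 2, ncol(X))
    fit <- fit_cppls(X[-i, , drop = FALSE], y[-i], n_components = ncomp_i,
                     power_grid = power_grid)
    pr <- predict(fit, X[i, , drop = FALSE])
    pred[i] <- as.character(pr$class)
    post[i, ] <- pr$posterior[1, lev]
  }
  pred <- factor(pred, levels = lev)
  rows <- lapply(lev, function(cls) {
    mt <- ovr_metrics(pred, y, cls)
    data.frame(task = paste(cls, "vs All"),
               auc = auc_score(post[, cls], y == cls),
               sensitivity = mt["sensitivity"],
               specificity = mt["specificity"],
               balanced_accuracy = mt["balanced_accuracy"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  structure(out, predicted = pred, posterior = post,
            class = c("classification_report", "data.frame"))
}

# mean balanced accuracy across one-vs-rest tasks: the scalar criterion
# used for component selection and for picking the elimination step
report_score <- function(report) mean(report$balanced_accuracy, na.rm = TRUE)

#' Choose the number of CPPLS components by LOO-CV
#'
#' Maximizes the mean one-vs-rest LOO-CV balanced accuracy over
#' `1..min(max_components, n - 2, m)`.  Ties go to the smaller model.
#'
#' @inheritParams loocv_evaluate
#' @param max_components upper cap (default 8)
#' @return list with `n_components` and the score per candidate
#' @export
select_ncomp <- function(X, y, max_components = 8,
                         power_grid = seq(0.05, 0.95, by = 0.05)) {
  X <- as.matrix(X)
  cand <- seq_len(min(max_components, nrow(X) - 2, ncol(X)))
  score <- vapply(cand, function(a)
    report_score(loocv_evaluate(X, y, n_components = a,
                                power_grid = power_grid)), numeric(1))
  list(n_components = cand[which.max(score)],
       scores = data.frame(n_components = cand, score = score))
}

#' Recursive VIP-based feature elimination
#'
#' Iterates: (1) record the LOO-CV performance of the current feature
#' set; (2) fit CPPLS-DA on all samples and rank molecules by VIP;
#' (3) drop the `max(1, floor(drop_fraction * m))` molecules with the
#' lowest VIP (ties at the boundary: alphabetically-last IDs drop
#' first).  The loop stops when fewer than `n_components + 1` molecules
#' would remain, and the feature set with the highest LOO-CV balanced
#' accuracy (mean over one-vs-rest tasks; ties broken toward fewer
#' molecules) is selected.
#'
#' @param X samples x molecules matrix
#' @param y class labels
#' @param drop_fraction fraction of current molecules dropped per step
#'   (default 0.05)
#' @param n_components number of components; `NULL` (default) selects it
#'   once by [select_ncomp()] before elimination begins
#' @param power_grid candidate powers
#' @param max_components cap for [select_ncomp()]
#' @return an `elimination_result`: list with `trace` (one row per step:
#'   step, n_retained, mean balanced accuracy, mean AUC), `selected`
#'   (character vector of molecules), `best_step`, `n_components`,
#'   `reports` (full per-step classification reports), `final_report`
#'   (report of the selected set) and `vip` (data.frame of molecule, VIP
#'   at the step before it was dropped, and `dropped_at_step`, `NA` when
#'   it survived).
#' @export
recursive_elimination <- function(X, y, drop_fraction = 0.05,
                                  n_components = NULL,
                                  power_grid = seq(0.05, 0.95, by = 0.05),
                                  max_components = 8) {
  X <- as.matrix(X); y <- droplevels(factor(y))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("M%03d", seq_len(ncol(X)))
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must be in (0, 1)")
  if (is.null(n_components))
    n_components <- select_ncomp(X, y, max_components = max_components,
                                 power_grid = power_grid)$n_components
  keep <- colnames(X)
  trace <- list(); reports <- list()
  vip_last <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  dropped_at <- stats::setNames(rep(NA_integer_, ncol(X)), colnames(X))
  sets <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    Xs <- X[, keep, drop = FALSE]
    rep_s <- loocv_evaluate(Xs, y, n_components = n_components,
                            power_grid = power_grid)
    trace[[step]] <- data.frame(step = step, n_retained = length(keep),
                                balanced_accuracy = report_score(rep_s),
                                auc = mean(rep_s$auc, na.rm = TRUE))
    reports[[step]] <- rep_s
    sets[[step]] <- keep
    fit <- fit_cppls(Xs, y, n_components = n_components,
                     power_grid = power_grid)
    vip <- vip_scores(fit)
    vip_last[vip$molecule] <- vip$vip
    n_drop <- max(1L, floor(drop_fraction * length(keep)))
    if (length(keep) - n_drop < n_components + 1) break
    # lowest VIP first; ties broken by reverse-alphabetical molecule ID
    ord <- order(vip$vip,
                 -xtfrm(vip$molecule))
    drop_ids <- vip$molecule[ord][seq_len(n_drop)]
    dropped_at[drop_ids] <- step
    keep <- setdiff(keep, drop_ids)
  }
  tr <- do.call(rbind, trace)
  best <- order(-tr$balanced_accuracy, tr$n_retained)[1]
  structure(list(trace = tr, selected = sets[[best]], best_step = best,
                 n_components = n_components, reports = reports,
                 final_report = reports[[best]],
                 vip = data.frame(molecule = names(vip_last),
                                  vip = unname(vip_last),
                                  dropped_at_step = unname(dropped_at),
                                  row.names = NULL)),
            class = "elimination_result")
}

#' @export
print.elimination_result <- function(x, ...) {
  cat(sprintf("<elimination_result> %d steps, selected %d molecules (step %d), balanced accuracy %.3f\n",
              nrow(x$trace), length(x$selected), x$best_step,
              x$trace$balanced_accuracy[x$best_step]))
  invisible(x)
}

#' Write a classification report as TSV
#'
#' Columns mirror the published performance table: task, fluid (if
#' given), AUC, sensitivity, specificity, balanced accuracy.
#'
#' @param report a `classification_report`
#' @param path output file
#' @param fluid optional fluid label column
#' @return `path`, invisibly
#' @export
write_classification_report <- function(report, path, fluid = NA_character_) {
  df <- as.data.frame(report)
  df <- cbind(task = df$task, fluid = fluid,
              df[, c("auc", "sensitivity", "specificity",
                     "balanced_accuracy")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
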