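#' Clinical covariate table
#'
#' Per-sample clinical covariates and the histological diagnosis label.
#' Required columns are `sample_id`, `group` (e.g. SCN / LGD / HGD /
#' Cancer), `fluid` (`"cyst"` or `"plasma"`), `age` (years) and `bmi`
#' (kg/m^2).  Additional columns (sex, statin use, diabetes, CA19-9,
#' albumin, bilirubin, ...) are carried along and can be used as candidate
#' covariates or correlation markers.
#'
#' @param df a data.frame with at least the required columns.
#' @return the validated data.frame with class `clinical_table`, `group`
#'   converted to factor (existing level order preserved).
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "group", "fluid", "age", "bmi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  if (!is.factor(df$group)) df$group <- factor(df$group)
  if (any(is.na(df$group)))
    stop("sample(s) without group label: ",
         paste(df$sample_id[is.na(df$group)], collapse = ", "))
  if (!all(df$fluid %in% c("cyst", "plasma")))
    stop("fluid must be 'cyst' or 'plasma'")
  if (!is.numeric(df$age) || !is.numeric(df$bmi))
    stop("age and bmi must be numeric")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Merge diagnosis groups
#'
#' Collapse several diagnosis labels into one, e.g. HGD and Cancer into a
#' combined high-risk group, or all IPMN grades into a single IPMN label
#' for the IPMN-vs-SCN task.  Any downstream model must be refit after
#' merging (the number of groups k changes).
#'
#' @param clinical a `clinical_table`
#' @param labels_to_merge character vector of existing group labels
#' @param new_label single character; must not collide with a label that
#'   is *not* being merged.
#' @return the relabeled `clinical_table`
#' @examples
#' cl <- clinical_table(data.frame(
#'   sample_id = paste0("s", 1:4),
#'   group = c("SCN", "LGD", "HGD", "Cancer"),
#'   fluid = "cyst", age = 60, bmi = 25))
#' table(merge_groups(cl, c("HGD", "Cancer"), "HGD/Cancer")$group)
#' @export
merge_groups <- function(clinical, labels_to_merge, new_label) {
  stopifnot(inherits(clinical, "clinical_table"))
  lev <- levels(clinical$group)
  unknown <- setdiff(labels_to_merge, lev)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(lev, labels_to_merge)
  if (new_label %in% keep)
    stop("new label '", new_label, "' collides with an existing unmerged group")
  g <- as.character(clinical$group)
  g[g %in% labels_to_merge] <- new_label
  # preserve original ordering: merged label takes the position of the
  # first merged level
  first <- match(labels_to_merge[1], lev)
  newlev <- lev
  newlev[first] <- new_label
  newlev <- newlev[!newlev %in% labels_to_merge]
  clinical$group <- factor(g, levels = unique(newlev))
  clinical
}

# internal: check that clinical rows line up with matrix samples
align_clinical <- function(clinical, sample_ids) {
  stopifnot(inherits(clinical, "clinical_table"))
  idx <- match(sample_ids, clinical$sample_id)
  if (anyNA(idx))
    stop("samples absent from clinical table: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  out <- clinical[idx, , drop = FALSE]
  out$group <- droplevels(out$group)
  out
}
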