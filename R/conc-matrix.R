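#' Concentration matrix container
#'
#' A `conc_matrix` holds a molecules x samples table of (semi)quantitative
#' concentrations in umol/L, together with a per-molecule class annotation
#' (lipid classes such as TAG, FFA, CER, PC, ... or metabolite classes such
#' as "amino acid").  Missing entries are stored as `NA` and are assumed to
#' be left-censored (missing-not-at-random at low concentration).
#'
#' @param values numeric matrix, molecules in rows, samples in columns.
#'   Must have row and column names (molecule IDs and sample IDs).
#' @param mol_class character vector of molecule classes, one per row of
#'   `values` (recycled if length 1).
#' @param log_scale logical; `TRUE` once the matrix has been log-transformed.
#'
#' @return An object of class `conc_matrix`: the numeric matrix with
#'   attributes `mol_class` (named character) and `log_scale`.
#' @export
conc_matrix <- function(values, mol_class = "unknown", log_scale = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("concentration values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("concentration matrix needs molecule rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate molecule IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  mol_class <- rep_len(as.character(mol_class), nrow(values))
  names(mol_class) <- rownames(values)
  structure(values,
            mol_class = mol_class,
            log_scale = isTRUE(log_scale),
            class = c("conc_matrix", "matrix", "array"))
}

#' @export
print.conc_matrix <- function(x, ...) {
  cat(sprintf("<conc_matrix> %d molecules x %d samples (%s scale), %d missing (%.1f%%)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "log_scale"))) "log" else "natural",
              sum(is.na(x)), 100 * mean(is.na(x))))
  cls <- table(attr(x, "mol_class"))
  cat("classes:", paste(sprintf("%s(%d)", names(cls), cls), collapse = " "),
      "\n")
  invisible(x)
}

#' Molecule class annotations
#' @param x a `conc_matrix`
#' @return named character vector of molecule classes
#' @export
mol_class <- function(x) attr(x, "mol_class")

#' Is the matrix on the log scale?
#' @param x a `conc_matrix`
#' @return logical scalar
#' @export
is_log_scale <- function(x) isTRUE(attr(x, "log_scale"))

#' Subset a concentration matrix, keeping annotations
#'
#' `[` on a plain matrix drops attributes; use this to subset molecules
#' and/or samples while keeping the class annotation in sync.
#'
#' @param x a `conc_matrix`
#' @param rows,cols row / column index (any form accepted by `[`);
#'   `NULL` keeps all.
#' @return a `conc_matrix`
#' @export
cm_subset <- function(x, rows = NULL, cols = NULL) {
  stopifnot(inherits(x, "conc_matrix"))
  if (is.null(rows)) rows <- seq_len(nrow(x))
  if (is.null(cols)) cols <- seq_len(ncol(x))
  vals <- unclass(x)[rows, cols, drop = FALSE]
  conc_matrix(vals, mol_class = attr(x, "mol_class")[rows],
              log_scale = attr(x, "log_scale"))
}

# internal: strict validation used at module boundaries
check_conc_matrix <- function(x, complete = FALSE) {
  if (!inherits(x, "conc_matrix"))
    stop("expected a conc_matrix (see ?conc_matrix)")
  if (complete && anyNA(x))
    stop("matrix still contains missing values; run qrilc_impute() first")
  invisible(x)
}
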