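# File formats: molecules are rows on disk (omics convention), the
# first two columns are `molecule` and `class`, remaining columns are
# sample IDs; empty cells or "NA" denote missing values.

#' Read a concentration CSV
#'
#' @param path CSV file: header `molecule,class,<sample ids...>`; one row
#'   per molecule.  Empty cells or `"NA"` are missing.  Duplicate
#'   molecule IDs, ragged rows, or non-numeric non-missing cells are
#'   parse errors reporting the offending line.
#' @return a [conc_matrix()]
#' @export
read_concentration_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 3 || header[1] != "molecule" || header[2] != "class")
    stop("expected header 'molecule,class,<sample ids>' in ", path)
  samples <- header[-(1:2)]
  n <- length(samples)
  body <- cells[-1]
  vals <- matrix(NA_real_, length(body), n)
  ids <- character(length(body)); cls <- character(length(body))
  for (r in seq_along(body)) {
    row <- body[[r]]
    length(row) <- 2 + n            # pad trailing empties with NA
    if (sum(!is.na(row)) < 2 || (length(body[[r]]) > 2 + n))
      stop("parse error at line ", r + 1, ": expected ", 2 + n,
           " fields, got ", length(body[[r]]))
    ids[r] <- row[1]; cls[r] <- row[2]
    raw <- row[-(1:2)]
    miss <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- !miss & is.na(num)
    if (any(bad))
      stop("parse error at line ", r + 1, ": non-numeric value '",
           raw[which(bad)[1]], "' for sample ", samples[which(bad)[1]])
    vals[r, ] <- num
  }
  if (anyDuplicated(ids))
    stop("parse error: duplicate molecule ID '",
         ids[duplicated(ids)][1], "' (line ",
         which(duplicated(ids))[1] + 1, ")")
  dimnames(vals) <- list(ids, samples)
  conc_matrix(vals, mol_class = cls)
}

#' Write a concentration CSV
#' @param mat a [conc_matrix()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_concentration_csv <- function(mat, path) {
  check_conc_matrix(mat)
  df <- data.frame(molecule = rownames(mat),
                   class = unname(mol_class(mat)),
                   unclass(mat), check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write the clinical covariate CSV (samples as rows)
#' @param path CSV file with a `sample_id` column and the columns
#'   required by [clinical_table()]
#' @return a [clinical_table()]
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = unique(df$group))
  clinical_table(df)
}

#' @rdname read_clinical_csv
#' @param clinical a [clinical_table()]
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' Write the missingness filtering report as TSV
#' @param report the `report` element of [modified_80_rule()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
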