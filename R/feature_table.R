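#' Patient-by-feature table with mixed nominal/numeric columns
#'
#' The basic container for clinical and imaging data: a data frame of
#' features (nominal columns stored as character, numeric as double), an
#' explicit type tag per column, an optional binary relapse label and a
#' per-row flag marking synthetic (SMOTE-generated) patients.
#'
#' @param data data.frame of feature columns (no label column).
#' @param types named character vector, one of `"nominal"` or `"numeric"`
#'   per column of `data`. Inferred from column classes when `NULL`.
#' @param label optional integer vector of 0/1 relapse outcomes, one per row.
#' @param patient_ids optional character ids; defaults to `P001`, `P002`, ...
#' @param synthetic optional logical per row; `TRUE` marks oversampled rows.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(data, types = NULL, label = NULL,
                          patient_ids = NULL, synthetic = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (j in seq_along(data)) {
    if (is.factor(data[[j]])) data[[j]] <- as.character(data[[j]])
  }
  if (is.null(types)) {
    types <- vapply(data, function(col)
      if (is.numeric(col)) "numeric" else "nominal", character(1))
  }
  types <- types[names(data)]
  if (anyNA(types) || !all(types %in% c("nominal", "numeric")))
    stop("every column needs a type tag 'nominal' or 'numeric'")
  if (!is.null(label)) {
    if (length(label) != nrow(data))
      stop("label length must equal the number of patients")
    label <- as.integer(label)
    if (!all(label %in% c(0L, 1L))) stop("label must be binary 0/1")
  }
  if (is.null(patient_ids))
    patient_ids <- sprintf("P%03d", seq_len(nrow(data)))
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(data))
  structure(list(data = data, types = types, label = label,
                 patient_ids = as.character(patient_ids),
                 synthetic = synthetic),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features (%d nominal, %d numeric)\n",
              nrow(x$data), ncol(x$data),
              sum(x$types == "nominal"), sum(x$types == "numeric")))
  if (!is.null(x$label))
    cat(sprintf("  label: %d relapsers / %d non-relapsers\n",
                sum(x$label == 1L), sum(x$label == 0L)))
  if (any(x$synthetic))
    cat(sprintf("  %d synthetic (SMOTE) rows\n", sum(x$synthetic)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$data)

# Row subset preserving all slots.
ft_subset <- function(t, i) {
  feature_table(t$data[i, , drop = FALSE], types = t$types,
                label = if (!is.null(t$label)) t$label[i],
                patient_ids = t$patient_ids[i],
                synthetic = t$synthetic[i])
}

# Column subset (by feature name), label untouched.
ft_select <- function(t, cols) {
  feature_table(t$data[, cols, drop = FALSE], types = t$types[cols],
                label = t$label, patient_ids = t$patient_ids,
                synthetic = t$synthetic)
}

#' Write a feature table as TSV
#'
#' Missing values are written as `NA`; when a label is present it is
#' appended as a final `relapse` column in 0/1 coding.
#'
#' @param t a [feature_table()].
#' @param path output file path.
#' @export
write_feature_table <- function(t, path) {
  out <- t$data
  out <- cbind(patient_id = t$patient_ids, out, stringsAsFactors = FALSE)
  if (!is.null(t$label)) out$relapse <- t$label
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path; a final `relapse` column, if present, becomes the
#'   label. Column types are re-inferred (character = nominal).
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  ids <- raw$patient_id
  raw$patient_id <- NULL
  label <- NULL
  if ("relapse" %in% names(raw)) {
    label <- raw$relapse
    raw$relapse <- NULL
  }
  feature_table(raw, label = label, patient_ids = ids)
}
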