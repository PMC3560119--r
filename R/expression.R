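#' Probe-by-sample expression matrix with probe annotation
#'
#' Intensities are stored on the log2 scale (one-channel array convention).
#' The annotation carries the probe-level QC flags consumed by
#' [filter_probes()]: control status, duplicate-group membership, a low
#' quality flag and the per-probe fraction of missing values.
#'
#' @param values numeric matrix, probes in rows, samples in columns; must
#'   carry rownames (probe ids) and colnames (sample ids).
#' @param annotation data.frame with columns `probe_id`, `is_control`
#'   (logical), `duplicate_of` (probe id or `NA`), `quality_flag` (logical)
#'   and `missing_frac` in `[0,1]`. Defaults to an all-clean annotation.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, annotation = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (is.null(annotation)) {
    annotation <- data.frame(probe_id = rownames(values),
                             is_control = FALSE,
                             duplicate_of = NA_character_,
                             quality_flag = FALSE,
                             missing_frac = rowMeans(is.na(values)),
                             stringsAsFactors = FALSE)
  }
  need <- c("probe_id", "is_control", "duplicate_of", "quality_flag",
            "missing_frac")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (!identical(annotation$probe_id, rownames(values)))
    stop("annotation rows must match probe order of the value matrix")
  structure(list(values = values, annotation = annotation),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  flags <- x$annotation
  cat(sprintf("  control: %d  duplicate: %d  low-quality: %d  missing>0.5: %d\n",
              sum(flags$is_control), sum(!is.na(flags$duplicate_of)),
              sum(flags$quality_flag), sum(flags$missing_frac > 0.5)))
  invisible(x)
}

#' Longitudinal blood-expression tensor over follow-up visits
#'
#' @param values 3-d numeric array, patients x genes x visits, with
#'   dimnames on all three margins.
#' @param relapse integer matrix (patients x visits) of 0/1 relapse states;
#'   relapse is absorbing (once 1, it stays 1 in later visits).
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(values, relapse) {
  stopifnot(length(dim(values)) == 3L, is.matrix(relapse),
            nrow(relapse) == dim(values)[1L],
            ncol(relapse) == dim(values)[3L])
  if (is.null(dimnames(values)))
    stop("timecourse values need dimnames (patients, genes, visits)")
  bad <- apply(relapse, 1L, function(r) any(diff(r) < 0))
  if (any(bad)) stop("relapse states must be absorbing within each patient")
  structure(list(values = values, relapse = relapse,
                 visits = dimnames(values)[[3L]]),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<timecourse> %d patients x %d genes x %d visits (%s)\n",
              d[1L], d[2L], d[3L], paste(x$visits, collapse = ", ")))
  cat(sprintf("  relapsers by final visit: %d\n",
              sum(x$relapse[, ncol(x$relapse)] == 1L)))
  invisible(x)
}

#' Write an expression matrix and its probe annotation as TSV
#'
#' @param m an [expression_matrix()].
#' @param path output TSV for intensities (rows = probes, columns = samples).
#' @param annotation_path optional output TSV for the probe annotation.
#' @export
write_expression_matrix <- function(m, path, annotation_path = NULL) {
  utils::write.table(data.frame(probe_id = rownames(m$values), m$values,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(annotation_path))
    utils::write.table(m$annotation, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a time course in long format
#'
#' Columns: `patient_id`, `visit`, `probe_id`, `value`.
#'
#' @param tc a [timecourse()].
#' @param path output TSV path.
#' @export
write_timecourse <- function(tc, path) {
  dn <- dimnames(tc$values)
  long <- expand.grid(patient_id = dn[[1L]], probe_id = dn[[2L]],
                      visit = dn[[3L]], stringsAsFactors = FALSE)
  long$value <- as.vector(tc$values)
  long <- long[, c("patient_id", "visit", "probe_id", "value")]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
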