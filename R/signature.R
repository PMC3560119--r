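#' Extract a patient's Personalized Genetic Signature
#'
#' Compares the pre-treatment (cancerous) and first-remission
#' (cancer-free) expression profiles of one patient on the log2 scale and
#' keeps the genes whose absolute difference reaches `threshold`; when no
#' gene passes, the `top_k` genes with the largest differences are used
#' as fallback so the signature is never empty (unless the two profiles
#' are identical). Each retained gene receives a weight proportional to
#' its absolute differential expression.
#'
#' @param cancerous named numeric vector: pre-treatment log2 profile.
#' @param cancer_free named numeric vector over the same probes: profile
#'   from the first stages of remission.
#' @param threshold minimum `|log2 difference|` for inclusion (default 1,
#'   i.e. a two-fold change).
#' @param top_k fallback size when no gene passes the threshold
#'   (default 50); set to 0 to disable the fallback.
#' @param patient_id optional identifier carried in the profile.
#' @return An object of class `signature_profile` with fields `gene_ids`,
#'   `cancerous`, `cancer_free`, `weights` (summing to 1) and the signed
#'   differential `d`.
#' @export
extract_signature <- function(cancerous, cancer_free, threshold = 1,
                              top_k = 50L, patient_id = NULL) {
  if (length(cancerous) != length(cancer_free))
    stop("profiles must cover the same probe set")
  if (!is.null(names(cancerous)) && !is.null(names(cancer_free)) &&
      !identical(names(cancerous), names(cancer_free)))
    stop("profiles must be aligned on the same probes")
  if (threshold <= 0) stop_field("threshold", "must be positive")
  ids <- names(cancerous) %||% sprintf("g%d", seq_along(cancerous))
  d <- cancerous - cancer_free
  pass <- which(abs(d) >= threshold)
  if (length(pass) == 0L && top_k > 0L) {
    nonzero <- which(abs(d) > 0)
    pass <- nonzero[order(-abs(d[nonzero]))]
    pass <- utils::head(pass, top_k)
  }
  if (length(pass) == 0L)
    stop("no differentially expressed gene: the cancerous and cancer-free ",
         "profiles are identical at this threshold; lower the threshold ",
         "or enable the top-k fallback")
  w <- abs(d[pass]) / sum(abs(d[pass]))
  structure(list(patient_id = patient_id, gene_ids = ids[pass],
                 cancerous = unname(cancerous[pass]),
                 cancer_free = unname(cancer_free[pass]),
                 weights = unname(w), d = unname(d[pass])),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("<signature_profile>%s %d genes, max |log2 diff| = %.2f\n",
              if (is.null(x$patient_id)) "" else paste0(" ", x$patient_id),
              length(x$gene_ids), max(abs(x$d))))
  invisible(x)
}

#' Weighted Euclidean distance between expression profiles
#'
#' `sqrt(sum_g w_g (x_g - ref_g)^2)`: the gene weights encode the
#' significance of each signature gene, so heavily differential genes
#' dominate the comparison. With uniform weights over k genes this equals
#' the ordinary Euclidean distance divided by `sqrt(k)`.
#'
#' @param x,ref aligned numeric vectors over the signature genes.
#' @param w nonnegative weights summing to 1.
#' @export
weighted_distance <- function(x, ref, w) {
  if (length(x) != length(ref) || length(x) != length(w))
    stop("x, ref and w must have equal length")
  if (any(w < 0)) stop("weights must be nonnegative")
  sqrt(sum(w * (x - ref)^2))
}

#' Track a patient's follow-up visits against both reference profiles
#'
#' Restricted to the signature genes, each visit is compared with the
#' cancerous and the cancer-free reference by Pearson correlation (the
#' qualitative measure) and weighted Euclidean distance (the quantitative
#' one). `closer_to` is the reference with the smaller weighted distance;
#' an exact tie resolves to `cancer_free` to avoid spurious alarms, and
#' the monitoring `flag` is raised when a visit sits closer to the
#' cancerous profile.
#'
#' @param profile a [signature_profile()].
#' @param visits a list (or single vector) of named expression vectors,
#'   one per follow-up visit, covering the signature genes.
#' @return A data.frame with one row per visit: `visit`,
#'   `corr_cancerous`, `corr_cancer_free`, `dist_cancerous`,
#'   `dist_cancer_free`, `closer_to`, `flag`. Correlations against a
#'   constant vector are reported as `NA` with distances still computed.
#' @export
track_trajectory <- function(profile, visits) {
  stopifnot(inherits(profile, "signature_profile"))
  if (!is.list(visits)) visits <- list(visits)
  if (length(visits) == 0L) stop("at least one visit is required")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  rows <- lapply(seq_along(visits), function(i) {
    v <- visits[[i]]
    if (!is.null(names(v))) {
      if (!all(profile$gene_ids %in% names(v)))
        stop("visit ", i, " does not cover the signature genes")
      v <- v[profile$gene_ids]
    } else if (length(v) != length(profile$gene_ids)) {
      stop("visit ", i, " has the wrong length")
    }
    dc <- weighted_distance(v, profile$cancerous, profile$weights)
    df <- weighted_distance(v, profile$cancer_free, profile$weights)
    closer <- if (dc < df) "cancerous" else "cancer_free"  # tie -> cancer_free
    vname <- names(visits)[i]
    if (is.null(vname) || is.na(vname) || vname == "")
      vname <- paste0("visit", i)
    data.frame(visit = vname,
               corr_cancerous = safe_cor(v, profile$cancerous),
               corr_cancer_free = safe_cor(v, profile$cancer_free),
               dist_cancerous = dc, dist_cancer_free = df,
               closer_to = closer, flag = closer == "cancerous",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
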