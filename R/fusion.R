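#' Weighted majority-vote fusion model
#'
#' @param sources character names of the per-source classifiers (clinical,
#'   imaging, tissue genomic, blood genomic, ...).
#' @param weights nonnegative weights, one per source; normalized to sum
#'   to 1.
#' @param tie_rule what a tied weighted vote resolves to; fixed to
#'   `"relapse"` (sensitivity-first: a false negative is the costly error
#'   in relapse surveillance).
#' @export
fusion_model <- function(sources, weights = NULL, tie_rule = "relapse") {
  stopifnot(length(sources) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(sources))
  if (length(weights) != length(sources) || any(weights < 0) ||
      sum(weights) == 0)
    stop("weights must be nonnegative, one per source, not all zero")
  structure(list(sources = sources,
                 weights = stats::setNames(weights / sum(weights), sources),
                 tie_rule = tie_rule),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model>\n")
  for (s in x$sources)
    cat(sprintf("  %-16s %.4f\n", s, x$weights[[s]]))
  invisible(x)
}

#' Fit fusion weights from per-source evaluation reports
#'
#' The paper-style consensus needs a weight per data source; here each
#' source's weight is proportional to its training-scheme accuracy
#' (`method = "accuracy"`), with uniform weighting available for
#' ablation.
#'
#' @param reports named list of `eval_report`s, one per source.
#' @param method `"accuracy"` or `"uniform"`.
#' @export
fit_fusion_weights <- function(reports, method = c("accuracy", "uniform")) {
  method <- match.arg(method)
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  w <- if (method == "uniform") rep(1, length(reports))
       else vapply(reports, function(r) r$accuracy, numeric(1))
  fusion_model(names(reports), w)
}

#' Fuse per-source predictions by weighted majority voting
#'
#' For each patient the weights of the sources voting relapse are summed;
#' the fused score is that sum divided by the total weight of the sources
#' available for the patient (sources may be missing per patient), and
#' the fused label is relapse when the score reaches 0.5 — an exact tie
#' resolves to relapse.
#'
#' @param predictions named list of per-source prediction data.frames
#'   (`patient_id`, `predicted_label`, `score`); names must match the
#'   fusion model's sources.
#' @param model a [fusion_model()].
#' @return A fused predictions data.frame.
#' @export
fuse <- function(predictions, model) {
  stopifnot(inherits(model, "fusion_model"), length(predictions) >= 1L)
  if (!all(names(predictions) %in% model$sources))
    stop("prediction sources must match the fusion model")
  ids <- unique(unlist(lapply(predictions, function(p) p$patient_id)))
  out <- data.frame(patient_id = ids, predicted_label = NA_integer_,
                    score = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    avail <- 0; vote1 <- 0
    for (s in names(predictions)) {
      p <- predictions[[s]]
      row <- match(ids[i], p$patient_id)
      if (is.na(row) || is.na(p$predicted_label[row])) next
      w <- model$weights[[s]]
      avail <- avail + w
      if (p$predicted_label[row] == 1L) vote1 <- vote1 + w
    }
    if (avail == 0)
      stop("no source available for patient ", ids[i])
    score <- vote1 / avail
    out$score[i] <- score
    out$predicted_label[i] <- as.integer(score >= 0.5)  # tie -> relapse
  }
  out
}
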