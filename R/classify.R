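#' Train a per-source relapse classifier
#'
#' Reference learners: `"nb"`, naive Bayes with Laplace-smoothed nominal
#' likelihoods and Gaussian numeric likelihoods (via \pkg{e1071}); `"dt"`,
#' a decision tree split on information gain with minimum-leaf and depth
#' stopping (via \pkg{rpart}). Any other learner (ANN, SVM, RF, BN, ...)
#' participates through the plugin contract: pass a factory
#' `function(table, seed)` that returns a scoring function
#' `function(new_table) -> numeric relapse probabilities`.
#'
#' @param t a complete (imputed), labeled [feature_table()].
#' @param kind `"nb"`, `"dt"`, or a plugin factory function.
#' @param seed integer seed forwarded to the learner.
#' @return An object of class `relapse_classifier` with a [predict()]
#'   method returning `patient_id`, `predicted_label` and `score`.
#' @export
train_classifier <- function(t, kind = "nb", seed = 1L) {
  stopifnot(inherits(t, "feature_table"))
  if (is.null(t$label)) stop("training requires a labeled table")
  if (anyNA(as.matrix(t$data))) stop("training requires a complete table")
  df <- t$data
  levels_map <- list()
  for (nm in names(df)) {
    if (t$types[[nm]] == "nominal") {
      df[[nm]] <- factor(df[[nm]])
      levels_map[[nm]] <- levels(df[[nm]])
    }
  }
  single_class <- length(unique(t$label)) < 2L
  if (is.function(kind)) {
    fit <- kind(t, seed)
    if (!is.function(fit))
      stop("a plugin factory must return a scoring function")
    kind_name <- "plugin"
  } else if (single_class) {
    const <- unique(t$label)
    fit <- const
    kind_name <- paste0(kind, "_constant")
  } else if (identical(kind, "nb")) {
    df$..y <- factor(t$label, levels = c(0L, 1L))
    fit <- e1071::naiveBayes(..y ~ ., data = df, laplace = 1)
    kind_name <- "nb"
  } else if (identical(kind, "dt")) {
    df$..y <- factor(t$label, levels = c(0L, 1L))
    fit <- withr::with_seed(seed,
      rpart::rpart(..y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(minsplit = 5L,
                                                  minbucket = 2L,
                                                  maxdepth = 10L,
                                                  cp = 0.01,
                                                  xval = 0L)))
    kind_name <- "dt"
  } else {
    stop("unknown classifier kind '", kind,
         "'; available kinds: nb, dt, or a plugin factory")
  }
  structure(list(kind = kind_name, fit = fit, features = names(t$data),
                 types = t$types, levels_map = levels_map, seed = seed),
            class = "relapse_classifier")
}

#' @export
predict.relapse_classifier <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_table"))
  if (object$kind == "plugin") {
    score <- as.numeric(object$fit(newdata))
  } else if (grepl("_constant$", object$kind)) {
    score <- rep(as.numeric(object$fit), nrow(newdata$data))
  } else {
    df <- newdata$data[, object$features, drop = FALSE]
    for (nm in names(object$levels_map))
      df[[nm]] <- factor(df[[nm]], levels = object$levels_map[[nm]])
    score <- if (object$kind == "nb") {
      as.numeric(stats::predict(object$fit, df, type = "raw")[, "1"])
    } else {
      as.numeric(stats::predict(object$fit, df, type = "prob")[, "1"])
    }
  }
  score <- pmin(pmax(score, 0), 1)
  data.frame(patient_id = newdata$patient_ids,
             predicted_label = as.integer(score >= 0.5),
             score = score, stringsAsFactors = FALSE)
}

#' @export
print.relapse_classifier <- function(x, ...) {
  cat(sprintf("<relapse_classifier> kind=%s, %d features\n",
              x$kind, length(x$features)))
  invisible(x)
}

#' Classification metric panel
#'
#' Sensitivity is computed on the relapse class (`TP / (TP + FN)`),
#' specificity on the relapse-free class, accuracy over all patients,
#' Cohen's kappa `(p_o - p_e) / (1 - p_e)` from the confusion table, and
#' AUC by the rank (Mann-Whitney) formulation over scores with midrank
#' tie handling.
#'
#' @param pred a predictions data.frame (`patient_id`, `predicted_label`,
#'   `score`) as returned by [predict.relapse_classifier()], or an
#'   integer 0/1 vector of predicted labels.
#' @param truth integer 0/1 vector of true labels, aligned with `pred`.
#' @param score optional numeric scores when `pred` is a plain vector;
#'   defaults to the predicted labels.
#' @return An object of class `eval_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `kappa`, `auc` (proportions, not
#'   percentages).
#' @export
compute_metrics <- function(pred, truth, score = NULL) {
  if (is.data.frame(pred)) {
    score <- pred$score
    pred <- pred$predicted_label
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth))
    stop("predictions and truth have different lengths")
  if (is.null(score)) score <- as.numeric(pred)
  tp <- sum(pred == 1L & truth == 1L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  n <- length(truth)
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((tn + fn) / n) * ((tn + fp) / n)
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (po >= 1 - 1e-12) 1 else 0
  } else (po - pe) / (1 - pe)
  n1 <- sum(truth == 1L); n0 <- n - n1
  auc <- if (n1 == 0L || n0 == 0L) NA_real_ else {
    rk <- rank(score)  # midranks
    (sum(rk[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(accuracy = po,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 kappa = kappa, auc = auc,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  fmt <- function(v, s = NULL) {
    if (is.null(s) || is.na(s)) sprintf("%.*f", digits, v)
    else sprintf("%.*f (±%.*f)", digits, v, digits, s)
  }
  cat("Acc:   ", fmt(x$accuracy, x$accuracy_sd), "\n")
  cat("Se:    ", fmt(x$sensitivity, x$sensitivity_sd), "\n")
  cat("Sp:    ", fmt(x$specificity, x$specificity_sd), "\n")
  cat("Kappa: ", fmt(x$kappa, x$kappa_sd), "\n")
  cat("AUC:   ", fmt(x$auc, x$auc_sd), "\n")
  invisible(x)
}

#' Evaluate a learner with stratified 10-fold CV or leave-one-patient-out
#'
#' Under `cv10`, per-fold metric panels are averaged with their standard
#' deviations reported as dispersion; under `lopo` each patient is held
#' out once and metrics are pooled over the held-out predictions. SMOTE
#' rebalancing and feature selection, when requested, are re-fit inside
#' each training fold only — held-out patients never influence the
#' synthetic rows or the selected features of their own fold.
#'
#' @param t a complete, labeled [feature_table()].
#' @param learner classifier kind or plugin factory, see
#'   [train_classifier()].
#' @param scheme `"cv10"` or `"lopo"`.
#' @param seed integer seed controlling fold assignment.
#' @param smote_cfg optional [smote_config()] applied to each training
#'   fold (skipped with a warning when a fold's minority class is too
#'   small for the requested k).
#' @param select optional per-fold feature selector: `"cfs"`, `"wrapper"`,
#'   or a function `feature_table -> character`.
#' @return An `eval_report`; under `cv10` with per-metric `*_sd` fields
#'   and a `per_fold` data.frame, under `lopo` pooled over all patients.
#' @export
evaluate <- function(t, learner = "nb", scheme = c("cv10", "lopo"),
                     seed = 1L, smote_cfg = NULL, select = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(t, "feature_table"), !is.null(t$label))
  if (length(unique(t$label)) < 2L) stop("both classes must be present")
  n <- nrow(t$data)
  k <- if (scheme == "cv10") 10L else n
  folds <- if (scheme == "cv10") stratified_folds(t$label, k, seed)
           else seq_len(n)

  selector <- if (is.null(select)) NULL
    else if (is.function(select)) select
    else if (identical(select, "cfs")) function(tt) cfs_select(tt)
    else if (identical(select, "wrapper"))
      function(tt) wrapper_select(tt, learner)
    else stop("unknown selector '", select, "'")

  all_pred <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- ft_subset(t, folds != f)
    te <- ft_subset(t, folds == f)
    if (length(unique(tr$label)) < 2L) {
      warning("fold ", f, " skipped: a class is absent from training")
      next
    }
    if (!is.null(smote_cfg)) {
      tr <- tryCatch(smote(tr, smote_cfg), error = function(e) {
        warning("SMOTE skipped in fold ", f, ": ", conditionMessage(e))
        tr
      })
    }
    if (!is.null(selector)) {
      feats <- selector(tr)
      if (length(feats) > 0L) {
        tr <- ft_select(tr, feats)
        te <- ft_select(te, feats)
      }
    }
    model <- train_classifier(tr, learner, seed = seed)
    pred <- predict(model, te)
    pred$truth <- te$label
    all_pred[[f]] <- pred
    if (scheme == "cv10") {
      m <- compute_metrics(pred, te$label)
      per_fold[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                  sensitivity = m$sensitivity,
                                  specificity = m$specificity,
                                  kappa = m$kappa, auc = m$auc)
    }
  }
  pooled <- do.call(rbind, all_pred)
  if (is.null(pooled)) stop("no fold could be evaluated")
  report <- compute_metrics(pooled[c("patient_id", "predicted_label", "score")],
                            pooled$truth)
  if (scheme == "cv10") {
    pf <- do.call(rbind, per_fold)
    for (metric in c("accuracy", "sensitivity", "specificity", "kappa", "auc")) {
      report[[metric]] <- mean(pf[[metric]], na.rm = TRUE)
      report[[paste0(metric, "_sd")]] <- stats::sd(pf[[metric]], na.rm = TRUE)
    }
    report$per_fold <- pf
  }
  report$scheme <- scheme
  report$predictions <- pooled
  report
}
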