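#' Drop features with a high fraction of missing values
#'
#' Removes every column whose missing fraction strictly exceeds
#' `max_missing` (a column at exactly the cutoff is retained). Column
#' order and the label are untouched.
#'
#' @param t a [feature_table()].
#' @param max_missing proportion in `[0, 1]`; default 0.9, i.e. the ">90%
#'   missing" omission rule.
#' @export
drop_sparse_features <- function(t, max_missing = 0.9) {
  stopifnot(inherits(t, "feature_table"))
  check_proportion(max_missing, "max_missing")
  frac <- vapply(t$data, function(col) mean(is.na(col)), numeric(1))
  keep <- names(t$data)[frac <= max_missing]
  if (length(keep) == 0L)
    message("drop_sparse_features: no feature survived the cutoff")
  ft_select(t, keep)
}

#' Impute missing values with column modes and means
#'
#' Nominal gaps are filled with the column mode (ties broken toward the
#' smallest value), numeric gaps with the column mean. Observed values are
#' never altered.
#'
#' @param t a [feature_table()]; every column must have at least one
#'   observed value (run [drop_sparse_features()] first).
#' @export
impute <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  for (nm in names(t$data)) {
    col <- t$data[[nm]]
    if (!anyNA(col)) next
    if (all(is.na(col)))
      stop("column '", nm, "' is entirely missing; ",
           "drop_sparse_features must be applied first")
    fill <- if (t$types[[nm]] == "numeric") mean(col, na.rm = TRUE)
            else col_mode(col)
    col[is.na(col)] <- fill
    t$data[[nm]] <- col
  }
  t
}

#' SMOTE configuration
#'
#' @param k_neighbors minority nearest neighbors considered per seed
#'   sample (default 5, the original SMOTE convention).
#' @param target_ratio desired minority:majority ratio after oversampling
#'   (1 = parity; values <= current ratio are a no-op).
#' @param seed integer seed.
#' @export
smote_config <- function(k_neighbors = 5L, target_ratio = 1, seed = 1L) {
  k_neighbors <- check_count(k_neighbors, "k_neighbors", 1L)
  if (!is.numeric(target_ratio) || target_ratio <= 0 || target_ratio > 1)
    stop_field("target_ratio", "must lie in (0, 1]")
  list(k_neighbors = k_neighbors, target_ratio = target_ratio,
       seed = as.integer(seed))
}

#' Synthetic Minority Oversampling (SMOTE)
#'
#' Appends synthetic minority-class rows until the minority:majority ratio
#' reaches `cfg$target_ratio`. Each synthetic row interpolates the numeric
#' features between a minority seed sample and one of its `k` nearest
#' minority neighbors (Euclidean distance over standardized numeric
#' features; nominal features are copied from the seed sample and excluded
#' from the metric). Original rows are unchanged; synthetic rows are
#' flagged in the `synthetic` slot and given `S`-prefixed patient ids.
#'
#' @param t a fully imputed, labeled [feature_table()] with both classes
#'   present.
#' @param cfg a [smote_config()].
#' @export
smote <- function(t, cfg = smote_config()) {
  stopifnot(inherits(t, "feature_table"))
  if (is.null(t$label)) stop("smote needs a labeled table")
  if (anyNA(as.matrix(t$data))) stop("smote requires a fully imputed table")
  counts <- table(factor(t$label, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present")
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  n_min <- min(counts); n_maj <- max(counts)
  n_synth <- ceiling(cfg$target_ratio * n_maj) - n_min
  if (n_synth <= 0L) return(t)
  if (n_min <= cfg$k_neighbors)
    stop("minority class (", n_min, ") must exceed k_neighbors (",
         cfg$k_neighbors, "); use a smaller k")

  min_idx <- which(t$label == minority)
  num_cols <- names(t$types)[t$types == "numeric"]
  if (length(num_cols)) {
    x <- as.matrix(t$data[num_cols])
    mu <- colMeans(x); sdv <- apply(x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    z <- scale(x, mu, sdv)[min_idx, , drop = FALSE]
    d <- as.matrix(stats::dist(z))
  } else {
    d <- matrix(0, length(min_idx), length(min_idx))
  }
  diag(d) <- Inf
  # k nearest minority neighbors, ties broken by row order
  nn <- apply(d, 1L, function(row)
    order(row)[seq_len(cfg$k_neighbors)], simplify = FALSE)

  seeds <- min_idx[(seq_len(n_synth) - 1L) %% n_min + 1L]
  new_rows <- vector("list", n_synth)
  withr::with_seed(cfg$seed, {
    pick <- sample.int(cfg$k_neighbors, n_synth, replace = TRUE)
    gap <- stats::runif(n_synth)
  })
  for (i in seq_len(n_synth)) {
    s <- seeds[i]
    nb <- min_idx[nn[[(match(s, min_idx))]][pick[i]]]
    row <- t$data[s, , drop = FALSE]
    for (nm in num_cols)
      row[[nm]] <- t$data[[nm]][s] + gap[i] * (t$data[[nm]][nb] - t$data[[nm]][s])
    new_rows[[i]] <- row
  }
  synth <- do.call(rbind, new_rows)
  feature_table(rbind(t$data, synth), types = t$types,
                label = c(t$label, rep(minority, n_synth)),
                patient_ids = c(t$patient_ids, sprintf("S%03d", seq_len(n_synth))),
                synthetic = c(t$synthetic, rep(TRUE, n_synth)))
}

#' Probe-level quality control
#'
#' Removes control probes, all but the first member of each duplicate
#' group, probes flagged low-quality, and probes with more than 50%
#' missing values. Probe order is preserved.
#'
#' @param m an [expression_matrix()] with complete annotation.
#' @param max_missing missing-fraction cutoff for probes (default 0.5).
#' @export
filter_probes <- function(m, max_missing = 0.5) {
  stopifnot(inherits(m, "expression_matrix"))
  ann <- m$annotation
  if (anyNA(ann$is_control) || anyNA(ann$quality_flag) ||
      anyNA(ann$missing_frac))
    stop("probe annotation contains missing QC flags")
  group <- ifelse(is.na(ann$duplicate_of) | ann$duplicate_of == "",
                  ann$probe_id, ann$duplicate_of)
  first_in_group <- !duplicated(group)
  keep <- !ann$is_control & !ann$quality_flag &
    ann$missing_frac <= max_missing & first_in_group
  expression_matrix(m$values[keep, , drop = FALSE],
                    ann[keep, , drop = FALSE])
}
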