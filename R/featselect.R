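#' CFS configuration
#'
#' @param discretization_bins equal-frequency bins used when computing
#'   symmetrical uncertainty on numeric features (default 4).
#' @param stall best-first search stops after this many consecutive
#'   non-improving expansions (default 5).
#' @param seed integer seed (kept for interface symmetry; CFS itself is
#'   deterministic given the table).
#' @export
cfs_config <- function(discretization_bins = 4L, stall = 5L, seed = 1L) {
  list(discretization_bins = check_count(discretization_bins,
                                         "discretization_bins", 2L),
       stall = check_count(stall, "stall", 1L),
       seed = as.integer(seed))
}

#' Wrapper-selection configuration
#'
#' @param inner_folds stratified cross-validation folds used to score each
#'   candidate subset (default 5).
#' @param stall best-first stall limit (default 5).
#' @param seed integer seed fixing the inner fold assignment.
#' @export
wrapper_config <- function(inner_folds = 5L, stall = 5L, seed = 1L) {
  list(inner_folds = check_count(inner_folds, "inner_folds", 2L),
       stall = check_count(stall, "stall", 1L),
       seed = as.integer(seed))
}

# Integer-coded view of a feature table: numerics equal-frequency binned,
# nominals coded by level; label appended as column "..class".
discretize_table <- function(t, bins) {
  stopifnot(!is.null(t$label))
  codes <- lapply(names(t$data), function(nm) {
    col <- t$data[[nm]]
    if (t$types[[nm]] == "numeric") equal_freq_codes(col, bins)
    else as.integer(factor(col))
  })
  names(codes) <- names(t$data)
  codes[["..class"]] <- t$label + 1L
  codes
}

#' CFS merit of a feature subset
#'
#' `merit_S = k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the mean
#' feature-class correlation and `rff` the mean pairwise feature-feature
#' correlation over the subset, both measured as symmetrical uncertainty
#' after equal-frequency discretization of numeric features.
#'
#' @param subset character vector of feature names (nonempty).
#' @param t a labeled [feature_table()].
#' @param cfg a [cfs_config()].
#' @export
cfs_merit <- function(subset, t, cfg = cfs_config()) {
  if (length(subset) == 0L) stop("subset must be nonempty")
  codes <- discretize_table(t, cfg$discretization_bins)
  merit_from_codes(subset, codes)
}

merit_from_codes <- function(subset, codes, su_cache = NULL) {
  k <- length(subset)
  su <- function(a, b) {
    if (is.null(su_cache))
      return(symmetrical_uncertainty(codes[[a]], codes[[b]]))
    key <- paste(sort(c(a, b)), collapse = "\r")
    val <- su_cache[[key]]
    if (is.null(val)) {
      val <- symmetrical_uncertainty(codes[[a]], codes[[b]])
      su_cache[[key]] <- val
    }
    val
  }
  rcf <- mean(vapply(subset, function(f) su(f, "..class"), numeric(1)))
  rff <- if (k > 1L) {
    prs <- utils::combn(subset, 2L)
    mean(vapply(seq_len(ncol(prs)),
                function(i) su(prs[1L, i], prs[2L, i]), numeric(1)))
  } else 0
  denom <- sqrt(k + k * (k - 1) * rff)
  if (denom == 0) return(0)
  k * rcf / denom
}

# Forward best-first search over feature subsets.
# score_fn(character vector) -> numeric; empty subset allowed.
# Ties favor smaller subsets, then lexicographic order of the sorted
# subset, making the result invariant to column order.
best_first_search <- function(features, score_fn, stall,
                              include_empty = FALSE) {
  key <- function(s) paste0("k:", paste(sort(s), collapse = "\r"))
  better <- function(s1, sc1, s2, sc2) {
    if (sc1 > sc2 + 1e-12) return(TRUE)
    if (sc1 < sc2 - 1e-12) return(FALSE)
    if (length(s1) != length(s2)) return(length(s1) < length(s2))
    key(s1) < key(s2)
  }
  visited <- new.env(parent = emptyenv())
  start <- character(0)
  start_score <- if (include_empty) score_fn(start) else -Inf
  assign(key(start), TRUE, visited)
  open_sets <- list(start)
  open_scores <- start_score
  best <- start; best_score <- start_score
  stalls <- 0L
  while (length(open_sets) > 0L && stalls < stall) {
    i <- which.max(open_scores)
    cur <- open_sets[[i]]
    open_sets <- open_sets[-i]; open_scores <- open_scores[-i]
    improved <- FALSE
    for (f in setdiff(features, cur)) {
      cand <- c(cur, f)
      k <- key(cand)
      if (!is.null(visited[[k]])) next
      assign(k, TRUE, visited)
      sc <- score_fn(cand)
      open_sets[[length(open_sets) + 1L]] <- cand
      open_scores <- c(open_scores, sc)
      if (better(cand, sc, best, best_score)) {
        best <- cand; best_score <- sc; improved <- TRUE
      }
    }
    stalls <- if (improved) 0L else stalls + 1L
  }
  list(subset = sort(best), score = best_score)
}

#' Correlation-based feature subset selection (CFS)
#'
#' Forward best-first search maximizing [cfs_merit()]: the retained subset
#' combines high feature-class correlation with low feature-feature
#' redundancy. Deterministic given the table.
#'
#' @param t a labeled [feature_table()] with at least one feature.
#' @param cfg a [cfs_config()].
#' @return Character vector of selected feature names (sorted).
#' @export
cfs_select <- function(t, cfg = cfs_config()) {
  stopifnot(inherits(t, "feature_table"), ncol(t$data) >= 1L)
  codes <- discretize_table(t, cfg$discretization_bins)
  su_cache <- new.env(parent = emptyenv())
  res <- best_first_search(names(t$data),
                           function(s) merit_from_codes(s, codes, su_cache),
                           cfg$stall)
  res$subset
}

#' Wrapper feature selection
#'
#' Forward best-first search scoring every candidate subset by the
#' stratified inner-CV accuracy of the target learner. The fold
#' assignment is fixed once from the seed, so the search is deterministic
#' and all subsets are scored on the same partitions. The empty subset
#' (majority-vote baseline) is the starting candidate, so the returned
#' subset never scores below it. Ties favor smaller subsets, then
#' lexicographic feature order.
#'
#' @param t a complete, labeled [feature_table()].
#' @param learner classifier kind (`"nb"`, `"dt"`) or a plugin factory as
#'   accepted by [train_classifier()].
#' @param cfg a [wrapper_config()].
#' @return Character vector of selected feature names (possibly empty).
#' @export
wrapper_select <- function(t, learner = "nb", cfg = wrapper_config()) {
  stopifnot(inherits(t, "feature_table"), !is.null(t$label))
  folds <- stratified_folds(t$label, cfg$inner_folds, cfg$seed)
  majority <- as.integer(names(which.max(table(t$label))))
  score_fn <- function(subset) {
    if (length(subset) == 0L) return(mean(t$label == majority))
    correct <- 0L
    for (f in seq_len(cfg$inner_folds)) {
      tr <- ft_subset(ft_select(t, subset), folds != f)
      te <- ft_subset(ft_select(t, subset), folds == f)
      if (length(unique(tr$label)) < 2L) {
        pred <- rep(as.integer(names(which.max(table(tr$label)))),
                    nrow(te$data))
      } else {
        model <- tryCatch(train_classifier(tr, learner, seed = cfg$seed),
                          error = function(e)
                            stop("learner failed on subset {",
                                 paste(subset, collapse = ", "), "}: ",
                                 conditionMessage(e), call. = FALSE))
        pred <- predict(model, te)$predicted_label
      }
      correct <- correct + sum(pred == te$label)
    }
    correct / nrow(t$data)
  }
  res <- best_first_search(names(t$data), score_fn, cfg$stall,
                           include_empty = TRUE)
  res$subset
}
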