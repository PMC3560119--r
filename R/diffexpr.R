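#' SAM configuration
#'
#' @param n_permutations label permutations for the null distribution; if
#'   at least the number of distinct label assignments, the permutation
#'   distribution is enumerated exhaustively.
#' @param s0_quantile quantile of the per-gene pooled standard errors used
#'   as the exchangeability (fudge) constant s0; default the median.
#' @param fold_change_threshold two-sided linear-scale fold-change cutoff
#'   (default 1.8).
#' @param q_cutoff q-value cutoff for selection (default 0.05).
#' @param seed integer seed for sampled permutations.
#' @export
sam_config <- function(n_permutations = 1000L, s0_quantile = 0.5,
                       fold_change_threshold = 1.8, q_cutoff = 0.05,
                       seed = 1L) {
  n_permutations <- check_count(n_permutations, "n_permutations", 1L)
  check_proportion(s0_quantile, "s0_quantile")
  check_proportion(q_cutoff, "q_cutoff")
  if (fold_change_threshold <= 0)
    stop_field("fold_change_threshold", "must be positive")
  list(n_permutations = n_permutations, s0_quantile = s0_quantile,
       fold_change_threshold = fold_change_threshold,
       q_cutoff = q_cutoff, seed = as.integer(seed))
}

# Moderated statistic d_i = (mean1 - mean0) / (s_i + s0) for every row of
# a log2 expression matrix. s_i is the two-sample pooled standard error.
sam_d_statistic <- function(x, labels, s0) {
  i1 <- labels == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- rowMeans(x[, i1, drop = FALSE], na.rm = TRUE)
  m0 <- rowMeans(x[, i0, drop = FALSE], na.rm = TRUE)
  v1 <- apply(x[, i1, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  v0 <- apply(x[, i0, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  pooled <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  s <- sqrt((1 / n1 + 1 / n0) * pooled)
  (m1 - m0) / (s + s0)
}

pooled_se <- function(x, labels) {
  i1 <- labels == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  v1 <- apply(x[, i1, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  v0 <- apply(x[, i0, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  sqrt((1 / n1 + 1 / n0) * ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
}

# All distinct relabelings with the observed class sizes, as a list of
# 0/1 vectors; NULL when there are too many to enumerate.
enumerate_labelings <- function(labels, limit) {
  n <- length(labels); n1 <- sum(labels == 1L)
  if (choose(n, n1) > limit) return(NULL)
  combos <- utils::combn(n, n1, simplify = FALSE)
  lapply(combos, function(ix) {
    l <- integer(n); l[ix] <- 1L; l
  })
}

# Permutation p-values from a null matrix (genes x permutations): SAM
# convention, pooling the order statistics of |d| across all genes and
# permutations, so p (and hence BH q) is monotone in |d|.
perm_pvalues <- function(d_obs, d_null, exhaustive) {
  null_sorted <- sort(abs(as.vector(d_null)))
  total <- length(null_sorted)
  below <- findInterval(abs(d_obs) - 1e-12, null_sorted)
  hits <- total - below
  if (exhaustive) hits / total else (1 + hits) / (1 + total)
}

#' SAM-style two-class gene ranking with permutation q-values
#'
#' Per gene, the moderated statistic `d = (mean1 - mean0) / (s + s0)` is
#' computed on the log2 scale, with `s` the pooled standard error and `s0`
#' the `s0_quantile` of all per-gene standard errors. Gene-specific
#' permutation p-values come from relabeled datasets (enumerated
#' exhaustively when feasible, otherwise sampled with the seed) and are
#' converted to q-values by Benjamini-Hochberg step-up adjustment. Fold
#' change is the linear-scale ratio of class means. A gene is selected
#' when its q-value passes `q_cutoff` and its two-sided fold change
#' passes `fold_change_threshold`.
#'
#' @param m an [expression_matrix()] or a plain numeric matrix of log2
#'   intensities (genes x samples).
#' @param labels 0/1 vector per sample (1 = relapser).
#' @param cfg a [sam_config()].
#' @return A `gene_ranking` data.frame: `gene_id`, `d`, `fold_change`,
#'   `q_value`, `selected`.
#' @export
sam_two_class <- function(m, labels, cfg = sam_config()) {
  x <- if (inherits(m, "expression_matrix")) m$values else m
  stopifnot(is.matrix(x), length(labels) == ncol(x))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 samples")

  s <- pooled_se(x, labels)
  s0 <- stats::quantile(s, cfg$s0_quantile, names = FALSE, na.rm = TRUE)
  d <- sam_d_statistic(x, labels, s0)

  all_lab <- enumerate_labelings(labels, cfg$n_permutations)
  if (!is.null(all_lab)) {
    d_null <- vapply(all_lab, function(l) sam_d_statistic(x, l, s0),
                     numeric(nrow(x)))
    exhaustive <- TRUE
  } else {
    d_null <- withr::with_seed(cfg$seed, {
      vapply(seq_len(cfg$n_permutations), function(b)
        sam_d_statistic(x, sample(labels), s0), numeric(nrow(x)))
    })
    exhaustive <- FALSE
  }
  if (nrow(x) == 1L) d_null <- matrix(d_null, nrow = 1L)
  p <- perm_pvalues(d, d_null, exhaustive)
  q <- stats::p.adjust(p, method = "BH")

  lin <- 2^x
  i1 <- labels == 1L
  fc <- rowMeans(lin[, i1, drop = FALSE], na.rm = TRUE) /
    rowMeans(lin[, !i1, drop = FALSE], na.rm = TRUE)
  r <- data.frame(gene_id = rownames(x) %||% sprintf("g%d", seq_len(nrow(x))),
                  d = d, fold_change = fc, q_value = q,
                  selected = FALSE, stringsAsFactors = FALSE,
                  row.names = NULL)
  class(r) <- c("gene_ranking", "data.frame")
  fold_change_filter(r, cfg$fold_change_threshold, cfg$q_cutoff)
}

#' Apply the two-sided fold-change and q-value selection rule
#'
#' A gene is selected when `max(fc, 1/fc) >= threshold` (direction is
#' ignored) and `q_value <= q_cutoff`. Thresholds are inclusive.
#'
#' @param r a `gene_ranking` from [sam_two_class()] or
#'   [sam_timecourse_wilcoxon()].
#' @param threshold linear-scale fold-change cutoff (default 1.8).
#' @param q_cutoff q-value cutoff (default 0.05).
#' @export
fold_change_filter <- function(r, threshold = 1.8, q_cutoff = 0.05) {
  stopifnot(inherits(r, "gene_ranking"))
  two_sided <- pmax(r$fold_change, 1 / r$fold_change)
  r$selected <- two_sided >= threshold & r$q_value <= q_cutoff
  r
}

#' Two-group time-course gene ranking (Wilcoxon rank-sum on trajectory
#' summaries)
#'
#' Each patient-by-gene trajectory is summarized by its signed trapezoidal
#' area across visits (unit slice spacing). Genes are ranked by the
#' Wilcoxon rank-sum statistic (midranks for ties) comparing the summaries
#' between relapser and non-relapser patients; q-values come from
#' group-label permutations with Benjamini-Hochberg adjustment. The
#' reported fold change maps the group difference in mean per-visit level
#' back to the linear scale.
#'
#' @param tc a [timecourse()].
#' @param group 0/1 vector per patient (1 = relapser); defaults to the
#'   final-visit relapse state stored in `tc`.
#' @param cfg a [sam_config()].
#' @param summary_fn trajectory summary: `"area"` (signed trapezoidal
#'   area, default) or `"slope"` (least-squares slope across visits).
#' @return A `gene_ranking` data.frame with the rank-sum statistic in
#'   column `d` (centered at its null expectation).
#' @export
sam_timecourse_wilcoxon <- function(tc, group = NULL, cfg = sam_config(),
                                    summary_fn = c("area", "slope")) {
  stopifnot(inherits(tc, "timecourse"))
  summary_fn <- match.arg(summary_fn)
  n_slices <- dim(tc$values)[3L]
  if (n_slices < 2L) stop("at least 2 slices are required")
  if (is.null(group)) group <- tc$relapse[, n_slices]
  group <- as.integer(group)
  if (min(table(group)) < 2L) stop("each group needs at least 2 patients")

  summaries <- trajectory_summaries(tc$values, summary_fn)
  w_stat <- function(g) {
    # centered rank-sum of group-1 summaries, midranks for ties
    apply(summaries, 2L, function(s) {
      rk <- rank(s)
      sum(rk[g == 1L]) - sum(g == 1L) * (length(s) + 1) / 2
    })
  }
  d <- w_stat(group)

  all_lab <- enumerate_labelings(group, cfg$n_permutations)
  if (!is.null(all_lab)) {
    d_null <- vapply(all_lab, w_stat, numeric(ncol(summaries)))
    exhaustive <- TRUE
  } else {
    d_null <- withr::with_seed(cfg$seed, {
      vapply(seq_len(cfg$n_permutations), function(b) w_stat(sample(group)),
             numeric(ncol(summaries)))
    })
    exhaustive <- FALSE
  }
  if (ncol(summaries) == 1L) d_null <- matrix(d_null, nrow = 1L)
  p <- perm_pvalues(d, d_null, exhaustive)
  q <- stats::p.adjust(p, method = "BH")

  span <- n_slices - 1L
  mean_diff <- colMeans(summaries[group == 1L, , drop = FALSE]) -
    colMeans(summaries[group == 0L, , drop = FALSE])
  fc <- if (summary_fn == "area") 2^(mean_diff / span) else 2^mean_diff
  r <- data.frame(gene_id = colnames(summaries), d = d, fold_change = fc,
                  q_value = q, selected = FALSE, stringsAsFactors = FALSE,
                  row.names = NULL)
  class(r) <- c("gene_ranking", "data.frame")
  fold_change_filter(r, cfg$fold_change_threshold, cfg$q_cutoff)
}

# Patients x genes matrix of per-trajectory scalar summaries.
trajectory_summaries <- function(vals, summary_fn) {
  n_slices <- dim(vals)[3L]
  t_axis <- seq_len(n_slices)
  out <- matrix(NA_real_, dim(vals)[1L], dim(vals)[2L],
                dimnames = dimnames(vals)[1:2])
  for (j in seq_len(dim(vals)[2L])) {
    traj <- vals[, j, , drop = TRUE]
    if (is.null(dim(traj))) traj <- matrix(traj, nrow = dim(vals)[1L])
    if (summary_fn == "area") {
      mids <- (traj[, -1L, drop = FALSE] + traj[, -n_slices, drop = FALSE]) / 2
      out[, j] <- rowSums(mids)
    } else {
      tc_c <- t_axis - mean(t_axis)
      out[, j] <- as.vector(traj %*% tc_c) / sum(tc_c^2)
    }
  }
  out
}

#' Write a gene ranking as TSV
#'
#' @param r a `gene_ranking`.
#' @param path output path.
#' @export
write_gene_ranking <- function(r, path) {
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
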