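# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_proportion <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a proportion in [0, 1]")
  x
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_field(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

# Column mode for nominal imputation; ties broken toward the smallest value
# so the result does not depend on row order.
col_mode <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(x)
  names(tab)[order(-tab, names(tab))][1L]
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold class ratios match the cohort as closely as possible.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Entropy (nats) of a discrete vector given as integer codes.
entropy_discrete <- function(x) {
  p <- tabulate(x)
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

# Symmetrical uncertainty between two integer-coded discrete vectors.
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy_discrete(x)
  hy <- entropy_discrete(y)
  if (hx + hy == 0) return(0)
  nx <- max(x)
  hxy <- entropy_discrete((y - 1L) * nx + x)
  2 * (hx + hy - hxy) / (hx + hy)
}

# Equal-frequency break points, placed at midpoints between consecutive
# distinct values so a boundary never lands on an observed value (ties /
# atoms would otherwise empty a bin). Each target quantile j/bins snaps
# to the widest inter-value gap within half a bin of cumulative mass:
# for continuous data this is essentially the empirical quantile, while
# clustered data (well-separated expression states) gets its boundaries
# in the density valleys instead of splitting a cluster.
equal_freq_breaks <- function(x, bins) {
  x <- x[!is.na(x)]
  u <- sort(unique(x))
  if (length(u) <= 1L) return(numeric(0))
  cumfrac <- cumsum(tabulate(match(x, u), nbins = length(u))) / length(x)
  cand <- (u[-length(u)] + u[-1L]) / 2
  candfrac <- cumfrac[-length(u)]
  gap <- diff(u)
  window <- 0.5 / bins
  picks <- vapply(seq_len(bins - 1L), function(j) {
    target <- j / bins
    near <- which(abs(candfrac - target) <= window)
    if (length(near) == 0L) return(which.min(abs(candfrac - target)))
    widest <- near[gap[near] >= max(gap[near]) - 1e-12]
    widest[which.min(abs(candfrac[widest] - target))]
  }, integer(1))
  sort(unique(cand[unique(picks)]))
}

# Equal-frequency discretization into integer codes 1..bins.
equal_freq_codes <- function(x, bins) {
  br <- equal_freq_breaks(x, bins)
  if (length(br) == 0L) return(rep(1L, length(x)))
  findInterval(x, br, left.open = TRUE) + 1L
}
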