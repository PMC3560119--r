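# Exact inference on the unrolled DBN by variable elimination.
# Factors are dense arrays over unrolled nodes named "<variable>@<slice>".

node_name <- function(variable, slice) paste0(variable, "@", slice)

# factor: list(vars, card, p) with p indexed mixed-radix, first var fastest
new_factor <- function(vars, card, p) list(vars = vars, card = card, p = p)

factor_from_cpt <- function(cp, child, cards, slice) {
  pa_nodes <- c(vapply(cp$intra, node_name, character(1), slice = slice),
                if (length(cp$inter))
                  vapply(cp$inter, node_name, character(1), slice = slice - 1L))
  vars <- c(node_name(child, slice), pa_nodes)
  card <- c(cards[[child]], unname(cards[c(cp$intra, cp$inter)]))
  # table rows = parent configs (first parent fastest), cols = child states
  new_factor(vars, card, as.vector(t(cp$table)))
}

factor_reduce <- function(f, node, state) {
  i <- match(node, f$vars)
  if (is.na(i)) return(f)
  arr <- array(f$p, dim = f$card)
  idx <- rep(list(quote(expr = )), length(f$card))
  idx[[i]] <- state
  arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), i)
  if (length(keep) == 0L)
    return(new_factor(character(0), integer(0), as.vector(arr)))
  new_factor(f$vars[keep], f$card[keep], as.vector(arr))
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0L) return(new_factor(f2$vars, f2$card, f1$p * f2$p))
  if (length(f2$vars) == 0L) return(new_factor(f1$vars, f1$card, f1$p * f2$p))
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  n <- prod(card)
  states <- arrayInd(seq_len(n), card)  # n x k, first var fastest
  idx_of <- function(f) {
    pos <- match(f$vars, vars)
    mult <- cumprod(c(1L, f$card[-length(f$card)]))
    as.integer(1L + (states[, pos, drop = FALSE] - 1L) %*% mult)
  }
  new_factor(vars, card, f1$p[idx_of(f1)] * f2$p[idx_of(f2)])
}

factor_marginalize <- function(f, node) {
  i <- match(node, f$vars)
  if (is.na(i)) return(f)
  keep <- setdiff(seq_along(f$vars), i)
  if (length(keep) == 0L)
    return(new_factor(character(0), integer(0), sum(f$p)))
  arr <- array(f$p, dim = f$card)
  summed <- apply(arr, keep, sum)
  new_factor(f$vars[keep], f$card[keep], as.vector(summed))
}

# Unrolled factor list with evidence applied.
unrolled_factors <- function(model, evidence, n_slices) {
  st <- model$structure
  cards <- model$cards
  factors <- list()
  for (t in seq_len(n_slices)) {
    cpts <- if (t == 1L) model$init_cpts else model$trans_cpts
    for (v in st$variables)
      factors[[length(factors) + 1L]] <- factor_from_cpt(cpts[[v]], v,
                                                         cards, t)
  }
  if (!is.null(evidence) && nrow(evidence) > 0L) {
    nodes <- paste(evidence$variable, evidence$slice)
    if (any(tapply(evidence$state, nodes, function(s) length(unique(s))) > 1L))
      stop("evidence assigns conflicting states to one node (inconsistent)")
    for (e in seq_len(nrow(evidence))) {
      node <- node_name(evidence$variable[e], evidence$slice[e])
      state <- evidence$state[e]
      if (state < 1L || state > cards[[evidence$variable[e]]])
        stop("evidence state out of range for ", node)
      factors <- lapply(factors, factor_reduce, node = node, state = state)
    }
  }
  factors
}

#' Exact posterior query on the unrolled DBN
#'
#' The 2-TBN is unrolled over `n_slices` visits and the posterior of one
#' variable at one slice given the evidence is computed exactly by
#' variable elimination (greedy min-size elimination order). Evidence
#' states use integer codes `1..cardinality` (for the binary relapse
#' node, 1 = relapse-free, 2 = relapse).
#'
#' @param model a [dbn_model()].
#' @param evidence `NULL` or a data.frame with columns `variable`,
#'   `slice`, `state`.
#' @param variable,slice the query node.
#' @param n_slices slices to unroll (default 3).
#' @return Named numeric vector over the query variable's states,
#'   summing to 1.
#' @export
infer <- function(model, evidence, variable, slice, n_slices = 3L) {
  stopifnot(inherits(model, "dbn_model"))
  if (slice > n_slices) stop("query slice exceeds n_slices")
  query <- node_name(variable, slice)
  observed <- if (!is.null(evidence) && nrow(evidence) > 0L)
    vapply(seq_len(nrow(evidence)), function(e)
      node_name(evidence$variable[e], evidence$slice[e]), character(1))
  else character(0)
  factors <- unrolled_factors(model, evidence, n_slices)

  r <- model$cards[[variable]]
  query_observed <- query %in% observed
  hidden <- unique(unlist(lapply(factors, `[[`, "vars")))
  if (!query_observed) hidden <- setdiff(hidden, query)
  while (length(hidden)) {
    # greedy: eliminate the node whose combined factor is smallest
    sizes <- vapply(hidden, function(h) {
      involved <- factors[vapply(factors, function(f) h %in% f$vars,
                                 logical(1))]
      vars <- unique(unlist(lapply(involved, `[[`, "vars")))
      prod(vapply(vars, function(v) {
        for (f in involved) {
          i <- match(v, f$vars)
          if (!is.na(i)) return(f$card[i])
        }
        1L
      }, numeric(1)))
    }, numeric(1))
    h <- hidden[which.min(sizes)]
    inv <- vapply(factors, function(f) h %in% f$vars, logical(1))
    prodf <- Reduce(factor_product, factors[inv])
    factors <- c(factors[!inv], list(factor_marginalize(prodf, h)))
    hidden <- setdiff(hidden, h)
  }
  res <- Reduce(factor_product, factors)
  total <- sum(res$p)
  if (total <= 0)
    stop("evidence has zero probability under the model (inconsistent)")
  if (query_observed) {
    p <- numeric(r)
    p[evidence$state[observed == query][1L]] <- 1
  } else {
    p <- res$p / total
  }
  stats::setNames(p, seq_len(r))
}

#' Forecast relapse probabilities for future visits
#'
#' Runs [infer()] for the relapse node at every slice after the last
#' evidence slice and thresholds the posterior for the binary call.
#'
#' @param model a [dbn_model()].
#' @param evidence data.frame (`variable`, `slice`, `state` codes) with
#'   observations up to some slice; must cover at least the baseline.
#' @param n_slices slices to unroll (default 3).
#' @param threshold posterior cutoff for calling a relapse (default 0.5;
#'   lower it for sensitivity-first operation).
#' @return data.frame with `slice`, `p_relapse`, `call` for every slice
#'   after the last evidence slice.
#' @export
predict_relapse <- function(model, evidence, n_slices = 3L,
                            threshold = 0.5) {
  stopifnot(is.data.frame(evidence), nrow(evidence) > 0L)
  last_seen <- max(evidence$slice)
  if (min(evidence$slice) > 1L)
    stop("evidence must cover at least the baseline slice")
  future <- seq_len(n_slices)[seq_len(n_slices) > last_seen]
  if (length(future) == 0L) stop("no future slice to forecast")
  p1 <- vapply(future, function(s)
    infer(model, evidence, "relapse", s, n_slices)[[2L]], numeric(1))
  data.frame(slice = future, p_relapse = p1,
             call = as.integer(p1 >= threshold))
}

# Evidence rows for one patient over given slices, from a dbn_discrete.
evidence_from_states <- function(disc, patient, slices) {
  vars <- disc$vars
  do.call(rbind, lapply(slices, function(t)
    data.frame(variable = vars, slice = t,
               state = disc$states[patient, , t],
               stringsAsFactors = FALSE)))
}

#' Leave-one-patient-out evaluation of the DBN monitor
#'
#' For every fold the held-out patient is removed; discretization
#' boundaries, the structure search and the CPT estimates are re-fit on
#' the training patients only. The held-out patient is then scored at two
#' evidence horizons: `baseline` (all baseline variables observed,
#' relapse forecast at follow-up #1) and `baseline_fu1` (baseline and
#' follow-up #1 observed, forecast at follow-up #2). Sensitivity,
#' specificity and pooled accuracy are reported per horizon, together
#' with the macro (class-balanced) accuracy, since pooled and
#' class-averaged rates differ on unbalanced cohorts.
#'
#' @param tc a [timecourse()] with at least 3 visits.
#' @param cfg a [score_config()].
#' @param sched optional [anneal_schedule()]; when supplied the structure
#'   search is simulated annealing, otherwise greedy hill climbing.
#' @param n_bins discretization bins per gene.
#' @param pseudocount CPT smoothing.
#' @param threshold posterior cutoff for the relapse call.
#' @param restarts greedy restarts per fold.
#' @return A list with one element per horizon (`baseline`,
#'   `baseline_fu1`), each an `eval_report` plus `balanced_accuracy`,
#'   and a `folds` data.frame of per-patient calls.
#' @export
lopo_evaluate <- function(tc, cfg = score_config(), sched = NULL,
                          n_bins = 3L, pseudocount = 1, threshold = 0.5,
                          restarts = 2L) {
  stopifnot(inherits(tc, "timecourse"))
  n_slices <- dim(tc$values)[3L]
  if (n_slices < 3L) stop("lopo_evaluate expects at least 3 visits")
  n <- dim(tc$values)[1L]
  final <- tc$relapse[, n_slices]
  if (min(table(factor(final, levels = 0:1))) < 3L)
    stop("at least 3 patients per class are required")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    tr_tc <- timecourse(tc$values[keep, , , drop = FALSE],
                        tc$relapse[keep, , drop = FALSE])
    if (length(unique(tr_tc$relapse[, n_slices])) < 2L) {
      warning("fold ", i, " skipped: a class is absent from training")
      next
    }
    disc_tr <- suppressWarnings(discretize(tr_tc, n_bins))
    dd <- dbn_data(disc_tr)
    st <- if (is.null(sched)) greedy_search(dd, cfg, restarts = restarts)
          else anneal_search(dd, cfg, sched)
    model <- fit_cpts(st, dd, pseudocount, breaks = disc_tr$breaks)
    disc_te <- discretize(timecourse(tc$values[i, , , drop = FALSE],
                                     tc$relapse[i, , drop = FALSE]),
                          n_bins, breaks = disc_tr$breaks)
    ev1 <- evidence_from_states(disc_te, 1L, 1L)
    f1 <- predict_relapse(model, ev1, n_slices, threshold)
    ev2 <- evidence_from_states(disc_te, 1L, 1:2)
    f2 <- predict_relapse(model, ev2, n_slices, threshold)
    rows[[i]] <- data.frame(patient = i,
                            truth_fu1 = tc$relapse[i, 2L],
                            truth_fu2 = tc$relapse[i, 3L],
                            p_fu1 = f1$p_relapse[f1$slice == 2L],
                            call_fu1 = f1$call[f1$slice == 2L],
                            p_fu2 = f2$p_relapse[f2$slice == 3L],
                            call_fu2 = f2$call[f2$slice == 3L])
  }
  folds <- do.call(rbind, rows)
  horizon <- function(call, truth, score) {
    rep <- compute_metrics(call, truth, score)
    rep$balanced_accuracy <- mean(c(rep$sensitivity, rep$specificity),
                                  na.rm = TRUE)
    rep
  }
  list(baseline = horizon(folds$call_fu1, folds$truth_fu1, folds$p_fu1),
       baseline_fu1 = horizon(folds$call_fu2, folds$truth_fu2, folds$p_fu2),
       folds = folds)
}
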