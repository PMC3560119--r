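#' Structure-score configuration
#'
#' @param score `"bde"` (Bayesian Dirichlet equivalent marginal
#'   likelihood, default) or `"bic"`.
#' @param ess equivalent sample size of the BDe prior (default 1).
#' @param max_parents cap on parents per family, intra- plus inter-slice
#'   (default 3), bounding CPT size at cohort scale.
#' @param seed integer seed used by the searches.
#' @export
score_config <- function(score = c("bde", "bic"), ess = 1,
                         max_parents = 3L, seed = 1L) {
  score <- match.arg(score)
  if (!is.numeric(ess) || ess <= 0) stop_field("ess", "must be positive")
  list(score = score, ess = ess,
       max_parents = check_count(max_parents, "max_parents", 0L),
       seed = as.integer(seed))
}

#' Simulated-annealing schedule
#'
#' @param t0 initial temperature (> `t_min`).
#' @param cooling geometric cooling factor in (0, 1).
#' @param moves_per_temp proposals evaluated at each temperature.
#' @param t_min final temperature.
#' @param seed integer seed.
#' @export
anneal_schedule <- function(t0 = 1, cooling = 0.9, moves_per_temp = 60L,
                            t_min = 0.01, seed = 1L) {
  if (t0 <= t_min) stop_field("t0", "must exceed t_min")
  if (cooling <= 0 || cooling >= 1) stop_field("cooling", "must lie in (0,1)")
  list(t0 = t0, cooling = cooling,
       moves_per_temp = check_count(moves_per_temp, "moves_per_temp", 1L),
       t_min = t_min, seed = as.integer(seed))
}

#' Discretize a time course for DBN learning
#'
#' Per-gene equal-frequency boundaries are computed on the training
#' patients pooled across all slices and applied unchanged to held-out
#' patients (values outside the training range clamp into the end bins).
#' The relapse variable passes through as binary. A constant gene falls
#' back to a single bin with a warning.
#'
#' @param tc a [timecourse()].
#' @param n_bins bins per gene (default 3: under/normal/over-expression).
#' @param breaks optional named list of precomputed boundaries (from a
#'   training call) applied instead of estimating new ones.
#' @return A `dbn_discrete` object: integer `states` (patients x
#'   variables x visits, codes 1..card), the `breaks` used, and per-
#'   variable cardinalities.
#' @export
discretize <- function(tc, n_bins = 3L, breaks = NULL) {
  stopifnot(inherits(tc, "timecourse"))
  n_bins <- check_count(n_bins, "n_bins", 2L)
  genes <- dimnames(tc$values)[[2L]]
  vars <- c(genes, "relapse")
  dims <- dim(tc$values)
  states <- array(NA_integer_, c(dims[1L], length(vars), dims[3L]),
                  dimnames = list(dimnames(tc$values)[[1L]], vars,
                                  dimnames(tc$values)[[3L]]))
  estimate <- is.null(breaks)
  if (estimate) breaks <- list()
  for (g in genes) {
    x <- tc$values[, g, ]
    if (estimate) {
      br <- equal_freq_breaks(as.vector(x), n_bins)
      if (length(br) == 0L)
        warning("gene '", g, "' is constant; single-bin fallback")
      breaks[[g]] <- br
    }
    states[, g, ] <- findInterval(x, breaks[[g]], left.open = TRUE) + 1L
  }
  states[, "relapse", ] <- tc$relapse + 1L
  cards <- stats::setNames(c(vapply(breaks, length, integer(1)) + 1L, 2L),
                           vars)
  structure(list(states = states, breaks = breaks, cards = cards,
                 vars = vars), class = "dbn_discrete")
}

#' Stack a discretized time course into scoring matrices
#'
#' Initial families are scored on slice-1 observations; transition
#' families on all consecutive slice pairs stacked (stationary 2-TBN).
#'
#' @param disc a `dbn_discrete` from [discretize()].
#' @return A `dbn_data` object with matrices `init`, `prev`, `cur` and
#'   the cardinalities.
#' @export
dbn_data <- function(disc) {
  stopifnot(inherits(disc, "dbn_discrete"))
  s <- disc$states
  n_slices <- dim(s)[3L]
  if (n_slices < 2L) stop("at least 2 slices of data are required")
  init <- s[, , 1L, drop = TRUE]
  if (is.null(dim(init))) init <- matrix(init, nrow = dim(s)[1L],
                                         dimnames = dimnames(s)[1:2])
  prev <- do.call(rbind, lapply(seq_len(n_slices - 1L),
                                function(t) s[, , t, drop = FALSE][, , 1L]))
  cur <- do.call(rbind, lapply(seq_len(n_slices - 1L) + 1L,
                               function(t) s[, , t, drop = FALSE][, , 1L]))
  structure(list(init = init, prev = prev, cur = cur,
                 cards = disc$cards, vars = disc$vars),
            class = "dbn_data")
}

#' Decomposable local family score
#'
#' BDe: log Dirichlet-multinomial marginal likelihood with pseudo-counts
#' `ess / (q * r)` (`q` parent configurations, `r` child states). BIC:
#' maximized log-likelihood minus `0.5 * log(N) * (r - 1) * q`.
#'
#' @param variable child variable name.
#' @param parents list with elements `intra` and `inter` (character
#'   vectors of parent names).
#' @param data a [dbn_data()].
#' @param cfg a [score_config()]; families larger than `max_parents` are
#'   rejected.
#' @param role `"transition"` (default) scores the stationary transition
#'   family; `"initial"` scores the slice-1 family (inter parents must be
#'   empty).
#' @export
family_score <- function(variable, parents, data, cfg = score_config(),
                         role = c("transition", "initial")) {
  role <- match.arg(role)
  pa_intra <- parents$intra %||% character(0)
  pa_inter <- parents$inter %||% character(0)
  if (role == "initial" && length(pa_inter) > 0L)
    stop("initial families cannot have inter-slice parents")
  if (length(pa_intra) + length(pa_inter) > cfg$max_parents)
    stop("family of '", variable, "' exceeds max_parents = ",
         cfg$max_parents)
  if (role == "initial") {
    child <- data$init[, variable]
    pa_states <- data$init[, pa_intra, drop = FALSE]
  } else {
    child <- data$cur[, variable]
    pa_states <- cbind(data$cur[, pa_intra, drop = FALSE],
                       data$prev[, pa_inter, drop = FALSE])
  }
  cards <- data$cards
  r <- cards[[variable]]
  pa_cards <- cards[c(pa_intra, pa_inter)]
  q <- prod(pa_cards)
  cfg_idx <- cfg_index(pa_states, pa_cards)
  counts <- matrix(tabulate((cfg_idx - 1L) * r + child, nbins = q * r),
                   nrow = q, byrow = TRUE)
  n_j <- rowSums(counts)
  if (cfg$score == "bde") {
    a_jk <- cfg$ess / (q * r)
    a_j <- cfg$ess / q
    sum(lgamma(a_j) - lgamma(a_j + n_j)) +
      sum(lgamma(a_jk + counts) - lgamma(a_jk))
  } else {
    ll <- counts * log(counts / n_j)
    ll[counts == 0L] <- 0
    sum(ll) - 0.5 * log(sum(n_j)) * (r - 1) * q
  }
}

# ---- structure search ------------------------------------------------------

# Internal search state: named lists of parent vectors.
ss_empty <- function(vars) {
  list(intra = stats::setNames(rep(list(character(0)), length(vars)), vars),
       inter = stats::setNames(rep(list(character(0)), length(vars)), vars),
       vars = vars)
}

ss_to_structure <- function(ss) {
  edges <- function(pl) {
    ch <- rep(names(pl), lengths(pl))
    data.frame(child = ch, parent = unlist(pl, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  dbn_structure(ss$vars, intra = edges(ss$intra), inter = edges(ss$inter))
}

ss_from_structure <- function(st) {
  ss <- ss_empty(st$variables)
  for (i in seq_len(nrow(st$intra)))
    ss$intra[[st$intra$child[i]]] <- c(ss$intra[[st$intra$child[i]]],
                                       st$intra$parent[i])
  for (i in seq_len(nrow(st$inter)))
    ss$inter[[st$inter$child[i]]] <- c(ss$inter[[st$inter$child[i]]],
                                       st$inter$parent[i])
  ss
}

# would adding intra edge parent -> child create a cycle?
ss_would_cycle <- function(ss, child, parent) {
  # cycle iff child reaches parent via existing intra edges (parent links)
  seen <- character(0)
  frontier <- parent
  while (length(frontier)) {
    v <- frontier[1L]; frontier <- frontier[-1L]
    if (v == child) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, ss$intra[[v]])
  }
  FALSE
}

# Cached family scores for the current dataset.
make_scorer <- function(dd, cfg) {
  cache <- new.env(parent = emptyenv())
  function(v, pa_intra, pa_inter, role) {
    key <- paste(role, v, paste(sort(pa_intra), collapse = ","),
                 paste(sort(pa_inter), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_score(v, list(intra = pa_intra, inter = pa_inter),
                          dd, cfg, role = role)
      cache[[key]] <- val
    }
    val
  }
}

# Score of one child's two families under the search state.
child_score <- function(ss, v, scorer) {
  scorer(v, ss$intra[[v]], character(0), "initial") +
    scorer(v, ss$intra[[v]], ss$inter[[v]], "transition")
}

ss_total_score <- function(ss, scorer) {
  sum(vapply(ss$vars, function(v) child_score(ss, v, scorer), numeric(1)))
}

# Enumerate legal single-edge moves as a list of
# list(type, child, parent); type in intra_add/intra_del/intra_rev/
# inter_add/inter_del.
ss_moves <- function(ss, max_parents) {
  vars <- ss$vars
  moves <- list()
  add <- function(type, child, parent)
    moves[[length(moves) + 1L]] <<- list(type = type, child = child,
                                         parent = parent)
  for (ch in vars) {
    n_pa <- length(ss$intra[[ch]]) + length(ss$inter[[ch]])
    for (pa in vars) {
      if (pa != ch) {
        if (pa %in% ss$intra[[ch]]) {
          add("intra_del", ch, pa)
          # reverse: pa becomes the child
          if (length(ss$intra[[pa]]) + length(ss$inter[[pa]]) < max_parents) {
            tmp <- ss
            tmp$intra[[ch]] <- setdiff(tmp$intra[[ch]], pa)
            if (!ss_would_cycle(tmp, pa, ch)) add("intra_rev", ch, pa)
          }
        } else if (n_pa < max_parents && !ss_would_cycle(ss, ch, pa)) {
          add("intra_add", ch, pa)
        }
      }
      if (pa %in% ss$inter[[ch]]) add("inter_del", ch, pa)
      else if (n_pa < max_parents) add("inter_add", ch, pa)
    }
  }
  moves
}

# O(1) random single-edge proposal for annealing: pick a child, a parent
# and an edge class, then derive the move from the current state.
# Returns NULL when the sampled move is illegal.
ss_propose <- function(ss, max_parents) {
  vars <- ss$vars
  ch <- vars[sample.int(length(vars), 1L)]
  pa <- vars[sample.int(length(vars), 1L)]
  n_pa <- length(ss$intra[[ch]]) + length(ss$inter[[ch]])
  if (stats::runif(1) < 0.5) {   # intra move
    if (pa == ch) return(NULL)
    if (pa %in% ss$intra[[ch]]) {
      if (stats::runif(1) < 0.5) return(list(type = "intra_del",
                                             child = ch, parent = pa))
      if (length(ss$intra[[pa]]) + length(ss$inter[[pa]]) >= max_parents)
        return(NULL)
      tmp <- ss
      tmp$intra[[ch]] <- setdiff(tmp$intra[[ch]], pa)
      if (ss_would_cycle(tmp, pa, ch)) return(NULL)
      return(list(type = "intra_rev", child = ch, parent = pa))
    }
    if (n_pa >= max_parents || ss_would_cycle(ss, ch, pa)) return(NULL)
    return(list(type = "intra_add", child = ch, parent = pa))
  }
  if (pa %in% ss$inter[[ch]])
    return(list(type = "inter_del", child = ch, parent = pa))
  if (n_pa >= max_parents) return(NULL)
  list(type = "inter_add", child = ch, parent = pa)
}

ss_apply <- function(ss, mv) {
  ch <- mv$child; pa <- mv$parent
  switch(mv$type,
    intra_add = { ss$intra[[ch]] <- c(ss$intra[[ch]], pa) },
    intra_del = { ss$intra[[ch]] <- setdiff(ss$intra[[ch]], pa) },
    intra_rev = {
      ss$intra[[ch]] <- setdiff(ss$intra[[ch]], pa)
      ss$intra[[pa]] <- c(ss$intra[[pa]], ch)
    },
    inter_add = { ss$inter[[ch]] <- c(ss$inter[[ch]], pa) },
    inter_del = { ss$inter[[ch]] <- setdiff(ss$inter[[ch]], pa) })
  ss
}

# Score change of a move: only the affected children are re-scored
# (decomposability of the family score).
ss_delta <- function(ss, mv, scorer) {
  affected <- if (mv$type == "intra_rev") c(mv$child, mv$parent) else mv$child
  new_ss <- ss_apply(ss, mv)
  sum(vapply(affected, function(v)
    child_score(new_ss, v, scorer) - child_score(ss, v, scorer), numeric(1)))
}

# Random legal structure used for greedy restarts.
ss_random <- function(vars, max_parents, cards) {
  ss <- ss_empty(vars)
  ord <- sample(vars)
  for (i in seq_along(ord)) {
    ch <- ord[i]
    budget <- sample.int(max_parents + 1L, 1L) - 1L
    if (budget > 0L && i > 1L) {
      n_intra <- sample.int(min(budget, i - 1L) + 1L, 1L) - 1L
      if (n_intra > 0L)
        ss$intra[[ch]] <- sample(ord[seq_len(i - 1L)], n_intra)
    }
    n_inter <- budget - length(ss$intra[[ch]])
    if (n_inter > 0L)
      ss$inter[[ch]] <- sample(vars, min(n_inter, length(vars)))
  }
  ss
}

hill_climb <- function(ss, scorer, max_parents) {
  repeat {
    moves <- ss_moves(ss, max_parents)
    if (length(moves) == 0L) break
    deltas <- vapply(moves, function(mv) ss_delta(ss, mv, scorer), numeric(1))
    best <- which.max(deltas)
    if (deltas[best] <= 1e-9) break
    ss <- ss_apply(ss, moves[[best]])
  }
  ss
}

#' Greedy hill-climbing DBN structure search
#'
#' Hill climbing over single-edge moves (add / delete / reverse within a
#' slice; add / delete across slices), taking the best score-improving
#' move until none remains. Additional restarts begin from random legal
#' structures; the best final structure is returned. Intra-slice
#' acyclicity and the parent cap are enforced on every move, and each
#' move re-scores only the affected families.
#'
#' @param data a [dbn_data()].
#' @param cfg a [score_config()].
#' @param restarts total hill-climbing runs (default 3: one from the
#'   empty structure, the rest from random structures).
#' @return A [dbn_structure()] with the achieved total score in
#'   attribute `score`.
#' @export
greedy_search <- function(data, cfg = score_config(), restarts = 3L) {
  stopifnot(inherits(data, "dbn_data"))
  scorer <- make_scorer(data, cfg)
  best <- NULL; best_score <- -Inf
  withr::with_seed(cfg$seed, {
    for (r in seq_len(max(1L, restarts))) {
      start <- if (r == 1L) ss_empty(data$vars)
               else ss_random(data$vars, cfg$max_parents, data$cards)
      ss <- hill_climb(start, scorer, cfg$max_parents)
      sc <- ss_total_score(ss, scorer)
      if (sc > best_score) { best <- ss; best_score <- sc }
    }
  })
  st <- ss_to_structure(best)
  attr(st, "score") <- best_score
  st
}

#' Simulated-annealing DBN structure search
#'
#' Random single-edge proposals are accepted with probability
#' `min(1, exp(delta / T))` under a geometric cooling schedule; the best
#' structure seen anywhere along the chain is retained and finished with
#' a greedy quench (hill climbing), so the returned structure is at least
#' a local optimum. Fully reproducible given the schedule seed.
#'
#' @param data a [dbn_data()].
#' @param cfg a [score_config()].
#' @param sched an [anneal_schedule()].
#' @return A [dbn_structure()] with attribute `score`.
#' @export
anneal_search <- function(data, cfg = score_config(),
                          sched = anneal_schedule()) {
  stopifnot(inherits(data, "dbn_data"))
  scorer <- make_scorer(data, cfg)
  ss <- ss_empty(data$vars)
  cur_score <- ss_total_score(ss, scorer)
  best <- ss; best_score <- cur_score
  withr::with_seed(sched$seed, {
    temp <- sched$t0
    while (temp >= sched$t_min) {
      for (m in seq_len(sched$moves_per_temp)) {
        mv <- ss_propose(ss, cfg$max_parents)
        if (is.null(mv)) next
        delta <- ss_delta(ss, mv, scorer)
        if (delta >= 0 || stats::runif(1) < exp(delta / temp)) {
          ss <- ss_apply(ss, mv)
          cur_score <- cur_score + delta
          if (cur_score > best_score) { best <- ss; best_score <- cur_score }
        }
      }
      temp <- temp * sched$cooling
    }
  })
  best <- hill_climb(best, scorer, cfg$max_parents)
  best_score <- ss_total_score(best, scorer)
  st <- ss_to_structure(best)
  attr(st, "score") <- best_score
  st
}

#' Estimate CPTs for a DBN structure
#'
#' Rows are `(counts + pseudocount) / (row total + pseudocount * r)`;
#' initial (slice-1) and stationary transition tables are estimated
#' separately, and a parent configuration never observed in training
#' falls back to a uniform row.
#'
#' @param structure a [dbn_structure()].
#' @param data a [dbn_data()].
#' @param pseudocount nonnegative smoothing constant (default 1).
#' @param breaks optional discretization map carried into the model.
#' @return A [dbn_model()].
#' @export
fit_cpts <- function(structure, data, pseudocount = 1, breaks = NULL) {
  stopifnot(inherits(structure, "dbn_structure"), inherits(data, "dbn_data"))
  if (pseudocount < 0) stop_field("pseudocount", "must be nonnegative")
  cards <- data$cards
  estimate <- function(child_states, pa_states, pa_cards, r, pa_i, pa_t) {
    q <- prod(pa_cards)
    idx <- cfg_index(pa_states, pa_cards)
    counts <- matrix(tabulate((idx - 1L) * r + child_states, nbins = q * r),
                     nrow = q, byrow = TRUE)
    tot <- rowSums(counts) + pseudocount * r
    tab <- (counts + pseudocount) / tot
    empty <- rowSums(counts) == 0L & pseudocount == 0
    tab[empty, ] <- 1 / r
    make_cpt(pa_i, pa_t, tab)
  }
  init <- list(); trans <- list()
  for (v in structure$variables) {
    pa_i <- intra_parents(structure, v)
    pa_t <- inter_parents(structure, v)
    r <- cards[[v]]
    init[[v]] <- estimate(data$init[, v],
                          data$init[, pa_i, drop = FALSE],
                          cards[pa_i], r, pa_i, character(0))
    trans[[v]] <- estimate(data$cur[, v],
                           cbind(data$cur[, pa_i, drop = FALSE],
                                 data$prev[, pa_t, drop = FALSE]),
                           cards[c(pa_i, pa_t)], r, pa_i, pa_t)
  }
  dbn_model(structure, cards, init, trans, breaks = breaks)
}
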