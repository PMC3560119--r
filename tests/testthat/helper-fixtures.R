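# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (enumeration, direct counting) and share
# no code with the implementation paths they check.

make_table <- function(df, label = NULL, types = NULL) {
  feature_table(as.data.frame(df, stringsAsFactors = FALSE),
                types = types, label = label)
}

small_cohort_spec <- function(seed = 7, ...) {
  args <- list(n_patients = 30, n_relapsers = 10, n_clinical = 12,
               n_imaging = 8, n_probes = 200,
               frac_control_probes = 0.05, frac_duplicate_probes = 0.1,
               frac_low_quality = 0.05, frac_missing_probes = 0.02,
               n_de_genes = 3, fold_change = 2, noise_sd = 0.5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# ---- metric oracles --------------------------------------------------------

oracle_confusion_metrics <- function(pred, truth) {
  tab <- table(factor(pred, levels = 0:1), factor(truth, levels = 0:1))
  tp <- tab["1", "1"]; fn <- tab["0", "1"]
  tn <- tab["0", "0"]; fp <- tab["1", "0"]
  n <- length(truth)
  po <- (tp + tn) / n
  pe <- (sum(tab["1", ]) / n) * (sum(tab[, "1"]) / n) +
    (sum(tab["0", ]) / n) * (sum(tab[, "0"]) / n)
  list(accuracy = po,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       kappa = if (abs(1 - pe) < 1e-12) {
         if (po >= 1 - 1e-12) 1 else 0
       } else (po - pe) / (1 - pe))
}

# AUC by exhaustive positive/negative pair counting (ties count 1/2).
oracle_auc_pairs <- function(score, truth) {
  pos <- score[truth == 1L]; neg <- score[truth == 0L]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# ---- rank-sum oracle -------------------------------------------------------

# Centered Wilcoxon rank-sum with midranks, computed directly.
oracle_ranksum <- function(x, g) {
  rk <- rank(x)
  sum(rk[g == 1L]) - sum(g == 1L) * (length(x) + 1) / 2
}

# ---- symmetrical-uncertainty / CFS oracles ---------------------------------

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

oracle_su <- function(x, y) {
  hx <- oracle_entropy(x); hy <- oracle_entropy(y)
  if (hx + hy == 0) return(0)
  hxy <- oracle_entropy(paste(x, y))
  2 * (hx + hy - hxy) / (hx + hy)
}

# Exhaustive CFS optimum over every nonempty subset (<= 10 features);
# ties resolved like the search: smaller subset, then lexicographic.
oracle_cfs_optimum <- function(t, cfg = cfs_config()) {
  feats <- names(t$data)
  codes <- oscctrack:::discretize_table(t, cfg$discretization_bins)
  su_cache <- new.env(parent = emptyenv())
  best <- NULL; best_m <- -Inf
  for (sz in seq_along(feats)) {
    for (ix in utils::combn(length(feats), sz, simplify = FALSE)) {
      s <- sort(feats[ix])
      m <- oscctrack:::merit_from_codes(s, codes, su_cache)
      if (m > best_m + 1e-12 ||
          (abs(m - best_m) <= 1e-12 && !is.null(best) &&
           (length(s) < length(best) ||
            (length(s) == length(best) &&
             paste(s, collapse = ",") < paste(best, collapse = ","))))) {
        best <- s; best_m <- m
      }
    }
  }
  list(subset = best, merit = best_m)
}

# ---- DBN oracles -----------------------------------------------------------

# Full-joint enumeration over the unrolled network: returns the exact
# posterior of `variable` at `slice` given evidence (codes 1..card).
oracle_dbn_posterior <- function(model, evidence, variable, slice,
                                 n_slices = 3L) {
  vars <- model$structure$variables
  cards <- model$cards
  nodes <- expand.grid(var = vars, t = seq_len(n_slices),
                       stringsAsFactors = FALSE)
  node_ids <- paste0(nodes$var, "@", nodes$t)
  grid_cards <- cards[nodes$var]
  combos <- as.matrix(expand.grid(lapply(grid_cards, seq_len)))
  colnames(combos) <- node_ids
  logp <- numeric(nrow(combos))
  for (k in seq_len(nrow(nodes))) {
    v <- nodes$var[k]; t <- nodes$t[k]
    cp <- if (t == 1L) model$init_cpts[[v]] else model$trans_cpts[[v]]
    pa <- c(if (length(cp$intra)) paste0(cp$intra, "@", t),
            if (length(cp$inter)) paste0(cp$inter, "@", t - 1L))
    pa_cards <- cards[c(cp$intra, cp$inter)]
    row <- if (length(pa) == 0L) rep(1L, nrow(combos)) else {
      mult <- cumprod(c(1, pa_cards[-length(pa_cards)]))
      as.integer(1 + (combos[, pa, drop = FALSE] - 1) %*% mult)
    }
    logp <- logp + log(cp$table[cbind(row, combos[, node_ids[k]])])
  }
  p <- exp(logp)
  keep <- rep(TRUE, length(p))
  if (!is.null(evidence) && nrow(evidence) > 0L) {
    for (e in seq_len(nrow(evidence))) {
      nd <- paste0(evidence$variable[e], "@", evidence$slice[e])
      keep <- keep & combos[, nd] == evidence$state[e]
    }
  }
  q <- paste0(variable, "@", slice)
  out <- vapply(seq_len(cards[[variable]]), function(s)
    sum(p[keep & combos[, q] == s]), numeric(1))
  out / sum(p[keep])
}

# Random 2-TBN over binary variables with random parent sets and CPTs.
random_binary_dbn <- function(n_vars, max_parents = 2L, seed = 1L) {
  withr::with_seed(seed, {
    vars <- c(paste0("v", seq_len(n_vars - 1L)), "relapse")
    ord <- sample(vars)
    intra <- list(); inter <- list()
    for (i in seq_along(ord)) {
      v <- ord[i]
      n_in <- sample(0:min(max_parents, i - 1L), 1L)
      pa_i <- if (n_in > 0) sample(ord[seq_len(i - 1L)], n_in) else character(0)
      n_x <- sample(0:(max_parents - n_in), 1L)
      pa_x <- if (n_x > 0) sample(vars, n_x) else character(0)
      if (length(pa_i))
        intra[[length(intra) + 1L]] <- data.frame(child = v, parent = pa_i)
      if (length(pa_x))
        inter[[length(inter) + 1L]] <- data.frame(child = v, parent = pa_x)
    }
    st <- dbn_structure(vars,
                        intra = if (length(intra)) do.call(rbind, intra),
                        inter = if (length(inter)) do.call(rbind, inter))
    cards <- stats::setNames(rep(2L, n_vars), vars)
    rand_cpt <- function(pa_i, pa_x) {
      q <- prod(cards[c(pa_i, pa_x)])
      tab <- matrix(stats::rgamma(q * 2L, 1) + 0.05, q, 2L)
      oscctrack:::make_cpt(pa_i, pa_x, tab / rowSums(tab))
    }
    init <- list(); trans <- list()
    for (v in vars) {
      pa_i <- st$intra$parent[st$intra$child == v]
      pa_x <- st$inter$parent[st$inter$child == v]
      init[[v]] <- rand_cpt(pa_i, character(0))
      trans[[v]] <- rand_cpt(pa_i, pa_x)
    }
    dbn_model(st, cards, init, trans)
  })
}

# Build a dbn_data object directly from matrices (for score tests).
manual_dbn_data <- function(init, prev, cur, cards) {
  structure(list(init = init, prev = prev, cur = cur, cards = cards,
                 vars = names(cards)), class = "dbn_data")
}

subsets_of <- function(set, max_size) {
  out <- list(character(0))
  for (sz in seq_len(min(length(set), max_size)))
    out <- c(out, utils::combn(set, sz, simplify = FALSE))
  out
}

# All acyclic intra-parent assignments (dataset-independent, so it can be
# precomputed once and reused across many scored datasets).
enum_acyclic_assignments <- function(vars, max_parents) {
  nv <- length(vars)
  choice_sets <- lapply(vars, function(v)
    subsets_of(setdiff(vars, v), max_parents))
  names(choice_sets) <- vars
  sizes <- vapply(choice_sets, length, integer(1))
  acyclic <- function(assign_list) {
    done <- character(0)
    repeat {
      ready <- setdiff(vars[vapply(vars, function(v)
        all(assign_list[[v]] %in% done), logical(1))], done)
      if (length(ready) == 0L) break
      done <- c(done, ready)
    }
    length(done) == nv
  }
  out <- list()
  idx <- rep(1L, nv)
  repeat {
    assign_list <- lapply(seq_len(nv), function(i) choice_sets[[i]][[idx[i]]])
    names(assign_list) <- vars
    if (acyclic(assign_list)) out[[length(out) + 1L]] <- assign_list
    j <- 1L
    while (j <= nv) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > nv) break
  }
  out
}

# Exhaustive structure-score optimum for small 2-slice problems: every
# acyclic intra assignment combined with the per-child best inter set
# under the parent cap.
oracle_structure_optimum <- function(dd, cfg, assignments = NULL) {
  vars <- dd$vars
  if (is.null(assignments))
    assignments <- enum_acyclic_assignments(vars, cfg$max_parents)
  # per child: g[intra key] = init + best-over-inter transition score
  g <- list()
  for (v in vars) {
    g[[v]] <- new.env(parent = emptyenv())
    for (pa_i in subsets_of(setdiff(vars, v), cfg$max_parents)) {
      init_sc <- family_score(v, list(intra = pa_i), dd, cfg, "initial")
      best_tr <- -Inf
      for (pa_x in subsets_of(vars, cfg$max_parents - length(pa_i))) {
        sc <- family_score(v, list(intra = pa_i, inter = pa_x), dd, cfg)
        if (sc > best_tr) best_tr <- sc
      }
      key <- paste(sort(pa_i), collapse = ",")
      g[[v]][[paste0("k:", key)]] <- init_sc + best_tr
    }
  }
  best <- -Inf
  for (assign_list in assignments) {
    tot <- sum(vapply(vars, function(v) {
      key <- paste(sort(assign_list[[v]]), collapse = ",")
      g[[v]][[paste0("k:", key)]]
    }, numeric(1)))
    if (tot > best) best <- tot
  }
  best
}

informative_table <- function(n = 80, seed = 1) {
  # f1 predicts the label strongly; f2..f4 pure noise; f5 duplicates f1
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), n / 2)
    f1 <- ifelse(label == 1L, "hi", "lo")
    flip <- sample(n, 4)
    f1[flip] <- ifelse(f1[flip] == "hi", "lo", "hi")
    df <- data.frame(f1 = f1,
                     f2 = sample(letters[1:3], n, TRUE),
                     f3 = rnorm(n),
                     f4 = sample(letters[1:2], n, TRUE),
                     stringsAsFactors = FALSE)
  })
  make_table(df, label = label)
}

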