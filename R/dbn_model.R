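#' Two-slice dynamic Bayesian network structure
#'
#' A 2-TBN: within-slice (intra) dependencies shared by every slice, and
#' forward dependencies (inter) from slice t to slice t+1 under a
#' stationary transition model. The intra-slice graph must be acyclic.
#'
#' @param variables ordered character vector of variable names (gene nodes
#'   plus the binary `relapse` node).
#' @param intra data.frame with columns `child`, `parent`: within-slice
#'   edges (parent and child in the same slice).
#' @param inter data.frame with columns `child`, `parent`: edges from
#'   `parent` at slice t to `child` at slice t+1 (self-edges allowed).
#' @return An object of class `dbn_structure`.
#' @export
dbn_structure <- function(variables, intra = NULL, inter = NULL) {
  empty <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  intra <- if (is.null(intra) || nrow(intra) == 0) empty else
    data.frame(child = as.character(intra$child),
               parent = as.character(intra$parent), stringsAsFactors = FALSE)
  inter <- if (is.null(inter) || nrow(inter) == 0) empty else
    data.frame(child = as.character(inter$child),
               parent = as.character(inter$parent), stringsAsFactors = FALSE)
  all_named <- c(intra$child, intra$parent, inter$child, inter$parent)
  if (!all(all_named %in% variables))
    stop("edge endpoints must be listed in 'variables'")
  if (any(intra$child == intra$parent))
    stop("intra-slice self-edges are not allowed")
  if (anyDuplicated(paste(intra$child, intra$parent)) ||
      anyDuplicated(paste(inter$child, inter$parent)))
    stop("duplicate edges")
  st <- structure(list(variables = variables, intra = intra, inter = inter),
                  class = "dbn_structure")
  if (is.null(topo_order(st)))
    stop("intra-slice edges must form an acyclic graph")
  st
}

#' @export
print.dbn_structure <- function(x, ...) {
  cat(sprintf("<dbn_structure> %d variables, %d intra-slice + %d inter-slice edges\n",
              length(x$variables), nrow(x$intra), nrow(x$inter)))
  invisible(x)
}

# Topological order of the intra-slice DAG; NULL if cyclic.
topo_order <- function(structure) {
  vars <- structure$variables
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (p in structure$intra$child) indeg[p] <- indeg[p] + 1L
  order <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order <- c(order, v)
    kids <- structure$intra$child[structure$intra$parent == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order) != length(vars)) NULL else order
}

intra_parents <- function(structure, v)
  structure$intra$parent[structure$intra$child == v]

inter_parents <- function(structure, v)
  structure$inter$parent[structure$inter$child == v]

# Mixed-radix row index into a CPT: first parent varies fastest.
# states: matrix (n x k) of integer codes 1..card; cards: length-k vector.
cfg_index <- function(states, cards) {
  if (length(cards) == 0L) return(rep(1L, nrow(states)))
  mult <- cumprod(c(1L, cards[-length(cards)]))
  as.integer(1L + (states - 1L) %*% mult)
}

# A CPT: parents split by role, table rows = parent configs (intra first,
# each block first-fastest), columns = child states; rows sum to 1.
make_cpt <- function(intra, inter, table) {
  stopifnot(is.matrix(table))
  if (max(abs(rowSums(table) - 1)) > 1e-9)
    stop("every CPT row must sum to 1")
  list(intra = intra, inter = inter, table = table)
}

uniform_cpt <- function(intra, inter, cards, r) {
  q <- prod(cards[c(intra, inter)])
  make_cpt(intra, inter, matrix(1 / r, q, r))
}

#' Discrete dynamic Bayesian network model
#'
#' Bundles a [dbn_structure()] with per-variable cardinalities, initial
#' (slice-1) CPTs, transition CPTs, and, when learned from continuous
#' expression, the per-gene discretization boundaries.
#'
#' Initial CPTs condition on the variable's intra-slice parents; transition
#' CPTs condition on intra-slice parents at the current slice plus
#' inter-slice parents at the previous slice. CPT rows are indexed by
#' parent configuration (intra block first, first parent fastest).
#'
#' @param structure a [dbn_structure()].
#' @param cards named integer vector of states per variable.
#' @param init_cpts,trans_cpts named lists of CPTs as built internally by
#'   [fit_cpts()]; each holds `intra`, `inter` parent names and a row-
#'   stochastic `table`.
#' @param breaks optional named list of per-gene discretization boundaries.
#' @return An object of class `dbn_model`.
#' @export
dbn_model <- function(structure, cards, init_cpts, trans_cpts, breaks = NULL) {
  stopifnot(inherits(structure, "dbn_structure"))
  vars <- structure$variables
  if (!all(vars %in% names(cards)))
    stop("cardinalities missing for some variables")
  for (v in vars) {
    for (cp in list(init_cpts[[v]], trans_cpts[[v]])) {
      if (is.null(cp)) stop("missing CPT for ", v)
      if (max(abs(rowSums(cp$table) - 1)) > 1e-9)
        stop("CPT rows for ", v, " must sum to 1")
    }
  }
  structure(list(structure = structure, cards = cards,
                 init_cpts = init_cpts, trans_cpts = trans_cpts,
                 breaks = breaks),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  print(x$structure)
  cat(sprintf("  cardinalities: %s\n",
              paste(sprintf("%s=%d", names(x$cards), x$cards), collapse = " ")))
  invisible(x)
}

#' Default ground-truth DBN for synthetic time courses
#'
#' Nine ternary gene nodes (under/normal/over-expressed) plus a binary
#' absorbing relapse node, mirroring the scale of the final monitoring
#' model the pipeline targets. Each gene persists in its state across
#' visits (doubly stochastic transition rows, so state marginals stay
#' uniform and equal-frequency discretization recovers the states); the
#' relapse hazard at slice t+1 depends on the first gene's state at t.
#'
#' @param n_genes number of gene nodes (>= 1).
#' @param persistence probability a gene keeps its state across one visit.
#' @param hazard length-3 vector: P(relapse at t+1 | gene1 state at t,
#'   no relapse yet).
#' @param init_relapse P(relapse already present at the first visit).
#' @param deterministic if `TRUE`, genes persist with probability 1, the
#'   relapse hazard is the indicator of gene1 over-expression, and every
#'   patient starts relapse-free: dynamics become a deterministic function
#'   of the initial gene states.
#' @return A [dbn_model()] usable as sampling ground truth.
#' @export
default_ground_truth_dbn <- function(n_genes = 9, persistence = 0.98,
                                     hazard = c(0.01, 0.03, 0.98),
                                     init_relapse = 0.1,
                                     deterministic = FALSE) {
  stopifnot(n_genes >= 1)
  if (deterministic) {
    persistence <- 1
    hazard <- c(0, 0, 1)
    init_relapse <- 0
  }
  genes <- paste0("g", seq_len(n_genes))
  vars <- c(genes, "relapse")
  # relapse parents listed g1-then-relapse, matching its CPT row layout
  inter <- data.frame(child = c(genes, "relapse", "relapse"),
                      parent = c(genes, genes[1L], "relapse"),
                      stringsAsFactors = FALSE)
  st <- dbn_structure(vars, intra = NULL, inter = inter)
  cards <- stats::setNames(c(rep(3L, n_genes), 2L), vars)
  persist3 <- matrix((1 - persistence) / 2, 3, 3)
  diag(persist3) <- persistence
  init <- list(); trans <- list()
  for (g in genes) {
    init[[g]] <- make_cpt(character(0), character(0),
                          matrix(1 / 3, 1, 3))
    trans[[g]] <- make_cpt(character(0), g, persist3)
  }
  init[["relapse"]] <- make_cpt(character(0), character(0),
                                matrix(c(1 - init_relapse, init_relapse), 1, 2))
  # rows: (g1, relapse_prev) with g1 fastest
  p1 <- c(hazard, 1, 1, 1)
  trans[["relapse"]] <- make_cpt(character(0), c(genes[1L], "relapse"),
                                 cbind(1 - p1, p1))
  dbn_model(st, cards, init, trans)
}

# Ancestral sampling of discrete states for one patient across n_slices.
# Returns an integer matrix (vars x slices) of codes 1..card; the relapse
# node is kept absorbing regardless of its CPT.
sample_states <- function(model, n_slices) {
  st <- model$structure
  vars <- st$variables
  ord <- topo_order(st)
  cards <- model$cards
  out <- matrix(NA_integer_, length(vars), n_slices,
                dimnames = list(vars, NULL))
  for (t in seq_len(n_slices)) {
    cpts <- if (t == 1L) model$init_cpts else model$trans_cpts
    for (v in ord) {
      if (v == "relapse" && t > 1L && out["relapse", t - 1L] == 2L) {
        out[v, t] <- 2L  # absorbing, regardless of parents
        next
      }
      cp <- cpts[[v]]
      pa_states <- c(out[cp$intra, t], if (t > 1L) out[cp$inter, t - 1L])
      row <- cfg_index(matrix(pa_states, nrow = 1L),
                       cards[c(cp$intra, cp$inter)])
      p <- cp$table[row, ]
      out[v, t] <- sample.int(length(p), 1L, prob = p)
    }
  }
  out
}

#' Sample a longitudinal expression cohort from a ground-truth DBN
#'
#' Discrete states are drawn by ancestral sampling slice by slice; each
#' gene then emits a log2-scale intensity from a state-conditional
#' Gaussian (means evenly spaced `emission_gap` apart around 8). The
#' relapse node is absorbing: once 1 it stays 1, whatever its CPT says.
#'
#' @param truth a [dbn_model()] whose variables end with a binary
#'   `relapse` node.
#' @param n_patients cohort size.
#' @param n_relapsers optional number of patients with relapse = 1 by the
#'   final visit; met by per-patient rejection sampling (`NULL` leaves the
#'   class split to the dynamics).
#' @param seed integer seed.
#' @param n_slices number of visits (default 3: baseline, fu1, fu2).
#' @param emission_sd Gaussian emission noise (log2 scale); 0 gives
#'   noiseless emissions at the state means.
#' @param emission_gap spacing between consecutive state means.
#' @return A [timecourse()] whose `states` element records the sampled
#'   ground-truth discrete states (patients x variables x visits).
#' @export
generate_timecourse <- function(truth, n_patients, n_relapsers = NULL,
                                seed = 1L, n_slices = 3L,
                                emission_sd = 0.25, emission_gap = 2) {
  stopifnot(inherits(truth, "dbn_model"), n_patients >= 1)
  genes <- setdiff(truth$structure$variables, "relapse")
  visits <- c("baseline", paste0("fu", seq_len(n_slices - 1L)))[seq_len(n_slices)]
  states <- array(NA_integer_,
                  dim = c(n_patients, length(genes) + 1L, n_slices),
                  dimnames = list(sprintf("P%03d", seq_len(n_patients)),
                                  c(genes, "relapse"), visits))
  withr::with_seed(seed, {
    filled <- 0L
    quota_r <- n_relapsers
    quota_n <- if (is.null(n_relapsers)) NULL else n_patients - n_relapsers
    attempts <- 0L
    while (filled < n_patients) {
      attempts <- attempts + 1L
      if (attempts > 10000L * n_patients)
        stop("rejection sampling failed to meet the requested class split")
      s <- sample_states(truth, n_slices)
      if (!is.null(n_relapsers)) {
        is_rel <- s["relapse", n_slices] == 2L
        if (is_rel) {
          if (quota_r == 0L) next
          quota_r <- quota_r - 1L
        } else {
          if (quota_n == 0L) next
          quota_n <- quota_n - 1L
        }
      }
      filled <- filled + 1L
      states[filled, , ] <- s
    }
    mu <- function(s, r) 8 + (s - (r + 1) / 2) * emission_gap
    vals <- array(NA_real_, dim = c(n_patients, length(genes), n_slices),
                  dimnames = list(rownames(states), genes, visits))
    for (g in genes) {
      r <- truth$cards[[g]]
      m <- mu(states[, g, , drop = FALSE], r)
      vals[, g, ] <- m + stats::rnorm(length(m), sd = emission_sd)
    }
  })
  relapse <- states[, "relapse", , drop = TRUE] - 1L
  if (n_patients == 1L) relapse <- matrix(relapse, 1L,
                                          dimnames = list(rownames(states), visits))
  tc <- timecourse(vals, relapse)
  tc$states <- states
  tc
}
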