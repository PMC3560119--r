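test_that("structure construction enforces acyclicity and CPT row sums", {
  expect_error(dbn_structure(c("a", "b"),
                             intra = data.frame(child = c("a", "b"),
                                                parent = c("b", "a"))),
               "acyclic")
  expect_error(oscctrack:::make_cpt(character(0), character(0),
                                    matrix(c(0.5, 0.4), 1)),
               "sum to 1")
})

test_that("discretization uses equal-frequency bins and clamps held-out values", {
  vals <- array(rep(1:9, each = 2), dim = c(2, 1, 9),
                dimnames = list(c("P1", "P2"), "g1", paste0("v", 1:9)))
  # reshape: 2 patients x 1 gene x 9 visits holding values 1..9 per patient
  tc <- timecourse(vals, matrix(0L, 2, 9))
  disc <- discretize(tc, 3)
  expect_equal(as.vector(table(disc$states[1, "g1", ])), c(3, 3, 3))
  # held-out values outside the training range clamp into the end bins
  vals2 <- array(c(-5, 99), dim = c(1, 1, 2),
                 dimnames = list("P9", "g1", c("v1", "v2")))
  tc2 <- timecourse(vals2, matrix(0L, 1, 2))
  d2 <- discretize(tc2, 3, breaks = disc$breaks)
  expect_equal(as.vector(d2$states[1, "g1", ]), c(1, 3))
  # deterministic re-estimation
  expect_identical(discretize(tc, 3)$breaks, disc$breaks)
  # constant gene falls back to a single bin with a warning
  vals3 <- array(7, dim = c(2, 1, 3),
                 dimnames = list(c("P1", "P2"), "g1", c("v1", "v2", "v3")))
  expect_warning(d3 <- discretize(timecourse(vals3, matrix(0L, 2, 3)), 3),
                 "constant")
  expect_true(all(d3$states[, "g1", ] == 1L))
})

test_that("BIC and BDe family scores match their closed forms", {
  cards <- c(x = 2L)
  init <- matrix(1L, 1, 1, dimnames = list(NULL, "x"))
  cur <- matrix(c(rep(1L, 5), rep(2L, 5)), ncol = 1,
                dimnames = list(NULL, "x"))
  dd <- manual_dbn_data(init, cur, cur, cards)
  sc_bic <- family_score("x", list(), dd, score_config("bic"))
  expect_equal(sc_bic, 10 * log(0.5) - 0.5 * log(10), tolerance = 1e-12)
  one <- matrix(1L, 1, 1, dimnames = list(NULL, "x"))
  dd1 <- manual_dbn_data(one, one, one, cards)
  sc_bde <- family_score("x", list(), dd1, score_config("bde", ess = 1))
  expect_equal(sc_bde, log(0.5), tolerance = 1e-12)
})

test_that("an independent parent cannot raise the BIC score on null data", {
  withr::with_seed(5, {
    n <- 2000
    cards <- c(x = 2L, z = 2L)
    cur <- cbind(x = sample(1:2, n, TRUE), z = sample(1:2, n, TRUE))
    dd <- manual_dbn_data(cur, cur, cur, cards)
    s0 <- family_score("x", list(), dd, score_config("bic"))
    s1 <- family_score("x", list(intra = "z"), dd, score_config("bic"))
    expect_lt(s1, s0)
  })
})

test_that("families beyond the parent cap are rejected by name", {
  cards <- stats::setNames(rep(2L, 5), letters[1:5])
  m <- matrix(1L, 4, 5, dimnames = list(NULL, letters[1:5]))
  dd <- manual_dbn_data(m, m, m, cards)
  expect_error(family_score("a", list(intra = c("b", "c"),
                                      inter = c("d", "e")),
                            dd, score_config(max_parents = 3)),
               "max_parents")
})

test_that("move deltas equal full re-scores (decomposability)", {
  truth <- default_ground_truth_dbn(n_genes = 3)
  tc <- generate_timecourse(truth, 40, seed = 2)
  dd <- dbn_data(discretize(tc))
  cfg <- score_config(seed = 1)
  scorer <- oscctrack:::make_scorer(dd, cfg)
  ss <- oscctrack:::ss_empty(dd$vars)
  withr::with_seed(8, {
    for (i in 1:30) {
      moves <- oscctrack:::ss_moves(ss, cfg$max_parents)
      mv <- moves[[sample.int(length(moves), 1)]]
      delta <- oscctrack:::ss_delta(ss, mv, scorer)
      new_ss <- oscctrack:::ss_apply(ss, mv)
      full <- oscctrack:::ss_total_score(new_ss, scorer) -
        oscctrack:::ss_total_score(ss, scorer)
      expect_equal(delta, full, tolerance = 1e-9)
      ss <- new_ss
    }
  })
})

test_that("greedy search stays near-empty on independent data", {
  withr::with_seed(6, {
    vals <- array(rnorm(100 * 3 * 3, 8), dim = c(100, 3, 3),
                  dimnames = list(sprintf("P%03d", 1:100),
                                  paste0("g", 1:3),
                                  c("baseline", "fu1", "fu2")))
  })
  tc <- timecourse(vals, matrix(0L, 100, 3))
  dd <- dbn_data(discretize(tc))
  st <- greedy_search(dd, score_config(seed = 3), restarts = 2)
  gene_edges <- sum(st$intra$child != "relapse" | st$intra$parent != "relapse") -
    sum(st$intra$child == "relapse") +
    sum(st$inter$child != "relapse")
  expect_lte(nrow(st$intra) + nrow(st$inter), 3)
})

test_that("a planted inter-slice chain is recovered", {
  truth <- default_ground_truth_dbn(n_genes = 2, persistence = 0.9)
  tc <- generate_timecourse(truth, 300, seed = 4)
  dd <- dbn_data(discretize(tc))
  st <- greedy_search(dd, score_config(seed = 2), restarts = 2)
  found <- paste(st$inter$child, st$inter$parent)
  expect_true("g1 g1" %in% found)
  expect_true("g2 g2" %in% found)
  expect_gte(attr(st, "score"),
             oscctrack:::ss_total_score(oscctrack:::ss_empty(dd$vars),
                                        oscctrack:::make_scorer(dd, score_config())))
})

test_that("annealing is seed-reproducible and never ends below the empty score", {
  truth <- default_ground_truth_dbn(n_genes = 3)
  tc <- generate_timecourse(truth, 60, seed = 9)
  dd <- dbn_data(discretize(tc))
  cfg <- score_config(seed = 5)
  sched <- anneal_schedule(moves_per_temp = 20, seed = 7)
  a <- anneal_search(dd, cfg, sched)
  b <- anneal_search(dd, cfg, sched)
  expect_identical(a$intra, b$intra)
  expect_identical(a$inter, b$inter)
  empty_score <- oscctrack:::ss_total_score(oscctrack:::ss_empty(dd$vars),
                                            oscctrack:::make_scorer(dd, cfg))
  expect_gte(attr(a, "score"), empty_score)
})

test_that("both searches attain the exhaustive optimum on a small problem", {
  truth <- random_binary_dbn(4, max_parents = 1L, seed = 31)
  tc <- generate_timecourse(truth, 120, seed = 32, n_slices = 2)
  disc <- discretize(tc, 2)
  dd <- dbn_data(disc)
  cfg <- score_config(seed = 3, max_parents = 2L)
  opt <- oracle_structure_optimum(dd, cfg)
  st_g <- greedy_search(dd, cfg, restarts = 4)
  st_a <- anneal_search(dd, cfg, anneal_schedule(seed = 11))
  expect_equal(attr(st_g, "score"), opt, tolerance = 1e-9)
  expect_equal(attr(st_a, "score"), opt, tolerance = 1e-9)
})

test_that("CPT estimation smooths, saturates and falls back to uniform", {
  cards <- c(x = 2L)
  st <- dbn_structure("x")
  cur <- matrix(c(1L, 1L, 1L, 2L), ncol = 1, dimnames = list(NULL, "x"))
  dd <- manual_dbn_data(cur, cur, cur, cards)
  m1 <- fit_cpts(st, dd, pseudocount = 1)
  expect_equal(as.vector(m1$trans_cpts$x$table), c(4 / 6, 2 / 6))
  cur5 <- matrix(rep(1L, 5), ncol = 1, dimnames = list(NULL, "x"))
  dd5 <- manual_dbn_data(cur5, cur5, cur5, cards)
  m0 <- fit_cpts(st, dd5, pseudocount = 0)
  expect_equal(as.vector(m0$trans_cpts$x$table), c(1, 0))
  # unseen parent configuration -> uniform row
  cards2 <- c(x = 2L, p = 2L)
  cur2 <- cbind(x = c(1L, 2L), p = c(1L, 1L))
  dd2 <- manual_dbn_data(cur2, cur2, cur2, cards2)
  st2 <- dbn_structure(c("x", "p"),
                       intra = data.frame(child = "x", parent = "p"))
  mu <- fit_cpts(st2, dd2, pseudocount = 0)
  expect_equal(as.vector(mu$init_cpts$x$table[2, ]), c(0.5, 0.5))
})

test_that("exact inference matches full-joint enumeration on random nets", {
  for (seed in 1:30) {
    model <- random_binary_dbn(sample(2:4, 1), seed = seed)
    withr::with_seed(seed + 100, {
      vars <- model$structure$variables
      ne <- sample(0:3, 1)
      evidence <- if (ne > 0) {
        ev <- data.frame(variable = sample(vars, ne, TRUE),
                         slice = sample(1:3, ne, TRUE),
                         state = sample(1:2, ne, TRUE))
        ev[!duplicated(ev[c("variable", "slice")]), ]
      } else NULL
      qv <- sample(vars, 1); qs <- sample(1:3, 1)
    })
    got <- tryCatch(infer(model, evidence, qv, qs),
                    error = function(e) e)
    want <- oracle_dbn_posterior(model, evidence, qv, qs)
    if (inherits(got, "error")) {
      expect_true(grepl("inconsistent", conditionMessage(got)))
      expect_true(is.nan(want[1]))
    } else if (!is.null(evidence) &&
               any(evidence$variable == qv & evidence$slice == qs)) {
      st <- evidence$state[evidence$variable == qv & evidence$slice == qs][1]
      expect_equal(unname(got[st]), 1)
    } else {
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})

test_that("a two-slice chain posterior reads the transition CPT directly", {
  truth <- default_ground_truth_dbn(n_genes = 1, persistence = 0.9)
  p <- infer(truth, data.frame(variable = "g1", slice = 1, state = 2),
             "g1", 2, n_slices = 2)
  expect_equal(unname(p[2]), 0.9, tolerance = 1e-12)
})

test_that("relapse forecasts follow the prior when genes carry no signal", {
  truth <- default_ground_truth_dbn(n_genes = 2, hazard = rep(0.2, 3),
                                    init_relapse = 0.1)
  ev <- data.frame(variable = c("g1", "g2", "relapse"), slice = 1,
                   state = c(1L, 2L, 1L))
  fc <- predict_relapse(truth, ev)
  expect_equal(fc$p_relapse[fc$slice == 2], 0.2, tolerance = 1e-9)
  expect_equal(fc$p_relapse[fc$slice == 3], 0.2 + 0.8 * 0.2, tolerance = 1e-9)
  # observed relapse propagates with certainty (absorbing CPT)
  ev2 <- data.frame(variable = "relapse", slice = 1, state = 2L)
  fc2 <- predict_relapse(truth, ev2)
  expect_equal(fc2$p_relapse, c(1, 1), tolerance = 1e-12)
})

test_that("lopo_evaluate scores every patient and reaches 1.0 on noiseless dynamics", {
  truth <- default_ground_truth_dbn(n_genes = 4, deterministic = TRUE)
  tc <- generate_timecourse(truth, 18, n_relapsers = 8, seed = 6,
                            emission_sd = 0)
  res <- lopo_evaluate(tc, score_config(seed = 1), restarts = 1)
  expect_equal(nrow(res$folds), 18)
  expect_equal(res$baseline$accuracy, 1)
  expect_equal(res$baseline_fu1$accuracy, 1)
})

test_that("lopo_evaluate insists on 3 patients per class", {
  truth <- default_ground_truth_dbn(n_genes = 2)
  tc <- generate_timecourse(truth, 8, n_relapsers = 2, seed = 3)
  expect_error(lopo_evaluate(tc), "3 patients per class")
})
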