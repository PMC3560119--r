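test_that("cohort_spec validates fields and names the offender", {
  expect_error(cohort_spec(n_relapsers = 90), "n_relapsers")
  expect_error(cohort_spec(fold_change = 0.9), "fold_change")
  expect_error(cohort_spec(frac_control_probes = 1.2), "frac_control_probes")
  expect_error(cohort_spec(missing_heavy_rate = 0.5), "missing_heavy_rate")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
})

test_that("generated cohorts carry the requested class composition", {
  co <- generate_baseline_cohort(small_cohort_spec(n_patients = 86,
                                                   n_relapsers = 26))
  expect_equal(sum(co$truth$label == 1L), 26)
  expect_equal(sum(co$truth$label == 0L), 60)
  expect_identical(co$clinical$label, co$truth$label)
  expect_identical(co$imaging$label, co$truth$label)
})

test_that("planted DE genes hit the requested fold change exactly at zero noise", {
  co <- generate_baseline_cohort(small_cohort_spec(noise_sd = 0,
                                                   fold_change = 2,
                                                   n_de_genes = 1))
  g <- co$truth$de_tissue
  lin <- 2^co$tissue$values[g, ]
  ratio <- mean(lin[co$truth$label == 1L]) / mean(lin[co$truth$label == 0L])
  expect_equal(ratio, 2, tolerance = 1e-12)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- generate_baseline_cohort(small_cohort_spec(seed = 11))
  b <- generate_baseline_cohort(small_cohort_spec(seed = 11))
  c <- generate_baseline_cohort(small_cohort_spec(seed = 12))
  expect_identical(a$clinical$data, b$clinical$data)
  expect_identical(a$tissue$values, b$tissue$values)
  expect_false(identical(a$tissue$values, c$tissue$values))
})

test_that("heavy-missing features exceed 90% missingness; flags are planted", {
  co <- generate_baseline_cohort(small_cohort_spec())
  for (nm in co$truth$heavy_missing_clinical)
    expect_gt(mean(is.na(co$clinical$data[[nm]])), 0.9)
  ann <- co$tissue$annotation
  expect_equal(sum(ann$is_control), round(0.05 * 200))
  expect_equal(sum(!is.na(ann$duplicate_of)), round(0.1 * 200))
})

test_that("edge-free uniform dynamics sample at their exact marginals", {
  genes <- paste0("g", 1:2)
  vars <- c(genes, "relapse")
  st <- dbn_structure(vars)
  cards <- stats::setNames(c(3L, 3L, 2L), vars)
  init <- list(); trans <- list()
  for (g in genes) {
    init[[g]] <- oscctrack:::uniform_cpt(character(0), character(0), cards, 3L)
    trans[[g]] <- oscctrack:::uniform_cpt(character(0), character(0), cards, 3L)
  }
  init$relapse <- oscctrack:::make_cpt(character(0), character(0),
                                       matrix(c(0.8, 0.2), 1))
  trans$relapse <- oscctrack:::make_cpt(character(0), character(0),
                                        matrix(c(0.9, 0.1), 1))
  truth <- dbn_model(st, cards, init, trans)
  n <- 1000
  tc <- generate_timecourse(truth, n, seed = 5)
  # genes: uniform 1/3 at every slice (3 SE band)
  for (g in genes) for (t in 1:3) {
    freq <- tabulate(tc$states[, g, t], 3) / n
    expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / n)))
  }
  # relapse at baseline: matches its initial CPT
  p0 <- mean(tc$relapse[, 1] == 1L)
  expect_lt(abs(p0 - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("deterministic CPTs collapse every patient onto one trajectory", {
  truth <- default_ground_truth_dbn(n_genes = 3, deterministic = TRUE)
  # also make the initial gene states deterministic
  for (g in paste0("g", 1:3))
    truth$init_cpts[[g]]$table <- matrix(c(0, 1, 0), 1)
  tc <- generate_timecourse(truth, 20, seed = 3, emission_sd = 0)
  for (t in 1:3)
    expect_true(all(apply(tc$states[, , t], 2, function(s)
      length(unique(s)) == 1L)))
})

test_that("relapse is absorbing regardless of parent configuration", {
  truth <- default_ground_truth_dbn(n_genes = 3, init_relapse = 0.9,
                                    hazard = c(0, 0, 0))
  tc <- generate_timecourse(truth, 200, seed = 9)
  rel <- tc$relapse
  expect_true(all(rel[, 2] >= rel[, 1]))
  expect_true(all(rel[, 3] >= rel[, 2]))
  started <- rel[, 1] == 1L
  expect_true(all(rel[started, 2] == 1L))
})

test_that("requested time-course class split is met by conditioning", {
  truth <- default_ground_truth_dbn(n_genes = 3)
  tc <- generate_timecourse(truth, 23, n_relapsers = 11, seed = 21)
  expect_equal(sum(tc$relapse[, 3] == 1L), 11)
  expect_equal(sum(tc$relapse[, 3] == 0L), 12)
})

test_that("sampled joint frequencies match exact enumeration (chi-square)", {
  truth <- random_binary_dbn(2, max_parents = 1L, seed = 13)
  n <- 5000
  tc <- generate_timecourse(truth, n, seed = 17)
  # joint over all 6 unrolled binary nodes, relapse absorption included
  combos <- as.matrix(expand.grid(rep(list(1:2), 6)))
  vars <- truth$structure$variables
  obs_code <- (tc$states[, vars[1], 1] - 1) +
    (tc$states[, vars[2], 1] - 1) * 2 +
    (tc$states[, vars[1], 2] - 1) * 4 +
    (tc$states[, vars[2], 2] - 1) * 8 +
    (tc$states[, vars[1], 3] - 1) * 16 +
    (tc$states[, vars[2], 3] - 1) * 32
  obs <- tabulate(obs_code + 1, 64)
  # expected: enumeration with explicit absorption of the relapse node
  p_exp <- numeric(64)
  for (i in seq_len(64)) {
    s <- matrix(combos[i, ], nrow = 2)  # vars x slices
    rownames(s) <- vars
    rel <- s["relapse", ]
    if (any(diff(rel) < 0)) { p_exp[i] <- 0; next }
    p <- 1
    for (t in 1:3) for (v in vars) {
      cp <- if (t == 1) truth$init_cpts[[v]] else truth$trans_cpts[[v]]
      if (v == "relapse" && t > 1 && rel[t - 1] == 2) next  # absorbed
      pa <- c(s[cp$intra, t], if (t > 1) s[cp$inter, t - 1])
      row <- oscctrack:::cfg_index(matrix(pa, nrow = 1),
                                   truth$cards[c(cp$intra, cp$inter)])
      p <- p * cp$table[row, s[v, t]]
    }
    p_exp[i] <- p
  }
  keep <- p_exp * n >= 5
  chi <- sum((obs[keep] - n * p_exp[keep])^2 / (n * p_exp[keep]))
  expect_lt(chi, stats::qchisq(0.99, df = sum(keep) - 1))
})

test_that("feature tables round-trip through the TSV writers", {
  co <- generate_baseline_cohort(small_cohort_spec())
  t <- drop_sparse_features(co$clinical)
  path <- tempfile(fileext = ".tsv")
  write_feature_table(t, path)
  back <- read_feature_table(path)
  expect_identical(back$label, t$label)
  expect_equal(back$data, t$data, tolerance = 1e-9)
})
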