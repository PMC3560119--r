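test_that("naive Bayes reproduces the hand-computed smoothed posterior", {
  # class 1: 3 of 4 positive; class 0: 1 of 4 positive; equal priors,
  # Laplace 1 -> P(class1 | positive) = (4/6) / ((4/6) + (2/6)) = 2/3
  t <- make_table(data.frame(f = c("pos", "pos", "pos", "neg",
                                   "pos", "neg", "neg", "neg"),
                             stringsAsFactors = FALSE),
                  label = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  m <- train_classifier(t, "nb")
  te <- make_table(data.frame(f = "pos", stringsAsFactors = FALSE))
  expect_equal(predict(m, te)$score, 2 / 3, tolerance = 1e-12)
})

test_that("a decision tree on a pure-label table predicts that label", {
  t <- make_table(data.frame(x = rnorm(10)), label = rep(1L, 10))
  m <- train_classifier(t, "dt")
  expect_true(all(predict(m, t)$predicted_label == 1L))
})

test_that("training is reproducible and unknown kinds are rejected", {
  t <- informative_table()
  m1 <- train_classifier(t, "dt", seed = 4)
  m2 <- train_classifier(t, "dt", seed = 4)
  expect_identical(predict(m1, t), predict(m2, t))
  expect_error(train_classifier(t, "svm"), "nb, dt")
})

test_that("metric panel matches brute-force confusion and pair counting", {
  withr::with_seed(10, {
    for (i in 1:200) {
      n <- sample(5:30, 1)
      truth <- rbinom(n, 1, 0.4)
      if (length(unique(truth)) < 2) next
      pred <- rbinom(n, 1, 0.5)
      score <- round(runif(n), 2)  # rounded to force score ties
      m <- compute_metrics(pred, truth, score)
      o <- oracle_confusion_metrics(pred, truth)
      expect_equal(m$accuracy, o$accuracy)
      expect_equal(m$sensitivity, o$sensitivity)
      expect_equal(m$specificity, o$specificity)
      expect_equal(m$kappa, o$kappa)
      expect_equal(m$auc, oracle_auc_pairs(score, truth), tolerance = 1e-12)
    }
  })
})

test_that("the Table-12-shaped confusion table gives Se 63.6%, Sp 100%", {
  truth <- c(rep(1L, 11), rep(0L, 12))
  pred <- c(rep(1L, 7), rep(0L, 4), rep(0L, 12))  # TP 7, FN 4, TN 12, FP 0
  m <- compute_metrics(pred, truth)
  expect_equal(round(100 * m$sensitivity, 1), 63.6)
  expect_equal(100 * m$specificity, 100)
})

test_that("degenerate panels behave: perfect kappa, all-tie AUC", {
  truth <- c(1L, 1L, 0L, 0L)
  m <- compute_metrics(truth, truth)
  expect_equal(m$kappa, 1)
  m2 <- compute_metrics(c(1L, 0L, 1L, 0L), truth, score = rep(0.5, 4))
  expect_equal(m2$auc, 0.5)
})

perfect_table <- function(n = 40, seed = 2) {
  label <- rep(c(0L, 1L), n / 2)
  make_table(data.frame(sig = ifelse(label == 1L, "yes", "no"),
                        stringsAsFactors = FALSE),
             label = label)
}

test_that("a perfect learner reaches 1.0 on every metric in both schemes", {
  t <- perfect_table()
  for (scheme in c("cv10", "lopo")) {
    ev <- evaluate(t, "nb", scheme, seed = 1)
    expect_equal(ev$accuracy, 1)
    expect_equal(ev$kappa, 1)
    expect_equal(ev$auc, 1)
  }
})

test_that("a constant-majority learner shows base-rate accuracy, kappa 0", {
  co <- generate_baseline_cohort(small_cohort_spec(n_patients = 86,
                                                   n_relapsers = 26))
  t <- impute(drop_sparse_features(co$clinical))
  constant0 <- function(table, seed) function(new) rep(0, nrow(new$data))
  ev <- evaluate(t, constant0, "lopo", seed = 1)
  expect_equal(ev$accuracy, 60 / 86, tolerance = 1e-12)
  expect_equal(ev$kappa, 0)
  expect_equal(nrow(ev$predictions), 86)  # fold count = patient count
})

test_that("held-out patients never leak into their own training fold", {
  t <- perfect_table(n = 30)
  seen <- list()
  spy <- function(table, seed) {
    seen[[length(seen) + 1L]] <<- table$patient_ids
    function(new) rep(0.5, nrow(new$data))
  }
  ev <- evaluate(t, spy, "cv10", seed = 3,
                 smote_cfg = smote_config(k_neighbors = 3))
  folds <- oscctrack:::stratified_folds(t$label, 10L, 3L)
  for (f in seq_along(seen)) {
    held_out <- t$patient_ids[folds == f]
    expect_length(intersect(held_out, seen[[f]]), 0)
  }
})

test_that("single-source fusion is the identity", {
  pred <- data.frame(patient_id = c("a", "b", "c"),
                     predicted_label = c(1L, 0L, 1L),
                     score = c(0.9, 0.2, 0.6))
  fm <- fusion_model("clinical")
  out <- fuse(list(clinical = pred), fm)
  expect_identical(out$predicted_label, pred$predicted_label)
})

test_that("uniform-weight fusion over an odd panel is simple majority", {
  mk <- function(labels) data.frame(patient_id = c("a", "b"),
                                    predicted_label = labels,
                                    score = labels)
  preds <- list(s1 = mk(c(1L, 0L)), s2 = mk(c(1L, 0L)), s3 = mk(c(0L, 1L)))
  fm <- fusion_model(names(preds))
  out <- fuse(preds, fm)
  expect_identical(out$predicted_label, c(1L, 0L))
  expect_equal(out$score, c(2 / 3, 1 / 3))
})

test_that("a dominant source outvotes the rest; exact ties call relapse", {
  mk <- function(l) data.frame(patient_id = "a", predicted_label = l,
                               score = l)
  preds <- list(s1 = mk(1L), s2 = mk(0L), s3 = mk(0L), s4 = mk(0L))
  fm <- fusion_model(names(preds), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(fuse(preds, fm)$predicted_label, 1L)
  tie <- fusion_model(c("s1", "s2"), c(0.5, 0.5))
  out <- fuse(list(s1 = mk(1L), s2 = mk(0L)), tie)
  expect_equal(out$score, 0.5)
  expect_equal(out$predicted_label, 1L)  # sensitivity-first tie rule
})

test_that("fusion weights normalize per-source accuracies", {
  rep_of <- function(acc) structure(list(accuracy = acc),
                                    class = "eval_report")
  fm <- fit_fusion_weights(list(a = rep_of(0.8), b = rep_of(0.8),
                                c = rep_of(0.8), d = rep_of(0.95)))
  expect_equal(sum(fm$weights), 1)
  expect_equal(unname(fm$weights["d"]), 0.95 / 3.35, tolerance = 1e-12)
  expect_equal(unname(fm$weights["a"]), 0.8 / 3.35, tolerance = 1e-12)
  # equal accuracies -> uniform; single source -> weight 1
  fm2 <- fit_fusion_weights(list(a = rep_of(0.7), b = rep_of(0.7)))
  expect_equal(unname(fm2$weights), c(0.5, 0.5))
  expect_equal(unname(fit_fusion_weights(list(a = rep_of(0.9)))$weights), 1)
})

test_that("fusion renormalizes over available sources and flags orphans", {
  p1 <- data.frame(patient_id = c("a", "b"), predicted_label = c(1L, 1L),
                   score = c(1, 1))
  p2 <- data.frame(patient_id = "a", predicted_label = 0L, score = 0)
  fm <- fusion_model(c("s1", "s2"), c(0.3, 0.7))
  out <- fuse(list(s1 = p1, s2 = p2), fm)
  expect_equal(out$predicted_label[out$patient_id == "b"], 1L)
  p1_na <- data.frame(patient_id = c("a", "b"),
                      predicted_label = c(1L, NA), score = c(1, NA))
  p2_na <- data.frame(patient_id = c("a", "b"),
                      predicted_label = c(0L, NA), score = c(0, NA))
  expect_error(fuse(list(s1 = p1_na, s2 = p2_na), fm), "no source")
})
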