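#' Specification of a synthetic multimodal cohort
#'
#' Defaults emulate the study conditions the pipeline is designed for: an
#' 86-patient OSCC cohort with 26 relapsers and 60 non-relapsers, clinical
#' (~62 features) and imaging (~16 features) tables, and 45,015-probe
#' one-channel arrays of which probe-level QC retains 33,491 (2251 control
#' + 4501 duplicate + 3601 low-quality + 1171 high-missing probes removed).
#'
#' @param n_patients,n_relapsers cohort size and relapse count.
#' @param n_clinical,n_imaging number of clinical / imaging features.
#' @param n_probes probes per array.
#' @param frac_control_probes,frac_duplicate_probes,frac_low_quality,frac_missing_probes
#'   proportions of probes flagged as control, duplicate (non-first member
#'   of a duplicate group), low quality, or carrying >50% missing values.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param fold_change planted linear-scale fold change (> 1) between
#'   relapsers and non-relapsers for the DE genes.
#' @param missing_heavy_features number of clinical/imaging columns given
#'   near-complete missingness (each table).
#' @param missing_heavy_rate missingness rate for those columns, in (0.9, 1].
#' @param noise_sd standard deviation of expression noise on the log2 scale.
#' @param seed integer seed controlling every random draw.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 86, n_relapsers = 26,
                        n_clinical = 62, n_imaging = 16,
                        n_probes = 45015,
                        frac_control_probes = 2251 / 45015,
                        frac_duplicate_probes = 4501 / 45015,
                        frac_low_quality = 3601 / 45015,
                        frac_missing_probes = 1171 / 45015,
                        n_de_genes = 9, fold_change = 1.8,
                        missing_heavy_features = 2,
                        missing_heavy_rate = 0.95,
                        noise_sd = 1, seed = 1L) {
  spec <- list(n_patients = check_count(n_patients, "n_patients", 2L),
               n_relapsers = check_count(n_relapsers, "n_relapsers", 1L),
               n_clinical = check_count(n_clinical, "n_clinical", 1L),
               n_imaging = check_count(n_imaging, "n_imaging", 1L),
               n_probes = check_count(n_probes, "n_probes", 1L),
               frac_control_probes = check_proportion(frac_control_probes, "frac_control_probes"),
               frac_duplicate_probes = check_proportion(frac_duplicate_probes, "frac_duplicate_probes"),
               frac_low_quality = check_proportion(frac_low_quality, "frac_low_quality"),
               frac_missing_probes = check_proportion(frac_missing_probes, "frac_missing_probes"),
               n_de_genes = check_count(n_de_genes, "n_de_genes", 0L),
               fold_change = fold_change,
               missing_heavy_features = check_count(missing_heavy_features, "missing_heavy_features", 0L),
               missing_heavy_rate = missing_heavy_rate,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (spec$n_relapsers > spec$n_patients)
    stop_field("n_relapsers", "cannot exceed n_patients")
  if (!is.numeric(fold_change) || fold_change <= 1)
    stop_field("fold_change", "must be a ratio > 1")
  if (missing_heavy_rate <= 0.9 || missing_heavy_rate > 1)
    stop_field("missing_heavy_rate", "must lie in (0.9, 1]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_field("noise_sd", "must be nonnegative")
  structure(spec, class = "cohort_spec")
}

# Mixed nominal/numeric table; informative features carry class signal.
simulate_feature_table <- function(prefix, n_features, label, n_informative,
                                   missing_heavy, missing_heavy_rate) {
  n <- length(label)
  nm <- sprintf("%s_%02d", prefix, seq_len(n_features))
  is_nominal <- rep_len(c(TRUE, TRUE, FALSE), n_features) # ~2/3 nominal
  informative <- sort(sample.int(n_features, min(n_informative, n_features)))
  cols <- vector("list", n_features)
  for (j in seq_len(n_features)) {
    if (is_nominal[j]) {
      k <- sample(2:4, 1L)
      lev <- letters[seq_len(k)]
      if (j %in% informative) {
        # class-dependent category probabilities
        p1 <- rep(1, k); p1[1L] <- 4
        p0 <- rep(1, k); p0[k] <- 4
        col <- ifelse(label == 1L,
                      sample(lev, n, TRUE, p1 / sum(p1)),
                      sample(lev, n, TRUE, p0 / sum(p0)))
      } else {
        col <- sample(lev, n, TRUE)
      }
    } else {
      shift <- if (j %in% informative) 1.2 else 0
      col <- stats::rnorm(n, mean = 10 + shift * label, sd = 1)
    }
    cols[[j]] <- col
  }
  df <- as.data.frame(cols, col.names = nm, stringsAsFactors = FALSE)
  # missingness, completely at random
  heavy <- setdiff(seq_len(n_features), informative)
  heavy <- utils::head(heavy, missing_heavy)
  for (j in seq_len(n_features)) {
    rate <- if (j %in% heavy) missing_heavy_rate else 0.05
    miss <- stats::runif(n) < rate
    if (j %in% heavy && sum(miss) / n <= 0.9) {
      # guarantee the >90% sparsity the heavy columns exist to exercise
      miss[sample.int(n, ceiling(0.9 * n) + 1L)] <- TRUE
    }
    df[[j]][miss] <- NA
  }
  list(table = feature_table(df, label = label),
       informative = nm[informative], heavy = nm[heavy])
}

# Probe annotation with disjoint control/duplicate/low-quality/high-missing
# sets; duplicate probes copy the values of a clean base probe.
simulate_expression <- function(spec, label, sample_prefix) {
  n <- spec$n_patients
  p <- spec$n_probes
  n_ctrl <- round(spec$frac_control_probes * p)
  n_dup <- round(spec$frac_duplicate_probes * p)
  n_lowq <- round(spec$frac_low_quality * p)
  n_miss <- round(spec$frac_missing_probes * p)
  if (n_ctrl + n_dup + n_lowq + n_miss + spec$n_de_genes > p)
    stop_field("n_probes", "too few probes for the requested flag fractions")
  probe_ids <- sprintf("PR%06d", seq_len(p))
  idx <- seq_len(p)
  ctrl <- idx[seq_len(n_ctrl)]
  dup <- idx[n_ctrl + seq_len(n_dup)]
  lowq <- idx[n_ctrl + n_dup + seq_len(n_lowq)]
  hmiss <- idx[n_ctrl + n_dup + n_lowq + seq_len(n_miss)]
  clean <- setdiff(idx, c(ctrl, dup, lowq, hmiss))
  de <- utils::tail(clean, spec$n_de_genes)

  vals <- matrix(stats::rnorm(p * n, mean = 8, sd = spec$noise_sd), p, n)
  if (spec$n_de_genes > 0)
    vals[de, label == 1L] <- vals[de, label == 1L] + log2(spec$fold_change)
  # duplicates replicate an unflagged base probe
  base <- if (length(clean)) clean[(seq_along(dup) - 1L) %% length(clean) + 1L] else integer(0)
  dup_of <- rep(NA_character_, p)
  if (length(dup)) {
    vals[dup, ] <- vals[base, , drop = FALSE]
    dup_of[dup] <- probe_ids[base]
  }
  if (length(lowq))
    vals[lowq, ] <- vals[lowq, ] + stats::rnorm(length(lowq) * n, sd = 2)
  if (length(hmiss)) {
    gone <- matrix(stats::runif(length(hmiss) * n) < 0.6, length(hmiss), n)
    short <- rowSums(gone) / n <= 0.5
    gone[short, seq_len(ceiling(0.5 * n) + 1L)] <- TRUE
    vals[hmiss, ][gone] <- NA
  }
  rownames(vals) <- probe_ids
  colnames(vals) <- sprintf("%s%03d", sample_prefix, seq_len(n))
  ann <- data.frame(probe_id = probe_ids,
                    is_control = idx %in% ctrl,
                    duplicate_of = dup_of,
                    quality_flag = idx %in% lowq,
                    missing_frac = rowMeans(is.na(vals)),
                    stringsAsFactors = FALSE)
  list(m = expression_matrix(vals, ann), de = probe_ids[de])
}

#' Generate a synthetic baseline cohort with known ground truth
#'
#' Produces clinical and imaging feature tables, tissue and blood
#' expression matrices with probe-level QC flags, and a record of the
#' planted signal. Non-DE probes are drawn around a log2 intensity of 8;
#' planted DE probes are shifted upward by `log2(fold_change)` in
#' relapsers, so the expected linear-scale class-mean ratio equals the
#' requested fold change. Regeneration with the same spec is bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `clinical`, `imaging` ([feature_table()]s),
#'   `tissue`, `blood` ([expression_matrix()]s) and `truth` (planted DE
#'   probe ids per matrix, informative feature ids, heavy-missing feature
#'   ids, and the label vector).
#' @export
generate_baseline_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    label <- sample(c(rep(1L, spec$n_relapsers),
                      rep(0L, spec$n_patients - spec$n_relapsers)))
    clin <- simulate_feature_table("clin", spec$n_clinical, label,
                                   n_informative = 6,
                                   spec$missing_heavy_features,
                                   spec$missing_heavy_rate)
    img <- simulate_feature_table("img", spec$n_imaging, label,
                                  n_informative = 4,
                                  spec$missing_heavy_features,
                                  spec$missing_heavy_rate)
    tissue <- simulate_expression(spec, label, "T")
    blood <- simulate_expression(spec, label, "B")
  })
  list(clinical = clin$table, imaging = img$table,
       tissue = tissue$m, blood = blood$m,
       truth = list(label = label,
                    de_tissue = tissue$de, de_blood = blood$de,
                    informative_clinical = clin$informative,
                    informative_imaging = img$informative,
                    heavy_missing_clinical = clin$heavy,
                    heavy_missing_imaging = img$heavy))
}
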