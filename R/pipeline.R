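# End-to-end experiment driver: generate -> QC -> harmonise -> MSN ->
# feature sets -> split -> algorithm/kernel selection on internal
# validation -> single held-out test evaluation -> robustness ->
# delta screens, with a run manifest recording seeds and sizes.

#' Default experiment configuration
#'
#' Nested configuration for [run_experiment()]. The evaluation defaults
#' are the scaled-down sizes used in day-to-day runs; `paper_scale =
#' TRUE` switches to 100 resampling partitions and 1000 permutations.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_subjects Cohort size before QC.
#' @param feature_sets Feature sets to model.
#' @param paper_scale Use full-size robustness settings.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, n_subjects = 361,
                               feature_sets = feature_set_names(),
                               paper_scale = FALSE) {
  structure(list(
    seed = as.integer(seed),
    generator = cohort_config(n_subjects = n_subjects, seed = seed),
    qc = list(z_cut = -1.5, max_fail = 1),
    harmonisation = list(eb = TRUE),
    msn = list(density_grid = NULL),   # e.g. seq(0.05, 0.5, 0.05)
    split = list(train_frac = 0.75, internal_frac = 5 / 6,
                 bin_width = 0.5, collapse_below = 9,
                 seed = seed + 1000L, internal_seed = seed + 2000L),
    model = list(algorithms = c("GPR", "RVR"),
                 kernels = c("laplacedot", "rbfdot"),
                 noise_var = 1),
    evaluation = list(
      n_partitions = if (paper_scale) 100L else 20L,
      n_perm = if (paper_scale) 1000L else 99L,
      alpha = 0.05, bonferroni_models = 10L,
      resample_seed = seed + 3000L, perm_seed = seed + 4000L,
      run_robustness = TRUE, run_permutation = TRUE),
    delta = list(alpha = 0.05, n_tests = 60L),
    feature_sets = feature_sets
  ), class = "run_config")
}

.fit_on <- function(cfg, algorithm, kernel, X, y) {
  if (algorithm == "GPR") {
    fit_age_model("GPR", X, y, kernel, noise_var = cfg$model$noise_var)
  } else {
    fit_age_model("RVR", X, y, kernel)
  }
}

#' Run the full Brainage experiment
#'
#' Executes the whole pipeline on a synthetic cohort (or a supplied
#' one): QC filtering, per-feature harmonisation protecting age, MSN
#' construction, age-stratified 3:1 train/test and 5:1 internal splits,
#' algorithm + kernel selection per feature set on the internal
#' validation cohort, retraining on the full training cohort with a
#' single evaluation on the held-out test cohort, then (optionally)
#' resampling CIs, permutation null models and the delta bias screen.
#'
#' @param config A [default_run_config()] list.
#' @param cohort Optional pre-generated cohort (as from
#'   [generate_cohort()]); generated from `config$generator` when
#'   `NULL`.
#' @param out_dir Optional directory; when given, all result tables and
#'   the manifest are written there as CSV/TSV/JSON.
#' @return List: `selection_grid`, `selection`, `test_results`,
#'   `robustness`, `deltas`, `bias_screen`, `manifest`, plus the
#'   intermediate `cohort`, `split`, `feature_matrices`.
#' @export
run_experiment <- function(config = default_run_config(), cohort = NULL,
                           out_dir = NULL) {
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, stages = list(),
                   versions = list(
                     package = as.character(utils::packageVersion("brainagemsn")),
                     r = R.version.string))
  tick <- function(stage, info) {
    manifest$stages[[stage]] <<- c(info, list(
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if (is.null(cohort)) cohort <- generate_cohort(config$generator)
  tick("generate", list(n_subjects = nrow(cohort$morphometry),
                        generator_seed = config$generator$seed))

  qc <- apply_qc_filter(zscore_qa_within_site(cohort$qa),
                        z_cut = config$qc$z_cut,
                        max_fail = config$qc$max_fail)
  included <- qc$subject_id[qc$included]
  morph <- cohort$morphometry[cohort$morphometry$subject_id %in% included, ]
  tick("qc", list(n_included = length(included),
                  n_excluded = sum(!qc$included)))

  harm <- harmonize_cohort(morph, eb = config$harmonisation$eb)
  morph <- harm$morphometry
  tick("harmonise", list(eb = config$harmonisation$eb))

  msns <- build_cohort_msns(morph)
  tick("msn", list(n_graphs = length(msns)))

  split <- stratified_undersample(
    morph$subject_id, morph$age,
    train_frac = config$split$train_frac,
    bin_width = config$split$bin_width,
    collapse_below = config$split$collapse_below,
    seed = config$split$seed)
  split <- internal_split(split, frac = config$split$internal_frac,
                          seed = config$split$internal_seed)
  tick("split", list(
    n_internal_train = sum(split$partition == "internal_train"),
    n_internal_validation = sum(split$partition == "internal_validation"),
    n_test = sum(split$partition == "test"),
    split_seed = config$split$seed))

  ages <- stats::setNames(morph$age, morph$subject_id)
  id_int <- split_ids(split, "internal_train")
  id_val <- split_ids(split, "internal_validation")
  id_train <- split_ids(split, "train")
  id_test <- split_ids(split, "test")

  feats <- lapply(config$feature_sets, function(fs) {
    assemble_feature_set(fs, morph, msns)
  })
  names(feats) <- config$feature_sets

  # --- algorithm / kernel selection on the internal validation cohort
  grid <- list()
  for (fs in config$feature_sets) {
    X <- feats[[fs]]
    for (alg in config$model$algorithms) {
      for (k in config$model$kernels) {
        m <- .fit_on(config, alg, k, X[id_int, , drop = FALSE],
                     ages[id_int])
        tr_m <- eval_metrics(m, X[id_int, , drop = FALSE], ages[id_int])
        va_m <- eval_metrics(m, X[id_val, , drop = FALSE], ages[id_val])
        grid[[length(grid) + 1]] <- tibble::tibble(
          feature_set = fs, algorithm = alg, kernel = k,
          train_mae = tr_m$mae, train_pred_r2 = tr_m$pred_r2,
          mae = va_m$mae, pred_r2 = va_m$pred_r2)
      }
    }
  }
  grid <- dplyr::bind_rows(grid)
  selection <- select_model(grid)
  tick("selection", list(n_cells = nrow(grid)))

  # --- retrain on the full training cohort; single held-out evaluation
  test_rows <- list()
  deltas <- list()
  test_access <- stats::setNames(integer(length(config$feature_sets)),
                                 config$feature_sets)
  for (i in seq_len(nrow(selection))) {
    fs <- selection$feature_set[i]
    X <- feats[[fs]]
    m <- .fit_on(config, selection$algorithm[i], selection$kernel[i],
                 X[id_train, , drop = FALSE], ages[id_train])
    tr_m <- eval_metrics(m, X[id_train, , drop = FALSE], ages[id_train])
    pred_test <- predict_age(m, X[id_test, , drop = FALSE])
    test_access[fs] <- test_access[fs] + 1L
    test_rows[[i]] <- tibble::tibble(
      feature_set = fs,
      algorithm = selection$algorithm[i], kernel = selection$kernel[i],
      train_mae = tr_m$mae, train_pred_r2 = tr_m$pred_r2,
      test_mae = mae(pred_test, ages[id_test]),
      test_pred_r2 = predicted_r2(pred_test, ages[id_test]))
    deltas[[fs]] <- compute_delta(id_test, as.numeric(ages[id_test]),
                                  pred_test)
  }
  test_results <- dplyr::bind_rows(test_rows)
  tick("test_evaluation", list(test_access = as.list(test_access)))

  # --- robustness: resampling CIs and permutation null models
  robustness <- NULL
  if (isTRUE(config$evaluation$run_robustness)) {
    rob_rows <- list()
    for (i in seq_len(nrow(selection))) {
      fs <- selection$feature_set[i]
      rr <- resample_performance(
        feats[[fs]], as.numeric(ages), selection$algorithm[i],
        selection$kernel[i],
        n_partitions = config$evaluation$n_partitions,
        seed = config$evaluation$resample_seed,
        train_frac = config$split$train_frac,
        bin_width = config$split$bin_width,
        collapse_below = config$split$collapse_below,
        noise_var = if (selection$algorithm[i] == "GPR")
          config$model$noise_var else NULL)
      p <- NA_real_
      if (isTRUE(config$evaluation$run_permutation)) {
        pt <- permutation_nhst(
          feats[[fs]], as.numeric(ages), split, rr$mean_pred_r2,
          selection$algorithm[i], selection$kernel[i],
          n_perm = config$evaluation$n_perm,
          seed = config$evaluation$perm_seed,
          noise_var = if (selection$algorithm[i] == "GPR")
            config$model$noise_var else NULL)
        p <- pt$p_value
      }
      alpha_bonf <- config$evaluation$alpha /
        config$evaluation$bonferroni_models
      rob_rows[[i]] <- tibble::tibble(
        feature_set = fs,
        mean_pred_r2 = rr$mean_pred_r2,
        ci_lower = rr$ci[1], ci_upper = rr$ci[2],
        n_partitions = rr$n_partitions, n_effective = rr$n_effective,
        p_value = p, n_perm = config$evaluation$n_perm,
        significant = !is.na(p) & p < alpha_bonf)
    }
    robustness <- dplyr::bind_rows(rob_rows)
    tick("robustness", list(n_partitions = config$evaluation$n_partitions,
                            n_perm = config$evaluation$n_perm))
  }

  # --- delta bias screen
  covars <- tibble::tibble(
    subject_id = morph$subject_id,
    efc = cohort$qa$efc[match(morph$subject_id, cohort$qa$subject_id)],
    iq = morph$iq, sex = morph$sex)
  bias_screen <- covariate_screen(deltas, covars,
                                  alpha = config$delta$alpha,
                                  n_tests = config$delta$n_tests)
  tick("delta_screen", list(n_rows = nrow(bias_screen)))

  result <- list(
    selection_grid = grid, selection = selection,
    test_results = test_results, robustness = robustness,
    deltas = deltas, bias_screen = bias_screen,
    manifest = manifest, split = split,
    cohort = cohort, feature_matrices = feats)

  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' Write an experiment's result tables and manifest
#'
#' @param result Output of [run_experiment()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(result$selection_grid, "selection_grid.tsv")
  wt(result$selection, "selection.tsv")
  wt(result$test_results, "test_results.tsv")
  if (!is.null(result$robustness)) wt(result$robustness, "robustness.tsv")
  wt(result$bias_screen, "bias_screen.tsv")
  wt(result$split, "split_assignment.tsv")
  for (fs in names(result$deltas)) {
    utils::write.csv(result$deltas[[fs]],
                     file.path(out_dir, paste0("delta_", fs, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
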