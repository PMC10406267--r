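#' Experiment configuration
#'
#' Bundles the cohort specification, model and training settings, the input
#' ablation arms, and the evaluation alignment conditions (vertex-jitter
#' levels emulating surface registrations of different quality, plus an
#' optional volumetric-correlation mode).
#'
#' @param cohort a [cohort_spec()].
#' @param arms character vector from `t1+t2+dti12`, `t1+t2`, `t1`,
#'   `cortex-mask`, `subcortical-mask`, `brain-mask`, `permutation`,
#'   `linear`.
#' @param model list of [model_config()] arguments (without
#'   `in_channels`/`out_maps`, filled per arm).
#' @param train a [train_config()].
#' @param alignment_conditions list of `list(name, type, jitter_mm)` with
#'   `type` `"surface"` or `"volume"`.
#' @param atlas a [task_atlas()].
#' @param linear_channels channel set used as the linear-baseline feature
#'   stack; the per-vertex OLS needs more training subjects than features + 1,
#'   so small cohorts should use `"t1+t2"` or `"t1"`.
#' @param output_dir optional directory for run artifacts (checkpoints,
#'   per-arm results, consolidated table).
#' @param seed master seed for splits, training and evaluation jitter.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              arms = c("t1+t2+dti12", "permutation"),
                              model = list(base_channels = 8L, depth = 3L),
                              train = train_config(max_epochs = 15L),
                              alignment_conditions = list(
                                list(name = "aligned", type = "surface", jitter_mm = 0)),
                              atlas = default_task_atlas(),
                              linear_channels = "t1+t2",
                              output_dir = NULL, seed = 1L) {
  valid <- c("t1+t2+dti12", "t1+t2", "t1", "cortex-mask", "subcortical-mask",
             "brain-mask", "permutation", "linear")
  bad <- setdiff(arms, valid)
  if (length(bad))
    stop(sprintf("unknown arm(s) %s; valid arms: %s",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")))
  if (length(arms) == 0L) stop("arms must be nonempty")
  for (cc in alignment_conditions)
    stopifnot(is.character(cc$name), cc$type %in% c("surface", "volume"))
  structure(list(cohort = cohort, arms = arms, model = model, train = train,
                 alignment_conditions = alignment_conditions, atlas = atlas,
                 linear_channels = linear_channels,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

arm_channels <- function(arm) {
  switch(arm,
         "t1+t2+dti12" = "t1+t2+dti12",
         "permutation" = "t1+t2+dti12",
         "t1+t2" = "t1+t2",
         "t1" = "t1",
         "cortex-mask" = "cortex-mask",
         "subcortical-mask" = "subcortical-mask",
         "brain-mask" = "brain-mask",
         stop(sprintf("arm '%s' has no channel configuration", arm)))
}

n_arm_channels <- function(channels) {
  switch(channels, "t1+t2+dti12" = 14L, "t1+t2" = 2L, 1L)
}

#' Predict activation volumes for a list of subjects
#'
#' @param model a trained `unet_model`.
#' @param subjects list of `subject_record`s.
#' @param atlas a [task_atlas()].
#' @param channels input channel set.
#' @param target_shape stack spatial shape.
#' @return list (per subject) of named lists of predicted volumes.
#' @export
predict_cohort <- function(model, subjects, atlas, channels = "t1+t2+dti12",
                           target_shape = NULL) {
  lapply(subjects, function(s) {
    stack <- build_feature_stack(s, target_shape = target_shape,
                                 channels = channels)
    predict_activations(model, stack, atlas)
  })
}

# per-subject jittered templates, seeded deterministically
subject_templates <- function(template, n, jitter_mm, seed) {
  lapply(seq_len(n), function(i) {
    if (jitter_mm <= 0) template
    else with_seed(seed + 7919L * i, jitter_template(template, jitter_mm))
  })
}

# sample per-subject volume lists onto per-subject templates:
# returns list(per_map = list of S x V matrices, all = S x (V*M) matrix)
surface_map_matrices <- function(vols_by_subject, atlas, templates, ids) {
  S <- length(vols_by_subject)
  per_map <- lapply(atlas$maps$map, function(m) {
    M <- t(vapply(seq_len(S), function(i)
      sample_to_surface(vols_by_subject[[i]][[m]], templates[[i]]),
      numeric(nrow(templates[[1]]$vertices))))
    rownames(M) <- ids
    M
  })
  names(per_map) <- atlas$maps$map
  all <- do.call(cbind, per_map)
  rownames(all) <- ids
  list(per_map = per_map, all = all)
}

volume_map_matrices <- function(vols_by_subject, atlas, mask, ids) {
  per_map <- lapply(atlas$maps$map, function(m) {
    M <- t(vapply(vols_by_subject, function(v) v[[m]][mask],
                  numeric(sum(mask))))
    rownames(M) <- ids
    M
  })
  names(per_map) <- atlas$maps$map
  all <- do.call(cbind, per_map)
  rownames(all) <- ids
  list(per_map = per_map, all = all)
}

# Core identifiability statistics given prebuilt subject x feature matrices.
surface_eval_stats <- function(mats_pred, mats_act, atlas, alpha = 0.05) {
  C <- correlation_matrix(mats_pred$all, mats_act$all)
  ks <- ks_diag_test(C, alpha = alpha)
  delta <- self_vs_other(C)
  thr <- bonferroni(alpha, atlas$n_maps)
  per_map <- do.call(rbind, lapply(atlas$maps$map, function(m) {
    Cm <- correlation_matrix(mats_pred$per_map[[m]], mats_act$per_map[[m]])
    km <- ks_diag_test(Cm, alpha = thr)
    data.frame(map = m, D = km$D, p = km$p, significant = km$p < thr,
               delta = self_vs_other(Cm))
  }))
  # pooled variant: each map's correlations are z-scored against that map's
  # own off-diagonal distribution (the pooled analogue of row/column
  # normalization), then diagonal/off-diagonal elements are pooled across
  # maps before the KS test — more powerful at small subject counts
  pooled <- lapply(atlas$maps$map, function(m) {
    Cm <- unclass(correlation_matrix(mats_pred$per_map[[m]],
                                     mats_act$per_map[[m]]))
    o <- Cm[row(Cm) != col(Cm)]
    list(d = (diag(Cm) - mean(o)) / sd(o), o = (o - mean(o)) / sd(o))
  })
  z_diag <- unlist(lapply(pooled, `[[`, "d"))
  z_offdiag <- unlist(lapply(pooled, `[[`, "o"))
  ksp <- ks_two_sample(z_diag, z_offdiag)
  list(C = C, ks = ks, delta = delta, per_map = per_map,
       ks_pooled = list(D = ksp$D, p = ksp$p,
                        n_diag = length(z_diag), n_offdiag = length(z_offdiag),
                        z_diag = z_diag, z_offdiag = z_offdiag),
       bonferroni_threshold = thr,
       mean_diag = mean(diag_values(C)), mean_offdiag = mean(offdiag_values(C)))
}

li_regressions <- function(mats_pred, mats_act, atlas, template,
                           li_domains = c("LANGUAGE", "SOCIAL", "WM"),
                           radius_mm = 10) {
  maps <- atlas$maps$map[atlas$maps$domain %in% li_domains]
  if (length(maps) == 0L) return(NULL)
  alpha <- bonferroni(0.05, length(maps))
  do.call(rbind, lapply(maps, function(m) {
    lis <- t(vapply(seq_len(nrow(mats_pred$per_map[[m]])), function(i) {
      r <- lateralization_index(mats_pred$per_map[[m]][i, ],
                                mats_act$per_map[[m]][i, ],
                                template, radius_mm = radius_mm)
      c(r$li_pred, r$li_actual)
    }, numeric(2)))
    if (sd(lis[, 1]) == 0 || sd(lis[, 2]) == 0)
      return(data.frame(map = m, slope = NA_real_, intercept = NA_real_,
                        r = NA_real_, p = NA_real_, significant = FALSE,
                        n = nrow(lis), row.names = NULL))
    fit <- lm(lis[, 2] ~ lis[, 1])
    ct <- stats::cor.test(lis[, 1], lis[, 2])
    data.frame(map = m, slope = coef(fit)[2], intercept = coef(fit)[1],
               r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha, n = nrow(lis),
               row.names = NULL)
  }))
}

# mean per-vertex ICC(3,1) across subjects for each map
icc_tables <- function(m1, m2) {
  vals <- vapply(seq_len(ncol(m1)), function(v) {
    tryCatch(icc31(m1[, v], m2[, v]), error = function(e) NA_real_)
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Evaluate predictions for one arm under one alignment condition
#'
#' @param pred_vols per-subject lists of predicted volumes (or an
#'   S x V x M array for the linear baseline).
#' @param subjects test `subject_record`s (session 1).
#' @param template shared [surface_template()].
#' @param atlas a [task_atlas()].
#' @param condition `list(name, type, jitter_mm)`.
#' @param seed evaluation seed (jitter draws).
#' @param retest_subjects optional session-2 records for the same subjects.
#' @param retest_pred optional per-subject predicted volumes for session 2
#'   (defaults to `pred_vols`: deterministic models predict identically from
#'   identical structural data).
#' @param covariate_vols optional per-subject predicted volumes from a
#'   covariate model (partial-correlation analysis).
#' @return list of evaluation statistics (class `eval_report`).
#' @export
evaluate_arm_condition <- function(pred_vols, subjects, template, atlas,
                                   condition = list(name = "aligned",
                                                    type = "surface",
                                                    jitter_mm = 0),
                                   seed = 1L, retest_subjects = NULL,
                                   retest_pred = NULL, covariate_vols = NULL) {
  ids <- vapply(subjects, `[[`, "", "subject_id")
  S <- length(subjects)
  act_vols <- lapply(subjects, `[[`, "activations")
  if (condition$type == "volume") {
    mask <- subjects[[1]]$brain_mask
    mats_act <- volume_map_matrices(act_vols, atlas, mask, ids)
    mats_pred <- volume_map_matrices(pred_vols, atlas, mask, ids)
    templates <- NULL
  } else {
    templates <- subject_templates(template, S, condition$jitter_mm %||% 0, seed)
    mats_act <- surface_map_matrices(act_vols, atlas, templates, ids)
    mats_pred <- if (is.array(pred_vols))
      vertex_array_to_matrices(pred_vols, atlas, ids)
    else surface_map_matrices(pred_vols, atlas, templates, ids)
  }
  stats <- surface_eval_stats(mats_pred, mats_act, atlas)
  li <- if (condition$type == "surface")
    li_regressions(mats_pred, mats_act, atlas, template) else NULL
  icc <- NULL
  if (!is.null(retest_subjects) && condition$type == "surface") {
    act2 <- lapply(retest_subjects, `[[`, "activations")
    mats_act2 <- surface_map_matrices(act2, atlas, templates, ids)
    pred2 <- retest_pred %||% pred_vols
    mats_pred2 <- if (is.array(pred2)) vertex_array_to_matrices(pred2, atlas, ids)
    else surface_map_matrices(pred2, atlas, templates, ids)
    icc <- data.frame(
      map = atlas$maps$map,
      icc_actual = vapply(atlas$maps$map, function(m)
        icc_tables(mats_act$per_map[[m]], mats_act2$per_map[[m]]), 0),
      icc_pred = vapply(atlas$maps$map, function(m)
        icc_tables(mats_pred$per_map[[m]], mats_pred2$per_map[[m]]), 0),
      row.names = NULL)
  }
  partial <- NULL
  if (!is.null(covariate_vols) && condition$type == "surface") {
    mats_cov <- surface_map_matrices(covariate_vols, atlas, templates, ids)
    Cp <- matrix(0, S, S, dimnames = list(ids, ids))
    for (i in seq_len(S)) for (j in seq_len(S))
      Cp[i, j] <- partial_correlation(mats_pred$all[i, ], mats_act$all[j, ],
                                      mats_cov$all[i, ])
    partial <- list(C = Cp, ks = ks_diag_test(Cp), delta = self_vs_other(Cp))
  }
  structure(c(stats, list(condition = condition$name, li = li, icc = icc,
                          partial = partial, n_subjects = S)),
            class = "eval_report")
}

#' Pool standardized correlations across evaluation sessions
#'
#' Combines the per-map standardized diagonal/off-diagonal correlation
#' samples of several `eval_report`s — e.g. evaluations of the same
#' predictions against independent acquisition sessions generated with
#' [regenerate_session()] — into a single two-sample KS test. More
#' measurement sessions mean more power for the same subjects.
#'
#' @param reports list of `eval_report`s.
#' @return list with `D`, `p`, `n_diag`, `n_offdiag`, `n_sessions`.
#' @export
pooled_session_ks <- function(reports) {
  zd <- unlist(lapply(reports, function(r) r$ks_pooled$z_diag))
  zo <- unlist(lapply(reports, function(r) r$ks_pooled$z_offdiag))
  ks <- ks_two_sample(zd, zo)
  list(D = ks$D, p = ks$p, n_diag = length(zd), n_offdiag = length(zo),
       n_sessions = length(reports))
}

vertex_array_to_matrices <- function(arr, atlas, ids) {
  per_map <- lapply(seq_len(atlas$n_maps), function(m) {
    M <- arr[, , m]
    rownames(M) <- ids
    M
  })
  names(per_map) <- atlas$maps$map
  all <- do.call(cbind, per_map)
  rownames(all) <- ids
  list(per_map = per_map, all = all)
}

split_cohort <- function(cohort) {
  n <- cohort$spec$n_subjects
  n_test <- max(4L, floor(0.3 * n))
  n_val <- max(2L, floor(0.1 * n))
  n_train <- n - n_test - n_val
  if (n_train < 1L) stop("cohort too small to split into train/val/test")
  list(train = cohort$subjects[seq_len(n_train)],
       val = cohort$subjects[n_train + seq_len(n_val)],
       test = cohort$subjects[n_train + n_val + seq_len(n_test)],
       test_retest = if (!is.null(cohort$retest))
         cohort$retest[n_train + n_val + seq_len(n_test)] else NULL)
}

#' Train one ablation arm on a cohort
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param arm arm name (see [experiment_config()]).
#' @param model_args list of extra [model_config()] arguments.
#' @param train_cfg a [train_config()].
#' @param linear_channels feature channel set for the linear arm.
#' @return list with `arm`, `channels`, and either `model`+`history` (CNN
#'   arms) or `fit` (linear arm).
#' @export
train_arm <- function(cohort, arm, model_args = list(),
                      train_cfg = train_config(), linear_channels = "t1+t2") {
  split <- split_cohort(cohort)
  atlas <- cohort$atlas
  if (arm == "linear") {
    feats <- vertex_feature_matrix(split$train, cohort$template,
                                   channels = linear_channels)
    targ <- vertex_target_array(split$train, cohort$template, atlas)
    fit <- fit_linear_baseline(feats, targ)
    return(list(arm = arm, channels = linear_channels, fit = fit))
  }
  channels <- arm_channels(arm)
  tr_data <- prepare_dataset(split$train, atlas, channels)
  va_data <- prepare_dataset(split$val, atlas, channels)
  cfg <- do.call(model_config, c(list(
    in_channels = n_arm_channels(channels), out_maps = atlas$n_maps,
    channel_names = tr_data[[1]]$stack$channel_names), model_args))
  model <- build_model(cfg, seed = train_cfg$seed)
  trainer <- if (arm == "permutation") train_permutation_baseline else train_model
  out <- trainer(model, tr_data, va_data, atlas, train_cfg)
  c(list(arm = arm, channels = channels), out)
}

#' Per-vertex activation targets for the linear baseline
#'
#' @param subjects list of `subject_record`s.
#' @param template a [surface_template()].
#' @param atlas a [task_atlas()].
#' @return subjects x vertices x maps array.
#' @export
vertex_target_array <- function(subjects, template, atlas) {
  out <- array(0, dim = c(length(subjects), nrow(template$vertices),
                          atlas$n_maps))
  for (i in seq_along(subjects))
    for (m in seq_len(atlas$n_maps))
      out[i, , m] <- sample_to_surface(
        subjects[[i]]$activations[[atlas$maps$map[m]]], template)
  out
}

#' Run a full ablation experiment
#'
#' Simulates the cohort, trains one model (or baseline) per arm on the
#' training split, predicts the held-out test split, and evaluates every
#' (arm, alignment condition) combination: self-vs-other delta, KS diagonal
#' test, per-map Bonferroni-corrected tests, lateralization regressions, and
#' (when the cohort has a retest session) ICC(3,1) reliability. Fully seeded;
#' when `output_dir` is set, per-arm results are written and completed arms
#' are resumed rather than retrained (a changed configuration for an existing
#' arm directory is an error).
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return object of class `experiment_report`: list with `table` (one row
#'   per arm x condition), `arms` (per-arm details), `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$cohort, atlas = config$atlas)
  split <- split_cohort(cohort)
  atlas <- config$atlas
  out_dir <- config$output_dir
  cfg_json <- jsonlite::toJSON(config[c("arms", "model", "alignment_conditions",
                                        "linear_channels", "seed")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  arms_out <- list()
  rows <- list()
  for (arm in config$arms) {
    arm_dir <- if (!is.null(out_dir)) file.path(out_dir, gsub("[^a-z0-9]+", "_", arm))
    resumed <- FALSE
    if (!is.null(arm_dir) && file.exists(file.path(arm_dir, "config.json"))) {
      stored <- paste(readLines(file.path(arm_dir, "config.json")), collapse = "")
      if (!identical(stored, as.character(cfg_json)))
        stop(sprintf("resume collision: arm '%s' was previously run with a different configuration", arm))
      if (file.exists(file.path(arm_dir, "checkpoint.rds"))) {
        trained <- readRDS(file.path(arm_dir, "checkpoint.rds"))
        resumed <- TRUE
      }
    }
    if (!resumed) {
      if (verbose) message("training arm: ", arm)
      tc <- config$train
      tc$seed <- config$seed + match(arm, config$arms)
      trained <- train_arm(cohort, arm, config$model, tc,
                           linear_channels = config$linear_channels)
      if (!is.null(arm_dir)) {
        dir.create(arm_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(as.character(cfg_json), file.path(arm_dir, "config.json"))
        saveRDS(trained, file.path(arm_dir, "checkpoint.rds"))
      }
    }
    pred <- if (arm == "linear") {
      feats_te <- vertex_feature_matrix(split$test, cohort$template,
                                        channels = trained$channels)
      predict_linear_baseline(trained$fit, feats_te)
    } else {
      predict_cohort(trained$model, split$test, atlas, trained$channels)
    }
    evals <- list()
    for (cond in config$alignment_conditions) {
      if (arm == "linear" && cond$type == "volume") next
      ev <- evaluate_arm_condition(pred, split$test, cohort$template, atlas,
                                   condition = cond, seed = config$seed,
                                   retest_subjects = split$test_retest)
      evals[[cond$name]] <- ev
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, condition = cond$name,
        delta = ev$delta, ks_D = ev$ks$D, ks_p = ev$ks$p,
        significant = ev$ks$significant,
        mean_diag = ev$mean_diag, mean_offdiag = ev$mean_offdiag,
        n_maps_significant = sum(ev$per_map$significant),
        icc_pred = if (!is.null(ev$icc)) mean(ev$icc$icc_pred) else NA_real_,
        icc_actual = if (!is.null(ev$icc)) mean(ev$icc$icc_actual) else NA_real_)
    }
    arms_out[[arm]] <- list(trained = trained, evals = evals)
  }
  table <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(table, file.path(out_dir, "ablation_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(table, file.path(out_dir, "ablation_table.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  structure(list(table = table, arms = arms_out, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("ablation experiment:", nrow(x$table), "arm x condition rows\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation (%s): n = %d subjects\n", x$condition, x$n_subjects))
  cat(sprintf("  self-vs-other delta: %.4f\n", x$delta))
  cat(sprintf("  KS diag vs off-diag: D = %.3f, p = %.3g\n", x$ks$D, x$ks$p))
  cat(sprintf("  per-map significant: %d / %d (threshold %.4g)\n",
              sum(x$per_map$significant), nrow(x$per_map),
              x$bonferroni_threshold))
  invisible(x)
}
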