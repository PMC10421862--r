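#' Pipeline run configuration
#'
#' Bundles all stage settings of an end-to-end run. Every stochastic stage
#' receives a seed derived from the single `seed`, and each stage's outputs
#' are cached under a directory keyed by the hash of the settings that stage
#' depends on, so rerunning after changing, say, the rim width reuses the
#' phantom cache but recomputes regions, features and models.
#'
#' @param cohort a [cohort_config()] (or list of its arguments).
#' @param rim_mm,fat_hu region settings.
#' @param glcm_levels,window,gabor_orientations,gabor_wavelengths texture
#'   settings.
#' @param n_folds,cv_criterion LASSO-Cox cross-validation settings.
#' @param horizon_months nomogram / calibration / DCA horizon.
#' @param n_boot calibration bootstrap resamples.
#' @param cv_folds,cv_iterations response-classifier cross-validation.
#' @param train_fraction leading fraction of patients used for training; the
#'   rest form the validation cohort.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), rim_mm = 12,
                            fat_hu = c(-100, -10), glcm_levels = 64,
                            window = 5, gabor_orientations = 8,
                            gabor_wavelengths = c(2, 4, 6, 8, 10, 12),
                            n_folds = 100, cv_criterion = "deviance",
                            horizon_months = 36, n_boot = 500,
                            cv_folds = 3, cv_iterations = 100,
                            train_fraction = 0.5, seed = 1L) {
  if (!inherits(cohort, "cohort_config"))
    cohort <- do.call(cohort_config, as.list(cohort))
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with (possibly partial) pipeline settings; unknown
#'   keys are rejected.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage_dir <- function(out_dir, stage, key) {
  file.path(out_dir, paste0(stage, "-", key))
}

stage_done <- function(dir) file.exists(file.path(dir, ".done"))

mark_done <- function(dir) {
  writeLines("ok", file.path(dir, ".done"))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
}

provenance <- function(config, extra = list()) {
  c(list(config_hash = config_hash(unclass(config)),
         package_version = as.character(utils::packageVersion("deltarad")),
         seed = config$seed), extra)
}

#' Run the full delta-radiomics pipeline
#'
#' Executes simulate -> extract -> delta -> fit-survival -> nomogram/DCA ->
#' classify on a synthetic cohort, with per-stage caches keyed by the hash of
#' the settings each stage depends on and a manifest per stage. The cohort is
#' split into a training block (leading `train_fraction` of patients) and a
#' validation block; normalization, the LASSO penalty, the RRS cutoff and the
#' classifier threshold are fitted on training patients only.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @param out_dir run directory (created if needed).
#' @param stages subset of stages to run (later stages require earlier ones'
#'   caches).
#' @return Invisibly, a list with stage directories and headline results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "extract", "delta",
                                    "fit-survival", "nomogram", "classify")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list(config_hash = config_hash(unclass(config)))

  ## --- simulate ------------------------------------------------------------
  sim_key <- config_hash(unclass(config$cohort))
  sim_dir <- stage_dir(out_dir, "simulate", sim_key)
  if ("simulate" %in% stages && !stage_done(sim_dir)) run_stage("simulate", {
    dir.create(sim_dir, showWarnings = FALSE)
    cohort <- generate_cohort(config$cohort, out_dir = sim_dir)
    write_json_out(provenance(config, list(stage = "simulate", key = sim_key,
                                           n_patients = config$cohort$n_patients)),
                   file.path(sim_dir, "stage_manifest.json"))
    mark_done(sim_dir)
  })
  res$simulate <- sim_dir

  load_cohort <- function() {
    manifest <- utils::read.csv(file.path(sim_dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
    clinical <- read_clinical_table(file.path(sim_dir, "clinical.csv"))
    patients <- lapply(seq_len(nrow(manifest)), function(i) {
      pre_v <- read_volume(manifest$pre_volume[i], timepoint = "pre")
      post_v <- read_volume(manifest$post_volume[i], timepoint = "post")
      list(pre = list(volume = pre_v,
                      mask = read_mask(manifest$pre_mask[i], pre_v)),
           post = list(volume = post_v,
                       mask = read_mask(manifest$post_mask[i], post_v)))
    })
    structure(list(patients = patients, clinical = clinical,
                   ground_truth = utils::read.csv(
                     file.path(sim_dir, "ground_truth.csv"),
                     stringsAsFactors = FALSE),
                   config = config$cohort),
              class = "synthetic_cohort")
  }

  ## --- extract -------------------------------------------------------------
  ext_key <- config_hash(list(sim = sim_key, rim_mm = config$rim_mm,
                              fat_hu = config$fat_hu,
                              glcm_levels = config$glcm_levels,
                              window = config$window,
                              gabor_orientations = config$gabor_orientations,
                              gabor_wavelengths = config$gabor_wavelengths))
  ext_dir <- stage_dir(out_dir, "extract", ext_key)
  if ("extract" %in% stages && !stage_done(ext_dir)) run_stage("extract", {
    dir.create(ext_dir, showWarnings = FALSE)
    cohort <- load_cohort()
    feats <- extract_cohort_features(
      cohort, rim_mm = config$rim_mm, fat_hu = config$fat_hu,
      glcm_levels = config$glcm_levels, window = config$window,
      gabor_orientations = config$gabor_orientations,
      gabor_wavelengths = config$gabor_wavelengths)
    write_feature_table(feats, file.path(ext_dir, "features.csv"))
    write_json_out(provenance(config, list(stage = "extract", key = ext_key,
                                           n_rows = nrow(feats))),
                   file.path(ext_dir, "stage_manifest.json"))
    mark_done(ext_dir)
  })
  res$extract <- ext_dir

  split_ids <- function(clinical) {
    n <- nrow(clinical)
    ## at least 10 training patients (LASSO-Cox minimum), at least 2 held out
    n_train <- min(n - 2L, max(10L, ceiling(n * config$train_fraction)))
    list(train = clinical$patient_id[seq_len(n_train)],
         valid = clinical$patient_id[-seq_len(n_train)])
  }

  ## --- delta ---------------------------------------------------------------
  del_key <- config_hash(list(ext = ext_key,
                              train_fraction = config$train_fraction))
  del_dir <- stage_dir(out_dir, "delta", del_key)
  if ("delta" %in% stages && !stage_done(del_dir)) run_stage("delta", {
    dir.create(del_dir, showWarnings = FALSE)
    feats <- read_feature_table(file.path(ext_dir, "features.csv"))
    clinical <- read_clinical_table(file.path(sim_dir, "clinical.csv"))
    ids <- split_ids(clinical)
    norm <- fit_normalization(feats[feats$patient_id %in% ids$train, ,
                                    drop = FALSE])
    delta <- build_delta_table(feats, normalization = norm)$delta
    write_feature_table(delta, file.path(del_dir, "delta.csv"))
    write_json_out(list(feature = norm$feature, mean = norm$mean,
                        sd = norm$sd, dropped = norm$dropped),
                   file.path(del_dir, "normalization.json"))
    write_json_out(provenance(config, list(stage = "delta", key = del_key)),
                   file.path(del_dir, "stage_manifest.json"))
    mark_done(del_dir)
  })
  res$delta <- del_dir

  load_delta_split <- function() {
    delta <- read_feature_table(file.path(del_dir, "delta.csv"))
    clinical <- read_clinical_table(file.path(sim_dir, "clinical.csv"))
    ids <- split_ids(clinical)
    list(delta = delta, clinical = clinical, ids = ids,
         train = delta[delta$patient_id %in% ids$train, , drop = FALSE],
         valid = delta[delta$patient_id %in% ids$valid, , drop = FALSE],
         clin_train = clinical[clinical$patient_id %in% ids$train, , drop = FALSE],
         clin_valid = clinical[clinical$patient_id %in% ids$valid, , drop = FALSE])
  }

  ## --- fit-survival ----------------------------------------------------------
  fit_key <- config_hash(list(del = del_key, n_folds = config$n_folds,
                              cv_criterion = config$cv_criterion,
                              seed = config$seed))
  fit_dir <- stage_dir(out_dir, "fit-survival", fit_key)
  if ("fit-survival" %in% stages && !stage_done(fit_dir)) run_stage("fit-survival", {
    dir.create(fit_dir, showWarnings = FALSE)
    d <- load_delta_split()
    model <- fit_lasso_cox(d$train, d$clin_train,
                           n_folds = config$n_folds,
                           seed = derive_seed(config$seed, "lasso"),
                           cv_criterion = config$cv_criterion)
    write_json_out(c(list(features = model$features,
                          coefficients = unname(model$coefficients),
                          lambda = model$lambda,
                          rrs_cutoff = model$rrs_cutoff,
                          cv_criterion = model$cv_criterion,
                          n_folds = model$n_folds,
                          train_c_index = model$train_c_index),
                     provenance(config, list(stage = "fit-survival"))),
                   file.path(fit_dir, "model.json"))
    summ <- lapply(list(train = list(d$train, d$clin_train),
                        valid = list(d$valid, d$clin_valid)), function(dd) {
      sc <- predict(model, dd[[1]])
      grp <- stratify_by_cutoff(sc, model$rrs_cutoff)
      km <- if (nlevels(droplevels(grp)) == 2) km_logrank(grp, dd[[2]]) else NULL
      data.frame(
        n = length(sc),
        c_index = tryCatch(
          concordance_index(sc, dd[[2]]$os_months, dd[[2]]$event),
          error = function(e) NA_real_),  # tiny blocks may lack usable pairs
        logrank_p = if (is.null(km)) NA_real_ else km$p,
        median_low = if (is.null(km)) NA_real_ else unname(km$median_survival[1]),
        median_high = if (is.null(km)) NA_real_ else unname(km$median_survival[2]))
    })
    out <- cbind(cohort = names(summ), do.call(rbind, summ))
    utils::write.csv(out, file.path(fit_dir, "survival_summary.csv"),
                     row.names = FALSE)
    scores <- data.frame(patient_id = d$delta$patient_id,
                         rrs = predict(model, d$delta),
                         cohort = ifelse(d$delta$patient_id %in% d$ids$train,
                                         "train", "valid"))
    utils::write.csv(scores, file.path(fit_dir, "rrs_scores.csv"),
                     row.names = FALSE)
    mark_done(fit_dir)
  })
  res$fit_survival <- fit_dir

  ## --- nomogram / calibration / DCA -----------------------------------------
  nom_key <- config_hash(list(fit = fit_key, horizon = config$horizon_months,
                              n_boot = config$n_boot))
  nom_dir <- stage_dir(out_dir, "nomogram", nom_key)
  if ("nomogram" %in% stages && !stage_done(nom_dir)) run_stage("nomogram", {
    dir.create(nom_dir, showWarnings = FALSE)
    d <- load_delta_split()
    scores <- utils::read.csv(file.path(fit_dir, "rrs_scores.csv"),
                              stringsAsFactors = FALSE)
    rrs_tr <- scores$rrs[match(d$clin_train$patient_id, scores$patient_id)]
    nomo <- build_nomogram(d$clin_train, rrs_tr,
                           horizon_months = config$horizon_months)
    calib <- assess_calibration(nomo, n_boot = config$n_boot,
                                groups = max(3L, min(10L, nrow(d$clin_train) %/% 2L)),
                                seed = derive_seed(config$seed, "boot"))
    utils::write.csv(calib$table, file.path(nom_dir, "calibration.csv"),
                     row.names = FALSE)
    ## DCA on the validation block at the horizon (evaluable patients only:
    ## events by the horizon, or followed beyond it)
    rrs_va <- scores$rrs[match(d$clin_valid$patient_id, scores$patient_id)]
    cv <- d$clin_valid
    evaluable <- cv$os_months >= config$horizon_months |
      (cv$event == 1 & cv$os_months < config$horizon_months)
    pred <- predict(nomo, data.frame(
      .time = cv$os_months, .event = cv$event, rrs = rrs_va,
      age = cv$age, race = factor(cv$race,
                                  levels = levels(nomo$train_data$race)),
      baseline_tumor_volume_ml = cv$baseline_tumor_volume_ml), type = "risk")
    outcome <- as.integer(cv$event == 1 & cv$os_months < config$horizon_months)
    dca <- decision_curve(pred[evaluable], outcome[evaluable])
    utils::write.csv(as.data.frame(dca), file.path(nom_dir, "dca.csv"),
                     row.names = FALSE)
    write_json_out(c(list(c_index = nomo$c_index,
                          hl_p = calib$p,
                          c_corrected = calib$c_corrected,
                          points = nomo$point_scale),
                     provenance(config, list(stage = "nomogram"))),
                   file.path(nom_dir, "nomogram.json"))
    mark_done(nom_dir)
  })
  res$nomogram <- nom_dir

  ## --- classify --------------------------------------------------------------
  cls_key <- config_hash(list(fit = fit_key, cv_folds = config$cv_folds,
                              cv_iterations = config$cv_iterations))
  cls_dir <- stage_dir(out_dir, "classify", cls_key)
  if ("classify" %in% stages && !stage_done(cls_dir)) run_stage("classify", {
    dir.create(cls_dir, showWarnings = FALSE)
    d <- load_delta_split()
    model_json <- jsonlite::read_json(file.path(fit_dir, "model.json"),
                                      simplifyVector = TRUE)
    feats <- model_json$features
    if (length(feats) == 0)
      stop("no LASSO-selected features available for the classifier")
    xtr <- as.matrix(d$train[, feats, drop = FALSE])
    ytr <- factor(d$clin_train$response,
                  levels = c("responder", "non-responder"))
    cva <- cv_auc(xtr, ytr, folds = config$cv_folds,
                  iterations = config$cv_iterations,
                  seed = derive_seed(config$seed, "cv"),
                  positive = "non-responder")
    lda <- train_lda(xtr, ytr, positive = "non-responder")
    rep_ <- evaluate_holdout(lda, as.matrix(d$valid[, feats, drop = FALSE]),
                             factor(d$clin_valid$response,
                                    levels = c("responder", "non-responder")))
    utils::write.csv(data.frame(iteration = seq_along(cva$trace),
                                auc = cva$trace),
                     file.path(cls_dir, "cv_trace.csv"), row.names = FALSE)
    write_json_out(c(list(cv_mean_auc = cva$mean_auc, cv_ci = cva$ci,
                          holdout_auc = rep_$auc, holdout_auc_ci = rep_$auc_ci,
                          accuracy = rep_$accuracy,
                          sensitivity = rep_$sensitivity,
                          specificity = rep_$specificity,
                          threshold = rep_$threshold),
                     provenance(config, list(stage = "classify"))),
                   file.path(cls_dir, "classifier.json"))
    mark_done(cls_dir)
  })
  res$classify <- cls_dir

  invisible(res)
}
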