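#' Pipeline configuration
#'
#' Bundles the cohort specifications, network/training configuration and
#' analysis parameters for a full desk-scale study run. The two
#' validation cohorts are never used for network training or LASSO
#' fitting; [run_pipeline()] enforces case-id disjointness and aborts on
#' any overlap.
#'
#' @param train_spec,indep_spec,ext_spec [cohort_spec()]s for the
#'   training, independent validation and external validation cohorts.
#' @param net_cfg a [network_config()].
#' @param train_cfg a [training_config()].
#' @param icc_threshold ICC retention cutoff (default 0.6).
#' @param cv_folds LASSO cross-validation folds.
#' @param perturb_magnitude boundary displacement (px) used to simulate
#'   the second rater and the repeat session.
#' @param patch_margin bounding-box margin (px) for patch extraction.
#' @param roi_area_mm2 measurement ROI area for SWE quantification.
#' @param repeat_jitter_sd kPa jitter between simulated repeat
#'   measurements.
#' @param seed master seed; all stage seeds are derived from it.
#' @param outdir run directory (created by [run_pipeline()]).
#' @param write_images also write the cohort image bundles under
#'   `outdir/cohorts` (slower; off by default).
#' @return object of class `swerad_pipeline_config`.
#' @export
pipeline_config <- function(train_spec, indep_spec, ext_spec, net_cfg,
                            train_cfg, icc_threshold = 0.6, cv_folds = 5,
                            perturb_magnitude = 1.5, patch_margin = 2L,
                            roi_area_mm2 = 2, repeat_jitter_sd = 2,
                            seed = 1L, outdir = tempfile("swerad_run_"),
                            write_images = FALSE) {
  structure(list(train_spec = train_spec, indep_spec = indep_spec,
                 ext_spec = ext_spec, net_cfg = net_cfg,
                 train_cfg = train_cfg, icc_threshold = icc_threshold,
                 cv_folds = cv_folds, perturb_magnitude = perturb_magnitude,
                 patch_margin = as.integer(patch_margin),
                 roi_area_mm2 = roi_area_mm2,
                 repeat_jitter_sd = repeat_jitter_sd,
                 seed = as.integer(seed), outdir = outdir,
                 write_images = write_images,
                 id_prefixes = c(training = "tr", independent = "iv",
                                 external = "ev")),
            class = "swerad_pipeline_config")
}

#' Default desk-scale configuration
#'
#' Cohorts of 40 (20/20), 16 (8/8) and 8 (4/4) cases with strong class
#' separation (stiffness gap 100 kPa, distinct texture heterogeneity) and
#' a reduced 48 x 64 network input, sized so a full run completes in
#' minutes on one CPU while exercising every stage.
#'
#' @param outdir run directory.
#' @param seed master seed.
#' @param epochs training epochs for the desk-scale CNN.
#' @param input_size reduced network input `c(h, w, channels)`.
#' @param null_cohort generate zero-separation cohorts (identical class
#'   distributions) instead of the separable defaults.
#' @param ... overrides passed to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
desk_config <- function(outdir = tempfile("swerad_run_"), seed = 1L,
                        epochs = 12L, input_size = c(48L, 64L, 3L),
                        null_cohort = FALSE, ...) {
  spec_for <- function(nb, nm, spec_seed) {
    if (null_cohort)
      cohort_spec(nb, nm, image_height = 128L, image_width = 128L,
                  benign_stiffness_mean = 45, malignant_stiffness_mean = 45,
                  rim_stiffness_boost = 0,
                  texture_heterogeneity = c(benign = 0.15, malignant = 0.15),
                  bmode_lesion_brightness = c(benign = 0.35,
                                              malignant = 0.35),
                  lesion_diameter_range = c(3, 5), birads_error_rate = 0.5,
                  seed = spec_seed)
    else
      cohort_spec(nb, nm, image_height = 128L, image_width = 128L,
                  lesion_diameter_range = c(3, 5), seed = spec_seed)
  }
  base_seed <- as.integer(seed)
  pipeline_config(
    train_spec = spec_for(20L, 20L, base_seed + 101L),
    indep_spec = spec_for(8L, 8L, base_seed + 202L),
    ext_spec = spec_for(4L, 4L, base_seed + 303L),
    net_cfg = network_config(input_size = input_size),
    train_cfg = training_config(epochs = epochs, seed = base_seed + 404L),
    seed = base_seed, outdir = outdir, ...)
}

# Null-cohort benign/malignant cases are drawn from one distribution; the
# generator still requires malignant mean >= benign mean, satisfied at
# equality above.

null_sum <- function(x) sum(unlist(lapply(x, as.numeric)), na.rm = TRUE)

config_hash <- function(cfg) {
  # order-stable fingerprint of the numeric content of the config
  v <- c(null_sum(cfg$train_spec), null_sum(cfg$indep_spec),
         null_sum(cfg$ext_spec), null_sum(cfg$net_cfg),
         null_sum(cfg$train_cfg), cfg$icc_threshold, cfg$cv_folds,
         cfg$perturb_magnitude, cfg$seed)
  sprintf("%08x", sum(as.integer(abs(v * 1000) %% 1e6) *
                        seq_along(v)) %% .Machine$integer.max)
}

stage_log <- function(run, stage, seed, t0) {
  row <- data.frame(stage = stage, seed = seed,
                    wall_seconds = round(as.numeric(Sys.time()) - t0, 2))
  path <- file.path(run, "run_log.csv")
  write.table(row, path, sep = ",", col.names = !file.exists(path),
              row.names = FALSE, append = file.exists(path))
}

modality_image <- function(case, modality) {
  switch(modality, bmode = case$bmode, swe = case$swe_color)
}

modality_mask <- function(case, modality) {
  switch(modality, bmode = case$bmode_mask, swe = case$swe_mask)
}

cohort_patches <- function(cases, modality, cfg, masks = NULL) {
  lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    extract_patch(modality_image(cs, modality),
                  if (is.null(masks)) modality_mask(cs, modality)
                  else masks[[i]],
                  margin = cfg$patch_margin,
                  target_size = cfg$net_cfg$input_size[1:2],
                  modality = modality, case_id = cs$case_id)
  })
}

cohort_labels <- function(cases)
  vapply(cases, `[[`, character(1), "label")

#' Run the full desk-scale study
#'
#' Executes, in order and for both modalities: cohort simulation,
#' rater-perturbed segmentations, patch extraction, CNN training,
#' deep-feature extraction, ICC reproducibility filtering, LASSO
#' signature fitting with Youden thresholds, quantitative SWE
#' parameters, and diagnostic evaluation of every classifier on the
#' training and both validation cohorts. Artifacts (signatures, feature
#' CSVs, report tables, run log) are written under `cfg$outdir` and
#' stamped with a config hash and the master seed.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with the signatures, reports and the run
#'   directory.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "swerad_pipeline_config"))
  run <- cfg$outdir
  if (!dir.exists(run)) dir.create(run, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  seeds <- with_seed(cfg$seed, sample.int(2^30, 64))
  jsonlite::write_json(list(config_hash = config_hash(cfg), seed = cfg$seed,
                            icc_threshold = cfg$icc_threshold),
                       file.path(run, "config.json"), auto_unbox = TRUE)

  px <- cfg$id_prefixes
  cohorts <- list(
    training = generate_cohort(cfg$train_spec, id_prefix = px[["training"]]),
    independent = generate_cohort(cfg$indep_spec,
                                  id_prefix = px[["independent"]]),
    external = generate_cohort(cfg$ext_spec, id_prefix = px[["external"]]))
  ids <- lapply(cohorts, function(ch) vapply(ch, `[[`, character(1),
                                             "case_id"))
  if (anyDuplicated(unlist(ids)))
    stop("leakage error: overlapping case ids across cohorts")
  if (cfg$write_images)
    for (nm in names(cohorts))
      write_cohort(cohorts[[nm]], file.path(run, "cohorts", nm))
  stage_log(run, "simulate", cfg$seed, t0)

  labels <- lapply(cohorts, cohort_labels)
  signatures <- list(); reports <- list(); scatter <- list()

  for (modality in c("bmode", "swe")) {
    tr <- cohorts$training
    # reader 1 session 1 = the given masks; session 2 and reader 2 are
    # smooth boundary perturbations with per-case derived seeds
    masks_r1s1 <- lapply(tr, modality_mask, modality = modality)
    pseed <- seeds[if (modality == "bmode") 1L else 2L]
    masks_r1s2 <- lapply(seq_along(tr), function(i)
      perturb_mask(masks_r1s1[[i]], cfg$perturb_magnitude, pseed + 2L * i))
    masks_r2 <- lapply(seq_along(tr), function(i)
      perturb_mask(masks_r1s1[[i]], cfg$perturb_magnitude,
                   pseed + 2L * i + 1L))

    patches <- list(
      r1s1 = cohort_patches(tr, modality, cfg),
      r1s2 = cohort_patches(tr, modality, cfg, masks_r1s2),
      r2 = cohort_patches(tr, modality, cfg, masks_r2))
    stage_log(run, paste0("patches_", modality), pseed, t0)

    tcfg <- cfg$train_cfg
    tcfg$seed <- seeds[if (modality == "bmode") 3L else 4L]
    cnn <- train_network(patches$r1s1, labels$training, cfg$net_cfg, tcfg)
    write_cnn(cnn, file.path(run, sprintf("cnn_%s.rds", modality)))
    stage_log(run, paste0("train_cnn_", modality), tcfg$seed, t0)

    feats <- lapply(patches, function(p) extract_features(cnn, p))
    val_feats <- lapply(cohorts[c("independent", "external")], function(ch)
      extract_features(cnn, cohort_patches(ch, modality, cfg)))
    utils::write.csv(
      data.frame(case_id = rownames(feats$r1s1), modality = modality,
                 feats$r1s1, check.names = FALSE),
      file.path(run, sprintf("features_%s_train.csv", modality)),
      row.names = FALSE)
    stage_log(run, paste0("features_", modality), NA, t0)

    iccs <- filter_reproducible_features(feats$r1s1, feats$r1s2, feats$r2,
                                         threshold = cfg$icc_threshold)
    utils::write.csv(iccs, file.path(run, sprintf("icc_%s.csv", modality)),
                     row.names = FALSE)
    retained <- iccs$feature_index[iccs$retained]
    if (length(retained) < 2)
      stop("fewer than two reproducible features survive the ICC screen")
    stage_log(run, paste0("icc_filter_", modality), NA, t0)

    lseed <- seeds[if (modality == "bmode") 5L else 6L]
    model <- fit_lasso_signature(feats$r1s1[, retained, drop = FALSE],
                                 labels$training, cv_folds = cfg$cv_folds,
                                 seed = lseed, modality = modality,
                                 column_index = retained)
    write_signature(model, file.path(run,
                                     sprintf("signature_%s.json", modality)))
    signatures[[modality]] <- model
    stage_log(run, paste0("fit_signature_", modality), lseed, t0)

    rs_name <- if (modality == "bmode") "B-US-RS" else "SWE-RS"
    all_feats <- c(list(training = feats$r1s1), val_feats)
    for (cohort in names(cohorts)) {
      scores <- rad_score(model, pad_features(all_feats[[cohort]], model))
      rep <- diagnostic_report(
        rs_name, scores, labels[[cohort]], model$threshold,
        positive_high = model$orientation == "higher_is_malignant")
      reports[[cohort]][[rs_name]] <- rep
      scatter[[length(scatter) + 1L]] <- data.frame(
        cohort = cohort, classifier = rs_name,
        case_id = ids[[cohort]], score = scores,
        label = labels[[cohort]], stringsAsFactors = FALSE)
    }
  }

  # quantitative SWE parameters + combined logistic model + ordinal row
  qseed <- seeds[7L]
  quant <- lapply(seq_along(cohorts), function(ci)
    cohort_quant_table(cohorts[[ci]], seed = qseed + ci,
                       roi_area_mm2 = cfg$roi_area_mm2,
                       repeat_jitter_sd = cfg$repeat_jitter_sd))
  names(quant) <- names(cohorts)
  for (nm in names(quant))
    utils::write.csv(quant[[nm]],
                     file.path(run, sprintf("swe_quant_%s.csv", nm)),
                     row.names = FALSE)
  stage_log(run, "swe_quant", qseed, t0)

  params <- c(e_max = "E_max", e_mean = "E_mean", e_ratio = "E_ratio",
              e_sd = "E_SD")
  for (p in names(params)) {
    thr <- youden_threshold(quant$training[[p]], labels$training)$threshold
    for (cohort in names(cohorts))
      reports[[cohort]][[params[[p]]]] <- diagnostic_report(
        params[[p]], quant[[cohort]][[p]], labels[[cohort]], thr)
  }
  comb <- suppressWarnings(
    glm(I(label == "malignant") ~ e_max + e_mean + e_ratio + e_sd,
        data = quant$training, family = binomial()))
  comb_scores <- lapply(quant, function(q)
    drop(predict(comb, newdata = q, type = "link")))
  comb_thr <- youden_threshold(comb_scores$training,
                               labels$training)$threshold
  for (cohort in names(cohorts))
    reports[[cohort]][["Combined SWE parameters"]] <- diagnostic_report(
      "Combined SWE parameters", comb_scores[[cohort]], labels[[cohort]],
      comb_thr)

  has_birads <- all(vapply(cohorts$training, function(cs)
    !is.null(cs$birads), logical(1)))
  if (has_birads) {
    for (cohort in names(cohorts)) {
      ord <- match(vapply(cohorts[[cohort]], `[[`, character(1), "birads"),
                   birads_levels)
      reports[[cohort]][["Ordinal category"]] <- diagnostic_report(
        "Ordinal category", ord, labels[[cohort]], 1)  # category > 3
    }
  } else warning("ordinal category column absent; ordinal row omitted")
  stage_log(run, "evaluate", NA, t0)

  tables <- lapply(names(reports), function(cohort) {
    tab <- do.call(rbind, lapply(reports[[cohort]], report_row))
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(run, sprintf("table_%s.csv", cohort)),
                     row.names = FALSE)
    tab
  })
  names(tables) <- names(reports)
  jsonlite::write_json(
    lapply(reports, function(rl) lapply(rl, report_json)),
    file.path(run, "reports.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  scatter_df <- do.call(rbind, scatter)
  utils::write.csv(scatter_df, file.path(run, "rad_score_scatter.csv"),
                   row.names = FALSE)
  stage_log(run, "report", NA, t0)

  invisible(list(run_dir = run, signatures = signatures, reports = reports,
                 tables = tables, quant = quant, scatter = scatter_df))
}

# zero-pad a feature matrix on the right so signature indices resolve
pad_features <- function(m, model) {
  need <- if (length(model$selected_indices)) max(model$selected_indices)
          else 0L
  if (ncol(m) >= need) return(m)
  cbind(m, matrix(0, nrow(m), need - ncol(m)))
}

report_json <- function(rep) {
  # JSON has no Inf/NA literals: encode Inf as the string "Inf" and drop
  # NA bounds (decoded back to NA by report_tables)
  enc_lr <- function(lr) Filter(Negate(is.null), lapply(lr, function(v) {
    if (!is.numeric(v) || length(v) != 1) return(v)
    if (is.na(v)) NULL else if (is.infinite(v)) "Inf" else v
  }))
  list(name = rep$name, threshold = rep$threshold,
       counts = as.list(rep$counts),
       sensitivity = rep$sensitivity, specificity = rep$specificity,
       auc = rep$auc, auc_ci = rep$auc_ci,
       plr = enc_lr(rep$plr), nlr = enc_lr(rep$nlr),
       plr_band = rep$plr_band, nlr_band = rep$nlr_band)
}

#' Render the report tables of a completed run
#'
#' Reads `reports.json` from a run directory and renders one table per
#' cohort in the standard column layout (threshold, sensitivity with CI
#' and counts, specificity with CI and counts, AUC with CI, positive and
#' negative likelihood ratios), plus the rad-score scatter data.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return list with `tables` (one data.frame per cohort) and `scatter`.
#' @export
report_tables <- function(run_dir) {
  rp <- file.path(run_dir, "reports.json")
  if (!file.exists(rp)) stop("incomplete-run error: missing ", rp)
  reports <- jsonlite::read_json(rp, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  tables <- lapply(reports, function(rl) {
    dec_lr <- function(lr) {
      one <- function(nm) {
        v <- lr[[nm]]
        if (is.null(v)) NA_real_
        else if (identical(v, "Inf")) Inf
        else as.numeric(v)
      }
      list(estimate = one("estimate"), lower = one("lower"),
           upper = one("upper"))
    }
    rows <- lapply(rl, function(o) {
      rep <- list(name = o$name, threshold = o$threshold,
                  counts = unlist(o$counts),
                  sensitivity = o$sensitivity, specificity = o$specificity,
                  auc = o$auc, auc_ci = unlist(o$auc_ci),
                  plr = dec_lr(o$plr), nlr = dec_lr(o$nlr))
      report_row(rep)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  })
  sp <- file.path(run_dir, "rad_score_scatter.csv")
  scatter <- if (file.exists(sp)) read.csv(sp, stringsAsFactors = FALSE)
  list(tables = tables, scatter = scatter)
}
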