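# End-to-end orchestration: simulate -> annotate -> stemi -> split ->
# train-encoder -> embed -> train-fusion -> evaluate, with a manifest of
# seeds, timings and artifact digests. Stages are resumable: pass a prior
# run's state and only missing stages are recomputed.

#' Pipeline configuration
#'
#' One master seed drives every stage through deterministically derived
#' stage seeds.
#'
#' @param n_patients cohort size.
#' @param seed master seed.
#' @param masks names of feature-group combinations to fit (see
#'   [all_feature_masks()]).
#' @param n_bootstrap bootstrap resamples for CIs.
#' @param encoder named list of [encoder_config()] overrides.
#' @param cohort named list of [cohort_config()] overrides.
#' @param j_offset_ms ST measurement offset for the STEMI rule.
#' @param ... further fields kept in the config echo.
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_patients = 3000, seed = 1L,
                            masks = c("history", "history+ecg",
                                      "history+ecg+troponin",
                                      "history+ecg+poc+troponin"),
                            n_bootstrap = 200,
                            encoder = list(), cohort = list(),
                            j_offset_ms = 60, ...) {
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 masks = masks, n_bootstrap = n_bootstrap,
                 encoder = encoder, cohort = cohort,
                 j_offset_ms = j_offset_ms, ...),
            class = "pipeline_config")
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[omipipe] ", fmt), ...))
}

#' Run the full OMI study pipeline
#'
#' @param config a [pipeline_config()], or a path to a YAML file with the
#'   same fields.
#' @param state a prior run's value for resumption; stages whose outputs are
#'   already present are skipped.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param verbose log stage progress to stderr.
#' @return a `pipeline_run` list: `cohort`, `labels`, `stemi`, `split`,
#'   `encoder`, `embeddings`, `ablation`, `reports`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), state = list(),
                         out_dir = NULL, verbose = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  timings <- list()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    val
  }

  if (is.null(state$cohort)) {
    stage_msg(verbose, "simulate: n=%d seed=%d", config$n_patients, config$seed)
    ccfg <- do.call(cohort_config,
                    c(list(n_patients = config$n_patients, seed = config$seed),
                      config$cohort))
    state$cohort <- tic("simulate", generate_cohort(ccfg))
  }
  cohort <- state$cohort

  if (is.null(state$labels)) {
    stage_msg(verbose, "annotate")
    state$labels <- tic("annotate", annotate_cohort(cohort))
  }
  labels <- state$labels

  if (is.null(state$stemi)) {
    stage_msg(verbose, "stemi rule on index ECGs")
    state$stemi <- tic("stemi", stemi_cohort(cohort, config$j_offset_ms))
  }
  stemi <- state$stemi

  modeled <- labels$status %in% c("OMI", "NOMI", "NO_AMI")
  y_all <- stats::setNames(labels$status == "OMI", labels$patient_id)

  if (is.null(state$split)) {
    stage_msg(verbose, "stratified split (50/25/25)")
    state$split <- tic("split", stratified_split(
      labels$patient_id[modeled], ifelse(y_all[modeled], "OMI", "notOMI"),
      seed = derive_seed(config$seed, "split")))
  }
  split <- state$split

  if (is.null(state$encoder)) {
    ecfg <- do.call(encoder_config,
                    c(list(seed = config$seed,
                           sampling_rate_hz = cohort$config$sampling_rate_hz),
                      config$encoder))
    train_ids <- split$id[split$split == "train"]
    tune_ids <- split$id[split$split == "tune"]
    train_pairs <- augment_training_set(cohort, labels, train_ids)
    tune_all <- augment_training_set(cohort, labels, tune_ids)
    tune_pairs <- tune_all[vapply(tune_all, `[[`, TRUE, "is_index")]
    stage_msg(verbose, "train-encoder: %d training pairs (%d visits)",
              length(train_pairs), length(train_ids))
    state$encoder <- tic("train_encoder",
                         train_encoder(train_pairs, tune_pairs, ecfg,
                                       verbose = verbose))
  }
  encoder <- state$encoder

  if (is.null(state$embeddings)) {
    stage_msg(verbose, "embed index ECGs")
    state$embeddings <- tic("embed", embed_cohort(encoder, cohort))
  }
  embeddings <- state$embeddings

  # comparator operating point: STEMI-rule specificity on the tuning set,
  # evaluated where the criteria are defined (no LBBB/LVH/VP)
  stemi_pos <- stats::setNames(stemi$verdict == "positive", stemi$patient_id)
  applicable <- stats::setNames(!is.na(stemi$verdict) &
                                  stemi$verdict != "not_applicable",
                                stemi$patient_id)
  tune_ids <- split$id[split$split == "tune"]
  tune_red <- tune_ids[applicable[tune_ids]]
  cm_tune <- confusion_metrics(stemi_pos[tune_red], y_all[tune_red])
  target_spec <- cm_tune$specificity
  stage_msg(verbose, "comparator tuning specificity: %.4f", target_spec)

  if (is.null(state$ablation)) {
    stage_msg(verbose, "train-fusion + evaluate: %d masks",
              length(config$masks))
    masks <- all_feature_masks()[config$masks]
    attr(masks, "cumulative") <- intersect(
      attr(all_feature_masks(), "cumulative"), config$masks)
    state$ablation <- tic("fusion", ablation_grid(
      cohort, labels, split, embeddings, masks,
      target_specificity = target_spec,
      n_bootstrap = config$n_bootstrap,
      seed = derive_seed(config$seed, "fusion")))
    state$models <- lapply(masks, function(m)
      train_fusion(cohort, labels, split, embeddings, m))
  }

  if (is.null(state$reports)) {
    stage_msg(verbose, "bootstrap reports (B=%d)", config$n_bootstrap)
    bseed <- derive_seed(config$seed, "bootstrap")
    valid_ids <- split$id[split$split == "validate"]
    full_mask <- config$masks[length(config$masks)]
    model <- state$models[[full_mask]]
    sc <- model$scores[valid_ids]; yv <- y_all[valid_ids]
    thr <- match_specificity_threshold(model$scores[tune_ids],
                                       y_all[tune_ids],
                                       target_spec)$threshold
    reports <- list()
    reports$model_full <- metrics_report(sc, yv, thr,
                                         n_bootstrap = config$n_bootstrap,
                                         seed = bseed, cohort = "validation")
    valid_red <- valid_ids[applicable[valid_ids]]
    reports$stemi <- metrics_report(as.numeric(stemi_pos[valid_red]),
                                    y_all[valid_red], 0.5,
                                    n_bootstrap = config$n_bootstrap,
                                    seed = bseed, binary = TRUE,
                                    cohort = "validation (no LBBB/LVH/VP)")
    # paired sensitivity difference, model vs rule, on the reduced cohort
    sc_red <- sc[valid_red]; y_red <- y_all[valid_red]
    sp_red <- stemi_pos[valid_red]
    reports$sens_difference <- bootstrap_difference(
      function(idx) confusion_metrics(sc_red[idx] >= thr, y_red[idx])$sensitivity,
      function(idx) confusion_metrics(sp_red[idx], y_red[idx])$sensitivity,
      length(valid_red), n_bootstrap = config$n_bootstrap, seed = bseed)
    # subgroups: sex, and the criteria-defined (no-confounder) cohort
    sexes <- vapply(cohort$cases, `[[`, "", "sex")
    names(sexes) <- vapply(cohort$cases, `[[`, "", "patient_id")
    reports$subgroups <- subgroup_eval(
      sc, yv,
      list(female = sexes[valid_ids] == "female",
           male = sexes[valid_ids] == "male",
           no_confounder = applicable[valid_ids]),
      thr, n_bootstrap = config$n_bootstrap, seed = bseed)
    reports$threshold <- thr
    reports$target_specificity <- target_spec
    state$reports <- reports
  }

  state$summary <- cohort_summary(cohort, labels,
                                  stemi_pos[labels$patient_id])
  state$manifest <- list(
    config = unclass(config),
    seeds = list(master = config$seed,
                 cohort = derive_seed(config$seed, "cohort"),
                 split = derive_seed(config$seed, "split"),
                 encoder = derive_seed(config$seed, "encoder"),
                 fusion = derive_seed(config$seed, "fusion"),
                 bootstrap = derive_seed(config$seed, "bootstrap")),
    versions = list(omipipe = as.character(utils::packageVersion("omipipe")),
                    R = R.version.string),
    timings_s = timings,
    created = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(state$labels, file.path(out_dir, "labels.csv"),
              row.names = FALSE)
    write.csv(state$stemi, file.path(out_dir, "stemi.csv"),
              row.names = FALSE)
    write.csv(state$split, file.path(out_dir, "split.csv"), row.names = FALSE)
    write.csv(data.frame(patient_id = rownames(state$embeddings),
                         state$embeddings, check.names = FALSE),
              file.path(out_dir, "embeddings.csv"), row.names = FALSE)
    write.csv(state$ablation, file.path(out_dir, "ablation.csv"),
              row.names = FALSE)
    jsonlite::write_json(report_payload(state),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    arts <- list.files(out_dir, full.names = TRUE)
    state$manifest$digests <- as.list(tools::md5sum(arts))
    jsonlite::write_json(state$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(state) <- "pipeline_run"
  state
}

report_payload <- function(run) {
  rp <- run$reports
  num <- function(x) lapply(as.list(x), unname)
  list(threshold = rp$threshold,
       target_specificity = rp$target_specificity,
       model_full = num(unlist(rp$model_full[c("auc", "sensitivity",
                                               "specificity", "ppv", "npv")])),
       stemi = num(unlist(rp$stemi[c("sensitivity", "specificity",
                                     "ppv", "npv")])),
       sensitivity_difference = rp$sens_difference[c("point", "lo", "hi")],
       ablation = run$ablation)
}

fmt_ci <- function(v, digits = 3) {
  if (is.null(v)) return("     N/A          ")
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
          v[["point"]], v[["lo"]], v[["hi"]])
}

#' Human-readable study report
#'
#' Prints a cohort characteristics table (counts with one-decimal
#' percentages) and a comparison table of the fitted feature-group models
#' against the STEMI rule; the rule rows carry no AUC, which is only
#' meaningful for nonbinary predictions.
#'
#' @param run a `pipeline_run`.
#' @return the report lines, invisibly.
#' @export
make_report <- function(run) {
  s <- run$summary
  row <- function(label, field) {
    vals <- vapply(c("All", "OMI", "NOMI"), function(g) {
      v <- s[[g]][[field]]
      if (length(v) == 2) sprintf("%d (%.1f)", v[["n"]], v[["pct"]])
      else sprintf("%.1f", v)
    }, "")
    sprintf("%-28s %16s %16s %16s", label, vals[1], vals[2], vals[3])
  }
  lines <- c(
    "== Cohort characteristics (annotated, non-excluded) ==",
    sprintf("%-28s %16s %16s %16s", "", "All", "OMI", "NOMI"),
    sprintf("%-28s %16d %16d %16d", "Patients, n",
            s$All$n, s$OMI$n, s$NOMI$n),
    row("Female, n (%)", "female"),
    row("AMI, n (%)", "ami"),
    row("OMI, n (%)", "omi"),
    row("NOMI, n (%)", "nomi"),
    if (!is.null(s$All$stemi_criteria)) row("STEMI criteria, n (%)",
                                            "stemi_criteria"),
    row("30-d mortality, n (%)", "mortality_30d"),
    row("Angio within 90 min, n (%)", "angio_within_90min"),
    "",
    "== Model comparison (validation set) ==",
    sprintf("%-26s %-20s %-20s %-20s", "Model", "AUC", "Sensitivity",
            "Specificity"))
  ab <- run$ablation
  for (i in seq_len(nrow(ab)))
    lines <- c(lines, sprintf("%-26s %-20s %-20.3f %-20.3f",
                              ab$mask[i], sprintf("%.3f", ab$validation_auc[i]),
                              ab$sensitivity[i], ab$specificity[i]))
  st <- run$reports$stemi
  lines <- c(lines,
             sprintf("%-26s %-20s %-20s %-20s", "STEMI criteria", "N/A",
                     fmt_ci(st$sensitivity), fmt_ci(st$specificity)),
             "",
             sprintf("Model threshold %.4g matched to STEMI tuning specificity %.3f",
                     run$reports$threshold, run$reports$target_specificity),
             sprintf("Sensitivity difference (model - STEMI): %s",
                     fmt_ci(run$reports$sens_difference)))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
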