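# Synthetic ED chest-pain cohort generator.
#
# Latent classes: OMI (acute MI with coronary occlusion), NOMI (MI without
# occlusion), NO_AMI. Class-conditional demographics, history/medication
# flags, labs and troponins follow published Swedish ED chest-pain cohort
# characteristics; registry outcomes are constructed so that every latent OMI
# satisfies at least one branch of the rule-based annotation tree and no
# latent NO_AMI satisfies any.

# per-class prevalence of history and medication flags
HISTORY_FLAGS <- data.frame(
  flag = c("ischemic_heart_disease", "prior_ami", "angina", "unstable_angina",
           "heart_failure", "diabetes", "hypertension", "pulmonary_embolism",
           "cerebrovascular_disease", "copd", "prior_cabg", "prior_pci"),
  p_omi   = c(0.141, 0.073, 0.054, 0.030, 0.036, 0.090, 0.199, 0.002,
              0.032, 0.019, 0.009, 0.066),
  p_nomi  = c(0.247, 0.141, 0.111, 0.035, 0.081, 0.145, 0.294, 0.012,
              0.047, 0.036, 0.019, 0.102),
  p_noami = c(0.143, 0.057, 0.063, 0.022, 0.059, 0.082, 0.200, 0.013,
              0.036, 0.038, 0.010, 0.055),
  stringsAsFactors = FALSE
)

MEDICATION_FLAGS <- data.frame(
  flag = c("antithrombotics", "statin", "other_lipid_lowering",
           "antihypertensive", "beta_blockers", "anticoagulants", "insulin",
           "other_antidiabetics", "diuretics", "thiazide", "ace_aii"),
  p_omi   = c(0.248, 0.257, 0.024, 0.420, 0.298, 0.034, 0.088, 0.131,
              0.128, 0.047, 0.345),
  p_nomi  = c(0.416, 0.403, 0.045, 0.553, 0.422, 0.051, 0.121, 0.169,
              0.214, 0.064, 0.480),
  p_noami = c(0.224, 0.267, 0.026, 0.356, 0.295, 0.054, 0.053, 0.095,
              0.145, 0.045, 0.302),
  stringsAsFactors = FALSE
)

# initial hs-cTnT log-normals per class: median (IQR) 7 (4-15) / 105 (29-441)
# / 51 (24-120) ng/L; sdlog = log(q3/q1) / (2 * qnorm(0.75))
TROPONIN_LNORM <- list(
  NO_AMI = c(meanlog = log(7),   sdlog = 0.980),
  OMI    = c(meanlog = log(105), sdlog = 2.018),
  NOMI   = c(meanlog = log(51),  sdlog = 1.193)
)
TROPONIN_FLOOR <- 3  # assay detection floor, ng/L

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the cohort emulates: ~1.9% OMI and
#' 4.6% NOMI among ED chest-pain visits, 60% of OMI with ST deviation below
#' the STEMI thresholds (subtle OMI), per-lab missing-at-random rates between
#' 0.8% (hs-cTnT) and 5% (glucose), and ~50% of visits with more than one
#' ECG.
#'
#' @param n_patients number of ED visits to generate.
#' @param omi_prevalence,nomi_prevalence latent class fractions; must sum to
#'   less than 1.
#' @param subtle_omi_fraction fraction of OMI whose maximal ST elevation is
#'   kept between 0.05 mV and the applicable STEMI threshold.
#' @param confounder_rates named fractions for LBBB, LVH and ventricular
#'   pacing morphologies.
#' @param missingness_rates named per-lab fractions (hs_ctnt, hemoglobin,
#'   creatinine, glucose).
#' @param extra_ecg_rate fraction of visits with a second ECG.
#' @param fp_st_rate fraction of non-OMI patients with benign ST elevation
#'   above threshold (early-repolarization mimic); sets the rule
#'   comparator's false-positive rate.
#' @param nonspecific_st_sd standard deviation (mV) of benign per-patient,
#'   per-channel ST-level variation present in everyone; sets the floor
#'   under which subtle OMI deviations hide.
#' @param no_ecg_rate,poor_quality_rate exclusion-path rates.
#' @param sampling_rate_hz,duration_s waveform geometry (500 Hz, 10 s).
#' @param noise_sd_mv,baseline_wander_amp_mv waveform noise levels.
#' @param seed integer master seed.
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_patients,
                          omi_prevalence = 0.019,
                          nomi_prevalence = 0.046,
                          subtle_omi_fraction = 0.6,
                          confounder_rates = c(LBBB = 0.010, LVH = 0.040,
                                               VP = 0.005),
                          missingness_rates = c(hs_ctnt = 0.008,
                                                hemoglobin = 0.010,
                                                creatinine = 0.020,
                                                glucose = 0.050),
                          extra_ecg_rate = 0.5,
                          fp_st_rate = 0.025,
                          nonspecific_st_sd = 0.03,
                          no_ecg_rate = 0.002,
                          poor_quality_rate = 0.004,
                          sampling_rate_hz = 500,
                          duration_s = 10,
                          noise_sd_mv = 0.05,
                          baseline_wander_amp_mv = 0.05,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer", call. = FALSE)
  assert_fraction(omi_prevalence, "omi_prevalence")
  assert_fraction(nomi_prevalence, "nomi_prevalence")
  if (omi_prevalence + nomi_prevalence >= 1)
    stop("class prevalences must sum to less than 1", call. = FALSE)
  assert_fraction(subtle_omi_fraction, "subtle_omi_fraction")
  for (nm in names(confounder_rates))
    assert_fraction(confounder_rates[[nm]], paste0("confounder_rates$", nm))
  for (nm in names(missingness_rates))
    assert_fraction(missingness_rates[[nm]], paste0("missingness_rates$", nm))
  assert_fraction(extra_ecg_rate, "extra_ecg_rate")
  assert_fraction(fp_st_rate, "fp_st_rate")
  structure(list(n_patients = as.integer(n_patients),
                 omi_prevalence = omi_prevalence,
                 nomi_prevalence = nomi_prevalence,
                 subtle_omi_fraction = subtle_omi_fraction,
                 confounder_rates = confounder_rates,
                 missingness_rates = missingness_rates,
                 extra_ecg_rate = extra_ecg_rate,
                 fp_st_rate = fp_st_rate,
                 nonspecific_st_sd = nonspecific_st_sd,
                 no_ecg_rate = no_ecg_rate,
                 poor_quality_rate = poor_quality_rate,
                 sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s,
                 noise_sd_mv = noise_sd_mv,
                 baseline_wander_amp_mv = baseline_wander_amp_mv,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

draw_flags <- function(tbl, cls) {
  n <- length(cls)
  out <- matrix(FALSE, n, nrow(tbl), dimnames = list(NULL, tbl$flag))
  p <- cbind(OMI = tbl$p_omi, NOMI = tbl$p_nomi, NO_AMI = tbl$p_noami)
  for (j in seq_len(nrow(tbl)))
    out[, j] <- runif(n) < p[j, ][cls]
  out
}

# ST-elevation targets per contiguous lead group; returns per-patient list of
# named channel offsets (on the 8 source channels) plus the max target value.
st_pattern <- function(group, target) {
  switch(group,
    inferior = c(II = target),                          # III, aVF inherit
    anterior = c(V1 = 0.5 * target, V2 = target, V3 = target,
                 V4 = 0.5 * target),
    lateral  = c(I = target, V5 = target, V6 = target)) # aVL inherits
}

# applicable threshold for a group given sex/age (V2-V3 carry special limits)
group_threshold <- function(group, sex, age) {
  if (group != "anterior") return(0.1)
  if (sex == "female") 0.15 else if (age < 40) 0.25 else 0.20
}

#' Generate a synthetic ED chest-pain cohort
#'
#' Deterministic given `config$seed`. Tabular data, latent classes and
#' registry outcomes are drawn first from one seeded stream; waveforms are
#' synthesized in a second pass with per-record derived seeds, so
#' `waveforms = FALSE` yields byte-identical tabular data at a fraction of
#' the cost.
#'
#' @param config a [cohort_config()].
#' @param waveforms synthesize ECG waveforms (`TRUE`) or leave the per-record
#'   morphology parameters on each case for lazy synthesis (`FALSE`).
#' @return an `omi_cohort`: list of `patient_case` objects plus the config.
#'   Each case carries demographics, history/medication flags, POC labs,
#'   initial hs-cTnT, ECGs, a `registry` outcome (consumed only by
#'   annotation), and a `latent` block (class, intended annotation branch,
#'   ST group/target) that must never enter model-facing features.
#' @export
generate_cohort <- function(config, waveforms = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(derive_seed(config$seed, "cohort"))

  cls <- sample(c("OMI", "NOMI", "NO_AMI"), n, replace = TRUE,
                prob = c(config$omi_prevalence, config$nomi_prevalence,
                         1 - config$omi_prevalence - config$nomi_prevalence))

  age <- numeric(n); sexf_p <- numeric(n)
  age[cls == "OMI"]    <- rnorm(sum(cls == "OMI"), 68, 13.4)
  age[cls == "NOMI"]   <- rnorm(sum(cls == "NOMI"), 71, 12.9)
  age[cls == "NO_AMI"] <- rnorm(sum(cls == "NO_AMI"), 58, 18.8)
  age <- pmin(pmax(round(age), 18), 100)
  sexf_p <- c(OMI = 0.255, NOMI = 0.373, NO_AMI = 0.491)[cls]
  sex <- ifelse(runif(n) < sexf_p, "female", "male")

  hist_flags <- draw_flags(HISTORY_FLAGS, cls)
  med_flags  <- draw_flags(MEDICATION_FLAGS, cls)

  mi <- cls != "NO_AMI"
  hemoglobin <- rnorm(n, 140, 16) - 2 * mi
  creatinine <- rlnorm(n, log(80) + 0.08 * mi, 0.30)
  glucose    <- rlnorm(n, log(6.2) + 0.12 * mi, 0.25)

  trop0 <- numeric(n)
  for (k in names(TROPONIN_LNORM)) {
    i <- cls == k
    trop0[i] <- rlnorm(sum(i), TROPONIN_LNORM[[k]]["meanlog"],
                       TROPONIN_LNORM[[k]]["sdlog"])
  }
  trop0 <- pmax(trop0, TROPONIN_FLOOR)

  rise <- numeric(n)
  rise[cls == "OMI"]    <- exp(abs(rnorm(sum(cls == "OMI"), 1.2, 0.7)))
  rise[cls == "NOMI"]   <- exp(abs(rnorm(sum(cls == "NOMI"), 0.5, 0.4)))
  rise[cls == "NO_AMI"] <- exp(abs(rnorm(sum(cls == "NO_AMI"), 0.03, 0.05)))
  trop_max <- trop0 * rise

  # --- registry outcomes, constructed per class -------------------------
  discharge_ami <- mi
  angio <- logical(n); culprit <- rep(NA, n); timi <- rep(NA_character_, n)
  scaar <- logical(n); pci <- logical(n); cabg <- logical(n)
  rwma <- rep(NA, n); arrest <- logical(n); hrs_angio <- rep(NA_real_, n)

  io <- which(cls == "OMI")
  angio[io] <- runif(length(io)) < 0.91
  ioa <- io[angio[io]]; ion <- io[!angio[io]]
  culprit[ioa] <- TRUE
  timi[ioa] <- sample(c("0", "1", "unclear"), length(ioa), replace = TRUE,
                      prob = c(0.55, 0.43, 0.02))
  scaar[ioa] <- runif(length(ioa)) < 0.80
  scaar[ioa][timi[ioa] == "unclear"] <- TRUE  # keep every OMI on a branch
  pci[ioa] <- runif(length(ioa)) < 0.85
  cabg[ioa] <- !pci[ioa] & runif(length(ioa)) < 0.30
  hrs_angio[ioa] <- rlnorm(length(ioa), log(6), 1.0)
  rwma[ioa] <- runif(length(ioa)) < 0.50
  arrest[ioa] <- runif(length(ioa)) < 0.05
  # OMI without angiography must satisfy the no-angiography branch
  trop_max[ion] <- pmax(trop_max[ion], 1001 * exp(abs(rnorm(length(ion), 0.3, 0.4))))
  rwma[ion] <- runif(length(ion)) < 0.70
  arrest[ion] <- !rwma[ion]          # arrest + STEMI-indicative ECG path

  im <- which(cls == "NOMI")
  angio[im] <- runif(length(im)) < 0.90
  ima <- im[angio[im]]; imn <- im[!angio[im]]
  culprit[ima] <- runif(length(ima)) < 0.25
  timi[ima] <- ifelse(unlist(culprit[ima]),
                      sample(c("2", "3", "unclear"), length(ima), replace = TRUE,
                             prob = c(0.55, 0.40, 0.05)),
                      sample(c("2", "3"), length(ima), replace = TRUE,
                             prob = c(0.2, 0.8)))
  pci[ima] <- runif(length(ima)) < 0.55
  cabg[ima] <- !pci[ima] & runif(length(ima)) < 0.08
  hrs_angio[ima] <- rlnorm(length(ima), log(28), 0.76)
  rwma[im] <- runif(length(im)) < 0.20
  arrest[im] <- runif(length(im)) < 0.02
  # guards: a latent NOMI must not satisfy any OMI branch
  over <- im[trop_max[im] > 1000 & (pci[im] | cabg[im])]
  trop_max[over] <- runif(length(over), 300, 995)
  bad4 <- imn[trop_max[imn] > 1000]
  rwma[bad4] <- FALSE; arrest[bad4] <- FALSE

  ix <- which(cls == "NO_AMI")
  angio[ix] <- runif(length(ix)) < 0.02
  ixa <- ix[angio[ix]]
  culprit[ixa] <- FALSE; timi[ixa] <- "3"
  pci[ixa] <- runif(length(ixa)) < 0.20
  hrs_angio[ixa] <- rlnorm(length(ixa), log(29), 0.9)

  d30 <- runif(n) < c(OMI = 0.066, NOMI = 0.033, NO_AMI = 0.009)[cls]
  d180 <- d30 | runif(n) < c(OMI = 0.028, NOMI = 0.031, NO_AMI = 0.016)[cls]
  d1y <- d180 | runif(n) < c(OMI = 0.009, NOMI = 0.022, NO_AMI = 0.012)[cls]

  # --- ECG morphology ---------------------------------------------------
  morph <- sample(c("normal", names(config$confounder_rates)), n,
                  replace = TRUE,
                  prob = c(1 - sum(config$confounder_rates),
                           config$confounder_rates))
  heart_rate <- pmin(pmax(rnorm(n, 75, 12), 45), 140)

  subtle <- rep(NA, n)
  subtle[io] <- runif(length(io)) < config$subtle_omi_fraction
  subtle[ion[arrest[ion]]] <- FALSE   # STEMI-indicative ECG recorded
  st_group <- rep(NA_character_, n); st_target <- rep(0, n)
  groups <- c("inferior", "anterior", "lateral")
  st_group[io] <- sample(groups, length(io), replace = TRUE)
  for (i in io) {
    thr <- group_threshold(st_group[i], sex[i], age[i])
    st_target[i] <- if (subtle[i]) runif(1, 0.05, thr - 0.01)
                    else thr + runif(1, 0.05, 0.25)
  }
  inx <- which(!mi | cls == "NOMI")
  fp <- inx[runif(length(inx)) < config$fp_st_rate]
  st_group[fp] <- sample(groups, length(fp), replace = TRUE)
  for (i in fp) {
    thr <- group_threshold(st_group[i], sex[i], age[i])
    st_target[i] <- thr + runif(1, 0.02, 0.15)
  }
  stemi_ecg <- rep(FALSE, n)
  stemi_ecg[io] <- !subtle[io]
  stemi_ecg[fp] <- TRUE

  no_ecg <- runif(n) < config$no_ecg_rate
  poor_q <- !no_ecg & runif(n) < config$poor_quality_rate
  extra  <- !no_ecg & runif(n) < config$extra_ecg_rate
  t_index <- runif(n, 0.05, 0.5)
  t_extra <- t_index + runif(n, 0.5, 3)

  # latent branch oracle, assigned by construction with R1 > R2 > R3 > R4
  branch <- rep(NA_character_, n)
  b1 <- discharge_ami & scaar
  b2 <- discharge_ami & !b1 & trop_max > 1000 & (pci | cabg)
  b3 <- discharge_ami & !b1 & !b2 & angio &
        !is.na(culprit) & unlist(culprit) & timi %in% c("0", "1")
  b4 <- discharge_ami & !b1 & !b2 & !b3 & !angio & trop_max > 1000 &
        (unlist(ifelse(is.na(rwma), FALSE, rwma)) | (stemi_ecg & arrest))
  branch[b1] <- "R1"; branch[b2] <- "R2"; branch[b3] <- "R3"; branch[b4] <- "R4"

  ecg_seed_base <- derive_seed(config$seed, "crops")
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    registry <- structure(list(
      discharge_ami = discharge_ami[i],
      scaar_aco = scaar[i],
      angiography_performed = angio[i],
      hours_to_angiography = if (angio[i]) hrs_angio[i] else NA_real_,
      culprit_lesion = if (angio[i]) as.logical(culprit[i]) else NA,
      timi_flow = if (angio[i]) timi[i] else NA_character_,
      urgent_pci = pci[i], cabg = cabg[i],
      max_hs_ctnt_24h_ng_l = trop_max[i],
      new_rwma = as.logical(rwma[i]),
      cardiac_arrest_before_angio = arrest[i],
      stemi_ecg_present = stemi_ecg[i],
      died_30d = d30[i], died_180d = d180[i], died_1y = d1y[i]),
      class = "registry_outcome")
    st <- stats::setNames(rnorm(length(LEADS_8), 0,
                                config$nonspecific_st_sd), LEADS_8)
    if (!is.na(st_group[i]) && st_target[i] > 0) {
      pat <- st_pattern(st_group[i], st_target[i])
      st[names(pat)] <- st[names(pat)] + pat
    }
    mp <- ecg_morph_params(heart_rate = heart_rate[i], st_offset_mv = st,
                           noise_sd_mv = config$noise_sd_mv,
                           baseline_wander_amp_mv = config$baseline_wander_amp_mv,
                           morphology = morph[i])
    ecg_plan <- if (no_ecg[i]) list() else {
      pl <- list(list(seed = ecg_seed_base + 7L * i, recorded_at = t_index[i],
                      quality_ok = !poor_q[i]))
      if (extra[i])
        pl <- c(pl, list(list(seed = ecg_seed_base + 7L * i + 3L,
                              recorded_at = t_extra[i], quality_ok = TRUE)))
      pl
    }
    cases[[i]] <- structure(list(
      patient_id = sprintf("P%06d", i),
      age = age[i], sex = sex[i],
      history_flags = hist_flags[i, ],
      medication_flags = med_flags[i, ],
      poc_labs = c(hemoglobin = hemoglobin[i], creatinine = creatinine[i],
                   glucose = glucose[i]),
      hs_ctnt_initial_ng_l = trop0[i],
      ecg_params = mp, ecg_plan = ecg_plan, ecgs = list(),
      registry = registry,
      latent = list(truth = cls[i], branch = branch[i],
                    st_group = st_group[i], st_target_mv = st_target[i],
                    subtle = as.logical(subtle[i]))),
      class = "patient_case")
  }
  cohort <- structure(list(cases = cases, config = config),
                      class = "omi_cohort")
  cohort <- apply_missingness(cohort, config$missingness_rates,
                              seed = derive_seed(config$seed, "missingness"))
  if (waveforms) cohort <- materialize_waveforms(cohort)
  cohort
}

#' Synthesize the waveforms planned for each case
#'
#' @param cohort an `omi_cohort` generated with `waveforms = FALSE`.
#' @return the cohort with `ecgs` populated (index ECG first).
#' @export
materialize_waveforms <- function(cohort) {
  cfg <- cohort$config
  cohort$cases <- lapply(cohort$cases, function(cs) {
    cs$ecgs <- lapply(cs$ecg_plan, function(pl)
      synthesize_ecg(cs$ecg_params, seed = pl$seed,
                     sampling_rate_hz = cfg$sampling_rate_hz,
                     duration_s = cfg$duration_s,
                     quality_ok = pl$quality_ok,
                     recorded_at = pl$recorded_at))
    cs
  })
  cohort
}

#' Mask lab values missing-at-random
#'
#' Each lab value is masked independently of the latent class with its
#' configured rate, emulating missingness dominated by hemolysis.
#'
#' @param cohort an `omi_cohort`.
#' @param rates named fractions for `hs_ctnt`, `hemoglobin`, `creatinine`,
#'   `glucose`.
#' @param seed integer seed.
#' @return the cohort with masked values set to `NA`.
#' @export
apply_missingness <- function(cohort, rates, seed = 1L) {
  for (nm in names(rates)) assert_fraction(rates[[nm]], nm)
  n <- length(cohort$cases)
  with_seed(seed, {
    mask <- lapply(c("hs_ctnt", "hemoglobin", "creatinine", "glucose"),
                   function(nm) runif(n) < (rates[[nm]] %||% 0))
    names(mask) <- c("hs_ctnt", "hemoglobin", "creatinine", "glucose")
    for (i in seq_len(n)) {
      if (mask$hs_ctnt[i]) cohort$cases[[i]]$hs_ctnt_initial_ng_l <- NA_real_
      for (lab in c("hemoglobin", "creatinine", "glucose"))
        if (mask[[lab]][i]) cohort$cases[[i]]$poc_labs[[lab]] <- NA_real_
    }
  })
  cohort
}

#' @export
print.omi_cohort <- function(x, ...) {
  cls <- vapply(x$cases, function(c) c$latent$truth, character(1))
  cat(sprintf("<omi_cohort> %d cases (%d OMI, %d NOMI, %d no AMI)%s\n",
              length(x$cases), sum(cls == "OMI"), sum(cls == "NOMI"),
              sum(cls == "NO_AMI"),
              if (length(x$cases) && length(x$cases[[1]]$ecgs))
                "" else ", waveforms pending"))
  invisible(x)
}

#' Tabulate a cohort into model-facing and registry data frames
#'
#' The `cases` table exposes only pre-outcome information (the latent block
#' never leaves the generator); `registry` holds post-visit facts for
#' annotation only.
#'
#' @param cohort an `omi_cohort`.
#' @return list of data frames `cases`, `registry`, `ecg_index`.
#' @export
cohort_tables <- function(cohort) {
  cs <- cohort$cases
  flag_df <- function(field) {
    m <- do.call(rbind, lapply(cs, function(c) c[[field]]))
    as.data.frame(m)
  }
  cases <- data.frame(
    patient_id = vapply(cs, `[[`, "", "patient_id"),
    age = vapply(cs, `[[`, 0, "age"),
    sex = vapply(cs, `[[`, "", "sex"),
    hemoglobin = vapply(cs, function(c) c$poc_labs[["hemoglobin"]], 0),
    creatinine = vapply(cs, function(c) c$poc_labs[["creatinine"]], 0),
    glucose = vapply(cs, function(c) c$poc_labs[["glucose"]], 0),
    hs_ctnt_initial_ng_l = vapply(cs, `[[`, 0, "hs_ctnt_initial_ng_l"),
    n_ecgs = vapply(cs, function(c) length(c$ecg_plan), 0L))
  cases <- cbind(cases, flag_df("history_flags"), flag_df("medication_flags"))
  registry <- cbind(patient_id = cases$patient_id,
                    as.data.frame(do.call(rbind, lapply(cs, function(c)
                      lapply(unclass(c$registry), function(v) v)))))
  registry[] <- lapply(registry, function(col)
    if (is.list(col)) unlist(lapply(col, function(v) if (is.null(v)) NA else v))
    else col)
  ei <- do.call(rbind, lapply(cs, function(c) {
    if (!length(c$ecg_plan)) return(NULL)
    data.frame(patient_id = c$patient_id,
               record = sprintf("%s_e%d", c$patient_id,
                                seq_along(c$ecg_plan)),
               recorded_at = vapply(c$ecg_plan, `[[`, 0, "recorded_at"),
               is_index = seq_along(c$ecg_plan) == 1L)
  }))
  list(cases = cases, registry = registry, ecg_index = ei)
}
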