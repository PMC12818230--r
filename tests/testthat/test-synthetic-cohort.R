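test_that("cohort generation is deterministic and respects the latent prevalence", {
  a <- generate_cohort(cohort_config(n_patients = 60, seed = 9))
  b <- generate_cohort(cohort_config(n_patients = 60, seed = 9))
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  co <- generate_cohort(cohort_config(n_patients = 24511, seed = 4),
                        waveforms = FALSE)
  n_omi <- sum(vapply(co$cases, function(c) c$latent$truth == "OMI", TRUE))
  bounds <- qbinom(c(0.005, 0.995), 24511, 0.019)
  expect_gte(n_omi, bounds[1])
  expect_lte(n_omi, bounds[2])
})

test_that("zero prevalence yields no occlusions anywhere", {
  co <- generate_cohort(cohort_config(n_patients = 400, omi_prevalence = 0,
                                      seed = 2), waveforms = FALSE)
  lt <- vapply(co$cases, function(c) c$latent$truth, "")
  expect_false(any(lt == "OMI"))
  lab <- annotate_cohort(co)
  expect_false(any(lab$status == "OMI"))
  expect_false(any(vapply(co$cases, function(c) isTRUE(c$registry$scaar_aco),
                          TRUE)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(0), "positive")
  expect_error(cohort_config(10, omi_prevalence = 1.2), "fraction")
  expect_error(cohort_config(10, omi_prevalence = 0.6,
                             nomi_prevalence = 0.5), "sum")
  expect_error(cohort_config(10, subtle_omi_fraction = -0.1), "fraction")
})

test_that("registry outcomes are internally consistent and every latent OMI sits on a branch", {
  co <- generate_cohort(cohort_config(n_patients = 3000, seed = 7),
                        waveforms = FALSE)
  for (cs in co$cases) {
    r <- cs$registry
    expect_identical(!is.na(r$hours_to_angiography), r$angiography_performed)
    if (!is.na(r$timi_flow)) expect_true(r$angiography_performed)
    if (cs$latent$truth == "OMI") expect_false(is.na(cs$latent$branch))
    if (cs$latent$truth == "NO_AMI") {
      expect_true(is.na(cs$latent$branch))
      expect_false(r$discharge_ami)
    }
    expect_true(r$died_1y >= r$died_180d, r$died_180d >= r$died_30d)
  }
  br <- vapply(co$cases, function(c)
    if (is.na(c$latent$branch)) "" else c$latent$branch, "")
  expect_setequal(intersect(unique(br), c("R1", "R2", "R3", "R4")),
                  c("R1", "R2", "R3", "R4"))
})

test_that("lead-derivation identities hold on every emitted ECG", {
  co <- generate_cohort(cohort_config(n_patients = 25, seed = 3))
  for (cs in co$cases) for (e in cs$ecgs) {
    s <- e$samples
    expect_lt(max(abs(s["III", ] - (s["II", ] - s["I", ]))), 1e-9)
    expect_lt(max(abs(s["aVR", ] + (s["I", ] + s["II", ]) / 2)), 1e-9)
    expect_lt(max(abs(s["aVL", ] - (s["I", ] - s["II", ] / 2))), 1e-9)
    expect_lt(max(abs(s["aVF", ] - (s["II", ] - s["I", ] / 2))), 1e-9)
  }
})

test_that("derived limb leads follow the Einthoven/Goldberger arithmetic", {
  m <- matrix(0, 8, 10, dimnames = list(c("I", "II", paste0("V", 1:6)), NULL))
  m["I", ] <- 0.2; m["II", ] <- 0.5
  d <- derive_limb_leads(m)
  expect_equal(unique(d["III", ]), 0.3)
  expect_equal(unique(d["aVR", ]), -0.35)
  expect_equal(unique(d["aVL", ]), -0.05)
  expect_equal(unique(d["aVF", ]), 0.4)
  expect_equal(derive_limb_leads(matrix(0, 8, 5,
    dimnames = list(rownames(m), NULL))), matrix(0, 12, 5,
    dimnames = list(c("I", "II", "III", "aVR", "aVL", "aVF",
                      paste0("V", 1:6)), NULL)))
  # idempotence: re-deriving from the retained I and II changes nothing
  set.seed(1)
  m[] <- rnorm(length(m))
  d1 <- derive_limb_leads(m)
  d2 <- derive_limb_leads(d1[rownames(m), ])
  expect_equal(d1, d2)
  expect_error(derive_limb_leads(m[-1, ]), "must contain")
})

test_that("synthesized ST level matches the configured offset on noiseless signals", {
  s0 <- synthesize_ecg(noiseless_params(heart_rate = 60), seed = 5)
  st0 <- measure_st(compute_median_beat(s0), 60)
  expect_true(all(abs(st0$st_mv) < 0.02))

  s1 <- synthesize_ecg(noiseless_params(heart_rate = 60,
                                        st_offset_mv = c(II = 0.3)), seed = 5)
  st1 <- measure_st(compute_median_beat(s1), 60)
  expect_lt(abs(st1$st_mv[["II"]] - 0.3), 0.02)
})

test_that("lab missingness is controlled and independent of the latent class", {
  co <- generate_cohort(cohort_config(n_patients = 10000, seed = 2,
                                      missingness_rates = c(hs_ctnt = 0,
                                        hemoglobin = 0, creatinine = 0,
                                        glucose = 0)), waveforms = FALSE)
  expect_false(any(vapply(co$cases, function(c)
    anyNA(c(c$poc_labs, c$hs_ctnt_initial_ng_l)), TRUE)))

  co <- apply_missingness(co, c(hs_ctnt = 0.008, hemoglobin = 0.01,
                                creatinine = 0.02, glucose = 0.05), seed = 6)
  miss <- vapply(co$cases, function(c) is.na(c$poc_labs[["glucose"]]), TRUE)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(sum(miss), bounds[1])
  expect_lte(sum(miss), bounds[2])
  omi <- vapply(co$cases, function(c) c$latent$truth == "OMI", TRUE)
  expect_lt(abs(cor(miss, omi)), 0.03)
})

test_that("cohort tables expose no outcome or latent information", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 8),
                        waveforms = FALSE)
  tb <- cohort_tables(co)
  expect_false(any(c("latent", "truth", "status") %in% names(tb$cases)))
  expect_false(any(names(tb$cases) %in% omipipe:::REGISTRY_FIELDS))
  expect_setequal(names(tb), c("cases", "registry", "ecg_index"))
  expect_true(all(tb$ecg_index$recorded_at[tb$ecg_index$is_index] <
                    tapply(tb$ecg_index$recorded_at, tb$ecg_index$patient_id,
                           max)[unique(tb$ecg_index$patient_id)] +
                    1e9))  # index rows exist for every patient with ECGs
  idx <- tb$ecg_index[tb$ecg_index$is_index, ]
  expect_equal(nrow(idx), length(unique(tb$ecg_index$patient_id)))
})

test_that("WFDB records round-trip within quantization error", {
  s <- synthesize_ecg(ecg_morph_params(morphology = "LBBB"), seed = 12,
                      recorded_at = 1.25)
  d <- withr::local_tempdir()
  write_wfdb(s, d, "r1")
  r <- read_wfdb(d, "r1")
  expect_lt(max(abs(r$samples - s$samples)), 1 / omipipe:::WFDB_GAIN)
  expect_identical(rownames(r$samples), rownames(s$samples))
  expect_equal(r$sampling_rate_hz, s$sampling_rate_hz)
  expect_identical(r$morphology_flags, "LBBB")
  expect_equal(r$recorded_at, 1.25)
})
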