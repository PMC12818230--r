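test_that("each annotation branch fires on its defining registry pattern", {
  cfg <- annotation_config()
  l1 <- annotate_omi(make_registry(discharge_ami = TRUE, scaar_aco = TRUE), cfg)
  expect_identical(l1$status, "OMI"); expect_identical(l1$rule_fired, "R1")

  l2 <- annotate_omi(make_registry(discharge_ami = TRUE,
                                   max_hs_ctnt_24h_ng_l = 1200,
                                   urgent_pci = TRUE), cfg)
  expect_identical(l2$status, "OMI"); expect_identical(l2$rule_fired, "R2")

  l3 <- annotate_omi(make_registry(discharge_ami = TRUE,
                                   angiography_performed = TRUE,
                                   hours_to_angiography = 4,
                                   culprit_lesion = TRUE, timi_flow = "1"), cfg)
  expect_identical(l3$status, "OMI"); expect_identical(l3$rule_fired, "R3")

  # reduced flow but TIMI 2: not occlusive -> NOMI
  l3b <- annotate_omi(make_registry(discharge_ami = TRUE,
                                    angiography_performed = TRUE,
                                    hours_to_angiography = 4,
                                    culprit_lesion = TRUE, timi_flow = "2"), cfg)
  expect_identical(l3b$status, "NOMI")

  lr <- annotate_omi(make_registry(discharge_ami = TRUE,
                                   angiography_performed = TRUE,
                                   hours_to_angiography = 4,
                                   culprit_lesion = TRUE,
                                   timi_flow = "unclear"), cfg)
  expect_identical(lr$status, "NEEDS_REVIEW")

  l4 <- annotate_omi(make_registry(discharge_ami = TRUE,
                                   max_hs_ctnt_24h_ng_l = 2400,
                                   new_rwma = TRUE), cfg)
  expect_identical(l4$status, "OMI"); expect_identical(l4$rule_fired, "R4")

  l4b <- annotate_omi(make_registry(discharge_ami = TRUE,
                                    max_hs_ctnt_24h_ng_l = 2400,
                                    new_rwma = FALSE,
                                    stemi_ecg_present = TRUE,
                                    cardiac_arrest_before_angio = TRUE), cfg)
  expect_identical(l4b$status, "OMI"); expect_identical(l4b$rule_fired, "R4")

  expect_identical(annotate_omi(make_registry(), cfg)$status, "NO_AMI")
  expect_error(annotate_omi(make_registry(timi_flow = "2"), cfg),
               "contradictory")
  # troponin at exactly the threshold does not qualify (strictly above)
  leq <- annotate_omi(make_registry(discharge_ami = TRUE,
                                    max_hs_ctnt_24h_ng_l = 1000,
                                    urgent_pci = TRUE), cfg)
  expect_identical(leq$status, "NOMI")
})

test_that("the annotation tree is total and deterministic over valid registries", {
  set.seed(21)
  for (i in 1:400) {
    reg <- random_registry()
    lab <- annotate_omi(reg)
    expect_true(lab$status %in% c("OMI", "NOMI", "NO_AMI", "NEEDS_REVIEW"))
    expect_identical(!is.na(lab$rule_fired), lab$status == "OMI")
    lab2 <- annotate_omi(reg)
    expect_identical(lab, lab2)
  }
})

test_that("raising the 24h troponin never demotes an OMI label", {
  set.seed(22)
  for (i in 1:200) {
    reg <- random_registry()
    lab <- annotate_omi(reg)
    reg$max_hs_ctnt_24h_ng_l <- reg$max_hs_ctnt_24h_ng_l + 3000
    lab_hi <- annotate_omi(reg)
    if (lab$status == "OMI") expect_identical(lab_hi$status, "OMI")
  }
})

test_that("exclusion flow matches its stated reasons and keeps STEMI diagnoses", {
  co <- generate_cohort(cohort_config(n_patients = 4, seed = 14,
                                      no_ecg_rate = 0, poor_quality_rate = 0),
                        waveforms = FALSE)
  cs <- co$cases[[1]]

  no_ecg <- cs; no_ecg$ecg_plan <- list(); no_ecg$ecgs <- list()
  expect_identical(apply_exclusions(no_ecg)$exclusion_reason, "no_ecg")

  poor <- cs; poor$ecg_plan[[1]]$quality_ok <- FALSE
  expect_identical(apply_exclusions(poor)$exclusion_reason, "poor_quality_ecg")

  unclear <- cs
  unclear$registry <- make_registry(discharge_ami = TRUE,
                                    max_hs_ctnt_24h_ng_l = NA_real_,
                                    scaar_aco = NA, new_rwma = NA)
  expect_identical(apply_exclusions(unclear)$exclusion_reason,
                   "unclear_outcome")

  # a STEMI-indicative ECG is not an exclusion: the case passes through
  stemi_case <- cs
  stemi_case$registry <- make_registry(discharge_ami = TRUE, scaar_aco = TRUE,
                                       stemi_ecg_present = TRUE)
  expect_null(apply_exclusions(stemi_case))
  expect_null(apply_exclusions(cs))
})

test_that("annotation recovers the generator's latent class and branch", {
  co <- generate_cohort(cohort_config(n_patients = 5000, seed = 17),
                        waveforms = FALSE)
  lab <- annotate_cohort(co)
  lt <- vapply(co$cases, function(c) c$latent$truth, "")
  br <- vapply(co$cases, function(c)
    if (is.na(c$latent$branch)) "" else c$latent$branch, "")
  decided <- lab$status %in% c("OMI", "NOMI", "NO_AMI")
  expect_identical(lab$status[decided & lt == "OMI"],
                   rep("OMI", sum(decided & lt == "OMI")))
  expect_identical(lab$status[decided & lt == "NO_AMI"],
                   rep("NO_AMI", sum(decided & lt == "NO_AMI")))
  omi_rows <- lab$status == "OMI"
  expect_identical(lab$rule_fired[omi_rows], br[omi_rows])
})

test_that("cohort summary reproduces printed-ratio arithmetic and identities", {
  co <- generate_cohort(cohort_config(n_patients = 2500, seed = 19),
                        waveforms = FALSE)
  lab <- annotate_cohort(co)
  s <- cohort_summary(co, lab)
  expect_equal(s$All$omi[["n"]] + s$All$nomi[["n"]], s$All$ami[["n"]])
  expect_equal(s$All$omi[["pct"]],
               round_half_away(100 * s$All$omi[["n"]] / s$All$n, 1))
  expect_equal(s$OMI$mortality_30d[["pct"]],
               round_half_away(100 * s$OMI$mortality_30d[["n"]] / s$OMI$n, 1))
  expect_equal(s$OMI$ami[["pct"]], 100)
  expect_error(cohort_summary(structure(list(cases = list(),
                                             config = co$config),
                                        class = "omi_cohort"), lab), "empty")
})

test_that("percentages round half away from zero to one decimal", {
  expect_equal(round_half_away(5.35, 1), 5.4)
  expect_equal(round_half_away(-5.35, 1), -5.4)
  expect_equal(round_half_away(2.249, 1), 2.2)
  expect_equal(pct_of(25, 467), 5.4)
  expect_equal(pct_of(107, 467), 22.9)
  expect_true(is.na(pct_of(1, 0)))
})
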