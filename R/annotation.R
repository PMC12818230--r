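# Rule-based OMI annotation.
#
# Exclusions (no ECG, poor-quality index ECG, unclear outcome) are applied
# first; remaining patients with a discharge AMI diagnosis are run through a
# fixed-order decision tree over registry data:
#   R1  registered coronary occlusion (SCAAR ACO)
#   R2  24 h max hs-cTnT > 1000 ng/L and urgent PCI or CABG
#   R3  angiography with an acute culprit lesion and TIMI flow 0-1
#       (TIMI flow "unclear" routes to NEEDS_REVIEW for human adjudication)
#   R4  no angiography, hs-cTnT > 1000 ng/L and new regional wall-motion
#       abnormality, or a STEMI-indicative ECG with cardiac arrest before
#       angiography could be performed
# AMI with no branch firing is NOMI; no AMI diagnosis is NO_AMI.

#' Annotation thresholds
#'
#' @param troponin_threshold_ng_l hs-cTnT cut-off for the troponin branches
#'   (default 1000 ng/L).
#' @param occlusive_timi TIMI flow grades counted as occlusion (default 0, 1).
#' @param revasc_window_days window within which PCI/CABG counts as urgent
#'   revascularization (default 7 days).
#' @return object of class `annotation_config`
#' @export
annotation_config <- function(troponin_threshold_ng_l = 1000,
                              occlusive_timi = c("0", "1"),
                              revasc_window_days = 7) {
  if (troponin_threshold_ng_l <= 0) stop("threshold must be > 0", call. = FALSE)
  structure(list(troponin_threshold_ng_l = troponin_threshold_ng_l,
                 occlusive_timi = as.character(occlusive_timi),
                 revasc_window_days = revasc_window_days),
            class = "annotation_config")
}

omi_label <- function(status, rule_fired = NA_character_,
                      exclusion_reason = NA_character_) {
  structure(list(status = status, rule_fired = rule_fired,
                 exclusion_reason = exclusion_reason), class = "omi_label")
}

#' @export
print.omi_label <- function(x, ...) {
  cat(sprintf("<omi_label> %s%s%s\n", x$status,
              if (!is.na(x$rule_fired)) paste0(" (", x$rule_fired, ")") else "",
              if (!is.na(x$exclusion_reason))
                paste0(" [", x$exclusion_reason, "]") else ""))
  invisible(x)
}

registry_complete_for_tree <- function(reg) {
  # at least one branch must be decidable; "unclear outcome" = AMI diagnosis
  # with every field needed by all four branches absent
  if (!isTRUE(reg$discharge_ami)) return(TRUE)
  any(c(!is.na(reg$scaar_aco),
        !is.na(reg$max_hs_ctnt_24h_ng_l),
        isTRUE(reg$angiography_performed) && !is.na(reg$culprit_lesion)))
}

#' Apply the cohort exclusion flow to one case
#'
#' Cases without an ECG, with a poor-technical-quality index ECG, or whose
#' outcome is undecidable from registry data are excluded. A STEMI discharge
#' diagnosis never excludes: those patients are kept to reflect normal ED
#' patient flow.
#'
#' @param case a `patient_case`.
#' @return an `omi_label` with status `EXCLUDED` (and a reason), or `NULL`
#'   when the case passes.
#' @export
apply_exclusions <- function(case) {
  plan <- if (length(case$ecgs)) case$ecgs else case$ecg_plan
  if (!length(plan))
    return(omi_label("EXCLUDED", exclusion_reason = "no_ecg"))
  if (!isTRUE(plan[[1]]$quality_ok))
    return(omi_label("EXCLUDED", exclusion_reason = "poor_quality_ecg"))
  if (!registry_complete_for_tree(case$registry))
    return(omi_label("EXCLUDED", exclusion_reason = "unclear_outcome"))
  NULL
}

#' Annotate the OMI outcome from registry data
#'
#' Total and deterministic over syntactically valid registry records;
#' branches are evaluated in fixed order R1..R4 with first-match-wins (the
#' order only affects which rule is reported, not the status).
#'
#' @param registry a `registry_outcome` (or plain list with its fields).
#' @param config an [annotation_config()].
#' @return an `omi_label` with status `OMI`, `NOMI`, `NO_AMI` or
#'   `NEEDS_REVIEW` and the rule that fired.
#' @export
annotate_omi <- function(registry, config = annotation_config()) {
  reg <- registry
  if (!is.na(reg$timi_flow %||% NA) && !isTRUE(reg$angiography_performed))
    stop("contradictory registry: TIMI flow without angiography",
         call. = FALSE)
  if (!isTRUE(reg$discharge_ami)) return(omi_label("NO_AMI"))
  trop_high <- !is.na(reg$max_hs_ctnt_24h_ng_l) &&
    reg$max_hs_ctnt_24h_ng_l > config$troponin_threshold_ng_l

  if (isTRUE(reg$scaar_aco)) return(omi_label("OMI", "R1"))
  if (trop_high && (isTRUE(reg$urgent_pci) || isTRUE(reg$cabg)))
    return(omi_label("OMI", "R2"))
  if (isTRUE(reg$angiography_performed) && isTRUE(reg$culprit_lesion)) {
    tf <- reg$timi_flow %||% NA_character_
    if (!is.na(tf) && tf %in% config$occlusive_timi)
      return(omi_label("OMI", "R3"))
    if (!is.na(tf) && tf == "unclear")
      return(omi_label("NEEDS_REVIEW"))
  }
  if (!isTRUE(reg$angiography_performed) && trop_high &&
      (isTRUE(reg$new_rwma) ||
       (isTRUE(reg$stemi_ecg_present) &&
        isTRUE(reg$cardiac_arrest_before_angio))))
    return(omi_label("OMI", "R4"))
  omi_label("NOMI")
}

#' Annotate every case of a cohort
#'
#' @param cohort an `omi_cohort`.
#' @param config an [annotation_config()].
#' @return data frame with `patient_id`, `status`, `rule_fired`,
#'   `exclusion_reason`.
#' @export
annotate_cohort <- function(cohort, config = annotation_config()) {
  rows <- lapply(cohort$cases, function(cs) {
    lab <- apply_exclusions(cs)
    if (is.null(lab)) lab <- annotate_omi(cs$registry, config)
    data.frame(patient_id = cs$patient_id, status = lab$status,
               rule_fired = lab$rule_fired,
               exclusion_reason = lab$exclusion_reason)
  })
  do.call(rbind, rows)
}

med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Cohort summary in patient-characteristics layout
#'
#' Counts and percentages (one decimal, half rounded away from zero) for the
#' whole cohort and the OMI / NOMI columns: class sizes, demographics,
#' STEMI-rule positives, mortality at 30/180/365 days, and
#' angiography-timing rows (median/IQR hours; fractions within 90 min and
#' 2/3/6 h). Percentages use the column patient count as denominator except
#' the timing medians, which are over patients receiving angiography.
#'
#' @param cohort an `omi_cohort`.
#' @param labels annotation data frame from [annotate_cohort()].
#' @param stemi_positive optional logical vector (one per case) of rule-based
#'   STEMI verdicts on the index ECG.
#' @return a `cohort_summary` list of named count/percentage entries.
#' @export
cohort_summary <- function(cohort, labels, stemi_positive = NULL) {
  if (!length(cohort$cases)) stop("empty cohort", call. = FALSE)
  st <- labels$status
  keep <- !(st %in% c("EXCLUDED"))
  cs <- cohort$cases[keep]; st <- st[keep]
  if (!is.null(stemi_positive)) stemi_positive <- stemi_positive[keep]
  reg <- lapply(cs, `[[`, "registry")
  n <- length(cs)
  grp <- list(All = rep(TRUE, n), OMI = st == "OMI", NOMI = st == "NOMI")
  one <- function(sel) {
    m <- sum(sel)
    died <- function(f) sum(vapply(reg[sel], function(r) isTRUE(r[[f]]), TRUE))
    hrs <- vapply(reg[sel], function(r) r$hours_to_angiography %||% NA_real_, 0)
    within_h <- function(h) sum(!is.na(hrs) & hrs <= h)
    sexf <- sum(vapply(cs[sel], function(c) c$sex == "female", TRUE))
    tr <- vapply(cs[sel], function(c) c$hs_ctnt_initial_ng_l %||% NA_real_, 0)
    out <- list(
      n = m,
      female = c(n = sexf, pct = pct_of(sexf, m)),
      age_mean = mean(vapply(cs[sel], `[[`, 0, "age")),
      age_sd = sd(vapply(cs[sel], `[[`, 0, "age")),
      ami = local({k <- sum(st[sel] %in% c("OMI", "NOMI"))
                   c(n = k, pct = pct_of(k, m))}),
      omi = local({k <- sum(st[sel] == "OMI"); c(n = k, pct = pct_of(k, m))}),
      nomi = local({k <- sum(st[sel] == "NOMI"); c(n = k, pct = pct_of(k, m))}),
      troponin = med_iqr(tr),
      mortality_30d = c(n = died("died_30d"), pct = pct_of(died("died_30d"), m)),
      mortality_180d = c(n = died("died_180d"), pct = pct_of(died("died_180d"), m)),
      mortality_1y = c(n = died("died_1y"), pct = pct_of(died("died_1y"), m)),
      hours_to_angiography = med_iqr(hrs),
      angio_within_90min = c(n = within_h(1.5), pct = pct_of(within_h(1.5), m)),
      angio_within_2h = c(n = within_h(2), pct = pct_of(within_h(2), m)),
      angio_within_3h = c(n = within_h(3), pct = pct_of(within_h(3), m)),
      angio_within_6h = c(n = within_h(6), pct = pct_of(within_h(6), m)))
    if (!is.null(stemi_positive)) {
      k <- sum(stemi_positive[sel], na.rm = TRUE)
      out$stemi_criteria <- c(n = k, pct = pct_of(k, m))
    }
    out
  }
  structure(lapply(grp, one), class = "cohort_summary")
}
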