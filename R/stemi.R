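# Rule-based STEMI comparator.
#
# The guideline ST-elevation rule is applied to measurements taken on a
# median beat: R peaks are detected on lead II, beats are aligned on the R
# peak and combined by a per-sample median, the PR segment provides the
# per-lead baseline, and ST deviation is read at the J point (QRS offset
# located by a slope threshold) plus a configurable offset.
#
# Threshold table (J-point elevation in >= 2 contiguous leads; 1 mm = 0.1 mV):
# 0.1 mV in all leads except V2-V3, where men < 40 y require 0.25 mV,
# men >= 40 y 0.2 mV, and women 0.15 mV. The criteria are undefined
# (not_applicable) under LBBB, LVH or ventricular pacing.

CONTIGUOUS_GROUPS <- list(
  inferior = c("II", "III", "aVF"),
  anterior = c("V1", "V2", "V3", "V4"),
  lateral  = c("I", "aVL", "V5", "V6"),
  V1V2 = c("V1", "V2"), V2V3 = c("V2", "V3"), V3V4 = c("V3", "V4"),
  V4V5 = c("V4", "V5"), V5V6 = c("V5", "V6")
)

# simple R-peak detector on one channel: amplitude threshold + refractory
detect_r_peaks <- function(x, fs, min_rr_s = 0.3) {
  rng <- max(x) - min(x)
  if (rng < 0.2) return(integer(0))   # flatline / no QRS energy
  thr <- min(x) + 0.7 * rng
  cand <- which(x >= thr)
  if (!length(cand)) return(integer(0))
  peaks <- integer(0)
  min_gap <- round(min_rr_s * fs)
  runs <- split(cand, cumsum(c(1L, diff(cand) > 1L)))
  for (r in runs) {
    p <- r[which.max(x[r])]
    if (!length(peaks) || p - peaks[length(peaks)] > min_gap)
      peaks <- c(peaks, p)
    else if (x[p] > x[peaks[length(peaks)]])
      peaks[length(peaks)] <- p
  }
  peaks
}

#' Compute a median beat from an ECG record
#'
#' R peaks are detected on lead II; full beats (window -300 ms to +500 ms
#' around R) are stacked and combined per sample with the median. The
#' baseline is the mean of the PR segment (-80 to -20 ms before QRS onset).
#'
#' @param signal an `ecg_signal` of at least 5 s with acceptable quality.
#' @return a `median_beat`: `samples` (leads x window matrix, mV),
#'   `r_peak_index` (sample of R within the window), `baseline_mv`,
#'   `n_beats_used`, `sampling_rate_hz`.
#' @export
compute_median_beat <- function(signal) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (signal$duration_s < 5) stop("signal shorter than 5 s", call. = FALSE)
  fs <- signal$sampling_rate_hz
  pre <- round(0.300 * fs); post <- round(0.500 * fs)
  peaks <- detect_r_peaks(signal$samples["II", ], fs)
  peaks <- peaks[peaks > pre & peaks + post <= ncol(signal$samples)]
  if (length(peaks) < 3)
    stop("fewer than 3 beats detected; cannot form a median beat",
         call. = FALSE)
  win <- seq(-pre, post)
  nl <- nrow(signal$samples)
  stack <- matrix(NA_real_, nl * length(win), length(peaks))
  for (b in seq_along(peaks))
    stack[, b] <- as.vector(signal$samples[, peaks[b] + win])
  beat <- matrix(row_medians_cpp(stack), nrow = nl,
                 dimnames = list(rownames(signal$samples), NULL))
  r_idx <- pre + 1L
  onset <- qrs_onset(beat, r_idx, fs)
  pr <- seq(onset - round(0.080 * fs), onset - round(0.020 * fs))
  pr <- pr[pr >= 1]
  baseline <- rowMeans(beat[, pr, drop = FALSE])
  structure(list(samples = beat, r_peak_index = r_idx,
                 baseline_mv = baseline, n_beats_used = length(peaks),
                 sampling_rate_hz = fs),
            class = "median_beat")
}

# slope-threshold QRS boundary location on the cross-lead RMS derivative;
# the RMS trace is smoothed (~22 ms running mean) and differentiated over
# +/-10 ms so residual noise on the median beat cannot mask the ST plateau
qrs_edge <- function(beat, r_idx, fs, direction) {
  rms <- sqrt(colMeans(beat^2))
  k <- max(3L, round(0.022 * fs)); if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(rms, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- rms[is.na(sm)]
  h <- max(1L, round(0.010 * fs))
  n <- length(sm)
  d <- numeric(n)
  idx <- (1 + h):(n - h)
  d[idx] <- abs(sm[idx + h] - sm[idx - h]) * fs / (2 * h)   # mV/s
  qrs_zone <- max(1, r_idx - round(0.06 * fs)):min(length(d), r_idx + round(0.06 * fs))
  ref <- max(d[qrs_zone])
  thr <- 0.06 * ref
  hold <- round(0.016 * fs)
  if (direction == "after") {
    lo <- r_idx + round(0.020 * fs); hi <- min(length(d) - hold, r_idx + round(0.160 * fs))
    for (i in lo:hi) if (all(d[i:(i + hold)] < thr)) return(i)
  } else {
    hi <- r_idx - round(0.020 * fs); lo <- max(1 + hold, r_idx - round(0.160 * fs))
    for (i in hi:lo) if (all(d[(i - hold):i] < thr)) return(i)
  }
  NA_integer_
}

qrs_onset <- function(beat, r_idx, fs) {
  on <- qrs_edge(beat, r_idx, fs, "before")
  if (is.na(on)) r_idx - round(0.065 * fs) else on
}

#' Measure per-lead ST deviation on a median beat
#'
#' The J point is the QRS offset, located where the rectified cross-lead
#' slope of the median beat stays below 6% of its intra-QRS maximum for
#' 16 ms; ST deviation is the amplitude at J + `j_offset_ms` minus the
#' per-lead PR baseline.
#'
#' @param beat a `median_beat`.
#' @param j_offset_ms measurement offset after the J point, ms (default 60;
#'   0/40/80 are other common conventions).
#' @return an `st_measurements` object: named per-lead deviations in mV plus
#'   `j_index` and `j_offset_ms`.
#' @export
measure_st <- function(beat, j_offset_ms = 60) {
  stopifnot(inherits(beat, "median_beat"))
  fs <- beat$sampling_rate_hz
  j <- qrs_edge(beat$samples, beat$r_peak_index, fs, "after")
  if (is.na(j)) stop("J point not locatable on this beat", call. = FALSE)
  at <- j + round(j_offset_ms / 1000 * fs)
  if (at > ncol(beat$samples)) stop("measurement point beyond beat window",
                                    call. = FALSE)
  st <- beat$samples[, at] - beat$baseline_mv
  structure(list(st_mv = st, j_index = j, j_offset_ms = j_offset_ms),
            class = "st_measurements")
}

stemi_threshold_mv <- function(lead, sex, age) {
  if (lead %in% c("V2", "V3")) {
    if (sex == "female") 0.15 else if (age < 40) 0.25 else 0.20
  } else 0.1
}

#' Evaluate the guideline ST-elevation criteria
#'
#' Positive when at least 2 leads within one contiguous group reach their
#' lead/age/sex-specific elevation threshold; `not_applicable` when the
#' record carries LBBB, LVH or ventricular-pacing morphology, for which the
#' criteria are undefined.
#'
#' @param st an `st_measurements` object (or named per-lead numeric vector
#'   of ST deviations in mV).
#' @param age patient age in years.
#' @param sex `"female"` or `"male"`.
#' @param morphology_flags character vector; any of LBBB, LVH, VP makes the
#'   verdict `not_applicable`.
#' @param groups named list of contiguous lead groups.
#' @return a `stemi_verdict`: `verdict` (positive/negative/not_applicable),
#'   `leads_meeting`, `contiguous_group`.
#' @export
evaluate_stemi <- function(st, age, sex, morphology_flags = character(0),
                           groups = CONTIGUOUS_GROUPS) {
  stv <- if (inherits(st, "st_measurements")) st$st_mv else st
  if (is.null(names(stv)) || !all(names(stv) %in% LEADS_12))
    stop("unknown lead names in ST measurements", call. = FALSE)
  if (length(morphology_flags) > 0 && any(morphology_flags %in% c("LBBB", "LVH", "VP")))
    return(structure(list(verdict = "not_applicable",
                          leads_meeting = character(0),
                          contiguous_group = NA_character_),
                     class = "stemi_verdict"))
  meets <- names(stv)[vapply(names(stv), function(ld)
    stv[[ld]] >= stemi_threshold_mv(ld, sex, age), TRUE)]
  group <- NA_character_
  for (g in names(groups)) {
    if (sum(groups[[g]] %in% meets) >= 2) { group <- g; break }
  }
  structure(list(verdict = if (!is.na(group)) "positive" else "negative",
                 leads_meeting = meets, contiguous_group = group),
            class = "stemi_verdict")
}

#' @export
print.stemi_verdict <- function(x, ...) {
  cat(sprintf("<stemi_verdict> %s%s\n", x$verdict,
              if (!is.na(x$contiguous_group))
                sprintf(" (%s: %s)", x$contiguous_group,
                        paste(x$leads_meeting, collapse = ","))
              else ""))
  invisible(x)
}

#' Apply the STEMI rule to every index ECG of a cohort
#'
#' Measurement failures (undetectable beats or J point) yield `NA` ST values
#' and a negative verdict, mirroring how an automated rule engine abstains.
#'
#' @param cohort an `omi_cohort` with waveforms.
#' @param j_offset_ms measurement offset after the J point, ms.
#' @return data frame with `patient_id`, `verdict`, `group`, and per-lead ST
#'   columns `st_<lead>`.
#' @export
stemi_cohort <- function(cohort, j_offset_ms = 60) {
  rows <- lapply(cohort$cases, function(cs) {
    base <- data.frame(patient_id = cs$patient_id, verdict = NA_character_,
                       group = NA_character_)
    stm <- matrix(NA_real_, 1, length(LEADS_12),
                  dimnames = list(NULL, paste0("st_", LEADS_12)))
    if (length(cs$ecgs) && isTRUE(cs$ecgs[[1]]$quality_ok)) {
      v <- tryCatch({
        beat <- compute_median_beat(cs$ecgs[[1]])
        st <- measure_st(beat, j_offset_ms)
        stm[1, ] <- st$st_mv[LEADS_12]
        evaluate_stemi(st, cs$age, cs$sex, cs$ecgs[[1]]$morphology_flags)
      }, error = function(e) NULL)
      if (!is.null(v)) {
        base$verdict <- v$verdict
        base$group <- v$contiguous_group
      } else base$verdict <- "negative"
    }
    cbind(base, as.data.frame(stm))
  })
  do.call(rbind, rows)
}
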