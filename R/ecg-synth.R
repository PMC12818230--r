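# Synthetic 12-lead ECG waveforms.
#
# One beat is a sum of 5 Gaussians (P, Q, R, S, T) on a common time base,
# projected onto the 8 linearly independent channels (I, II, V1-V6) through a
# fixed lead-amplitude matrix; the 4 remaining limb leads are derived through
# the Einthoven/Goldberger identities. ST-segment deviation is added as a
# smooth plateau between the end of the S wave and the onset of the T wave so
# that the level measured at the J point (and J+40/60/80 ms) equals the
# configured per-lead offset.

WAVE_TABLE <- data.frame(
  wave     = c("P", "Q", "R", "S", "T"),
  center_s = c(-0.200, -0.035, 0.000, 0.035, 0.300),
  width_s  = c(0.025, 0.010, 0.012, 0.010, 0.060),
  stringsAsFactors = FALSE
)

# rows: P Q R S T; columns: I II V1..V6 (mV)
LEAD_AMP <- matrix(c(
  0.08,  0.12, 0.04,  0.05,  0.06,  0.07,  0.07,  0.06,
 -0.06, -0.08, -0.02, -0.03, -0.05, -0.08, -0.08, -0.06,
  0.70,  1.00, 0.30,  0.60,  0.90,  1.40,  1.20,  0.90,
 -0.15, -0.20, -0.70, -0.80, -0.50, -0.30, -0.15, -0.10,
  0.25,  0.35, 0.10,  0.30,  0.40,  0.40,  0.30,  0.25),
  nrow = 5, byrow = TRUE,
  dimnames = list(c("P", "Q", "R", "S", "T"), LEADS_8))

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Morphology parameters for one synthetic ECG
#'
#' @param heart_rate beats per minute, in `[30, 220]`.
#' @param st_offset_mv named numeric vector of per-channel ST-segment offsets
#'   in mV over the 8 synthesized channels (I, II, V1-V6); unnamed leads
#'   default to 0.
#' @param noise_sd_mv standard deviation of additive white noise, mV.
#' @param baseline_wander_amp_mv amplitude of a slow sinusoidal baseline
#'   drift, mV.
#' @param morphology one of `"normal"`, `"LBBB"`, `"LVH"`, `"VP"`.
#'   LBBB and ventricular pacing widen the QRS Gaussians (x2.5); LVH scales
#'   the R-wave amplitude (x1.8).
#' @param waves data frame with columns `wave`, `center_s`, `width_s` for the
#'   P/Q/R/S/T Gaussians (centers relative to the R peak, seconds).
#' @param lead_amp 5 x 8 matrix of per-wave, per-channel amplitudes in mV.
#' @return an object of class `ecg_morph_params`
#' @export
ecg_morph_params <- function(heart_rate = 75,
                             st_offset_mv = numeric(0),
                             noise_sd_mv = 0.02,
                             baseline_wander_amp_mv = 0.03,
                             morphology = c("normal", "LBBB", "LVH", "VP"),
                             waves = WAVE_TABLE,
                             lead_amp = LEAD_AMP) {
  morphology <- match.arg(morphology)
  if (!is.numeric(heart_rate) || heart_rate < 30 || heart_rate > 220)
    stop("heart_rate must be in [30, 220] bpm", call. = FALSE)
  if (any(waves$width_s <= 0)) stop("wave widths must be positive", call. = FALSE)
  st <- stats::setNames(numeric(length(LEADS_8)), LEADS_8)
  if (length(st_offset_mv)) {
    if (is.null(names(st_offset_mv)) || !all(names(st_offset_mv) %in% LEADS_8))
      stop("st_offset_mv must be named with channels among I, II, V1-V6",
           call. = FALSE)
    st[names(st_offset_mv)] <- st_offset_mv
  }
  if (morphology %in% c("LBBB", "VP"))
    waves$width_s[waves$wave %in% c("Q", "R", "S")] <-
      2.5 * waves$width_s[waves$wave %in% c("Q", "R", "S")]
  if (morphology == "LVH")
    lead_amp["R", ] <- 1.8 * lead_amp["R", ]
  structure(list(heart_rate = heart_rate, waves = waves, lead_amp = lead_amp,
                 st_offset_mv = st, noise_sd_mv = noise_sd_mv,
                 baseline_wander_amp_mv = baseline_wander_amp_mv,
                 morphology = morphology),
            class = "ecg_morph_params")
}

# C1 smoothstep between 0 and 1 on [a, b]
smoothstep <- function(t, a, b) {
  u <- pmin(pmax((t - a) / (b - a), 0), 1)
  u * u * (3 - 2 * u)
}

# ST plateau shape relative to the R peak: ramps up over the S-wave tail,
# holds through the ST segment, and releases into the T wave.
st_bump <- function(tau) {
  smoothstep(tau, 0.030, 0.055) * (1 - smoothstep(tau, 0.180, 0.260))
}

# one beat on relative time tau (seconds from R peak), all 8 channels
beat_template <- function(params, tau) {
  w <- params$waves
  out <- matrix(0, nrow = length(LEADS_8), ncol = length(tau),
                dimnames = list(LEADS_8, NULL))
  for (i in seq_len(nrow(w))) {
    g <- exp(-(tau - w$center_s[i])^2 / (2 * w$width_s[i]^2))
    out <- out + params$lead_amp[w$wave[i], ] %o% g
  }
  out + params$st_offset_mv %o% st_bump(tau)
}

#' Synthesize one 12-lead ECG record
#'
#' Builds the 8 independent channels from the beat template (tiled at a fixed
#' RR interval with random phase), adds baseline wander and white noise, then
#' derives leads III, aVR, aVL, aVF from the (noisy) I and II so the lead
#' identities hold exactly.
#'
#' @param params an [ecg_morph_params()] object.
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param sampling_rate_hz samples per second (default 500).
#' @param duration_s record length in seconds (default 10).
#' @param quality_ok technical-quality flag carried on the record.
#' @param recorded_at numeric timestamp (hours from ED arrival).
#' @return an `ecg_signal`: list with `samples` (12 x T matrix, mV,
#'   rownames = lead names), `lead_names`, `sampling_rate_hz`, `duration_s`,
#'   `quality_ok`, `morphology_flags`, `recorded_at`.
#' @export
synthesize_ecg <- function(params, seed = NULL, sampling_rate_hz = 500,
                           duration_s = 10, quality_ok = TRUE,
                           recorded_at = 0) {
  stopifnot(inherits(params, "ecg_morph_params"))
  with_seed(seed, {
    fs <- sampling_rate_hz
    n <- round(fs * duration_s)
    rr_samp <- max(2L, round(fs * 60 / params$heart_rate))
    tau <- (seq_len(rr_samp) - 1) / fs - 0.30   # R peak 0.30 s into the beat
    # fold Gaussian tails from the neighbouring beats so tiling is seamless
    tmpl <- beat_template(params, tau) +
      beat_template(params, tau + rr_samp / fs) +
      beat_template(params, tau - rr_samp / fs)
    phase <- sample.int(rr_samp, 1L) - 1L
    idx <- ((phase + seq_len(n) - 1L) %% rr_samp) + 1L
    sig8 <- tmpl[, idx, drop = FALSE]
    t_abs <- (seq_len(n) - 1) / fs
    if (params$baseline_wander_amp_mv > 0) {
      f <- runif(1, 0.10, 0.35); ph <- runif(1, 0, 2 * pi)
      wander <- params$baseline_wander_amp_mv * sin(2 * pi * f * t_abs + ph)
      sig8 <- sweep(sig8, 2, wander, "+")
    }
    if (params$noise_sd_mv > 0)
      sig8 <- sig8 + matrix(rnorm(length(sig8), sd = params$noise_sd_mv),
                            nrow = nrow(sig8))
    samples <- derive_limb_leads(sig8)
    structure(list(samples = samples, lead_names = rownames(samples),
                   sampling_rate_hz = fs, duration_s = duration_s,
                   quality_ok = quality_ok,
                   morphology_flags =
                     if (params$morphology == "normal") character(0)
                     else params$morphology,
                   recorded_at = recorded_at),
              class = "ecg_signal")
  })
}

#' Derive the dependent limb leads from an 8-channel ECG
#'
#' Leads III, aVR, aVL and aVF are linear combinations of I and II
#' (Einthoven/Goldberger): III = II - I, aVR = -(I + II)/2, aVL = I - II/2,
#' aVF = II - I/2.
#'
#' @param eight_leads matrix with rownames containing at least
#'   I, II, V1-V6, or an `ecg_signal`.
#' @return 12 x T matrix ordered I, II, III, aVR, aVL, aVF, V1-V6.
#' @export
derive_limb_leads <- function(eight_leads) {
  m <- if (inherits(eight_leads, "ecg_signal")) eight_leads$samples else eight_leads
  if (is.null(rownames(m)) || !all(LEADS_8 %in% rownames(m)))
    stop("input must contain leads ", paste(LEADS_8, collapse = ", "),
         call. = FALSE)
  I <- m["I", ]; II <- m["II", ]
  out <- rbind(I = I, II = II, III = II - I, aVR = -(I + II) / 2,
               aVL = I - II / 2, aVF = II - I / 2,
               m[c("V1", "V2", "V3", "V4", "V5", "V6"), , drop = FALSE])
  out[LEADS_12, , drop = FALSE]
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d leads x %d samples @ %g Hz (%g s)%s%s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              x$duration_s,
              if (length(x$morphology_flags))
                paste0(", flags: ", paste(x$morphology_flags, collapse = "+"))
              else "",
              if (x$quality_ok) "" else ", POOR QUALITY"))
  invisible(x)
}
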