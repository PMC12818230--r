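# Minimal WFDB record I/O: text header (.hea) plus format-16 signal file
# (.dat, interleaved little-endian int16). Amplitudes are stored at a gain
# of 1000 adu/mV (1 uV resolution), which is recorded in the header.

WFDB_GAIN <- 1000

#' Write an ECG record in WFDB format
#'
#' @param signal an `ecg_signal`.
#' @param dir output directory (created if needed).
#' @param record record name (basename of the .hea/.dat pair).
#' @return the header path, invisibly.
#' @export
write_wfdb <- function(signal, dir, record) {
  stopifnot(inherits(signal, "ecg_signal"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- signal$samples
  adu <- round(m * WFDB_GAIN)
  adu <- pmin(pmax(adu, -32768), 32767)
  n <- ncol(adu); nsig <- nrow(adu)
  dat <- paste0(record, ".dat")
  hea <- file.path(dir, paste0(record, ".hea"))
  chks <- (rowSums(adu) %% 65536)
  chks <- ifelse(chks > 32767, chks - 65536, chks)
  lines <- c(sprintf("%s %d %g %d", record, nsig, signal$sampling_rate_hz, n),
             sprintf("%s 16 %d(0)/mV 16 0 %d %d 0 %s", dat, WFDB_GAIN,
                     as.integer(adu[, 1]), as.integer(chks),
                     rownames(m)),
             sprintf("# quality_ok: %s", signal$quality_ok),
             sprintf("# morphology: %s",
                     paste(signal$morphology_flags, collapse = ",")),
             sprintf("# recorded_at: %g", signal$recorded_at))
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(adu)), con, size = 2, endian = "little")
  invisible(hea)
}

#' Read a WFDB record written by [write_wfdb()]
#'
#' @param dir directory holding the record.
#' @param record record name.
#' @return an `ecg_signal` (amplitudes in mV).
#' @export
read_wfdb <- function(dir, record) {
  hea <- readLines(file.path(dir, paste0(record, ".hea")))
  top <- strsplit(hea[1], " ")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig_lines <- hea[2:(1 + nsig)]
  leads <- vapply(strsplit(sig_lines, " "), function(f) f[length(f)], "")
  gain <- as.numeric(sub("\\(.*", "", vapply(strsplit(sig_lines, " "),
                                             `[[`, "", 3)))
  meta <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hea, value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  dat <- file.path(dir, paste0(record, ".dat"))
  raw <- readBin(dat, integer(), n = nsig * n, size = 2, endian = "little")
  m <- matrix(raw, nrow = nsig)
  m <- sweep(m, 1, gain, "/")
  rownames(m) <- leads
  flags <- meta("morphology", "")
  structure(list(samples = m, lead_names = leads, sampling_rate_hz = fs,
                 duration_s = n / fs,
                 quality_ok = identical(meta("quality_ok", "TRUE"), "TRUE"),
                 morphology_flags = if (nzchar(flags))
                   strsplit(flags, ",")[[1]] else character(0),
                 recorded_at = as.numeric(meta("recorded_at", "0"))),
            class = "ecg_signal")
}
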