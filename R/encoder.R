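# ECG encoder: a residual 1-D convolutional network mapping an 8-lead ECG
# (V1-V6, I, II; the 4 remaining leads are linear combinations of I and II)
# to a compact embedding. Training uses random 2.5 s crops and, when a visit
# has more than one ECG, the extra recordings with the index visit's label;
# evaluation averages over 10 evenly spaced overlapping crops of the index
# ECG only.

ENCODER_LEADS <- c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II")

#' Encoder configuration
#'
#' @param input_leads ordered lead subset fed to the network.
#' @param crop_seconds training/evaluation crop length (default 2.5 s).
#' @param eval_crops overlapping crops averaged at evaluation (default 10).
#' @param embedding_dim width of the embedding bottleneck (default 50).
#' @param stem_channels,block_channels widths of the stem and of each
#'   residual block (one entry per block).
#' @param sampling_rate_hz sampling rate of the input records (sets the
#'   crop length in samples).
#' @param epochs,batch_size,learning_rate Adam settings.
#' @param pos_weight weight of positive examples in the loss; `"auto"` uses
#'   the training-set negative:positive ratio.
#' @param patience early-stopping patience on tuning discrimination.
#' @param seed integer seed for init, shuffling and crop positions.
#' @return object of class `encoder_config`
#' @export
encoder_config <- function(input_leads = ENCODER_LEADS, crop_seconds = 2.5,
                           eval_crops = 10, embedding_dim = 50,
                           sampling_rate_hz = 500,
                           stem_channels = 16, block_channels = c(24, 32),
                           epochs = 6, batch_size = 32,
                           learning_rate = 1e-3, pos_weight = "auto",
                           patience = 5, seed = 1L) {
  if (eval_crops < 1) stop("eval_crops must be >= 1", call. = FALSE)
  if (embedding_dim < 1) stop("embedding_dim must be >= 1", call. = FALSE)
  structure(list(input_leads = input_leads, crop_seconds = crop_seconds,
                 eval_crops = eval_crops, embedding_dim = embedding_dim,
                 sampling_rate_hz = sampling_rate_hz,
                 stem_channels = stem_channels,
                 block_channels = block_channels, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 pos_weight = pos_weight, patience = patience,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Reduce a 12-lead record to the encoder's input leads
#'
#' @param signal an `ecg_signal` (or leads x time matrix with rownames).
#' @param input_leads ordered leads to keep.
#' @return leads x time matrix in the requested order.
#' @export
select_leads <- function(signal, input_leads = ENCODER_LEADS) {
  m <- if (inherits(signal, "ecg_signal")) signal$samples else signal
  missing_leads <- setdiff(input_leads, rownames(m))
  if (length(missing_leads))
    stop("requested leads not present: ",
         paste(missing_leads, collapse = ", "), call. = FALSE)
  m[input_leads, , drop = FALSE]
}

#' Random contiguous crop
#'
#' Start position uniform over the valid range; all leads share the window.
#'
#' @param x leads x time matrix (or `ecg_signal`).
#' @param crop_samples window length in samples.
#' @param seed optional seed.
#' @return leads x crop_samples matrix.
#' @export
random_crop <- function(x, crop_samples, seed = NULL) {
  m <- if (inherits(x, "ecg_signal")) x$samples else x
  T <- ncol(m)
  if (crop_samples > T) stop("signal shorter than the crop", call. = FALSE)
  start <- with_seed(seed, sample.int(T - crop_samples + 1L, 1L))
  m[, start:(start + crop_samples - 1L), drop = FALSE]
}

#' Evenly spaced overlapping crop windows
#'
#' `n` windows, the first starting at 0 and the last ending at the signal
#' end; non-integer strides are rounded to the nearest sample. `n = 1`
#' yields a single centered window.
#'
#' @param n_samples signal length in samples.
#' @param crop_samples window length in samples.
#' @param n number of windows.
#' @return integer vector of 1-based start indices.
#' @export
crop_starts <- function(n_samples, crop_samples, n) {
  if (n < 1) stop("need at least one crop", call. = FALSE)
  if (crop_samples > n_samples) stop("signal shorter than the crop", call. = FALSE)
  last <- n_samples - crop_samples
  if (n == 1) return(1L + as.integer(round(last / 2)))
  1L + as.integer(round(seq(0, last, length.out = n)))
}

#' Overlapping evaluation crops of a record
#'
#' @param x leads x time matrix (or `ecg_signal`).
#' @param n number of crops.
#' @param crop_samples window length in samples.
#' @return list of leads x crop_samples matrices.
#' @export
overlapping_crops <- function(x, n, crop_samples) {
  m <- if (inherits(x, "ecg_signal")) x$samples else x
  lapply(crop_starts(ncol(m), crop_samples, n), function(s)
    m[, s:(s + crop_samples - 1L), drop = FALSE])
}

#' Expand training visits into (ECG, label) pairs
#'
#' One pair per ECG of every visit; extra (non-index) ECGs carry the index
#' visit's label and are flagged, because they are used only to train the
#' encoder, never for feature extraction.
#'
#' @param cohort an `omi_cohort` with waveforms.
#' @param labels annotation data frame; OMI is the positive class, EXCLUDED
#'   and NEEDS_REVIEW visits are dropped.
#' @param ids optional patient ids to restrict to (e.g. the training split).
#' @return list of pairs: `signal` (8-lead matrix), `label`, `is_index`,
#'   `patient_id`.
#' @export
augment_training_set <- function(cohort, labels, ids = NULL) {
  status <- stats::setNames(labels$status, labels$patient_id)
  pairs <- list()
  for (cs in cohort$cases) {
    st <- status[[cs$patient_id]]
    if (is.na(st) || !(st %in% c("OMI", "NOMI", "NO_AMI"))) next
    if (!is.null(ids) && !(cs$patient_id %in% ids)) next
    for (k in seq_along(cs$ecgs)) {
      pairs[[length(pairs) + 1L]] <-
        list(signal = select_leads(cs$ecgs[[k]]), label = st == "OMI",
             is_index = k == 1L, patient_id = cs$patient_id)
    }
  }
  pairs
}

init_resnet_weights <- function(config, n_leads) {
  he <- function(rows, cols, fan_in)
    matrix(rnorm(rows * cols, sd = sqrt(2 / fan_in)), rows, cols)
  w <- list()
  ch <- c(config$stem_channels, config$block_channels)
  w$W_stem <- he(ch[1], n_leads * 7, n_leads * 7)
  w$b_stem <- matrix(0, ch[1], 1)
  for (b in seq_along(config$block_channels)) {
    ci <- ch[b]; co <- ch[b + 1]
    w[[sprintf("W1_%d", b)]] <- he(co, ci * 5, ci * 5)
    w[[sprintf("b1_%d", b)]] <- matrix(0, co, 1)
    w[[sprintf("W2_%d", b)]] <- he(co, co * 5, co * 5)
    w[[sprintf("b2_%d", b)]] <- matrix(0, co, 1)
    w[[sprintf("Ws_%d", b)]] <- he(co, ci, ci)
    w[[sprintf("bs_%d", b)]] <- matrix(0, co, 1)
  }
  c_last <- ch[length(ch)]
  w$W_emb <- he(config$embedding_dim, c_last, c_last)
  w$b_emb <- matrix(0, config$embedding_dim, 1)
  w$W_out <- he(1, config$embedding_dim, config$embedding_dim)
  w$b_out <- matrix(0, 1, 1)
  w
}

pairs_to_cube <- function(pairs, starts, crop_samples) {
  n <- length(pairs)
  X <- array(0, c(nrow(pairs[[1]]$signal), crop_samples, n))
  for (i in seq_len(n))
    X[, , i] <- pairs[[i]]$signal[, starts[i]:(starts[i] + crop_samples - 1L)]
  X
}

encoder_logits <- function(weights, pairs, crop_samples, starts = NULL) {
  if (is.null(starts))
    starts <- vapply(pairs, function(p)
      crop_starts(ncol(p$signal), crop_samples, 1L), 0L)
  out <- resnet_forward_cpp(weights, pairs_to_cube(pairs, starts, crop_samples))
  as.numeric(out$logits)
}

#' Train the residual ECG encoder
#'
#' Adam on weighted binary cross-entropy over random crops; after each
#' epoch, tuning discrimination (AUC on a centered crop) drives model
#' selection and early stopping. Deterministic given `config$seed`.
#'
#' @param train_pairs,tune_pairs pair lists from [augment_training_set()];
#'   tuning pairs should be index ECGs only.
#' @param config an [encoder_config()].
#' @param init_weights optional pre-trained weight list (transfer-learning
#'   hook); default is a fresh He initialization.
#' @param verbose print per-epoch progress.
#' @return an `ecg_encoder`: weights, config, per-epoch tuning AUC history.
#' @export
train_encoder <- function(train_pairs, tune_pairs, config = encoder_config(),
                          init_weights = NULL, verbose = FALSE) {
  y <- vapply(train_pairs, `[[`, TRUE, "label")
  if (length(unique(y)) < 2)
    stop("training pairs contain a single class", call. = FALSE)
  crop <- round(config$crop_seconds * config$sampling_rate_hz)
  pos_w <- if (identical(config$pos_weight, "auto"))
    sum(!y) / sum(y) else config$pos_weight

  set.seed(derive_seed(config$seed, "encoder"))
  w <- init_weights %||% init_resnet_weights(config,
                                             length(config$input_leads))
  m <- lapply(w, function(x) x * 0); v <- m; t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(auc = -Inf, weights = w, epoch = 0L)
  y_tune <- vapply(tune_pairs, `[[`, TRUE, "label")
  history <- numeric(0)
  n <- length(train_pairs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts_all <- vapply(train_pairs, function(p)
      sample.int(ncol(p$signal) - crop + 1L, 1L), 0L)
    for (i0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[i0:min(i0 + config$batch_size - 1L, n)]
      X <- pairs_to_cube(train_pairs[idx], starts_all[idx], crop)
      gr <- resnet_grad_cpp(w, X, as.numeric(y[idx]), pos_w)
      t_step <- t_step + 1
      for (j in seq_along(w)) {
        g <- gr$grads[[j]]
        m[[j]] <- b1 * m[[j]] + (1 - b1) * g
        v[[j]] <- b2 * v[[j]] + (1 - b2) * g^2
        mh <- m[[j]] / (1 - b1^t_step)
        vh <- v[[j]] / (1 - b2^t_step)
        w[[j]] <- w[[j]] - config$learning_rate * mh / (sqrt(vh) + eps)
      }
    }
    auc <- roc_auc(encoder_logits(w, tune_pairs, crop), y_tune)
    history <- c(history, auc)
    if (verbose)
      message(sprintf("epoch %d: tuning AUC %.3f", epoch, auc))
    if (auc > best$auc) best <- list(auc = auc, weights = w, epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  structure(list(weights = best$weights, config = config,
                 tuning_auc = best$auc, history = history,
                 pos_weight = pos_w, crop_samples = crop),
            class = "ecg_encoder")
}

#' Embed one ECG record
#'
#' Mean embedding (and mean head probability) over the evaluation crops.
#'
#' @param model a trained `ecg_encoder`.
#' @param signal an `ecg_signal` or 8-lead matrix.
#' @return list `embedding` (length `embedding_dim`), `probability`.
#' @export
embed_ecg <- function(model, signal) {
  if (!inherits(model, "ecg_encoder")) stop("untrained model", call. = FALSE)
  m <- if (inherits(signal, "ecg_signal"))
    select_leads(signal, model$config$input_leads) else signal
  crops <- overlapping_crops(m, model$config$eval_crops, model$crop_samples)
  X <- array(0, c(nrow(m), model$crop_samples, length(crops)))
  for (i in seq_along(crops)) X[, , i] <- crops[[i]]
  out <- resnet_forward_cpp(model$weights, X)
  list(embedding = rowMeans(out$embedding),
       probability = mean(stats::plogis(as.numeric(out$logits))))
}

#' Embed every index ECG of a cohort
#'
#' Feature extraction consumes index ECGs only (extra recordings are a
#' training-time augmentation).
#'
#' @param model a trained `ecg_encoder`.
#' @param cohort an `omi_cohort` with waveforms.
#' @return matrix (patients x embedding_dim) with patient-id rownames;
#'   `probability` attribute carries the crop-averaged head probabilities.
#' @export
embed_cohort <- function(model, cohort) {
  has_ecg <- vapply(cohort$cases, function(c) length(c$ecgs) > 0, TRUE)
  cs <- cohort$cases[has_ecg]
  rows <- lapply(cs, function(c) embed_ecg(model, c$ecgs[[1]]))
  emb <- do.call(rbind, lapply(rows, `[[`, "embedding"))
  rownames(emb) <- vapply(cs, `[[`, "", "patient_id")
  attr(emb, "probability") <- stats::setNames(
    vapply(rows, `[[`, 0, "probability"), rownames(emb))
  emb
}
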