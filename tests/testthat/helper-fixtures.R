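# shared fixtures, built in code

# a syntactically valid registry record with overridable fields
make_registry <- function(...) {
  base <- list(discharge_ami = FALSE, scaar_aco = FALSE,
               angiography_performed = FALSE, hours_to_angiography = NA_real_,
               culprit_lesion = NA, timi_flow = NA_character_,
               urgent_pci = FALSE, cabg = FALSE,
               max_hs_ctnt_24h_ng_l = 50, new_rwma = NA,
               cardiac_arrest_before_angio = FALSE,
               stemi_ecg_present = FALSE,
               died_30d = FALSE, died_180d = FALSE, died_1y = FALSE)
  over <- list(...)
  base[names(over)] <- over
  structure(base, class = "registry_outcome")
}

# random syntactically valid registry (invariants: timi/hours iff angio)
random_registry <- function() {
  angio <- runif(1) < 0.5
  make_registry(
    discharge_ami = runif(1) < 0.5,
    scaar_aco = runif(1) < 0.3,
    angiography_performed = angio,
    hours_to_angiography = if (angio) rlnorm(1, 2, 1) else NA_real_,
    culprit_lesion = if (angio) runif(1) < 0.5 else NA,
    timi_flow = if (angio) sample(c("0", "1", "2", "3", "unclear"), 1)
                else NA_character_,
    urgent_pci = runif(1) < 0.4, cabg = runif(1) < 0.1,
    max_hs_ctnt_24h_ng_l = rlnorm(1, 4, 2),
    new_rwma = sample(c(TRUE, FALSE, NA), 1),
    cardiac_arrest_before_angio = runif(1) < 0.1,
    stemi_ecg_present = runif(1) < 0.2)
}

noiseless_params <- function(...) {
  ecg_morph_params(noise_sd_mv = 0, baseline_wander_amp_mv = 0, ...)
}

# small balanced encoder training pairs with a controllable ST effect
make_encoder_pairs <- function(n_per_class, st_mv = 0.25, noise = 0.01,
                               seed0 = 0) {
  mk <- function(i, omi) {
    st <- if (omi) {
      g <- sample(c("inferior", "anterior", "lateral"), 1)
      omipipe:::st_pattern(g, st_mv)
    } else numeric(0)
    p <- ecg_morph_params(heart_rate = runif(1, 55, 100), st_offset_mv = st,
                          noise_sd_mv = noise)
    list(signal = select_leads(synthesize_ecg(p, seed = seed0 + i)),
         label = omi, is_index = TRUE, patient_id = sprintf("p%d", i))
  }
  c(lapply(seq_len(n_per_class), mk, omi = TRUE),
    lapply(n_per_class + seq_len(n_per_class), mk, omi = FALSE))
}

small_encoder_config <- function(epochs = 4, ...) {
  encoder_config(stem_channels = 12, block_channels = c(16, 24),
                 embedding_dim = 16, epochs = epochs, ...)
}

# brute-force AUC oracle: count concordant pairs, ties half
auc_bruteforce <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
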