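test_that("lead reduction keeps the 8 informative leads and is lossless", {
  s <- synthesize_ecg(ecg_morph_params(), seed = 2)
  m <- select_leads(s)
  expect_identical(rownames(m), c(paste0("V", 1:6), "I", "II"))
  expect_equal(nrow(m), 8)
  # the dropped leads are exact linear combinations of the retained ones
  expect_equal(m["II", ] - m["I", ], s$samples["III", ])
  expect_equal(-(m["I", ] + m["II", ]) / 2, s$samples["aVR", ])
  expect_error(select_leads(s, c("I", "V9")), "V9")
})

test_that("random crops have the right geometry and uniform starts", {
  s <- synthesize_ecg(ecg_morph_params(), seed = 3)
  cr <- random_crop(s, 1250, seed = 1)
  expect_equal(dim(cr), c(12, 1250))
  expect_identical(random_crop(s, 5000, seed = 1), s$samples)
  expect_error(random_crop(s, 6000), "shorter")

  # encode the start position in the sample values to audit uniformity
  probe <- matrix(rep(1:1000, each = 1), 1, 1000)
  set.seed(7)
  starts <- replicate(10000, random_crop(probe, 1)[1, 1])
  cnt <- table(cut(starts, breaks = seq(0.5, 1000.5, length.out = 11)))
  p <- chisq.test(cnt)$p.value
  expect_gt(p, 0.01)
})

test_that("overlapping evaluation windows tile the record as specified", {
  st <- crop_starts(5000, 1250, 10)
  expect_equal(st[1], 1L)
  expect_equal(st[10], 3751L)           # last window ends at the signal end
  expect_equal(st, 1L + as.integer(round(seq(0, 3750, length.out = 10))))
  expect_equal((st[2] - 1) / 500, 7.5 / 9, tolerance = 0.002)  # stride in s
  # union of windows covers the full signal
  covered <- logical(5000)
  for (s0 in st) covered[s0:(s0 + 1249)] <- TRUE
  expect_true(all(covered))
  expect_equal(crop_starts(5000, 1250, 1), 1876L)  # centered
  expect_error(crop_starts(5000, 1250, 0), "at least one")
  cr <- overlapping_crops(matrix(rnorm(24), 2, 12), 3, 4)
  expect_length(cr, 3)
})

test_that("training-set augmentation carries the index label to extra ECGs", {
  co <- generate_cohort(cohort_config(n_patients = 120, seed = 41,
                                      no_ecg_rate = 0,
                                      poor_quality_rate = 0))
  lab <- annotate_cohort(co)
  pairs <- augment_training_set(co, lab)
  per_case <- table(vapply(pairs, `[[`, "", "patient_id"))
  n2 <- vapply(co$cases, function(c) length(c$ecgs), 0L)
  names(n2) <- vapply(co$cases, `[[`, "", "patient_id")
  for (id in names(per_case))
    expect_equal(unname(per_case[id]), unname(n2[id]), ignore_attr = TRUE)
  # extra-ECG rate 0.5 -> pair count about 1.5x the visit count
  expect_lt(abs(length(pairs) / length(unique(names(per_case))) - 1.5), 0.2)
  status <- setNames(lab$status, lab$patient_id)
  for (p in pairs)
    expect_identical(p$label, unname(status[p$patient_id] == "OMI"))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  cfg <- encoder_config(embedding_dim = 5, stem_channels = 4,
                        block_channels = c(5, 6), sampling_rate_hz = 100,
                        crop_seconds = 1)
  w <- omipipe:::init_resnet_weights(cfg, 3)
  X <- array(rnorm(3 * 100 * 4), c(3, 100, 4))
  y <- c(1, 0, 1, 0)
  gr <- omipipe:::resnet_grad_cpp(w, X, y, 2.0)
  loss_fn <- function(w) {
    lg <- omipipe:::resnet_forward_cpp(w, X)$logits
    wts <- ifelse(y == 1, 2, 1)
    mean(wts * (log1p(exp(-abs(lg))) + pmax(lg, 0) - y * lg))
  }
  expect_equal(gr$loss, loss_fn(w), tolerance = 1e-10)
  eps <- 1e-6
  for (j in seq_along(w)) {
    for (k in sample(length(w[[j]]), min(3, length(w[[j]])))) {
      wp <- w; wp[[j]][k] <- wp[[j]][k] + eps
      wm <- w; wm[[j]][k] <- wm[[j]][k] - eps
      num <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
      expect_equal(gr$grads[[j]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("the encoder separates a strong ST effect and not shuffled labels", {
  set.seed(50)
  train <- make_encoder_pairs(120, st_mv = 0.25, noise = 0.01, seed0 = 0)
  tune <- make_encoder_pairs(60, st_mv = 0.25, noise = 0.01, seed0 = 5000)
  model <- train_encoder(train, tune, small_encoder_config(epochs = 8, seed = 5))
  expect_gt(model$tuning_auc, 0.90)

  # label-shuffled null: discrimination collapses to chance
  big_tune <- make_encoder_pairs(300, st_mv = 0.25, noise = 0.01,
                                 seed0 = 9000)
  null_aucs <- vapply(1:3, function(s) {
    set.seed(600 + s)
    shuffled <- train
    perm <- sample(length(shuffled))
    for (i in seq_along(shuffled))
      shuffled[[i]]$label <- train[[perm[i]]]$label
    null_tune <- big_tune
    for (i in seq_along(null_tune))
      null_tune[[i]]$label <- runif(1) < 0.5
    m0 <- train_encoder(shuffled, null_tune,
                        small_encoder_config(epochs = 2, seed = 600 + s))
    m0$tuning_auc
  }, 0)
  expect_gt(median(null_aucs), 0.45)
  expect_lt(median(null_aucs), 0.55)
})

test_that("embeddings are deterministic, crop-robust, and 50-dimensional by default", {
  set.seed(51)
  train <- make_encoder_pairs(60, st_mv = 0.3, noise = 0.01, seed0 = 100)
  tune <- make_encoder_pairs(30, st_mv = 0.3, noise = 0.01, seed0 = 7000)
  cfg <- encoder_config(stem_channels = 8, block_channels = 12, epochs = 2,
                        seed = 9)
  expect_equal(cfg$embedding_dim, 50)
  model <- train_encoder(train, tune, cfg)

  s <- synthesize_ecg(noiseless_params(st_offset_mv = c(II = 0.2)), seed = 77)
  e1 <- embed_ecg(model, s)
  e2 <- embed_ecg(model, s)
  expect_identical(e1, e2)
  expect_length(e1$embedding, 50)

  # a periodic noiseless signal embeds almost identically with 1 or 10 crops
  m1 <- model; m1$config$eval_crops <- 1
  e_single <- embed_ecg(m1, s)
  scale_ref <- stats::sd(e1$embedding)
  expect_lt(max(abs(e1$embedding - e_single$embedding)), 0.25 * scale_ref)

  expect_error(embed_ecg(list(), s), "untrained")
  expect_error(train_encoder(train[1:10][vapply(train[1:10], `[[`, TRUE,
                                                "label")],
                             tune, cfg), "single class")
})
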