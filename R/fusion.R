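# Feature fusion: concatenate feature groups (history, ECG embedding, POC
# labs, initial troponin), fit the preprocessing chain on training rows only
# (Yeo-Johnson for skewed labs, standardization, training-mean imputation),
# and train an L2-regularized logistic model whose strength is chosen on
# tuning-set discrimination.

REGISTRY_FIELDS <- c("discharge_ami", "scaar_aco", "angiography_performed",
                     "hours_to_angiography", "culprit_lesion", "timi_flow",
                     "urgent_pci", "cabg", "max_hs_ctnt_24h_ng_l", "new_rwma",
                     "cardiac_arrest_before_angio", "stemi_ecg_present",
                     "died_30d", "died_180d", "died_1y")

#' Feature-group mask
#'
#' @param history,ecg,poc,troponin logical flags; at least one must be TRUE.
#' @return named logical vector of class `feature_mask`
#' @export
feature_mask <- function(history = TRUE, ecg = FALSE, poc = FALSE,
                         troponin = FALSE) {
  m <- c(history = history, ecg = ecg, poc = poc, troponin = troponin)
  if (!any(m)) stop("at least one feature group must be enabled", call. = FALSE)
  structure(m, class = "feature_mask")
}

#' All 15 non-empty feature-group masks
#'
#' The 5 cumulative masks (history; +ecg; +poc; +troponin variants) used in
#' the headline comparison are flagged in the `cumulative` attribute.
#'
#' @return list of `feature_mask` objects named by their groups
#' @export
all_feature_masks <- function() {
  combos <- expand.grid(history = c(FALSE, TRUE), ecg = c(FALSE, TRUE),
                        poc = c(FALSE, TRUE), troponin = c(FALSE, TRUE))
  combos <- combos[rowSums(combos) > 0, ]
  masks <- lapply(seq_len(nrow(combos)), function(i)
    feature_mask(combos$history[i], combos$ecg[i], combos$poc[i],
                 combos$troponin[i]))
  names(masks) <- vapply(masks, function(m)
    paste(names(m)[m], collapse = "+"), "")
  cumulative <- c("history", "history+ecg", "history+ecg+poc",
                  "history+ecg+troponin", "history+ecg+poc+troponin")
  attr(masks, "cumulative") <- cumulative
  masks
}

#' Build one patient's feature vector
#'
#' Deterministic concatenation in fixed block order (history, ecg, poc,
#' troponin). Missing labs stay `NA` with a companion indicator set to 1;
#' imputation happens later, in the preprocessor. Registry-derived fields
#' are statically rejected.
#'
#' @param case a `patient_case`.
#' @param embedding numeric ECG embedding (required iff `mask["ecg"]`).
#' @param mask a [feature_mask()].
#' @param extra_features optional named numerics appended to the history
#'   block; names colliding with registry outcome fields are rejected.
#' @return named numeric vector with a `block` attribute.
#' @export
build_features <- function(case, embedding = NULL, mask = feature_mask(),
                           extra_features = NULL) {
  if (mask[["ecg"]] && is.null(embedding))
    stop("mask requests the ecg block but no embedding was given",
         call. = FALSE)
  if (!is.null(extra_features)) {
    bad <- intersect(names(extra_features), REGISTRY_FIELDS)
    if (length(bad))
      stop("registry-derived fields are not allowed in features: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  vec <- numeric(0); block <- character(0)
  if (mask[["history"]]) {
    h <- c(age = case$age, sex_male = as.numeric(case$sex == "male"),
           as.numeric(case$history_flags), as.numeric(case$medication_flags))
    names(h) <- c("age", "sex_male", names(case$history_flags),
                  names(case$medication_flags))
    h <- c(h, extra_features)
    vec <- c(vec, h); block <- c(block, rep("history", length(h)))
  }
  if (mask[["ecg"]]) {
    e <- as.numeric(embedding)
    names(e) <- sprintf("ecg_%02d", seq_along(e))
    vec <- c(vec, e); block <- c(block, rep("ecg", length(e)))
  }
  if (mask[["poc"]]) {
    p <- case$poc_labs
    ind <- as.numeric(is.na(p))
    names(ind) <- paste0("miss_", names(p))
    vec <- c(vec, p, ind); block <- c(block, rep("poc", length(p) + length(ind)))
  }
  if (mask[["troponin"]]) {
    tr <- c(hs_ctnt_initial = case$hs_ctnt_initial_ng_l,
            miss_hs_ctnt = as.numeric(is.na(case$hs_ctnt_initial_ng_l)))
    vec <- c(vec, tr); block <- c(block, rep("troponin", length(tr)))
  }
  attr(vec, "block") <- block
  vec
}

#' Build the feature matrix for a whole cohort
#'
#' @param cohort an `omi_cohort`.
#' @param embeddings optional matrix (cases x embedding dim), rownames =
#'   patient ids.
#' @param mask a [feature_mask()].
#' @return numeric matrix (cases x features) with `block` attribute and
#'   patient ids as rownames.
#' @export
build_feature_matrix <- function(cohort, embeddings = NULL,
                                 mask = feature_mask()) {
  rows <- lapply(cohort$cases, function(cs) {
    emb <- if (mask[["ecg"]]) embeddings[cs$patient_id, ] else NULL
    build_features(cs, emb, mask)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort$cases, `[[`, "", "patient_id")
  attr(X, "block") <- attr(rows[[1]], "block")
  X
}

yj_transform <- function(x, lambda) {
  out <- x
  pos <- !is.na(x) & x >= 0
  if (abs(lambda) < 1e-8) out[pos] <- log1p(x[pos])
  else out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  neg <- !is.na(x) & x < 0
  if (abs(lambda - 2) < 1e-8) out[neg] <- -log1p(-x[neg])
  else out[neg] <- -((1 - x[neg])^(2 - lambda) - 1) / (2 - lambda)
  out
}

estimate_yj_lambda <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || sd(x) == 0) return(1)
  tryCatch(as.numeric(car::powerTransform(x, family = "yjPower")$lambda),
           error = function(e) 1)
}

#' Fit the preprocessing chain on training rows
#'
#' hs-cTnT and POC lab values get a maximum-likelihood Yeo-Johnson power
#' transform before standardization; every other scalar is standardized to
#' zero mean, unit variance. Missing values are imputed with the training
#' mean of the transformed feature. All statistics come from the training
#' rows alone, to prevent leakage into tuning/validation.
#'
#' @param X_train training feature matrix from [build_feature_matrix()].
#' @return a `preprocessor` with per-feature transform specs.
#' @export
fit_preprocessor <- function(X_train) {
  if (nrow(X_train) < 2) stop("need at least 2 training rows", call. = FALSE)
  block <- attr(X_train, "block")
  yj_cols <- colnames(X_train) %in%
    c("hemoglobin", "creatinine", "glucose", "hs_ctnt_initial")
  spec <- vector("list", ncol(X_train))
  names(spec) <- colnames(X_train)
  for (j in seq_len(ncol(X_train))) {
    x <- X_train[, j]
    lambda <- if (yj_cols[j]) estimate_yj_lambda(x) else NA_real_
    t <- if (yj_cols[j]) yj_transform(x, lambda) else x
    mu <- mean(t, na.rm = TRUE); s <- sd(t, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("zero-variance feature '", colnames(X_train)[j],
              "'; passing through", call. = FALSE)
      spec[[j]] <- list(type = "passthrough", lambda = lambda,
                        mean = if (is.na(mu)) 0 else mu, sd = 1)
    } else {
      spec[[j]] <- list(type = if (yj_cols[j]) "yeo-johnson" else "standardize",
                        lambda = lambda, mean = mu, sd = s)
    }
  }
  structure(list(spec = spec, block = block, n_train = nrow(X_train)),
            class = "preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param prep a `preprocessor`.
#' @param X feature matrix with the same columns as the training matrix.
#' @return transformed matrix, no missing values.
#' @export
apply_preprocessor <- function(prep, X) {
  if (!identical(colnames(X), names(prep$spec)))
    stop("feature columns do not match the fitted preprocessor",
         call. = FALSE)
  out <- X
  for (j in seq_len(ncol(X))) {
    sp <- prep$spec[[j]]
    t <- if (sp$type == "yeo-johnson") yj_transform(X[, j], sp$lambda)
         else X[, j]
    t <- (t - sp$mean) / sp$sd
    t[is.na(t)] <- 0   # training-mean imputation on the transformed scale
    out[, j] <- t
  }
  attr(out, "block") <- prep$block
  out
}

#' Fit the fused logistic risk model
#'
#' L2-regularized logistic regression over the preprocessed feature blocks;
#' the penalty strength is selected on tuning-set AUC over a log-spaced
#' grid.
#'
#' @param X_train,y_train preprocessed training features and outcomes.
#' @param X_tune,y_tune tuning data for penalty selection.
#' @param mask the [feature_mask()] the features were built with.
#' @param lambda_grid decreasing penalty grid.
#' @return a `fusion_model`: coefficients, intercept, chosen penalty,
#'   tuning AUC, preprocessor slot (set by [train_fusion()]).
#' @export
fit_classifier <- function(X_train, y_train, X_tune, y_tune,
                           mask = feature_mask(),
                           lambda_grid = 10^seq(2, -4, length.out = 25)) {
  y_train <- as.logical(y_train)
  if (length(unique(y_train)) < 2)
    stop("training data contain a single class", call. = FALSE)
  padded <- ncol(X_train) == 1   # glmnet needs >= 2 columns
  if (padded) {
    X_train <- cbind(X_train, .pad = 0)
    X_tune <- cbind(X_tune, .pad = 0)
  }
  fit <- glmnet::glmnet(X_train, factor(y_train, c(FALSE, TRUE)),
                        family = "binomial", alpha = 0,
                        lambda = lambda_grid, standardize = FALSE)
  pr <- predict(fit, newx = X_tune, type = "response")
  aucs <- apply(pr, 2, function(p) roc_auc(p, y_tune))
  best <- which.max(aucs)
  beta <- as.numeric(fit$beta[, best])
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[names(beta) != ".pad"]
  structure(list(mask = mask, coefficients = beta,
                 intercept = as.numeric(fit$a0[best]),
                 lambda = fit$lambda[best], tuning_auc = max(aucs),
                 preprocessor = NULL),
            class = "fusion_model")
}

#' Predict OMI risk
#'
#' @param model a `fusion_model`.
#' @param X preprocessed feature matrix (or single named vector).
#' @return probabilities in (0, 1).
#' @export
predict_risk <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  if (ncol(X) != length(model$coefficients))
    stop("feature dimension does not match the model", call. = FALSE)
  as.numeric(stats::plogis(model$intercept + X %*% model$coefficients))
}

#' Fit preprocessor + classifier for one mask
#'
#' @param cohort an `omi_cohort`.
#' @param labels annotation data frame (status column); OMI is the positive
#'   class, EXCLUDED/NEEDS_REVIEW patients are dropped.
#' @param split data frame from [stratified_split()].
#' @param embeddings embedding matrix (needed iff the mask has ecg).
#' @param mask a [feature_mask()].
#' @return a `fusion_model` with its fitted `preprocessor` attached, plus
#'   `scores` (named risk for every modeled patient) in `$scores`.
#' @export
train_fusion <- function(cohort, labels, split, embeddings = NULL,
                         mask = feature_mask()) {
  keep <- labels$status %in% c("OMI", "NOMI", "NO_AMI")
  sub <- cohort; sub$cases <- cohort$cases[keep]
  y <- labels$status[keep] == "OMI"
  ids <- labels$patient_id[keep]
  X <- build_feature_matrix(sub, embeddings, mask)
  sp <- split$split[match(ids, split$id)]
  prep <- fit_preprocessor(X[sp == "train", , drop = FALSE])
  Xt <- apply_preprocessor(prep, X)
  model <- fit_classifier(Xt[sp == "train", , drop = FALSE], y[sp == "train"],
                          Xt[sp == "tune", , drop = FALSE], y[sp == "tune"],
                          mask)
  model$preprocessor <- prep
  model$scores <- stats::setNames(predict_risk(model, Xt), ids)
  model$split <- stats::setNames(sp, ids)
  model$labels <- stats::setNames(y, ids)
  model
}

#' Ablation over feature-group combinations
#'
#' Fits one model per mask and reports validation metrics at a threshold
#' matched to `target_specificity` on the tuning set.
#'
#' @param cohort,labels,split,embeddings as in [train_fusion()].
#' @param masks list of masks (default [all_feature_masks()]).
#' @param target_specificity matched operating point (e.g. the STEMI rule's
#'   tuning specificity).
#' @param n_bootstrap bootstrap resamples for the CIs.
#' @param seed integer seed for the bootstrap.
#' @return data frame, one row per mask: tuning AUC, validation AUC,
#'   sensitivity/specificity/ppv/npv at the matched threshold, and a
#'   `cumulative` flag.
#' @export
ablation_grid <- function(cohort, labels, split, embeddings = NULL,
                          masks = all_feature_masks(),
                          target_specificity = 0.974,
                          n_bootstrap = 200, seed = 1L) {
  cum <- attr(masks, "cumulative") %||% character(0)
  rows <- lapply(names(masks), function(nm) {
    model <- train_fusion(cohort, labels, split, embeddings, masks[[nm]])
    sc <- model$scores; sp <- model$split; y <- model$labels
    thr <- match_specificity_threshold(sc[sp == "tune"], y[sp == "tune"],
                                       target_specificity)$threshold
    vy <- y[sp == "validate"]; vs <- sc[sp == "validate"]
    cm <- confusion_metrics(vs >= thr, vy)
    data.frame(mask = nm, cumulative = nm %in% cum,
               tuning_auc = model$tuning_auc,
               validation_auc = roc_auc(vs, vy),
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               ppv = cm$ppv, npv = cm$npv, threshold = thr)
  })
  do.call(rbind, rows)
}
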