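#' Features of a chip for the baseline block classifier
#'
#' A compact, interpretable summary of a block image: overall vegetation
#' fraction, per-channel intensity mean and standard deviation, and the
#' vegetation fraction in each 2 x 2 spatial quadrant (which separates a
#' stand centred in the block from a green sliver at its edge).  Eleven
#' features in total.
#'
#' @param chip a chip (list with `pixels`) or an h x w x 3 array.
#' @param thr a [green_thresholds()].
#' @return named numeric feature vector.
#' @export
chip_features <- function(chip, thr = green_thresholds()) {
  px <- if (is.list(chip)) chip$pixels else chip
  d <- dim(px)
  g <- green_mask(cs_raster(px, gsd = 1), thr)$values
  h2 <- max(1L, floor(d[1] / 2)); w2 <- max(1L, floor(d[2] / 2))
  q <- c(mean(g[1:h2, 1:w2]),
         mean(g[1:h2, (w2 + 1):d[2]]),
         mean(g[(h2 + 1):d[1], 1:w2]),
         mean(g[(h2 + 1):d[1], (w2 + 1):d[2]]))
  means <- vapply(1:3, function(ch) mean(px[, , ch]), numeric(1)) / 255
  sds <- vapply(1:3, function(ch) sd(as.vector(px[, , ch])), numeric(1)) / 255
  c(green_frac = mean(g),
    mean_r = means[1], mean_g = means[2], mean_b = means[3],
    sd_r = sds[1], sd_g = sds[2], sd_b = sds[3],
    q_tl = q[1], q_tr = q[2], q_bl = q[3], q_br = q[4])
}

chip_feature_matrix <- function(chips, thr = green_thresholds()) {
  t(vapply(chips, chip_features, numeric(11), thr = thr))
}

#' Fit the baseline corn/non-corn block classifier
#'
#' A ridge-regularised logistic regression on [chip_features()], fitted
#' with a deterministic optimiser (\pkg{glmnet} at a single fixed, small
#' penalty).  The training set is enlarged with `n_aug` seeded random
#' augmentations of every chip ([augment_chip()]: rotation, zoom,
#' horizontal flips).  Augmentation is what makes the fit transfer across
#' fields: block labels are nearly separable by greenness alone, and
#' without it the optimiser inflates weights onto incidental,
#' field-constant statistics — most notably *where inside the block* the
#' green sits, which is constant within one field because the row spacing
#' is an exact multiple of the across-row block pitch, and which reverses
#' on a field with a different row phase.  This is the built-in classifier
#' behind the uniform model contract; heavier backbones plug in through
#' the same fit/predict signatures (see [predict_proba()]).
#'
#' @param train,val chip lists; validation may be empty.
#' @param seed training seed; drives the augmentation draws (the
#'   optimiser itself is deterministic).
#' @param input_size chips are resized to this `c(h, w)` before feature
#'   extraction.
#' @param lambda ridge penalty.
#' @param n_aug augmented copies of each training chip (0 disables).
#' @param augment an [augment_spec()] for the copies.
#' @param thr a [green_thresholds()] used for the vegetation features.
#' @return list with `model` (class `cs_classifier`) and `report` (train
#'   and, when a validation set is given, validation accuracy and log
#'   loss).
#' @export
fit_baseline <- function(train, val = list(), seed = 1L,
                         input_size = c(16L, 16L), lambda = 1e-4,
                         n_aug = 4L, augment = augment_spec(),
                         thr = green_thresholds()) {
  labs <- vapply(train, `[[`, character(1), "label")
  if (length(unique(labs)) < 2) stop("training set must contain both classes")
  pool <- train
  if (n_aug > 0)
    pool <- c(pool, with_seed(seed, {
      unlist(lapply(seq_len(n_aug), function(k)
        lapply(train, augment_chip, spec = augment)), recursive = FALSE)
    }))
  rs <- function(chs) lapply(chs, resize_chip, target = input_size)
  X <- chip_feature_matrix(rs(pool), thr)
  y <- as.integer(rep(labs, n_aug + 1L) == "corn")
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  model <- structure(list(kind = "baseline", input_size = input_size,
                          fit = fit, lambda = lambda, thr = thr,
                          train_seed = seed),
                     class = "cs_classifier")
  y0 <- as.integer(labs == "corn")
  p_tr <- predict_proba(model, train)
  report <- list(
    train_accuracy = mean((p_tr >= 0.5) == (y0 == 1)),
    train_logloss = logloss(y0, p_tr))
  if (length(val)) {
    yv <- as.integer(vapply(val, `[[`, character(1), "label") == "corn")
    p_v <- predict_proba(model, val)
    report$val_accuracy <- mean((p_v >= 0.5) == (yv == 1))
    report$val_logloss <- logloss(yv, p_v)
  }
  list(model = model, report = report)
}

logloss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Corn probabilities for a list of chips
#'
#' @param model a fitted `cs_classifier` from [fit_baseline()].
#' @param chips list of chips (any native size; resized internally to the
#'   model input size).
#' @return numeric vector of corn probabilities in `[0, 1]`, one per chip,
#'   input order preserved.
#' @export
predict_proba <- function(model, chips) {
  stopifnot(inherits(model, "cs_classifier"))
  if (!length(chips)) return(numeric(0))
  chs <- lapply(chips, resize_chip, target = model$input_size)
  X <- chip_feature_matrix(chs, model$thr)
  as.numeric(predict(model$fit, newx = X, type = "response"))
}

#' Multi-seed training protocol
#'
#' Trains one model version per seed to assess how sensitive performance
#' is to the random selection of training data: for each seed the labelled
#' pool is balanced by undersampling, split 70/30 into training and
#' validation, fitted, and scored.  When held-out test chips with labels
#' are supplied, block-level precision/recall/F1 on them is reported per
#' version.
#'
#' @param chips labelled chip pool (e.g. from [extract_chips()]).
#' @param seeds integer vector of seeds (default five).
#' @param test_chips optional held-out labelled chips.
#' @param train_fraction training share of the balanced pool.
#' @param ... passed to [fit_baseline()].
#' @return list with `models` (per-seed classifiers) and `metrics` (one
#'   data frame row per seed: accuracies plus, with test chips, `precision`,
#'   `recall`, `f1`).
#' @export
run_seed_protocol <- function(chips, seeds = 1:5, test_chips = NULL,
                              train_fraction = 0.7, ...) {
  rows <- list(); models <- list()
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    bal <- undersample_balance(chips, seed = s)
    sp <- split_train_val(bal, train_fraction = train_fraction, seed = s)
    fb <- fit_baseline(sp$train, sp$val, seed = s, ...)
    row <- data.frame(seed = s,
                      train_accuracy = fb$report$train_accuracy,
                      val_accuracy = fb$report$val_accuracy)
    if (!is.null(test_chips)) {
      p <- predict_proba(fb$model, test_chips)
      pred <- ifelse(p >= 0.5, "corn", "non_corn")
      truth <- vapply(test_chips, `[[`, character(1), "label")
      cc <- confusion_counts(pred, truth)
      prf <- precision_recall_f1(cc)
      row$precision <- prf[["precision"]]
      row$recall <- prf[["recall"]]
      row$f1 <- prf[["f1"]]
    }
    rows[[i]] <- row
    models[[i]] <- fb$model
  }
  list(models = models, metrics = do.call(rbind, rows))
}
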