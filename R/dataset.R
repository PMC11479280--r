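#' Extract image chips for labelled blocks
#'
#' Crops the pixels of each block rectangle out of the rotated raster.
#' Chips are stored at their native resolution; resizing to a classifier's
#' input size happens at load time with [resize_chip()], so one annotation
#' run serves any model.
#'
#' @param raster_rot the rotated-frame [cs_raster()] (e.g.
#'   `annotate_field()$raster_rot`).
#' @param blocks labelled block data frame from [annotate_field()].
#' @return list of chips; each chip is a list with `pixels` (h x w x 3),
#'   `label`, `chip_id` and `rect` (named numeric `x0, y0, x1, y1`).
#' @export
extract_chips <- function(raster_rot, blocks) {
  d <- dim(raster_rot$pixels)
  gsd <- raster_rot$gsd
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    idx <- rect_pixels(b, d, gsd)
    out[[i]] <- list(
      pixels = raster_rot$pixels[idx$rows, idx$cols, , drop = FALSE],
      label = b$label, chip_id = i,
      rect = c(x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1))
  }
  out
}

#' Resize a chip by area-weighted box filtering
#'
#' Each output pixel is the mean of the source pixels it covers, weighting
#' partially covered source pixels by their covered fraction (the standard
#' "area" resampling used when shrinking imagery).  Per-channel mean
#' intensity is preserved exactly before rounding; final intensities are
#' rounded half-up to integers.
#'
#' @param chip a chip (list with a `pixels` array) or a bare h x w x 3
#'   array / h x w matrix.
#' @param target integer `c(h, w)` output size.
#' @return same type as the input, resized.
#' @export
resize_chip <- function(chip, target) {
  stopifnot(length(target) == 2, all(target >= 1))
  bare <- !is.list(chip)
  px <- if (bare) chip else chip$pixels
  was_mat <- is.matrix(px)
  if (was_mat) px <- array(px, c(dim(px), 1L))
  d <- dim(px)
  if (d[1] == 0 || d[2] == 0) stop("zero-size source chip")
  Wr <- box_weights(d[1], target[1])
  Wc <- box_weights(d[2], target[2])
  out <- array(0, c(target[1], target[2], d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- Wr %*% px[, , ch] %*% t(Wc)
  out <- floor(out + 0.5)
  if (was_mat) out <- matrix(out, target[1], target[2])
  if (bare) out else { chip$pixels <- out; chip }
}

## n_out x n_in row-stochastic matrix of fractional interval overlaps
box_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale; b <- i * scale
    j0 <- floor(a); j1 <- min(ceiling(b), n_in)
    for (j in seq.int(j0, j1 - 1)) {
      W[i, j + 1] <- min(b, j + 1) - max(a, j)
    }
  }
  W / scale
}

#' Balance classes by random undersampling
#'
#' Reduces the majority class to a uniformly random (seeded) subset the
#' size of the minority class; the minority class is untouched.  The
#' result is deterministically shuffled.
#'
#' @param chips list of chips with `label` fields.
#' @param seed RNG seed.
#' @return balanced list of chips (a subset of the input).
#' @export
undersample_balance <- function(chips, seed = 1L) {
  labs <- vapply(chips, `[[`, character(1), "label")
  tab <- table(labs)
  if (length(tab) < 2 || any(tab == 0))
    stop("undersampling needs both classes present")
  n_min <- min(tab)
  with_seed(seed, {
    keep <- unlist(lapply(names(tab), function(cl) {
      idx <- which(labs == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
    chips[sample(keep)]
  })
}

#' Split chips into training and validation sets
#'
#' Seeded shuffle followed by a split; stratified per class by default,
#' with `floor(n * train_fraction)` training chips per class and the
#' remainder in validation.
#'
#' @param chips list of chips.
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed RNG seed.
#' @param stratified split within each class separately.
#' @return list with `train` and `val` chip lists.
#' @export
split_train_val <- function(chips, train_fraction = 0.7, seed = 1L,
                            stratified = TRUE) {
  if (!length(chips)) stop("no chips to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  labs <- vapply(chips, `[[`, character(1), "label")
  with_seed(seed, {
    tr_idx <- integer(0)
    groups <- if (stratified) split(seq_along(chips), labs)
              else list(seq_along(chips))
    for (idx in groups) {
      idx <- sample(idx)
      tr_idx <- c(tr_idx, idx[seq_len(floor(length(idx) * train_fraction))])
    }
    list(train = chips[sort(tr_idx)],
         val = chips[sort(setdiff(seq_along(chips), tr_idx))])
  })
}

#' Augmentation settings
#'
#' The transform families used to enlarge the training set: small random
#' rotations, zooms, and horizontal flips.  Magnitudes are configurable;
#' the defaults are mild, as chips are small and labels must survive.
#'
#' @param rotation_deg maximum absolute rotation, degrees.
#' @param zoom_range `c(lo, hi)` multiplicative zoom bounds.
#' @param hflip_prob probability of a horizontal flip.
#' @return list of class `augment_spec`.
#' @export
augment_spec <- function(rotation_deg = 20, zoom_range = c(0.9, 1.1),
                         hflip_prob = 0.5) {
  stopifnot(rotation_deg >= 0, all(zoom_range > 0),
            zoom_range[1] <= zoom_range[2],
            hflip_prob >= 0, hflip_prob <= 1)
  structure(list(rotation_deg = rotation_deg, zoom_range = zoom_range,
                 hflip_prob = hflip_prob), class = "augment_spec")
}

#' Randomly augment a chip
#'
#' Applies, in order: a random rotation within `rotation_deg` (about the
#' chip centre, cropped back to the original size), a random zoom within
#' `zoom_range` (centre crop or zero-pad back to size), and a horizontal
#' flip with probability `hflip_prob`.  The label is unchanged.  Uses the
#' current RNG stream; wrap in a seeded context for reproducibility.
#'
#' @param chip a chip (list with `pixels`).
#' @param spec an [augment_spec()].
#' @return the augmented chip.
#' @export
augment_chip <- function(chip, spec = augment_spec()) {
  px <- chip$pixels
  d <- dim(px)
  if (spec$rotation_deg > 0) {
    ang <- runif(1, -spec$rotation_deg, spec$rotation_deg)
    img <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
    rot <- EBImage::rotate(img, ang, filter = "bilinear", bg.col = 0)
    rpx <- aperm(EBImage::imageData(rot), c(2, 1, 3))
    px <- center_crop_pad(rpx, d[1:2])
  }
  if (spec$zoom_range[1] != 1 || spec$zoom_range[2] != 1) {
    z <- runif(1, spec$zoom_range[1], spec$zoom_range[2])
    nh <- max(1L, round(d[1] * z)); nw <- max(1L, round(d[2] * z))
    px <- center_crop_pad(resize_chip(px, c(nh, nw)), d[1:2])
  }
  if (spec$hflip_prob > 0 && runif(1) < spec$hflip_prob)
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  px[px < 0] <- 0L; px[px > 255] <- 255L
  chip$pixels <- px
  chip
}

center_crop_pad <- function(px, target) {
  d <- dim(px)
  out <- array(0, c(target, d[3]))
  ro <- max(0, floor((target[1] - d[1]) / 2))
  co <- max(0, floor((target[2] - d[2]) / 2))
  ri <- max(0, floor((d[1] - target[1]) / 2))
  ci <- max(0, floor((d[2] - target[2]) / 2))
  nr <- min(d[1], target[1]); nc <- min(d[2], target[2])
  out[ro + seq_len(nr), co + seq_len(nc), ] <-
    px[ri + seq_len(nr), ci + seq_len(nc), , drop = FALSE]
  out
}

#' Write a chip manifest
#'
#' Writes each chip as a PNG plus a `labels.csv` manifest with columns
#' `chip_id, path, label, x0, y0, x1, y1, green_fraction`.
#'
#' @param chips chip list from [extract_chips()].
#' @param blocks the labelled block data frame the chips came from.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_chip_manifest <- function(chips, blocks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(chips))
  for (i in seq_along(chips)) {
    paths[i] <- file.path(dir, sprintf("chip_%05d.png", chips[[i]]$chip_id))
    png::writePNG(chips[[i]]$pixels / 255, paths[i])
  }
  man <- data.frame(chip_id = vapply(chips, `[[`, numeric(1), "chip_id"),
                    path = paths,
                    label = vapply(chips, `[[`, character(1), "label"),
                    blocks[, c("x0", "y0", "x1", "y1", "green_fraction")])
  write.csv(man, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(file.path(dir, "labels.csv"))
}
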