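# Independent oracles kept deliberately naive: per-pixel inverse affine
# mapping for rotation, and exhaustive pairwise greedy suppression.

# Rotate an H x W matrix (one channel) clockwise about its centre onto the
# minimal expanded canvas, sampling the input by inverse mapping.
oracle_rotate_channel <- function(ch, theta_deg, interp = "bilinear") {
  h <- nrow(ch); w <- ncol(ch)
  t <- theta_deg * pi / 180
  ho <- ceiling(w * abs(sin(t)) + h * abs(cos(t)) - 1e-9)
  wo <- ceiling(w * abs(cos(t)) + h * abs(sin(t)) - 1e-9)
  out <- matrix(0, ho, wo)
  for (r in seq_len(ho)) {
    for (cc in seq_len(wo)) {
      dx <- (cc - 0.5) - wo / 2
      dy <- (r - 0.5) - ho / 2
      x <- cos(t) * dx + sin(t) * dy + w / 2   # inverse of clockwise rot
      y <- -sin(t) * dx + cos(t) * dy + h / 2
      ci <- x - 0.5; ri <- y - 0.5             # 0-based source pixel coords
      if (interp == "nearest") {
        rn <- round(ri); cn <- round(ci)
        if (rn >= 0 && rn < h && cn >= 0 && cn < w)
          out[r, cc] <- ch[rn + 1, cn + 1]
      } else {
        r0 <- floor(ri); c0 <- floor(ci)
        fr <- ri - r0; fc <- ci - c0
        acc <- 0
        for (dr in 0:1) for (dc in 0:1) {
          rr <- r0 + dr; c2 <- c0 + dc
          v <- if (rr >= 0 && rr < h && c2 >= 0 && c2 < w) ch[rr + 1, c2 + 1] else 0
          wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
          acc <- acc + wgt * v
        }
        out[r, cc] <- acc
      }
    }
  }
  out
}

# Validity of output pixels under the same mapping (source centre in bounds).
oracle_rotate_validity <- function(h, w, theta_deg) {
  t <- theta_deg * pi / 180
  ho <- ceiling(w * abs(sin(t)) + h * abs(cos(t)) - 1e-9)
  wo <- ceiling(w * abs(cos(t)) + h * abs(sin(t)) - 1e-9)
  val <- matrix(FALSE, ho, wo)
  for (r in seq_len(ho)) for (cc in seq_len(wo)) {
    dx <- (cc - 0.5) - wo / 2; dy <- (r - 0.5) - ho / 2
    x <- cos(t) * dx + sin(t) * dy + w / 2
    y <- -sin(t) * dx + cos(t) * dy + h / 2
    rn <- round(y - 0.5); cn <- round(x - 0.5)
    val[r, cc] <- rn >= 0 && rn < h && cn >= 0 && cn < w
  }
  val
}

# Exhaustive greedy suppression oracle: same ordering rule, all pairs
# checked against already-kept expanded rects.
oracle_nms <- function(preds, expand_frac = 0.25, iou_threshold = 0.1) {
  w <- (preds$x1 - preds$x0) * expand_frac / 2
  h <- (preds$y1 - preds$y0) * expand_frac / 2
  ex <- data.frame(x0 = preds$x0 - w, y0 = preds$y0 - h,
                   x1 = preds$x1 + w, y1 = preds$y1 + h)
  pair_iou <- function(i, j) {
    iw <- min(ex$x1[i], ex$x1[j]) - max(ex$x0[i], ex$x0[j])
    ih <- min(ex$y1[i], ex$y1[j]) - max(ex$y0[i], ex$y0[j])
    if (iw <= 0 || ih <= 0) return(0)
    ai <- (ex$x1[i] - ex$x0[i]) * (ex$y1[i] - ex$y0[i])
    aj <- (ex$x1[j] - ex$x0[j]) * (ex$y1[j] - ex$y0[j])
    iw * ih / (ai + aj - iw * ih)
  }
  ord <- order(-preds$probability, preds$y0, preds$x0)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) if (pair_iou(i, k) > iou_threshold) { ok <- FALSE; break }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

random_preds <- function(n, grid = FALSE) {
  if (grid) {
    ix <- sample(0:6, n, replace = TRUE); iy <- sample(0:6, n, replace = TRUE)
    data.frame(x0 = ix * 0.2, y0 = iy * 0.25,
               x1 = ix * 0.2 + 0.2, y1 = iy * 0.25 + 0.25,
               probability = round(runif(n), 3))
  } else {
    x0 <- runif(n, 0, 2); y0 <- runif(n, 0, 2)
    data.frame(x0 = x0, y0 = y0,
               x1 = x0 + runif(n, 0.1, 0.5), y1 = y0 + runif(n, 0.1, 0.5),
               probability = round(runif(n), 3))
  }
}

# A small field used by several test files (cached per session).
small_field <- local({
  cache <- list()
  function(seed = 1, ...) {
    key <- paste(seed, paste(deparse(substitute(list(...))), collapse = ""))
    if (is.null(cache[[key]])) {
      cfg <- field_config(width_m = 6, height_m = 6, seed = seed, ...)
      cache[[key]] <<- list(cfg = cfg, field = generate_field(cfg))
    }
    cache[[key]]
  }
})

solid_raster <- function(h, w, rgb = c(0, 255, 0), gsd = 0.015) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  cs_raster(px, gsd)
}

# Erode a logical mask by one pixel (4-neighbourhood); used to compare
# resampling away from the footprint boundary, where out-of-bounds
# neighbour handling is implementation-defined.
erode1 <- function(m) {
  e <- m
  e[-1, ] <- e[-1, ] & m[-nrow(m), ]
  e[-nrow(m), ] <- e[-nrow(m), ] & m[-1, ]
  e[, -1] <- e[, -1] & m[, -ncol(m)]
  e[, -ncol(m)] <- e[, -ncol(m)] & m[, -1]
  e
}
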