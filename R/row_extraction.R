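#' Vegetation (green) HSV thresholds
#'
#' Lower/upper bounds of the vegetation colour box in HSV space with hue on
#' the half-degree scale `[0, 180]` (the OpenCV 8-bit convention) and
#' saturation/value in `[0, 255]`.  The defaults `(36, 25, 25)` and
#' `(70, 255, 255)` select hues between 72 and 140 degrees -- the green
#' band -- with at least minimal saturation and brightness, which isolates
#' young corn foliage from bare soil and residue.
#'
#' @param lo,hi length-3 numeric vectors `(h, s, v)`.
#' @return a list of class `green_thresholds`.
#' @export
green_thresholds <- function(lo = c(36, 25, 25), hi = c(70, 255, 255)) {
  stopifnot(length(lo) == 3, length(hi) == 3, all(lo <= hi),
            lo[1] >= 0, hi[1] <= 180)
  structure(list(lo = lo, hi = hi), class = "green_thresholds")
}

#' Vegetation mask of an RGB raster
#'
#' Marks pixels whose colour falls inside the HSV vegetation box.  HSV is
#' computed with the standard RGB-to-HSV transform; hue is halved onto
#' `[0, 180]` and saturation/value scaled to `[0, 255]` before comparing
#' componentwise against the thresholds (inclusive on both ends).
#'
#' @param raster a 3-channel [cs_raster()].
#' @param thr a [green_thresholds()].
#' @return a [cs_mask()] in the raster's frame.
#' @export
green_mask <- function(raster, thr = green_thresholds()) {
  if (!inherits(raster, "cs_raster") || dim(raster$pixels)[3] != 3L)
    stop("green_mask needs a 3-channel RGB raster")
  d <- dim(raster$pixels)
  rgb <- rbind(as.vector(raster$pixels[, , 1]),
               as.vector(raster$pixels[, , 2]),
               as.vector(raster$pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  h <- hsv[1, ] * 180          # fraction of 360 deg -> half-degree scale
  s <- hsv[2, ] * 255
  v <- hsv[3, ] * 255
  ok <- h >= thr$lo[1] & h <= thr$hi[1] &
        s >= thr$lo[2] & s <= thr$hi[2] &
        v >= thr$lo[3] & v <= thr$hi[3]
  m <- matrix(ok, d[1], d[2])
  if (!is.null(raster$validity)) m <- m & raster$validity
  cs_mask(m, frame = raster$frame)
}

#' Estimate crop-row orientation from a vegetation mask
#'
#' Searches for the rotation angle that makes the rows horizontal, by
#' maximising the variance of per-pixel-row true counts of the rotated
#' mask (a spiky projection profile means rows are aligned with the scan
#' lines).  Only the central window (central 50% in both dimensions) is
#' used, matching the assumption that rows are straightest near the field
#' centre.  A coarse grid is scanned first, then a fine grid around the
#' best coarse angle; ties break toward the smaller `|theta|`.
#'
#' The returned angle is the *correction*: rotating the raster by it (see
#' [rotate_raster()]) aligns the rows horizontally, so a field whose rows
#' run at +7 degrees yields approximately -7.
#'
#' @param mask a [cs_mask()] from [green_mask()].
#' @param search_deg half-width of the search range in degrees.
#' @param coarse,fine grid steps in degrees.
#' @return the correction angle in degrees.
#' @export
estimate_row_orientation <- function(mask, search_deg = 45,
                                     coarse = 1.0, fine = 0.1) {
  stopifnot(inherits(mask, "cs_mask"))
  d <- dim(mask$values)
  r0 <- floor(d[1] / 4); r1 <- ceiling(3 * d[1] / 4)
  c0 <- floor(d[2] / 4); c1 <- ceiling(3 * d[2] / 4)
  win <- mask$values[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  pts <- which(win, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("no vegetation found in the central window")
  ## pixel centres relative to the window centre
  y <- pts[, 1] - 0.5 - nrow(win) / 2
  x <- pts[, 2] - 0.5 - ncol(win) / 2

  score <- function(theta) {
    t <- theta * pi / 180
    ## row coordinate after rotating the mask by theta (clockwise, y down)
    yr <- sin(t) * x + cos(t) * y
    bins <- floor(yr - min(yr)) + 1L
    counts <- tabulate(bins, nbins = max(bins))
    if (length(counts) < 2) return(0)
    var(counts)
  }
  pick <- function(grid) {
    sc <- vapply(grid, score, numeric(1))
    best <- max(sc)
    cand <- grid[sc >= best - 1e-9]
    cand[which.min(abs(cand))]
  }
  b <- pick(seq(-search_deg, search_deg, by = coarse))
  pick(seq(b - coarse + fine, b + coarse - fine, by = fine))
}

#' Partition a rows-horizontal mask into one-row strips
#'
#' In the default `peaks` mode the per-pixel-row true-count profile is
#' smoothed with a moving mean of width `0.2 * spacing_px`, local maxima at
#' least `0.7 * spacing_px` apart are taken as row centres, and strip
#' boundaries are placed midway between consecutive peaks (clamped to
#' `0.75 * spacing_px` from each peak and to the field edges, so every
#' strip holds exactly one peak and is at most `1.5 * spacing_px` tall).
#' `uniform` mode simply tiles consecutive intervals of one row spacing
#' from pixel row 0, discarding a trailing partial strip.
#'
#' @param mask a [cs_mask()] in the rotated (rows-horizontal) frame.
#' @param row_spacing_m nominal distance between rows, metres.
#' @param gsd metres per pixel.
#' @param mode `"peaks"` (default) or `"uniform"`.
#' @return list of class `strip_set`: `strips` (data frame `r0, r1`,
#'   half-open pixel-row intervals) and `spacing_px`.
#' @export
partition_strips <- function(mask, row_spacing_m, gsd,
                             mode = c("peaks", "uniform")) {
  stopifnot(inherits(mask, "cs_mask"))
  mode <- match.arg(mode)
  H <- nrow(mask$values)
  sp <- row_spacing_m / gsd
  if (mode == "uniform") {
    bounds <- round(seq(0, H + 0.5 * sp, by = sp))
    bounds <- bounds[bounds <= H]
    if (length(bounds) < 2) stop("no full strip fits the mask")
    strips <- data.frame(r0 = bounds[-length(bounds)], r1 = bounds[-1])
    return(structure(list(strips = strips, spacing_px = sp),
                     class = "strip_set"))
  }
  prof <- rowSums(mask$values)
  if (all(prof == 0)) stop("no peaks found: empty mask")
  w <- max(1L, round(0.2 * sp))
  if (w %% 2 == 0) w <- w + 1L
  sm <- as.numeric(stats::filter(prof, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  ## local maxima, then greedy enforcement of the minimum separation
  is_max <- sm > 0 & sm >= c(-Inf, sm[-H]) & sm > c(sm[-1], -Inf)
  cand <- which(is_max)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (p in cand)
    if (!length(peaks) || min(abs(peaks - p)) >= 0.7 * sp)
      peaks <- c(peaks, p)
  if (!length(peaks)) stop("no peaks found")
  peaks <- sort(peaks)
  n <- length(peaks)
  mids <- if (n > 1) round((peaks[-n] + peaks[-1]) / 2) else integer(0)
  lo <- pmax(0L, c(0L, mids), round(peaks - 0.75 * sp))
  hi <- pmin(H, c(mids, H), round(peaks + 0.75 * sp))
  structure(list(strips = data.frame(r0 = lo, r1 = hi), spacing_px = sp),
            class = "strip_set")
}

#' Fit a line to the corn row inside one strip
#'
#' The default `endpoints` method finds the first and last pixel columns of
#' the strip containing any vegetation, anchors a point at each (column,
#' centroid pixel-row of the vegetation in that column) and returns the
#' line through the two anchors.  `least_squares` fits the per-column
#' vegetation centroids of all occupied columns by ordinary least squares.
#' A single occupied column degenerates to a horizontal line through its
#' centroid.
#'
#' Because a strip spans the full inter-row band, stray off-row vegetation
#' (inter-row weeds) would otherwise capture the endpoint anchors and tilt
#' the fit off the row.  The fit therefore first restricts to the strip's
#' dominant vegetation band: the pixel rows within
#' `row_band_frac / 2` of the strip's own vegetation-profile peak.  This
#' realises "the corn pixels of the strip" rather than "any green in the
#' strip"; set `row_band_frac = Inf` to fit all strip vegetation.
#'
#' @param strip numeric `c(r0, r1)`, a half-open pixel-row interval.
#' @param mask a [cs_mask()] in the rotated frame.
#' @param method `"endpoints"` (default) or `"least_squares"`.
#' @param row_band_frac width of the retained vegetation band as a
#'   fraction of the strip height.
#' @return one-row data frame: `slope`, `intercept` (pixel units, line
#'   `row = slope * col + intercept` through pixel centres), `col_start`,
#'   `col_end` (first/last occupied columns), or `NULL` for an empty strip.
#' @export
fit_row_line <- function(strip, mask, method = c("endpoints", "least_squares"),
                         row_band_frac = 0.35) {
  method <- match.arg(method)
  sub <- mask$values[(strip[1] + 1):strip[2], , drop = FALSE]
  if (is.finite(row_band_frac) && any(sub)) {
    prof <- rowSums(sub)
    peak <- which.max(prof)
    half <- max(1, row_band_frac * nrow(sub) / 2)
    keep <- abs(seq_len(nrow(sub)) - peak) <= half
    sub[!keep, ] <- FALSE
  }
  occ <- which(colSums(sub) > 0)
  if (!length(occ)) return(NULL)
  cent <- vapply(occ, function(j) {
    r <- which(sub[, j])
    mean(r - 1) + strip[1]           # 0-based pixel rows
  }, numeric(1))
  cols <- occ - 1                     # 0-based pixel columns
  if (length(occ) == 1L || method == "endpoints") {
    if (length(occ) == 1L || cols[1] == cols[length(cols)]) {
      slope <- 0; intercept <- cent[1]
    } else {
      i <- c(1L, length(occ))
      slope <- (cent[i[2]] - cent[i[1]]) / (cols[i[2]] - cols[i[1]])
      intercept <- cent[i[1]] - slope * cols[i[1]]
    }
  } else {
    fit <- stats::lm.fit(cbind(1, cols), cent)
    intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  }
  data.frame(slope = slope, intercept = intercept,
             col_start = cols[1], col_end = cols[length(cols)])
}

#' Extract crop rows from a field raster
#'
#' Full row-detection chain: vegetation mask, orientation estimate,
#' nearest-neighbour rotation of the mask to a rows-horizontal frame,
#' strip partition, and a per-strip line fit.  Strips with no vegetation
#' are skipped (reported in the result, not errors).
#'
#' @param raster a [cs_raster()] in the original frame.
#' @param thr a [green_thresholds()].
#' @param row_spacing_m nominal row spacing in metres.
#' @param mode strip placement mode, see [partition_strips()].
#' @return list of class `row_set`: `theta_deg` (rotation applied),
#'   `rows` (data frame with `strip_id, slope, intercept, col_start,
#'   col_end` in rotated pixel coordinates), `strips` (the [partition_strips()]
#'   result), `mask_rot` (the rotated [cs_mask()]), `skipped_strips`.
#' @export
extract_rows <- function(raster, thr = green_thresholds(),
                         row_spacing_m = 1.0, mode = "peaks") {
  m <- green_mask(raster, thr)
  theta <- estimate_row_orientation(m)
  mrot <- rotate_mask(m, theta)
  ss <- partition_strips(mrot, row_spacing_m, raster$gsd, mode = mode)
  fits <- list(); skipped <- integer(0)
  for (i in seq_len(nrow(ss$strips))) {
    f <- fit_row_line(as.numeric(ss$strips[i, ]), mrot)
    if (is.null(f)) { skipped <- c(skipped, i); next }
    f$strip_id <- i
    fits[[length(fits) + 1L]] <- f
  }
  rows <- if (length(fits)) do.call(rbind, fits) else
    data.frame(slope = numeric(), intercept = numeric(),
               col_start = numeric(), col_end = numeric(),
               strip_id = integer())
  structure(list(theta_deg = theta, rows = rows, strips = ss,
                 mask_rot = mrot, skipped_strips = skipped),
            class = "row_set")
}

#' @export
print.row_set <- function(x, ...) {
  cat(sprintf("<row_set> %d rows, rotation %.2f deg (%d strips skipped)\n",
              nrow(x$rows), x$theta_deg, length(x$skipped_strips)))
  invisible(x)
}
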