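#' Construct a georeferenced RGB raster
#'
#' The basic image container shared by every stage of the pipeline: an
#' 8-bit-per-channel H x W x 3 intensity grid plus a scalar ground-sampling
#' distance (GSD, metres per pixel, square pixels) and a frame tag recording
#' whether the image is in its original orientation or has been rotated.
#'
#' Pixel coordinates are 0-based, row-major, origin at the top-left corner;
#' map coordinates are in metres with y increasing downward, so pixel
#' `(row, col)` has its centre at `((col + 0.5) * gsd, (row + 0.5) * gsd)`.
#'
#' @param pixels numeric H x W x 3 array of intensities in `[0, 255]`
#'   (a single H x W matrix is promoted to three identical channels).
#' @param gsd ground-sampling distance in metres per pixel (> 0).
#' @param frame frame tag: `"original"`, or `rotated_frame(theta)` for a
#'   rotated raster.
#' @param validity optional H x W logical matrix flagging pixels inside the
#'   original image footprint (used after rotation, where the expanded
#'   canvas contains padding).
#' @return an object of class `cs_raster`.
#' @export
cs_raster <- function(pixels, gsd, frame = "original", validity = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) stop("raster must have at least one pixel")
  if (!is.numeric(gsd) || length(gsd) != 1L || !is.finite(gsd) || gsd <= 0)
    stop("gsd must be a positive scalar")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) stop("intensities must lie in [0, 255]")
  if (!is.null(validity)) stopifnot(identical(dim(validity), d[1:2]))
  structure(list(pixels = pixels, gsd = gsd, frame = frame,
                 validity = validity),
            class = "cs_raster")
}

#' @export
print.cs_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<cs_raster> %d x %d px, gsd %.4g m/px (%.2f x %.2f m), frame: %s\n",
              d[1], d[2], x$gsd, d[2] * x$gsd, d[1] * x$gsd,
              format_frame(x$frame)))
  invisible(x)
}

#' @export
dim.cs_raster <- function(x) dim(x$pixels)

#' Frame tag for a rotated raster
#'
#' @param theta_deg rotation applied, in degrees (positive = clockwise in
#'   screen coordinates, i.e. y down).
#' @return a frame tag usable in [cs_raster()].
#' @export
rotated_frame <- function(theta_deg) {
  structure(list(theta_deg = theta_deg), class = "cs_frame_rotated")
}

format_frame <- function(frame) {
  if (inherits(frame, "cs_frame_rotated"))
    sprintf("rotated(%.3g deg)", frame$theta_deg) else as.character(frame)
}

#' Binary mask tied to a raster frame
#'
#' @param values H x W logical matrix.
#' @param frame frame tag of the source raster.
#' @return an object of class `cs_mask`.
#' @export
cs_mask <- function(values, frame = "original") {
  stopifnot(is.matrix(values), is.logical(values))
  structure(list(values = values, frame = frame), class = "cs_mask")
}

#' @export
dim.cs_mask <- function(x) dim(x$values)

#' Axis-aligned rectangle in map metres
#'
#' Rectangles are half-open on their high edges when rasterised: a pixel
#' centre exactly on `x1` or `y1` is outside.
#'
#' @param x0,y0,x1,y1 corner coordinates in metres, `x0 < x1`, `y0 < y1`.
#' @return a named numeric vector of class `cs_rect`.
#' @export
cs_rect <- function(x0, y0, x1, y1) {
  stopifnot(is.finite(c(x0, y0, x1, y1)))
  if (x0 >= x1 || y0 >= y1) stop("degenerate rectangle: need x0 < x1 and y0 < y1")
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "cs_rect")
}

rect_center <- function(r) c((r[["x0"]] + r[["x1"]]) / 2, (r[["y0"]] + r[["y1"]]) / 2)
rect_area   <- function(r) (r[["x1"]] - r[["x0"]]) * (r[["y1"]] - r[["y0"]])

#' Pixel-centre to map coordinates and back
#'
#' `pixel_to_map` returns the map position of a pixel centre; `map_to_pixel`
#' floors a map point to the containing pixel.  Both follow the shared
#' convention: 0-based indices, `x = (col + 0.5) * gsd`, y down.
#'
#' @param row,col 0-based pixel indices (vectorised).
#' @param x,y map coordinates in metres (vectorised).
#' @param raster a [cs_raster()] (only `gsd` and the dimensions are used).
#' @return `pixel_to_map`: a list with `x`, `y`; `map_to_pixel`: a list with
#'   `row`, `col`.  `map_to_pixel` errors if any point falls outside the
#'   raster footprint.
#' @export
pixel_to_map <- function(row, col, raster) {
  list(x = (col + 0.5) * raster$gsd, y = (row + 0.5) * raster$gsd)
}

#' @rdname pixel_to_map
#' @export
map_to_pixel <- function(x, y, raster) {
  d <- dim(raster$pixels)
  col <- as.integer(floor(x / raster$gsd))
  row <- as.integer(floor(y / raster$gsd))
  if (any(row < 0 | row >= d[1] | col < 0 | col >= d[2]))
    stop("map point outside raster footprint")
  list(row = row, col = col)
}

## Canvas size of the minimal axis-aligned bounding box of a W x H image
## rotated by theta degrees (matches EBImage::rotate).
rotated_canvas_dim <- function(h, w, theta_deg) {
  t <- theta_deg * pi / 180
  c(h = ceiling(w * abs(sin(t)) + h * abs(cos(t)) - 1e-9),
    w = ceiling(w * abs(cos(t)) + h * abs(sin(t)) - 1e-9))
}

## Rotate one H x W matrix clockwise (y down) by theta about its centre
## onto the minimal expanded canvas.  Exact array permutations for
## multiples of 90 degrees; EBImage::affine resampling otherwise, with the
## transform matrix built so continuous output coords p_out satisfy
## p_out = R %*% (p_in - c_in) + c_out.
rotate_channel <- function(ch, theta_deg, filter = "bilinear") {
  theta <- theta_deg %% 360
  if (theta == 0) return(ch)
  h <- nrow(ch); w <- ncol(ch)
  if (theta %% 90 == 0) {
    return(switch(as.character(theta),
      "90"  = t(ch)[, seq(h, 1), drop = FALSE],
      "180" = ch[seq(h, 1), seq(w, 1), drop = FALSE],
      "270" = t(ch)[seq(w, 1), , drop = FALSE]))
  }
  t <- theta_deg * pi / 180
  d <- rotated_canvas_dim(h, w, theta_deg)
  R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
  tt <- c(d[["w"]] / 2, d[["h"]] / 2) - R %*% c(w / 2, h / 2)
  m <- rbind(t(R), as.numeric(tt))
  out <- EBImage::affine(EBImage::Image(t(ch)), m, filter = filter,
                         output.dim = c(d[["w"]], d[["h"]]), bg.col = 0,
                         antialias = FALSE)
  t(EBImage::imageData(out))
}

#' Rotate a raster about its centre
#'
#' Rotates the image clockwise (screen convention, y down) by `theta_deg`
#' about the image centre.  The output canvas is the minimal axis-aligned
#' bounding box of the rotated footprint, so no content is cropped;
#' out-of-footprint pixels are set to 0 and flagged `FALSE` in the returned
#' raster's `validity` matrix.  Resampling is delegated to
#' `EBImage::affine()`; masks must use nearest-neighbour interpolation.
#'
#' @param raster a [cs_raster()].
#' @param theta_deg rotation angle in degrees; a feature at direction
#'   `alpha` (measured from +x toward +y) ends up at `alpha + theta_deg`.
#' @param interp `"bilinear"` (default, for imagery) or `"nearest"`.
#' @return a [cs_raster()] in the rotated frame with a validity mask.
#' @export
rotate_raster <- function(raster, theta_deg, interp = c("bilinear", "nearest")) {
  stopifnot(inherits(raster, "cs_raster"), is.finite(theta_deg))
  interp <- match.arg(interp)
  if (theta_deg %% 360 == 0) {
    out <- raster
    out$validity <- matrix(TRUE, dim(raster$pixels)[1], dim(raster$pixels)[2])
    return(out)
  }
  filt <- if (interp == "bilinear") "bilinear" else "none"
  d <- dim(raster$pixels)
  chans <- lapply(1:3, function(ch)
    rotate_channel(raster$pixels[, , ch], theta_deg, filt))
  px <- array(unlist(chans), c(dim(chans[[1]]), 3L))
  px[px < 0] <- 0L; px[px > 255] <- 255L
  val <- rotate_channel(matrix(1, d[1], d[2]), theta_deg, "none") > 0.5
  base <- if (inherits(raster$frame, "cs_frame_rotated")) raster$frame$theta_deg else 0
  cs_raster(px, raster$gsd, frame = rotated_frame(base + theta_deg),
            validity = val)
}

#' Rotate a binary mask about its centre (nearest neighbour)
#'
#' @param mask a [cs_mask()].
#' @param theta_deg rotation in degrees (same convention as
#'   [rotate_raster()]).
#' @return a [cs_mask()] on the expanded canvas.
#' @export
rotate_mask <- function(mask, theta_deg) {
  stopifnot(inherits(mask, "cs_mask"))
  if (theta_deg %% 360 == 0) return(mask)
  cs_mask(rotate_channel(mask$values * 1, theta_deg, "none") > 0.5,
          frame = rotated_frame(theta_deg))
}

#' Map points between the original and rotated frames
#'
#' Applies the same centre rotation as [rotate_raster()] to map
#' coordinates (metres), accounting for the canvas expansion.  With
#' `inverse = TRUE`, maps rotated-frame points back to the original frame.
#'
#' @param x,y map coordinates in metres (vectorised).
#' @param theta_deg rotation applied to the raster.
#' @param dim_px `c(H, W)` pixel dimensions of the *original* raster.
#' @param gsd metres per pixel.
#' @param inverse map from the rotated frame back to the original frame.
#' @return list with transformed `x`, `y` in metres.
#' @export
rotate_map_points <- function(x, y, theta_deg, dim_px, gsd, inverse = FALSE) {
  t <- theta_deg * pi / 180
  dr <- rotated_canvas_dim(dim_px[1], dim_px[2], theta_deg)
  c_in  <- c(dim_px[2], dim_px[1]) * gsd / 2   # (x, y) of original centre
  c_out <- c(dr[["w"]], dr[["h"]]) * gsd / 2
  if (inverse) { t <- -t; tmp <- c_in; c_in <- c_out; c_out <- tmp }
  dx <- x - c_in[1]; dy <- y - c_in[2]
  list(x = cos(t) * dx - sin(t) * dy + c_out[1],
       y = sin(t) * dx + cos(t) * dy + c_out[2])
}

#' Read and write rasters
#'
#' GeoTIFF-style `.tif`/`.tiff` and `.png` files are supported through the
#' \pkg{tiff} and \pkg{png} packages.  Neither format carries the
#' ground-sampling distance here, so it is stored in a YAML sidecar
#' (`<file>.meta.yaml`) holding `gsd` and the frame tag; `read_raster`
#' falls back to `gsd = 0.015` m/px with a warning when no sidecar exists.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param raster a [cs_raster()] to write.
#' @param gsd override the sidecar/default GSD on read.
#' @return `read_raster`: a [cs_raster()]; `write_raster`: the path,
#'   invisibly.
#' @export
read_raster <- function(path, gsd = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext))
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  arr <- arr[, , 1:3, drop = FALSE] * 255
  side <- paste0(path, ".meta.yaml")
  if (is.null(gsd)) {
    if (file.exists(side)) {
      gsd <- yaml::read_yaml(side)$gsd
    } else {
      warning("no GSD sidecar found; assuming 0.015 m/px")
      gsd <- 0.015
    }
  }
  cs_raster(round(arr), gsd)
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  arr <- raster$pixels / 255
  switch(ext,
    png  = png::writePNG(arr, path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported raster format: ", ext))
  yaml::write_yaml(list(gsd = raster$gsd, frame = format_frame(raster$frame)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Export rectangles or row lines as GeoJSON
#'
#' Writes features in map metres (not an earth CRS; the pipeline is not
#' georeferenced).  Rectangles become Polygon features; row lines become
#' two-point LineString features with slope/intercept properties.
#'
#' @param rects data frame with columns `x0, y0, x1, y1` plus any extra
#'   property columns.
#' @param rows data frame as returned by [extract_rows()] (pixel
#'   coordinates are converted using `gsd`).
#' @param gsd metres per pixel, used to convert row-line pixel coordinates.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rects_geojson <- function(rects, path) {
  feats <- lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    ring <- list(c(r$x0, r$y0), c(r$x1, r$y0), c(r$x1, r$y1),
                 c(r$x0, r$y1), c(r$x0, r$y0))
    props <- as.list(r[setdiff(names(r), c("x0", "y0", "x1", "y1"))])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rects_geojson
#' @export
write_rows_geojson <- function(rows, gsd, path) {
  feats <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    p <- function(col) c((col + 0.5) * gsd,
                         (r$slope * col + r$intercept + 0.5) * gsd)
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(p(r$col_start), p(r$col_end))),
         properties = list(strip_id = r$strip_id, slope = r$slope,
                           intercept = r$intercept))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
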