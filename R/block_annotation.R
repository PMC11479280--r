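#' Annotation block geometry and labelling criterion
#'
#' Blocks are fixed-size rectangles tiled along the (rotated,
#' rows-horizontal) field: 0.20 m along the row by 0.25 m across the row
#' by default, labelled corn when they lie on a detected row line *and*
#' contain at least 7% vegetation pixels.  The along-row pitch is close to
#' the in-row plant spacing regime the block classifier expects, so one
#' block captures roughly one stand.
#'
#' @param along_row_m block size along the row direction (x), metres.
#' @param across_row_m block size across rows (y), metres.
#' @param green_threshold minimum vegetation fraction for a corn label
#'   (inclusive).
#' @return a list of class `block_spec`.
#' @export
block_spec <- function(along_row_m = 0.20, across_row_m = 0.25,
                       green_threshold = 0.07) {
  stopifnot(along_row_m > 0, across_row_m > 0,
            green_threshold > 0, green_threshold < 1)
  structure(list(along_row_m = along_row_m, across_row_m = across_row_m,
                 green_threshold = green_threshold), class = "block_spec")
}

#' Tile an extent into annotation blocks
#'
#' Non-overlapping grid anchored at the extent origin with x-pitch
#' `along_row_m` and y-pitch `across_row_m`; partial blocks at the high
#' edges are discarded.
#'
#' @param extent a [cs_rect()] in rotated-frame metres.
#' @param spec a [block_spec()].
#' @return data frame of block rectangles `x0, y0, x1, y1` (possibly
#'   zero rows, with a warning, when the extent is smaller than one block).
#' @export
tile_blocks <- function(extent, spec = block_spec()) {
  wx <- extent[["x1"]] - extent[["x0"]]
  wy <- extent[["y1"]] - extent[["y0"]]
  nx <- floor(wx / spec$along_row_m + 1e-9)
  ny <- floor(wy / spec$across_row_m + 1e-9)
  if (nx < 1 || ny < 1) {
    warning("extent smaller than one block; returning no blocks")
    return(data.frame(x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()))
  }
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  data.frame(x0 = extent[["x0"]] + ix * spec$along_row_m,
             y0 = extent[["y0"]] + iy * spec$across_row_m,
             x1 = extent[["x0"]] + (ix + 1L) * spec$along_row_m,
             y1 = extent[["y0"]] + (iy + 1L) * spec$across_row_m)
}

#' Vegetation fraction of a rectangle
#'
#' Counts mask pixels whose centres fall in the (half-open) rectangle and
#' divides by the number of pixel centres it contains.
#'
#' @param rect a [cs_rect()] or anything with `x0, y0, x1, y1` in metres.
#' @param mask a [cs_mask()].
#' @param gsd metres per pixel.
#' @return fraction in `[0, 1]`.
#' @export
green_fraction <- function(rect, mask, gsd) {
  d <- dim(mask$values)
  idx <- rect_pixels(rect, d, gsd)
  if (is.null(idx)) stop("rectangle outside the mask footprint")
  sub <- mask$values[idx$rows, idx$cols, drop = FALSE]
  sum(sub) / length(sub)
}

## 1-based pixel index ranges of centres inside a half-open rect; NULL if
## the rect lies outside the grid.
rect_pixels <- function(rect, dim_px, gsd) {
  x0 <- if (is.list(rect) || is.data.frame(rect)) rect$x0 else rect[["x0"]]
  y0 <- if (is.list(rect) || is.data.frame(rect)) rect$y0 else rect[["y0"]]
  x1 <- if (is.list(rect) || is.data.frame(rect)) rect$x1 else rect[["x1"]]
  y1 <- if (is.list(rect) || is.data.frame(rect)) rect$y1 else rect[["y1"]]
  c0 <- ceiling(x0 / gsd - 0.5); c1 <- ceiling(x1 / gsd - 0.5) - 1
  r0 <- ceiling(y0 / gsd - 0.5); r1 <- ceiling(y1 / gsd - 0.5) - 1
  r0 <- max(r0, 0); c0 <- max(c0, 0)
  r1 <- min(r1, dim_px[1] - 1); c1 <- min(c1, dim_px[2] - 1)
  if (r0 > r1 || c0 > c1) return(NULL)
  list(rows = (r0 + 1):(r1 + 1), cols = (c0 + 1):(c1 + 1))
}

## Does the row line segment (pixel coords) intersect the rect (metres)?
line_hits_rect <- function(row, rect, gsd) {
  ## convert rect to pixel coordinates (pixel-centre continuous coords)
  rx0 <- rect$x0 / gsd - 0.5; rx1 <- rect$x1 / gsd - 0.5
  ry0 <- rect$y0 / gsd - 0.5; ry1 <- rect$y1 / gsd - 0.5
  xlo <- max(rx0, row$col_start); xhi <- min(rx1, row$col_end)
  if (xlo > xhi) return(FALSE)
  ya <- row$slope * xlo + row$intercept
  yb <- row$slope * xhi + row$intercept
  max(min(ya, yb), ry0) <= min(max(ya, yb), ry1)
}

#' Label annotation blocks as corn or non-corn
#'
#' A block is *on-row* when at least one fitted row-line segment intersects
#' its rectangle (no buffer).  It is labelled `corn` iff it is on-row and
#' its vegetation fraction is at least the block spec's threshold
#' (inclusive); all other blocks -- on-row but below the threshold, or
#' off-row however green (inter-row weeds) -- are `non_corn`.
#'
#' @param blocks data frame of rectangles from [tile_blocks()], in
#'   rotated-frame metres.
#' @param rows data frame of row lines (rotated pixel coordinates), as in
#'   [extract_rows()]'s `rows`.
#' @param mask the rotated-frame [cs_mask()].
#' @param gsd metres per pixel.
#' @param spec a [block_spec()].
#' @return the `blocks` data frame with added columns `green_fraction`,
#'   `on_row`, `label` (`"corn"`/`"non_corn"`) and `row_id` (`NA` for
#'   non-corn blocks).
#' @export
label_blocks <- function(blocks, rows, mask, gsd, spec = block_spec()) {
  n <- nrow(blocks)
  gf <- numeric(n); on_row <- logical(n); rid <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    b <- blocks[i, ]
    gf[i] <- green_fraction(b, mask, gsd)
    for (j in seq_len(nrow(rows))) {
      if (line_hits_rect(rows[j, ], b, gsd)) {
        on_row[i] <- TRUE
        rid[i] <- rows$strip_id[j]
        break
      }
    }
  }
  blocks$green_fraction <- gf
  blocks$on_row <- on_row
  blocks$label <- ifelse(on_row & gf >= spec$green_threshold,
                         "corn", "non_corn")
  blocks$row_id <- ifelse(blocks$label == "corn", rid, NA_integer_)
  blocks
}

#' Automatically annotate a field into corn / non-corn blocks
#'
#' Full auto-annotation chain: vegetation mask, row extraction, rotation of
#' the raster to the rows-horizontal frame, block tiling over the rotated
#' canvas, and row-gated green-fraction labelling.  Deterministic.
#'
#' @param raster a [cs_raster()], original frame.
#' @param thr a [green_thresholds()].
#' @param row_spacing_m nominal row spacing, metres.
#' @param spec a [block_spec()].
#' @return list of class `annotation`: `blocks` (labelled block data
#'   frame, rotated-frame metres), `theta_deg`, `rows` (fitted lines),
#'   `raster_rot` (rotated raster), `mask_rot`, and `report` (class counts
#'   and per-row corn-block counts).
#' @export
annotate_field <- function(raster, thr = green_thresholds(),
                           row_spacing_m = 1.0, spec = block_spec()) {
  rs <- extract_rows(raster, thr, row_spacing_m)
  ## nearest-neighbour: chip colours are resampled, never blended, so the
  ## chip statistics stay exactly consistent with the rotated label mask
  rrot <- rotate_raster(raster, rs$theta_deg, interp = "nearest")
  mrot <- rs$mask_rot
  d <- dim(mrot$values)
  extent <- cs_rect(0, 0, d[2] * raster$gsd, d[1] * raster$gsd)
  blocks <- tile_blocks(extent, spec)
  blocks <- label_blocks(blocks, rs$rows, mrot, raster$gsd, spec)
  report <- list(
    n_blocks = nrow(blocks),
    n_corn = sum(blocks$label == "corn"),
    n_non_corn = sum(blocks$label == "non_corn"),
    corn_per_row = table(blocks$row_id[blocks$label == "corn"]))
  structure(list(blocks = blocks, theta_deg = rs$theta_deg, rows = rs$rows,
                 raster_rot = rrot, mask_rot = mrot, report = report),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d blocks: %d corn / %d non-corn (rotation %.2f deg, %d rows)\n",
              x$report$n_blocks, x$report$n_corn, x$report$n_non_corn,
              x$theta_deg, nrow(x$rows)))
  invisible(x)
}

#' Score auto-annotation against synthetic ground truth
#'
#' Plant-level quality of an annotation: *recall* is the fraction of truth
#' plants covered by at least one corn block (plant centre, mapped into the
#' rotated frame, within `tol_m` of the block rectangle) and *precision*
#' the fraction of corn blocks within `tol_m` of at least one truth plant
#' centre.  The tolerance defaults to the rendered plant radius, i.e. a
#' block touching any part of a plant footprint counts as covering it.
#'
#' @param annotation result of [annotate_field()].
#' @param truth ground truth from [generate_field()].
#' @param dim_px original raster dimensions `c(H, W)` in pixels.
#' @param gsd metres per pixel.
#' @param tol_m match tolerance in metres.
#' @return list with `recall`, `precision`, `n_plants`, `n_corn_blocks`.
#' @export
annotation_quality <- function(annotation, truth, dim_px, gsd,
                               tol_m = 0.08) {
  pl <- truth$plants
  p <- rotate_map_points(pl$x_m, pl$y_m, annotation$theta_deg, dim_px, gsd)
  corn <- annotation$blocks[annotation$blocks$label == "corn", ]
  if (nrow(pl) == 0)
    return(list(recall = NA_real_, precision = NA_real_,
                n_plants = 0L, n_corn_blocks = nrow(corn)))
  dist_pt_rect <- function(x, y, b) {
    dx <- pmax(b$x0 - x, 0, x - b$x1)
    dy <- pmax(b$y0 - y, 0, y - b$y1)
    sqrt(dx^2 + dy^2)
  }
  covered <- logical(nrow(pl)); hit <- logical(nrow(corn))
  for (j in seq_len(nrow(corn))) {
    d <- dist_pt_rect(p$x, p$y, corn[j, ])
    near <- d <= tol_m
    hit[j] <- any(near)
    covered <- covered | near
  }
  list(recall = mean(covered), precision = if (nrow(corn)) mean(hit) else NA_real_,
       n_plants = nrow(pl), n_corn_blocks = nrow(corn))
}
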