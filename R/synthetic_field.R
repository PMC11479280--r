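#' Configuration for the synthetic corn-field generator
#'
#' Describes an early-vegetative (V2--V4 stage) row-crop scene: parallel
#' straight rows at fixed spacing, small leaf-rosette plants along each row,
#' bare-soil background with pixel noise and optional crop-residue streaks,
#' and optional off-row weeds.  Defaults emulate the imaging conditions the
#' pipeline targets: 1.5 cm ground-sampling distance, 1 m row spacing,
#' plants with 2--4 leaves whose pixels fall inside the vegetation HSV box
#' used by [green_mask()] while soil pixels stay outside it.
#'
#' In-row plant spacing defaults to 0.45 m so that each stand's ~0.16 m
#' footprint occupies its own block cluster with at least one full
#' background block between neighbours; see the methods vignette for the
#' rationale and for what this implies about denser stands.
#'
#' @param width_m,height_m field extent in metres.
#' @param gsd ground-sampling distance, metres per pixel.
#' @param row_spacing_m distance between adjacent row lines.
#' @param row_angle_deg row direction, degrees from +x toward +y (y down).
#' @param plant_spacing_m mean in-row distance between consecutive plants.
#' @param spacing_jitter fraction of `plant_spacing_m` used as uniform
#'   longitudinal jitter.
#' @param lateral_jitter_m maximum uniform offset of a plant centre off its
#'   row line (kept well under half the row spacing).
#' @param plant_radius_m mean leaf length from the plant centre.
#' @param leaves_per_plant integer range `c(min, max)` of leaves per plant.
#' @param missing_rate probability that a planned plant is absent (skips in
#'   the seed line).
#' @param weed_density_per_m2 expected off-row weeds per square metre.
#' @param soil_base RGB triplet (0--255) of the mean bare-soil colour.
#' @param soil_noise standard deviation of Gaussian per-pixel soil noise.
#' @param residue_density expected residue streaks per square metre.
#' @param seed RNG seed making the field reproducible.
#' @return a list of class `field_config`.
#' @export
field_config <- function(width_m = 9, height_m = 9, gsd = 0.015,
                         row_spacing_m = 1.0, row_angle_deg = 0,
                         plant_spacing_m = 0.45, spacing_jitter = 0.1,
                         lateral_jitter_m = 0.02, plant_radius_m = 0.085,
                         leaves_per_plant = c(2L, 4L), missing_rate = 0.05,
                         weed_density_per_m2 = 0,
                         soil_base = c(130, 82, 55), soil_noise = 6,
                         residue_density = 0.05, seed = 1L) {
  stopifnot(width_m > 0, height_m > 0, gsd > 0, row_spacing_m > 0,
            plant_spacing_m > 0, plant_radius_m >= 0,
            missing_rate >= 0, missing_rate <= 1,
            weed_density_per_m2 >= 0,
            length(leaves_per_plant) == 2L,
            leaves_per_plant[1] >= 1L, leaves_per_plant[2] <= 8L,
            leaves_per_plant[1] <= leaves_per_plant[2])
  structure(as.list(environment()), class = "field_config")
}

## Run expr with a private, seeded RNG stream; restores the global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## HSV (hue on the half-degree [0,180] scale, S/V in 0..255) -> RGB 0..255.
hsv_to_rgb255 <- function(h_half, s, v) {
  col <- grDevices::hsv(h_half * 2 / 360, s / 255, v / 255)
  t(grDevices::col2rgb(col))
}

#' Generate a ground-truthed synthetic corn field
#'
#' Renders a field described by a [field_config()] and returns both the RGB
#' raster and an exact ground-truth table: every plant centre with its row
#' id, the true row-line endpoints, and any weed centres.  Deterministic
#' for a given config (the seed is part of the config).
#'
#' Rows are straight lines at `row_angle_deg`, centred in the field and
#' spaced `row_spacing_m` apart perpendicular to the row direction.
#' Planned plant positions march along each row at
#' `plant_spacing_m` plus longitudinal jitter; each is dropped with
#' probability `missing_rate`.  Weeds are placed uniformly but rejected
#' within `0.25 * row_spacing_m` of any row line, so on-row/off-row truth
#' is unambiguous.
#'
#' @param config a [field_config()].
#' @return list with `raster` (a [cs_raster()], original frame) and `truth`
#'   (list with data frames `plants` (`plant_id, x_m, y_m, row_id`),
#'   `rows` (`row_id, ax, ay, bx, by`), and `weeds` (`x_m, y_m`)).
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  if (min(config$width_m, config$height_m) < 2 * config$row_spacing_m)
    stop("field extent smaller than two row spacings")
  with_seed(config$seed, generate_field_impl(config))
}

generate_field_impl <- function(cfg) {
  H <- round(cfg$height_m / cfg$gsd)
  W <- round(cfg$width_m / cfg$gsd)

  px <- render_soil(H, W, cfg)

  ## Row geometry: direction u at row_angle, normal n; offsets centred.
  th <- cfg$row_angle_deg * pi / 180
  u <- c(cos(th), sin(th)); n <- c(-sin(th), cos(th))
  ctr <- c(cfg$width_m, cfg$height_m) / 2
  ## how many rows fit: project field corners on the normal
  corners <- rbind(c(0, 0), c(cfg$width_m, 0), c(0, cfg$height_m),
                   c(cfg$width_m, cfg$height_m))
  dproj <- (corners[, 1] - ctr[1]) * n[1] + (corners[, 2] - ctr[2]) * n[2]
  half_sp <- cfg$row_spacing_m / 2
  offs <- seq(min(dproj) + half_sp, max(dproj) - half_sp + 1e-9,
              by = cfg$row_spacing_m)
  if (length(offs) < 2) stop("field extent smaller than one row spacing")
  ## centre the row set, then shift it by a random sub-spacing phase so row
  ## positions are not aligned with any later tiling grid
  offs <- offs - mean(offs) + runif(1, -0.125, 0.125) * cfg$row_spacing_m / 1


  tmax <- max(cfg$width_m, cfg$height_m)
  rows_df <- data.frame(row_id = integer(), ax = numeric(), ay = numeric(),
                        bx = numeric(), by = numeric())
  plants <- list()
  pid <- 0L
  for (i in seq_along(offs)) {
    base <- ctr + offs[i] * n
    seg <- clip_line_to_rect(base, u, cfg$width_m, cfg$height_m,
                             margin = cfg$plant_radius_m + 0.02)
    if (is.null(seg)) next
    rows_df <- rbind(rows_df, data.frame(
      row_id = i, ax = seg$a[1], ay = seg$a[2], bx = seg$b[1], by = seg$b[2]))
    tlen <- seg$t1 - seg$t0
    npl <- floor(tlen / cfg$plant_spacing_m)
    if (npl < 1) next
    t0 <- seg$t0 + (tlen - npl * cfg$plant_spacing_m) / 2 +
      cfg$plant_spacing_m / 2
    for (k in seq_len(npl)) {
      tk <- t0 + (k - 1) * cfg$plant_spacing_m +
        runif(1, -1, 1) * cfg$spacing_jitter * cfg$plant_spacing_m
      lat <- runif(1, -1, 1) * cfg$lateral_jitter_m
      present <- runif(1) >= cfg$missing_rate
      if (!present) next
      p <- base + tk * u + lat * n
      pid <- pid + 1L
      plants[[pid]] <- c(p[1], p[2], i)
      px <- render_plant(px, p, cfg)
    }
  }
  plants_df <- if (pid > 0) {
    m <- do.call(rbind, plants)
    data.frame(plant_id = seq_len(pid), x_m = m[, 1], y_m = m[, 2],
               row_id = as.integer(m[, 3]))
  } else data.frame(plant_id = integer(), x_m = numeric(), y_m = numeric(),
                    row_id = integer())

  ## off-row weeds: uniform, rejected near row lines
  weeds <- matrix(numeric(0), ncol = 2)
  nw <- rpois(1, cfg$weed_density_per_m2 * cfg$width_m * cfg$height_m)
  if (nw > 0 && nrow(rows_df) > 0) {
    got <- 0L; tries <- 0L
    while (got < nw && tries < 50L * nw) {
      tries <- tries + 1L
      p <- c(runif(1, 0.1, cfg$width_m - 0.1), runif(1, 0.1, cfg$height_m - 0.1))
      dmin <- min(abs((p[1] - ctr[1]) * n[1] + (p[2] - ctr[2]) * n[2] - offs))
      ## keep the whole weed footprint (radius ~0.7 x plant) off the row
      if (dmin < 0.25 * cfg$row_spacing_m + 0.7 * cfg$plant_radius_m) next
      got <- got + 1L
      weeds <- rbind(weeds, p)
      px <- render_plant(px, p, cfg, scale = 0.7)
    }
  }
  weeds_df <- data.frame(x_m = weeds[, 1], y_m = weeds[, 2])

  list(raster = cs_raster(px, cfg$gsd),
       truth = list(plants = plants_df, rows = rows_df, weeds = weeds_df))
}

## Clip the line base + t*u to the field rect (with a margin); returns
## endpoints and the parameter interval, or NULL if outside.
clip_line_to_rect <- function(base, u, w, h, margin = 0) {
  lo <- c(margin, margin); hi <- c(w - margin, h - margin)
  t0 <- -Inf; t1 <- Inf
  for (d in 1:2) {
    if (abs(u[d]) < 1e-12) {
      if (base[d] < lo[d] || base[d] > hi[d]) return(NULL)
    } else {
      ta <- (lo[d] - base[d]) / u[d]; tb <- (hi[d] - base[d]) / u[d]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(NULL)
  list(a = base + t0 * u, b = base + t1 * u, t0 = t0, t1 = t1)
}

render_soil <- function(H, W, cfg) {
  n <- H * W
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    v <- cfg$soil_base[ch] + rnorm(n, 0, cfg$soil_noise)
    px[, , ch] <- matrix(v, H, W)
  }
  ## residue streaks: short light-tan line segments
  nres <- rpois(1, cfg$residue_density * H * W * cfg$gsd^2)
  if (nres > 0) {
    for (i in seq_len(nres)) {
      r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
      ang <- runif(1, 0, pi); len <- runif(1, 0.1, 0.4) / cfg$gsd
      tt <- seq(0, len, by = 0.7)
      rr <- pmin(H, pmax(1, round(r0 + tt * sin(ang))))
      cc <- pmin(W, pmax(1, round(c0 + tt * cos(ang))))
      tone <- c(200, 175, 130) + rnorm(3, 0, 5)
      for (ch in 1:3) px[cbind(rr, cc, ch)] <- tone[ch]
    }
  }
  px[px < 0] <- 0; px[px > 255] <- 255
  round(px)
}

#' Render one plant rosette onto a canvas
#'
#' Draws `leaves_per_plant` elliptical leaves radiating from the plant
#' centre.  Leaf colours are drawn inside the vegetation HSV box (hue
#' 40--65 on the half-degree scale, saturation and value well above the
#' 25 threshold), so every rendered pixel passes [green_mask()] with the
#' default thresholds.  Consumes the current RNG stream; out-of-canvas
#' leaf pixels are clipped silently.
#'
#' @param canvas H x W x 3 pixel array (0--255) *or* a [cs_raster()].
#' @param center plant centre `c(x_m, y_m)` in map metres.
#' @param config a [field_config()].
#' @param scale size multiplier (used for weeds).
#' @return the canvas with the plant drawn, same type as the input.
#' @export
render_plant <- function(canvas, center, config, scale = 1) {
  is_raster <- inherits(canvas, "cs_raster")
  px <- if (is_raster) canvas$pixels else canvas
  H <- dim(px)[1]; W <- dim(px)[2]
  gsd <- config$gsd
  rad <- config$plant_radius_m * scale
  if (rad > 0) {
    ## central whorl: from overhead at this GSD a V2-V4 plant reads as a
    ## compact lobed blob, most biomass within ~60% of the leaf reach
    rgb <- hsv_to_rgb255(runif(1, 45, 60), runif(1, 150, 230), runif(1, 140, 210))
    core <- 0.8 * rad * runif(1, 0.92, 1.05)
    px <- draw_ellipse(px, center[1], center[2], core, core * runif(1, 0.85, 1),
                       runif(1, 0, pi), rgb, gsd)
    nl <- sample(seq(config$leaves_per_plant[1], config$leaves_per_plant[2]), 1)
    ang0 <- runif(1, 0, 2 * pi)
    for (l in seq_len(nl)) {
      a <- ang0 + (l - 1) * 2 * pi / nl + rnorm(1, 0, 0.15)
      len <- rad * runif(1, 0.9, 1.05)
      wid <- max(1.6 * gsd, rad * 0.55 * runif(1, 0.8, 1.2))
      hue <- runif(1, 40, 65); sat <- runif(1, 120, 220); val <- runif(1, 110, 200)
      rgb <- hsv_to_rgb255(hue, sat, val)
      px <- draw_ellipse(px, center[1] + cos(a) * len * 0.55,
                         center[2] + sin(a) * len * 0.55,
                         len * 0.45, wid / 2, a, rgb, gsd)
    }
  }
  if (is_raster) { canvas$pixels <- px; canvas } else px
}

## Fill pixels whose centres fall inside an oriented ellipse.
draw_ellipse <- function(px, cx, cy, semi_a, semi_b, ang, rgb, gsd) {
  H <- dim(px)[1]; W <- dim(px)[2]
  r0 <- max(0, floor((cy - semi_a) / gsd)); r1 <- min(H - 1, ceiling((cy + semi_a) / gsd))
  c0 <- max(0, floor((cx - semi_a) / gsd)); c1 <- min(W - 1, ceiling((cx + semi_a) / gsd))
  if (r0 > r1 || c0 > c1) return(px)
  rr <- r0:r1; cc <- c0:c1
  xs <- (cc + 0.5) * gsd - cx; ys <- (rr + 0.5) * gsd - cy
  X <- matrix(xs, length(rr), length(cc), byrow = TRUE)
  Y <- matrix(ys, length(rr), length(cc))
  xr <- cos(ang) * X + sin(ang) * Y
  yr <- -sin(ang) * X + cos(ang) * Y
  inside <- (xr / semi_a)^2 + (yr / semi_b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(px)
  gr <- rr[idx[, 1]] + 1L; gc <- cc[idx[, 2]] + 1L
  for (ch in 1:3) px[cbind(gr, gc, ch)] <- rgb[ch]
  px
}

#' Write a synthetic field to disk
#'
#' Writes `field.png` (with GSD sidecar), `truth_plants.csv` and
#' `truth_rows.geojson` into a directory; the on-disk layout used by the
#' command-line interface.
#'
#' @param field result of [generate_field()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(field$raster, file.path(dir, "field.png"))
  write.csv(field$truth$plants, file.path(dir, "truth_plants.csv"),
            row.names = FALSE)
  rows <- field$truth$rows
  feats <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(r$ax, r$ay), c(r$bx, r$by))),
         properties = list(row_id = r$row_id))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "truth_rows.geojson"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
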