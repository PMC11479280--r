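test_that("pixel/map transforms follow the pixel-centre convention and invert", {
  r <- solid_raster(10, 20, gsd = 0.015)
  expect_equal(pixel_to_map(0, 0, r), list(x = 0.0075, y = 0.0075))
  expect_equal(map_to_pixel(0.0075, 0.0075, r), list(row = 0, col = 0))
  rows <- rep(0:9, each = 20); cols <- rep(0:19, times = 10)
  m <- pixel_to_map(rows, cols, r)
  back <- map_to_pixel(m$x, m$y, r)
  expect_identical(back$row, rows)
  expect_identical(back$col, cols)
  expect_error(map_to_pixel(1, 1, r), "outside")
})

test_that("rotation by 0 and 180 degrees are exact symmetries", {
  set.seed(42)
  px <- array(sample(0:255, 12 * 17 * 3, replace = TRUE), c(12, 17, 3))
  r <- cs_raster(px, 0.015)
  expect_identical(rotate_raster(r, 0)$pixels, px)
  r180 <- rotate_raster(r, 180, interp = "nearest")
  expect_equal(r180$pixels, px[12:1, 17:1, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(r180$validity))
})

test_that("rotation matches the independent inverse-affine oracle", {
  set.seed(7)
  px <- array(runif(30 * 24 * 3, 0, 255), c(30, 24, 3))
  r <- cs_raster(px, 0.015)
  for (theta in c(17, -33, 90)) {
    got <- rotate_raster(r, theta, interp = "bilinear")
    want <- oracle_rotate_channel(px[, , 2], theta, "bilinear")
    expect_equal(dim(got$pixels)[1:2], dim(want))
    val <- oracle_rotate_validity(30, 24, theta)
    ## footprint-boundary rounding ties are implementation-defined
    expect_gt(mean(got$validity == val), 0.99)
    ## away from the footprint boundary the two samplers agree exactly
    core <- erode1(val & got$validity)
    expect_lt(max(abs(got$pixels[, , 2][core] - want[core])), 1e-6)
  }
})

test_that("rotate there-and-back reproduces the interior within tolerance", {
  ## field imagery, the content class the tolerance is stated for
  f <- small_field(1)$field
  ## orthomosaics are optically smooth; soften the synthetic pixel noise
  px <- f$raster$pixels
  for (ch in 1:3)
    px[, , ch] <- t(as.matrix(EBImage::gblur(EBImage::Image(t(px[, , ch])), 1)))
  px <- pmin(pmax(px, 0), 255)
  r <- cs_raster(px, f$raster$gsd)
  h <- dim(r$pixels)[1]; w <- dim(r$pixels)[2]
  fwd <- rotate_raster(r, 17, interp = "bilinear")
  back <- rotate_raster(fwd, -17, interp = "bilinear")
  d <- dim(back$pixels)
  ro <- floor((d[1] - h) / 2); co <- floor((d[2] - w) / 2)
  rows <- floor(h / 4):floor(3 * h / 4)
  cols <- floor(w / 4):floor(3 * w / 4)
  centre <- back$pixels[ro + rows, co + cols, 2]
  expect_lt(mean(abs(centre - r$pixels[rows, cols, 2])), 2)
})

test_that("nearest-neighbour rotation approximately preserves blob mass", {
  m <- matrix(FALSE, 80, 80)
  m[20:50, 25:60] <- TRUE
  for (theta in c(10, 45, -30)) {
    rot <- rotate_mask(cs_mask(m), theta)
    expect_lt(abs(sum(rot$values) - sum(m)) / sum(m), 0.02)
  }
})

test_that("map points track pixels through rotation and back", {
  set.seed(3)
  dim_px <- c(40, 60); gsd <- 0.015
  x <- runif(20, 0.1, 0.8); y <- runif(20, 0.1, 0.5)
  fwd <- rotate_map_points(x, y, 23, dim_px, gsd)
  back <- rotate_map_points(fwd$x, fwd$y, 23, dim_px, gsd, inverse = TRUE)
  expect_equal(back$x, x, tolerance = 1e-10)
  expect_equal(back$y, y, tolerance = 1e-10)
})

test_that("raster IO round-trips pixels and GSD through PNG and TIFF", {
  set.seed(5)
  px <- array(sample(0:255, 8 * 9 * 3, replace = TRUE), c(8, 9, 3))
  r <- cs_raster(px, 0.02)
  for (ext in c("png", "tif")) {
    path <- file.path(withr::local_tempdir(), paste0("f.", ext))
    write_raster(r, path)
    r2 <- read_raster(path)
    expect_equal(r2$pixels, px)
    expect_equal(r2$gsd, 0.02)
  }
})

test_that("GeoJSON exports are valid FeatureCollections in map metres", {
  dir <- withr::local_tempdir()
  rects <- data.frame(x0 = c(0, 1), y0 = c(0, 0.5), x1 = c(0.2, 1.2),
                      y1 = c(0.25, 0.75), label = c("corn", "non_corn"))
  p1 <- file.path(dir, "rects.geojson")
  write_rects_geojson(rects, p1)
  gj <- jsonlite::read_json(p1)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  expect_equal(gj$features[[1]]$properties$label, "corn")
  rows <- data.frame(strip_id = 1L, slope = 0.01, intercept = 33,
                     col_start = 4, col_end = 380)
  p2 <- file.path(dir, "rows.geojson")
  write_rows_geojson(rows, 0.015, p2)
  gj2 <- jsonlite::read_json(p2)
  expect_equal(gj2$features[[1]]$geometry$type, "LineString")
})

test_that("degenerate rasters and rects are rejected", {
  expect_error(cs_raster(array(0, c(0, 3, 3)), 0.015))
  expect_error(cs_raster(array(300, c(2, 2, 3)), 0.015), "0, 255")
  expect_error(cs_raster(array(1, c(2, 2, 3)), -1), "gsd")
  expect_error(cs_rect(1, 0, 1, 2), "degenerate")
})
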