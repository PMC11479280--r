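test_that("green_mask implements the HSV box on the half-degree scale", {
  px <- array(0, c(1, 4, 3))
  px[1, 1, ] <- c(0, 255, 0)      # pure green: H = 60, S = V = 255 -> in
  px[1, 2, ] <- c(128, 128, 128)  # grey: S = 0 -> out
  px[1, 3, ] <- c(255, 0, 0)      # pure red: H = 0 -> out
  px[1, 4, ] <- c(60, 120, 70)    # dull vegetation green -> in
  m <- green_mask(cs_raster(px, 0.015))
  expect_identical(as.vector(m$values), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("green_mask is monotone in the threshold box", {
  set.seed(20)
  px <- array(sample(0:255, 40 * 40 * 3, replace = TRUE), c(40, 40, 3))
  r <- cs_raster(px, 0.015)
  tight <- green_mask(r, green_thresholds(c(40, 50, 50), c(65, 255, 255)))
  wide <- green_mask(r, green_thresholds(c(36, 25, 25), c(70, 255, 255)))
  expect_true(all(wide$values[tight$values]))
})

test_that("orientation search recovers known rotations and rejects empties", {
  f0 <- small_field(1)$field
  m <- green_mask(f0$raster)
  expect_lt(abs(estimate_row_orientation(m)), 0.2)
  cfg7 <- field_config(width_m = 6, height_m = 6, row_angle_deg = 7, seed = 1)
  m7 <- green_mask(generate_field(cfg7)$raster)
  expect_lt(abs(estimate_row_orientation(m7) - (-7)), 0.5)
  empty <- cs_mask(matrix(FALSE, 50, 50))
  expect_error(estimate_row_orientation(empty), "no vegetation")
})

test_that("orientation estimate inverts an applied mask rotation", {
  f <- small_field(1)$field
  m <- green_mask(f$raster)
  for (phi in c(10, -25, 40)) {
    mr <- rotate_mask(m, phi)
    expect_lt(abs(estimate_row_orientation(mr) - (-phi)), 0.5)
  }
})

test_that("peak strips isolate one truth row each on an ideal field", {
  cfg <- field_config(width_m = 4, height_m = 3.5, seed = 4)
  f <- generate_field(cfg)
  m <- green_mask(f$raster)
  ss <- partition_strips(m, 1.0, cfg$gsd)
  expect_equal(nrow(ss$strips), 3)
  ys <- sort(f$truth$rows$ay) / cfg$gsd
  for (i in seq_len(3))
    expect_true(ys[i] >= ss$strips$r0[i] && ys[i] < ss$strips$r1[i])
  expect_error(partition_strips(cs_mask(matrix(FALSE, 60, 60)), 1.0, 0.015),
               "empty mask")
})

test_that("uniform strips tile by rounded spacing and drop the partial tail", {
  m <- cs_mask(matrix(TRUE, 400, 10))
  ss <- partition_strips(m, 66.7 * 0.015, 0.015, mode = "uniform")
  expect_equal(nrow(ss$strips), 6)
  expect_equal(ss$strips$r0[1], 0)
  expect_equal(ss$strips$r1[6], 400)
  expect_true(all(ss$strips$r1 - ss$strips$r0 <= 1.5 * ss$spacing_px))
})

test_that("fit_row_line handles constant, sloped and degenerate rows", {
  ## all vegetation on pixel-row 12
  m <- matrix(FALSE, 30, 50); m[13, ] <- TRUE
  f <- fit_row_line(c(0, 30), cs_mask(m))
  expect_equal(f$slope, 0)
  expect_equal(f$intercept, 12)
  ## single occupied column -> horizontal through its centroid
  m2 <- matrix(FALSE, 30, 50); m2[11:15, 20] <- TRUE
  f2 <- fit_row_line(c(0, 30), cs_mask(m2))
  expect_equal(f2$slope, 0)
  expect_equal(f2$intercept, 12)
  expect_equal(f2$col_start, 19)
  ## empty strip signals NULL
  expect_null(fit_row_line(c(0, 30), cs_mask(matrix(FALSE, 30, 5))))
})

test_that("fit recovers a gently sloping row from sampled plants", {
  set.seed(31)
  m <- matrix(FALSE, 60, 400)
  cols <- seq(5, 395, by = 12)
  for (cc in cols) {
    r0 <- 0.01 * cc + 25
    rows <- round(r0 + (-2:2))          # 0-based pixel rows on the line
    m[cbind(pmin(pmax(rows, 0), 59) + 1, cc + 1)] <- TRUE
  }
  for (method in c("endpoints", "least_squares")) {
    f <- fit_row_line(c(0, 60), cs_mask(m), method = method)
    pred <- f$slope * cols + f$intercept
    expect_lt(sqrt(mean((pred - (0.01 * cols + 25))^2)), 0.5)
  }
})

test_that("extract_rows finds every row on a clean field and maps back", {
  cfg <- field_config(width_m = 6, height_m = 6, seed = 13)
  f <- generate_field(cfg)
  rs <- extract_rows(f$raster)
  expect_equal(nrow(rs$rows), nrow(f$truth$rows))
  expect_true(all(abs(rs$rows$slope) <= 0.2))
  all_err <- numeric(0)
  ## each fitted line, mapped to the original frame, hugs a truth row
  d <- dim(f$raster$pixels)[1:2]
  for (i in seq_len(nrow(rs$rows))) {
    r <- rs$rows[i, ]
    cols <- seq(r$col_start, r$col_end, length.out = 30)
    o <- rotate_map_points((cols + 0.5) * cfg$gsd,
                           (r$slope * cols + r$intercept + 0.5) * cfg$gsd,
                           rs$theta_deg, d, cfg$gsd, inverse = TRUE)
    derr <- abs(o$y - sort(f$truth$rows$ay)[i])
    expect_lt(mean(derr) / cfg$gsd, 4)   # every line close
  }
})

test_that("weed-free row recovery is exact for several seeds", {
  for (s in 14:16) {
    cfg <- field_config(width_m = 5, height_m = 5, seed = s)
    f <- generate_field(cfg)
    rs <- extract_rows(f$raster)
    expect_equal(nrow(rs$rows), nrow(f$truth$rows))
  }
})
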