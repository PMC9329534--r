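test_that("polarity inversion maps dark bands to positive signal", {
  img <- matrix(5, 4, 4)
  expect_identical(invert_gel(img, "signal_positive"), img)
  expect_true(all(invert_gel(img) == 0))  # constant c -> max - c = 0
  g <- gen_gel_lane(noise_sd = 0, background = NULL)
  inv <- invert_gel(g$image)
  # after inversion the band pixels carry the largest values
  expect_true(which.max(lane_profile(inv)) %in% 195:205)
  expect_true(which.min(lane_profile(g$image)) %in% 195:205)
})

test_that("rolling-ball subtraction matches a brute-force opening and its basic laws", {
  # constant image -> all zeros, any radius
  flat <- matrix(1000, 120, 30)
  expect_true(all(subtract_background(flat, 10) == 0))

  # single bright pixel survives a radius-2 ball (7x7 grid, brute force)
  px <- matrix(0.001, 7, 7)
  px[4, 4] <- 500
  got <- subtract_background(px, 2, smooth = 1)
  want <- brute_rolling_ball(px, 2)
  expect_equal(got, want, tolerance = 1e-10)
  expect_gt(got[4, 4], 490)

  # brute-force agreement on a random image
  set.seed(11)
  rnd <- matrix(runif(15 * 12, 0, 100), 15, 12)
  expect_equal(subtract_background(rnd, 3, smooth = 1),
               brute_rolling_ball(rnd, 3), tolerance = 1e-10)

  # subtraction never increases any pixel
  g <- gen_gel_lane(seed = 3)
  inv <- invert_gel(g$image)
  out <- subtract_background(inv, 50)
  expect_true(all(out <= inv + 1e-9))
  expect_lte(sum(out), sum(inv))
})

test_that("lane profiles are column sums with the obvious linearity", {
  z <- matrix(0, 10, 6)
  expect_identical(lane_profile(z), rep(0, 10))
  m <- matrix(as.numeric(1:30), 10, 3)
  expect_identical(lane_profile(m, c(2, 3)), m[, 2])
  two <- cbind(m, m)
  expect_equal(lane_profile(two), 2 * lane_profile(m))
  expect_error(lane_profile(m, c(3, 3)), "non-empty")
})

test_that("band quantification handles symmetry, edge cases and errors", {
  prof <- c(rep(0, 10), rep(4, 5), rep(0, 10), rep(4, 5), rep(0, 10))
  q <- quantify_bands(prof, c(11, 16), c(26, 31))
  expect_equal(q$fraction_folded, 0.5)
  prof2 <- c(rep(2, 5), rep(0, 20))
  q2 <- quantify_bands(prof2, c(1, 6), c(10, 15))
  expect_equal(q2$fraction_folded, 1)
  expect_error(quantify_bands(prof, c(11, 20), c(15, 25)), "disjoint")
  expect_error(quantify_bands(rep(0, 30), c(1, 5), c(10, 15)), "Empty lane")
})

test_that("the folded fraction is invariant under a global gain change", {
  g <- gen_gel_lane(seed = 5)
  lanes <- tibble::tibble(lane = 1, col_start = 1, col_end = 81)
  q1 <- quantify_gel(g$image, lanes, c(170, 231), c(370, 431))
  q2 <- quantify_gel(g$image * 3.7, lanes, c(170, 231), c(370, 431))
  expect_equal(q1$fraction_folded, q2$fraction_folded, tolerance = 1e-12)
})

test_that("synthetic gels are recovered: exact when clean, within tolerance with background and noise", {
  lanes <- tibble::tibble(lane = 1, col_start = 1, col_end = 81)
  win_f <- c(170, 231); win_u <- c(370, 431)

  clean <- gen_gel_lane(noise_sd = 0, background = NULL)
  q0 <- quantify_gel(clean$image, lanes, win_f, win_u, radius = NULL)
  expect_equal(q0$fraction_folded, clean$truth$fraction_folded,
               tolerance = 1e-6)

  noisy <- gen_gel_lane(seed = 21)
  q1 <- quantify_gel(noisy$image, lanes, win_f, win_u, radius = 50)
  expect_lt(abs(q1$fraction_folded - 0.70), 0.03)

  # monotonicity: larger folded integral -> larger recovered fraction
  fr <- vapply(c(3e6, 5e6, 7e6, 9e6), function(fi) {
    g <- gen_gel_lane(band_integrals = c(fi, 3e6), seed = 9)
    quantify_gel(g$image, lanes, win_f, win_u, radius = 50)$fraction_folded
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("band-window auto-detection finds the two synthetic bands", {
  g <- gen_gel_lane(noise_sd = 0)
  prof <- lane_profile(subtract_background(invert_gel(g$image), 50))
  w <- find_band_windows(prof, half_width = 30, min_gap = 50)
  expect_true(w$first[1] <= 200 && 200 < w$first[2])
  expect_true(w$second[1] <= 400 && 400 < w$second[2])
})

test_that("gel images survive a 16-bit TIFF round trip", {
  g <- gen_gel_lane(seed = 2)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_gel(g$image / 65535, path)
  back <- read_gel(path)
  expect_equal(dim(back), dim(g$image))
  expect_lt(max(abs(back * 65535 - g$image)), 1)
})
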