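test_that("every generator is bit-reproducible for a fixed seed", {
  expect_identical(gen_gel_lane(seed = 3)$image, gen_gel_lane(seed = 3)$image)
  expect_identical(gen_timecourse_panel(seed = 3),
                   gen_timecourse_panel(seed = 3))
  t1 <- gen_toy_trajectory(n_frames = 4, seed = 3)
  t2 <- gen_toy_trajectory(n_frames = 4, seed = 3)
  expect_identical(t1$trajectory$frames, t2$trajectory$frames)
  expect_identical(gen_descriptor_rate_set(-1, 2, 0.5, seed = 3),
                   gen_descriptor_rate_set(-1, 2, 0.5, seed = 3))
  # generators do not disturb the global RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_gel_lane(seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("gel ground truth carries the band parameters and flags overlap", {
  g <- gen_gel_lane(noise_sd = 0)
  expect_equal(g$truth$fraction_folded, 0.7)
  expect_false(g$truth$overlap_warning)
  expect_warning(
    o <- gen_gel_lane(band_centers = c(200, 210), band_sigmas = c(8, 8),
                      noise_sd = 0),
    "3 sigma"
  )
  expect_true(o$truth$overlap_warning)
  # dark-band polarity: band rows are darker than their surroundings
  expect_lt(mean(g$image[195:205, ]), mean(g$image[100:110, ]))
})

test_that("the time-course panel reproduces reference kinetics and the non-folder path", {
  panel <- gen_timecourse_panel(noise_sd = 0, n_replicates = 1)
  wt <- panel[panel$construct == "WT", ]
  fit <- fit_folding(wt)
  expect_equal(fit$k, 0.123, tolerance = 1e-6)
  expect_equal(fit$A, 0.885, tolerance = 1e-6)

  nf <- panel[panel$construct == "AGPGAx4_L2L3", ]
  expect_true(all(nf$fraction_folded == 0))
  expect_error(fit_folding(nf), "unidentifiable")
})

test_that("toy trajectories encode their contact regime and jitter schedule", {
  sep <- gen_toy_trajectory(jitter_sd = c(loop = 0, rest = 0),
                            inter_loop_gap = 50, n_frames = 2, seed = 1)
  expect_identical(sep$truth$contact_regime, "separated")
  sel <- loop_selection(sep$trajectory$topology)
  xyz <- sep$trajectory$frames[[1]]
  expect_lt(contact_area(xyz, sep$trajectory$topology$radius,
                         sel$loop2, sel$loop3, n_points = 240), 1e-9)

  touch <- gen_toy_trajectory(inter_loop_gap = 5, n_frames = 2, seed = 1)
  expect_identical(touch$truth$contact_regime, "touching")

  toy <- gen_toy_trajectory(n_frames = 2, seed = 1)
  expect_equal(toy$truth$expected_rmsf[49], 0.5 * sqrt(3))
  expect_equal(toy$truth$expected_rmsf[1], 0.1 * sqrt(3))
  expect_identical(length(toy$truth$sd_per_residue), 125L)
})

test_that("descriptor/rate sets regress back to their generating line", {
  clean <- gen_descriptor_rate_set(-0.01, 2, noise_sd = 0, n = 14)
  fit <- descriptor_rate_regression(clean)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$n, 14L)

  two <- gen_descriptor_rate_set(-0.01, 2, noise_sd = 0, n = 2)
  expect_error(descriptor_rate_regression(two), "3 points")
})

test_that("the construct panel holds the fifteen named variants with correct lengths", {
  panel <- construct_panel()
  expect_identical(nrow(panel), 15L)
  expect_identical(sum(panel$construct == "WT"), 1L)
  base_len <- nchar(ompx_mature())
  expect_identical(nchar(panel$sequence[panel$construct == "WT"]), base_len)
  expect_identical(nchar(panel$sequence[panel$construct == "SPLATx4_L2L3"]),
                   base_len + 40L)
  expect_identical(nchar(panel$sequence[panel$construct == "AGPGAx2_L3"]),
                   base_len + 10L)
  expect_identical(anyDuplicated(panel$construct), 0L)
  # panel labels match the reference parameter table
  expect_setequal(panel$construct, reference_folding_params()$construct)
})
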