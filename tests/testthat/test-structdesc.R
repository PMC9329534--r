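test_that("SASA quadrature matches analytic spheres and closed-form two-sphere cases", {
  # isolated sphere
  one <- matrix(0, 1, 3)
  got <- sasa(one, 1.7)
  expect_lt(abs(got - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)

  # two atoms far apart: strictly additive
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sasa(far, c(1.7, 1.5)),
               sasa(far[1, , drop = FALSE], 1.7) +
                 sasa(far[2, , drop = FALSE], 1.5), tolerance = 1e-12)

  # overlapping spheres vs the closed-form lens formula
  for (d in c(2.0, 3.5, 5.0)) {
    pair <- rbind(c(0, 0, 0), c(d, 0, 0))
    got <- sasa(pair, c(1.7, 1.5))
    want <- two_sphere_sasa(1.7, 1.5, d)
    expect_lt(abs(got - want) / want, 0.02)
  }

  # rotation/translation invariance within quadrature discretization
  # (chain-like geometry at bonded spacing, as in a backbone trace)
  set.seed(4)
  cloud <- cbind(3.8 * (1:10), sin(1:10), cos(1:10))
  radii <- runif(10, 1.4, 1.9)
  s0 <- sasa(cloud, radii)
  for (i in 1:3) {
    s1 <- sasa(random_rigid_copy(cloud), radii)
    expect_lt(abs(s1 - s0) / s0, 0.005)
  }

  expect_warning(s_empty <- sasa(cloud, radii, group = integer(0)), "Empty")
  expect_identical(s_empty, 0)
})

test_that("contact area is a symmetric, bounded half-buried-surface measure", {
  set.seed(8)
  a_xyz <- matrix(rnorm(12, sd = 1.5), 4, 3)
  b_xyz <- sweep(matrix(rnorm(12, sd = 1.5), 4, 3), 2, c(4, 0, 0), "+")
  coords <- rbind(a_xyz, b_xyz)
  radii <- rep(1.7, 8)

  ab <- contact_area(coords, radii, 1:4, 5:8)
  ba <- contact_area(coords, radii, 5:8, 1:4)
  expect_identical(ab, ba)

  # bounded by the smaller isolated-group SASA
  expect_lte(ab, min(sasa(a_xyz, radii[1:4]), sasa(b_xyz, radii[5:8])))

  # separated groups have zero contact
  far <- rbind(a_xyz, sweep(b_xyz, 2, c(100, 0, 0), "+"))
  expect_lt(contact_area(far, radii, 1:4, 5:8), 1e-9)

  expect_error(contact_area(coords, radii, 1:4, 4:8), "disjoint")

  # the three-term definition itself, evaluated independently at high
  # resolution, reproduces contact_area at its default quadrature
  hi <- function(idx) sasa(coords[idx, , drop = FALSE], radii[idx],
                           n_points = 10000)
  want <- max(0.5 * (hi(1:4) + hi(5:8) - hi(1:8)), 0)
  got <- contact_area(coords, radii, 1:4, 5:8, n_points = 10000)
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(abs(contact_area(coords, radii, 1:4, 5:8) - want) /
              max(want, 1), 0.02)
})

test_that("hydrogen bonds obey the distance and angle gates", {
  expect_identical(hbond_count(make_hbond_frame(2.9, 180)), 1L)
  expect_identical(hbond_count(make_hbond_frame(5.0, 180)), 0L)
  expect_identical(hbond_count(make_hbond_frame(2.9, 90)), 0L)
  # just inside / outside the angle cutoff
  expect_identical(hbond_count(make_hbond_frame(2.9, 155)), 1L)
  expect_identical(hbond_count(make_hbond_frame(2.9, 145)), 0L)

  # selection gating: both partners must lie inside the span
  fr <- make_hbond_frame(2.9, 180)
  expect_identical(hbond_count(fr, selection = 1:4), 0L)
  expect_identical(hbond_count(fr, selection = 1:5), 1L)

  # invariant under atom reordering
  perm <- fr[sample(nrow(fr)), ]
  expect_identical(hbond_count(perm), 1L)

  # inferred amide hydrogens: drop the explicit H, keep C(i-1)/CA geometry
  no_h <- fr[fr$element != "H", ]
  no_h$resid[no_h$resid == 5L] <- 2L
  # residue 2 has no N, residue 1 has no preceding C: donor inference yields
  # no donors, count 0 (not an error)
  expect_identical(hbond_count(no_h), 0L)
})

test_that("RMSF is zero for rigid motion and recovers isotropic jitter amplitudes", {
  toy0 <- gen_toy_trajectory(jitter_sd = c(loop = 0, rest = 0),
                             n_frames = 10, rigid_motion = TRUE, seed = 2)
  r0 <- rmsf(toy0$trajectory)
  expect_lt(max(r0$rmsf), 1e-6)

  toy <- gen_toy_trajectory(n_frames = 400, seed = 12)
  r <- rmsf(toy$trajectory)
  loops <- c(49:59, 91:103)
  expect_lt(abs(mean(r$rmsf[r$resid %in% loops]) - 0.5 * sqrt(3)) /
              (0.5 * sqrt(3)), 0.05)
  expect_lt(abs(mean(r$rmsf[!r$resid %in% loops]) - 0.1 * sqrt(3)) /
              (0.1 * sqrt(3)), 0.05)

  # applying one global rigid transform to every frame changes nothing
  tr <- gen_toy_trajectory(n_frames = 20, seed = 7)$trajectory
  r1 <- rmsf(tr)
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  moved <- trajectory(tr$topology, lapply(tr$frames, function(f) {
    sweep(f %*% Q, 2, c(5, -2, 9), "+")
  }))
  r_moved <- rmsf(moved)
  expect_equal(r_moved$rmsf, r1$rmsf, tolerance = 1e-6)

  line <- matrix(c(1:5, rep(0, 10)), 5, 3)
  frames <- list(line, line + 0.1)
  topo <- tibble::tibble(atom = "CA", element = "C", resid = 1:5,
                         resname = "GLY")
  expect_error(rmsf(trajectory(topo, frames)), "degenerate")
})

test_that("descriptor series and summaries respond to the loop-contact regime", {
  touching <- gen_toy_trajectory(jitter_sd = c(loop = 0.05, rest = 0.05),
                                 inter_loop_gap = 5, n_frames = 3, seed = 1)
  apart <- gen_toy_trajectory(jitter_sd = c(loop = 0.05, rest = 0.05),
                              inter_loop_gap = 50, n_frames = 3, seed = 1)
  s_touch <- descriptor_series(touching$trajectory, n_points = 240)
  s_apart <- descriptor_series(apart$trajectory, n_points = 240)
  expect_gt(mean(s_touch$contact_l2_l3_A2), 50)
  expect_lt(mean(s_apart$contact_l2_l3_A2), 1e-6)
  # loops always touch their chain neighbours in "rest"
  expect_gt(mean(s_touch$contact_loops_rest_A2), 0)

  summ <- summarise_descriptors(s_touch)
  expect_setequal(summ$descriptor,
                  c("contact_l2_l3_A2", "contact_loops_rest_A2",
                    "hbonds_l2", "hbonds_l3"))
  expect_true(all(summ$n_frames == 3))
})

test_that("descriptor-rate regression recovers exact lines and rejects degenerate input", {
  exact <- tibble::tibble(descriptor = 1:10,
                          rate = -0.01 * (1:10) + 0.25)
  fit <- descriptor_rate_regression(exact)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.25, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(descriptor_rate_regression(exact[1:2, ]), "3 points")
  const <- tibble::tibble(descriptor = rep(1, 5), rate = rnorm(5))
  expect_error(descriptor_rate_regression(const), "variance")

  # permutation null: R^2 collapses when y is shuffled independently of x
  set.seed(31)
  x <- seq(0, 100, length.out = 60)
  y <- -0.01 * x + 2 + rnorm(60, sd = 0.05)
  r2_perm <- replicate(1000, {
    descriptor_rate_regression(
      tibble::tibble(descriptor = x, rate = sample(y))
    )$r_squared
  })
  r2_true <- descriptor_rate_regression(
    tibble::tibble(descriptor = x, rate = y)
  )$r_squared
  expect_gt(r2_true, quantile(r2_perm, 0.999))
  expect_lt(median(r2_perm), 0.05)
})
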