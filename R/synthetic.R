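# Synthetic-data generators with known ground truth: gel lanes, folding
# time-course panels, toy trajectories and descriptor/rate sets. Every
# generator is a pure function of its parameters plus a seed (one seeded RNG
# stream per call via withr; the global RNG state is never touched), and each
# returns the exact parameters that produced the artifact so the expected
# downstream answer can be computed without re-running the generator.

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code() else withr::with_seed(seed, code())
}

#' Generate a synthetic gel lane image
#'
#' Emulates a Coomassie-stained SDS-PAGE lane imaged at 16-bit depth: dark
#' protein bands (Gaussian along the migration axis, uniform across the lane
#' width) over a smooth bright background (tilted plane plus a broad
#' Gaussian illumination bump) with Gaussian shot-like noise. Intensities
#' are on the 16-bit scale (0-65535). Default band integrals correspond to a
#' folded fraction of 0.70.
#'
#' @param band_centers Band centre rows (pixels; default folded at 200,
#'   unfolded at 400 — band order is configurable, not normative).
#' @param band_integrals Total integrated density of each band
#'   (intensity x pixels).
#' @param band_sigmas Gaussian widths along the migration axis (pixels);
#'   keep well below the rolling-ball radius for recoverability.
#' @param n_rows,n_cols Image size (migration axis x lane width).
#' @param background List with `offset`, `slope_row`, `slope_col` (total
#'   intensity change across the image), `gauss_amp`, `gauss_center`,
#'   `gauss_sigma`; `NULL` for a flat background at intensity 45000.
#' @param noise_sd Gaussian noise sd in intensity units (default 150, about
#'   0.2 percent of full scale, typical of cooled-CCD gel documentation
#'   systems).
#' @param seed Optional integer seed (bit-reproducible output).
#' @return List with `image` (matrix, dark-band polarity) and `truth` (band
#'   parameters, the implied `fraction_folded`, background, noise, seed, and
#'   an `overlap_warning` flag set when bands sit closer than 3 sigma).
#' @export
gen_gel_lane <- function(band_centers = c(200, 400),
                         band_integrals = c(7e6, 3e6),
                         band_sigmas = c(8, 8),
                         n_rows = 600, n_cols = 80,
                         background = list(offset = 45000, slope_row = 3000,
                                           slope_col = 1000, gauss_amp = 3000,
                                           gauss_center = 300,
                                           gauss_sigma = 350),
                         noise_sd = 150, seed = NULL) {
  stopifnot(length(band_centers) == length(band_integrals),
            length(band_centers) == length(band_sigmas),
            all(band_centers >= 1 & band_centers <= n_rows), noise_sd >= 0)
  overlap <- FALSE
  if (length(band_centers) >= 2) {
    gaps <- diff(sort(band_centers))
    if (any(gaps < 3 * max(band_sigmas))) {
      warn("Bands are closer than 3 sigma; integrals may not separate cleanly.")
      overlap <- TRUE
    }
  }
  rows <- seq_len(n_rows)
  signal_profile <- rowSums(vapply(seq_along(band_centers), function(b) {
    band_integrals[b] / n_cols * dnorm(rows, band_centers[b], band_sigmas[b])
  }, numeric(n_rows)))
  signal <- matrix(signal_profile, n_rows, n_cols)
  if (is.null(background)) {
    bg <- matrix(45000, n_rows, n_cols)
  } else {
    cols <- seq_len(n_cols)
    bg <- outer(rows / n_rows, rep(1, n_cols)) * background$slope_row +
      outer(rep(1, n_rows), cols / n_cols) * background$slope_col +
      background$offset +
      background$gauss_amp *
        exp(-((rows - background$gauss_center)^2) /
              (2 * background$gauss_sigma^2))
  }
  img <- with_seed_maybe(seed, function() {
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_rows * n_cols, sd = noise_sd), n_rows, n_cols)
    } else 0
    pmin(pmax(bg - signal + noise, 0), 65535)
  })
  list(
    image = img,
    truth = list(
      band_centers = band_centers, band_integrals = band_integrals,
      band_sigmas = band_sigmas,
      fraction_folded = band_integrals[1] / sum(band_integrals),
      background = background, noise_sd = noise_sd, seed = seed,
      overlap_warning = overlap
    )
  )
}

#' Generate folding time courses for a construct panel
#'
#' Vectorizes [simulate_timecourse()] over a parameter table, one sub-seed
#' per construct (seed + row index). A row with `folds = FALSE` (or `NA`
#' rate) represents a construct that never folds: its fractions are noise
#' around zero, which with zero noise exercises the "rate unidentifiable"
#' error path of [fit_folding()].
#'
#' @param params Parameter table with columns `construct`, `k`, `yield` and
#'   optionally `folds`; defaults to [reference_folding_params()].
#' @param times,noise_sd,n_replicates As in [simulate_timecourse()].
#' @param seed Optional integer seed.
#' @return Tibble with columns `construct`, `time_min`, `replicate`,
#'   `fraction_folded`.
#' @export
gen_timecourse_panel <- function(params = reference_folding_params(),
                                 times = c(0, 1, 2, 4, 8, 16, 32, 64),
                                 noise_sd = 0.02, n_replicates = 3,
                                 seed = NULL) {
  stopifnot(all(c("construct", "k", "yield") %in% names(params)))
  folds <- if ("folds" %in% names(params)) params$folds else !is.na(params$k)
  purrr::map_dfr(seq_len(nrow(params)), function(i) {
    sub_seed <- if (is.null(seed)) NULL else seed + i
    if (isTRUE(folds[i])) {
      simulate_timecourse(params$k[i], params$yield[i], times = times,
                          noise_sd = noise_sd, n_replicates = n_replicates,
                          seed = sub_seed, construct = params$construct[i])
    } else {
      # Never folds: pure (clamped) noise around zero.
      tc <- simulate_timecourse(1, 0, times = times, noise_sd = noise_sd,
                                n_replicates = n_replicates, seed = sub_seed,
                                construct = params$construct[i])
      tc
    }
  })
}

#' Generate a toy hairpin trajectory with known fluctuation amplitudes
#'
#' A backbone-like chain (4 pseudo-atoms N, CA, C, O per residue, 3.8
#' Angstrom CA spacing) folded into a hairpin: the first arm carries the
#' loop-2 span, the returning arm carries the loop-3 span, and the two arms
#' face each other across `inter_loop_gap` Angstrom, so the gap parameter
#' switches the loops between touching and well-separated contact regimes.
#' Frames are the reference structure plus independent Gaussian jitter with
#' a per-residue sd schedule, optionally wrapped in a random global rigid
#' transform per frame (to exercise superposition).
#'
#' @param n_residues Chain length (default 125; the hairpin turns after
#'   residue 75).
#' @param loop2,loop3 Residue spans (defaults 49-59 and 91-103).
#' @param jitter_sd Either a length-2 named vector `c(loop = , rest = )` of
#'   per-coordinate jitter sds (Angstrom; defaults loop 0.5, rest 0.1) or a
#'   full per-residue vector.
#' @param inter_loop_gap Arm separation in Angstrom (default 5: loops in
#'   contact; 50: separated).
#' @param n_frames Number of frames (default 100).
#' @param rigid_motion Apply a random global rotation + translation to each
#'   frame (default FALSE).
#' @param seed Optional integer seed.
#' @return List with `trajectory` (a [trajectory()]) and `truth` (per-residue
#'   sd schedule, expected per-residue RMSF `sd * sqrt(3)`, the gap, and the
#'   expected contact regime).
#' @export
gen_toy_trajectory <- function(n_residues = 125, loop2 = 49:59,
                               loop3 = 91:103,
                               jitter_sd = c(loop = 0.5, rest = 0.1),
                               inter_loop_gap = 5, n_frames = 100,
                               rigid_motion = FALSE, seed = NULL) {
  stopifnot(n_frames >= 2, n_residues >= max(loop3))
  turn <- 75L
  stopifnot(max(loop2) <= turn, min(loop3) > turn)
  if (length(jitter_sd) == n_residues) {
    sd_res <- jitter_sd
  } else {
    stopifnot(all(c("loop", "rest") %in% names(jitter_sd)))
    sd_res <- rep(jitter_sd[["rest"]], n_residues)
    sd_res[c(loop2, loop3)] <- jitter_sd[["loop"]]
  }
  ca <- t(vapply(seq_len(n_residues), function(i) {
    if (i <= turn) c(3.8 * i, 0, 0)
    else c(3.8 * (2 * turn - i), inter_loop_gap, 0)
  }, numeric(3)))
  offsets <- list(N = c(-1.2, 0, 0.4), CA = c(0, 0, 0),
                  C = c(1.2, 0, 0.4), O = c(1.3, 0, 1.6))
  topology <- purrr::map_dfr(seq_len(n_residues), function(i) {
    tibble::tibble(atom = names(offsets),
                   element = c("N", "C", "C", "O"),
                   resid = i, resname = "GLY")
  })
  ref <- do.call(rbind, purrr::map(seq_len(n_residues), function(i) {
    t(vapply(offsets, function(o) ca[i, ] + o, numeric(3)))
  }))
  sd_atom <- rep(sd_res, each = length(offsets))
  frames <- with_seed_maybe(seed, function() {
    purrr::map(seq_len(n_frames), function(f) {
      fr <- ref + matrix(rnorm(length(ref), sd = rep(sd_atom, 3)),
                         nrow(ref), 3)
      if (rigid_motion) {
        R <- random_rotation()
        fr <- sweep(fr %*% R, 2, stats::runif(3, -20, 20), "+")
      }
      fr
    })
  })
  list(
    trajectory = trajectory(topology, frames),
    truth = list(
      sd_per_residue = sd_res,
      expected_rmsf = sd_res * sqrt(3),
      inter_loop_gap = inter_loop_gap,
      contact_regime = if (inter_loop_gap > 2 * (1.7 + 1.4)) "separated"
                       else "touching",
      loop2 = loop2, loop3 = loop3, seed = seed
    )
  )
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a linear descriptor/rate dataset
#'
#' `y = slope * x + intercept + Gaussian noise` over an evenly spaced
#' descriptor grid — the synthetic stand-in for per-construct descriptor
#' means plotted against folding rates.
#'
#' @param slope,intercept Line parameters.
#' @param noise_sd Gaussian noise sd on y.
#' @param n Number of points (>= 3 required downstream).
#' @param x_range Range of the descriptor values (default 0-100).
#' @param seed Optional integer seed.
#' @return Tibble with columns `descriptor`, `rate`, plus the truth as
#'   attribute `truth`.
#' @export
gen_descriptor_rate_set <- function(slope, intercept, noise_sd = 0, n = 14,
                                    x_range = c(0, 100), seed = NULL) {
  stopifnot(n >= 2)
  x <- seq(x_range[1], x_range[2], length.out = n)
  y <- with_seed_maybe(seed, function() {
    slope * x + intercept + rnorm(n, sd = noise_sd)
  })
  out <- tibble::tibble(descriptor = x, rate = y)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' The loop-insertion construct panel
#'
#' The 15 constructs of the OmpX loop-insertion study: wildtype plus SPLAT
#' and AGPGA inserted as 1, 2 or 4 tandem copies into loop 2 or loop 3, and
#' the two 4x double-loop constructs.
#'
#' @param base Mature base sequence (default packaged OmpX).
#' @return Tibble with columns `construct`, `insert`, `repeats`, `loops`
#'   (`"L2"`, `"L3"`, `"L2L3"` or `NA` for wildtype) and `sequence` (built
#'   with [build_construct()]).
#' @export
construct_panel <- function(base = ompx_mature()) {
  single <- tidyr::expand_grid(insert = c("SPLAT", "AGPGA"),
                               loops = c("L2", "L3"),
                               repeats = c(1L, 2L, 4L))
  panel <- dplyr::bind_rows(
    tibble::tibble(insert = NA_character_, loops = NA_character_,
                   repeats = NA_integer_),
    single,
    tibble::tibble(insert = c("SPLAT", "AGPGA"), loops = "L2L3",
                   repeats = 4L)
  )
  panel %>%
    dplyr::mutate(
      construct = dplyr::if_else(
        is.na(.data$insert), "WT",
        paste0(.data$insert, "x", .data$repeats, "_", .data$loops)
      ),
      sequence = purrr::pmap_chr(
        list(.data$insert, .data$loops, .data$repeats),
        function(ins, lp, rep) {
          if (is.na(ins)) return(as.character(build_construct(base)))
          loops <- switch(lp, L2 = 2, L3 = 3, L2L3 = c(2, 3))
          as.character(build_construct(base, tibble::tibble(
            loop = loops, insert = ins, repeats = rep
          )))
        }
      )
    ) %>%
    dplyr::select("construct", "insert", "repeats", "loops", "sequence")
}

#' Reference folding parameters for the construct panel
#'
#' The measured folding rates and yields (with their reported errors) for
#' the 15-construct OmpX loop-insertion panel, as determined by SDS-PAGE
#' heat-modifiability densitometry and single-exponential fitting. The
#' AGPGAx4 double-loop construct did not fold in that assay (`folds =
#' FALSE`, NA parameters). These values serve as simulation inputs and
#' self-consistency references throughout the package.
#'
#' @return Tibble with columns `construct`, `insert`, `repeats`, `loops`,
#'   `k` (min^-1), `k_err`, `yield`, `yield_err`, `folds`.
#' @export
reference_folding_params <- function() {
  tibble::tribble(
    ~construct,      ~insert, ~repeats, ~loops,  ~k,    ~k_err, ~yield, ~yield_err,
    "WT",            NA,      NA_integer_, NA,   0.123, 0.007,  0.885,  0.017,
    "SPLATx1_L2",    "SPLAT", 1L,       "L2",    0.081, 0.002,  0.916,  0.009,
    "SPLATx2_L2",    "SPLAT", 2L,       "L2",    0.061, 0.003,  0.902,  0.020,
    "SPLATx4_L2",    "SPLAT", 4L,       "L2",    0.048, 0.004,  0.874,  0.028,
    "AGPGAx1_L2",    "AGPGA", 1L,       "L2",    0.103, 0.006,  0.897,  0.017,
    "AGPGAx2_L2",    "AGPGA", 2L,       "L2",    0.091, 0.006,  0.877,  0.021,
    "AGPGAx4_L2",    "AGPGA", 4L,       "L2",    0.064, 0.005,  0.860,  0.028,
    "SPLATx1_L3",    "SPLAT", 1L,       "L3",    0.142, 0.005,  0.896,  0.011,
    "SPLATx2_L3",    "SPLAT", 2L,       "L3",    0.116, 0.004,  0.924,  0.010,
    "SPLATx4_L3",    "SPLAT", 4L,       "L3",    0.068, 0.001,  0.905,  0.006,
    "AGPGAx1_L3",    "AGPGA", 1L,       "L3",    0.216, 0.007,  0.909,  0.008,
    "AGPGAx2_L3",    "AGPGA", 2L,       "L3",    0.186, 0.007,  0.878,  0.009,
    "AGPGAx4_L3",    "AGPGA", 4L,       "L3",    0.141, 0.004,  0.888,  0.009,
    "SPLATx4_L2L3",  "SPLAT", 4L,       "L2L3",  0.039, 0.003,  0.790,  0.030,
    "AGPGAx4_L2L3",  "AGPGA", 4L,       "L2L3",  NA,    NA,     NA,     NA
  ) %>%
    dplyr::mutate(folds = !is.na(.data$k))
}
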