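# Trajectory descriptors: Shrake-Rupley SASA by deterministic sphere-point
# quadrature, buried-surface contact area between residue groups, geometric
# hydrogen-bond counting, and per-residue RMSF after iterative Kabsch
# superposition. Trajectories are lightweight S3 objects: a topology tibble
# plus a list of n_atoms x 3 coordinate matrices (Angstrom).

#' Construct a trajectory object
#'
#' @param topology Tibble with one row per atom: `atom` (name), `element`,
#'   `resid` (1-based residue index), `resname`, and optionally `radius`
#'   (vdW, Angstrom; filled from a Bondi-type table by element if absent).
#' @param frames List of numeric matrices, each `n_atoms x 3`, all sharing
#'   the topology's atom order.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(is.data.frame(topology),
            all(c("atom", "element", "resid") %in% names(topology)),
            is.list(frames), length(frames) >= 1L)
  n <- nrow(topology)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3L && all(is.finite(f)), logical(1))
  if (!all(ok)) {
    abort("Every frame must be a finite n_atoms x 3 matrix matching the topology.")
  }
  topology <- tibble::as_tibble(topology)
  if (!"radius" %in% names(topology)) {
    topology$radius <- vdw_radius(topology$element)
  }
  if (any(topology$radius <= 0)) abort("vdW radii must be positive.")
  structure(list(topology = topology, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms, %d residues\n",
              length(x$frames), nrow(x$topology),
              dplyr::n_distinct(x$topology$resid)))
  invisible(x)
}

# Deterministic quasi-uniform point set on the unit sphere (Fibonacci
# spiral). Determinism keeps SASA values bit-stable across runs.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point quadrature: each atom is expanded by the probe radius and
#' covered with a deterministic Fibonacci point set; a point is accessible
#' when it lies outside every other expanded sphere among the atoms present
#' in `coords`. The group's SASA is the accessible-point fraction times
#' \eqn{4\pi(r_i + probe)^2}, summed over the group atoms. Occlusion is
#' tested only against the atoms supplied: to evaluate a subset "alone",
#' pass only that subset.
#'
#' @param coords Numeric `n x 3` matrix of coordinates (Angstrom).
#' @param radii vdW radii, length `n`.
#' @param group Indices of atoms whose area is summed (default all).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Quadrature points per atom (default 960).
#' @return Area in Angstrom^2.
#' @export
sasa <- function(coords, radii, group = seq_len(nrow(coords)),
                 probe = 1.4, n_points = 960) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, length(radii) == nrow(coords),
            probe >= 0, n_points >= 92)
  if (length(group) == 0L) {
    warn("Empty atom group: SASA is 0.")
    return(0)
  }
  pts <- fibonacci_sphere(n_points)
  rr <- radii + probe
  total <- 0
  for (i in group) {
    sph <- sweep(pts * rr[i], 2, coords[i, ], "+")
    # Only neighbours that can occlude points on sphere i matter.
    d2 <- rowSums(sweep(coords, 2, coords[i, ], "-")^2)
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(nrow(coords)) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(sph[acc, , drop = FALSE], 2, coords[j, ], "-")
      acc[acc] <- rowSums(dj^2) >= rr[j]^2
    }
    total <- total + mean(acc) * 4 * pi * rr[i]^2
  }
  total
}

#' Contact area between two atom groups
#'
#' Half the buried surface area:
#' \eqn{\tfrac12[SASA(A) + SASA(B) - SASA(A \cup B)]}, each term evaluated
#' with only the named atoms present. Symmetric in (A, B); clamped at zero
#' against quadrature noise; zero for well-separated groups.
#'
#' @inheritParams sasa
#' @param a,b Disjoint index vectors into `coords`.
#' @return Contact area in Angstrom^2.
#' @export
contact_area <- function(coords, radii, a, b, probe = 1.4, n_points = 960) {
  if (length(intersect(a, b)) > 0L) {
    abort("Atom groups must be disjoint.")
  }
  s_a <- sasa(coords[a, , drop = FALSE], radii[a], probe = probe,
              n_points = n_points)
  s_b <- sasa(coords[b, , drop = FALSE], radii[b], probe = probe,
              n_points = n_points)
  ab <- sort(c(a, b))  # fixed order keeps contact_area(A,B) == contact_area(B,A) bit-identical
  s_ab <- sasa(coords[ab, , drop = FALSE], radii[ab], probe = probe,
               n_points = n_points)
  max(0.5 * (s_a + s_b - s_ab), 0)
}

#' Count hydrogen bonds within a residue selection
#'
#' Geometric criterion: a donor-acceptor pair is counted when both residues
#' lie inside the selection, the donor and acceptor belong to different
#' residues, the donor-acceptor distance is at most `dist_cutoff` and the
#' donor-H...acceptor angle is at least `angle_cutoff`. Backbone donors are
#' amide nitrogens; backbone acceptors are carbonyl oxygens. When the frame
#' carries no amide hydrogens they are placed by the idealized bisector rule
#' (H on the bisector of the C(i-1)-N and CA-N directions, reversed, at
#' 1.01 Angstrom); the N-terminal nitrogen is skipped in that case. With
#' `backbone_only = FALSE`, side-chain N/O atoms also act as donors (if an
#' attached hydrogen is present) and acceptors.
#'
#' @param frame Tibble with columns `atom`, `element`, `resid` and
#'   coordinates `x`, `y`, `z` (one MD frame).
#' @param selection Residue indices defining "within the loop"; both partners
#'   must fall inside (default all residues).
#' @param dist_cutoff Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cutoff Donor-H...acceptor angle cutoff, degrees (default 150).
#' @param backbone_only Restrict to backbone donors/acceptors (default TRUE).
#' @return Integer hydrogen-bond count.
#' @export
hbond_count <- function(frame, selection = unique(frame$resid),
                        dist_cutoff = 3.5, angle_cutoff = 150,
                        backbone_only = TRUE) {
  stopifnot(is.data.frame(frame),
            all(c("atom", "element", "resid", "x", "y", "z") %in% names(frame)))
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  at <- toupper(frame$atom); el <- toupper(frame$element); resid <- frame$resid

  donors <- list()  # each: list(d = donor row, h = H position)
  add_donor <- function(i, hpos) {
    donors[[length(donors) + 1L]] <<- list(i = i, h = hpos)
  }
  has_h <- any(el == "H")
  for (i in which(at == "N" & el == "N")) {
    if (has_h) {
      hj <- which(el == "H" & resid == resid[i] & at %in% c("H", "HN", "H1"))
      for (j in hj) add_donor(i, xyz[j, ])
    } else {
      # Idealized amide H: reverse bisector of (C_prev - N) and (CA - N).
      cp <- which(at == "C" & resid == resid[i] - 1L)
      ca <- which(at == "CA" & resid == resid[i])
      if (length(cp) == 1L && length(ca) == 1L) {
        u1 <- xyz[cp, ] - xyz[i, ]; u1 <- u1 / sqrt(sum(u1^2))
        u2 <- xyz[ca, ] - xyz[i, ]; u2 <- u2 / sqrt(sum(u2^2))
        d <- -(u1 + u2); nd <- sqrt(sum(d^2))
        if (nd > 1e-8) add_donor(i, xyz[i, ] + 1.01 * d / nd)
      }
    }
  }
  acceptors <- which(at == "O" & el == "O")
  if (!backbone_only) {
    side_n <- which(el == "N" & at != "N")
    for (i in side_n) {
      hj <- which(el == "H" & resid == resid[i])
      for (j in hj) {
        if (sqrt(sum((xyz[j, ] - xyz[i, ])^2)) < 1.3) add_donor(i, xyz[j, ])
      }
    }
    acceptors <- which(el == "O" | (el == "N" & at != "N"))
  }
  if (length(donors) == 0L || length(acceptors) == 0L) return(0L)

  count <- 0L
  for (d in donors) {
    if (!(resid[d$i] %in% selection)) next
    for (aidx in acceptors) {
      if (resid[aidx] == resid[d$i] || !(resid[aidx] %in% selection)) next
      da <- xyz[aidx, ] - xyz[d$i, ]
      if (sqrt(sum(da^2)) > dist_cutoff) next
      v1 <- xyz[d$i, ] - d$h
      v2 <- xyz[aidx, ] - d$h
      ang <- acos(pmin(pmax(sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1))
      if (ang * 180 / pi >= angle_cutoff) count <- count + 1L
    }
  }
  count
}

# Optimal rotation (Kabsch) mapping P onto Q, both centred.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

align_frames <- function(frames, align_idx) {
  ref <- frames[[1]]
  if (length(align_idx) < 3L) {
    abort("Alignment selection needs at least 3 atoms.")
  }
  centred <- sweep(ref[align_idx, , drop = FALSE], 2,
                   colMeans(ref[align_idx, , drop = FALSE]))
  if (sum(svd(centred)$d > 1e-8) < 2L) {
    abort("Alignment selection is degenerate (collinear or coincident points).")
  }
  superpose <- function(fr, target) {
    pc <- colMeans(fr[align_idx, , drop = FALSE])
    qc <- colMeans(target[align_idx, , drop = FALSE])
    R <- kabsch_rotation(sweep(fr[align_idx, , drop = FALSE], 2, pc),
                         sweep(target[align_idx, , drop = FALSE], 2, qc))
    sweep(sweep(fr, 2, pc) %*% R, 2, qc, "+")
  }
  mean_str <- frames[[1]]
  aligned <- frames
  for (it in seq_len(10L)) {
    aligned <- lapply(frames, superpose, target = mean_str)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    shift <- sqrt(mean(rowSums((new_mean - mean_str)^2)))
    mean_str <- new_mean
    if (shift < 1e-6) break
  }
  list(frames = aligned, mean = mean_str)
}

#' Root-mean-square fluctuation per residue
#'
#' Each frame is superposed (least-squares rigid rotation + translation,
#' Kabsch) onto an iteratively refined mean structure computed over the
#' alignment selection; iteration stops when the mean structure moves less
#' than 1e-6 Angstrom (max 10 rounds). The per-atom RMSF is
#' \eqn{\sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}} over frames,
#' then averaged over each residue's selected atoms.
#'
#' @param traj A [trajectory()].
#' @param align Atom indices used for superposition (default all atoms).
#' @param target Atom indices to report (default all atoms).
#' @return Tibble with columns `resid`, `rmsf` (Angstrom); the per-atom
#'   values are attached as attribute `per_atom`.
#' @export
rmsf <- function(traj, align = NULL, target = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2L) abort("RMSF needs at least 2 frames.")
  n <- nrow(traj$topology)
  align <- align %||% seq_len(n)
  target <- target %||% seq_len(n)
  al <- align_frames(traj$frames, align)
  dev2 <- Reduce(`+`, lapply(al$frames, function(f) {
    rowSums((f - al$mean)^2)
  })) / length(al$frames)
  per_atom <- sqrt(dev2)
  out <- tibble::tibble(resid = traj$topology$resid[target],
                        rmsf_atom = per_atom[target]) %>%
    dplyr::group_by(.data$resid) %>%
    dplyr::summarise(rmsf = mean(.data$rmsf_atom), .groups = "drop")
  attr(out, "per_atom") <- per_atom[target]
  out
}

#' Loop / rest atom selections for a construct
#'
#' Maps the extracellular loop residue spans (49-59 and 91-103 in mature
#' numbering, widened by any inserted residues — see [build_construct()])
#' onto atom indices of a topology. The "rest" selection is the complement
#' of the two loops.
#'
#' @param topology Trajectory topology tibble (needs `resid`).
#' @param loop2,loop3 Residue index vectors (defaults: mature OmpX spans).
#' @return List with atom index vectors `loop2`, `loop3`, `rest` and the
#'   residue spans used.
#' @export
loop_selection <- function(topology, loop2 = 49:59, loop3 = 91:103) {
  if (length(intersect(loop2, loop3)) > 0L) {
    abort("Loop residue spans must be disjoint.")
  }
  list(
    loop2 = which(topology$resid %in% loop2),
    loop3 = which(topology$resid %in% loop3),
    rest = which(!topology$resid %in% c(loop2, loop3)),
    spans = list(loop2 = loop2, loop3 = loop3)
  )
}

#' Per-frame structural descriptors for a trajectory
#'
#' Computes, for every frame: contact area between loop 2 and loop 3,
#' contact area between the two loops jointly and the rest of the protein,
#' and the hydrogen-bond count within each loop. Means and standard
#' deviations over frames are attached via [summarise_descriptors()].
#'
#' @param traj A [trajectory()].
#' @param loops A [loop_selection()] (default: mature OmpX spans applied to
#'   the trajectory topology).
#' @param probe,n_points SASA quadrature settings.
#' @param dist_cutoff,angle_cutoff,backbone_only Hydrogen-bond criteria.
#' @return Tibble with one row per frame: `frame`, `contact_l2_l3_A2`,
#'   `contact_loops_rest_A2`, `hbonds_l2`, `hbonds_l3`.
#' @export
descriptor_series <- function(traj, loops = loop_selection(traj$topology),
                              probe = 1.4, n_points = 960,
                              dist_cutoff = 3.5, angle_cutoff = 150,
                              backbone_only = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  radii <- traj$topology$radius
  both <- c(loops$loop2, loops$loop3)
  purrr::imap_dfr(traj$frames, function(xyz, i) {
    fr <- dplyr::mutate(traj$topology, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3])
    tibble::tibble(
      frame = i,
      contact_l2_l3_A2 = contact_area(xyz, radii, loops$loop2, loops$loop3,
                                      probe = probe, n_points = n_points),
      contact_loops_rest_A2 = contact_area(xyz, radii, both, loops$rest,
                                           probe = probe,
                                           n_points = n_points),
      hbonds_l2 = hbond_count(fr, loops$spans$loop2, dist_cutoff,
                              angle_cutoff, backbone_only),
      hbonds_l3 = hbond_count(fr, loops$spans$loop3, dist_cutoff,
                              angle_cutoff, backbone_only)
    )
  })
}

#' Summarise a descriptor series
#'
#' @param series Output of [descriptor_series()].
#' @return Tibble with `descriptor`, `mean`, `sd`, `n_frames`.
#' @export
summarise_descriptors <- function(series) {
  series %>%
    tidyr::pivot_longer(-"frame", names_to = "descriptor") %>%
    dplyr::group_by(.data$descriptor) %>%
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n_frames = dplyr::n(), .groups = "drop")
}

#' Regress a structural descriptor against folding rates
#'
#' Ordinary least squares of rate on descriptor mean, one point per
#' construct, as used to relate time-averaged loop descriptors to measured
#' folding rates.
#'
#' @param data Data frame with one row per construct.
#' @param descriptor,rate Column names (strings) for the x and y variables.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
descriptor_rate_regression <- function(data, descriptor = "descriptor",
                                       rate = "rate") {
  stopifnot(is.data.frame(data), descriptor %in% names(data),
            rate %in% names(data))
  x <- data[[descriptor]]; y <- data[[rate]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("At least 3 points are required for the regression.")
  if (var(x) == 0) abort("No variance in descriptor: regression is undefined.")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = length(x)
  )
}

#' Plot a descriptor-rate regression
#'
#' @param data Data frame of per-construct points.
#' @param descriptor,rate Column names (strings).
#' @param fit Optional precomputed [descriptor_rate_regression()] result.
#' @return A ggplot object.
#' @export
plot_rate_regression <- function(data, descriptor = "descriptor",
                                 rate = "rate", fit = NULL) {
  fit <- fit %||% descriptor_rate_regression(data, descriptor, rate)
  ggplot2::ggplot(data, ggplot2::aes(.data[[descriptor]], .data[[rate]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = "dotted") +
    ggplot2::labs(
      x = descriptor, y = rate,
      subtitle = sprintf("y = %.3g x + %.3g,  R^2 = %.3f",
                         fit$slope, fit$intercept, fit$r_squared)
    )
}
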