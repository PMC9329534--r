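# Independent oracles used by the tests. Each implements the target quantity
# by a route separate from the package's production path: dense grid scans,
# brute-force definitions, closed forms.

# Zero crossing of the peptide net-charge function on a dense pH grid.
grid_pi <- function(sequence, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- peptide_charge(sequence, grid)
  i <- which(q <= 0)[1]
  # linear interpolation between the bracketing grid points
  if (i == 1) return(grid[1])
  x0 <- grid[i - 1]; x1 <- grid[i]
  q0 <- q[i - 1]; q1 <- q[i]
  x0 + (0 - q0) * (x1 - x0) / (q1 - q0)
}

# Brute-force rolling-ball subtraction: grayscale opening with a
# spherical-cap element computed by direct looping over every pixel and
# offset, with replicate padding and max -> height_scale normalization
# (the same normative definition, independently implemented; smoothing
# disabled).
brute_rolling_ball <- function(img, radius, height_scale = 65535) {
  mx <- max(img)
  scale <- height_scale / mx
  r <- ceiling(radius)
  ri <- c(rep(1, r), seq_len(nrow(img)), rep(nrow(img), r))
  ci <- c(rep(1, r), seq_len(ncol(img)), rep(ncol(img), r))
  p <- (img * scale)[ri, ci, drop = FALSE]
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dx^2 - offs$dy^2) - radius
  nr <- nrow(p); nc <- ncol(p)
  er <- matrix(Inf, nr, nc)
  for (s in seq_len(nrow(offs))) {
    ii <- seq_len(nr) + offs$dx[s]
    jj <- seq_len(nc) + offs$dy[s]
    okr <- ii >= 1 & ii <= nr; okc <- jj >= 1 & jj <= nc
    er[okr, okc] <- pmin(er[okr, okc],
                         p[ii[okr], jj[okc], drop = FALSE] - offs$h[s])
  }
  di <- matrix(-Inf, nr, nc)
  for (s in seq_len(nrow(offs))) {
    ii <- seq_len(nr) - offs$dx[s]
    jj <- seq_len(nc) - offs$dy[s]
    okr <- ii >= 1 & ii <= nr; okc <- jj >= 1 & jj <= nc
    di[okr, okc] <- pmax(di[okr, okc],
                         er[ii[okr], jj[okc], drop = FALSE] + offs$h[s])
  }
  bg <- di[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img)), drop = FALSE] /
    scale
  pmax(img - bg, 0)
}

# Closed-form accessible area of two intersecting spheres with radii
# (r1 + probe), (r2 + probe) at centre distance d: each sphere loses the
# spherical cap buried inside the other.
two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)  # plane offset from centre 1
  a1 <- 4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
  x2 <- d - x1
  a2 <- 4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2)
  a1 + a2
}

# Minimal frame tibble for hydrogen-bond geometry tests: an idealized
# backbone N-H ... O=C pair across two residues, with the donor-acceptor
# distance and D-H...A angle configurable. The acceptor O is placed along
# the N-H axis (angle 180) and then rotated about H to the requested angle.
make_hbond_frame <- function(da_dist = 2.9, angle_deg = 180) {
  n <- c(0, 0, 0)
  h <- c(1.01, 0, 0)
  # place acceptor so that the D-H...A angle is as requested
  theta <- (180 - angle_deg) * pi / 180
  ha <- da_dist - 1.01  # approximate H...A leg along the axis for angle 180
  a_pos <- h + c(cos(theta), sin(theta), 0) * ha
  # recompute to hit the exact D-A distance when angle != 180:
  # scale the H->A leg so |N - A| = da_dist
  f <- function(s) {
    p <- h + c(cos(theta), sin(theta), 0) * s
    sqrt(sum((p - n)^2)) - da_dist
  }
  s <- uniroot(f, c(0.1, da_dist + 2))$root
  a_pos <- h + c(cos(theta), sin(theta), 0) * s
  c_pos <- a_pos + c(1.23, 0, 0)
  ca1 <- c(-0.5, -1.3, 0)
  tibble::tibble(
    atom = c("N", "H", "CA", "O", "C", "CA"),
    element = c("N", "H", "C", "O", "C", "C"),
    resid = c(1L, 1L, 1L, 5L, 5L, 5L),
    resname = "GLY",
    x = c(n[1], h[1], ca1[1], a_pos[1], c_pos[1], c_pos[1] + 1),
    y = c(n[2], h[2], ca1[2], a_pos[2], c_pos[2], c_pos[2] + 1),
    z = c(n[3], h[3], ca1[3], a_pos[3], c_pos[3], c_pos[3])
  )
}

random_rigid_copy <- function(xyz) {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(xyz %*% Q, 2, runif(3, -10, 10), "+")
}
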