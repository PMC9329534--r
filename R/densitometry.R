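# Gel densitometry: polarity handling, rolling-ball background subtraction,
# lane profiling and band quantification for SDS-PAGE heat-modifiability
# assays. Images are plain numeric matrices, rows = migration axis, columns =
# lane width, intensities >= 0 (16-bit nominal, but any non-negative scale
# works: the folded fraction is invariant under global rescaling).

check_gel_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort("A gel image must be a numeric matrix (rows = migration axis).")
  }
  if (any(!is.finite(img)) || any(img < 0)) {
    abort("Gel intensities must be finite and non-negative.")
  }
  invisible(img)
}

#' Convert a gel image to signal-positive polarity
#'
#' Coomassie bands are dark on a bright background; quantification wants
#' bands as positive signal on a near-zero background. `polarity =
#' "dark_bands"` flips the image as `max(img) - img`; `"signal_positive"`
#' returns it unchanged.
#'
#' @param img Numeric matrix, rows = migration axis.
#' @param polarity `"dark_bands"` (default) or `"signal_positive"`.
#' @return Matrix in signal-positive convention.
#' @export
invert_gel <- function(img, polarity = c("dark_bands", "signal_positive")) {
  polarity <- match.arg(polarity)
  check_gel_image(img)
  if (polarity == "signal_positive") return(img)
  max(img) - img
}

# Offsets and spherical-cap heights of a ball structuring element. Heights
# are <= 0 with 0 at the centre, so morphological operations reduce to
# img -/+ height at each offset.
ball_element <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- g$dx^2 + g$dy^2
  keep <- d2 <= radius^2
  list(dx = as.integer(g$dx[keep]), dy = as.integer(g$dy[keep]),
       h = sqrt(radius^2 - d2[keep]) - radius)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped (spherical-cap height profile) structuring element and
#' subtracts it, clamping at zero. A ball of the given radius rolled under
#' the intensity surface cannot follow structures narrower than itself, so
#' bands with widths well below the radius survive while smooth backgrounds
#' are removed. The image must already be in signal-positive convention
#' (see [invert_gel()]).
#'
#' The ball's height profile lives on the intensity axis while its footprint
#' lives on the pixel grid, so the intensity scale must be pinned down:
#' before rolling the ball, the image is rescaled so that its maximum maps
#' to `height_scale` (default 65535, the 16-bit convention), and the
#' background is scaled back before subtraction. This makes the result
#' exactly invariant under a global gain change of the image.
#'
#' On noisy images the opening tracks the lower envelope of the noise, which
#' would bias the background low (and, after clamping, the signal high); the
#' background is therefore estimated on a lightly smoothed copy (`smooth` x
#' `smooth` box mean, default 3, as is standard in gel-imaging practice) and
#' subtracted from the unsmoothed image. Set `smooth = 1` to roll the ball
#' on the raw intensities.
#'
#' @param img Numeric matrix in signal-positive convention.
#' @param radius Ball radius in pixels (default 50).
#' @param height_scale Intensity value the image maximum is mapped to while
#'   the ball is rolled (default 65535).
#' @param smooth Box-filter width (odd, pixels) for the background estimate;
#'   1 disables smoothing (default 3).
#' @return Matrix of the same size; every pixel is `<=` its input value.
#' @export
subtract_background <- function(img, radius = 50, height_scale = 65535,
                                smooth = 3) {
  check_gel_image(img)
  if (radius < 1) abort("`radius` must be >= 1 pixel.")
  if (2 * radius > nrow(img)) {
    warn(sprintf(
      "Ball radius %s exceeds half the migration extent (%s rows); background estimate will be coarse.",
      radius, nrow(img)
    ))
  }
  mx <- max(img)
  if (mx == 0) return(img)
  scale <- height_scale / mx
  el <- ball_element(radius)
  # Replicate-pad by the radius so the ball sees a continued surface at the
  # borders (avoids edge underestimation of tilted backgrounds), then crop.
  r <- ceiling(radius)
  padded <- pad_replicate(box_blur(img, smooth) * scale, r)
  bg <- cpp_gray_dilate(cpp_gray_erode(padded, el$dx, el$dy, el$h),
                        el$dx, el$dy, el$h)
  bg <- bg[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img)), drop = FALSE] /
    scale
  pmax(img - bg, 0)
}

pad_replicate <- function(img, r) {
  ri <- c(rep(1L, r), seq_len(nrow(img)), rep(nrow(img), r))
  ci <- c(rep(1L, r), seq_len(ncol(img)), rep(ncol(img), r))
  img[ri, ci, drop = FALSE]
}

# Separable box mean with replicate borders; k = 1 is the identity.
box_blur <- function(img, k) {
  if (k <= 1) return(img)
  if (k %% 2 == 0) abort("`smooth` must be odd.")
  r <- (k - 1L) / 2L
  p <- pad_replicate(img, r)
  kern <- rep(1 / k, k)
  sm <- apply(p, 2, function(col) stats::filter(col, kern, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, kern, sides = 2)))
  sm[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img)), drop = FALSE]
}

#' Lane intensity profile
#'
#' Sums background-subtracted signal across the lane's columns, giving a 1-D
#' profile indexed by migration position (pixel row).
#'
#' @param img Numeric matrix.
#' @param cols Half-open column interval `c(start, end)` (1-based; `end`
#'   excluded). Defaults to the full image width.
#' @return Numeric vector of length `nrow(img)`.
#' @export
lane_profile <- function(img, cols = c(1, ncol(img) + 1)) {
  check_gel_image(img)
  stopifnot(length(cols) == 2)
  if (cols[2] <= cols[1] || cols[1] < 1 || cols[2] > ncol(img) + 1) {
    abort("`cols` must be a non-empty half-open interval inside the image width.")
  }
  idx <- seq(cols[1], cols[2] - 1)
  rowSums(img[, idx, drop = FALSE])
}

#' Quantify folded and unfolded bands from a lane profile
#'
#' Integrates the profile over the two (disjoint, half-open) band windows and
#' reports the folded fraction F / (F + U). An empty lane (F + U = 0) is an
#' explicit error, never a silent 0.
#'
#' @param profile Numeric lane profile (see [lane_profile()]).
#' @param folded,unfolded Half-open pixel intervals `c(start, end)` on the
#'   migration axis.
#' @return One-row tibble with columns `folded`, `unfolded`,
#'   `fraction_folded`.
#' @export
quantify_bands <- function(profile, folded, unfolded) {
  stopifnot(is.numeric(profile), length(folded) == 2, length(unfolded) == 2)
  win_idx <- function(w, label) {
    if (w[2] <= w[1] || w[1] < 1 || w[2] > length(profile) + 1) {
      abort(sprintf("%s window must be a non-empty half-open interval inside the profile.", label))
    }
    seq(w[1], w[2] - 1)
  }
  fi <- win_idx(folded, "Folded")
  ui <- win_idx(unfolded, "Unfolded")
  if (length(intersect(fi, ui)) > 0L) {
    abort("Folded and unfolded band windows must be disjoint.")
  }
  f <- sum(profile[fi])
  u <- sum(profile[ui])
  if (f + u <= 0) {
    abort("Empty lane: folded + unfolded integrated density is zero.")
  }
  tibble::tibble(folded = f, unfolded = u, fraction_folded = f / (f + u))
}

#' Locate band windows from a lane profile (helper)
#'
#' Optional peak-finding aid: takes the two largest local maxima separated by
#' at least `min_gap` pixels and returns symmetric windows of `half_width`
#' pixels around each, ordered by migration position. Manual window placement
#' is the normative path; this helper is a convenience for synthetic data and
#' quick looks.
#'
#' @param profile Numeric lane profile.
#' @param half_width Half-width of each returned window (pixels).
#' @param min_gap Minimum separation between the two peaks (pixels).
#' @return List with elements `first` and `second`, each a half-open interval
#'   `c(start, end)`, ordered by increasing row index.
#' @export
find_band_windows <- function(profile, half_width = 30, min_gap = 50) {
  n <- length(profile)
  is_peak <- c(FALSE, diff(sign(diff(profile))) < 0, FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2L) abort("Fewer than two local maxima in the profile.")
  peaks <- peaks[order(profile[peaks], decreasing = TRUE)]
  p1 <- peaks[1]
  p2 <- peaks[abs(peaks - p1) >= min_gap][1]
  if (is.na(p2)) abort("No second peak at the required separation.")
  mk <- function(p) c(max(1, p - half_width), min(n + 1, p + half_width + 1))
  ps <- sort(c(p1, p2))
  list(first = mk(ps[1]), second = mk(ps[2]))
}

#' Quantify a full gel: invert, subtract background, integrate bands
#'
#' Convenience wrapper running the normative densitometry chain on one or
#' more lanes of a gel image.
#'
#' @param img Numeric matrix (raw polarity as imaged).
#' @param lanes Data frame with columns `lane` (id), `col_start`, `col_end`
#'   (half-open column intervals); optionally `time_min`.
#' @param folded,unfolded Band windows as in [quantify_bands()].
#' @param radius Rolling-ball radius in pixels (default 50); `NULL` skips
#'   background subtraction (appropriate when the background is known flat,
#'   e.g. clean synthetic gels).
#' @param polarity Passed to [invert_gel()].
#' @return Tibble with one row per lane: lane metadata plus `folded`,
#'   `unfolded`, `fraction_folded`.
#' @export
quantify_gel <- function(img, lanes, folded, unfolded, radius = 50,
                         polarity = "dark_bands") {
  stopifnot(is.data.frame(lanes),
            all(c("lane", "col_start", "col_end") %in% names(lanes)))
  clean <- invert_gel(img, polarity)
  if (!is.null(radius)) clean <- subtract_background(clean, radius)
  lanes %>%
    tibble::as_tibble() %>%
    dplyr::mutate(quant = purrr::map2(.data$col_start, .data$col_end, function(a, b) {
      quantify_bands(lane_profile(clean, c(a, b)), folded, unfolded)
    })) %>%
    tidyr::unnest("quant")
}

#' Read / write grayscale gel images
#'
#' TIFF images are read/written at 16-bit depth; PNG is supported for 8-bit
#' copies. Intensities are scaled to [0, 1] in memory (the folded fraction is
#' scale-invariant). Multi-channel images are averaged to grayscale.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param img Numeric matrix with values in [0, 1].
#' @return `read_gel()`: numeric matrix. `write_gel()`: `path`, invisibly.
#' @export
read_gel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort("Unsupported image format: use TIFF or PNG.")
  )
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  check_gel_image(x)
  x
}

#' @rdname read_gel
#' @export
write_gel <- function(img, path) {
  check_gel_image(img)
  if (max(img) > 1) img <- img / max(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    png = png::writePNG(img, path),
    abort("Unsupported image format: use TIFF or PNG.")
  )
  invisible(path)
}
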