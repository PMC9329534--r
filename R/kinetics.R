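# Single-exponential folding kinetics: the model XF(t) = A (1 - exp(-k t)),
# simulation of replicate time courses, and Levenberg-Marquardt fitting with
# asymptotic standard errors. Folded OMPs accumulate with first-order rate k
# (min^-1) towards an asymptotic yield A (fraction folded).

#' Single-exponential folding model
#'
#' \eqn{XF(t) = A (1 - e^{-k t})}: fraction folded at time t for folding rate
#' `k` (min^-1) and yield `A` (asymptotic folded fraction).
#'
#' @param t Time(s) in minutes, `>= 0`.
#' @param k Folding rate constant (min^-1, `> 0`).
#' @param A Folding yield in [0, 1].
#' @return Fraction folded, vectorized over `t`.
#' @examples
#' model_xf(c(0, log(2) / 0.123, Inf), k = 0.123, A = 0.885)
#' @export
model_xf <- function(t, k, A) {
  stopifnot(all(t >= 0), k > 0, A >= 0)
  A * (1 - exp(-k * t))
}

#' Simulate a replicate folding time course
#'
#' Model values plus independent Gaussian noise, clamped to [0, 1] (a folded
#' fraction is a ratio of band densities and cannot leave the unit interval).
#' With a seed the result is bit-reproducible and the global RNG state is
#' left untouched.
#'
#' @inheritParams model_xf
#' @param times Sampling times in minutes (default the geometric schedule
#'   0, 1, 2, 4, 8, 16, 32, 64 used for folding assays run to 64 min).
#' @param noise_sd Gaussian noise standard deviation on the fraction scale
#'   (default 0.02).
#' @param n_replicates Technical replicates per time point (default 3).
#' @param seed Optional integer seed.
#' @param construct Optional construct label column.
#' @return Tibble with columns (`construct`,) `time_min`, `replicate`,
#'   `fraction_folded`.
#' @export
simulate_timecourse <- function(k, A, times = c(0, 1, 2, 4, 8, 16, 32, 64),
                                noise_sd = 0.02, n_replicates = 3,
                                seed = NULL, construct = NULL) {
  stopifnot(noise_sd >= 0, n_replicates >= 1)
  draw <- function() {
    tidyr::expand_grid(replicate = seq_len(n_replicates), time_min = times) %>%
      dplyr::mutate(
        fraction_folded = pmin(1, pmax(0,
          model_xf(.data$time_min, k, A) +
            rnorm(dplyr::n(), sd = noise_sd)))
      ) %>%
      dplyr::select("time_min", "replicate", "fraction_folded")
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (!is.null(construct)) out <- dplyr::mutate(out, construct = construct,
                                                .before = 1)
  out
}

#' Fit single-exponential folding kinetics
#'
#' Nonlinear least squares for \eqn{XF(t) = A (1 - e^{-kt})} over the pooled
#' replicate observations (replicates enter the residual vector individually,
#' not averaged). Optimization is Levenberg-Marquardt on the transformed
#' parameters (log k, logit A), which enforces k > 0 and 0 < A < 1 without
#' constraints. Standard errors are asymptotic: the Jacobian with respect to
#' (k, A) at the optimum gives cov = s^2 (J'J)^-1 with s^2 = RSS / (n - 2).
#' When every replicate can also be fitted on its own, the spread (sd) of the
#' per-replicate estimates is reported alongside as an alternative error
#' measure.
#'
#' Observations are sorted by (time, fraction) before fitting, so the result
#' is invariant to the order in which replicates are supplied.
#'
#' @param data Data frame of observations.
#' @param time,fraction Column names (strings) holding times (min) and folded
#'   fractions (default `"time_min"`, `"fraction_folded"`).
#' @param replicate Optional replicate id column used for the per-replicate
#'   error spread (default `"replicate"` if present).
#' @param max_iter Maximum LM iterations (default 500).
#' @param tol Relative objective-change tolerance (default 1e-10).
#' @return An object of class `folding_fit`: list with `k`, `A`, `k_se`,
#'   `A_se`, `k_sd_replicates`, `A_sd_replicates`, `rss`, `converged`,
#'   `n_iter`, `n_obs` and the fitting data. Non-convergence is flagged, not
#'   thrown; a time course with no signal at all throws a
#'   "rate unidentifiable" error.
#' @examples
#' tc <- simulate_timecourse(0.123, 0.885, noise_sd = 0, seed = 1)
#' fit <- fit_folding(tc)
#' glance(fit)
#' @export
fit_folding <- function(data, time = "time_min", fraction = "fraction_folded",
                        replicate = "replicate", max_iter = 500, tol = 1e-10) {
  stopifnot(is.data.frame(data), time %in% names(data),
            fraction %in% names(data))
  t_obs <- data[[time]]
  y_obs <- data[[fraction]]
  keep <- is.finite(t_obs) & is.finite(y_obs)
  t_obs <- t_obs[keep]; y_obs <- y_obs[keep]
  if (any(t_obs < 0)) abort("Times must be non-negative.")
  if (any(y_obs < 0 | y_obs > 1)) abort("Folded fractions must lie in [0, 1].")
  if (length(unique(t_obs)) < 3L) {
    abort("At least 3 distinct time points are required to fit (k, A).")
  }
  if (all(y_obs <= 0)) {
    abort("rate unidentifiable: no folded protein observed at any time point.")
  }
  ord <- order(t_obs, y_obs)
  t_obs <- t_obs[ord]; y_obs <- y_obs[ord]

  core <- fit_xf_core(t_obs, y_obs, max_iter = max_iter, tol = tol)

  # Per-replicate spread as an alternative error estimate.
  k_sd_rep <- A_sd_rep <- NA_real_
  if (replicate %in% names(data) &&
      dplyr::n_distinct(data[[replicate]][keep]) >= 2L) {
    per <- split(seq_along(data[[time]][keep]), data[[replicate]][keep])
    fits <- purrr::map(per, function(idx) {
      tryCatch({
        ti <- data[[time]][keep][idx]; yi <- data[[fraction]][keep][idx]
        if (length(unique(ti)) < 3L || all(yi <= 0)) return(NULL)
        o <- order(ti, yi)
        fit_xf_core(ti[o], yi[o], max_iter = max_iter, tol = tol)
      }, error = function(e) NULL)
    })
    fits <- purrr::compact(fits)
    if (length(fits) >= 2L) {
      k_sd_rep <- sd(purrr::map_dbl(fits, "k"))
      A_sd_rep <- sd(purrr::map_dbl(fits, "A"))
    }
  }

  structure(
    c(core, list(k_sd_replicates = k_sd_rep, A_sd_replicates = A_sd_rep,
                 data = tibble::tibble(time_min = t_obs,
                                       fraction_folded = y_obs))),
    class = "folding_fit"
  )
}

# LM fit on (log k, logit A); returns estimates, asymptotic SEs, RSS and
# convergence diagnostics.
fit_xf_core <- function(t_obs, y_obs, max_iter = 500, tol = 1e-10) {
  # Deterministic, scale-free initialization: A0 from the plateau, k0 from
  # the first crossing of A0/2 by the per-time mean.
  A0 <- min(max(max(y_obs), 0.05), 0.99)
  mt <- tapply(y_obs, t_obs, mean)
  tt <- as.numeric(names(mt))
  cross <- which(mt >= A0 / 2 & tt > 0)
  k0 <- if (length(cross) > 0) log(2) / tt[cross[1]] else 1 / median(tt[tt > 0])
  k0 <- min(max(k0, 1e-4), 1e3)

  theta0 <- c(log(k0), qlogis(A0))
  resid_fn <- function(theta) {
    y_obs - model_xf(t_obs, exp(theta[1]), plogis(theta[2]))
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                    ptol = 1e-12)
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn, control = ctl)

  k <- exp(fit$par[1]); A <- plogis(fit$par[2])
  r <- resid_fn(fit$par)
  rss <- sum(r^2)
  # Descent guard: LM must not end above its start.
  if (rss > sum(resid_fn(theta0)^2) + 1e-12) {
    k <- k0; A <- A0; rss <- sum(resid_fn(theta0)^2)
  }
  n <- length(y_obs)
  ek <- exp(-k * t_obs)
  J <- cbind(k = A * t_obs * ek, A = 1 - ek)
  s2 <- rss / max(n - 2L, 1L)
  covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  converged <- fit$info %in% 1:4
  list(k = k, A = A,
       k_se = sqrt(pmax(covm[1, 1], 0)), A_se = sqrt(pmax(covm[2, 2], 0)),
       rss = rss, converged = converged, n_iter = fit$niter, n_obs = n)
}

#' @export
print.folding_fit <- function(x, ...) {
  cat("Single-exponential folding fit  XF(t) = A(1 - exp(-k t))\n")
  cat(sprintf("  k = %.4f min^-1 (SE %.4f)\n", x$k, x$k_se))
  cat(sprintf("  A = %.4f        (SE %.4f)\n", x$A, x$A_se))
  cat(sprintf("  RSS %.3g on %d observations; converged: %s (%d iterations)\n",
              x$rss, x$n_obs, x$converged, x$n_iter))
  invisible(x)
}

#' @export
predict.folding_fit <- function(object, times = NULL, ...) {
  times <- times %||% object$data$time_min
  model_xf(times, object$k, object$A)
}

#' Tidy a folding fit
#'
#' @param x A `folding_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`,
#'   `std.error.replicates`.
#' @export
tidy.folding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "A"),
    estimate = c(x$k, x$A),
    std.error = c(x$k_se, x$A_se),
    std.error.replicates = c(x$k_sd_replicates, x$A_sd_replicates)
  )
}

#' Glance at a folding fit
#'
#' @param x A `folding_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `k_per_min`, `k_se`, `yield`, `yield_se`, `rss`,
#'   `converged`, `n_iter`, `n_obs`.
#' @export
glance.folding_fit <- function(x, ...) {
  tibble::tibble(
    k_per_min = x$k, k_se = x$k_se, yield = x$A, yield_se = x$A_se,
    rss = x$rss, converged = x$converged, n_iter = x$n_iter, n_obs = x$n_obs
  )
}

#' Plot a folding fit
#'
#' Observed folded fractions and the fitted single-exponential curve.
#'
#' @param object A `folding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.folding_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_min = seq(0, max(object$data$time_min), length.out = 200)
  )
  grid$fraction_folded <- predict(object, grid$time_min)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$time_min, .data$fraction_folded)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "black", linetype = "dotted") +
    ggplot2::labs(x = "Time (min)", y = "Fraction folded",
                  subtitle = sprintf("k = %.3f min^-1, A = %.3f",
                                     object$k, object$A)) +
    ggplot2::ylim(0, 1)
}

#' Fit folding kinetics for a panel of constructs
#'
#' Groups a pooled time-course table by construct and fits each group. A
#' construct whose observations carry no signal (the "did not fold" case) is
#' reported with `did_not_fold = TRUE` and NA parameters rather than an
#' error.
#'
#' @param data Data frame with columns `construct`, `time_min`, `replicate`,
#'   `fraction_folded`.
#' @param ... Passed to [fit_folding()].
#' @return Tibble with one row per construct: [glance()] columns plus
#'   `did_not_fold`.
#' @export
fit_folding_panel <- function(data, ...) {
  stopifnot("construct" %in% names(data))
  data %>%
    dplyr::group_by(.data$construct) %>%
    dplyr::group_modify(function(d, key) {
      res <- tryCatch(glance(fit_folding(d, ...)), error = function(e) {
        if (grepl("unidentifiable", conditionMessage(e))) NULL else stop(e)
      })
      if (is.null(res)) {
        res <- tibble::tibble(k_per_min = NA_real_, k_se = NA_real_,
                              yield = NA_real_, yield_se = NA_real_,
                              rss = NA_real_, converged = NA,
                              n_iter = NA_integer_, n_obs = nrow(d))
        res$did_not_fold <- TRUE
      } else {
        res$did_not_fold <- FALSE
      }
      res
    }) %>%
    dplyr::ungroup()
}
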