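assert_trajectories <- function(trajectories) {
  need <- c("airineme_id", "frame", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(trajectories))
  if (length(miss) > 0) {
    stop("trajectory table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(trajectories) == 0) stop("empty trajectory table", call. = FALSE)
  invisible(trajectories)
}

# Split a trajectory table into per-airineme matrices (t, x, y[, heading]),
# sorted by frame.
split_paths <- function(trajectories) {
  assert_trajectories(trajectories)
  trajectories <- dplyr::arrange(trajectories, .data$airineme_id, .data$frame)
  split(trajectories, trajectories$airineme_id)
}

sampling_interval <- function(trajectories) {
  dts <- trajectories |>
    dplyr::group_by(.data$airineme_id) |>
    dplyr::summarise(dt = min(diff(.data$t_min)), .groups = "drop")
  stats::median(dts$dt)
}

#' Mean squared displacement of tracked trajectories
#'
#' The MSD at lag `tau` is the mean of `|r(t + tau) - r(t)|^2` over all
#' trajectories and all valid start frames (overlapping windows, the
#' standard MSD convention). Lags must be multiples of the sampling
#' interval.
#'
#' @param trajectories Tibble with columns `airineme_id`, `frame`, `t_min`,
#'   `x_um`, `y_um` (one row per stored frame).
#' @param lags Lag times, min. Default: all multiples of the sampling
#'   interval up to half the longest trajectory.
#' @return A `prw_msd` tibble with columns `lag_min`, `msd_um2`, `n_pairs`.
#' @examples
#' tr <- simulate_airineme(prw_params(dtheta = 0), initial_angle = 0, seed = 1)
#' path <- dplyr::mutate(tr$path, airineme_id = 1L)
#' compute_msd(path, lags = c(1, 2, 5))[, 1:2] # ballistic: (v * tau)^2
#' @export
compute_msd <- function(trajectories, lags = NULL) {
  paths <- split_paths(trajectories)
  dt <- sampling_interval(trajectories)
  if (is.null(lags)) {
    max_t <- max(purrr::map_dbl(paths, ~ diff(range(.x$t_min))))
    lags <- dt * seq_len(max(1, floor(max_t / (2 * dt))))
  }
  stopifnot(all(lags > 0))
  steps <- as.integer(round(lags / dt))
  if (any(abs(lags - steps * dt) > 1e-6 * dt)) {
    stop("lags must be multiples of the sampling interval (", signif(dt, 4),
         " min)", call. = FALSE)
  }
  acc <- purrr::map(steps, function(k) {
    sums <- 0; npairs <- 0L
    for (p in paths) {
      m <- nrow(p)
      if (m > k) {
        dx <- p$x_um[(k + 1):m] - p$x_um[1:(m - k)]
        dy <- p$y_um[(k + 1):m] - p$y_um[1:(m - k)]
        sums <- sums + sum(dx^2 + dy^2)
        npairs <- npairs + (m - k)
      }
    }
    c(sums, npairs)
  })
  out <- tibble::tibble(
    lag_min = lags,
    msd_um2 = purrr::map_dbl(acc, ~ if (.x[2] > 0) .x[1] / .x[2] else NA_real_),
    n_pairs = purrr::map_int(acc, ~ as.integer(.x[2]))
  ) |> dplyr::filter(.data$n_pairs > 0)
  class(out) <- c("prw_msd", class(out))
  out
}

#' Power-law fit of an MSD curve
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` over a lag window,
#' i.e. the fit `msd = gamma * t^alpha`. `alpha = 2` is ballistic motion,
#' `alpha = 1` simple diffusion; persistent random walks cross over from 2
#' to 1 around the persistence time, so a single exponent fitted across the
#' crossover lands strictly between.
#'
#' @param curve A `prw_msd` tibble from [compute_msd()].
#' @param window Lag window `c(min, max)` in min; default `c(0, 15)`,
#'   covering the near-ballistic regime seen in airineme data. Must retain
#'   at least 4 lags.
#' @return A `prw_msd_fit` object; see [tidy.prw_msd_fit()].
#' @export
fit_msd_power_law <- function(curve, window = c(0, 15)) {
  stopifnot(all(c("lag_min", "msd_um2") %in% names(curve)))
  sel <- curve$lag_min >= window[1] & curve$lag_min <= window[2]
  d <- curve[sel, ]
  if (nrow(d) < 4) stop("window must retain at least 4 lags", call. = FALSE)
  if (any(d$msd_um2 <= 0)) stop("non-positive MSD in window", call. = FALSE)
  fit <- lm(log(msd_um2) ~ log(lag_min), data = d)
  ci <- confint(fit, "log(lag_min)", level = 0.90)
  structure(list(
    gamma = exp(unname(coef(fit)[1])),
    alpha = unname(coef(fit)[2]),
    alpha_ci90 = c(lower = ci[1], upper = ci[2]),
    window = window, n_lags = nrow(d), fit = fit
  ), class = "prw_msd_fit")
}

#' @export
print.prw_msd_fit <- function(x, ...) {
  cat(sprintf(
    "<prw_msd_fit> msd = %.4g * t^%.3f  (alpha 90%% CI %.3f-%.3f, %d lags in [%g, %g] min)\n",
    x$gamma, x$alpha, x$alpha_ci90[1], x$alpha_ci90[2], x$n_lags,
    x$window[1], x$window[2]))
  invisible(x)
}

#' Tidy an MSD power-law fit
#' @param x A `prw_msd_fit`.
#' @param ... Unused.
#' @return One row per parameter (`tidy`) or a one-row summary (`glance`).
#' @export
tidy.prw_msd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "alpha"),
    estimate = c(x$gamma, x$alpha),
    conf.low = c(NA, unname(x$alpha_ci90[1])),
    conf.high = c(NA, unname(x$alpha_ci90[2]))
  )
}

#' @rdname tidy.prw_msd_fit
#' @export
glance.prw_msd_fit <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, alpha = x$alpha,
                 alpha_ci90_lower = unname(x$alpha_ci90[1]),
                 alpha_ci90_upper = unname(x$alpha_ci90[2]),
                 n_lags = x$n_lags)
}

#' Step-length complementary cumulative distribution
#'
#' Steps are tip displacements over non-overlapping windows of length
#' `interval` (a multiple of the sampling interval), pooled over
#' trajectories; the CCDF reports the fraction of steps at least as large
#' as each observed value. The tail exponent of the CCDF is the standard
#' Levy-walk diagnostic: Levy models in 2-D have CCDF tails with exponent
#' between 1 and 3.
#'
#' @param trajectories Trajectory tibble (see [compute_msd()]).
#' @param interval Window length, min.
#' @return A `prw_ccdf` tibble with columns `step_um`, `ccdf` (survival
#'   fraction, from 1 at the smallest step), and attribute `interval`.
#' @export
step_length_ccdf <- function(trajectories, interval) {
  paths <- split_paths(trajectories)
  dt <- sampling_interval(trajectories)
  k <- as.integer(round(interval / dt))
  if (k < 1 || abs(interval - k * dt) > 1e-6 * dt) {
    stop("interval must be a positive multiple of the sampling interval (",
         signif(dt, 4), " min)", call. = FALSE)
  }
  steps <- purrr::map(paths, function(p) {
    idx <- seq(1, nrow(p), by = k)
    if (length(idx) < 2) return(numeric(0))
    sqrt(diff(p$x_um[idx])^2 + diff(p$y_um[idx])^2)
  })
  steps <- sort(unlist(steps, use.names = FALSE))
  if (length(steps) == 0) {
    stop("interval longer than every trajectory", call. = FALSE)
  }
  n <- length(steps)
  out <- tibble::tibble(step_um = steps, ccdf = (n - seq_len(n) + 1) / n)
  attr(out, "interval") <- interval
  class(out) <- c("prw_ccdf", class(out))
  out
}

#' Power-law fit of a CCDF tail
#'
#' OLS slope of `log(ccdf)` against `log(step)` over the largest
#' `tail_fraction` of steps; the reported exponent is the magnitude of the
#' slope with a 90% CI. (The step-length *density* exponent is this value
#' plus one.) Levy-consistency means an exponent in (1, 3); the
#' `levy_band` field records whether the point estimate falls in that band.
#'
#' @param ccdf A `prw_ccdf` from [step_length_ccdf()].
#' @param tail_fraction Fraction of largest steps used; default 0.3. The
#'   tail must retain at least 10 points.
#' @return A `prw_ccdf_fit` object with `exponent`, `ci90`, `levy_band`,
#'   `n_tail`.
#' @export
fit_ccdf_tail <- function(ccdf, tail_fraction = 0.3) {
  stopifnot(tail_fraction > 0, tail_fraction < 1)
  n <- nrow(ccdf)
  m <- max(1, floor(tail_fraction * n))
  d <- ccdf[(n - m + 1):n, ]
  if (nrow(d) < 10) stop("tail retains fewer than 10 points", call. = FALSE)
  if (length(unique(d$step_um)) < 2) {
    stop("degenerate step distribution (an atom, not a power law)",
         call. = FALSE)
  }
  fit <- lm(log(ccdf) ~ log(step_um), data = d)
  sl <- unname(coef(fit)[2])
  ci <- confint(fit, "log(step_um)", level = 0.90)
  structure(list(
    exponent = abs(sl),
    ci90 = sort(abs(c(ci[1], ci[2]))),
    levy_band = abs(sl) > 1 && abs(sl) < 3,
    n_tail = nrow(d), tail_fraction = tail_fraction, fit = fit
  ), class = "prw_ccdf_fit")
}

#' @export
print.prw_ccdf_fit <- function(x, ...) {
  cat(sprintf(
    "<prw_ccdf_fit> CCDF tail exponent %.3f (90%% CI %.3f-%.3f, %d tail points)%s\n",
    x$exponent, x$ci90[1], x$ci90[2], x$n_tail,
    if (x$levy_band) " [in Levy band (1,3)]" else " [outside Levy band]"))
  invisible(x)
}

#' @rdname tidy.prw_msd_fit
#' @export
glance.prw_ccdf_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent,
                 ci90_lower = x$ci90[1], ci90_upper = x$ci90[2],
                 levy_band = x$levy_band, n_tail = x$n_tail,
                 tail_fraction = x$tail_fraction)
}

# Arc-length positions: with a known growth speed the frozen-shape model
# gives the exact arc coordinate s = v * t; otherwise fall back on chord
# lengths, which understate arc length on curved paths.
path_headings <- function(p, use_stored = TRUE, v = NULL) {
  arc_s <- function() {
    if (!is.null(v)) {
      v * (p$t_min - p$t_min[1])
    } else {
      cumsum(c(0, sqrt(diff(p$x_um)^2 + diff(p$y_um)^2)))
    }
  }
  if (use_stored && "heading_rad" %in% names(p) &&
      !anyNA(p$heading_rad)) {
    list(theta = p$heading_rad, s = arc_s(), source = "stored")
  } else {
    dx <- diff(p$x_um); dy <- diff(p$y_um)
    seglen <- sqrt(dx^2 + dy^2)
    keep <- seglen > 0
    s <- arc_s()
    s_mid <- (s[-1] + s[-length(s)]) / 2
    list(theta = atan2(dy[keep], dx[keep]), s = s_mid[keep],
         source = "chord")
  }
}

#' Isotropy test of final tangent angles
#'
#' For every trajectory whose growth time is at least `min_duration`, the
#' final angle is the heading at the tip minus the heading at the origin,
#' wrapped to (-pi, pi]. For a persistent random walk observed for times
#' well beyond `1 / dtheta` this distribution is isotropic; a two-sided
#' Kolmogorov--Smirnov test against uniform(-pi, pi) quantifies agreement.
#' Headings come from a stored `heading_rad` column when present, otherwise
#' from chord directions between consecutive positions.
#'
#' @param trajectories Trajectory tibble.
#' @param min_duration Minimum growth time, min (default 15).
#' @return A list with `angles` (rad), `ks_stat`, `p_value`, `n`.
#' @export
final_angle_isotropy <- function(trajectories, min_duration = 15) {
  stopifnot(min_duration >= 0)
  paths <- split_paths(trajectories)
  angles <- purrr::map_dbl(paths, function(p) {
    if (diff(range(p$t_min)) < min_duration || nrow(p) < 3) return(NA_real_)
    h <- path_headings(p)
    wrap_angle(h$theta[length(h$theta)] - h$theta[1])
  })
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) {
    stop("no trajectory qualifies (duration >= ", min_duration, " min)",
         call. = FALSE)
  }
  ks <- suppressWarnings(ks.test(angles, "punif", -pi, pi))
  list(angles = unname(angles), ks_stat = unname(ks$statistic),
       p_value = ks$p.value, n = length(angles))
}

#' Tangent-angle autocorrelation along trajectories
#'
#' For each ordered pair of points on the same trajectory separated by arc
#' length `s`, records `cos(theta(s) - theta(0))`; the binned mean traces
#' the exponential decay `exp(-dtheta * s / v)` characteristic of a
#' persistent random walk. Also collects the per-step heading increments
#' `(delta_theta, delta_s)` (wrapped to (-pi, pi]) that feed the
#' maximum-likelihood estimator [mle_dtheta()].
#'
#' Headings are taken from a stored `heading_rad` column when present
#' (exact tangents, e.g. noise-free synthetic data); otherwise they are
#' estimated as chord directions of consecutive displacements, the only
#' option for real tracings. The heading source is recorded because chord
#' directions are window-averaged tangents whose increments carry 2/3 of
#' the tangent-increment variance (see [mle_dtheta()]).
#'
#' @param trajectories Trajectory tibble.
#' @param bin_width Arc-length bin for the correlation curve, um; default
#'   the median step length.
#' @param v Growth speed, um/min. When supplied, arc-length positions are
#'   the exact frozen-shape coordinates `v * t`; when `NULL`, chord-sum
#'   arc lengths are used, which slightly understate arc length on curved
#'   paths.
#' @param use_stored Use the `heading_rad` column when available.
#' @param max_pairs_per_path Cap on sampled pairs per trajectory (the curve
#'   is for display; the estimator uses only consecutive increments). `0`
#'   skips the correlation curve entirely and returns empty bins.
#' @return A `prw_acf` object: list with `bins` (tibble `s_um`, `mean_cos`,
#'   `n`), `increments` (tibble `dtheta_rad`, `ds_um`), `heading_source`.
#' @export
tangent_autocorrelation <- function(trajectories, bin_width = NULL,
                                    v = NULL, use_stored = TRUE,
                                    max_pairs_per_path = 5000) {
  paths <- split_paths(trajectories)
  hs <- purrr::map(paths, path_headings, use_stored = use_stored, v = v)
  hs <- purrr::keep(hs, ~ length(.x$theta) >= 2)
  if (length(hs) == 0) stop("no usable trajectories", call. = FALSE)
  source <- hs[[1]]$source

  increments <- purrr::map_dfr(hs, function(h) {
    tibble::tibble(dtheta_rad = wrap_angle(diff(h$theta)),
                   ds_um = diff(h$s))
  })
  increments <- increments[increments$ds_um > 0, ]

  if (max_pairs_per_path == 0) {
    return(structure(list(
      bins = tibble::tibble(s_um = 0, mean_cos = 1, n = NA_integer_),
      increments = increments, heading_source = source), class = "prw_acf"))
  }
  pairs <- purrr::map_dfr(hs, function(h) {
    m <- length(h$theta)
    ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    if (nrow(ij) > max_pairs_per_path) {
      ij <- ij[sample.int(nrow(ij), max_pairs_per_path), , drop = FALSE]
    }
    tibble::tibble(s = h$s[ij[, 2]] - h$s[ij[, 1]],
                   cosdiff = cos(h$theta[ij[, 2]] - h$theta[ij[, 1]]))
  })
  if (is.null(bin_width)) bin_width <- stats::median(increments$ds_um)
  bins <- pairs |>
    dplyr::mutate(s_bin = (floor(.data$s / bin_width) + 0.5) * bin_width) |>
    dplyr::group_by(s_um = .data$s_bin) |>
    dplyr::summarise(mean_cos = mean(.data$cosdiff), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$s_um)
  bins <- dplyr::bind_rows(tibble::tibble(s_um = 0, mean_cos = 1,
                                          n = NA_integer_), bins)
  structure(list(bins = bins, increments = increments,
                 heading_source = source),
            class = "prw_acf")
}

#' @export
print.prw_acf <- function(x, ...) {
  cat(sprintf("<prw_acf> %d increments (%s headings), %d correlation bins\n",
              nrow(x$increments), x$heading_source, nrow(x$bins)))
  invisible(x)
}

#' Maximum-likelihood estimate of the angular diffusion coefficient
#'
#' Under the persistent random walk, tangent-angle increments over arc
#' length `ds` are independent zero-mean Gaussians with variance
#' `2 * dtheta * ds / v`. The closed-form MLE is
#' `dtheta_hat = (v / (2 N)) * sum(dtheta_i^2 / ds_i)`, with a 90% CI from
#' the observed information, `dtheta_hat * (1 +/- 1.645 * sqrt(2 / N))`.
#'
#' When headings were estimated from chord directions (positions-only
#' data), each chord is effectively the tangent averaged over its window,
#' and consecutive window-averages of a Wiener process have increment
#' variance `(2/3) * 2 * dtheta * ds / v`. The estimator therefore applies
#' a 3/2 correction factor in chord mode (`chord_correction = TRUE`), and
#' widens the CI by `sqrt(9/8)` to account for the lag-one correlation
#' (coefficient 1/4) that window averaging induces between consecutive
#' increments. Stored exact tangents need neither adjustment.
#'
#' @param acf_data A `prw_acf` from [tangent_autocorrelation()].
#' @param v Tip speed, um/min.
#' @param chord_correction Apply the 3/2 chord-variance correction when the
#'   headings were chord-estimated.
#' @return A `prw_dtheta_fit` with `dtheta_hat`, `ci90`, `lp_hat`, `n`.
#'   All-zero increments give `dtheta_hat = 0` with a degenerate CI and a
#'   `degenerate` flag.
#' @export
mle_dtheta <- function(acf_data, v, chord_correction = TRUE) {
  stopifnot(inherits(acf_data, "prw_acf"), v > 0)
  inc <- acf_data$increments
  n <- nrow(inc)
  if (n < 2) stop("need at least 2 increments", call. = FALSE)
  chord <- identical(acf_data$heading_source, "chord")
  corr <- if (chord && chord_correction) 3 / 2 else 1
  dhat <- corr * v / (2 * n) * sum(inc$dtheta_rad^2 / inc$ds_um)
  degenerate <- dhat == 0
  z <- qnorm(0.95)
  infl <- if (chord && chord_correction) sqrt(9 / 8) else 1
  ci <- if (degenerate) c(0, 0) else dhat * (1 + c(-1, 1) * z * infl * sqrt(2 / n))
  structure(list(
    dtheta_hat = dhat,
    ci90 = c(lower = max(0, ci[1]), upper = ci[2]),
    lp_hat = if (degenerate) Inf else v / (2 * dhat),
    n = n, v = v, degenerate = degenerate,
    heading_source = acf_data$heading_source,
    chord_correction = chord && chord_correction
  ), class = "prw_dtheta_fit")
}

#' @export
print.prw_dtheta_fit <- function(x, ...) {
  cat(sprintf(
    "<prw_dtheta_fit> dtheta = %.4g /min (90%% CI %.4g-%.4g), lp = %.4g um, N = %d%s\n",
    x$dtheta_hat, x$ci90[1], x$ci90[2], x$lp_hat, x$n,
    if (x$degenerate) " [degenerate: all increments zero]" else ""))
  invisible(x)
}

#' @rdname tidy.prw_msd_fit
#' @export
glance.prw_dtheta_fit <- function(x, ...) {
  tibble::tibble(dtheta_hat = x$dtheta_hat,
                 ci90_lower = unname(x$ci90[1]),
                 ci90_upper = unname(x$ci90[2]),
                 lp_hat = x$lp_hat, n = x$n,
                 heading_source = x$heading_source,
                 degenerate = x$degenerate)
}
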