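#' Model parameters for a finite-length persistent random walk search
#'
#' Bundles the five physical parameters of the search model together with the
#' integration step. The searcher tip moves at constant speed `v` while its
#' heading diffuses with angular diffusion coefficient `dtheta`; the search
#' terminates at first contact with a disk target of radius `rtarg`, or when
#' the contour length reaches `lmax`. The source sits at distance `dtarg`
#' from the *surface* of the target, i.e. at `rtarg + dtarg` from its centre.
#'
#' Defaults are the measured airineme values: speed 4.5 um/min, maximum
#' length 250 um, surface-to-source gap 50 um, target radius 25 um, and the
#' maximum-likelihood angular diffusion 0.1838 rad^2/min.
#'
#' Two discretisation guards are enforced: `v * dt <= rtarg / 10` so a single
#' step cannot tunnel past the target (contact detection additionally uses
#' the swept segment, making results robust in `dt`), and
#' `dtheta * dt <= 0.05` so the Euler--Maruyama heading update resolves the
#' angular diffusion (`dt` must be well below `1 / dtheta`).
#'
#' @param v Tip speed, um/min. Positive.
#' @param dtheta Angular diffusion coefficient, rad^2/min. Non-negative.
#' @param lmax Maximum contour length, um. Positive.
#' @param dtarg Gap from source point to the target surface, um. Non-negative.
#' @param rtarg Target radius, um. Positive.
#' @param dt Integration step, min. Positive; see guards above.
#'
#' @return An object of class `prw_params`: a named list of the six values.
#' @examples
#' p <- prw_params()
#' p$dtheta
#' prw_params(dtheta = 0.5, dt = 0.1)
#' @export
prw_params <- function(v = 4.5, dtheta = 0.1838, lmax = 250,
                       dtarg = 50, rtarg = 25, dt = 0.1) {
  stopifnot(is.numeric(v), is.numeric(dtheta), is.numeric(lmax),
            is.numeric(dtarg), is.numeric(rtarg), is.numeric(dt))
  if (!(v > 0)) stop("`v` must be positive", call. = FALSE)
  if (dtheta < 0) stop("`dtheta` must be non-negative", call. = FALSE)
  if (!(lmax > 0)) stop("`lmax` must be positive", call. = FALSE)
  if (dtarg < 0) stop("`dtarg` must be non-negative", call. = FALSE)
  if (!(rtarg > 0)) stop("`rtarg` must be positive", call. = FALSE)
  if (!(dt > 0)) stop("`dt` must be positive", call. = FALSE)
  if (v * dt > rtarg / 10 + 1e-12) {
    stop("anti-tunneling guard violated: need v * dt <= rtarg / 10 (got ",
         signif(v * dt, 4), " > ", signif(rtarg / 10, 4), ")", call. = FALSE)
  }
  if (dtheta * dt > 0.05 + 1e-12) {
    stop("discretization guard violated: need dtheta * dt <= 0.05 (got ",
         signif(dtheta * dt, 4), ")", call. = FALSE)
  }
  structure(list(v = v, dtheta = dtheta, lmax = lmax,
                 dtarg = dtarg, rtarg = rtarg, dt = dt),
            class = "prw_params")
}

#' @export
print.prw_params <- function(x, ...) {
  cat("<prw_params>\n")
  cat(sprintf("  v      %8.4g um/min\n", x$v))
  cat(sprintf("  dtheta %8.4g rad^2/min  (lp = %.4g um)\n",
              x$dtheta, persistence_from_dtheta(x$dtheta, x$v)))
  cat(sprintf("  lmax   %8.4g um\n", x$lmax))
  cat(sprintf("  dtarg  %8.4g um (surface gap; source at %.4g um from centre)\n",
              x$dtarg, x$rtarg + x$dtarg))
  cat(sprintf("  rtarg  %8.4g um\n", x$rtarg))
  cat(sprintf("  dt     %8.4g min\n", x$dt))
  invisible(x)
}

#' Convert between angular diffusion and directional persistence length
#'
#' In two dimensions a persistent random walk with speed `v` and angular
#' diffusion `dtheta` has tangent autocorrelation
#' `<cos theta(s)> = exp(-dtheta * s / v)` along arc length `s`, so the
#' directional persistence length is `lp = v / (2 * dtheta)` (the arc-length
#' scale on which `<cos>` decays by `exp(-1/2)`; equivalently the worm-like
#' chain persistence length).
#'
#' @param dtheta Angular diffusion coefficient, rad^2/min.
#' @param lp Persistence length, um.
#' @param v Tip speed, um/min.
#' @return The converted scalar. `persistence_from_dtheta(0, v)` is `Inf`
#'   (a perfectly straight path) with a warning.
#' @examples
#' dtheta_from_persistence(12.24, v = 4.5) # 0.1838...
#' persistence_from_dtheta(0.1838, v = 4.5)
#' @export
persistence_from_dtheta <- function(dtheta, v) {
  stopifnot(v > 0, dtheta >= 0)
  if (any(dtheta == 0)) {
    warning("dtheta = 0: persistence length is infinite (ballistic path)")
  }
  v / (2 * dtheta)
}

#' @rdname persistence_from_dtheta
#' @export
dtheta_from_persistence <- function(lp, v) {
  stopifnot(v > 0, all(lp > 0))
  v / (2 * lp)
}

#' Characteristic timescales of the search process
#'
#' Two bookkeeping timescales: the mean waiting time between successive
#' search initiations from one source cell (`1 / rate`, converted to
#' minutes), and the duration of a single full-length search (`lmax / v`).
#' For airinemes (initiation rate 0.15 per cell per hour, `lmax` 250 um,
#' `v` 4.5 um/min) these are 400 min and about 56 min: initiations are rare
#' compared to the extension time, so searches can be treated as independent
#' one-at-a-time events.
#'
#' @param rate_per_hour Search initiation rate, events per cell per hour.
#' @param lmax Maximum contour length, um.
#' @param v Tip speed, um/min.
#' @return A tibble with columns `mean_wait_min` and `extension_min`.
#' @examples
#' search_timescales()
#' @export
search_timescales <- function(rate_per_hour = 0.15, lmax = 250, v = 4.5) {
  stopifnot(rate_per_hour > 0, lmax > 0, v > 0)
  tibble::tibble(
    mean_wait_min = 60 / rate_per_hour,
    extension_min = lmax / v
  )
}

#' Search geometry implied by a parameter set
#'
#' The target disk is centred at the origin; the source point lies on the
#' positive x-axis at `rtarg + dtarg` from the centre. Angles on the target
#' circle are measured at the centre with the source direction at angle 0,
#' counterclockwise positive, in (-pi, pi].
#'
#' @param params A [prw_params()] object.
#' @return A list with `target_center`, `source_point`, `rtarg`.
#' @examples
#' search_geometry(prw_params())$source_point
#' @export
search_geometry <- function(params) {
  stopifnot(inherits(params, "prw_params"))
  list(target_center = c(0, 0),
       source_point = c(params$rtarg + params$dtarg, 0),
       rtarg = params$rtarg)
}
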