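#' Circular density estimate of contact angles
#'
#' Wrapped-kernel density estimate of the contact-angle distribution
#' `f(theta_contact)` on a uniform periodic grid over (-pi, pi]. The model
#' is rotationally symmetric, so with the source placed at angle 0 the
#' distribution depends only on `theta_contact - theta_origin`, and the
#' estimated density is a location family in the source direction.
#'
#' Samples are binned on the grid and convolved (circularly, via FFT) with
#' a wrapped Gaussian kernel. The default bandwidth is the circular
#' Silverman rule `sigma_hat * (4 / (3 n))^(1/5)` with
#' `sigma_hat = sqrt(-2 log Rbar)` the circular standard deviation. The
#' density is floored at `1e-6` and renormalised so the downstream Fisher
#' information ratio `f'^2 / f` stays conditioned where contacts are absent.
#'
#' @param x A `prw_ensemble` (its contact angles are used) or a numeric
#'   vector of contact angles in rad.
#' @param bandwidth Kernel bandwidth, rad; default circular Silverman.
#' @param grid_size Number of grid nodes (default 720).
#' @return A `prw_angle_density`: list with `grid` (tibble `theta_rad`,
#'   `density`), `bandwidth`, `n`, `samples`.
#' @examples
#' ens <- simulate_ensemble(prw_params(), n = 3000, seed = 2)
#' d <- contact_angle_distribution(ens)
#' fisher_information(d)
#' @export
contact_angle_distribution <- function(x, bandwidth = NULL, grid_size = 720) {
  samples <- if (inherits(x, "prw_ensemble")) x$contact_angles else as.numeric(x)
  if (length(samples) == 0) {
    stop("no contacts: the contact-angle distribution is undefined ",
         "(this is not the same as zero Fisher information)", call. = FALSE)
  }
  stopifnot(grid_size >= 16)
  samples <- wrap_angle(samples)
  n <- length(samples)
  if (is.null(bandwidth)) {
    rbar <- Mod(mean(exp(1i * samples)))
    sig <- sqrt(pmax(-2 * log(pmax(rbar, 1e-12)), 1e-8))
    bandwidth <- sig * (4 / (3 * n))^(1 / 5)
  }
  stopifnot(bandwidth > 0)
  h <- 2 * pi / grid_size
  # bin counts on grid cell midpoints, then circular convolution with a
  # wrapped Gaussian kernel
  edges <- seq(-pi, pi, length.out = grid_size + 1)
  counts <- tabulate(findInterval(samples, edges, all.inside = TRUE),
                     nbins = grid_size)
  mids <- edges[-1] - h / 2
  dd <- wrap_angle(mids - mids[1])
  kern <- rowSums(vapply(-3:3, function(k) dnorm(dd + 2 * pi * k, sd = bandwidth),
                         numeric(grid_size)))
  dens <- Re(stats::fft(stats::fft(counts) * stats::fft(kern), inverse = TRUE)) /
    grid_size
  dens <- dens / (n)  # kernel is a density in theta already
  dens <- pmax(dens, 1e-6)
  dens <- dens / (sum(dens) * h)
  dens <- pmax(dens, 1e-6)  # keep the floor after renormalisation
  structure(list(
    grid = tibble::tibble(theta_rad = mids, density = dens),
    bandwidth = bandwidth, n = n, samples = samples
  ), class = "prw_angle_density")
}

#' @export
print.prw_angle_density <- function(x, ...) {
  cat(sprintf(
    "<prw_angle_density> %d contact angles, bandwidth %.4g rad, %d grid nodes\n",
    x$n, x$bandwidth, nrow(x$grid)))
  invisible(x)
}

#' Fisher information of a single contact
#'
#' The directional information one contact carries about the source
#' direction. For the rotationally symmetric model the conditional density
#' is a location family, `p(theta_contact | theta_origin) =
#' f(theta_contact - theta_origin)`, so the expected-curvature definition
#' of Fisher information reduces to `I1 = integral (f'(theta))^2 / f(theta)
#' dtheta` over the circle. Computed on the estimation grid with periodic
#' central differences. For a Gaussian-like density of circular variance
#' `sigma^2`, `I1` is approximately `1 / sigma^2`: narrow contact-angle
#' distributions are informative, the uniform density carries none
#' (`I1 = 0`).
#'
#' @param distribution A `prw_angle_density` from
#'   [contact_angle_distribution()].
#' @param units `"rad"` (default) or `"deg"`; degree-mode information is
#'   `I1_rad * (pi / 180)^2` exactly.
#' @return Non-negative scalar, rad^-2 (or deg^-2).
#' @export
fisher_information <- function(distribution, units = c("rad", "deg")) {
  stopifnot(inherits(distribution, "prw_angle_density"))
  units <- match.arg(units)
  f <- distribution$grid$density
  th <- distribution$grid$theta_rad
  h <- th[2] - th[1]
  if (abs(sum(f) * h - 1) > 1e-3) {
    stop("density is not normalised", call. = FALSE)
  }
  m <- length(f)
  fp <- (f[c(2:m, 1)] - f[c(m, 1:(m - 1))]) / (2 * h)
  I1 <- sum(fp^2 / f) * h
  if (units == "deg") I1 <- I1 * (pi / 180)^2
  I1
}

#' Contact-probability-weighted Fisher information
#'
#' A target that is almost never contacted receives almost no directional
#' information however sharp the contact-angle distribution is; weighting
#' the per-contact Fisher information by the contact probability scores
#' that trade-off: `mod_fi = I1 * p_contact`.
#'
#' @param I1 Per-contact Fisher information (>= 0).
#' @param p_contact Contact probability in `[0, 1]`.
#' @return `I1 * p_contact`.
#' @examples
#' modified_fisher_information(100, 0.185)
#' @export
modified_fisher_information <- function(I1, p_contact) {
  stopifnot(all(I1 >= 0), all(p_contact >= 0), all(p_contact <= 1))
  I1 * p_contact
}

#' Signed three-point contact angle
#'
#' The angle at the target centre between the ray toward the search origin
#' and the ray toward the contact point, as measured on images by
#' connecting origin, target centre, and docking site with two intersecting
#' lines. Counterclockwise is positive; the result is in degrees in
#' (-180, 180].
#'
#' @param origin_point,target_center,contact_point Numeric length-2 points
#'   (um); pairwise distinct.
#' @return Signed angle in degrees.
#' @examples
#' three_point_contact_angle(c(100, 0), c(0, 0), c(0, 25)) # +90
#' @export
three_point_contact_angle <- function(origin_point, target_center,
                                      contact_point) {
  r1 <- origin_point - target_center
  r2 <- contact_point - target_center
  if (sum(r1^2) == 0 || sum(r2^2) == 0) {
    stop("points must be pairwise distinct from the target centre",
         call. = FALSE)
  }
  ang <- atan2(r1[1] * r2[2] - r1[2] * r2[1], sum(r1 * r2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
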