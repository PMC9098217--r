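#' Advance a persistent random walk by one Euler--Maruyama step
#'
#' The reference single-step update: the displacement uses the *current*
#' heading, and the heading is then advanced by the stochastic increment
#' `sqrt(2 * dtheta * dt) * noise_draw` (explicit Euler--Maruyama). The
#' returned heading is the one the *next* step will use, so the displacement
#' magnitude is exactly `v * dt` every step.
#'
#' This scalar R implementation documents the update convention and backs the
#' unit tests; ensemble simulation runs the same update in compiled code.
#'
#' @param position Numeric length-2, current tip position (um).
#' @param heading Current heading angle, rad (unwrapped).
#' @param params A [prw_params()] object.
#' @param noise_draw A standard-normal variate.
#' @return A list with `position` (length-2) and `heading` (scalar).
#' @examples
#' step_prw(c(0, 0), 0, prw_params(dtheta = 0), noise_draw = 0)
#' @export
step_prw <- function(position, heading, params, noise_draw) {
  stopifnot(inherits(params, "prw_params"), length(position) == 2,
            is.finite(heading), is.finite(noise_draw))
  new_pos <- position + params$v * params$dt * c(cos(heading), sin(heading))
  new_heading <- heading + sqrt(2 * params$dtheta * params$dt) * noise_draw
  list(position = new_pos, heading = new_heading)
}

#' First contact of a segment with the target disk
#'
#' Returns the earliest point of the directed segment at distance `rtarg`
#' from the target centre, or `NULL` if the segment's closest approach stays
#' outside the disk. Testing the swept segment (rather than only the
#' endpoint) prevents a fast tip from tunnelling through the target between
#' frames; with it, contact detection is robust in the integration step.
#' A zero-length segment degenerates to a point-on-disk test.
#'
#' @param segment_start,segment_end Numeric length-2 endpoints (um).
#' @param geometry A [search_geometry()] list (target centre and radius).
#' @return Numeric length-2 contact point, or `NULL`.
#' @examples
#' g <- search_geometry(prw_params())
#' detect_contact(c(30, 0), c(20, 0), g) # (25, 0)
#' detect_contact(c(100, 100), c(90, 100), g) # NULL
#' @export
detect_contact <- function(segment_start, segment_end, geometry) {
  p0 <- segment_start - geometry$target_center
  p1 <- segment_end - geometry$target_center
  r <- geometry$rtarg
  c0 <- sum(p0^2) - r^2
  if (c0 <= 0) return(segment_start)  # already on/inside the surface
  d <- p1 - p0
  a <- sum(d^2)
  if (a == 0) return(NULL)
  b <- 2 * sum(p0 * d)
  disc <- b^2 - 4 * a * c0
  if (disc < 0) return(NULL)
  s <- (-b - sqrt(disc)) / (2 * a)
  if (s < 0 || s > 1) return(NULL)
  geometry$target_center + p0 + s * d
}

#' Simulate one finite-length search trajectory
#'
#' Runs a single persistent random walk from the source point until first
#' contact with the target disk or until the contour length reaches `lmax`,
#' recording every integration step.
#'
#' @param params A [prw_params()] object.
#' @param initial_angle Initial heading, rad. Drawn uniformly on (-pi, pi]
#'   when `NULL`.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG state.
#' @return A `prw_trajectory`: a list with `path` (tibble: `frame`, `t_min`,
#'   `x_um`, `y_um`, `heading_rad`), `contacted`, `t_contact`,
#'   `contact_point`, `contact_angle` (rad, source direction = 0),
#'   `final_length`, and `params`.
#' @examples
#' tr <- simulate_airineme(prw_params(dtheta = 0), initial_angle = pi, seed = 1)
#' tr$contacted; tr$t_contact # straight shot: contact after dtarg / v min
#' @export
simulate_airineme <- function(params, initial_angle = NULL, seed = NULL) {
  stopifnot(inherits(params, "prw_params"))
  run <- function() {
    if (is.null(initial_angle)) initial_angle <- runif(1, -pi, pi)
    raw <- prw_ensemble_cpp(1L, params$v, params$dtheta, params$lmax,
                            params$rtarg + params$dtarg, 0, params$rtarg,
                            params$dt, initial_angle, params$lmax / params$v,
                            1L)
    raw
  }
  raw <- if (is.null(seed)) run() else with_seed(seed, run())
  path <- tibble::tibble(
    frame = seq_along(raw$rec_t) - 1L,
    t_min = raw$rec_t,
    x_um = raw$rec_x,
    y_um = raw$rec_y,
    heading_rad = raw$rec_theta
  )
  contacted <- raw$contacted[1]
  structure(list(
    path = path,
    contacted = contacted,
    t_contact = if (contacted) raw$t_contact[1] else NA_real_,
    contact_point = if (contacted) c(raw$contact_x[1], raw$contact_y[1]) else NULL,
    contact_angle = if (contacted) atan2(raw$contact_y[1], raw$contact_x[1]) else NA_real_,
    final_length = raw$final_length[1],
    params = params
  ), class = "prw_trajectory")
}

#' @export
print.prw_trajectory <- function(x, ...) {
  cat("<prw_trajectory> ", nrow(x$path), " frames, ",
      if (x$contacted) sprintf("contact at t = %.3g min, angle %.3g rad",
                               x$t_contact, x$contact_angle)
      else sprintf("no contact (final length %.4g um)", x$final_length),
      "\n", sep = "")
  invisible(x)
}

wilson_ci <- function(k, n, level = 0.90) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, mid - half), upper = min(1, mid + half))
}

#' Simulate an ensemble of independent searches
#'
#' Runs `n` independent finite-length persistent random walks from the source
#' point, each with an initial heading drawn uniformly on (-pi, pi], and
#' summarises contact outcomes. The contact probability carries a Wilson
#' score 90% confidence interval. An identical `(seed, n, params)` triple
#' reproduces the ensemble bit-identically.
#'
#' @param params A [prw_params()] object.
#' @param n Number of trajectories (>= 1).
#' @param seed Integer root seed.
#' @param durations Optional per-trajectory growth times, min (recycled);
#'   default `lmax / v` (all searches run to full length).
#' @param record_every Record tip state every this many steps (0 = record
#'   nothing; memory grows with `n` when recording).
#' @return A `prw_ensemble` object; see [glance.prw_ensemble()] and
#'   [tidy.prw_ensemble()].
#' @examples
#' ens <- simulate_ensemble(prw_params(), n = 2000, seed = 1)
#' glance(ens)
#' @export
simulate_ensemble <- function(params, n, seed = 1L, durations = NULL,
                              record_every = 0L) {
  stopifnot(inherits(params, "prw_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.null(durations)) durations <- params$lmax / params$v
  raw <- with_seed(derive_seed(seed, 1L), {
    init <- runif(n, -pi, pi)
    prw_ensemble_cpp(n, params$v, params$dtheta, params$lmax,
                     params$rtarg + params$dtarg, 0, params$rtarg, params$dt,
                     init, durations, as.integer(record_every))
  })
  k <- sum(raw$contacted)
  hit <- which(raw$contacted)
  recorded <- if (record_every > 0) {
    tibble::tibble(
      airineme_id = raw$rec_id, t_min = raw$rec_t,
      x_um = raw$rec_x, y_um = raw$rec_y, heading_rad = raw$rec_theta
    ) |>
      dplyr::group_by(.data$airineme_id) |>
      dplyr::mutate(frame = dplyr::row_number() - 1L) |>
      dplyr::ungroup() |>
      dplyr::select("airineme_id", "frame", "t_min", "x_um", "y_um",
                    "heading_rad")
  } else NULL
  structure(list(
    params = params, n = n, n_contacts = k,
    p_contact = k / n,
    ci90 = wilson_ci(k, n, 0.90),
    contacted = raw$contacted,
    contact_angles = atan2(raw$contact_y[hit], raw$contact_x[hit]),
    t_contact = raw$t_contact[hit],
    length_distribution = raw$final_length,
    seed = as.integer(seed),
    recorded = recorded
  ), class = "prw_ensemble")
}

#' @export
print.prw_ensemble <- function(x, ...) {
  cat(sprintf(
    "<prw_ensemble> n = %d, contacts = %d, p_contact = %.4f (90%% CI %.4f-%.4f)\n",
    x$n, x$n_contacts, x$p_contact, x$ci90[1], x$ci90[2]))
  invisible(x)
}

#' Summarise an ensemble
#'
#' `glance()` returns the one-row Monte-Carlo summary; `tidy()` returns one
#' row per contact with the contact angle and time.
#'
#' @param x A `prw_ensemble` from [simulate_ensemble()].
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.prw_ensemble <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_contacts = x$n_contacts, p_contact = x$p_contact,
    ci90_lower = unname(x$ci90[1]), ci90_upper = unname(x$ci90[2]),
    mean_final_length = mean(x$length_distribution), seed = x$seed
  )
}

#' @rdname glance.prw_ensemble
#' @export
tidy.prw_ensemble <- function(x, ...) {
  tibble::tibble(
    contact = seq_len(x$n_contacts),
    theta_contact_rad = x$contact_angles,
    t_contact_min = x$t_contact
  )
}
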