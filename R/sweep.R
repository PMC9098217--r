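#' Default log-spaced angular-diffusion grid
#'
#' 20 log-spaced values on `[0.02, 2]` rad^2/min, the default sweep grid:
#' the contact-optimal curvature moves over decades as the geometry
#' changes, so log spacing gives even resolution everywhere.
#'
#' @param from,to Grid limits, rad^2/min.
#' @param length.out Number of grid points.
#' @return Numeric vector of `dtheta` values.
#' @export
default_dtheta_grid <- function(from = 0.02, to = 2, length.out = 20) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# Adjust the integration step so the discretisation guards hold at this
# dtheta (high-curvature grid points need a finer step).
params_at_dtheta <- function(params, dtheta) {
  dt <- min(params$dt, if (dtheta > 0) 0.05 / dtheta else Inf,
            params$rtarg / (10 * params$v))
  prw_params(v = params$v, dtheta = dtheta, lmax = params$lmax,
             dtarg = params$dtarg, rtarg = params$rtarg, dt = dt)
}

#' Contact probability across a grid of angular diffusion values
#'
#' Runs an independent Monte-Carlo ensemble at every `dtheta` grid point
#' (sub-seeds derived from the root seed, so grid points are independent
#' and the whole sweep is reproducible) and reports the contact fraction
#' with its binomial standard error. The integration step is refined
#' automatically at high-curvature grid points to keep
#' `dtheta * dt <= 0.05`.
#'
#' @param dtheta_grid Angular diffusion values, rad^2/min; default 20
#'   log-spaced points in `[0.02, 2]` (the optimum moves over decades as
#'   geometry changes, so a log grid is the natural resolution).
#' @param params A [prw_params()] object (its `dtheta` is ignored).
#' @param n Trajectories per grid point.
#' @param seed Root seed.
#' @param keep_angles Also keep each grid point's contact angles (needed by
#'   [tradeoff_curve()]).
#' @return A `prw_sweep` tibble: `dtheta`, `p_contact`, `se`, `n`
#'   (and a list-column `angles` when `keep_angles`).
#' @examples
#' sw <- sweep_contact_probability(c(0.05, 0.2, 1), n = 2000, seed = 1)
#' @export
sweep_contact_probability <- function(dtheta_grid = default_dtheta_grid(),
                                      params = prw_params(), n = 1e4,
                                      seed = 1L, keep_angles = FALSE) {
  stopifnot(length(dtheta_grid) >= 1, all(dtheta_grid >= 0), n >= 1)
  rows <- purrr::imap(dtheta_grid, function(dth, j) {
    p <- params_at_dtheta(params, dth)
    ens <- simulate_ensemble(p, n = n, seed = derive_seed(seed, j))
    tibble::tibble(
      dtheta = dth, p_contact = ens$p_contact,
      se = sqrt(ens$p_contact * (1 - ens$p_contact) / n),
      n = as.integer(n),
      angles = if (keep_angles) list(ens$contact_angles) else list(NULL)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_angles) out$angles <- NULL
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("prw_sweep", class(out))
  out
}

# Quadratic fit of p against dtheta on a window of grid points around the
# empirical argmax; returns the fitted vertex. The fit is on the linear
# dtheta axis: on a log axis the peak is strongly skewed and the vertex of
# any local quadratic lands systematically below the true argmax, whereas
# in linear dtheta the peak is nearly symmetric and the vertex estimator is
# consistent (checked against high-precision scans of the contact curve).
quad_peak <- function(d, p, centre, half) {
  idx <- max(1, centre - half):min(length(p), centre + half)
  fit <- lm(p[idx] ~ poly(d[idx], 2, raw = TRUE))
  b <- coef(fit)
  if (!is.finite(b[3]) || b[3] >= 0) return(d[centre])  # no curvature: keep argmax
  vertex <- -b[2] / (2 * b[3])
  min(max(vertex, min(d[idx])), max(d[idx]))
}

#' Refine the contact-probability-optimal angular diffusion
#'
#' Takes a sweep curve, finds the empirical argmax, and fits a local
#' quadratic in `p` versus `dtheta` over a window of grid points to
#' de-noise Monte-Carlo jitter; the fitted vertex is the reported optimum.
#' The fit uses the linear `dtheta` axis: the contact-probability peak is
#' close to symmetric there, whereas on the log axis it is skewed enough
#' that a local quadratic vertex is biased below the true argmax. A
#' parametric bootstrap (binomial resampling of each grid point's contact
#' count) gives the 90% CI.
#'
#' @param curve A `prw_sweep` from [sweep_contact_probability()] (needs
#'   >= 5 points spanning the peak).
#' @param window Number of grid points in the quadratic window (odd;
#'   default 5).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return A list with `dtheta_star`, `ci90`, `window_index`.
#' @export
optimal_dtheta <- function(curve, window = 5, n_boot = 200, seed = 1L) {
  stopifnot(nrow(curve) >= 5, window >= 3)
  ord <- order(curve$dtheta)
  d <- curve$dtheta[ord]; p <- curve$p_contact[ord]
  n <- curve$n[ord]
  k <- which.max(p)
  if (k == 1 || k == length(p)) {
    stop("empirical argmax lies on the grid edge; extend the dtheta grid",
         call. = FALSE)
  }
  half <- floor(window / 2)
  star <- quad_peak(d, p, k, half)
  boot <- with_seed(derive_seed(seed, 97L), {
    replicate(n_boot, {
      pb <- stats::rbinom(length(p), n, p) / n
      kb <- which.max(pb)
      kb <- min(max(kb, 2), length(p) - 1)
      quad_peak(d, pb, kb, half)
    })
  })
  list(dtheta_star = star,
       ci90 = unname(quantile(boot, c(0.05, 0.95))),
       window_index = max(1, k - half):min(length(p), k + half))
}

#' Map of the optimal angular diffusion over search geometries
#'
#' Repeats the sweep-and-refine procedure of
#' [sweep_contact_probability()] + [optimal_dtheta()] for every
#' combination of source gap and target radius. Cells whose empirical
#' argmax falls on the grid edge are flagged (`edge = TRUE`, `dtheta_star =
#' NA`) rather than failing the whole map. Far or large targets favour
#' straighter searches (small optimum); small or near targets favour
#' diffusive ones.
#'
#' @param dtarg_grid,rtarg_grid Geometry grids, um.
#' @param dtheta_grid Angular diffusion grid, rad^2/min.
#' @param params Base [prw_params()].
#' @param n Trajectories per (geometry, dtheta) point.
#' @param seed Root seed.
#' @return A tibble: `dtarg`, `rtarg`, `dtheta_star`, `ci90_lower`,
#'   `ci90_upper`, `edge`.
#' @export
optimal_dtheta_map <- function(dtarg_grid, rtarg_grid,
                               dtheta_grid = default_dtheta_grid(),
                               params = prw_params(), n = 1e4, seed = 1L) {
  stopifnot(length(dtarg_grid) >= 1, length(rtarg_grid) >= 1)
  cells <- tidyr::expand_grid(dtarg = dtarg_grid, rtarg = rtarg_grid)
  purrr::pmap_dfr(cells, function(dtarg, rtarg) {
    p <- prw_params(v = params$v, dtheta = params$dtheta, lmax = params$lmax,
                    dtarg = dtarg, rtarg = rtarg,
                    dt = min(params$dt, rtarg / (10 * params$v)))
    cell_seed <- derive_seed(seed, round(dtarg * 1e3 + rtarg))
    sw <- sweep_contact_probability(dtheta_grid, p, n = n, seed = cell_seed)
    opt <- tryCatch(optimal_dtheta(sw, seed = cell_seed),
                    error = function(e) NULL)
    tibble::tibble(
      dtarg = dtarg, rtarg = rtarg,
      dtheta_star = if (is.null(opt)) NA_real_ else opt$dtheta_star,
      ci90_lower = if (is.null(opt)) NA_real_ else opt$ci90[1],
      ci90_upper = if (is.null(opt)) NA_real_ else opt$ci90[2],
      edge = is.null(opt)
    )
  })
}

#' Pareto-optimal points of a two-objective set
#'
#' A point is Pareto-optimal when no other point is at least as good in
#' both objectives and strictly better in one (both objectives maximised).
#' Implemented as a sort-based scan, O(n log n).
#'
#' @param x,y Objective values (same length).
#' @return Logical vector: `TRUE` for non-dominated points.
#' @examples
#' pareto_front(c(1, 2, 3), c(3, 2, 1)) # all on the front
#' pareto_front(c(1, 2), c(1, 2)) # second dominates first
#' @export
pareto_front <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  keep <- logical(n)
  ord <- order(-x, -y)
  best_y <- -Inf
  i <- 1
  while (i <= n) {
    # group of tied x values
    j <- i
    while (j < n && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    grp <- ord[i:j]
    gy <- y[grp]
    gmax <- max(gy)
    keep[grp] <- (gy > best_y) & (gy == gmax)
    best_y <- max(best_y, gmax)
    i <- j + 1
  }
  keep
}

#' Search-success / directional-information trade-off curve
#'
#' For each angular diffusion value, one Monte-Carlo ensemble supplies both
#' objectives (common random numbers stabilise the parametric curve): the
#' contact probability, and the modified Fisher information
#' `I1 * p_contact` computed from that ensemble's contact angles. Points
#' are ordered by `dtheta` and flagged for Pareto optimality; `turn` is the
#' cross product of successive chords of the parametric curve
#' (negative = locally concave-down, the shape that creates an interior
#' Pareto optimum).
#'
#' Grid points with zero contacts get `mod_fi = 0` and are flagged
#' `no_contacts`; points with a single contact (no density estimate) get
#' `NA` information and are excluded from the Pareto scan.
#'
#' @param dtheta_grid Angular diffusion grid, rad^2/min.
#' @param params Base [prw_params()].
#' @param n Trajectories per grid point.
#' @param seed Root seed.
#' @param bandwidth,grid_size Passed to [contact_angle_distribution()].
#' @param units Angle units for the Fisher information.
#' @return A `prw_tradeoff` tibble: `dtheta`, `p_contact`, `I1`, `mod_fi`,
#'   `pareto`, `turn`, `no_contacts`.
#' @export
tradeoff_curve <- function(dtheta_grid = default_dtheta_grid(),
                           params = prw_params(), n = 1e4, seed = 1L,
                           bandwidth = NULL, grid_size = 720,
                           units = "rad") {
  sw <- sweep_contact_probability(dtheta_grid, params, n = n, seed = seed,
                                  keep_angles = TRUE)
  out <- sw |>
    dplyr::mutate(
      I1 = purrr::map_dbl(.data$angles, function(a) {
        if (length(a) < 2) return(NA_real_)
        fisher_information(
          contact_angle_distribution(a, bandwidth = bandwidth,
                                     grid_size = grid_size),
          units = units)
      }),
      no_contacts = purrr::map_int(.data$angles, length) == 0,
      mod_fi = dplyr::if_else(.data$no_contacts, 0,
                              .data$I1 * .data$p_contact)
    ) |>
    dplyr::select(-"angles", -"se") |>
    dplyr::arrange(.data$dtheta)
  ok <- !is.na(out$mod_fi)
  out$pareto <- FALSE
  out$pareto[ok] <- pareto_front(out$p_contact[ok], out$mod_fi[ok])
  m <- nrow(out)
  turn <- rep(NA_real_, m)
  if (m >= 3) {
    dp <- diff(out$p_contact); dm <- diff(out$mod_fi)
    turn[2:(m - 1)] <- dp[-(m - 1)] * dm[-1] - dm[-(m - 1)] * dp[-1]
  }
  out$turn <- turn
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("prw_tradeoff", class(out))
  out
}
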