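# Shared fixtures and tiny independent oracles used across test files.

# A straight constant-speed path as a trajectory table.
straight_path <- function(n_frames = 20, v = 4.5, dt = 5, angle = 0,
                          id = 1L, x0 = 0, y0 = 0) {
  t <- (seq_len(n_frames) - 1) * dt
  tibble::tibble(
    airineme_id = id, frame = seq_len(n_frames) - 1L, t_min = t,
    x_um = x0 + v * t * cos(angle), y_um = y0 + v * t * sin(angle),
    heading_rad = angle
  )
}

# Brute-force O(n^2) Pareto dominance scan (the oracle for pareto_front).
pareto_brute <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    dominated <- any(x >= x[i] & y >= y[i] & (x > x[i] | y > y[i]))
    !dominated
  }, logical(1))
}

# Brownian trajectory table generator (oracle for the MSD estimator).
brownian_paths <- function(n_paths, n_frames, D, dt) {
  purrr::map_dfr(seq_len(n_paths), function(i) {
    dx <- rnorm(n_frames - 1, sd = sqrt(2 * D * dt))
    dy <- rnorm(n_frames - 1, sd = sqrt(2 * D * dt))
    tibble::tibble(
      airineme_id = i, frame = seq_len(n_frames) - 1L,
      t_min = (seq_len(n_frames) - 1) * dt,
      x_um = c(0, cumsum(dx)), y_um = c(0, cumsum(dy))
    )
  })
}

default_geom <- function() search_geometry(prw_params())
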