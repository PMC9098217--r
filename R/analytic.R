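#' Contact probability of a straight (ballistic) search
#'
#' In the `dtheta -> 0` limit the searcher travels along a ray with uniform
#' initial direction. A ray from a source at distance `rtarg + dtarg` from
#' the centre hits the disk iff its direction lies within the half-angle
#' subtended by the target, so
#' `p = phi / pi` with `phi = pi/2 - acos(rtarg / (rtarg + dtarg))`.
#' (Only rays aimed toward the target can hit, hence the value is at most
#' 1/2; it reaches 1/2 when the source sits on the target surface.)
#' Reachability (`lmax >= dtarg`) is assumed; the value is purely geometric.
#'
#' @param dtarg Gap from source to target surface, um (>= 0).
#' @param rtarg Target radius, um (> 0).
#' @return Probability in `[0, 1/2]`. Vectorised over both arguments.
#' @examples
#' ballistic_contact_probability(50, 25) # (pi/2 - acos(1/3)) / pi ~ 0.108
#' ballistic_contact_probability(0, 25) # 1/2
#' @export
ballistic_contact_probability <- function(dtarg, rtarg) {
  if (any(dtarg < 0) || any(rtarg <= 0)) {
    stop("need dtarg >= 0 and rtarg > 0", call. = FALSE)
  }
  phi <- pi / 2 - acos(rtarg / (rtarg + dtarg))
  phi / pi
}

#' Mean squared displacement of a persistent random walk
#'
#' Closed form for the 2-D persistent random walk with speed `v` and
#' persistence length `lp`:
#' `msd(t) = 4 lp v t (1 - (2 lp / (v t)) (1 - exp(-v t / (2 lp))))`.
#' Ballistic at short times (`msd ~ v^2 t^2` for `v t << lp`), diffusive at
#' long times (`msd ~ 4 lp v t`, i.e. `4 D t` with `D = lp v = v^2 / (2
#' dtheta)`). Evaluated via a series expansion near `t = 0` for numerical
#' continuity, with `msd(0) = 0`.
#'
#' @param t Elapsed time, min (>= 0). Vectorised.
#' @param v Speed, um/min.
#' @param lp Persistence length, um.
#' @return MSD in um^2.
#' @examples
#' msd_prw(c(1, 5, 50), v = 4.5, lp = 12.24)
#' @export
msd_prw <- function(t, v, lp) {
  stopifnot(all(t >= 0), v > 0, lp > 0)
  u <- v * t / (2 * lp)  # dimensionless time
  out <- numeric(length(u))
  small <- u < 1e-4
  # series: msd = 8 lp^2 (u^2/2 - u^3/6 + u^4/24 - ...)
  us <- u[small]
  out[small] <- 8 * lp^2 * (us^2 / 2 - us^3 / 6 + us^4 / 24)
  ul <- u[!small]
  out[!small] <- 8 * lp^2 * (ul - (1 - exp(-ul)))
  out
}

#' Radial grid for the diffusive-limit survival PDE
#'
#' Discretisation of the radially symmetric survival problem on
#' `[rtarg, r_max]`. The outer radius defaults to
#' `r0 + 4 * sqrt(2 * D * t_max)` (with `r0 = rtarg + dtarg`), far enough
#' that the reflecting outer boundary cannot influence the absorbed mass.
#'
#' @param rtarg Absorbing (target) radius, um.
#' @param dtarg Source gap, um (sets the default domain size).
#' @param D Diffusion coefficient, um^2/min.
#' @param t_max Time horizon, min.
#' @param nr Radial nodes.
#' @param nt Time steps.
#' @param r_max Outer radius, um (default by the 4-sigma rule).
#' @return A list of grid settings used by [diffusive_contact_probability()].
#' @export
pde_grid <- function(rtarg, dtarg, D, t_max, nr = 600, nt = 1200,
                     r_max = NULL) {
  stopifnot(rtarg > 0, dtarg >= 0, D > 0, t_max > 0, nr >= 10, nt >= 10)
  r0 <- rtarg + dtarg
  if (is.null(r_max)) r_max <- r0 + 4 * sqrt(2 * D * t_max)
  if (r_max < r0 + 4 * sqrt(2 * D * t_max) - 1e-9) {
    stop("r_max too small: outer boundary would not be immaterial ",
         "(need r_max >= r0 + 4 * sqrt(2 * D * t_max))", call. = FALSE)
  }
  list(rtarg = rtarg, r_max = r_max, nr = as.integer(nr),
       t_max = t_max, nt = as.integer(nt), D = D)
}

# Crank-Nicolson solve of dS/dt = D (S'' + S'/r) on [rtarg, r_max],
# S(rtarg, t) = 0 (absorbing), zero flux at r_max, S(r, 0) = 1.
# Returns S(r, t_max) on the grid.
solve_survival_pde <- function(grid) {
  nr <- grid$nr
  r <- seq(grid$rtarg, grid$r_max, length.out = nr)
  dr <- r[2] - r[1]
  dtau <- grid$t_max / grid$nt
  lam <- grid$D * dtau / (2 * dr^2)
  mu <- grid$D * dtau / (4 * dr)

  # spatial operator L S (rows 2..nr-1); one-sided handling at boundaries
  lower <- lam - mu / r
  upper <- lam + mu / r
  A <- matrix(0, nr, nr)  # I - (dtau/2) L
  B <- matrix(0, nr, nr)  # I + (dtau/2) L
  for (i in 2:(nr - 1)) {
    A[i, i - 1] <- -lower[i]; A[i, i] <- 1 + 2 * lam; A[i, i + 1] <- -upper[i]
    B[i, i - 1] <- lower[i];  B[i, i] <- 1 - 2 * lam; B[i, i + 1] <- upper[i]
  }
  # absorbing inner boundary
  A[1, 1] <- 1; B[1, 1] <- 0
  # reflecting outer boundary: ghost node S[nr+1] = S[nr-1]
  A[nr, nr - 1] <- -(lower[nr] + upper[nr]); A[nr, nr] <- 1 + 2 * lam
  B[nr, nr - 1] <- lower[nr] + upper[nr];   B[nr, nr] <- 1 - 2 * lam

  P <- solve(A, B)  # constant-coefficient: factor once
  S <- rep(1, nr)
  S[1] <- 0
  for (k in seq_len(grid$nt)) {
    S <- P %*% S
  }
  S <- pmin(pmax(as.numeric(S), 0), 1)
  list(r = r, S = S)
}

#' Contact probability in the diffusive limit (survival PDE)
#'
#' When the persistence length is much smaller than the source gap, the
#' persistent random walk is well approximated by Brownian motion with
#' `D = v^2 / (2 * dtheta)`. The probability that a finite-time diffusive
#' search (duration `t_max`, default `lmax / v`) touches the absorbing disk
#' is `1 - S(r0, t_max)`, where the survival probability `S(r, t)` obeys the
#' radially symmetric diffusion equation with `S = 0` on the target surface
#' and `S(r, 0) = 1`. Solved by Crank--Nicolson time stepping on a uniform
#' radial grid with a reflecting outer boundary placed by a 4-sigma rule.
#'
#' The approximation is meaningful only for `lp << dtarg`; this is
#' documented, not enforced.
#'
#' @param dtheta Angular diffusion, rad^2/min (> 0).
#' @param v Speed, um/min.
#' @param dtarg Source gap, um.
#' @param rtarg Target radius, um.
#' @param t_max Search duration, min; default `lmax / v`.
#' @param lmax Maximum contour length, um (used only for the default
#'   `t_max`).
#' @param grid Optional [pde_grid()] override.
#' @return Contact probability in `[0, 1]`.
#' @examples
#' diffusive_contact_probability(dtheta = 2, v = 4.5, dtarg = 50, rtarg = 25)
#' @export
diffusive_contact_probability <- function(dtheta, v, dtarg, rtarg,
                                          t_max = NULL, lmax = 250,
                                          grid = NULL) {
  stopifnot(dtheta > 0, v > 0, dtarg >= 0, rtarg > 0)
  if (is.null(t_max)) t_max <- lmax / v
  if (t_max == 0) return(0)
  if (dtarg == 0) return(1)  # starts on the absorbing surface
  D <- v^2 / (2 * dtheta)
  if (is.null(grid)) grid <- pde_grid(rtarg, dtarg, D, t_max)
  if (abs(grid$D - D) > 1e-9 * D) {
    stop("grid$D does not match v^2 / (2 * dtheta)", call. = FALSE)
  }
  sol <- solve_survival_pde(grid)
  r0 <- rtarg + dtarg
  S0 <- approx(sol$r, sol$S, xout = r0)$y
  min(max(1 - S0, 0), 1)
}
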