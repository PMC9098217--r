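test_that("a single step displaces by exactly v*dt along the current heading", {
  p <- prw_params(v = 4.5, dtheta = 0, dt = 0.1)
  s <- step_prw(c(0, 0), 0, p, noise_draw = 1)
  expect_equal(s$position, c(0.45, 0))
  expect_equal(s$heading, 0)  # dtheta = 0: noise has no effect
  # noise_draw = 0 leaves the heading unchanged for any dtheta
  p2 <- prw_params(dtheta = 0.3)
  s2 <- step_prw(c(1, 2), 0.7, p2, noise_draw = 0)
  expect_equal(s2$heading, 0.7)
  expect_equal(sqrt(sum((s2$position - c(1, 2))^2)), p2$v * p2$dt)
})

test_that("accumulated heading increments have variance 2*Dtheta*dt", {
  p <- prw_params(dtheta = 0.1838, dt = 0.1)
  n <- 1e5
  withr::with_seed(42, {
    draws <- rnorm(n)
    h <- 0.3 + sqrt(2 * p$dtheta * p$dt) * cumsum(draws)
  })
  v_obs <- var(diff(c(0.3, h)))
  v_exp <- 2 * p$dtheta * p$dt  # 0.03676
  se <- v_exp * sqrt(2 / n)
  expect_lt(abs(v_obs - v_exp), 3 * se)
  expect_lt(abs(mean(diff(h))), 3 * sqrt(v_exp / n))
})

test_that("segment-disk contact detection matches a dense-subsampling oracle", {
  g <- search_geometry(prw_params(dtarg = 50, rtarg = 25))
  expect_equal(detect_contact(c(30, 0), c(20, 0), g), c(25, 0))
  expect_null(detect_contact(c(100, 100), c(90, 100), g))
  # zero-length segment: point test
  expect_null(detect_contact(c(30, 0), c(30, 0), g))
  expect_equal(detect_contact(c(20, 0), c(20, 0), g), c(20, 0))

  # chords with both endpoints outside the disk, random orientations
  oracle_hits <- function(a, b, r, k = 1000) {
    s <- seq(0, 1, length.out = k)
    pts <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
    any(sqrt(rowSums(pts^2)) <= r)
  }
  withr::with_seed(7, {
    for (i in 1:50) {
      ang <- runif(2, -pi, pi)
      a <- 26 * c(cos(ang[1]), sin(ang[1]))
      b <- 40 * c(cos(ang[2]), sin(ang[2]))
      hit <- !is.null(detect_contact(a, b, g))
      expect_identical(hit, oracle_hits(a, b, 25))
      if (hit) {
        cp <- detect_contact(a, b, g)
        expect_equal(sqrt(sum(cp^2)), 25, tolerance = 1e-9)
      }
    }
  })
})

test_that("single-trajectory simulation honours geometry and termination", {
  # unreachable target: lmax < dtarg
  p <- prw_params(lmax = 250, dtarg = 300)
  tr <- simulate_airineme(p, seed = 1)
  expect_false(tr$contacted)
  expect_lte(tr$final_length, p$lmax + p$v * p$dt)

  # straight shot aimed at the centre: contact at angle 0 after dtarg/v
  p0 <- prw_params(dtheta = 0)
  tr0 <- simulate_airineme(p0, initial_angle = pi, seed = 1)
  expect_true(tr0$contacted)
  expect_equal(tr0$contact_angle, 0)
  expect_equal(tr0$t_contact, p0$dtarg / p0$v, tolerance = 1e-9)
  expect_equal(sqrt(sum(tr0$contact_point^2)), p0$rtarg, tolerance = 1e-9)

  # path invariants: uniform spacing v*dt, start at source
  p1 <- prw_params(dtheta = 0.5, dt = 0.05)
  tr1 <- simulate_airineme(p1, seed = 3)
  expect_equal(unlist(tr1$path[1, c("x_um", "y_um")], use.names = FALSE),
               c(p1$rtarg + p1$dtarg, 0))
  steps <- sqrt(diff(tr1$path$x_um)^2 + diff(tr1$path$y_um)^2)
  m <- length(steps)
  expect_equal(steps[-m], rep(p1$v * p1$dt, m - 1), tolerance = 1e-9)
  # pre-contact path never inside the disk
  rr <- sqrt(tr1$path$x_um^2 + tr1$path$y_um^2)
  expect_true(all(rr >= p1$rtarg - 1e-9))
})

test_that("ensembles are seed-reproducible and count contacts coherently", {
  p <- prw_params()
  e1 <- simulate_ensemble(p, n = 500, seed = 10)
  e2 <- simulate_ensemble(p, n = 500, seed = 10)
  e3 <- simulate_ensemble(p, n = 500, seed = 11)
  expect_identical(e1$p_contact, e2$p_contact)
  expect_identical(e1$contact_angles, e2$contact_angles)
  expect_false(identical(e1$contact_angles, e3$contact_angles))
  expect_equal(e1$n_contacts, length(e1$contact_angles))
  expect_gte(e1$ci90[1], 0)
  expect_true(e1$ci90[1] <= e1$p_contact && e1$p_contact <= e1$ci90[2])
  expect_error(simulate_ensemble(p, n = 0), "positive")
  # unreachable target: p = 0 exactly
  e0 <- simulate_ensemble(prw_params(dtarg = 300), n = 200, seed = 1)
  expect_identical(e0$p_contact, 0)
})

test_that("ballistic ensembles reproduce the geometric contact probability", {
  p <- prw_params(dtheta = 0)
  n <- 1e5
  e <- simulate_ensemble(p, n = n, seed = 3)
  p_exact <- ballistic_contact_probability(p$dtarg, p$rtarg)
  expect_lt(abs(e$p_contact - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / n))
})

test_that("contact probability is monotone in geometry on a 3-point grid", {
  n <- 3e4
  p_of <- function(dtarg, rtarg) {
    simulate_ensemble(prw_params(dtarg = dtarg, rtarg = rtarg),
                      n = n, seed = 77)$p_contact
  }
  # non-increasing in dtarg
  pd <- c(p_of(30, 25), p_of(50, 25), p_of(80, 25))
  # non-decreasing in rtarg
  pr <- c(p_of(50, 15), p_of(50, 20), p_of(50, 25))
  tol <- 3 * sqrt(0.25 / n) * sqrt(2)
  expect_true(all(diff(pd) < tol))
  expect_true(all(diff(pr) > -tol))
})

test_that("long runs lose memory of the initial heading (isotropy)", {
  p <- prw_params(dtheta = 0.1838, dtarg = 1e4)
  # duration 30 min > 5 / dtheta = 27.2 min
  e <- simulate_ensemble(p, n = 400, seed = 5, durations = 30,
                         record_every = 50L)
  iso <- final_angle_isotropy(e$recorded, min_duration = 29)
  expect_gt(iso$p_value, 0.01)
})
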