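# Population-balance solutions: Green's function, Lambert-W depletion,
# warped time, and the advection-diffusion oracle

test_that("the Green's function has Gaussian moments and unit mass", {
  L <- seq(-50, 150, by = 0.01)
  for (tt in c(1, 5, 25)) {
    g <- green_function(L, tt, L0 = 10)
    dL <- L[2] - L[1]
    expect_equal(sum(g) * dL, 1, tolerance = 1e-8)
    expect_equal(sum(L * g) * dL, 10 + tt, tolerance = 1e-6)
    expect_equal(sum((L - 10 - tt)^2 * g) * dL, tt, tolerance = 1e-6)
  }
  expect_error(green_function(1, 0), "t must be")
})

test_that("the Green's function approximates the unit-rate birth process", {
  # the underlying stochastic process is a Poisson pure-birth chain; at
  # t = 25 the second-order truncation should be close in total variation
  set.seed(3)
  n <- 2e5
  L0 <- 10; tt <- 25
  lengths <- L0 + rpois(n, tt)
  breaks <- seq(L0 - 0.5, L0 + 80.5, by = 1)
  emp <- tabulate(cut(lengths, breaks, labels = FALSE),
                  nbins = length(breaks) - 1) / n
  centers <- breaks[-1] - 0.5
  gau <- green_function(centers, tt, L0)
  tv <- sum(abs(emp - gau / sum(gau))) / 2
  expect_lt(tv, 0.05)
})

test_that("monomer depletion solves its separable ODE to 1e-8", {
  skip_if_not_installed("deSolve")
  for (ab in list(c(0.5, 0.02), c(3, 0.005), c(12, 0.1))) {
    alpha <- ab[1]; eps <- ab[2]
    tt <- seq(0, 8 / eps, length.out = 40)[-1]
    ode <- deSolve::lsoda(c(m = 1), c(0, tt),
                          function(t, y, parms)
                            list(-eps * (1 + alpha) * y / (1 + alpha * y)),
                          parms = NULL, rtol = 1e-11, atol = 1e-12)
    expect_equal(monomer_depletion(tt, alpha, eps), unname(ode[-1, "m"]),
                 tolerance = 1e-8)
  }
})

test_that("Lambert-W evaluation agrees with an independent series solver", {
  # cross-check the log-form Newton solver against pracma on arguments
  # where the latter's iteration is safe
  skip_if_not_installed("pracma")
  for (y in c(-30, -5, -1, 0, 2, 8, 15)) {
    expect_equal(docklock:::lambertw_exp(y), pracma::lambertWp(exp(y)),
                 tolerance = 1e-10)
  }
  # and against the defining identity w * exp(w) = exp(y) over a wide range
  y <- seq(-20, 600, by = 7.3)
  w <- docklock:::lambertw_exp(y)
  expect_equal(log(w) + w, y, tolerance = 1e-10)
})

test_that("depletion limits: m(0) = 1, m(Inf) = 0, alpha -> 0 exponential", {
  expect_equal(monomer_depletion(0, 2, 0.01), 1, tolerance = 1e-12)
  expect_lt(monomer_depletion(1e5, 2, 0.01), 1e-10)
  tt <- seq(0, 300, by = 10)
  expect_equal(monomer_depletion(tt, 1e-9, 0.01), exp(-0.01 * tt),
               tolerance = 1e-7)
  # the log-stable Lambert branch handles huge saturation parameters
  expect_equal(monomer_depletion(0, 500, 0.01), 1, tolerance = 1e-10)
  expect_true(is.finite(monomer_depletion(10, 2000, 1e-3)))
})

test_that("warped time: unit initial slope, saturation at 1/eps, concavity", {
  alpha <- 2; eps <- 0.02
  h <- 1e-6
  expect_equal(warped_time(h, alpha, eps) / h, 1, tolerance = 1e-4)
  expect_equal(warped_time(1e6, alpha, eps), 1 / eps, tolerance = 1e-6)
  tt <- seq(0, 400, by = 2)[-1]
  tau <- warped_time(tt, alpha, eps)
  expect_true(all(diff(tau) > -1e-14))
  expect_true(all(diff(diff(tau)) < 1e-10))
  # small-alpha limit matches (1 - exp(-eps t)) / eps and the defining
  # quadrature of dtau/dt = (1 + alpha) m / (1 + alpha m)
  expect_equal(warped_time(tt, 1e-6, eps), (1 - exp(-eps * tt)) / eps,
               tolerance = 1e-4)
  tau_quad <- vapply(tt, function(T)
    integrate(function(s) {
      m <- monomer_depletion(s, alpha, eps)
      (1 + alpha) * m / (1 + alpha * m)
    }, 0, T, rel.tol = 1e-10)$value, 0)
  expect_equal(tau, tau_quad, tolerance = 1e-7)
})

test_that("mass-balance identity 1 - m = eps * tau holds to 1e-12", {
  set.seed(4)
  for (i in 1:200) {
    alpha <- 10^runif(1, -3, 2)
    eps <- 10^runif(1, -4, 0)
    tt <- 10^runif(1, -2, 6)
    expect_equal(1 - monomer_depletion(tt, alpha, eps),
                 eps * warped_time(tt, alpha, eps), tolerance = 1e-12)
  }
})

test_that("population propagation conserves mass and matches a PDE oracle", {
  # crank through the advection-diffusion equation with central differences
  # (2nd order) and compare with the analytic convolution at t = 5
  pde_oracle <- function(x0_vec, L, t_end, dt_fd) {
    dL <- L[2] - L[1]
    x <- x0_vec
    n <- length(L)
    steps <- round(t_end / dt_fd)
    for (s in seq_len(steps)) {
      adv <- c(0, (x[3:n] - x[1:(n - 2)]) / (2 * dL), 0)
      dif <- c(0, (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dL^2, 0)
      x <- x + dt_fd * (-adv + 0.5 * dif)
    }
    x
  }
  L <- seq(0, 40, by = 0.025)
  x0 <- green_function(L, 0.5, 10)       # narrow Gaussian as near-delta
  sol <- solve_population(function(l) green_function(l, 0.5, 10),
                          times = 5, L_grid = L)
  fd <- pde_oracle(x0, L, 5, 2e-4)
  expect_lt(max(abs(sol$x[, 1] - fd)), 1e-3)
  expect_equal(sol$mass[1], 1, tolerance = 1e-6)

  # depletion mode equals the constant-concentration solution at tau(t)
  L2 <- seq(0, 80, by = 0.05)
  alpha <- 1.5; eps <- 0.05
  dep <- solve_population(list(delta = 10), times = c(2, 10, 25),
                          alpha = alpha, eps = eps, mode = "depletion",
                          L_grid = L2)
  tau <- warped_time(c(2, 10, 25), alpha, eps)
  for (j in 1:3)
    expect_lt(max(abs(dep$x[, j] - green_function(L2, tau[j], 10))), 1e-12)
  # depleted peaks sit at lower L than constant-clock peaks at equal t
  con <- solve_population(list(delta = 10), times = c(2, 10, 25), L_grid = L2)
  for (j in 1:3) {
    expect_lt(L2[which.max(dep$x[, j])], L2[which.max(con$x[, j])])
    expect_gt(max(dep$x[, j]), max(con$x[, j]))
  }
})

test_that("depletion-mode mass conservation links mean growth to 1 - m", {
  alpha <- 2; eps <- 0.04
  L <- seq(0, 120, by = 0.05)
  sol <- solve_population(list(delta = 10), times = c(5, 20, 80),
                          alpha = alpha, eps = eps, mode = "depletion",
                          L_grid = L)
  dL <- L[2] - L[1]
  for (j in seq_along(sol$times)) {
    meanL <- sum(L * sol$x[, j]) * dL / (sum(sol$x[, j]) * dL)
    expect_equal(eps * (meanL - 10), 1 - sol$m[j], tolerance = 1e-5)
  }
})

test_that("a two-ends system is the one-end system on a doubled clock", {
  L <- seq(0, 60, by = 0.1)
  two <- solve_population(list(delta = 6), times = c(4, 9), alpha = 1,
                          eps = 0.05, mode = "depletion", L_grid = L,
                          ends_factor = 2)
  one <- solve_population(list(delta = 6), times = c(8, 18), alpha = 1,
                          eps = 0.05, mode = "depletion", L_grid = L)
  expect_lt(max(abs(two$x - one$x)), 1e-12)
})

test_that("grid truncation is detected", {
  expect_warning(
    solve_population(list(delta = 10), times = 50,
                     L_grid = seq(0, 30, by = 0.1)),
    "truncation")
})

test_that("pbe_params assembles alpha and eps from rate constants", {
  rc <- rate_constants(kD = 1.21e9, kL = 9.852e7, KD = 8.44e2)
  pp <- pbe_params(rc, M0 = 0.1, rho_tot = 1e-3)
  expect_equal(pp$eps, 0.01)
  expect_equal(pp$alpha,
               1.21e9 * 0.1 / 9.852e7 / (1 + 1.21e9 / (8.44e2 * 9.852e7)),
               tolerance = 1e-12)
  expect_equal(pp$rg0, growth_rate_full(rc, 0.1))
})
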