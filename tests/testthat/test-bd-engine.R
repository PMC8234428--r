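# Overdamped Euler-Maruyama propagation

test_that("zero potential and zero noise leave positions unchanged", {
  p <- params_default()
  cfg <- single_dumbbell()
  out <- bd_step(cfg, p, n_steps = 50L, noise_scale = 0)
  expect_equal(out$pos, cfg$pos)
})

test_that("deterministic drift follows D * beta * f * dt exactly", {
  p <- params_default()
  # stretch the bond: restoring force f = kb * (r - r0) on each atom
  r0 <- p[["r0"]]
  stretch <- 0.1
  cfg <- configuration(rbind(c(0, 0, 0), c(r0 + stretch, 0, 0)), 1L)
  f <- forces(cfg, p)
  expect_equal(f[1, 1], p[["kb"]] * stretch, tolerance = 1e-12)
  out <- bd_step(cfg, p, n_steps = 1L, noise_scale = 0)
  drift <- p[["D_atom"]] * p[["beta"]] * p[["dt"]]
  expect_equal(out$pos[1, 1], cfg$pos[1, 1] + drift * f[1, 1],
               tolerance = 1e-12)
  expect_equal(out$pos[2, 1], cfg$pos[2, 1] + drift * f[2, 1],
               tolerance = 1e-12)
})

test_that("free particles diffuse with MSD = 6 D t", {
  # kb = 0 turns a dumbbell into two independent free particles
  p <- params_default(kb = 1e-30, eps_lj = 0, eps_lj_c = 0, eps_wca = 0,
                      ew = 0, ec = 0, et = 0)
  n_steps <- 50L
  n_rep <- 3000L
  set.seed(123)
  disp2 <- numeric(n_rep)
  cfg <- single_dumbbell()
  for (i in seq_len(n_rep)) {
    out <- bd_step(cfg, p, n_steps = n_steps)
    disp2[i] <- sum((out$pos[1, ] - cfg$pos[1, ])^2)
  }
  expected <- 6 * p[["D_atom"]] * n_steps * p[["dt"]]
  se <- sd(disp2) / sqrt(n_rep)
  expect_lt(abs(mean(disp2) - expected), 3 * se)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- params_default()
  cfg <- pair_at(2.5, 0.3, mobile = c(TRUE, TRUE))
  set.seed(77)
  a <- bd_step(cfg, p, n_steps = 200L)
  set.seed(77)
  b <- bd_step(cfg, p, n_steps = 200L)
  expect_identical(a$pos, b$pos)
  set.seed(78)
  c <- bd_step(cfg, p, n_steps = 200L)
  expect_false(identical(a$pos, c$pos))
})

test_that("a too-large step size warns", {
  p <- params_default(dt = 1e-10)
  expect_warning(bd_step(single_dumbbell(), p), "RMS displacement")
})

test_that("run_until honours predicates and step budgets", {
  p <- params_default()
  cfg <- pair_at(3.0, 0.0, mobile = c(FALSE, TRUE))
  # always-true predicate: zero steps
  out <- bd_run(cfg, p, max_steps = 1000, stop_predicate = function(x) TRUE)
  expect_equal(out$steps, 0L)
  expect_equal(out$reason, "predicate")
  # exhausting the budget is a reported outcome, not an error
  set.seed(5)
  out2 <- bd_run(cfg, p, max_steps = 500,
                 stop_predicate = function(x) FALSE, check_every = 100)
  expect_equal(out2$steps, 500L)
  expect_equal(out2$reason, "max_steps")
  # a capture predicate fires quickly: the pair starts inside the channel
  # attraction and is pulled inward
  set.seed(6)
  sep <- function(x) pair_coordinates(x$pos[1:2, ], x$pos[3:4, ], 2)["rcom"]
  out3 <- bd_run(cfg, p, max_steps = 5e5,
                 stop_predicate = function(x) sep(x) < 2.0, check_every = 50)
  expect_equal(out3$reason, "predicate")
  expect_lt(sep(out3$config), 2.0)
})

test_that("first-passage times of a harmonic walker match the MFPT quadrature", {
  # 1-D overdamped walker in F = k/2 x^2 started at x0, absorbed at x_abs.
  # Independent oracle: double-quadrature MFPT for the Smoluchowski equation
  # with a reflecting boundary far to the left,
  #   T(x0) = (1/D) int_{x0}^{b} dy e^{U(y)} int_{-inf}^{y} dz e^{-U(z)}
  k <- 2; D <- 1; x0 <- 0; xb <- 1.5
  inner <- function(y) {
    vapply(y, function(yy)
      integrate(function(z) exp(-k * z^2 / 2), -Inf, yy,
                rel.tol = 1e-10)$value, 0)
  }
  oracle <- integrate(function(y) exp(k * y^2 / 2) * inner(y), x0, xb,
                      rel.tol = 1e-9)$value / D
  set.seed(31)
  fpt <- docklock:::cpp_harmonic_fpt(k, D, dt = 5e-4, x0 = x0, x_abs = xb,
                          n = 10000L, max_steps = 1e7)
  rel_err <- abs(mean(fpt) - oracle) / oracle
  expect_lt(rel_err, 0.05)
})

test_that("BD equilibrium sampling agrees with a Metropolis MC oracle", {
  # the same bound dumbbell pair sampled by the integrator and by an
  # energy-only Monte Carlo chain must histogram to the same (rcom, q)
  # density; the KL divergence over well-sampled bins shrinks with run length
  p <- params_default()
  fib <- single_dumbbell(1L, mobile = FALSE)
  start <- pair_at(1.5, -0.9, mobile = c(FALSE, TRUE))
  r_edges <- seq(1.2, 2.4, by = 0.1)
  q_edges <- seq(-1.1, 0.1, by = 0.1)
  kl <- function(n_steps) {
    set.seed(42)
    bd <- docklock:::cpp_bd_run(start$pos, start$species, start$mobile, start$role,
                     0, p, as.integer(n_steps), 1.0, 0L, 1L, 10L)
    h_bd <- table(cut(bd$traj[, "rcom"], r_edges),
                  cut(bd$traj[, "q"], q_edges))
    set.seed(43)
    mc <- docklock:::cpp_mc_hist(start$pos, start$species, start$mobile, start$role,
                      0, p, as.integer(n_steps / 2), 0.12, 0L, 1L,
                      r_edges, q_edges, 5L)
    a <- h_bd / sum(h_bd)
    b <- mc$counts / sum(mc$counts)
    keep <- a > 5e-4 & b > 5e-4
    sum(a[keep] * log(a[keep] / b[keep]))
  }
  kl_short <- kl(4e4)
  kl_long <- kl(4e5)
  expect_lt(kl_long, kl_short)
  expect_lt(kl_long, 0.05)
})
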