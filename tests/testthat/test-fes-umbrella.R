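# Umbrella sampling, WHAM, stationary points, docking equilibrium constant

# --- synthetic WHAM oracle ---------------------------------------------------
# Draw window histograms directly from a known 2-D density under known
# biases (multinomial sampling on the grid), so WHAM's output can be
# compared with the exact surface.
synthetic_umbrella <- function(Ftrue, grid, windows, n_per_window = 40000,
                               seed = 1) {
  set.seed(seed)
  nr <- length(grid$r_mid); nq <- length(grid$q_mid)
  nw <- nrow(windows)
  counts <- array(0, c(nr, nq, nw))
  rq <- expand.grid(r = grid$r_mid, q = grid$q_mid)
  for (w in seq_len(nw)) {
    bias <- windows$kr[w] / 2 * (rq$r - windows$c_r[w])^2 +
      windows$kq[w] / 2 * (rq$q - windows$c_q[w])^2
    pr <- exp(-(as.vector(Ftrue) + bias))
    pr <- pr / sum(pr)
    counts[, , w] <- matrix(as.numeric(stats::rmultinom(1, n_per_window, pr)),
                            nr, nq)
  }
  list(counts = counts, windows = windows, grid = grid)
}

double_well_surface <- function(grid) {
  outer(grid$r_mid, grid$q_mid, function(r, q)
    8 * (1 - exp(-((r - 1.7)^2 / 0.16 + (q - 0.6)^2 / 0.36)) -
           1.4 * exp(-((r - 1.3)^2 / 0.1 + (q + 0.8)^2 / 0.2))))
}

test_that("WHAM recovers a known double-well surface from biased samples", {
  grid <- fes_grid(r_lim = c(1.0, 2.6), q_lim = c(-1.1, 1.1))
  Ftrue <- double_well_surface(grid)
  windows <- umbrella_windows(r_range = c(1.05, 2.55), n_r = 12,
                              q_range = c(-1.0, 1.0), n_q = 9,
                              kr = 30, kq = 30)
  umb <- synthetic_umbrella(Ftrue, grid, windows)
  fes <- wham_2d(umb)
  resid <- fes$F - (Ftrue - min(Ftrue))
  well <- !is.na(fes$F) & fes$counts > 200
  rmse <- sqrt(mean((resid[well] - mean(resid[well], na.rm = TRUE))^2,
                    na.rm = TRUE))
  expect_lt(rmse, 0.1)
})

test_that("WHAM is invariant to window order and degenerates correctly", {
  grid <- fes_grid(r_lim = c(1.0, 2.6), q_lim = c(-1.1, 1.1))
  Ftrue <- double_well_surface(grid)
  windows <- umbrella_windows(r_range = c(1.1, 2.5), n_r = 8,
                              q_range = c(-0.9, 0.9), n_q = 7, kr = 30,
                              kq = 30)
  umb <- synthetic_umbrella(Ftrue, grid, windows, seed = 4)
  fes <- wham_2d(umb)
  perm <- sample(nrow(windows))
  umb2 <- list(counts = umb$counts[, , perm],
               windows = windows[perm, ], grid = grid)
  fes2 <- wham_2d(umb2)
  expect_equal(fes$F, fes2$F, tolerance = 1e-6)

  # a single unbiased window: WHAM equals -log(histogram) up to a constant
  w1 <- data.frame(c_r = 1.5, c_q = 0, kr = 1e-12, kq = 1e-12)
  umb1 <- synthetic_umbrella(Ftrue, grid, w1, n_per_window = 2e5, seed = 5)
  fes1 <- wham_2d(umb1)
  h <- umb1$counts[, , 1]
  ref <- -log(h / sum(h))
  ref[h == 0] <- NA
  ref <- ref - min(ref, na.rm = TRUE)
  ok <- !is.na(fes1$F) & h > 100
  expect_lt(max(abs(fes1$F[ok] - ref[ok])), 1e-6)
})

test_that("stationary points of an analytic two-well surface are recovered", {
  grid <- fes_grid(r_lim = c(1.0, 2.6), q_lim = c(-1.1, 1.1))
  Ftrue <- double_well_surface(grid)
  fes <- list(F = Ftrue - min(Ftrue), prob = exp(-(Ftrue - min(Ftrue))),
              counts = matrix(1e4, nrow(Ftrue), ncol(Ftrue)),
              r_edges = grid$r_edges, q_edges = grid$q_edges,
              r_mid = grid$r_mid, q_mid = grid$q_mid, beta = 1,
              empty_bins = 0)
  class(fes) <- "dl_fes"
  stat <- locate_stationary_points(fes, params_default(), fit_radius = 2)
  expect_equal(stat$docked[1], 1.7, tolerance = 0.051)   # within one bin
  expect_equal(stat$docked[2], 0.6, tolerance = 0.051)
  expect_equal(stat$locked[1], 1.3, tolerance = 0.051)
  expect_equal(stat$locked[2], -0.8, tolerance = 0.051)
  # curvatures within 5% of the analytic Hessian at the docked minimum:
  # A_rr = 2*8/0.16 = 100, A_qq = 2*8/0.36 = 44.4, A_rq = 0
  expect_equal(stat$A0[1, 1], 100, tolerance = 0.05 * 100)
  expect_equal(stat$A0[2, 2], 44.4, tolerance = 0.05 * 44.4)
  expect_lt(abs(stat$A0[1, 2]), 6)
  # saddle signature
  ev <- eigen(stat$A, symmetric = TRUE)$values
  expect_equal(sum(ev < 0), 1L)
  expect_gt(stat$barrier, 0)

  # gauge invariance: adding a constant changes nothing
  fes2 <- fes
  fes2$F <- fes2$F + 3.21
  stat2 <- locate_stationary_points(fes2, params_default(), fit_radius = 2)
  expect_equal(stat2$docked, stat$docked)
  expect_equal(stat2$A0, stat$A0, tolerance = 1e-10)
  expect_equal(stat2$barrier, stat$barrier, tolerance = 1e-10)
})

test_that("umbrella runs are deterministic under a fixed seed and cover q", {
  p <- params_default()
  win <- umbrella_windows(r_range = c(1.4, 2.0), n_r = 3,
                          q_range = c(-0.6, 0.6), n_q = 3,
                          n_steps = 4000, n_equil = 500)
  set.seed(9)
  u1 <- suppressWarnings(run_umbrella(p, win, fibril_length = 4))
  set.seed(9)
  u2 <- suppressWarnings(run_umbrella(p, win, fibril_length = 4))
  expect_identical(u1$counts, u2$counts)
  expect_true(all(u1$meta[, "n"] > 0))
})

test_that("docking equilibrium constant responds to basin depth as exp(delta)", {
  # synthetic sampled density with the unbound r^2 w(q) envelope and one
  # Gaussian well; deepening the well by delta multiplies KD by e^delta
  grid <- fes_grid(r_lim = c(1.0, 5.6), q_lim = c(-1.1, 1.1))
  w <- chirality_density(grid$q_mid)
  build <- function(depth) {
    Phi <- outer(grid$r_mid, grid$q_mid, function(r, q)
      -depth * exp(-((r - 1.6)^2 / 0.05 + (q - 0.6)^2 / 0.1)))
    dens <- outer(grid$r_mid^2, w) * exp(-Phi)
    dens[outer(grid$r_mid < 1.2, rep(TRUE, length(grid$q_mid)))] <- 0
    P <- dens / sum(dens)
    F <- -log(P)
    F[!is.finite(F)] <- NA
    F <- F - min(F, na.rm = TRUE)
    fes <- list(F = F, prob = P, counts = 0 * P + 1e4,
                r_edges = grid$r_edges, q_edges = grid$q_edges,
                r_mid = grid$r_mid, q_mid = grid$q_mid, beta = 1,
                empty_bins = 0)
    class(fes) <- "dl_fes"
    fes
  }
  fes8 <- build(8)
  stat8 <- list(bins = list(docked = c(which.min(abs(grid$r_mid - 1.6)),
                                       which.min(abs(grid$q_mid - 0.6)))),
                sep_level = max(fes8$F, na.rm = TRUE))
  # rectangular basin keeps the integration domain fixed across depths
  basin <- list(r_range = c(1.3, 1.95), q_range = c(0.2, 1.0))
  ratio_at <- function(d) {
    kd_lo <- docking_equilibrium_constant(build(d), stat8, params_default(),
                                          basin = basin)
    kd_hi <- docking_equilibrium_constant(build(d + 1), stat8,
                                          params_default(), basin = basin)
    kd_hi$KD / kd_lo$KD
  }
  # e^delta to first order: the log-ratio approaches 1 from below as the
  # well deepens (a finite-width 2-D well gives e * d/(d+1) by Laplace)
  r8 <- ratio_at(8); r25 <- ratio_at(25)
  expect_gt(log(r8), 0.85)
  expect_lt(log(r8), 1.0)
  expect_gt(log(r25), log(r8))
  expect_equal(r25, exp(1) * 25 / 26, tolerance = 0.02)
  # no-binding limit: KD approaches the bare shell volume of the window
  kd0 <- docking_equilibrium_constant(build(1e-9), stat8, params_default(),
                                      basin = basin)
  shell <- integrate(function(r) 4 * pi * r^2, 1.3, 1.95)$value
  dq <- grid$q_mid[2] - grid$q_mid[1]
  qs <- grid$q_mid >= 0.2 & grid$q_mid <= 1.0
  frac_q <- sum(w[qs]) * dq
  expect_equal(kd0$KD_A3, shell * frac_q, tolerance = 0.05 * shell * frac_q)
})

test_that("chirality density is a symmetric unit-mass density peaked at 0", {
  q <- seq(-0.975, 0.975, by = 0.05)
  w <- chirality_density(q, n = 5e5)
  expect_equal(sum(w) * 0.05, 1, tolerance = 0.02)
  expect_gt(w[which.min(abs(q))], w[1] * 3)
  expect_equal(w, rev(w), tolerance = 0.05 * max(w))
})
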