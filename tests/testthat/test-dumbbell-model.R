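# Chiral-dumbbell potential, forces, and pair coordinates

test_that("pair coordinates match hand-evaluated definitions", {
  # parallel bonds: cross product vanishes, q = 0
  a <- rbind(c(0, 0, 0), c(2, 0, 0))
  b <- rbind(c(0, 0, 2), c(2, 0, 2))
  pc <- pair_coordinates(a, b, r0 = 2)
  expect_equal(unname(pc["rcom"]), 2)      # |u| = 2 Angstrom
  expect_equal(unname(pc["q"]), 0)

  # perpendicular bonds, hand evaluation:
  # u = (1,-1,-2), v = (0,2,0) x (2,0,0) = (0,0,-4),
  # q = u.v/(r0^2 |u|) = 8 / (4 sqrt(6)) = sqrt(2/3)
  b2 <- rbind(c(0, 0, 2), c(0, 2, 2))
  pc2 <- pair_coordinates(a, b2, r0 = 2)
  expect_equal(unname(pc2["rcom"]), sqrt(6), tolerance = 1e-12)
  expect_equal(unname(pc2["q"]), sqrt(2 / 3), tolerance = 1e-12)

  # zero COM separation is undefined
  expect_error(pair_coordinates(a, a + c(0, 0, 0), 2), "undefined")
})

test_that("q is bounded by the bond-length product over r0^2", {
  set.seed(42)
  for (i in 1:200) {
    cfg <- random_config(2)
    a <- cfg$pos[1:2, ]; b <- cfg$pos[3:4, ]
    pc <- pair_coordinates(a, b, 2)
    ba <- sqrt(sum((a[2, ] - a[1, ])^2))
    bb <- sqrt(sum((b[2, ] - b[1, ])^2))
    expect_lte(abs(pc["q"]), ba * bb / 4 + 1e-12)
  }
  # exact-bond-length configurations stay in [-1, 1]
  for (q in seq(-1, 1, by = 0.25)) {
    cfg <- pair_at(1.6, q)
    pc <- pair_coordinates(cfg$pos[1:2, ], cfg$pos[3:4, ], 2)
    expect_lte(abs(pc["q"]), 1 + 1e-12)
    expect_equal(unname(pc["q"]), q, tolerance = 1e-12)
  }
})

test_that("swapping dumbbells with labels swapped preserves rcom and q", {
  set.seed(7)
  for (i in 1:20) {
    cfg <- random_config(2)
    a <- cfg$pos[1:2, ]; b <- cfg$pos[3:4, ]
    pc <- pair_coordinates(a, b, 2)
    # same physical pair, roles swapped: u flips sign, and the bond order of
    # both dumbbells flips (particle labels swap within each molecule), so
    # v also flips and q is unchanged
    pc2 <- pair_coordinates(b[2:1, ], a[2:1, ], 2)
    expect_equal(unname(pc2["rcom"]), unname(pc["rcom"]), tolerance = 1e-12)
    expect_equal(unname(pc2["q"]), unname(pc["q"]), tolerance = 1e-12)
  }
})

test_that("energy terms hit their analytic reference values", {
  p <- params_default()
  # isolated dumbbell at its equilibrium bond length: everything vanishes
  expect_equal(as.numeric(total_potential(single_dumbbell(), p)), 0)

  # unlike atom pair at the LJ minimum contributes exactly -eps_lj
  expect_equal(docklock:::cpp_lj(p[["r_lj_m"]], p[["eps_lj"]], p[["r_lj_m"]]),
               -p[["eps_lj"]])
  expect_equal(docklock:::cpp_lj(p[["r_lj_m"]] * 2^(-1 / 6), p[["eps_lj"]],
                      p[["r_lj_m"]]), 0, tolerance = 1e-12)
  # WCA is zero beyond its minimum and eps at the LJ zero
  expect_equal(docklock:::cpp_wca(p[["r_wca_m"]], p[["eps_wca"]], p[["r_wca_m"]]), 0)
  expect_equal(docklock:::cpp_wca(p[["r_wca_m"]] * 2^(-1 / 6), p[["eps_wca"]],
                       p[["r_wca_m"]]), p[["eps_wca"]], tolerance = 1e-12)

  # unlike pair placed exactly at the tilt centre (1.4 A, q = -1):
  # the tilt Gaussian contributes its full depth et = -35 kBT
  cfg <- pair_at(p[["r0_t"]], p[["q0_t"]])
  terms <- potential_terms(cfg, p)
  expect_equal(unname(terms["tilt"]), p[["et"]], tolerance = 1e-6)
  # and the COM LJ sits at its own minimum (r_lj_cm = 1.4 A)
  expect_equal(unname(terms["lj_com"]), -p[["eps_lj_c"]], tolerance = 1e-6)
})

test_that("energy is invariant under rigid-body motion (open boundary)", {
  p <- params_default()
  set.seed(1)
  for (i in 1:5) {
    cfg <- random_config(3)
    U0 <- as.numeric(total_potential(cfg, p))
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    cfg2 <- cfg
    cfg2$pos <- cfg$pos %*% R + matrix(rnorm(3, sd = 5), 2 * 3,
                                       3, byrow = TRUE)
    expect_lt(abs(as.numeric(total_potential(cfg2, p)) - U0),
              1e-9 * max(1, abs(U0)))
  }
})

test_that("forces match central finite differences of the energy", {
  p <- params_default()
  set.seed(99)
  worst <- 0
  for (rep in 1:100) {
    cfg <- random_config(3)
    # keep away from singular cores where finite differences degrade
    if (as.numeric(total_potential(cfg, p)) > 500) next
    f <- forces(cfg, p)
    h <- 1e-6
    for (i in sample(nrow(cfg$pos), 2)) {
      for (k in 1:3) {
        cp <- cfg; cp$pos[i, k] <- cp$pos[i, k] + h
        cm <- cfg; cm$pos[i, k] <- cm$pos[i, k] - h
        fd <- -(as.numeric(total_potential(cp, p)) -
                  as.numeric(total_potential(cm, p))) / (2 * h)
        worst <- max(worst, abs(fd - f[i, k]) / max(abs(f[i, k]), 1))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("net force on an isolated interacting pair is zero", {
  p <- params_default()
  cfg <- pair_at(1.8, 0.4)
  f <- forces(cfg, p)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)
})

test_that("forces respect the minimum-image convention in a periodic box", {
  p <- params_default()
  # pair interacting across the boundary of a 20 A box
  a <- rbind(c(0.5, 10, 10), c(2.5, 10, 10))
  b <- rbind(c(18.6, 10, 9), c(18.6, 12, 9))
  cfg <- configuration(rbind(a, b), c(1L, 2L), box = 20)
  f <- forces(cfg, p)
  expect_true(any(abs(f) > 1e-6))           # they do interact through the wall
  cfg_open <- configuration(rbind(a, b), c(1L, 2L))
  f_open <- forces(cfg_open, p)
  expect_true(all(abs(f_open) < 1e-6))      # but not in open space
})

test_that("overlapping particles give a large but capped, finite energy", {
  p <- params_default()
  pos <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 1e-4), c(2, 0, 1e-4))
  cfg <- configuration(pos, c(1L, 2L))
  u <- total_potential(cfg, p)
  expect_true(is.finite(as.numeric(u)))
  expect_true(attr(u, "capped"))
  expect_equal(as.numeric(u), p[["ecap"]])
})

test_that("the potential carves docked and locked wells behind a wall", {
  p <- params_default()
  U <- function(r, q, par = p) as.numeric(total_potential(pair_at(r, q), par))
  # locked well is the global minimum; the docked-side (q = +1) well is
  # bound but shallower
  expect_lt(U(p[["r0_t"]], -1), U(1.55, 1))
  expect_lt(U(1.55, 1), 0)
  expect_lt(U(1.55, 1), U(2.9, 1))
  # the wall term contributes its full +ew barrier at its centre (2.2, -1)
  terms <- potential_terms(pair_at(2.2, -1), p)
  expect_equal(unname(terms["wall"]), p[["ew"]], tolerance = 1e-6)
  no_wall <- params_default(ew = 1e-12)
  expect_equal(U(2.2, -1) - U(2.2, -1, no_wall), p[["ew"]], tolerance = 1e-6)
})

test_that("model parameters validate and round-trip through config files", {
  p <- params_default()
  expect_error(dumbbell_params(kb = -1), "kb")
  expect_error(dumbbell_params(sr_w = 0), "length scales")
  expect_error(dumbbell_params(bogus = 1), "unknown parameter")
  f <- tempfile(fileext = ".cfg")
  write_model_config(p, f, box = 60, seed = 7L)
  back <- read_model_config(f)
  expect_equal(as.numeric(back$params), as.numeric(p))
  expect_equal(back$box, 60)
  expect_equal(back$seed, 7L)
  unlink(f)
})

test_that("configurations validate their invariants and export XYZ", {
  expect_error(configuration(matrix(0, 3, 3), c(1L, 2L)), "exactly 2")
  expect_error(configuration(matrix(0, 4, 3), c(1L, 3L)), "species")
  fib <- build_fibril(4, params_default())
  f <- tempfile(fileext = ".xyz")
  write_xyz(fib, f)
  write_xyz(fib, f, append = TRUE)
  lines <- readLines(f)
  expect_equal(length(lines), 2 * (2 + 8))
  expect_equal(lines[1], "8")
  expect_match(lines[3], "^[CNOS] ")
  unlink(f)
})
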