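#' Settings for the NAM docking-rate construction
#'
#' The Northrup-Allison-McCammon method launches Brownian trajectories of a
#' free dumbbell from a sphere of radius `b1` around the fibril end and
#' classifies each as docked (COM separation from the terminal dumbbell below
#' `dock_dist`), escaped (beyond `b2`), or directly locked (the lock
#' criterion `rcom < lock_rcom & q < lock_q` fires first). The committor
#' estimate p is converted to an infinite-domain association rate constant
#' with the return probability Omega.
#'
#' @param b1 launch radius (Angstrom).
#' @param b2 escape radius (Angstrom), `b2 > b1 > dock_dist`.
#' @param n_traj number of trajectories.
#' @param dock_dist docked-state COM-COM distance criterion (Angstrom);
#'   default the docked-basin COM separation `r0_c = 1.7`.
#' @param lock_rcom,lock_q direct-lock criterion on (rcom [Angstrom], q).
#' @param D0 relative diffusivity used in the Smoluchowski prefactor
#'   (Angstrom^2/s); defaults to the sum of the COM diffusivities of two free
#'   dumbbells, `2 * (D_atom / 2) = D_atom`.
#' @param fibril_length number of dumbbells in the preformed fibril.
#' @param max_steps per-trajectory step budget.
#' @param include_direct_lock count direct-lock trajectories as docked
#'   successes instead of omitting them from numerator and denominator.
#' @return A list of class `dl_nam_config`.
#' @export
nam_config <- function(b1 = 12, b2 = 20, n_traj = 10000, dock_dist = NULL,
                       lock_rcom = 1.55, lock_q = -0.8, D0 = NULL,
                       fibril_length = 4, max_steps = 2e6,
                       include_direct_lock = FALSE) {
  if (n_traj < 1) stop("n_traj must be >= 1")
  structure(list(b1 = b1, b2 = b2, n_traj = as.integer(n_traj),
                 dock_dist = dock_dist, lock_rcom = lock_rcom,
                 lock_q = lock_q, D0 = D0,
                 fibril_length = as.integer(fibril_length),
                 max_steps = max_steps,
                 include_direct_lock = include_direct_lock),
            class = "dl_nam_config")
}

#' Return probability of a diffusing particle
#'
#' Probability that a particle at radius `b2` returns to `b1` before
#' escaping to infinity, for an isotropic potential `U(r)` and diffusivity
#' profile `D(r)`:
#' \deqn{\Omega = \left(\int_{b_1}^\infty \frac{e^{\beta U}}{4\pi r^2 D} dr
#'   \right)^{-1} \int_{b_2}^\infty \frac{e^{\beta U}}{4\pi r^2 D}\, dr.}
#' For free diffusion (`U = 0`, constant `D`) this reduces analytically to
#' `b1 / b2`.
#'
#' @param b1,b2 inner and outer radii, `b2 >= b1 > 0`.
#' @param U optional potential function of r (kBT when `beta = 1`).
#' @param D diffusivity: a constant or a function of r.
#' @param beta inverse thermal energy.
#' @return Omega in `[0, 1]`.
#' @export
return_probability <- function(b1, b2, U = NULL, D = 1, beta = 1) {
  stopifnot(b2 >= b1, b1 > 0)
  if (is.null(U) && !is.function(D)) return(b1 / b2)
  Ufun <- if (is.null(U)) function(r) 0 else U
  Dfun <- if (is.function(D)) D else function(r) D + 0 * r
  integrand <- function(r) exp(beta * Ufun(r)) / (4 * pi * r^2 * Dfun(r))
  lower <- integrate(integrand, b1, Inf, rel.tol = 1e-10)
  upper <- integrate(integrand, b2, Inf, rel.tol = 1e-10)
  if (!is.finite(lower$value) || lower$value <= 0)
    stop("divergent or invalid radial integral")
  upper$value / lower$value
}

#' Committor batch around a preformed fibril
#'
#' Launches `n_traj` Brownian trajectories of a free B-species dumbbell from
#' uniformly random points on the `b1` sphere (uniform random bond
#' orientation) around a held-fixed fibril whose terminal dumbbell sits at
#' the origin, and classifies each trajectory. The committor p excludes
#' direct-lock events from both numerator and denominator (they bypass the
#' docked state that p is conditioned on) unless `include_direct_lock`.
#'
#' @param params model parameters.
#' @param nam a [nam_config()].
#' @return List of class `dl_nam_result` with the committor `p`, its Wilson
#'   95% interval, outcome `counts`, `fraction_direct_lock`, and inputs.
#' @export
nam_committor <- function(params, nam = nam_config()) {
  dock_dist <- nam$dock_dist %||% params[["r0_c"]]
  if (!(nam$b2 > nam$b1) || !(nam$b2 > dock_dist))
    stop("need b2 > b1 and b2 > dock_dist")
  if (nam$b1 <= dock_dist)
    warning("launch radius b1 inside the dock criterion: p is trivially 1")
  fib <- build_fibril(nam$fibril_length, params)
  out <- cpp_nam_batch(fib$pos, fib$species, params, nam$b1, nam$b2,
                       dock_dist, nam$lock_rcom, nam$lock_q, nam$n_traj,
                       nam$max_steps)
  oc <- out$outcome
  counts <- c(docked = sum(oc == 1L), escaped = sum(oc == 2L),
              direct_lock = sum(oc == 3L), censored = sum(oc == 0L))
  censored_frac <- counts[["censored"]] / nam$n_traj
  if (censored_frac > 0.01)
    warning(sprintf("%.1f%% of trajectories censored at max_steps",
                    100 * censored_frac))
  if (nam$include_direct_lock) {
    n_eff <- sum(counts[c("docked", "escaped", "direct_lock")])
    n_succ <- counts[["docked"]] + counts[["direct_lock"]]
  } else {
    n_eff <- counts[["docked"]] + counts[["escaped"]]
    n_succ <- counts[["docked"]]
  }
  p <- n_succ / n_eff
  structure(list(p = p, ci = wilson_ci(n_succ, n_eff),
                 counts = counts,
                 fraction_direct_lock = counts[["direct_lock"]] / nam$n_traj,
                 n_eff = n_eff, mean_steps = mean(out$steps),
                 nam = nam, dock_dist = dock_dist),
            class = "dl_nam_result")
}

wilson_ci <- function(k, n, z = 1.959964) {
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Second-order docking rate constant from a committor
#'
#' Converts the finite-domain committor p into the infinite-domain docking
#' probability \eqn{p_\infty = p / (1 - (1 - p)\Omega)} and the association
#' rate constant \eqn{k_D = 4 \pi D_0 b_1 p_\infty}, reported in L/mol/s.
#'
#' @param p committor at `b1`.
#' @param b1 launch radius (Angstrom).
#' @param omega return probability from `b2` to `b1`.
#' @param D0 relative diffusivity (Angstrom^2/s).
#' @return `kD` in L/mol/s.
#' @export
docking_rate <- function(p, b1, omega, D0) {
  stopifnot(p >= 0, p <= 1, omega >= 0, omega <= 1)
  p_inf <- if (p == 1 && omega == 1) 1 else p / (1 - (1 - p) * omega)
  4 * pi * D0 * b1 * p_inf * .A3_to_Lmol
}

#' Full NAM docking-rate calculation
#'
#' Runs [nam_committor()], computes the free-diffusion return probability
#' `b1 / b2` (all interactions vanish well inside `b1`), and assembles the
#' docking rate constant with a linearly propagated 95% interval.
#'
#' @inheritParams nam_committor
#' @return List of class `dl_nam_result` extended with `omega`, `p_inf`,
#'   `kD` (L/mol/s) and `kD_ci`.
#' @examples
#' \donttest{
#' set.seed(1)
#' res <- nam_docking(dumbbell_params(), nam_config(n_traj = 200))
#' res$p
#' }
#' @export
nam_docking <- function(params, nam = nam_config()) {
  res <- nam_committor(params, nam)
  D0 <- nam$D0 %||% params[["D_atom"]]
  omega <- return_probability(nam$b1, nam$b2)
  res$omega <- omega
  res$p_inf <- res$p / (1 - (1 - res$p) * omega)
  res$D0 <- D0
  res$kD <- docking_rate(res$p, nam$b1, omega, D0)
  res$kD_ci <- vapply(res$ci, docking_rate, 0, b1 = nam$b1, omega = omega,
                      D0 = D0)
  res
}

#' @export
print.dl_nam_result <- function(x, ...) {
  cat(sprintf("<dl_nam_result> b1 = %g, b2 = %g A, n = %d\n",
              x$nam$b1, x$nam$b2, x$nam$n_traj))
  cat(sprintf("  p = %.4f  (95%% CI %.4f-%.4f)\n", x$p, x$ci[1], x$ci[2]))
  cat(sprintf("  direct lock: %.2f%%   censored: %d\n",
              100 * x$fraction_direct_lock, x$counts[["censored"]]))
  if (!is.null(x$kD))
    cat(sprintf("  kD = %.3e L/mol/s  (omega = %.3f, D0 = %.3g A^2/s)\n",
                x$kD, x$omega, x$D0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
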