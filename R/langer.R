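#' Saddle-point diffusion tensor from short unbiased bursts
#'
#' Prepares a saddle-restrained ensemble (stiff harmonic biases on the pair
#' coordinates of the mobile dumbbell against the fixed fibril end), releases
#' each member unbiased for a short time t, and estimates
#' \deqn{2 D_{ij} t = \langle \delta q_i(t)\, \delta q_j(t) \rangle^{\ddag}}
#' with \eqn{\delta q_i(t)} the fluctuation of coordinate i around the
#' ensemble mean, evaluated on per-trajectory displacements so that the
#' finite width of the restrained starting ensemble cancels. The first
#' coordinate is carried in Angstrom (COM separation), so `Drr` is in A^2/s,
#' `Dqq` in 1/s and `Drq` in A/s. Linearity of the covariance growth is
#' checked against t/2; more than 20% discrepancy warns that t is too long.
#'
#' @param params model parameters.
#' @param saddle `c(rcom, q)` saddle location (rcom in Angstrom).
#' @param t burst length (seconds), checked for linearity at t/2. The
#'   default 0.1 ps keeps the burst well inside the linear regime: the
#'   unstable saddle mode grows at a rate of order 1e12/s here, so
#'   covariances measured over a full picosecond are already inflated by
#'   the deterministic flow (the t/2 check catches this).
#' @param n_traj ensemble size.
#' @param fibril_length fibril size used for the restrained ensemble.
#' @param k_restrain restraint strengths (kBT per squared coordinate unit).
#' @param n_equil equilibration steps of the restrained run.
#' @param stride decorrelation stride (steps) between stored snapshots.
#' @return List of class `dl_diffusion`: `D` (2 x 2 matrix), `Drr`, `Dqq`,
#'   `Drq`, standard errors, `t`, `n_traj`, `nonlinearity`.
#' @export
estimate_diffusion_tensor <- function(params, saddle, t = 1e-13,
                                      n_traj = 5000, fibril_length = 6,
                                      k_restrain = 400, n_equil = 20000,
                                      stride = 50) {
  params6 <- dumbbell_params(modifyList(as.list(unclass(params)),
                                        list(rcom_cutoff = 8)))
  t_steps <- max(2L, as.integer(round(t / params[["dt"]])))
  fib <- build_fibril(fibril_length, params6)
  snaps <- cpp_saddle_snapshots(fib$pos, fib$species, params6,
                                saddle[1], saddle[2], k_restrain, k_restrain,
                                as.integer(n_equil), as.integer(stride),
                                as.integer(n_traj))
  rec <- cpp_tensor_batch(fib$pos, fib$species, params6, snaps,
                          t_steps)
  # displacement covariance: removes the finite width of the restrained
  # starting ensemble, which would otherwise swamp short bursts
  est <- function(r, q, tt) {
    dr <- r - rec[, "r0"]; dq <- q - rec[, "q0"]
    dr <- dr - mean(dr); dq <- dq - mean(dq)
    m <- cbind(dr * dr, dr * dq, dq * dq) / (2 * tt)
    list(D = matrix(c(mean(m[, 1]), mean(m[, 2]), mean(m[, 2]), mean(m[, 3])),
                    2, 2),
         se = apply(m, 2, sd) / sqrt(length(r)))
  }
  t_full <- t_steps * params[["dt"]]
  full <- est(rec[, "r_full"], rec[, "q_full"], t_full)
  half <- est(rec[, "r_half"], rec[, "q_half"], (t_steps %/% 2) * params[["dt"]])
  nonlin <- abs(diag(half$D) - diag(full$D)) / diag(full$D)
  if (any(nonlin > 0.2))
    warning(sprintf(
      "covariance growth nonlinear between t/2 and t (%.0f%%); t too long?",
      100 * max(nonlin)))
  structure(list(D = full$D, Drr = full$D[1, 1], Dqq = full$D[2, 2],
                 Drq = full$D[1, 2],
                 se = c(Drr = full$se[1], Drq = full$se[2], Dqq = full$se[3]),
                 t = t_full, n_traj = n_traj, nonlinearity = nonlin,
                 D_half = half$D),
            class = "dl_diffusion")
}

#' @export
print.dl_diffusion <- function(x, ...) {
  cat(sprintf(
    "<dl_diffusion> t = %.3g s, n = %d\n  Drr = %.4g A^2/s (se %.2g)\n  Dqq = %.4g /s (se %.2g)\n  Drq = %.4g A/s (se %.2g)\n",
    x$t, x$n_traj, x$Drr, x$se[1], x$Dqq, x$se[3], x$Drq, x$se[2]))
  invisible(x)
}

#' Langer's multidimensional barrier-crossing rate
#'
#' Overdamped multidimensional rate formula
#' \deqn{k_L = \frac{1}{2\pi} \sqrt{\frac{\det A_0}{|\det A|}}\;
#'   \lambda_+\; e^{-\beta \Delta F},}
#' where \eqn{A_0} and \eqn{A} are the curvature matrices of the
#' beta-reduced free energy at the reactant minimum and at the saddle,
#' \eqn{\Delta F} the barrier height, and \eqn{-\lambda_+} the unique
#' negative eigenvalue of \eqn{D A} (the deterministic unstable relaxation
#' rate through the saddle).
#'
#' Coordinate conventions: `A0`, `A` and `D` must be expressed in the same
#' coordinates (here COM separation in Angstrom and dimensionless q, the
#' outputs of [locate_stationary_points()] and
#' [estimate_diffusion_tensor()]).
#'
#' @param A0 curvature matrix at the reactant (docked) minimum; positive
#'   definite.
#' @param A curvature matrix at the saddle; exactly one negative eigenvalue.
#' @param deltaF barrier height F(saddle) - F(min), kBT.
#' @param D diffusion tensor (2 x 2, same coordinates).
#' @param beta inverse temperature.
#' @return `kL` (1/s) with attributes `lambda_plus` and `det_ratio`.
#' @export
langer_rate <- function(A0, A, deltaF, D, beta = 1) {
  ev0 <- eigen(A0, symmetric = TRUE, only.values = TRUE)$values
  evA <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev0 <= 0)) stop("A0 must be positive definite (eigenvalues ",
                          paste(signif(ev0, 4), collapse = ", "), ")")
  if (sum(evA < 0) != 1L) stop("A must have exactly one negative eigenvalue")
  eig_DA <- eigen(D %*% A, only.values = TRUE)$values
  eig_DA <- Re(eig_DA[abs(Im(eig_DA)) < 1e-8 * max(abs(eig_DA))])
  neg <- eig_DA[eig_DA < 0]
  if (length(neg) != 1L)
    stop(sprintf("D %%*%% A has %d negative eigenvalues; expected 1",
                 length(neg)))
  lambda_plus <- -neg
  det_ratio <- det(A0) / abs(det(A))
  kL <- sqrt(det_ratio) * lambda_plus * exp(-beta * deltaF) / (2 * pi)
  structure(kL, lambda_plus = lambda_plus, det_ratio = det_ratio)
}
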