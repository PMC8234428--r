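#' Orientational density of the chirality coordinate
#'
#' For two dumbbells with uncorrelated uniformly random bond orientations,
#' the chirality coordinate \eqn{q = \hat u \cdot (\hat b_B \times \hat
#' b_A)} (bonds at their equilibrium length) has a universal density w(q) on
#' \eqn{[-1, 1]}, strongly peaked at 0: large |q| requires the two bonds to
#' be simultaneously perpendicular to each other and to the separation
#' vector. This density is the orientational reference for the unbound state
#' when converting the sampled \eqn{(r_{COM}, q)} histogram into a docking
#' equilibrium constant.
#'
#' @param q_mid evaluation points (bin centres).
#' @param n Monte Carlo sample count.
#' @return Numeric density values at `q_mid` (integrates to 1 over [-1, 1]).
#' @export
chirality_density <- function(q_mid, n = 4e6) {
  # fixed internal stream; does not disturb the caller's RNG
  state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(state)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", state, .GlobalEnv)
  })
  set.seed(20210617L)
  ra <- matrix(rnorm(3 * n), n, 3)
  rb <- matrix(rnorm(3 * n), n, 3)
  ra <- ra / sqrt(rowSums(ra^2))
  rb <- rb / sqrt(rowSums(rb^2))
  # z component of rb x ra  (u along z by isotropy)
  qs <- rb[, 1] * ra[, 2] - rb[, 2] * ra[, 1]
  dq <- if (length(q_mid) > 1) q_mid[2] - q_mid[1] else 0.05
  edges <- c(q_mid - dq / 2, q_mid[length(q_mid)] + dq / 2)
  h <- graphics::hist(qs[qs >= edges[1] & qs <= edges[length(edges)]],
                      breaks = edges, plot = FALSE)
  h$counts / (n * dq)
}

#' Docking equilibrium constant from a free energy surface
#'
#' Integrates the unbiased \eqn{(r_{COM}, q)} probability of the docked
#' basin and references it to the unbound state at standard concentration.
#' The sampled histogram absorbs the coordinate Jacobian, so in the
#' non-interacting outer region the bin probabilities follow
#' \eqn{p(r, q) \propto r^2 w(q)} with w(q) the orientational density of q
#' ([chirality_density()]). Matching that form over `ref_r_range` calibrates
#' the free-state number density; the docked basin is the set of bins below
#' the saddle level that are 4-connected to the docked minimum (or a
#' rectangular window via `basin`).
#'
#' The association constant is returned in L/mol; its inverse (mol/L) is the
#' \eqn{K_D^{-1}} term of the microkinetic rate law.
#'
#' @param fes a `dl_fes`.
#' @param stat a `dl_stationary` from [locate_stationary_points()].
#' @param params model parameters.
#' @param ref_r_range rcom band treated as unbound reference.
#' @param basin `"saddle-contour"` (default: bins below the raw-grid
#'   separating level that are 4-connected to the docked minimum, which by
#'   construction excludes the locked funnel) or `list(r_range =, q_range =)`
#'   for a rectangular window.
#' @return List of class `dl_kd`: `KD` (L/mol), `KD_inv_molar`, `KD_A3`
#'   (effective bound volume, Angstrom^3), `n_basin_bins`, `flat_range_kBT`.
#' @export
docking_equilibrium_constant <- function(fes, stat, params = dumbbell_params(),
                                         ref_r_range = c(4.8, 5.4),
                                         basin = "saddle-contour") {
  p <- fes$prob
  p[is.na(fes$F)] <- 0
  dr <- fes$r_edges[2] - fes$r_edges[1]
  dq <- fes$q_edges[2] - fes$q_edges[1]
  w <- chirality_density(fes$q_mid)

  in_ref <- fes$r_mid >= ref_r_range[1] & fes$r_mid <= ref_r_range[2]
  if (!any(in_ref)) stop("reference band outside the grid")
  ref_p <- p[in_ref, , drop = FALSE]
  shape <- outer(fes$r_mid[in_ref]^2, w)          # propto density / const
  use <- ref_p > 0 & shape > 0
  if (sum(use) < 10) stop("too few sampled bins in the unbound reference band")
  # flatness check on the Jacobian-corrected free energy
  Fcorr <- -log(ref_p[use] / shape[use])
  flat_range <- diff(range(Fcorr))
  if (flat_range > 0.5)
    warning(sprintf(
      "unbound reference not flat: corrected F spans %.2f kBT", flat_range))
  # free-state number density (per A^3) implied by the sampled histogram:
  # p_bin = n0 * 4 pi r^2 w(q) dr dq  in the unbound region (r in Angstrom)
  n0 <- sum(ref_p[use]) /
    (4 * pi * dr * dq * sum(shape[use]))

  if (identical(basin, "saddle-contour")) {
    level <- stat$sep_level %||% stat$F_saddle
    mask <- connected_below(fes$F, stat$bins$docked, level)
  } else {
    mask <- outer(fes$r_mid >= basin$r_range[1] & fes$r_mid <= basin$r_range[2],
                  fes$q_mid >= basin$q_range[1] & fes$q_mid <= basin$q_range[2],
                  "&")
  }
  KD_A3 <- sum(p[mask]) / n0
  structure(list(KD = KD_A3 * .A3_to_Lmol,
                 KD_inv_molar = 1 / (KD_A3 * .A3_to_Lmol),
                 KD_A3 = KD_A3, n_basin_bins = sum(mask),
                 flat_range_kBT = flat_range, n0 = n0),
            class = "dl_kd")
}

#' @export
print.dl_kd <- function(x, ...) {
  cat(sprintf(
    "<dl_kd> KD = %.4g L/mol (association), KD^-1 = %.4g mol/L, %d basin bins\n",
    x$KD, x$KD_inv_molar, x$n_basin_bins))
  invisible(x)
}

# bins with F < level 4-connected to seed bin
connected_below <- function(F, seed, level) {
  nr <- nrow(F); nq <- ncol(F)
  ok <- !is.na(F) & F < level
  mask <- matrix(FALSE, nr, nq)
  if (!ok[seed[1], seed[2]]) {
    mask[seed[1], seed[2]] <- TRUE
    return(mask)
  }
  stack <- list(seed)
  mask[seed[1], seed[2]] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      i <- cur[1] + d[1]; j <- cur[2] + d[2]
      if (i < 1L || i > nr || j < 1L || j > nq) next
      if (ok[i, j] && !mask[i, j]) {
        mask[i, j] <- TRUE
        stack[[length(stack) + 1L]] <- c(i, j)
      }
    }
  }
  mask
}

#' Mean COM separation of the docked state
#'
#' Boltzmann-weighted mean of the COM separation over the docked basin of a
#' free energy surface; this is the distance criterion that terminates NAM
#' committor trajectories as "docked".
#'
#' @param fes a `dl_fes`.
#' @param stat a `dl_stationary`.
#' @return Mean separation (Angstrom).
#' @export
docked_mean_separation <- function(fes, stat) {
  level <- stat$sep_level %||% stat$F_saddle
  mask <- connected_below(fes$F, stat$bins$docked, level)
  pr <- fes$prob
  pr[is.na(fes$F)] <- 0
  w <- pr * mask
  sum(matrix(fes$r_mid, nrow(w), ncol(w)) * w) / sum(w)
}
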