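#' Stationary points and curvatures of a 2-D free energy surface
#'
#' Locates the docked and locked minima (the global minima of the raw
#' surface on the positive- and negative-chirality half-planes `|q| >=
#' q_split`; the basins hug the two enantiomeric stacking geometries, so a
#' local descent from the Gaussian centres can strand on a shoulder), the
#' saddle between them (the lowest ridge crossing on a smoothed copy: the
#' smallest level at which the two basins become 4-connected), and local
#' quadratic expansions around the minima and the saddle.
#'
#' Curvature matrices are obtained by weighted least-squares quadratic fits
#' on the *raw* grid in a neighbourhood of `fit_radius` bins and are
#' symmetric by construction. They are reported in physical coordinates
#' (COM separation in Angstrom, q dimensionless) as curvatures of the
#' beta-reduced surface, the form needed by [langer_rate()].
#'
#' @param fes a `dl_fes` from [wham_2d()].
#' @param params model parameters (provides `r0` and the Gaussian centres
#'   used as descent seeds).
#' @param fit_radius neighbourhood radius (bins) of the quadratic fits.
#' @param smooth_df spline degrees of freedom per grid line for the smoothed
#'   copy used only to locate the saddle.
#' @param q_split half-plane boundary for the two minima searches.
#' @return List of class `dl_stationary`: `docked`, `locked`, `saddle`
#'   (each `c(rcom, q)`), `F_docked`, `F_locked`, `F_saddle`, `barrier`
#'   (= F_saddle - F_docked, kBT), curvature matrices `A0` (docked) and `A`
#'   (saddle) with attribute `units = "Angstrom"`.
#' @export
locate_stationary_points <- function(fes, params = dumbbell_params(),
                                     fit_radius = 3, smooth_df = 10,
                                     q_split = 0.3) {
  Fs <- smooth_surface(fes$F, smooth_df)
  i_dock <- halfplane_min(fes, fes$q_mid >= q_split)
  i_lock <- halfplane_min(fes, fes$q_mid <= -q_split)
  if (all(i_dock == i_lock)) stop("docked and locked minima coincide")
  i_sad <- saddle_bin(Fs, i_dock, i_lock)

  docked <- c(fes$r_mid[i_dock[1]], fes$q_mid[i_dock[2]])
  locked <- c(fes$r_mid[i_lock[1]], fes$q_mid[i_lock[2]])
  saddle <- c(fes$r_mid[i_sad[1]], fes$q_mid[i_sad[2]])

  fit0 <- quad_fit(fes, i_dock, fit_radius)
  fitS <- quad_fit(fes, i_sad, fit_radius)
  ev0 <- eigen(fit0$A, symmetric = TRUE, only.values = TRUE)$values
  evS <- eigen(fitS$A, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev0 <= 0))
    stop(sprintf("docked curvature not positive definite (eigenvalues %s)",
                 paste(signif(ev0, 4), collapse = ", ")))
  if (sum(evS < 0) != 1L)
    stop(sprintf("saddle has %d negative eigenvalues (%s); expected 1",
                 sum(evS < 0), paste(signif(evS, 4), collapse = ", ")))
  F_d <- fes$F[i_dock[1], i_dock[2]]
  F_l <- fes$F[i_lock[1], i_lock[2]]
  F_s <- fes$F[i_sad[1], i_sad[2]]
  if (!(F_s > F_d)) stop("saddle not above the docked minimum")
  # largest level at which the two basins are still disconnected on the RAW
  # grid (can sit slightly below the smoothed-surface saddle); used as the
  # docked-basin boundary by the equilibrium-constant integral
  Fr <- fes$F
  Fr[is.na(Fr)] <- Inf
  i_sad_raw <- saddle_bin(Fr, i_dock, i_lock)
  sep_level <- Fr[i_sad_raw[1], i_sad_raw[2]]
  structure(list(docked = docked, locked = locked, saddle = saddle,
                 F_docked = F_d, F_locked = F_l, F_saddle = F_s,
                 barrier = F_s - F_d, sep_level = sep_level,
                 A0 = structure(fit0$A, units = "Angstrom"),
                 A = structure(fitS$A, units = "Angstrom"),
                 bins = list(docked = i_dock, locked = i_lock,
                             saddle = i_sad)),
            class = "dl_stationary")
}

#' @export
print.dl_stationary <- function(x, ...) {
  cat("<dl_stationary>\n")
  cat(sprintf("  docked  (%.3f, %.3f)  F = %.3f kBT\n", x$docked[1],
              x$docked[2], x$F_docked))
  cat(sprintf("  locked  (%.3f, %.3f)  F = %.3f kBT\n", x$locked[1],
              x$locked[2], x$F_locked))
  cat(sprintf("  saddle  (%.3f, %.3f)  F = %.3f kBT (barrier %.3f)\n",
              x$saddle[1], x$saddle[2], x$F_saddle, x$barrier))
  invisible(x)
}

# separable cubic smoothing spline along each grid line; NA-safe.
smooth_surface <- function(F, df = 10) {
  big <- max(F, na.rm = TRUE) + 5
  G <- F
  G[is.na(G)] <- big
  sm_line <- function(y) {
    n <- length(y)
    fit <- try(stats::smooth.spline(seq_len(n), y, df = min(df, n - 1)),
               silent = TRUE)
    if (inherits(fit, "try-error")) y
    else stats::predict(fit, seq_len(n))$y
  }
  G <- t(apply(G, 1, sm_line))
  G <- apply(G, 2, sm_line)
  G
}

halfplane_min <- function(fes, q_mask) {
  F <- fes$F
  F[, !q_mask] <- NA
  if (all(is.na(F))) stop("no sampled bins in half-plane")
  i <- which(F == min(F, na.rm = TRUE), arr.ind = TRUE)[1, ]
  c(i[[1]], i[[2]])
}

descend <- function(Fs, fes, start) {
  i <- c(which.min(abs(fes$r_mid - start[1])),
         which.min(abs(fes$q_mid - start[2])))
  nr <- nrow(Fs); nq <- ncol(Fs)
  for (step in 1:10000) {
    nb <- expand.grid(di = -1:1, dj = -1:1)
    ii <- pmin(pmax(i[1] + nb$di, 1), nr)
    jj <- pmin(pmax(i[2] + nb$dj, 1), nq)
    vals <- Fs[cbind(ii, jj)]
    k <- which.min(vals)
    if (ii[k] == i[1] && jj[k] == i[2]) break
    i <- c(ii[k], jj[k])
  }
  i
}

# lowest ridge crossing between two basins: sweep bins in increasing F and
# union-find 4-neighbour components until the basin seeds connect.
saddle_bin <- function(Fs, i_a, i_b) {
  nr <- nrow(Fs); nq <- ncol(Fs)
  idx <- function(i, j) (j - 1L) * nr + i
  ord <- order(Fs)
  parent <- seq_len(nr * nq)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  active <- logical(nr * nq)
  a <- idx(i_a[1], i_a[2]); b <- idx(i_b[1], i_b[2])
  for (o in ord) {
    active[o] <- TRUE
    i <- (o - 1L) %% nr + 1L
    j <- (o - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni < 1L || ni > nr || nj < 1L || nj > nq) next
      no <- idx(ni, nj)
      if (active[no]) {
        ra <- find(o); rb <- find(no)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (active[a] && active[b] && find(a) == find(b))
      return(c(i, j))
  }
  stop("basins never connect on the grid")
}

# weighted quadratic LSQ in a (2*radius+1)^2 neighbourhood on the raw grid;
# returns the symmetric Hessian in (rcom_Angstrom, q) coordinates.
quad_fit <- function(fes, i0, radius) {
  nr <- length(fes$r_mid); nq <- length(fes$q_mid)
  ii <- max(1, i0[1] - radius):min(nr, i0[1] + radius)
  jj <- max(1, i0[2] - radius):min(nq, i0[2] + radius)
  g <- expand.grid(i = ii, j = jj)
  z <- fes$F[cbind(g$i, g$j)]
  ok <- !is.na(z)
  if (sum(ok) < 8) stop("too few sampled bins for a quadratic fit")
  dr <- fes$r_mid[g$i] - fes$r_mid[i0[1]]   # Angstrom
  dq <- fes$q_mid[g$j] - fes$q_mid[i0[2]]
  sr <- radius * (fes$r_mid[2] - fes$r_mid[1])
  sq <- radius * (fes$q_mid[2] - fes$q_mid[1])
  w <- exp(-(dr / sr)^2 - (dq / sq)^2)
  X <- cbind(1, dr, dq, dr^2, dr * dq, dq^2)[ok, , drop = FALSE]
  fit <- stats::lm.wfit(X, z[ok], w[ok])
  cf <- fit$coefficients
  A <- matrix(c(2 * cf[4], cf[5], cf[5], 2 * cf[6]), 2, 2)
  A <- (A + t(A)) / 2
  list(A = A, coef = cf)
}
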