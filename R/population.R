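#' Green's function of the fibril-length population balance
#'
#' In dimensionless time (one unit = one expected monomer addition) the
#' length distribution obeys an advection-diffusion equation whose Green's
#' function is Gaussian with mean `L0 + t` and variance `t`:
#' \deqn{g(L, t | L_0) = \frac{1}{\sqrt{2 \pi t}}
#'   \exp\!\left(-\frac{(L - L_0 - t)^2}{2 t}\right).}
#'
#' @param L fibril length (monomers), scalar or vector.
#' @param t dimensionless time, > 0.
#' @param L0 initial length.
#' @return Density values.
#' @export
green_function <- function(L, t, L0 = 0) {
  if (any(t <= 0)) stop("t must be > 0 (the t = 0 delta limit is the caller's)")
  dnorm(L, mean = L0 + t, sd = sqrt(t))
}

# Principal-branch Lambert W of exp(y), solved in the overflow-safe log form
# w + log w = y. Newton on that form is globally convergent from the
# initial guesses below; for very negative y the fixed point
# w = exp(y - w) converges quadratically fast from w = exp(y).
lambertw_exp <- function(y) {
  out <- numeric(length(y))
  tiny <- y < -2
  if (any(tiny)) {
    w <- exp(y[tiny])
    for (i in 1:50) {
      w_new <- exp(y[tiny] - w)
      if (max(abs(w_new - w)) < 1e-16) { w <- w_new; break }
      w <- w_new
    }
    out[tiny] <- w
  }
  if (any(!tiny)) {
    yl <- y[!tiny]
    w <- 0.5 + 0.35 * yl
    big <- yl > 1
    w[big] <- yl[big] - log(yl[big])
    w <- pmax(w, 1e-8)
    for (i in 1:200) {
      delta <- (w + log(w) - yl) / (1 + 1 / w)
      delta <- pmax(pmin(delta, w / 2), -w)  # keep w positive
      w <- w - delta
      if (max(abs(delta)) < 1e-15 * max(w, 1e-10)) break
    }
    out[!tiny] <- w
  }
  out
}

#' Monomer depletion in a closed system
#'
#' Dimensionless free-monomer concentration \eqn{m(t) = [M](t)/[M]_0} when a
#' fixed pool of monomers feeds fibril growth:
#' \deqn{m(t) = \frac{1}{\alpha} W\!\left[\alpha e^{\alpha}
#'   e^{-(1+\alpha)\varepsilon t}\right],}
#' with W the principal Lambert function,
#' \eqn{\alpha = k_D k_L^{-1} [M]_0 / (1 + k_D K_D^{-1} k_L^{-1})} the
#' saturation parameter and \eqn{\varepsilon = \rho_{tot}/[M]_0} the
#' fibril-to-monomer ratio.
#'
#' @param t dimensionless time, scalar or vector.
#' @param alpha saturation parameter, >= 0 (`alpha = 0` gives the analytic
#'   limit `exp(-eps * t)`).
#' @param eps fibril-end to initial-monomer concentration ratio, > 0.
#' @return m(t) in `[0, 1]`.
#' @export
monomer_depletion <- function(t, alpha, eps) {
  stopifnot(alpha >= 0, eps > 0, all(t >= 0))
  if (alpha < 1e-8) return(exp(-eps * t))
  y <- log(alpha) + alpha - (1 + alpha) * eps * t
  lambertw_exp(y) / alpha
}

#' Warped time absorbing monomer depletion
#'
#' The substitution \eqn{d\tau = \frac{(1+\alpha) m}{1 + \alpha m} dt}
#' returns the depleting-monomer population balance to its
#' constant-concentration form. The closed form is
#' \deqn{\tau(t) = \frac{1}{\varepsilon}\left[1 - \frac{1}{\alpha}
#'   W\!\left(\alpha e^{\alpha} e^{-(1+\alpha)\varepsilon t}\right)\right]
#'   = \frac{1 - m(t)}{\varepsilon},}
#' which starts with unit slope and saturates at \eqn{1/\varepsilon}, the
#' total growth available per fibril end.
#'
#' @inheritParams monomer_depletion
#' @export
warped_time <- function(t, alpha, eps) {
  (1 - monomer_depletion(t, alpha, eps)) / eps
}

#' Dimensionless population-balance parameters from rate constants
#'
#' @param rc a [rate_constants()] object.
#' @param M0 initial monomer concentration (mol/L).
#' @param rho_tot fibril (end) number concentration (mol/L).
#' @return List with `alpha`, `eps` and the dimensionless-time scale
#'   `rg0 = ` growth rate at `M0` (1/s), so physical time = t / rg0.
#' @export
pbe_params <- function(rc, M0, rho_tot) {
  stopifnot(M0 > 0, rho_tot > 0)
  alpha <- rc$kD * M0 / rc$kL / (1 + rc$kD / (rc$KD * rc$kL))
  list(alpha = alpha, eps = rho_tot / M0, rg0 = growth_rate_full(rc, M0))
}

#' Evolve a fibril length distribution
#'
#' Propagates an initial normalized length distribution through the
#' population balance, either at constant monomer concentration (clock = t)
#' or with monomer depletion (the same Green's function evaluated at the
#' warped time tau(t)). The solution is the convolution
#' \eqn{x(L, \cdot) = \int_0^\infty g(L, \cdot | L_0) x_0(L_0) dL_0},
#' evaluated on `L_grid`.
#'
#' @param x0 initial distribution: either `list(delta = L0)` for a point
#'   mass or a function of L (normalized on the grid).
#' @param times dimensionless clock values (increasing, > 0).
#' @param alpha,eps depletion parameters (used in `mode = "depletion"`).
#' @param mode `"constant"` or `"depletion"`.
#' @param L_grid evaluation grid; default `seq(0, L0 + 10 / eps, 0.1)`
#'   style range wide enough to hold the advected Gaussian.
#' @param ends_factor 1 (single growing end) or 2 (both ends; rescales the
#'   clock).
#' @return Object of class `dl_population`: `L`, matrix `x` (length x
#'   time), `times`, `tau`, `m`, `mass` (grid-captured mass per clock
#'   value).
#' @export
solve_population <- function(x0, times, alpha = 1, eps = 0.01,
                             mode = c("constant", "depletion"),
                             L_grid = NULL, ends_factor = 1) {
  mode <- match.arg(mode)
  stopifnot(all(diff(times) > 0), all(times > 0))
  t_eff <- ends_factor * times
  if (mode == "depletion") {
    tau <- warped_time(t_eff, alpha, eps)
    m <- monomer_depletion(t_eff, alpha, eps)
  } else {
    tau <- t_eff
    m <- rep(1, length(times))
  }
  if (is.null(L_grid)) {
    L0max <- if (is.list(x0)) x0$delta else 50
    L_grid <- seq(0, L0max + max(tau) + 8 * sqrt(max(tau)) + 5, by = 0.1)
  }
  nx <- length(L_grid); nt <- length(times)
  X <- matrix(0, nx, nt)
  if (is.list(x0) && !is.null(x0$delta)) {
    for (j in seq_len(nt)) X[, j] <- green_function(L_grid, tau[j], x0$delta)
  } else {
    w0 <- x0(L_grid)
    w0 <- w0 / sum(w0 * c(diff(L_grid), 0))
    dL <- L_grid[2] - L_grid[1]
    for (j in seq_len(nt)) {
      G <- outer(L_grid, L_grid,
                 function(L, L0) green_function(L, tau[j], L0))
      X[, j] <- as.vector(G %*% (w0 * dL))
    }
  }
  mass <- apply(X, 2, function(x) trapz_mass(L_grid, x))
  if (any(mass < 1 - 1e-6))
    warning(sprintf(
      "grid truncation: only %.8f of the mass captured at the last clock; widen L_grid",
      min(mass)))
  structure(list(L = L_grid, x = X, times = times, tau = tau, m = m,
                 mode = mode, alpha = alpha, eps = eps,
                 ends_factor = ends_factor, mass = mass),
            class = "dl_population")
}

trapz_mass <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' @export
print.dl_population <- function(x, ...) {
  cat(sprintf("<dl_population> mode %s, %d clock values, alpha = %g, eps = %g\n",
              x$mode, length(x$times), x$alpha, x$eps))
  invisible(x)
}

#' @export
plot.dl_population <- function(x, ...) {
  graphics::matplot(x$L, x$x, type = "l", lty = 1,
                    xlab = "L (monomers)", ylab = "x(L)", ...)
  invisible(x)
}
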