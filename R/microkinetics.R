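#' Dock-lock rate constants
#'
#' Container for the elementary rate constants of the dock-lock cycle and
#' the derived Michaelis constant \eqn{K = k_L / k_D + K_D^{-1}}. `KD` is
#' stored in the rate-law-consistent association convention (L/mol, so that
#' \eqn{K_D^{-1}} is a concentration in mol/L).
#'
#' @param kD docking rate constant (L/mol/s).
#' @param kL locking rate constant (1/s).
#' @param kUL reverse locking rate constant (1/s).
#' @param KD docking equilibrium constant (L/mol).
#' @return List of class `dl_rates` with an added `K` (mol/L).
#' @examples
#' rc <- rate_constants(kD = 1.21e9, kL = 9.852e7, KD = 8.440e2)
#' rc$K   # ~0.08 mol/L
#' @export
rate_constants <- function(kD, kL, kUL = 0, KD) {
  stopifnot(kD >= 0, kL >= 0, kUL >= 0, KD > 0)
  structure(list(kD = kD, kL = kL, kUL = kUL, KD = KD,
                 K = kL / kD + 1 / KD),
            class = "dl_rates")
}

#' @export
print.dl_rates <- function(x, ...) {
  cat("<dl_rates>\n")
  cat(sprintf("  kD  = %.4g L/mol/s\n  kL  = %.4g /s\n  kUL = %.4g /s\n",
              x$kD, x$kL, x$kUL))
  cat(sprintf("  KD  = %.4g L/mol (KD^-1 = %.4g mol/L)\n  K   = %.4g mol/L\n",
              x$KD, 1 / x$KD, x$K))
  invisible(x)
}

#' JSON round-trip of rate constants
#' @param x a `dl_rates`.
#' @param file optional path; when `NULL` the JSON string is returned.
#' @export
rates_to_json <- function(x, file = NULL) {
  obj <- list(kD_L_per_mol_s = x$kD, kL_per_s = x$kL, kUL_per_s = x$kUL,
              KD_L_per_mol = x$KD, K_mol_per_L = x$K)
  if (is.null(file)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
}

#' @rdname rates_to_json
#' @param json JSON string or file path.
#' @export
rates_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  rate_constants(kD = o$kD_L_per_mol_s, kL = o$kL_per_s, kUL = o$kUL_per_s,
                 KD = o$KD_L_per_mol)
}

#' Net fibril growth rate of the dock-lock cycle
#'
#' Pseudo-steady-state rate law of the two-state (docked/locked) fibril end,
#' \deqn{r_{growth} = \frac{k_L k_D [M] - k_D K_D^{-1} k_{UL}}
#'   {k_L + k_D K_D^{-1} + k_{UL} + k_D [M]},}
#' in monomers per second per fibril end. The rate is negative (net
#' dissolution) when \eqn{k_{UL} K_D^{-1} > k_L [M] } scaled accordingly.
#'
#' @param rc a [rate_constants()] object.
#' @param M monomer concentration (mol/L), scalar or vector.
#' @return Growth rate(s), 1/s.
#' @export
growth_rate_full <- function(rc, M) {
  stopifnot(all(M >= 0))
  den <- rc$kL + rc$kD / rc$KD + rc$kUL + rc$kD * M
  if (any(den == 0)) stop("zero denominator: all rate constants vanish")
  (rc$kL * rc$kD * M - rc$kD * rc$kUL / rc$KD) / den
}

#' Michaelis-Menten form of the growth rate
#'
#' Irreversible-locking limit of [growth_rate_full()] re-parameterised by
#' the Michaelis constant: \eqn{r_g = k_L [M] / (K + [M])} with
#' \eqn{K = k_L / k_D + K_D^{-1}}.
#'
#' @param kL locking rate constant (1/s).
#' @param K Michaelis constant (mol/L).
#' @param M monomer concentration (mol/L), scalar or vector.
#' @export
growth_rate_mm <- function(kL, K, M) {
  stopifnot(K > 0, all(M >= 0))
  kL * M / (K + M)
}

#' Convert a first-order MSM docking rate to second order
#'
#' A Markov-state-model docking rate \eqn{k_{MSM}} (1/s) measured in a
#' simulation box is a transition probability per time conditional on one
#' monomer being present; in the dilute regime (\eqn{V_{box} [M] \ll 1})
#' the bimolecular constant is \eqn{k_D = k_{MSM} V_{box}}.
#'
#' @param kMSM first-order docking rate (1/s).
#' @param Vbox box volume (Angstrom^3).
#' @return `kD` in L/mol/s.
#' @export
msm_to_second_order <- function(kMSM, Vbox) {
  stopifnot(kMSM >= 0, Vbox > 0)
  kMSM * Vbox * .A3_to_Lmol
}
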