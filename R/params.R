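#' Model parameters for the chiral-dumbbell system
#'
#' Returns the full parameter set of the coarse-grained dumbbell model: the
#' harmonic bond, the three Lennard-Jones/WCA terms, the three 2-D Gaussian
#' terms (wall, channel, tilt) acting on the pair coordinates
#' \eqn{(r_{COM}, q)}, and the integrator settings. Defaults are the model's
#' reference parameterisation.
#'
#' The Gaussian centres `r0_w`, `r0_c`, `r0_t`, their widths `sr_*` and the
#' COM-COM Lennard-Jones minimum `r_lj_cm` are COM separations in Angstrom:
#' the locked state sits at 1.4 A COM separation (where the four unlike
#' atom pairs of a perpendicular dumbbell pair sit exactly at the 2.0 A
#' atom-LJ minimum), the docked state near 1.7 A, and the wall ridge near
#' 2.2 A.
#'
#' @param ... named overrides of any default, e.g. `dumbbell_params(dt = 5e-14)`.
#' @return A named numeric vector of class `dl_params`.
#' @details
#' Energy parameters are in kBT, lengths in Angstrom. `D_atom` (Angstrom^2/s)
#' is the common diffusivity of every atom; its default is calibrated so that
#' the measured radial diffusivity of a dumbbell approaching a held-fixed
#' fibril end reproduces the model's reference value of
#' \eqn{D_{rr} = 1.696\times 10^{10}} A^2/s (see the methods vignette).
#' `dt` (seconds) keeps the Euler-Maruyama scheme well inside its stability
#' region for the stiffest force term (the bond:
#' \eqn{k_b D \beta \Delta t \approx 0.35}, where values above 2 diverge and
#' values near 2 inflate the sampled bond variance). `rcom_cutoff` (Angstrom)
#' truncates all pair interactions beyond that COM separation; `ecap` is a hard
#' cap on the total energy to keep the integrator finite on rare overlaps.
#' `gauss_all_pairs = 1` evaluates the Gaussian terms on every unlike
#' dumbbell pair; `0` restricts them to interface pairs (free-free, free vs
#' terminal fibril member, consecutive fibril members) as labelled by the
#' configuration's `role` field.
#' @examples
#' p <- dumbbell_params()
#' p[["et"]]     # tilt depth, kBT
#' @export
dumbbell_params <- function(...) {
  p <- c(
    kb = 1000, r0 = 2.0,
    eps_lj = 3.0, r_lj_m = 2.0,
    eps_lj_c = 5.0, r_lj_cm = 1.4,
    eps_wca = 15.0, r_wca_m = 2.8,
    ew = 6.0,   r0_w = 2.2, sr_w = 0.4, q0_w = -1.0, sq_w = 1.2,
    ec = -8.0,  r0_c = 1.7, sr_c = 1.0, q0_c = 0.65, sq_c = 0.6,
    et = -35.0, r0_t = 1.4, sr_t = 0.4, q0_t = -1.0, sq_t = 0.6,
    beta = 1.0, D_atom = 3.47e10, dt = 1e-14,
    rcom_cutoff = 6.0, ecap = 1e6, gauss_all_pairs = 1
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- unlist(over)
  }
  validate_params(p)
  class(p) <- c("dl_params", "numeric")
  p
}

validate_params <- function(p) {
  lengths_pos <- c("r0", "r_lj_m", "r_lj_cm", "r_wca_m", "sr_w", "sr_c",
                   "sr_t", "sq_w", "sq_c", "sq_t")
  if (any(p[lengths_pos] <= 0))
    stop("all length scales and Gaussian widths must be > 0")
  for (nm in c("kb", "beta", "D_atom", "dt", "rcom_cutoff", "ecap"))
    if (p[[nm]] <= 0) stop(nm, " must be > 0")
  invisible(p)
}

#' @export
print.dl_params <- function(x, ...) {
  cat("<dl_params> chiral-dumbbell model parameters\n")
  print(unclass(x))
  invisible(x)
}

#' Write / read a model configuration file
#'
#' Plain-text `key=value` files carrying every model parameter plus optional
#' `box` and `seed` entries.
#'
#' @param params a [dumbbell_params()] vector.
#' @param file path.
#' @param box,seed optional extras recorded alongside the parameters.
#' @return `read_model_config()` returns a list with elements `params`,
#'   `box`, `seed`.
#' @export
write_model_config <- function(params, file, box = NULL, seed = NULL) {
  lines <- sprintf("%s=%.17g", names(params), as.numeric(params))
  if (!is.null(box)) lines <- c(lines, sprintf("box=%.17g", box))
  if (!is.null(seed)) lines <- c(lines, sprintf("seed=%d", as.integer(seed)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  names(vals) <- keys
  box <- if ("box" %in% keys) vals[["box"]] else NULL
  seed <- if ("seed" %in% keys) as.integer(vals[["seed"]]) else NULL
  pv <- vals[setdiff(keys, c("box", "seed"))]
  list(params = dumbbell_params(as.list(pv)), box = box, seed = seed)
}
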