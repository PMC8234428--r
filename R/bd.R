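#' Overdamped Brownian-dynamics propagation
#'
#' Advances every mobile particle by one Euler-Maruyama step,
#' \deqn{x(t + \Delta t) = x(t) - D \beta \frac{\partial U}{\partial x}
#'   \Delta t + \sqrt{2 D \Delta t}\, \xi,}
#' with a single diffusivity `D_atom` for all atoms and independent standard
#' Gaussian noise \eqn{\xi} per coordinate. Randomness is drawn from R's
#' global generator, so `set.seed()` gives bit-identical trajectories for an
#' identical call sequence.
#'
#' @param config a [configuration()].
#' @param params model parameters; a warning is issued if the per-step RMS
#'   displacement \eqn{\sqrt{2 D \Delta t}} exceeds `0.2 * r0`.
#' @param n_steps number of steps.
#' @param noise_scale set to 0 to disable the stochastic term (deterministic
#'   drift, used for testing).
#' @return `bd_step()` returns the advanced `dl_config`. `bd_run()` returns a
#'   list with `config`, `steps`, `reason` (`"predicate"`, `"max_steps"`) and,
#'   when a pair is tracked, a `traj` matrix of `(time_s, rcom, q)`.
#' @export
bd_step <- function(config, params, n_steps = 1L, noise_scale = 1) {
  check_step_size(params)
  out <- cpp_bd_run(config$pos, config$species, config$mobile, config$role,
                    box_or_zero(config), params, as.integer(n_steps),
                    noise_scale)
  config$pos <- out$pos
  config
}

check_step_size <- function(params) {
  rms <- sqrt(2 * params[["D_atom"]] * params[["dt"]])
  if (rms >= 0.2 * params[["r0"]])
    warning(sprintf(
      "per-step RMS displacement %.3g A exceeds 0.2 * r0; reduce dt", rms))
  invisible(rms)
}

#' @rdname bd_step
#' @param stop_predicate optional function of a `dl_config` returning `TRUE`
#'   to stop; evaluated every `check_every` steps (and once before the first
#'   step, so an always-true predicate takes zero steps).
#' @param max_steps step budget; exhausting it is a reported outcome
#'   (`reason = "max_steps"`), not an error.
#' @param check_every predicate evaluation interval (steps).
#' @param track optional `c(a, b)` dumbbell indices (A-species first) whose
#'   pair coordinates are recorded every `stride` steps.
#' @param stride recording stride for `track`.
#' @export
bd_run <- function(config, params, max_steps, stop_predicate = NULL,
                   check_every = 1L, track = NULL, stride = 0L,
                   noise_scale = 1) {
  check_step_size(params)
  steps <- 0L
  traj <- NULL
  if (!is.null(stop_predicate) && isTRUE(stop_predicate(config)))
    return(list(config = config, steps = 0L, reason = "predicate",
                traj = traj))
  ta <- if (is.null(track)) -1L else as.integer(track[1] - 1L)
  tb <- if (is.null(track)) -1L else as.integer(track[2] - 1L)
  while (steps < max_steps) {
    chunk <- as.integer(min(check_every, max_steps - steps))
    out <- cpp_bd_run(config$pos, config$species, config$mobile, config$role,
                      box_or_zero(config), params, chunk, noise_scale,
                      ta, tb, as.integer(stride))
    config$pos <- out$pos
    steps <- steps + chunk
    if (!is.null(track) && stride > 0) {
      t0 <- (steps - chunk) * params[["dt"]]
      out$traj[, "time_s"] <- out$traj[, "time_s"] + t0
      traj <- rbind(traj, out$traj)
    }
    if (!is.null(stop_predicate) && isTRUE(stop_predicate(config)))
      return(list(config = config, steps = steps, reason = "predicate",
                  traj = traj))
  }
  list(config = config, steps = steps, reason = "max_steps", traj = traj)
}
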