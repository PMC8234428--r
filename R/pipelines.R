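#' Bottom-up rate constants from rare-events calculations
#'
#' Runs the full molecular pipeline: NAM committor batch for the docking
#' rate, umbrella sampling + WHAM for the free energy surface, stationary
#' points and the docking equilibrium constant, saddle diffusion tensor, and
#' Langer's formula for the locking rate. Returns the assembled
#' [rate_constants()] plus every intermediate, with a run manifest.
#'
#' @param params model parameters.
#' @param seed master seed; each stochastic stage consumes its own derived
#'   child seed, so stages are individually reproducible.
#' @param nam a [nam_config()].
#' @param windows umbrella window table.
#' @param fibril_length fibril size of the umbrella/Langer system.
#' @param tensor_n ensemble size of the diffusion-tensor estimate.
#' @param dry_run return only the manifest, without computing.
#' @return List of class `dl_bottom_up`: `rates`, `nam`, `fes`, `stat`,
#'   `kd`, `tensor`, `kL`, `manifest`.
#' @export
bottom_up <- function(params = dumbbell_params(), seed = 1,
                      nam = nam_config(),
                      windows = umbrella_windows(),
                      fibril_length = 6, tensor_n = 5000,
                      dry_run = FALSE) {
  manifest <- run_manifest("bottom_up", seed, params,
                           list(nam = unclass(nam),
                                n_windows = nrow(windows),
                                fibril_length = fibril_length,
                                tensor_n = tensor_n))
  if (dry_run)
    return(structure(list(manifest = manifest), class = "dl_bottom_up"))

  set.seed(child_seed(seed, 1))
  nam_res <- nam_docking(params, nam)

  set.seed(child_seed(seed, 2))
  umb <- run_umbrella(params, windows, fibril_length = fibril_length)
  fes <- wham_2d(umb)
  stat <- locate_stationary_points(fes, params)
  kd <- docking_equilibrium_constant(fes, stat, params)

  set.seed(child_seed(seed, 3))
  tensor <- estimate_diffusion_tensor(params, stat$saddle,
                                      n_traj = tensor_n,
                                      fibril_length = fibril_length)
  kL <- langer_rate(stat$A0, stat$A, stat$barrier, tensor$D,
                    beta = params[["beta"]])
  rates <- rate_constants(kD = nam_res$kD, kL = as.numeric(kL), KD = kd$KD)
  structure(list(rates = rates, nam = nam_res, fes = fes, stat = stat,
                 kd = kd, tensor = tensor, kL = as.numeric(kL),
                 manifest = manifest),
            class = "dl_bottom_up")
}

#' @export
print.dl_bottom_up <- function(x, ...) {
  cat("<dl_bottom_up>\n")
  if (!is.null(x$rates)) {
    print(x$rates)
    cat(sprintf("  barrier %.2f kBT, Drr %.3g A^2/s, Dqq %.3g /s\n",
                x$stat$barrier, x$tensor$Drr, x$tensor$Dqq))
  } else cat("  (dry run: manifest only)\n")
  invisible(x)
}

#' Top-down rate constants from growth simulations + MLE
#'
#' Runs seeded growth boxes over a grid of monomer concentrations, resamples
#' the traces on a regular clock, and extracts (kL, K) by maximum
#' likelihood.
#'
#' @param params model parameters.
#' @param seed master seed.
#' @param n_free_grid free-dumbbell counts (per species) defining the
#'   concentration grid.
#' @param n_boxes replicate boxes per concentration.
#' @param t_total simulated time per box (seconds).
#' @param n_intervals resampling intervals per trace.
#' @param cfg base [growth_sim_config()]; `n_free`, `n_boxes`, `t_total`
#'   are overridden per grid point.
#' @param dry_run return only the manifest.
#' @return List of class `dl_top_down`: `mle`, `traces`, `manifest`.
#' @export
top_down <- function(params = dumbbell_params(), seed = 1,
                     n_free_grid = c(2, 4, 8, 16, 28), n_boxes = 2,
                     t_total = 4e-8, n_intervals = 12,
                     cfg = growth_sim_config(box = 45), dry_run = FALSE) {
  manifest <- run_manifest("top_down", seed, params,
                           list(n_free_grid = n_free_grid,
                                n_boxes = n_boxes, t_total = t_total))
  if (dry_run)
    return(structure(list(manifest = manifest), class = "dl_top_down"))
  all_traces <- list()
  for (i in seq_along(n_free_grid)) {
    set.seed(child_seed(seed, 10 + i))
    cfg_i <- cfg
    cfg_i$n_free <- as.integer(n_free_grid[i])
    cfg_i$n_boxes <- as.integer(n_boxes)
    cfg_i$t_total <- t_total
    all_traces[[i]] <- growth_sim(params, cfg_i,
                                  replicate_offset = (i - 1L) * n_boxes)
  }
  traces <- do.call(rbind, all_traces)
  class(traces) <- c("dl_traces", "data.frame")
  obs <- resample_traces(traces, n_intervals = n_intervals)
  mle <- fit_growth_mle(obs)
  structure(list(mle = mle, traces = traces, obs = obs,
                 manifest = manifest),
            class = "dl_top_down")
}

#' @export
print.dl_top_down <- function(x, ...) {
  cat("<dl_top_down>\n")
  if (!is.null(x$mle)) print(x$mle) else cat("  (dry run: manifest only)\n")
  invisible(x)
}

child_seed <- function(seed, stage) {
  ((as.integer(seed) %% 1000003L) * 1009L + as.integer(stage) * 9973L) %%
    2147483647L
}

run_manifest <- function(workflow, seed, params, extra) {
  list(workflow = workflow, seed = seed,
       child_seeds = vapply(1:20, function(s) child_seed(seed, s), 0L),
       params = as.list(unclass(params)), extra = extra,
       package_version = as.character(utils::packageVersion("docklock")),
       timestamp = format(Sys.time(), tz = "UTC"))
}
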