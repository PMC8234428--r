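#' Settings for seeded fibril-growth simulations
#'
#' @param box periodic box edge (Angstrom).
#' @param L0 seed fibril length (dumbbells).
#' @param n_free free dumbbells of EACH species held in the box; the
#'   dockable-species monomer concentration is
#'   `n_free / (N_A box^3)` mol/L at all times.
#' @param n_boxes replicate boxes.
#' @param t_total simulated time per box (seconds).
#' @param lock_rcom,lock_q lock-event criterion on the pair coordinates with
#'   the active fibril terminal.
#' @param persistence consecutive steps the criterion must hold (filters
#'   barrier recrossings).
#' @param dimer_rcom free-free unlike pairs with COM separation (Angstrom)
#'   below this are separated at every check.
#' @param check_interval steps between anti-nucleation checks.
#' @param min_insert_dist minimum particle distance for random insertions,
#'   default `1.2 * r_wca_m`.
#' @param max_events cap on growth events per box.
#' @return List of class `dl_growth_config`.
#' @export
growth_sim_config <- function(box = 60, L0 = 6, n_free = 10, n_boxes = 1,
                              t_total = 5e-8, lock_rcom = 1.55,
                              lock_q = -0.8, persistence = 100,
                              dimer_rcom = 4.0, check_interval = 1000,
                              min_insert_dist = NULL, max_events = 4000) {
  structure(list(box = box, L0 = as.integer(L0), n_free = as.integer(n_free),
                 n_boxes = as.integer(n_boxes), t_total = t_total,
                 lock_rcom = lock_rcom, lock_q = lock_q,
                 persistence = as.integer(persistence),
                 dimer_rcom = dimer_rcom,
                 check_interval = as.integer(check_interval),
                 min_insert_dist = min_insert_dist,
                 max_events = as.integer(max_events)),
            class = "dl_growth_config")
}

#' Monomer concentration of a growth box
#' @param n_free dockable dumbbells in the box.
#' @param box box edge (Angstrom).
#' @return mol/L.
#' @export
box_concentration <- function(n_free, box) {
  n_free / (.avogadro * box^3 * 1e-27)   # box^3 A^3 -> litres
}

#' Brute-force seeded fibril growth at fixed concentration
#'
#' Runs `n_boxes` independent periodic boxes, each holding a frozen seed
#' fibril (built in its locked geometry, centred in the box) and `n_free`
#' free dumbbells of each species. Growth events fire when a free dumbbell
#' of the species opposite the active terminal satisfies the lock criterion
#' for `persistence` consecutive steps; the dumbbell is annexed (frozen) and
#' a fresh one inserted at random, so the concentration never drifts.
#' Nucleation in solution is suppressed by periodically separating free
#' unlike dimers; free dumbbells occupying the passive fibril end are
#' likewise relocated.
#'
#' @param params model parameters.
#' @param cfg a [growth_sim_config()].
#' @param replicate_offset integer added to replicate ids (for combining
#'   batches at several concentrations).
#' @return data.frame of class `dl_traces` with columns `time_s`,
#'   `length_monomers`, `replicate_id`, `conc_molar`; one row per growth
#'   event plus the start and end of each box. Bookkeeping logs are attached
#'   as the attribute `"logs"`.
#' @export
growth_sim <- function(params, cfg = growth_sim_config(),
                       replicate_offset = 0L) {
  n_steps <- ceiling(cfg$t_total / params[["dt"]])
  conc <- box_concentration(cfg$n_free, cfg$box)
  mid <- cfg$min_insert_dist %||% (1.2 * params[["r_wca_m"]])
  out <- vector("list", cfg$n_boxes)
  logs <- vector("list", cfg$n_boxes)
  for (b in seq_len(cfg$n_boxes)) {
    fib <- build_fibril(cfg$L0, params,
                        origin = c(cfg$box / 2, cfg$box / 2,
                                   cfg$box / 2 - cfg$L0 / 2 * params[["r0_t"]]))
    res <- cpp_growth_box(fib$pos, fib$species, params, cfg$box, cfg$n_free,
                          n_steps, cfg$lock_rcom, cfg$lock_q,
                          cfg$persistence, cfg$dimer_rcom,
                          params[["r0_c"]],
                          cfg$check_interval, cfg$max_events, mid)
    ev <- res$event_times
    id <- b + replicate_offset
    out[[b]] <- data.frame(
      time_s = c(0, ev, cfg$t_total),
      length_monomers = c(cfg$L0, cfg$L0 + seq_along(ev),
                          cfg$L0 + length(ev)),
      replicate_id = id, conc_molar = conc)
    logs[[b]] <- list(replicate_id = id, n_events = res$n_events,
                      dimer_splits = res$dimer_splits,
                      evictions = res$evictions,
                      free_a = res$free_a, free_b = res$free_b,
                      final_length = res$final_length)
  }
  traces <- do.call(rbind, out)
  class(traces) <- c("dl_traces", "data.frame")
  attr(traces, "logs") <- logs
  traces
}

#' Resample growth traces on a regular time grid
#'
#' Converts event-resolution traces to fixed-interval observations (the
#' increment representation used by the likelihood).
#'
#' @param traces a `dl_traces` / data.frame with the standard columns.
#' @param n_intervals intervals per replicate.
#' @return data.frame with the same columns.
#' @export
resample_traces <- function(traces, n_intervals = 20) {
  parts <- split(traces, traces$replicate_id)
  out <- lapply(parts, function(tr) {
    tt <- seq(min(tr$time_s), max(tr$time_s), length.out = n_intervals + 1)
    LL <- vapply(tt, function(t0) max(tr$length_monomers[tr$time_s <= t0]), 0)
    data.frame(time_s = tt, length_monomers = LL,
               replicate_id = tr$replicate_id[1],
               conc_molar = tr$conc_molar[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read growth traces as CSV
#' @param traces a `dl_traces` data.frame.
#' @param file path.
#' @export
write_traces_csv <- function(traces, file) {
  write.table(traces, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(file) {
  df <- read.table(file, sep = ",", header = TRUE)
  need <- c("time_s", "length_monomers", "replicate_id", "conc_molar")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  class(df) <- c("dl_traces", "data.frame")
  df
}
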