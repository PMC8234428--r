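#' Umbrella-window layout
#'
#' Regular grid of harmonic bias centres over \eqn{(r_{COM}, q)} between a
#' free dumbbell and the terminal dumbbell of a preformed fibril. The default
#' covers the docked and locked basins, the wall ridge, and extends far
#' enough in \eqn{r_{COM}} that the outermost windows sample the
#' non-interacting (unbound) region needed to reference the docking
#' equilibrium constant.
#'
#' @param r_range,n_r range and count of rcom centres (Angstrom).
#' @param q_range,n_q range and count of q centres.
#' @param kr,kq bias strengths (kBT per squared coordinate unit).
#' @param n_steps,n_equil production / equilibration steps per window.
#' @param stride sampling stride (steps).
#' @return data.frame with one row per window.
#' @export
umbrella_windows <- function(r_range = c(1.1, 5.5), n_r = 33,
                             q_range = c(-1.05, 1.05), n_q = 12,
                             kr = 50, kq = 50, n_steps = 2e5, n_equil = 2e4,
                             stride = 10) {
  stopifnot(kr > 0, kq > 0)
  g <- expand.grid(c_r = seq(r_range[1], r_range[2], length.out = n_r),
                   c_q = seq(q_range[1], q_range[2], length.out = n_q))
  g$kr <- kr; g$kq <- kq
  g$n_steps <- n_steps; g$n_equil <- n_equil; g$stride <- stride
  g
}

#' Default histogram grid for the free energy surface
#' @param r_lim,q_lim grid limits in (rcom, q).
#' @param dr,dq bin widths (rcom in Angstrom).
#' @return list with `r_edges`, `q_edges` and bin centres.
#' @export
fes_grid <- function(r_lim = c(1.0, 5.6), q_lim = c(-1.1, 1.1),
                     dr = 0.05, dq = 0.05) {
  r_edges <- seq(r_lim[1], r_lim[2], by = dr)
  q_edges <- seq(q_lim[1], q_lim[2], by = dq)
  list(r_edges = r_edges, q_edges = q_edges,
       r_mid = r_edges[-1] - dr / 2, q_mid = q_edges[-1] - dq / 2)
}

#' Run umbrella sampling against a preformed fibril
#'
#' Propagates one biased Brownian trajectory per window (fibril of
#' `fibril_length` dumbbells held fixed, terminal dumbbell at the origin) and
#' histograms the sampled \eqn{(r_{COM}, q)} pairs on a common grid. The
#' pair-interaction cutoff is raised to 8 Angstrom here so that no
#' truncation step falls inside the sampled range.
#'
#' @param params model parameters.
#' @param windows a [umbrella_windows()] data.frame.
#' @param fibril_length fibril size (default 6).
#' @param grid a [fes_grid()].
#' @param progress print progress every 50 windows.
#' @return List of class `dl_umbrella`: `counts` (array nr x nq x nwin),
#'   `windows`, `grid`, `n_samples`, window means/SDs.
#' @export
run_umbrella <- function(params, windows = umbrella_windows(),
                         fibril_length = 6, grid = fes_grid(),
                         progress = FALSE) {
  params <- dumbbell_params(modifyList(as.list(unclass(params)),
                                       list(rcom_cutoff = 8)))
  fib <- build_fibril(fibril_length, params)
  nw <- nrow(windows)
  nr <- length(grid$r_edges) - 1L
  nq <- length(grid$q_edges) - 1L
  counts <- array(0, c(nr, nq, nw))
  meta <- matrix(0, nw, 5,
                 dimnames = list(NULL, c("n", "mean_r", "mean_q", "sd_r", "sd_q")))
  for (w in seq_len(nw)) {
    res <- cpp_umbrella_window(fib$pos, fib$species, params,
                               windows$c_r[w], windows$c_q[w],
                               windows$kr[w], windows$kq[w],
                               as.integer(windows$n_equil[w]),
                               as.integer(windows$n_steps[w]),
                               as.integer(windows$stride[w]),
                               grid$r_edges, grid$q_edges)
    if (res$n_samples == 0 || sum(res$counts) == 0)
      stop(sprintf("window %d at (%.2f, %.2f) produced no samples", w,
                   windows$c_r[w], windows$c_q[w]))
    counts[, , w] <- res$counts
    meta[w, ] <- c(res$n_samples, res$mean_r, res$mean_q, res$sd_r, res$sd_q)
    if (progress && w %% 50 == 0)
      message(sprintf("umbrella window %d / %d", w, nw))
  }
  check_window_overlap(counts, windows)
  structure(list(counts = counts, windows = windows, grid = grid,
                 meta = meta, params = params,
                 fibril_length = fibril_length),
            class = "dl_umbrella")
}

# Warn (naming the gap) when neighbouring windows share < 10% of histogram mass.
check_window_overlap <- function(counts, windows) {
  nw <- dim(counts)[3]
  cr <- windows$c_r; cq <- windows$c_q
  ur <- sort(unique(cr)); uq <- sort(unique(cq))
  gaps <- character(0)
  hist_overlap <- function(i, j) {
    a <- counts[, , i]; b <- counts[, , j]
    sum(pmin(a / sum(a), b / sum(b)))
  }
  for (i in seq_len(nw)) {
    ri <- match(cr[i], ur); qi <- match(cq[i], uq)
    if (ri < length(ur)) {
      j <- which(cr == ur[ri + 1] & cq == cq[i])[1]
      if (!is.na(j) && hist_overlap(i, j) < 0.10)
        gaps <- c(gaps, sprintf("(%.2f,%.2f)-(%.2f,%.2f)",
                                cr[i], cq[i], cr[j], cq[j]))
    }
    if (qi < length(uq)) {
      j <- which(cq == uq[qi + 1] & cr == cr[i])[1]
      if (!is.na(j) && hist_overlap(i, j) < 0.10)
        gaps <- c(gaps, sprintf("(%.2f,%.2f)-(%.2f,%.2f)",
                                cr[i], cq[i], cr[j], cq[j]))
    }
  }
  if (length(gaps))
    warning("low histogram overlap between umbrella windows: ",
            paste(head(gaps, 8), collapse = ", "),
            if (length(gaps) > 8) sprintf(" (+%d more)", length(gaps) - 8))
  invisible(length(gaps))
}

#' Weighted-histogram analysis of umbrella windows
#'
#' Standard self-consistent WHAM on the 2-D grid: window free-energy offsets
#' f_w and unbiased bin probabilities are iterated until the largest change
#' in any `log f_w` falls below `tolerance`. The result is returned as a
#' free energy surface in kBT, shifted so its minimum is zero; bins never
#' visited by any window are `NA` and flagged, never interpolated.
#'
#' @param umb a `dl_umbrella` object (or a compatible list with `counts`,
#'   `windows`, `grid`).
#' @param tolerance convergence threshold on the window offsets (kBT).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param beta inverse temperature.
#' @return Object of class `dl_fes`: `F` (nr x nq, kBT, min 0), `prob`
#'   (unbiased bin probabilities), `counts` (total samples per bin), grid
#'   edges and centres, `beta`, `f_w` offsets.
#' @export
wham_2d <- function(umb, tolerance = 1e-7, max_iter = 50000, beta = 1) {
  counts <- umb$counts
  grid <- umb$grid
  windows <- umb$windows
  nr <- dim(counts)[1]; nq <- dim(counts)[2]; nw <- dim(counts)[3]
  H <- matrix(rowSums(matrix(counts, nr * nq, nw), na.rm = TRUE), nr, nq)
  h <- as.vector(H)
  N_w <- colSums(matrix(counts, nr * nq, nw))
  # bias Boltzmann factors at bin centres: B x W
  rq <- expand.grid(r = grid$r_mid, q = grid$q_mid)
  Cmat <- exp(-beta * (outer(rq$r, windows$c_r, "-")^2 *
                         rep(windows$kr / 2, each = nr * nq) +
                       outer(rq$q, windows$c_q, "-")^2 *
                         rep(windows$kq / 2, each = nr * nq)))
  g <- rep(0, nw)                      # log f_w
  seen <- h > 0
  p <- h / sum(h)
  for (it in seq_len(max_iter)) {
    denom <- as.vector(Cmat %*% (N_w * exp(g)))
    p <- ifelse(seen & denom > 0, h / denom, 0)
    p <- p / sum(p)
    z <- as.vector(crossprod(Cmat, p))   # sum_b c_wb p_b
    g_new <- -log(z)
    g_new <- g_new - g_new[1]
    delta <- max(abs(g_new - g))
    g <- g_new
    if (delta < tolerance) break
  }
  if (delta >= tolerance)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                 max_iter, delta))
  P <- matrix(p, nr, nq)
  F <- -log(P) / beta
  F[!seen] <- NA
  F <- F - min(F, na.rm = TRUE)
  structure(list(F = F, prob = P, counts = H,
                 r_edges = grid$r_edges, q_edges = grid$q_edges,
                 r_mid = grid$r_mid, q_mid = grid$q_mid,
                 beta = beta, f_w = g, iterations = it,
                 empty_bins = sum(!seen)),
            class = "dl_fes")
}

#' @export
print.dl_fes <- function(x, ...) {
  cat(sprintf("<dl_fes> %d x %d bins, rcom [%g, %g], q [%g, %g]\n",
              length(x$r_mid), length(x$q_mid), min(x$r_edges),
              max(x$r_edges), min(x$q_edges), max(x$q_edges)))
  cat(sprintf("  %d empty bins; max F %.2f kBT\n", x$empty_bins,
              max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Contour plot of a free energy surface
#' @param x a `dl_fes`.
#' @param levels contour levels (kBT).
#' @param ... passed to [graphics::contour()].
#' @export
plot.dl_fes <- function(x, levels = seq(0, 20, by = 1), ...) {
  graphics::filled.contour(
    x$r_mid, x$q_mid, pmin(x$F, max(levels)), levels = levels,
    color.palette = grDevices::hcl.colors,
    xlab = "rCOM (Angstrom)", ylab = "q",
    main = "Free energy surface (kBT)", ...)
  invisible(x)
}

#' Export a free energy surface as CSV
#' @param fes a `dl_fes`.
#' @param file path.
#' @export
write_fes_csv <- function(fes, file) {
  df <- expand.grid(rcom = fes$r_mid, q = fes$q_mid)
  df$F_kBT <- as.vector(fes$F)
  df$counts <- as.vector(fes$counts)
  write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
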