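#' Particle configurations of dumbbell systems
#'
#' A configuration holds the Cartesian positions of all particles, grouped in
#' consecutive pairs into dumbbells. Two dumbbell species exist: species A
#' carries particle types (1, 2) and species B types (3, 4); only unlike
#' species attract. Rows `2d - 1` and `2d` of `pos` are the two bonded atoms
#' of dumbbell `d`, stored in bond order (type 1 then 2, or 3 then 4).
#'
#' @param pos numeric matrix (2 * n_dumbbells) x 3 of positions (Angstrom).
#' @param species integer vector per dumbbell: 1 = A (types 1-2), 2 = B
#'   (types 3-4).
#' @param mobile logical/integer per dumbbell; immobile dumbbells are held
#'   fixed by the integrator.
#' @param box box edge length (Angstrom) for periodic boundaries, or `NULL`
#'   for an open boundary.
#' @param role per-dumbbell fibril-chain label: `-1` for a free dumbbell,
#'   otherwise the position along the fibril. The wall/channel/tilt Gaussian
#'   terms act only on interface pairs: free-free, free vs a terminal fibril
#'   member, and consecutive fibril members (see the methods vignette).
#' @return An object of class `dl_config`.
#' @export
configuration <- function(pos, species, mobile = rep(TRUE, length(species)),
                          box = NULL, role = rep(-1L, length(species))) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  species <- as.integer(species)
  if (ncol(pos) != 3L) stop("pos must have 3 columns")
  if (nrow(pos) != 2L * length(species))
    stop("each dumbbell must have exactly 2 particles")
  if (!all(species %in% c(1L, 2L))) stop("species must be 1 (A) or 2 (B)")
  if (!is.null(box) && box <= 0) stop("box must be positive or NULL")
  if (length(role) != length(species)) stop("role must match species length")
  structure(list(pos = pos, species = species,
                 mobile = as.integer(as.logical(mobile)),
                 box = box, role = as.integer(role)),
            class = "dl_config")
}

#' @export
print.dl_config <- function(x, ...) {
  cat(sprintf("<dl_config> %d dumbbells (%d A, %d B), %s boundary\n",
              length(x$species), sum(x$species == 1L), sum(x$species == 2L),
              if (is.null(x$box)) "open" else sprintf("periodic box %g A", x$box)))
  invisible(x)
}

n_dumbbells <- function(config) length(config$species)

particle_types <- function(config) {
  t1 <- ifelse(config$species == 1L, 1L, 3L)
  as.integer(rbind(t1, t1 + 1L))
}

box_or_zero <- function(config) if (is.null(config$box)) 0.0 else config$box

#' Build a fibril in its locked geometry
#'
#' Stacks `n` dumbbells of alternating species along the z axis at the
#' locked-state spacing (`r0_t` Angstrom between neighbouring COMs) with
#' bond directions rotating by -90 degrees per layer, which makes the
#' chirality coordinate of every neighbouring unlike pair equal to -1 (the
#' locked enantiomer). The COM of the first dumbbell sits at `origin`.
#'
#' @param n fibril length (number of dumbbells).
#' @param params model parameters.
#' @param origin 3-vector, COM of the terminal (first) dumbbell.
#' @param mobile logical per dumbbell (default all fixed, the convention used
#'   by the rate-constant calculations).
#' @param box optional periodic box.
#' @return A `dl_config`.
#' @examples
#' fib <- build_fibril(4, dumbbell_params())
#' pair_coordinates(fib$pos[1:2, ], fib$pos[3:4, ], r0 = 2)  # rcom 1.4 A, q -1
#' @export
build_fibril <- function(n, params, origin = c(0, 0, 0),
                         mobile = rep(FALSE, n), box = NULL) {
  r0 <- params[["r0"]]
  dz <- params[["r0_t"]]
  dirs <- list(c(1, 0, 0), c(0, -1, 0), c(-1, 0, 0), c(0, 1, 0))
  pos <- matrix(0.0, 2 * n, 3)
  for (k in seq_len(n)) {
    com <- origin + c(0, 0, (k - 1) * dz)
    b <- r0 * unlist(dirs[[(k - 1) %% 4 + 1]])
    pos[2 * k - 1, ] <- com - b / 2
    pos[2 * k, ] <- com + b / 2
  }
  configuration(pos, species = rep_len(c(1L, 2L), n), mobile = mobile,
                box = box, role = seq_len(n) - 1L)
}

#' Pair reaction coordinates of two dumbbells
#'
#' Computes the COM separation \eqn{r_{COM} = |u|} (Angstrom) and the
#' chirality coordinate \eqn{q = u \cdot v / (r_0^2 |u|)}, where
#' \eqn{u = COM(a) - COM(b)} and \eqn{v = (x_4 - x_3) \times (x_2 - x_1)}.
#' Dumbbell `a` must be of species A (atoms are its type-1 and type-2
#' particles, in that row order) and `b` of species B (types 3 then 4). `q`
#' distinguishes the two enantiomeric stacking geometries; its magnitude is
#' bounded by the product of the instantaneous bond lengths over
#' \eqn{r_0^2}, so it lies in \eqn{[-1, 1]} for bonds at their equilibrium
#' length.
#'
#' @param a,b 2 x 3 position matrices of the two dumbbells.
#' @param r0 equilibrium bond length.
#' @param box optional periodic box edge (minimum image applied).
#' @return Named numeric vector `c(rcom, q)`.
#' @export
pair_coordinates <- function(a, b, r0, box = NULL) {
  cpp_pair_coordinates(as.matrix(a), as.matrix(b), r0,
                       if (is.null(box)) 0.0 else box)
}

#' Total potential energy
#'
#' Sum of the seven interaction terms: harmonic bonds, atom-atom LJ between
#' unlike species, COM-COM LJ between unlike dumbbells, WCA between
#' same-species dumbbells, and the wall/channel/tilt Gaussians on
#' \eqn{(r_{COM}, q)} of interface unlike pairs (free-free, free vs terminal
#' fibril member, consecutive fibril members) within the cutoff. With a
#' periodic box the minimum-image convention applies to every pair distance.
#' The value is capped at `ecap`; the cap is reported via the `"capped"`
#' attribute.
#'
#' @param config a [configuration()].
#' @param params model parameters.
#' @return Energy in kBT with attribute `capped`; see [potential_terms()] for
#'   the per-term breakdown.
#' @export
total_potential <- function(config, params) {
  e <- cpp_energy(config$pos, config$species, config$mobile, config$role,
                  box_or_zero(config), params, FALSE)
  structure(e$energy, capped = e$capped)
}

#' @rdname total_potential
#' @export
potential_terms <- function(config, params) {
  cpp_energy(config$pos, config$species, config$mobile, config$role,
             box_or_zero(config), params, FALSE)$terms
}

#' Analytic forces
#'
#' Minus the gradient of [total_potential()] for every particle, including
#' the chain rule of the Gaussian terms through \eqn{r_{COM}} and \eqn{q}.
#'
#' @inheritParams total_potential
#' @return (2 * n_dumbbells) x 3 matrix of forces (kBT / Angstrom).
#' @export
forces <- function(config, params) {
  cpp_forces(config$pos, config$species, config$mobile, config$role,
             box_or_zero(config), params, FALSE)
}

#' Export a configuration as an XYZ frame
#'
#' One frame in plain XYZ format (readable by VMD and friends); particle
#' types 1-4 are mapped to the element labels C, N, O, S.
#'
#' @param config a [configuration()].
#' @param file path.
#' @param append append as an additional frame.
#' @param comment comment line of the frame.
#' @export
write_xyz <- function(config, file, append = FALSE, comment = "docklock frame") {
  el <- c("C", "N", "O", "S")[particle_types(config)]
  lines <- c(sprintf("%d", nrow(config$pos)), comment,
             sprintf("%s %.6f %.6f %.6f", el,
                     config$pos[, 1], config$pos[, 2], config$pos[, 3]))
  con <- file(file, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}
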