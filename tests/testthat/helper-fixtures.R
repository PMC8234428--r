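# Small configurations used across test files. Everything is built in code;
# no stored fixtures.

params_default <- function(...) dumbbell_params(...)

# an isolated dumbbell of species `sp` with bond exactly r0 along `dir`
single_dumbbell <- function(sp = 1L, com = c(0, 0, 0), dir = c(1, 0, 0),
                            r0 = 2, mobile = TRUE) {
  dir <- dir / sqrt(sum(dir^2))
  configuration(rbind(com - r0 * dir / 2, com + r0 * dir / 2),
                species = sp, mobile = mobile)
}

# unlike pair placed at prescribed pair coordinates (rcom in Angstrom, q):
# A along x at origin, B at distance rcom along -z with bond
# (sqrt(1-q^2), -q, 0), which gives chirality exactly q for ideal bonds
pair_at <- function(rcom, q, r0 = 2, mobile = c(FALSE, TRUE)) {
  qc <- max(-1, min(1, q))
  bhat <- c(sqrt(1 - qc^2), -qc, 0)
  a <- rbind(c(-r0 / 2, 0, 0), c(r0 / 2, 0, 0))
  b <- rbind(c(0, 0, -rcom) - r0 * bhat / 2, c(0, 0, -rcom) + r0 * bhat / 2)
  configuration(rbind(a, b), species = c(1L, 2L), mobile = mobile)
}

# random non-degenerate multi-dumbbell configuration
random_config <- function(n = 3, spread = 4, seed = NULL, box = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(0, 2 * n, 3)
  for (d in seq_len(n)) {
    com <- runif(3, 1, spread + 1)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    len <- 2 + rnorm(1, 0, 0.05)
    pos[2 * d - 1, ] <- com - len * dir / 2
    pos[2 * d, ] <- com + len * dir / 2
  }
  configuration(pos, species = rep_len(c(1L, 2L), n), box = box)
}
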