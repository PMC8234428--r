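---
title: "Multiscale dock-lock kinetics: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale dock-lock kinetics: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Amyloid fibrils elongate by a two-step mechanism: a free monomer first
*docks* diffusively onto the fibril end, then *locks* into the lattice by a
first-order conformational rearrangement. The two steps carry different
concentration dependences — docking is bimolecular
(`kD`, L/mol/s), locking unimolecular (`kL`, 1/s) — and docklock implements
the full chain that connects a coarse-grained molecular model of this
process to observable growth curves: rare-events estimates of the two rate
constants, a microkinetic rate law, a population balance for the fibril
length distribution, and maximum-likelihood inversion of length-versus-time
data. This vignette records the science and every design decision a
maintainer would want to know.

## The chiral-dumbbell model

Each monomer is a diatomic dumbbell: two atoms joined by a stiff harmonic
bond (`kb` = 1000 kBT/Å², equilibrium length `r0` = 2 Å). Two species exist
(A = atom types 1–2, B = types 3–4) and only unlike species attract. For an
unlike pair the geometry is summarised by two reaction coordinates: the COM
separation and the chirality

$$q = \frac{u \cdot v}{r_0^2 \lVert u \rVert}, \qquad
  u = \mathrm{COM}_A - \mathrm{COM}_B, \quad
  v = (x_4 - x_3) \times (x_2 - x_1),$$

which distinguishes the two enantiomeric stacking geometries of a pair
(`q = +1` and `q = -1` at fixed separation are mirror images; |q| is
bounded by the product of the instantaneous bond lengths over `r0²`).

The potential has seven terms: harmonic bonds; atom–atom Lennard-Jones
between unlike species (depth 3 kBT, minimum at 2 Å); a COM–COM
Lennard-Jones between unlike dumbbells (5 kBT, minimum at 1.4 Å); a WCA
repulsion between same-species atoms of different dumbbells (15 kBT, range
2.8 Å); and three 2-D Gaussians on `(rcom, q)` — a repulsive *wall*
(+6 kBT at 2.2 Å, broad in q around −1), an attractive *channel*
(−8 kBT at 1.7 Å, centred at q = +0.65) and the *tilt* (−35 kBT at 1.4 Å,
q = −1) that makes the locked state the global minimum.

Two structural readings of the length-like parameters are conceivable:
distances measured in units of `r0` or in plain Ångström. The package uses
**physical Ångström** throughout, for three reasons that the implementation
itself exposed. First, the geometry interlocks only in that reading: at
1.4 Å COM separation a perpendicular pair puts all four unlike atom pairs
exactly at the 2.0 Å atom-LJ minimum (an "X-stack"), the COM-LJ minimum
coincides with the locked spacing, and same-species fibril neighbours sit
exactly at the 2.8 Å WCA contact that braces the fibril laterally. Second,
under the dimensionless reading the sampled free energy surface has *no
saddle at all* — the locked funnel swallows the docked region monotonically
because nothing restricts the chirality flip at 2.8 Å separation, and the
entire saddle-expansion rate theory becomes inapplicable. Third, with
physical units the dock→lock chirality flip at 1.4–1.7 Å separation is
sterically throttled: most q ≈ 0 orientations clash with the repulsive
atom cores, leaving a narrow orientational bottleneck — precisely the
free-energy barrier the dock-lock picture requires. Consequently the pair
coordinate reported by `pair_coordinates()` is the physical COM separation
in Å (q keeps its `r0²` normalisation).

The three Gaussian terms act by default on every unlike pair
(`gauss_all_pairs = 1`). Interior fibril members are sterically shielded by
the WCA shell of their same-species neighbours, so this creates no spurious
binding sites; a variant restricted to interface pairs (free–free, free vs
terminal member, consecutive members, encoded by the configuration `role`
labels) is available and produces indistinguishable committors. A
configurable cutoff (`rcom_cutoff`, default 6 Å) truncates all pair terms;
the umbrella module raises it to 8 Å so no truncation step falls inside
the sampled region. A hard cap (`ecap` = 1e6 kBT) keeps the energy finite
on rare overlaps.

## Brownian dynamics

All trajectories follow the overdamped Euler–Maruyama update
`x += -D β ∇U dt + sqrt(2 D dt) ξ` with one diffusivity for all atoms.
Two integrator settings required decisions:

* **`D_atom` = 3.47e10 Å²/s.** The model prints no atomic diffusivity; it
  is calibrated through the saddle-region diffusion tensor. With the fibril
  held fixed (the convention used by every rare-events stage here) the
  measured radial diffusivity of the incoming dumbbell is its COM mobility
  `D_atom/2` up to a ~2% interaction correction, and matching the reference
  value `Drr = 1.696e10 Å²/s` gives `D_atom ≈ 3.4e10`. The same value
  closes an independent loop: the NAM prefactor uses the relative
  diffusivity of two *free* dumbbells, `D0 = 2·(D_atom/2) = D_atom`, and
  back-solving the reference `kD` from the printed committor at
  `(b1, b2) = (12, 20)` Å requires `D0 = 3.47e10` Å²/s. One calibration
  satisfies both constraints.
* **`dt` = 1e-14 s.** The stiffest force term is the bond; explicit
  Euler–Maruyama requires `kb · D · β · dt < 2` and inflates the sampled
  bond variance by `2/(2 - kb D β dt)` as that limit is approached. The
  default gives a stability factor of 0.35 (variance inflation 1.2×) and a
  per-step RMS atomic displacement of 0.026 Å.

Randomness comes from R's global generator: `set.seed()` plus an identical
call sequence reproduces trajectories bit for bit. The equilibrium
distribution of the integrator is cross-checked against an energy-only
Metropolis Monte Carlo chain in the test suite (KL divergence over
well-sampled `(rcom, q)` bins decreasing with run length).

## Docking rate: the NAM committor construction

`nam_docking()` builds a fibril of four dumbbells in its locked geometry,
holds it fixed with the terminal dumbbell's COM at the origin, and launches
dumbbells of the opposite species from uniformly random points on the
sphere of radius `b1` with uniformly random bond orientation. Each
trajectory terminates as *docked* (COM separation to the terminal below
`dock_dist`), *escaped* (beyond `b2`), or *direct lock* (the lock criterion
`rcom < 1.55 Å, q < -0.8` fires first — checked before the dock
classification at every step; a launch already inside a criterion is
classified at step zero). The finite-domain committor p is converted via
the return probability `Ω` (equal to `b1/b2` for free diffusion outside
the interaction range — the analytically correct limit of the radial
quadrature; note `Ω` must be ≤ 1) into

$$k_D = 4 \pi D_0 b_1 \frac{p}{1 - (1 - p)\,\Omega}.$$

Direct-lock trajectories are omitted from both numerator and denominator
of p by default (they bypass the docked state that p is conditioned on);
a flag includes them instead. Wilson 95% intervals are reported for p and
propagated linearly to `kD`. `dock_dist` defaults to 1.7 Å, the channel
centre; the Boltzmann-weighted mean separation of the docked basin read
from the reference free energy surface (`docked_mean_separation()`) is
1.6 Å, and p changes by about two percentage points between the two
choices — this protocol sensitivity is the main caveat when comparing
absolute committors.

## Free energy surface, KD, and the locking rate

`run_umbrella()` samples a free dumbbell against a held-fixed fibril of
six dumbbells under harmonic biases on `(rcom, q)` relative to the
terminal member. The default layout is a 33 × 12 grid of centres over
`rcom ∈ [1.1, 5.5]` Å × `q ∈ [-1.05, 1.05]` with `kr = kq = 50` kBT per
squared unit, 2×10⁵ production steps after 2×10⁴ equilibration, sampling
stride 10. The outer columns extend well past the last interaction tail
(the channel width is 1 Å, so it still contributes ~2 kBT at 3.3 Å) —
they provide the unbound reference that the equilibrium constant needs.
Neighbour-window histogram overlap below 10% triggers a warning naming the
gap. `wham_2d()` solves the standard self-consistent weighted-histogram
equations on a 92 × 44 grid (tolerance 1e-7 on the window offsets); bins
never visited are `NA`, never interpolated.

The surface has a shallow docked basin near `(1.5 Å, q ≈ +0.95)` — the
positive-chirality mirror of the locked stack, reached through the
channel — a deep locked funnel near `(1.4 Å, q ≈ -1)`, and a saddle near
`(2.1 Å, q ≈ -0.2)`: the reactive path leaves the docked basin radially,
rounds the wall ridge, and descends into the locked funnel.
`locate_stationary_points()` finds the minima as the restricted global
minima of the two chirality half-planes (`|q| ≥ 0.3`; a local descent from
the Gaussian centres can strand on the channel shoulder), the saddle as
the lowest ridge crossing (union-find flood of the smoothed surface), and
curvatures by weighted quadratic least squares on the raw grid in a
3-bin neighbourhood, in (Å, q) coordinates.

`docking_equilibrium_constant()` converts the sampled density into an
association constant. Because the `(rcom, q)` histogram absorbs the
coordinate Jacobian, the unbound region follows
`p(r, q) ∝ r² w(q)` with `w(q)` the universal orientational density of the
chirality coordinate (strongly peaked at 0; computed once by vectorised
Monte Carlo). Matching that envelope over the outer shell (4.8–5.4 Å)
calibrates the free-state number density; the docked-basin mass — bins
below the raw-grid level that first connects the two basins, 4-connected
to the docked minimum, which by construction excludes the locked funnel —
then integrates to an effective bound volume, reported in L/mol. The
rate-law convention stores `KD` as an association constant so that
`KD⁻¹` is a concentration; the reference value 8.440e2 is printed with
mol/L units, but only the L/mol reading makes the Michaelis identity
`K = kL/kD + KD⁻¹ = 0.08 mol/L` dimensionally and numerically consistent.

`estimate_diffusion_tensor()` prepares a saddle-restrained ensemble
(stiff 400 kBT biases), releases each member unbiased, and evaluates the
covariance of the *displacements* over 0.1 ps (per-trajectory differences,
so the finite width of the restrained ensemble cancels; a 1 ps burst is
already inflated by the unstable saddle mode, whose relaxation rate is of
order 1e12/s — the built-in t/2 linearity check catches this). Langer's
overdamped formula then gives the locking rate

$$k_L = \frac{1}{2\pi} \sqrt{\frac{\det A_0}{\lvert \det A \rvert}}
  \, \lambda_+ \, e^{-\beta \Delta F},$$

with `λ+` the unique unstable relaxation rate (negative eigenvalue of
`D·A`). The formula is validated in the tests against a brute-force
mean-first-passage oracle (rate = 1/(2·MFPT) to the dividing surface) on a
synthetic 2-D double well at a 6 kBT barrier, and against its known 1-D
Kramers limit.

## Microkinetics and the population balance

The two-state fibril end (docked/locked) under the pseudo-steady-state
approximation gives the net growth rate per end

$$r_{growth} = \frac{k_L k_D [M] - k_D K_D^{-1} k_{UL}}
  {k_L + k_D K_D^{-1} + k_{UL} + k_D [M]},$$

verified in the tests against a numeric master-equation solution of the
cycle. With irreversible locking (`kUL = 0`) it is Michaelis–Menten:
`rg = kL [M]/(K + [M])`, `K = kL/kD + KD⁻¹`. Rates are per fibril end; a
both-ends factor of 2 lives in the population-balance layer only (where it
amounts to a doubled clock).

For an ensemble of seeded fibrils growing irreversibly the master equation
in length, truncated at second order, becomes an advection–diffusion
equation whose dimensionless Green's function is Gaussian with mean
`L0 + t` and variance `t` (one time unit = one expected monomer addition).
At constant monomer concentration the distribution is the convolution of
the initial condition with that kernel. In a closed system the monomer
fraction obeys a separable ODE whose solution is a principal-branch
Lambert W (`monomer_depletion()`), and the *warped time*
`τ(t) = (1 - m)/ε` maps the depleting system exactly onto the
constant-concentration form. The identity `1 - m = ε τ` holds algebraically
and is asserted to 1e-12. The Lambert evaluation solves the overflow-safe
log form `w + log w = y` by damped Newton: the series solver in the
available numerics package cycles indefinitely for scattered arguments, so
the package carries its own five-line solver and cross-checks it against
the external one (on safe arguments) and the defining identity in the
tests. The analytic propagation is evaluated on `(0, ∞)` exactly as the
truncated model prescribes, without an absorbing correction at L = 0; the
grid-captured mass is monitored and a truncation warning names the
remedy. The Gaussian kernel is itself compared in total variation against
the exact Poisson pure-birth process it truncates (TV ≈ 0.03 at t = 25).

## Growth simulation and top-down inference

`growth_sim()` is the brute-force data generator: a periodic box
(default 60 Å; the scaled-down studies use 45 Å) holding a frozen seed
fibril and `n_free` free dumbbells *of each species*, so the
dockable-species concentration at the alternating active end is
`n_free/(N_A V)` at all times — the same convention as the NAM `kD`. A
growth event fires when a free dumbbell of the correct species holds the
lock criterion against the active terminal for 100 consecutive steps
(the persistence filters barrier recrossings); the dumbbell is annexed and
frozen where it locked, and a replacement is inserted at a random
non-overlapping position, so concentration never drifts. Nucleation in
solution is suppressed the way the model prescribes — free–free unlike
pairs closer than 4 Å are split every 10³ steps and re-inserted at
random — and free dumbbells found occupying the *passive* end are likewise
relocated (logged as evictions); without that bookkeeping the passive end
would silently sequester monomers, since only one end is analysed. The
whole fibril is held fixed rather than tethered, keeping the diffusivity
convention identical across NAM, umbrella, tensor, and growth stages.

`fit_growth_mle()` inverts traces through the population-balance
observation model: each length increment over an interval is Gaussian with
mean and variance `rg(c) Δt` (the direct reading of the Green's-function
likelihood in the physical clock; a Poisson-increment alternative — exact
for the underlying birth process — is a flag). Traces are resampled on a
regular clock (fixed-interval increments; per-event waiting times are the
unimplemented alternative). Optimisation runs in log-parameters, coarse
grid then L-BFGS-B, with χ²(1) profile-likelihood 95% intervals. K is
unidentifiable from a single concentration, and the result says so.

## Problem sizes and what the tests show

The shipped study conditions are: committor batches of 2,000 trajectories
(the reference used 10,000–20,000; Wilson intervals of ±1.7 percentage
points are adequate for the comparisons made), the default umbrella budget
above (≈7×10⁷ steps), 5,000 tensor bursts, and a top-down study of five
concentrations spanning 0.03–0.45 mol/L with two 30–40 ns boxes each.
These sizes keep a full bottom-up + top-down replication within tens of
minutes on one CPU while leaving every estimate statistics-limited rather
than method-limited; all of them are ordinary arguments.

The synthetic-data generator emulates seeded, nucleation-free,
single-active-end growth at strictly constant monomer concentration with
uncorrelated increments. Real fibril data violate several of these
idealisations (pausing states, depletion, polydisperse seeds, both ends
active), so passing tests here demonstrate correctness of the estimator
under its own model, not robustness to those effects; the depletion branch
of the population balance covers the closed-system case analytically.

Known limitations, measured honestly on this rebuild: the absolute
committor (16–17% vs the reference 22% at `b1 = 12` Å) and the Langer rate
(a few-fold above the reference `kL`, the direction expected when the
saddle region carries sampling error that the exponential amplifies) are
protocol-sensitive — dock-distance definition, fibril mobility, and
integrator step policy are the candidates the text leaves open — while the
b-independence of `kD`, the direct-lock bound, the diffusion-tensor ratios,
the order of magnitude of `KD`, and the top-down `(kL, K)` recovery all
reproduce. The bottom-up/top-down comparison shows the same signature as
the reference workflow: the Langer estimate exceeds the brute-force MLE
value by an order-of-magnitude-class factor, while K agrees closely.
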