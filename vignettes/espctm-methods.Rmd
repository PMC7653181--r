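---
title: "Metastable states from energy-rescaled trajectory mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastable states from energy-rescaled trajectory mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Long simulations of complex systems — molecular dynamics of a peptide, or a
Brownian particle on a rugged landscape — spend most of their time
fluctuating rapidly inside a handful of long-lived regions of configuration
space, and only rarely hop between them.  The scientifically interesting
content is usually the *slow* part: which metastable states exist, how
heavily each is populated at equilibrium, and at what rates the system moves
between them.  `espctm` extracts exactly that: it turns a set of trajectories
of structural metrics (backbone dihedral angles, particle coordinates) plus a
recorded total potential energy into a kinetic transition network — a Markov
model over automatically discovered metastable states.

The key difficulty is that neither high-variance directions (plain PCA) nor
the raw energy identify slow degrees of freedom: the energy of every frame is
dominated by fast fluctuation, of the environment above all.  The central
idea implemented here is to *let the energy choose the coordinates*: the
slow, low-frequency component of the energy is isolated by Fourier
filtering, regressed onto a basis-function expansion of the structural
metrics, and the regression coefficients then re-weight (rescale) those basis
functions before dimensionality reduction.  Directions that explain the slow
energy get amplified; directions that only carry fast noise get suppressed —
with no hyper-parameter supplied by the user.

## The pipeline

Given trajectories $j = 1..M$, each with $N_t$ frames of metrics
$\vec q_n$ and energies $\varepsilon_n$ recorded at a fixed interval $\tau$:

**1. Basis expansion.**  Each frame is mapped through the basis
$\{\sin(n\theta), \cos(n\theta)\}$ over every metric $\theta$ and multiplier
$n = 1..n_{max}$, giving an $N_t \times N_b$ feature matrix $V$ per
trajectory ($N_b = 2 \times \text{metrics} \times n_{max}$).  Every
dimension is z-scored using moments pooled over *all* trajectories — pooling
is required because the energy regression below is performed on the joined
dataset, and per-trajectory scaling would make coefficients incomparable.
Zero-variance columns are kept (as zeros) rather than dropped so that weight
vectors stay index-aligned with the basis; they naturally receive zero
weight downstream.

**2. Effective energy.**  Each trajectory's energy series is mirrored
(`c(e, rev(e))`, the standard even extension, which removes the boundary
discontinuity that would otherwise leak across the whole spectrum),
Fourier-transformed, truncated to the first $K$ frequency indices of the
extended grid (the DC term included; conjugate partners retained so the
inverse is real), and inverse-transformed.  The filtered energies of all
trajectories are joined and regressed (ordinary least squares with
intercept) on the joined features:

$$\tilde\varepsilon^K = a_0^K + V \hat a^K + \epsilon^K, \qquad
  r(K) = 1 - \overline{(\epsilon^K)^2} / \sigma_K^2 .$$

$r(K)$ is scanned over a cutoff range and the selected cutoff is
$K^* = \arg\max_K r(K)$; the *effective energy* of every frame is the fitted
value $a_0 + V\hat a$ at $K^*$.  Ties are broken toward the smaller $K$
(the smoother energy).  By convention $r = 0$ when the filtered energy has
zero variance.

Two implementation notes.  First, the scan is computed spectrally: because
the kept frequency set grows one index at a time, the cross-products
$V^\top \tilde\varepsilon^K$ and $\|\tilde\varepsilon^K\|^2$ are cumulative
sums over the energy's cross- and power spectra (Parseval, using the mirror
symmetry of the filtered extension), so each additional $K$ costs one small
$N_b \times N_b$ solve instead of a fresh pass over all frames.  The unit
tests verify this path against literal filter-then-regress at each $K$.
Second, a property of $r(K)$ worth knowing: if the energy were an *exact*
linear function of the features with no added noise, every truncated energy
would also be exactly explainable and $r(K)$ would plateau at 1 — the
interior maximum that makes $K^*$ meaningful only exists when substantial
feature-independent noise rides on the recorded energy.  That is precisely
the regime the method is designed for (a recorded total energy dominated by
environment fluctuation), and the bundled simulator reproduces it by
default (see below).

**3. E-space.**  Features are rescaled column-wise by the regression
weights, $\tilde V = V\,\mathrm{diag}(\hat a^{K^*})$, pooled, centered, and
eigen-decomposed (covariance PCA — correlation PCA would undo the weighting,
which *is* the intended anisotropy).  The mapping operator $M$ keeps the
smallest number $N_c$ of leading eigenvectors whose cumulative eigenvalue
fraction reaches the retention target (default 0.90).  Projection of new
data applies the *same* weighting and centering before $M$; this is the
only reading under which $M$'s orthogonality is meaningful (a flag
`project_raw` provides the literal unweighted alternative for comparison).
Each eigenvector's largest-magnitude component is made positive, so
results are reproducible run to run.

**4. Discretization.**  Each projected trajectory is cut into isometric
segments of $L$ frames (trailing remainders dropped), and each segment is
replaced by its average vector — the averaging suppresses fast intra-state
fluctuation.  Segment similarity is the cosine of the average vectors
augmented with one constant component per dimension:

$$S(t,t') = \frac{\sum_i [B_i(t)B_i(t') + 1]}
  {\sqrt{\sum_i [B_i(t)^2 + 1]\sum_i [B_i(t')^2 + 1]}},$$

symmetric, unit diagonal, entries in $[-1, 1]$.  (The augmentation keeps
near-zero vectors from producing unstable cosines.)  Negative entries are
clipped and rows normalized, giving a reversible row-stochastic matrix whose
real spectrum is computed through the symmetric similarity transform
$D^{-1/2} W D^{-1/2}$.  The number of states $N_s$ is the position of the
largest consecutive gap among the top ten eigenvalues (metastable counts in
practice are small, and gap search on noisy spectral tails is unstable; an
override and a raw-spectrum variant are available).  Robust Perron cluster
analysis (PCCA+) then converts the top-$N_s$ right eigenvectors into fuzzy
memberships by the inner-simplex construction: the most mutually distant
eigenvector rows are taken as simplex vertices, the eigenvector matrix is
transformed by the inverse vertex matrix (rows then sum to one exactly),
small negative entries are clipped, and crisp labels are the membership
argmax.  The procedure is deterministic — no optimization restarts.

**5. Markov model.**  Transitions between segment labels are counted in a
sliding window at a configurable lag (never across trajectory boundaries),
row-normalized into $P$ (maximum-likelihood, non-reversible; a
`reversible = TRUE` option symmetrizes counts), and summarized by the
stationary distribution (left unit eigenvector, with an irreducibility
check) and the state lifetimes $\text{lag time}/(1 - P_{ii})$ under a
geometric-exit model — the formula that reproduces published lifetime
tables for both reference systems bundled with the package.

## The toy simulator

`simulate_brownian()` integrates the underdamped Langevin equation
$m\dot v = -\nabla U - \gamma v + \xi(t)$ with the BAOAB splitting on the
two-dimensional three-well landscape

$$U(x,y) = -\epsilon\{\cos x + \sin x + \tfrac12\cos y + 2\cos 3x
  + 2e^{-20(x + 2\pi/3)^2 - 2y^2}\},\qquad \epsilon = 40 .$$

Design choices, in the order they matter:

* **Periodicity.**  The landscape is treated as periodic on
  $[-\pi,\pi)^2$ (the Gaussian-basin term uses wrapped displacements).
  The trigonometric terms are periodic anyway, and at temperatures high
  enough for barrier crossing the particle would otherwise drift over the
  shallow $y$ ridges into cells lacking the Gaussian well, leaving no
  well-defined equilibrium.  On the torus the Boltzmann measure is proper,
  matches the quadrature oracle's domain exactly, and the sine/cosine
  basis cannot distinguish cells in any case.  Recorded coordinates are
  wrapped to the primary cell.

* **Temperature.**  The landscape's published equilibrium weights come
  without a printed temperature.  `calibrate_temperature()` scans $kT$
  against those weights using the Boltzmann quadrature; the minimizer is
  $kT \approx 60$ (in potential units), which the simulator uses as its
  default.  No temperature reproduces the published triple exactly —
  the narrow Gaussian well holds less Boltzmann weight than published at
  every temperature — so validation pins the *ordering* of the weights
  plus agreement between the pipeline's stationary distribution and the
  quadrature oracle *at the simulation temperature*, which is the
  internally consistent comparison.

* **Energy noise.**  Recorded energies are the instantaneous potential
  plus Gaussian noise of standard deviation $5\epsilon$ (default).  The
  noise emulates the energy fluctuation of an unresolved environment
  (a thermostated solvent), and its scale is chosen to dominate the raw
  signal — the raw series then looks featureless while the filter-plus-
  regression recovers the landscape component, which is the behaviour the
  method exists to demonstrate.  With weak noise $r(K)$ would increase
  monotonically (see the note in step 2) and the cutoff scan would be
  uninformative.

* **Other defaults.**  $m = 1$, $\gamma = 1$, $dt = 0.002$ (the stiffest
  curvature is the Gaussian well, $\omega\,dt \approx 0.11$), recording
  stride 50 (interval 0.1 time units), 100 time units of discarded
  equilibration — several times the longest basin lifetime, so recording
  starts near equilibrium even from uniform random initial positions.
  A zero-friction, zero-noise limit and a harmonic-well mode
  (`simulate_harmonic()`) expose the integrator to equipartition and
  drift checks independent of the landscape.

* **Ground truth.**  `assign_basins()` implements the watershed partition
  (steepest descent to a minimum, with periodic wrapping); points landing
  exactly on zero-gradient separatrix ridges — a measure-zero set that a
  regular grid does hit — are tie-broken to the nearest minimum.
  `boltzmann_basin_weights()` integrates $e^{-U/kT}$ on a cell-centered
  grid partitioned the same way, with a convergence check between two
  resolutions; the unit tests verify it independently against Monte Carlo
  importance estimates.

## Problem sizes and what the validation shows

The packaged toy reproduction (`reproduce_toy()`) runs 10 trajectories of
10,000 frames (stride 50, i.e. $10^7$ integrator steps), segments of 20
frames — 2 time units, well below the shortest basin dwell time of roughly
6 — giving 5,000 segment vectors, a 40-dimensional basis ($n \le 10$), a
cutoff scan over $K \le N_t/10$, and a lag of one segment.  On this size
the pipeline recovers exactly three states, localizes them in the three
wells (over 95 % of segments carry the label of the well containing their
mean position), and matches the Boltzmann oracle's stationary weights
within 0.05.

Passing this validation shows the pipeline's machinery — filtering,
regression, rescaling, spectral discretization, Markov estimation — is
internally consistent on data with genuine metastability and a known
answer.  It does not show that real molecular systems satisfy the method's
assumptions: real energy noise is neither white nor Gaussian and is
correlated with conformation; real features (dihedral sines/cosines) may
miss slow coordinates entirely; and real trajectories are rarely long
enough to visit every state many times.  The peptide-scale layer is
therefore validated separately on published 3-state and 6-state reference
transition matrices shipped with the package (`reference_model()`): their
stationary distributions and lifetime columns are reproduced from the
matrices alone to print precision, confirming the Markov-layer mathematics
on real-system numbers without re-running a 5-microsecond simulation.

## Numerical details worth knowing

* Frequency indices refer to the *even-extended* grid (length $2N_t$);
  the physical cutoff frequency reported alongside is $K/(2N_t\tau)$.
* The regression solve uses the normal equations with a Cholesky path and
  an eigenvalue-based minimum-norm fallback for rank-deficient designs
  (logged, never fatal).  $r$ is clamped to $[0,1]$ against rounding.
* All randomness flows from one seed: the simulator consumes R's RNG
  (including inside compiled code), and the pipeline seeds once at entry.
  Identical seeds give bit-identical trajectories and results.
* Degenerate leading eigenvalues (perfectly separated states) are handled
  in PCCA+ by forcing the Perron vector to the constant vector before the
  simplex search.
* Trajectory files are written with 17 significant digits, so write/read
  round-trips are exact at double precision.

## Limitations

* The basis is fixed to sines/cosines of integer multiples of the metrics;
  metrics that are not angles (distances, contact counts) work but the
  periodicity assumption behind the basis does not hold for them.
* Segment length trades fluctuation suppression against state mixing; the
  frames/100 default is a convention, not an optimum, and should be kept
  well below the expected dwell times.
* The similarity spectrum's eigen-gap can be ambiguous for weakly separated
  or hierarchically nested states; the state-count override exists for
  exactly that case.
* Lifetimes assume geometric exit at the counting lag; they are only as
  Markovian as the discretization.
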