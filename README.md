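# espctm

Kinetic transition networks from trajectory mapping in an
effective-energy rescaled space.

`espctm` is for simulators of complex systems — molecular dynamics of
peptides and proteins, Brownian dynamics on rugged landscapes — who want to
turn raw trajectories into an interpretable picture: which metastable
states the system visits, their equilibrium populations, their lifetimes,
and the transition network between them.

## The method

Input is a set of equally long trajectories of structural metrics
$\vec q_n$ (e.g. backbone dihedral angles, or particle coordinates) with a
per-frame total potential energy $\varepsilon_n$, recorded at a fixed
interval.  The pipeline:

1. **Featurize** — expand every frame in the basis
   $\{\sin(n\theta),\cos(n\theta)\}$ over all metrics ($N_b$ functions),
   z-scored over the pooled dataset.
2. **Effective energy** — even-extend and Fourier-transform each energy
   series, keep the first $K$ frequencies, and regress the filtered energy
   on the features: $\tilde\varepsilon^K = a_0^K + V\hat a^K + \epsilon^K$.
   The cutoff $K^*=\arg\max_K r(K)$ maximizes the multiple correlation
   coefficient $r(K)=1-\overline{(\epsilon^K)^2}/\sigma_K^2$; the fitted
   values at $K^*$ are the *effective energy*, the slow,
   feature-explainable component of the recorded energy.
3. **E-space** — rescale the features column-wise by the regression
   weights, $\tilde V = V\,\mathrm{diag}(\hat a^{K^*})$, and reduce by PCA,
   keeping the smallest $N_c$ components holding ≥ 90 % of the variance.
4. **Discretize** — cut projected trajectories into isometric segments,
   average each segment, build the segment-similarity matrix
   $S(t,t')=\sum_i[B_iB_i'+1]\,/\sqrt{\sum_i[B_i^2+1]\sum_i[B_i'^2+1]}$,
   pick the state count from its leading eigenvalue gap, and assign
   metastable states by robust Perron cluster analysis (PCCA+).
5. **Markov model** — count lagged transitions between segment labels,
   row-normalize into $P$, and report the stationary distribution $\pi$
   ($\pi P = \pi$) and lifetimes $\text{lag}/(1-P_{ii})$.

No hyper-parameter expresses "which motions are slow": the energy
regression decides the weighting automatically.

A Langevin simulator for a Brownian particle on a periodic three-well
landscape ($U = -\epsilon\{\cos x+\sin x+\frac12\cos y+2\cos 3x+
2e^{-20(x+2\pi/3)^2-2y^2}\}$, $\epsilon=40$), plus a Boltzmann quadrature
oracle for the exact basin weights, is included for validation.

## Worked example

Simulate the toy system and run the whole pipeline:

```r
library(espctm)
rep <- reproduce_toy(seed = 1)
#> [espctm:simulate] 10 trajectories x 10000 frames (kT = 60, eps = 40)
#> [espctm:energy] K* = 125 (cutoff 0.0625 per time unit), r = 0.2953
#> [espctm:espace] retained N_c = 3 of 40 (91.2% of variance)
#> [espctm:discretize] eigen-gap at 3 (top eigenvalues: 1.000, 0.983,
#>   0.858, 0.173, 0.076, 0.052)
#> [espctm:toy] N_s = 3, purity = 0.956, max |pi - Boltzmann| = 0.014
round(rep$stationary, 3)   # recovered equilibrium populations, by well
#> [1] 0.151 0.498 0.351
round(rep$boltzmann, 3)    # independent Boltzmann quadrature at kT = 60
#>    S0    S1    S2
#> 0.137 0.512 0.351
```

Reading this: the raw recorded energy is dominated by noise (r of the
unfiltered fit would be near zero), but at the selected cutoff the
regression explains ~30 % of the filtered energy's variance; rescaling by
those weights compresses 40 basis functions into 3 components; the
similarity spectrum shows three eigenvalues near 1 followed by a clear gap,
so three metastable states are kept, and 95.6 % of segments carry the
label of the potential well containing their mean position.  The Markov
model's stationary distribution agrees with the exact Boltzmann weights to
0.014.

The same machinery works on files:

```r
trajs <- read_trajectories(c("t1.csv", "t2.csv"), dt = 5)  # columns x, y, ..., energy
res <- run_espctm(trajs, espctm_config(max_n = 10, lag = 1,
                                       out_dir = "results"))
res$markov$P            # transition matrix
res$markov$lifetimes    # in time units of dt
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/espctm simulate --out toydata --seed 1
Rscript inst/cli/espctm run --out results --dt 0.1 toydata/traj*.csv
Rscript inst/cli/espctm reproduce-toy --seed 1 --out report
```

Two published reference transition matrices (the 3-state Brownian-particle
network and a 6-state peptide-folding network) ship with the package for
validating the Markov layer:

```r
m <- reference_model("toy")
round(stationary_distribution(m$P), 3)
#> [1] 0.185 0.531 0.284
round(state_lifetimes(m$P, 1), 2)    # units of 100 recording intervals
#> [1] 8.47 7.04 3.95
```

## Package layout

- `R/` — pipeline modules: io/config, basis features, effective energy,
  E-space, discretization (PCCA+), Markov estimation, Brownian simulator,
  orchestration.
- `src/` — compiled BAOAB Langevin integrator and watershed descent.
- `inst/extdata/` — the two reference transition matrices (CSV).
- `vignettes/espctm-methods.Rmd` — model, assumptions, tunables, design
  decisions, limitations.
- `tests/testthat/` — unit, property and end-to-end suites.
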