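---
title: "Mapping neighbor QTL: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping neighbor QTL: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neiqtl)
```

This vignette is the package's own account of the science it implements: the
models, the parameters that matter, what the synthetic data emulate, and the
places where the design was genuinely open and a choice had to be made.

## 1. The problem

In a planting of genetically variable individuals, a focal plant's phenotype
can depend on whether its neighbors carry the *same or different alleles* at
particular loci — through herbivore movement, volatile communication, or
competition. The goal is to map such loci in experimental crosses (F2
intercross, backcross, selfed recombinant inbred lines) from a single
randomized planting, without exhaustive pairwise mixing experiments. The
modelling idea is borrowed from the two-dimensional Ising model of
ferromagnetism: individuals are magnets, the two homozygous genotypes are the
two dipoles, and the trait plays the role of energy; the neighbor-effect
coefficient is the interaction strength, the self effect the external field.
These physical aliases are interpretation only — no Ising computation is
performed anywhere in the package.

## 2. Trait model and genotype-pair effects

With genotypes AA/AB/BB, self effects are coded $(a_1, d_1, -a_1)$ and the
effect of a focal/neighbor genotype pair is the product of codes
$(a_2, d_2, -a_2)$, giving the 3×3 table with entries $\pm a_2^2$,
$\pm a_2 d_2$, $d_2^2$. The trait of individual $i$ is the population mean
plus its self effect, plus the average pair effect over its $L_i$ neighbors
within distance $s$, plus residual noise.

Because genotypes between markers are unobserved, every quantity is computed
from conditional genotype probabilities (Section 3), and the pair effect
becomes the *conditional neighbor genotypic identity*
$z_i(s) = \sum_{j\in N(i,s)}\sum_v\sum_w p_{i,v} p_{j,w} C[v,w] / L_i$ for a
fixed weight table $C$:

* **quadratic** (F2 scans): $C = \{1, 0.25, 0, -0.25, -1\}$ over the nine
  ordered pairs — the quadratic-regression encoding of the pair table;
* **additive-polygenic** (F2 genome-wide kernel): as above with $\pm 0.5$ in
  place of $\pm 0.25$ (one shared allele between a heterozygote and a
  homozygote);
* **inbred/backcross linear** (two-genotype crosses): products of $\pm 1$
  self codes. For a backcross the constraint $d_2 = -a_2$ makes the pair
  table proportional to the product of symmetric $\pm 1$ codes, which is why
  the backcross and inbred linear models are exactly equivalent — a property
  the test suite asserts.

Two non-obvious consequences of these tables, found during implementation
and worth recording:

* The tables are *not* even under a genome-wide allele swap: the
  $a_2 d_2$ cross terms change sign with $a_2$. Swap invariance holds on
  homozygote pairs and for the linear codings, and is tested there.
* On a two-genotype cross the additive-polygenic table degenerates to
  $(x_i + x_j)/2$ with $x$ the AA indicator — a *separable* score with no
  pair interaction at all. A genome-wide kernel built from it is blind to
  backcross neighbor effects ($d_2 = -a_2$ is a pure product). The kernel
  therefore uses the cross's own $\pm 1$ product coding for two-genotype
  crosses and the additive table only for F2.

## 3. Genotype probabilities

`calc_genoprob()` runs a forward–backward hidden Markov chain per
chromosome over markers and inserted pseudomarkers. Transition matrices
derive from inter-position cM gaps through the map function; emissions allow
a symmetric genotyping error rate; missing genotypes emit uniformly. Exact
correctness is checked against brute-force enumeration of all hidden paths
on chromosomes with up to 4 markers (tolerance 1e-10).

Parameters and defaults (all exposed):

| parameter | default | meaning |
|---|---|---|
| `map_function` | `"haldane"` | no crossover interference; `"kosambi"` selectable |
| `error_prob` | `1e-4` | genotyping error rate; 0 allowed for exact tests |
| `step` | 1 cM | pseudomarker spacing; `Inf` = markers only |

The originating method does not state a map function, error model, or grid
density; these defaults are the field's conventions. Selfed-RIL transitions
use the RIL-expanded recombination fraction $R = 2r/(1+2r)$, the standard
correction for repeated selfing, and `estimate_map()` inverts the same
expansion when re-estimating a map from RIL genotypes. Recombination
fractions are capped at 0.49 before cM conversion so unlinked markers yield a
finite (warned-about) distance. Heterozygote calls in a selfed RIL are
demoted to missing with a warning rather than rejected: they are usually
residual heterozygosity or genotyping slips, and the two-state chain cannot
represent them.

## 4. Stepwise scans

`scan_self()` regresses the trait on the standardized expected additive
score (codes −1/0/1) and, for F2, the dominance score (0/1/0), plus
covariates; `lod_self` is the log10 likelihood ratio against the
covariates-only model. For gaussian traits this is Haley–Knott regression
and equals $(n/2)\log_{10}(RSS_0/RSS_1)$, which the tests verify against an
independent least-squares oracle at 1e-8.

`scan_neighbor()` then *fixes* the fitted self effect
$\hat g = \hat a_1 x_\text{add} + \hat d_1 x_\text{dom}$ as a single
covariate and adds the standardized identity $z$ (and $z^2$ for F2).
Fitting $\hat g$ rather than re-estimating free self coefficients follows
the method's step 4; for least squares the two give identical residual sums
of squares (the fitted self effect spans the projection), so the stepwise
LOD is exactly the likelihood-ratio definition while nesting guarantees
`lod_nei >= 0`. Self and neighbor effects are inevitably correlated — the
self code appears inside the identity — and testing neighbor effects against
the residuals of self effects is what keeps the neighbor test conservative.

Reported effects: `eff_2a1` is the fitted homozygote difference
$\bar y_{AA} - \bar y_{BB}$ (the effect of replacing both alleles);
`eff_d1` the heterozygote deviation from the homozygote midpoint;
`eff_2a2sq` twice the raw-scale linear coefficient on the identity, signed —
positive when sharing alleles raises the trait; `eff_d2sq` the quadratic
coefficient. The quadratic coefficient is fitted *unconstrained*; because
the model writes it as a square, a negative fit is floored at zero and
flagged in `d2_floored` rather than silently reported.

Binary traits use logistic regression throughout, with a small ridge
fallback (lambda = 1e-4, warned) under separation. Permutation thresholds
shuffle phenotype and covariate rows jointly against the fixed
genotype/spatial structure — the permutation preserves exactly the
correlation structure the test conditions on — and use nearest-rank
percentiles of genome-wide maxima with the seed recorded.
`scan_epistasis()` compares the additive-joint model of two identities
against the model with their product, excluding the focal position and
flagging positions within 1 cM as linked.

## 5. Variance components and the effective distance

`build_covariance()` forms $K_1 = P_1 P_1^\top/(q-1)$ from expected additive
scores and $K_2 = P_2 P_2^\top/(q-1)$ from neighbor identities at all $q$
grid positions; `fit_varcomp()` estimates
$(\sigma_1^2, \sigma_2^2, \sigma_e^2)$ by average-information REML with an
EM warm-up, projection of components onto $[0,\infty)$, and log-likelihood
backtracking. When the AI steps stall — which happens when the two kernels
are nearly collinear, e.g. at a scale so large that every individual is
every other's neighbor — the fit is handed to a quasi-Newton polish on
log-variances driven by the analytic REML score (convergence: gradient below
1e-6 relative, at most 200 AI iterations; a non-converged fit is always
flagged, never silent). The optimizer is checked
against a dense grid search over variance proportions (step 0.02 at n = 50,
agreement within 0.05 log-units). Gaussian fits are run on the
unit-variance scale internally, which makes the estimates exactly
equivariant under trait rescaling.

Columns of $P_1/P_2$ are standardized (mean 0, variance 1) before the
cross-product, not merely centered. This is load-bearing: the identity's
per-position variance shrinks as the scale grows, so without column
standardization the two kernels sit on incomparable scales across $s$,
PVE\_nei saturates regardless of scale, and the ΔPVE argmax degenerates to
the smallest scale. Standardization puts every scale's kernel diagonal near
1 and makes the profile informative; `standardize = FALSE` restores the
centered-only convention.

`delta_pve()` profiles PVE\_nei over percentile scales of the pairwise
distance distribution (default every 10th percentile, the granularity used
for the real-data analyses). ΔPVE at the first scale is PVE\_nei itself
(the increment from $s = 0$); later increments are taken between consecutive
*usable* scales — scales with isolated individuals or failed fits stay in
the profile flagged `converged = FALSE` and are skipped. Ties in the argmax
go to the smaller scale (conservative locality). For binary traits the
logistic mixed model provides no residual variance, so the profile uses
RVE\_nei $= \hat\sigma_2^2/\hat\sigma_1^2$, fitted by penalized
quasi-likelihood. `marker_h2()` is the single-kernel fit — the two-kernel
model with the neighbor variance and scale forced to zero.

## 6. What the synthetic data emulate — and what they do not

`sim_cross()` draws genotypes from the cross-appropriate Markov chain along
a default map of 5 chromosomes × 6 markers at 12 cM spacing (the marker
density of a sparse experimental-cross panel); `sim_spatial()` places
individuals uniformly on $(1,100)^2$; `sim_phenotype()` builds a trait in
the benchmark's image:

* a self component with a major additive effect $a_1$ at one marker
  (defaults 0.56 for F2/RIL and 0.28 for backcross, the benchmark's
  estimated signal strengths), $10^{-3} a_1$ at every other marker, unit
  normal residuals, standardized to mean 0 / variance 1;
* a neighbor component from the genotype-pair table at the true scale
  (scenarios: additive $d_2 = 0.25\,a_2$, dominant $d_2 = a_2$,
  overdominant $d_2 = 1.25\,a_2$, backcross $d_2 = -a_2$), with the same
  polygenic background, rescaled *empirically per replicate* so that exactly
  the requested share (default 50%) of the summed trait's variance is
  neighbor-attributable — the share is stated by the benchmark, the
  mechanism was open, and per-replicate rescaling makes the share exact
  rather than expected;
* the major self-QTL marker and the major neighbor-QTL marker are
  *different* (random) markers. This mirrors a trait with its own QTL
  architecture receiving neighbor effects at an unrelated locus; placing
  both at one marker induces a strong negative correlation between the self
  phenotype and the neighbor component (the pair table has a nonzero mean
  when $d_2 \ne 0$, so the identity contains a self-aligned part) and
  roughly halves the neighbor scan's power — a harder and different problem
  from the one the benchmark poses;
* the `neighbor-phenotype` scenario replaces the genotype-pair component by
  the scaled mean *phenotype* of neighbors — the false-positive control: a
  neighbor-genotype model fitted to such traits should stay quiet.

What passing the benchmark does *not* show about real data: residuals are
homoscedastic normal (field counts are not); positions are uniform with no
spatial autocorrelation in the environment (a real tray has edges and
gradients — the real-data analyses used an edge covariate, and
environmental autocorrelation kernels are out of scope); genotypes are
complete and error-free at generation; and the 50% neighbor share is far
stronger than the few-percent PVE seen in real traits.

`run_benchmark()` runs the full pipeline per replicate (probabilities →
ΔPVE scale → neighbor scan at $\hat s$) and reports the major-marker
`lod_nei`, $\hat s$, PVE terms and the net neighbor contribution
(PVE\_self + PVE\_nei) − $h^2$. Problem sizes used by the shipped
acceptance checks: n = 200 individuals, 10 replicates per scenario ×
percentile, markers-only grid — the scale at which the benchmark's medians
(short-range power, backcross power at all ranges, distance-recovery
monotonicity, false-positive bound) are reproduced in the test suite.

## 7. Numerical choices and degenerate inputs

* Constant scores/identities at a position (no variance) are dropped from
  the design rather than divided by ~0; the position reports `lod = 0` and
  `NA` effects.
* Zero-RSS (noiseless) fits are floored at 1e-280 so LODs stay finite.
* Zero-neighbor individuals at a scale reject the scale by default with a
  diagnostic naming them (`zero_policy = "drop"` excludes the individuals
  instead); silent zeros would bias the regression.
* The distance predicate is a closed ball (≤ s) excluding self, and the
  identity is scaled by each individual's own neighbor count — counts differ
  at map edges; the `L` range is retained in the result object.
* Percentile scales use linear-interpolation empirical percentiles,
  deduplicated keeping the smallest percentile per distinct distance.
* REML components pinned at the zero boundary with inward gradients are
  treated as converged at the boundary (the estimate is genuinely 0).

## 8. Known limitations

Autosomes only (sex chromosomes need one-to-three extra degrees of freedom
and their neighbor-effect inheritance is unexplored); two kernels only (no
spatial-autocorrelation random effect); no multi-QTL model selection or
Bayesian interval estimates; the quadratic approximation assumes equal
variance across the nine genotype combinations and loses power against
purely additive F2 traits relative to the linear model — the benchmark shows
exactly this pattern, with backcross power uniformly higher.
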