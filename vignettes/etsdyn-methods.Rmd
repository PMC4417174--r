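---
title: "Models and methods behind etsdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind etsdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etsdyn)
```

# What the package analyses

ETS-family transcription factors share a structurally conserved DNA-binding
domain and overlapping sequence preferences around a 5'-GGA(A/T)-3' core, yet
individual members regulate distinct target genes. `etsdyn` implements the
quantitative machinery for one experimental strategy to dissect this: compare
high- and low-affinity sequence-specific complexes of different ETS domains
(e.g. PU.1 versus Ets-1) across four orthogonal measurements — circular
permutation electrophoresis, dynamic light scattering, chemical footprinting,
and binding-motif information content — and ask where the complexes differ.

Every analysis is paired with a seeded synthetic-data generator, so the entire
pipeline runs and is tested without instrument files.

# The circular-permutation bend model

A panel of equal-length DNA fragments carries one binding site at positions
running from one end to the other. The *flexure displacement* $x \in (0,1)$ is
the fractional position of the site center along the fragment; with 1-based
fully-closed coordinates (base $i$ occupies $[i-1, i]$), the center of a site
of length $l$ starting at base $s$ sits at $s - 1 + l/2$, so a centrally
placed even-length site gives exactly $x = 0.5$. `make_series()` spaces site
centers exactly evenly, which keeps the series mirror symmetric
($x_i + x_{n+1-i} = 1$); for the default 11 x 143-bp series with a 10-bp site
this requires the central placement to sit half a base off the integer grid,
which we allow — real construct panels built from restriction digests are
themselves slightly off-center.

Protein-induced bending is modeled as a fixed point kink of angle $\theta$
(the deflection from linearity; $180°$ minus the included angle). This is
appropriate when the site is short relative to the fragment — here 10/143 bp,
i.e. 7% of the fragment length. Under reptation, electrophoretic mobility
tracks the squared end-to-end distance of the migrating chain, giving

$$ R_f(x) = K\,\bigl[1 - 2x(1-x)\,(1 - \cos\theta)\bigr], $$

the squared end-to-end distance of a unit rod kinked by $\theta$ at fractional
position $x$, scaled by a dimensionless factor $K$ that absorbs all non-bend
contributions (effective charge, frictional coupling with the gel matrix).
The form is quadratic in $x$, minimized at $x = 0.5$, and satisfies
$R_f(0) = R_f(1) = K$ for *any* bend angle — so the fitted end value reads out
non-bend effects directly (`k_from_ends()`), while curvature reads out the
bend. Whether the curvature term carries $\cos\theta$ or $\cos(\theta/2)$ is a
convention choice that rescales $\theta$ without changing the fit's quality or
the model comparison; the $\cos\theta$ (rigid-kink end-to-end) convention is
used and is isolated in `predict_rf()`, and reports state it.

## Fitting and inference

`fit_profile()` minimizes weighted least squares (weights $1/\mathrm{SE}^2$;
unweighted when any SE is zero) by damped (Levenberg–Marquardt) least squares
with an analytic Jacobian and a deterministic start: $K_0$ is the mean
mobility at the two most extreme placements, $\theta_0$ inverts the
near-midpoint value, with a floor of $0.5°$ because the $\theta$ Jacobian
column vanishes identically at $\theta = 0$. Bounds are
$K > 0$, $0 \le \theta < 180°$. A flat profile converges to the $\theta = 0$
boundary, where the covariance is singular and reported as `NA`.

Confidence limits and the 95% confidence band are linearized (delta-method):
$\pm t_{0.975,\,n-2}\sqrt{g^\top C\, g}$ with $g$ the parameter gradient. A
profile-likelihood option is not implemented; for this two-parameter model,
which is linear in $(K,\, K(1-\cos\theta))$, the linearization is accurate at
the measured noise level (Monte-Carlo coverage of the per-parameter intervals
is close to nominal in the test suite).

`compare_profiles()` asks whether two complexes share one $(K, \theta)$ by
Fisher's $F$ test on residual sums of squares: separate fits (4 parameters)
versus a global fit (2 parameters),
$F = \frac{(\mathrm{RSS}_g - \mathrm{RSS}_s)/2}{\mathrm{RSS}_s/\mathrm{df}_s}$
against $F(2, \mathrm{df}_s)$. **The RSS entering this ratio is unweighted by
default.** This is a deliberate design choice: the assay's replicate error is
homoscedastic (quadruplicate SEs are ±0.005 or better at every position), and
per-point weights estimated from only 4 replicates carry 3 degrees of freedom
each, which in simulation inflates the size of the weighted RSS-ratio test to
roughly 0.18 at a nominal $\alpha = 0.05$. With unweighted RSS the null
rejection rate is at its nominal level (checked over 500 simulated null
datasets in the test suite). `weighted = TRUE` restores $1/\mathrm{SE}^2$
weights for data with well-determined variances.

Per-position inference uses Welch's $t$ test assembled from summary statistics
(means, SEs, replicate counts; Welch–Satterthwaite df) with
Benjamini–Hochberg adjustment across positions (`position_tests()`).
p-values are kept at floating precision and printed with a floor of
`"<0.00001"`.

# Dynamic light scattering

`stokes_einstein_dh()` converts translational diffusion to hydrodynamic
diameter, $D_H = k_B T / (3\pi\eta D_t)$. Defaults are 298.15 K and
$\eta = 0.8872$ mPa·s — water at 25 °C standing in for phosphate-buffered
saline, an assumption the configuration makes explicit and overridable.

`fit_lognormal()` summarizes an intensity-weighted $D_H$ distribution by
least-squares fitting $A \cdot \mathrm{dlnorm}(D_H;\, \ln\mu_g,\, \ln\sigma_g)$
with the amplitude $A$ free, so the fit is invariant to uniform rescaling of
the weights. $\mu_g$ (geometric mean = median) and $\sigma_g$ (dimensionless
geometric SD) are reported with delta-method SEs, and the diameter range is
$\mu_g \div \sigma_g$ to $\mu_g \times \sigma_g$. The raw autocorrelation
inversion performed by instrument firmware is out of scope; the module starts
from distributions, the level at which DLS results are reported.
`compare_distributions()` reports the median shift and the broadening ratio
($\sigma_g$ ratio; below 1 is a tightening) with z-scores from propagated SEs.

# Footprint quantitation

DMS methylates guanine N7 through the major groove; after strand scission each
reactive guanine yields one electropherogram peak. `integrate_peaks()`
trapezoid-integrates the signal over per-base windows supplied by an index map
(emulating sizing-software output); `normalize_to_control()` divides by a
distal control peak to cancel recovery differences, making the whole pipeline
invariant to uniform intensity rescaling. Baseline drift, when present, is
removed by a rolling-minimum subtraction with a window much wider than a peak.
`protection()` reports $100\,(1 - \sum \text{core}_\text{bound} / \sum
\text{core}_\text{unbound})$ on normalized areas, negative values denoting
hypersensitivity, with core fractions reported at 0.1 granularity.
`flag_changes()` marks bases whose normalized areas change by strictly more
than 20% (the unbound state is the denominator); `hypersensitivity_check()`
calls a complex site-specific when any base of the interrogation window shows
a bound/unbound ratio strictly above a factor (default 2), the DNase I
diagnostic of minor-groove widening at the core.

# Motif information content and discrimination energetics

Under an equiprobable background, positional information content is
$IC = 2 + \sum_b p_b \log_2 p_b$ bits ($0\log 0 = 0$), from 0 bits (uniform)
to 2 bits (one absolutely preferred base); the total IC of a site sums its
positions, and logo stack heights are $IC \times p_b$. No small-sample
(Miller–Madow) correction is applied, keeping counts-derived and
probability-derived ICs identical; the background is fixed equiprobable so
that total-IC differences remain comparable with the energetic bound below.

For two optimized discriminators A and B,

$$ \Delta(\text{total IC})_{A-B} = \varepsilon_r \left( \log_2
\frac{K_{sp,A}}{K_{ns,A}} - \log_2 \frac{K_{sp,B}}{K_{ns,B}} \right), $$

with conversion efficiency at most $\varepsilon_r = \ln 2 \approx 0.7$ under
isothermal conditions (the default). `delta_total_ic()` accepts
**dissociation** constants — the form in which affinities are quoted — and
inverts them internally ($K_{sp}/K_{ns} = K_{d,ns}/K_{d,sp}$); reports restate
this convention so signs cannot be misread. With both specific Kd at
$10^{-10}$ M and nonspecific Kd of $10^{-5}$ versus $10^{-7}$ M, the
difference is $\ln 2 \cdot \log_2 100 = 4.6$ bits:

```{r}
delta_total_ic(kd_sp_a = 1e-10, kd_ns_a = 1e-5,
               kd_sp_b = 1e-10, kd_ns_b = 1e-7)
```

# The synthetic-data generator

`scenario_spec()` bundles the generating parameters; three built-in scenarios
encode the qualitative contrasts the analyses are designed to detect:

* **PU.1-like** — high- and low-affinity complexes differ in both $K$
  (0.92 vs 0.85) and $\theta$ (63° vs ~55°), with $\theta_\text{low}$ chosen
  once so the two mobility curves coincide exactly at $x = 0.5$: mobility
  differences are maximal for terminal sites and vanish for centered sites.
  Weak nonspecific binding ($K_d = 10^{-5}$ M).
* **Ets-1-minimal-like** — both affinities share one $(K, \theta)$; tighter
  size distributions; stronger nonspecific binding ($10^{-7}$ M).
* **Ets-1-autoinhibited-like** — shared $(K, \theta)$, a larger unbound
  hydrodynamic diameter, and right-shifted, broadened distributions upon
  binding (unfolding of autoinhibitory helices).

These parameter values are qualitative stand-ins chosen to reproduce the
patterns above at realistic magnitudes; they are not measured estimates, and
nothing downstream treats them as ground truth. The noise model is the
assay's: mobility replicates are Gaussian with per-replicate SD
$0.005\sqrt{n}$ so the quadruplicate mean has SE 0.005; DLS curves carry
multiplicative log-normal noise (CV 5%); electropherograms are Gaussian peak
ladders (20 scans apart, SD 3) with configurable additive noise. Every
generator is a pure function of its arguments and a seed, restoring the
caller's RNG state.

What the generators deliberately do **not** emulate: band-shape asymmetry and
smearing in gels, multimodal or dust-contaminated DLS distributions, dye
mobility shifts and sequence-dependent peak efficiencies in capillary traces,
and phylogenetic or compositional bias in motif counts. Passing tests
therefore demonstrate correctness of the estimators under the stated noise
models, not robustness to every artifact of real instruments.

# Numerical choices and problem sizes

* Optimizer: damped least squares with analytic Jacobians, deterministic
  starts, tight tolerances (`ftol = ptol = 1e-15`, ≤ 200 iterations); no
  random restarts.
* Band/peak detection: noise floor at baseline + 3 MAD; regions split at
  local minima; intensity-weighted centroids.
* Degenerate inputs: flat profiles fit $\theta$ at the 0 boundary with NA
  covariance; single-point size distributions and zero control peaks raise
  descriptive errors; zero-SE Welch comparisons return p = 1 (equal means) or
  p = 0 with a warning.
* Simulation sizes used in the test suite — 500 null datasets for the F-test
  size check, 200 replicates for CI coverage and for noisy DLS recovery,
  1000 random vectors for the BH oracle — were chosen so Monte-Carlo error is
  small relative to the asserted margins while the whole suite stays fast.

# Known limitations

* The $\theta$ scale depends on the kink convention noted above; compare
  angles only within this package's convention.
* Delta-method confidence limits only; no profile likelihood.
* A single log-normal component per DLS distribution (no mixtures).
* Footprint quantitation requires an externally supplied index map; automatic
  peak calling is a convenience, not a replacement for sizing software.
* Motif-pair IC differences are demonstrated on synthetic or fixture matrices;
  published database matrices are inputs, not recomputed.
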