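# etsdyn

Quantitative analyses for comparing sequence-specific DNA complexes of
ETS-family transcription factor DNA-binding domains. ETS proteins (PU.1,
Ets-1, and relatives) share a conserved domain and overlapping preferences
around a 5'-GGA(A/T)-3' core, yet regulate distinct genes; one way to dissect
how is to compare their high- and low-affinity complexes across orthogonal
solution measurements. `etsdyn` is aimed at biophysicists and nucleic-acid
biochemists running such comparisons; it implements:

* **Circular-permutation bend analysis** (`constructs`, `bend_model`,
  `gel_quant`). For a panel of equal-length fragments with a binding site at
  fractional position *x* (flexure displacement), relative mobility follows a
  point-kink reptation model

  *R*<sub>f</sub>(*x*) = *K* · [1 − 2*x*(1−*x*)(1 − cos *θ*)],

  quadratic in *x*, minimized at *x* = 0.5, with
  *R*<sub>f</sub>(0) = *R*<sub>f</sub>(1) = *K* regardless of the bend angle
  *θ*. Fitting separates bending (*θ*) from non-bend charge/friction effects
  (*K*); nested-model Fisher *F* tests ask whether two complexes share one
  (*K*, *θ*), and per-position Welch *t* tests with Benjamini–Hochberg FDR
  control localize mobility differences.
* **Dynamic light scattering** (`dls_analysis`): Stokes–Einstein conversion
  *D*<sub>H</sub> = *k*<sub>B</sub>*T*/(3π*η D*<sub>t</sub>) and log-normal
  fits of intensity-weighted size distributions, summarized by the geometric
  mean *μ*<sub>g</sub> and dimensionless geometric SD *σ*<sub>g</sub>
  (range = *μ*<sub>g</sub> ×/÷ *σ*<sub>g</sub>).
* **Footprint quantitation** (`footprint_quant`): peak integration of
  capillary electropherograms over an index map, control-peak normalization,
  core-guanine protection percentages, >20% change flags, and DNase I
  hypersensitivity calls.
* **Motif information content** (`motif_information`): positional IC
  (2 + Σ *p* log₂ *p* bits), total IC and logo stack heights, plus the
  discrimination-energetics bound
  Δ(total IC)<sub>A−B</sub> = *ε*<sub>r</sub>(log₂ *K*<sub>sp,A</sub>/*K*<sub>ns,A</sub> −
  log₂ *K*<sub>sp,B</sub>/*K*<sub>ns,B</sub>), *ε*<sub>r</sub> = ln 2 by
  default; JASPAR / MEME-minimal / counts-TSV readers.
* **Synthetic data** (`synthetic_data`) and **orchestration** (`run_all()` and
  friends): seeded generators for every input plus JSON/TSV reporting, so the
  full pipeline runs end to end with no instrument files.

## Worked example

Generate a synthetic scenario in which the high- and low-affinity complexes
differ in both bend angle and non-bend effects, then analyze it:

```r
library(etsdyn)

spec <- scenario_pu1_like(seed = 42)
pr <- gen_mobility_profiles(spec)   # 11 fragments x 143 bp, quadruplicates

fit_profile(pr$high)
#> <bend_fit> PU.1-like high-affinity
#>   K     = 0.9219 [0.9138, 0.9300]
#>   theta = 63.17 deg (deflection from linearity) [61.69, 64.65]
#>   RSS 15.33 on 9 df (weighted)

compare_profiles(pr$high, pr$low)
#> <bend_comparison> PU.1-like high-affinity vs PU.1-like low-affinity
#>   F(2, 18) = 97.95, P = <0.00001 -> distinguishable at alpha = 0.05

head(position_tests(pr$high, pr$low)[, c("x", "t_stat", "p_adjusted", "significant")], 3)
#>        x  t_stat p_adjusted significant
#> 1 0.0350  8.8085 0.00106479        TRUE
#> 2 0.1280  8.6510 0.00079805        TRUE
#> 3 0.2210  4.7033 0.01426325        TRUE
```

The fit recovers the generating parameters (K = 0.92, θ = 63°) within its
confidence limits; the *F* test declares the two complexes structurally
distinguishable, and the per-position tests flag terminal placements (where
the two mobility curves diverge) but not centered ones (where they coincide).

```r
fit_lognormal(gen_dls(4.2, 1.4, noise_cv = 0.05, seed = 42))
#> <lognormal_fit> mu_g = 4.21 nm (SE 0.0135), sigma_g = 1.406 (SE 0.00374)
#>   D_H range (mu_g */ sigma_g): 2.99 - 5.92 nm

delta_total_ic(kd_sp_a = 1e-10, kd_ns_a = 1e-5, kd_sp_b = 1e-10, kd_ns_b = 1e-7)
#> <discrimination_result> Delta(total IC)_{A-B} = 4.605 bits (eps_r = 0.693)
#>   A: 11.513 bits, B: 6.908 bits (Kd convention: Ksp/Kns = Kd_ns/Kd_sp)
```

A protein whose nonspecific binding is 100-fold weaker (Kd 10⁻⁵ vs 10⁻⁷ M, at
equal specific affinity) can extract ln 2 · log₂ 100 ≈ 4.6 additional bits of
sequence selectivity — i.e. suppressing nonspecific binding is itself a
discrimination mechanism.

`run_all(spec, dir)` writes every synthetic input and all reports
(`bend_report.json`, `dls_report.json`, `footprint_report.json`,
`motif_report.json`, `position_tests.tsv`) into `dir`; payloads are
byte-identical across runs at a fixed seed, with provenance (seed, version,
input hashes, timestamp) in a separate `meta` field.

See the methods vignette (`vignettes/etsdyn-methods.Rmd`) for the models,
conventions (θ scale, Kd inversion), noise assumptions, and design decisions.

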