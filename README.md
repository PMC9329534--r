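# loopfold

Quantitative analysis of how extracellular-loop insertions affect the
folding of outer membrane proteins (OMPs), built around the *E. coli*
8-stranded β-barrel **OmpX**.

Transmembrane β-barrels are attractive scaffolds for surface display:
their extracellular loops tolerate engineered insertions. But insertions
change folding behaviour, and quantifying *how* requires a chain of
analyses: characterize the insert, quantify folded/unfolded protein from
heat-modifiability SDS-PAGE gels, fit folding kinetics, and relate
structural descriptors of the loops to the measured rates. `loopfold`
implements that chain as a tested, tidyverse-style R package for protein
biochemists and structural bioinformaticians, with seeded synthetic-data
generators standing in for raw gels and MD trajectories so that every
stage is verifiable against known ground truth.

## The models at the core

**Folding kinetics.** The folded fraction over time follows a single
exponential,

    XF(t) = A (1 − e^(−k t))

with folding rate *k* (min⁻¹) and yield *A* (asymptotic folded fraction).
Fits are Levenberg–Marquardt nonlinear least squares on (log k, logit A)
over pooled technical replicates, with asymptotic standard errors from the
scaled Jacobian covariance.

**Densitometry.** Gel lanes are inverted to signal-positive polarity,
background-subtracted by grayscale opening with a spherical-cap
("rolling-ball") structuring element of radius 50 px, profiled along the
migration axis, and integrated over folded/unfolded band windows;
fraction folded = F/(F+U).

**Insert physicochemistry.** Additive average-residue masses, isoelectric
points by bisection on the Henderson–Hasselbalch net-charge function
(Bjellqvist/ProtParam pKa set), Wimley–White water→octanol hydrophobicity,
and ProtParam extinction coefficients (ε₂₈₀ = 5500·nW + 1490·nY + 125·nCystine).

**Trajectory descriptors.** Shrake–Rupley SASA on a deterministic
Fibonacci point set; contact area between atom groups as half the buried
surface ½[SASA(A)+SASA(B)−SASA(A∪B)]; geometric hydrogen bonds (D–A ≤
3.5 Å, D–H⋯A ≥ 150°); per-residue RMSF after iterative Kabsch
superposition; and ordinary least-squares regression of descriptor means
against folding rates.

See `vignettes/loopfold-methods.Rmd` for the full account of the methods,
conventions and limitations.

## Worked example

```r
library(loopfold)

# 1. Insert properties for the six-panel inserts
run_insert_table()
#> # A tibble: 6 × 6
#>   insert_label insert repeats mass_da    pi ww_octanol_kcal_mol
#> 1 SPLAT        SPLAT        1    470.  5.24                0.1
#> 2 SPLATx2      SPLAT        2    939.  5.24                0.2
#> 3 SPLATx4      SPLAT        4   1878.  5.24                0.4
#> 4 AGPGA        AGPGA        1    353.  5.57                3.44
#> 5 AGPGAx2      AGPGA        2    707.  5.57                6.88
#> 6 AGPGAx4      AGPGA        4   1414.  5.57               13.8
```

Mass (Da) and hydrophobicity (kcal/mol) are exactly additive in the repeat
number; the pI depends only on the termini for these uncharged inserts, so
it is constant across repeats. SPLAT (+0.10 kcal/mol per copy) partitions
into a hydrophobic phase far more readily than AGPGA (+3.44).

```r
# 2. Simulate the construct panel at assay-like noise and fit the wildtype
tc  <- gen_timecourse_panel(noise_sd = 0.02, seed = 1)
fit <- fit_folding(dplyr::filter(tc, construct == "WT"))
fit
#> Single-exponential folding fit  XF(t) = A(1 - exp(-k t))
#>   k = 0.1243 min^-1 (SE 0.0043)
#>   A = 0.8899        (SE 0.0102)
#>   RSS 0.0129 on 24 observations; converged: TRUE (5 iterations)
```

The simulated wildtype (true k = 0.123 min⁻¹, A = 0.885) is recovered
within one standard error from 8 time points × 3 replicates. `tidy(fit)`
and `glance(fit)` give the broom-style tables, `autoplot(fit)` the fitted
curve over the data points.

```r
# 3. Inverse descriptor-rate relationship on the 14 folding constructs
run_correlation_demo(seed = 1)
#> # A tibble: 1 × 4
#>      slope intercept r_squared     n
#> 1 -0.00346     0.342     0.896    14
```

A synthetic loop descriptor constructed to increase as folding slows is
fit by `descriptor_rate_regression()`: the negative slope recovers the
inverse correlation, with R² reflecting the injected noise.

Other entry points: `quantify_gel()` for densitometry on (synthetic or
real) lane images, `gen_toy_trajectory()` + `descriptor_series()` +
`rmsf()` for trajectory descriptors, `construct_panel()` for the 15
loop-insertion sequence variants, `run_pipeline(out_dir)` for a one-shot
seeded run of every stage with a reproducibility manifest, and
`make_fixtures(out_dir)` to write gel/time-course/trajectory fixtures with
a ground-truth manifest.

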