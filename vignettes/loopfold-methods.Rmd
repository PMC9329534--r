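---
title: "Methods: quantifying loop-insertion effects on OMP folding"
author: "loopfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying loop-insertion effects on OMP folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopfold)
```

## The scientific problem

Outer membrane proteins (OMPs) of Gram-negative bacteria are transmembrane
β-barrels whose extracellular loops tolerate engineering — epitope display,
metal adsorption, protease sites — remarkably well. How a loop insertion's
*length* and *hydrophobic character* affect the barrel's folding kinetics is
the question this package quantifies, using the 8-stranded *E. coli* model
protein OmpX (mature chain, 148 residues) as the scaffold. Two pentapeptide
units, SPLAT and AGPGA, inserted as 1, 2 or 4 tandem copies into
extracellular loop 2 (residues 49–59) or loop 3 (residues 91–103), define a
15-construct panel (wildtype + 14 variants).

`loopfold` implements the full analysis chain around that panel:

1. **Insert physicochemistry** — additive masses, isoelectric points,
   Wimley–White octanol hydrophobicity, extinction coefficients.
2. **Gel densitometry** — folded/unfolded band quantification from
   heat-modifiability SDS-PAGE images, with rolling-ball background
   subtraction.
3. **Folding kinetics** — nonlinear least-squares fits of the
   single-exponential model to folded-fraction time courses.
4. **Trajectory descriptors** — SASA-based contact areas, intra-loop
   hydrogen bonds, and per-residue RMSF from coordinate ensembles, regressed
   against folding rates.
5. **Synthetic data** — seeded generators with exact ground truth for every
   stage, so the whole pipeline is testable without laboratory data.

## Insert physicochemistry

**Masses.** The mass added by an insert is the sum of *average residue
masses* (no water term — the peptide is inserted into a chain, not free),
times the repeat count. The packaged scale carries residue masses at
2-decimal precision. This convention is deliberate: it makes concatemer
masses *exactly* linear in the repeat number at the 2-decimal reporting
precision used throughout (e.g. 4 × 469.54 = 1878.16 for SPLATx4), whereas
4-decimal masses would accumulate a 0.01 Da discrepancy at 4 repeats.

**Isoelectric points.** The net charge of a free peptide is the
Henderson–Hasselbalch sum over its ionizable groups: a free N-terminal amine
whose pKa depends on the first residue (Ser 6.93, Ala 7.59, …), a free
C-terminal carboxyl (pKa 3.55), and the seven ionizable side chains, all
using the Bjellqvist/ProtParam pKa set. The function is strictly decreasing
in pH, so the pI is the unique root; bisection on [0, 14] stops at
|charge| < 1e-4 or an interval < 0.005 pH. For inserts without ionizable
side chains (both SPLAT and AGPGA), the pI depends only on the termini and
is invariant under concatemerization. The pI is computed for the *free*
peptide with both termini — the values reported for insert panels follow
that convention.

**Hydrophobicity.** The Wimley–White *water→octanol* whole-residue transfer
free-energy scale (kcal/mol; positive disfavours octanol) is used, summed
over residues and repeats. The octanol scale — not the interface scale — is
the normative choice here because insert hydrophobicity is interpreted
against a bulk hydrophobic phase; its additivity means values scale exactly
with repeats (+0.10 per SPLAT, +3.44 per AGPGA).

**Extinction coefficients** follow the ProtParam counting rule
ε₂₈₀ = 5500·nTrp + 1490·nTyr + 125·nCystine (M⁻¹cm⁻¹). The packaged mature
OmpX sequence (2 Trp, 16 Tyr, no Cys) gives ε = 34,840 M⁻¹cm⁻¹.

**Construct building.** Each insert block is placed after the *midpoint*
residue of its loop span (after residue 54 in loop 2, after 97 in loop 3).
The exact insertion codon used experimentally in such constructs is
generally a cloning detail; the midpoint is chosen for symmetry and is a
documented package convention, not a reconstruction. Loop spans returned
with a built construct include the inserted residues, and a loop-2
insertion shifts the loop-3 span accordingly, so "rest of protein"
selections stay consistent across constructs.

## Gel densitometry

Folded OMPs resist SDS denaturation unless heated, and bind SDS
differently, so folded and unfolded species separate on semi-native
SDS-PAGE ("heat modifiability"). Densitometry of the two bands yields the
folded fraction at each quench time.

The normative chain is: **invert** (Coomassie bands are dark on a bright
background; quantification wants signal-positive polarity) →
**rolling-ball background subtraction** → **lane profile** (row sums over
the lane's columns) → **band integration** over two disjoint, half-open
pixel windows → fraction folded = F/(F + U). An empty lane (F + U = 0) is an
explicit error, never a silent zero.

The rolling-ball background is the grayscale *opening* of the image with a
ball-shaped structuring element — a spherical cap of radius 50 px by
default — implemented as a true erosion/dilation pair in compiled code, not
the paraboloid approximation some imaging tools substitute. Three
implementation details matter and are part of the package's definition of
the operation:

* **Intensity scale.** The ball's footprint lives on the pixel grid but its
  height profile lives on the intensity axis, so the intensity units must
  be pinned: the image is rescaled so its maximum maps to 65535 (the 16-bit
  convention) before the ball is rolled, and the background is scaled back
  before subtraction. A by-product is that the folded fraction becomes
  *exactly* invariant under a global gain change, which would not hold for
  a non-flat structuring element otherwise.
* **Borders.** The image is replicate-padded by one ball radius before the
  opening; without padding, the restricted structuring element
  under-follows tilted backgrounds near the edges (the lane width, 80 px by
  default, is narrower than the 101-px ball footprint).
* **Noise.** The opening of a noisy surface tracks the noise's lower
  envelope, which biases the background low and — after the subtraction is
  clamped at zero — the integrated signal high. The background is therefore
  estimated on a 3×3 box-smoothed copy of the image (standard gel-imaging
  practice) and subtracted from the unsmoothed image. The residual clamp
  bias raises the noise floor slightly; it largely cancels in the F/(F+U)
  ratio and is part of the 3%-absolute recovery tolerance quoted below.

Band windows are supplied by configuration; a peak-finding helper (two
largest local maxima at a configurable minimum separation) exists as a
convenience but manual windows are the normative path, mirroring how bands
are called in practice. Histogram-based display adjustments performed by
imaging software are subsumed by the explicit inversion + subtraction and
are not separately modelled.

On synthetic lanes with the default background (tilted plane + broad
Gaussian illumination bump) and noise (sd 150 counts ≈ 0.2% of full scale,
typical of cooled-CCD gel documentation systems), the recovered folded
fraction is within 3% absolute of the generator's truth; with noise and
background disabled there is nothing to subtract, and the chain without the
subtraction step recovers the truth to better than 1e-6.

## Folding kinetics

At high detergent-to-protein ratios OMP folding is well described by a
single exponential; the model is

$$X_F(t) = A\,(1 - e^{-kt})$$

with folding rate $k$ (min⁻¹) and yield $A$ (asymptotic folded fraction;
rapid-dilution protocols lose some protein to aggregation, so $A < 1$).

Fitting is Levenberg–Marquardt nonlinear least squares over the pooled
replicate observations (each replicate point enters the residual vector;
replicates are not averaged first). The optimizer works on transformed
parameters $(\log k, \operatorname{logit} A)$, enforcing $k > 0$ and
$0 < A < 1$ without explicit constraints, with tolerance 1e-10 on the
relative objective change and at most 500 iterations. Initialization is
deterministic and scale-free: $A_0$ from the observed plateau, $k_0$ from
the first crossing of $A_0/2$ by the per-time mean (fallback: the
reciprocal median sampling time). Observations are sorted by (time, value)
before fitting, so the result is invariant to replicate ordering.

Standard errors are asymptotic: with Jacobian $J$ of the model with respect
to $(k, A)$ at the optimum, $\widehat{\mathrm{cov}} = s^2 (J^\top J)^{-1}$,
$s^2 = \mathrm{RSS}/(n-2)$. Because it is ambiguous in practice whether
reported error bars on such fits are covariance-based SEs or
across-replicate spreads, both are computed (`tidy()` exposes the two
columns); the asymptotic SE is the headline value.

A time course with no signal at all raises a "rate unidentifiable" error —
the panel-level fitter converts this into a labelled *did-not-fold* row,
mirroring how a non-folding construct is reported. Non-convergence is
flagged on the result, not thrown.

Default simulation conditions match the assay design: sampling at
t = 0, 1, 2, 4, 8, 16, 32, 64 min (folding run to 64 min), 3 technical
replicates, Gaussian noise with sd 0.02 on the fraction scale (chosen to
visually match typical scatter of gel-derived folded fractions; values are
clamped to [0, 1] because a band-density ratio cannot leave the unit
interval). Noiseless refits of all 14 reference (k, A) pairs recover the
parameters to better than 1e-4 relative error; 200 Monte-Carlo refits at
the default noise keep the median rate within 5% of truth.

## Trajectory descriptors

Descriptors operate on supplied or synthetic coordinate ensembles (no MD is
run; multi-model PDB files are read via bio3d).

**SASA** uses Shrake–Rupley sphere-point quadrature with a *deterministic*
Fibonacci-spiral point set (960 points per atom by default, probe 1.4 Å,
Bondi-type vdW radii by element). Determinism keeps values bit-stable
across runs — there is no Monte-Carlo scatter to average away. Occlusion is
tested only against the atoms present in the evaluated subset, which is
what the contact-area definition below requires. A single isolated sphere
is reproduced within 1% at 960 points; a two-sphere overlap case matches
the closed-form lens formula within 2%.

**Contact area** between disjoint atom groups A and B is half the buried
surface area,
$\tfrac12[\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(A \cup B)]$,
each term evaluated with only the named atoms present. Trajectory viewers
compute "contact area" in tool-specific ways; this definition is chosen
because it is explicit, symmetric, and testable against independent SASA
evaluations. It is clamped at zero against quadrature noise and is bounded
above by the smaller isolated-group SASA.

**Hydrogen bonds** use the common geometric criterion: donor–acceptor
distance ≤ 3.5 Å and donor–H⋯acceptor angle ≥ 150°, both configurable.
Backbone amide N (donor) and carbonyl O (acceptor) are the default
participants — intra-loop hydrogen bonds in β-hairpin-like loops are almost
entirely backbone–backbone — with a switch to include side-chain N/O. When
a structure lacks hydrogens, backbone amide H positions are rebuilt by the
idealized bisector rule (N–H 1.01 Å, reversed bisector of the C(i−1)–N and
CA–N directions); side-chain donors are not rebuilt, a documented
limitation. "Within loop 2" counts pairs whose *both* partners lie in the
loop span (inserted residues included); same-residue pairs are excluded.

**RMSF.** Each frame is rigid-body superposed (Kabsch) onto an iteratively
refined mean structure over the alignment selection — iterate
alignment ↔ mean until the mean moves < 1e-6 Å (max 10 rounds) — then
RMSF per atom is the root-mean-square deviation from the mean, averaged
per residue. Isotropic per-coordinate jitter of sd σ has expected RMSF
σ√3; a 2000-frame toy trajectory recovers this within 5%, and a trajectory
differing only by rigid motions gives RMSF < 1e-6 Å after alignment.
Whether fluctuations are better summarized per atom or per residue is a
reporting choice; the per-atom values are attached as an attribute.

**Descriptor–rate regression** is ordinary least squares of folding rate on
a per-construct descriptor mean, reporting slope, intercept, R² and n. At
least 3 points and non-constant descriptor values are required. The
scientific claim being probed is an *inverse* relationship (more inter-loop
contact, more intra-loop hydrogen bonding → slower folding), which is a
sign property: synthetic descriptor/rate sets built with negative slope and
moderate noise recover a negative fitted slope in ≥ 95% of 500 seeded
replications.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and a seed (one
seeded stream per call; the global RNG state is untouched), and returns the
exact parameters that produced the artifact.

* **Gel lanes** (600 × 80 px, 16-bit scale): Gaussian bands along the
  migration axis (defaults: centres 200 and 400 px, σ 8 px, integrals
  7×10⁶ and 3×10⁶ giving truth fraction 0.70) over a bright smooth
  background (offset 45,000; plane tilts 3,000/1,000 counts across the
  image; broad Gaussian bump amp 3,000, σ 350 px) with Gaussian noise
  (sd 150). Which band migrates further is configurable, not normative.
  Bands closer than 3σ set an overlap warning in the truth bundle. Real
  gels add lane smile, streaking, saturation and ladder lanes — none
  emulated, so passing tests validate the densitometry *algorithm*, not
  robustness to gel artefacts.
* **Time courses**: the 15-construct reference parameter panel on the
  standard schedule, 3 replicates, sd 0.02; the non-folding construct
  produces clamped noise around zero and exercises the unidentifiability
  path. Real kinetics may deviate from single-exponential behaviour at low
  detergent ratios; that regime is out of scope by design.
* **Toy trajectories**: a backbone-like hairpin chain (4 pseudo-atoms per
  residue, 3.8 Å CA spacing, 125 residues, turn after residue 75) whose two
  arms face each other across a configurable gap, so loop 2 and loop 3 can
  be switched between touching (gap 5 Å) and separated (gap 50 Å) contact
  regimes. Frames add independent Gaussian jitter with a per-residue sd
  schedule (defaults: 0.5 Å in loops, 0.1 Å elsewhere), optionally wrapped
  in random global rigid motions. This validates the descriptor machinery
  against exact expectations; it does not emulate real protein geometry,
  membranes or LPS contacts.
* **Descriptor/rate sets**: y = slope·x + intercept + noise on an even
  descriptor grid, defaults n = 14 (the number of folding constructs).

## Numerical choices and degenerate inputs

* pI bisection: unique root by strict monotonicity; tolerance 1e-4 charge
  or 0.005 pH.
* Rolling ball: radius ≥ 1 required; a radius above half the migration
  extent warns but proceeds. Constant images subtract to exactly zero.
* Band windows: half-open [start, end), must be disjoint and inside the
  profile; overlapping windows and empty lanes are errors.
* LM fitting: descent is guaranteed (the fit is rejected in favour of the
  initialization in the pathological case where the optimizer ends above
  its start); `A` is bounded in (0, 1) by the logit parameterization, so
  clamped noisy data cannot push the yield above 1.
* SASA: n_points ≥ 92 enforced; empty groups return 0 with a warning.
* Alignment: fewer than 3 alignment atoms, or a collinear/coincident
  selection, is rejected.
* Regression: < 3 points or zero descriptor variance is rejected.
* Ties in peak finding resolve to the larger profile value first.

## Problem sizes used in the shipped checks

The test suite and reproduction script run at desk scale, chosen as the
package's own verification sizes: 600 × 80 px gel lanes (radius-50 ball),
14-construct kinetic panels at 8 time points × 3 replicates, 200-replicate
Monte-Carlo calibration of the rate estimator, 2000-frame × 500-atom RMSF
recovery, SASA oracles at 960–10,000 quadrature points, and 500-seed
regression sign-recovery runs.

## Known limitations

* The densitometry stage quantifies single lanes; gel warping, smile
  correction, molecular-weight calibration and cross-gel normalization are
  out of scope.
* Only the single-exponential kinetic family is implemented — no lag
  phases, no multi-exponential mixtures, no mechanistic aggregation model
  (yields < 1 are descriptive).
* Hydrogen placement is idealized for backbone amides only; protonation
  states are not modelled (side-chain donors require explicit hydrogens).
* The contact-area and hydrogen-bond definitions are declared package
  conventions with configurable cutoffs, selected from common practice;
  they are not reconstructions of any specific analysis tool's internals.
* Binary MD trajectory formats are not read; multi-model PDB (and the toy
  generators) are the supported ensemble sources.
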