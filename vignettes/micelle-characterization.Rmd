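---
title: "Characterizing charged peptoid micelles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing charged peptoid micelles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicelleMetrics)
```

## The system and the questions

Sequence-defined peptoid block copolymers — 25-mers with a block of five
hydrophobic *N*-decyl (DEC) residues followed by twenty hydrophilic
residues (*N*-methoxyethyl, MOE, plus one or three anionic
*N*-carboxyethyl, COE, sites) — self-assemble in water into micelles whose
aggregation number, size and shape depend on how many charges each chain
carries and where they sit along the chain. Characterizing such micelles
from simulation trajectories involves a standard battery of descriptors:
gyration-tensor shape statistics, neutron-scattering observables for
comparison with SANS, solvent-accessible surface area, and the ionic
structure around the carboxylate groups (counterion condensation,
sodium-bridged charge pairs, hydration). This package implements that
battery as reusable, tested components, and supplies a synthetic micelle
generator so each component can be validated against planted ground truth
and closed-form limits rather than against any particular trajectory.

## Shape descriptors

For a selection with positions $r_i$ and weights $w_i$, the weighted
gyration tensor is the second-moment tensor about the weighted center,

$$T = \frac{\sum_i w_i\,(r_i - c)(r_i - c)^{\mathsf T}}{\sum_i w_i},
\qquad c = \frac{\sum_i w_i r_i}{\sum_i w_i}.$$

Its ordered eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$
(nm²) are the squared principal radii, and
$R_g^2 = \lambda_1 + \lambda_2 + \lambda_3 = \operatorname{tr} T$. We
implement this second-moment ("gyration") tensor rather than the physics
moment-of-inertia tensor: only the former satisfies the
$R_g^2 = \sum_i \lambda_i$ identity that anchors the whole analysis.

Two weightings are supported. Mass weights give the conventional $R_g$;
coherent neutron scattering lengths give $R_{gb}$, the quantity a SANS
experiment actually measures. Scattering lengths may be negative (¹H is
−3.74 fm), which is legitimate in the weighted mean; when the *net*
scattering length of a selection falls below 1 fm the weighted center
becomes ill-conditioned and the package warns.

From the spectrum we compute

$$b = 1 - 3\,\frac{\lambda_1\lambda_2 + \lambda_2\lambda_3 +
\lambda_3\lambda_1}{(\lambda_1+\lambda_2+\lambda_3)^2},
\qquad
S = 27\,\frac{(\lambda_1-\bar\lambda)(\lambda_2-\bar\lambda)
(\lambda_3-\bar\lambda)}{(\lambda_1+\lambda_2+\lambda_3)^3}.$$

These normalizations are the standard ones and are pinned by their
analytic limits, which the test suite asserts exactly: a sphere
($\lambda_1=\lambda_2=\lambda_3$) gives $b = 0$, $S = 0$; a perfect
oblate ($\lambda_1=\lambda_2$, $\lambda_3=0$) gives $S = -0.25$; a
perfect prolate ($\lambda_2=\lambda_3=0$) gives $S = 2$, $b = 1$; and
over any valid spectrum $b \in [0, 1]$, $S \in [-0.25, 2]$. A uniform
solid ball of radius $R$ has $R_g = \sqrt{3/5}\,R \approx 0.775\,R$, the
relation used to compare SASA and $R_g^2$ ratios below. Degenerate
eigenvalues are ordered by a stable descending sort; tiny negative
eigenvalues from floating-point round-off are clipped to zero, while a
significantly negative eigenvalue is an error.

Micelles in periodic boxes are made whole before the tensor is formed:
each molecule is unwrapped by minimum-image chaining from its first atom,
and every molecule is then re-imaged so its center sits at the minimum
image relative to the first chain. A micelle wrapped across a boundary
would otherwise produce a meaningless $R_g$.

### The hydration-shell variant

Experimental $R_g$ values include tightly bound water, so
`analyzeFrames(..., includeShell = TRUE)` augments the selection with its
first solvation shell before computing the tensor: every water molecule
whose **oxygen** lies strictly within 0.35 nm of any selected atom. The
0.35 nm cutoff is the first minimum of the water oxygen–oxygen radial
distribution function, the conventional definition of a solvation
environment. Whole molecules are included — the oxygen decides, its
hydrogens follow — because fragmenting molecules would corrupt the
mass-weighted tensor. Whether the shell criterion should test all solute
atoms or heavy atoms only is a genuinely open convention; the default
tests all atoms, with `heavyOnly = TRUE` available.

## Neutron scattering

The route to $S(Q)$ is: element-pair partial RDFs
$g_{\alpha\beta}(r)$ (pair counts normalized by the ideal-gas shell
count, minimum image, self-pairs excluded, $r_{max}$ capped at half the
smallest box edge), combined with the Faber–Ziman weighting

$$g(r) = \frac{\sum_{\alpha\beta} c_\alpha c_\beta b_\alpha b_\beta\,
g_{\alpha\beta}(r)}{\big(\sum_\alpha c_\alpha b_\alpha\big)^2},$$

then the isotropic Fourier transform

$$S(Q) = 1 + 4\pi\rho \int_0^{r_{max}} r^2\,(g(r)-1)\,
\frac{\sin Qr}{Qr}\,W(r)\,\mathrm{d}r$$

by midpoint quadrature over the histogram bins, with the $\sin x / x$
kernel evaluated by its series limit near zero. $Q$ is reported in
Å⁻¹ (the SANS axis convention) while $r$ is handled in nm. A Lorch
window $W(r) = \operatorname{sinc}(\pi r/r_{max})$ is applied by default
to suppress truncation ripples; the raw transform is available with
`window = "none"`. The micelle-only convention is the default selection
(water never enters the structure factor; Na⁺ is excluded by default and
can be included by selection). Hydrogens carry the ¹H scattering length
by default, matching a simulation in H₂O; deuterated comparisons can be
made by editing the scattering-length table, which is an explicit,
user-overridable input.

Guinier analysis fits $\ln S$ against $Q^2$ over $Q \le 0.1$ Å⁻¹ (at
least five points) and returns $R_g = \sqrt{-3 \times \text{slope}}$; a
non-negative slope is an error signaling non-Guinier input.

One numerical note for finite bodies: $r_{max}$ should comfortably
exceed the body's diameter. With $r_{max}$ only marginally beyond the
diameter the window damps genuine pair signal and biases the Guinier
$R_g$ low by several percent; with $r_{max}$ near twice the diameter
(and a box large enough to keep the density term small) the
forward-model $R_g$ agrees with the direct tensor $R_g$ to a few tenths
of a percent, which the test suite checks at the 5% level.

## Solvent-accessible surface area

SASA follows the Shrake–Rupley point-counting construction exactly as
usually described: each atom's van der Waals sphere is inflated by the
probe radius (0.14 nm, a water-sized probe), covered with a
quasi-uniform set of test points, and a point is accessible iff it lies
outside every other inflated sphere; the per-atom area is the accessible
fraction times $4\pi(r_{vdW}+r_{probe})^2$. Design choices:

- **Radius set.** Bondi radii by default, passed explicitly and
  overridable — radius sets differ between software packages, and making
  the table an argument is the only defensible convention.
- **Deterministic points.** A golden-spiral distribution, no RNG:
  results are exactly reproducible, translation-invariant by
  construction, and rotation-reproducible to roughly 0.1–0.3% at the
  default 960 points (the fixed point set re-samples buried caps under
  rotation).
- **Solute definition.** Water and ions are excluded by default: the
  quantity of interest is the micelle's exposure to solvent. SASA per
  chain is total SASA divided by the aggregation number.
- **Periodicity.** Images are ignored; simulated boxes are an order of
  magnitude larger than the micelle.

For spherically symmetric micelles the ratio of total SASA between two
systems approximately equals the ratio of their $R_g^2$ (sphere surface
$4\pi R_H^2$ with $R_g = 0.775 R_H$); `sasaRgRatioTable()` reports both
ratios, reference system in the numerator, and their difference as a
sphericity/roughness diagnostic.

## Ionic structure

All cutoff comparisons in the package use strict `<`, uniformly. The
statistics:

- **Coordination** (`coordinationHistogram`): for each COO⁻ group and
  frame, the number of distinct partners (Na⁺ or water oxygens) strictly
  within 0.35 nm of *either* carboxylate oxygen. Counting is group-level
  (a partner close to both oxygens counts once), matching how
  coordination of "the carboxylate group" is conventionally reported.
- **Neighbor distances** (`nearestInterchainCarboxylate`): for every
  carboxylate carbon, the distance to the nearest carboxylate carbon on
  a *different* chain; same-chain carboxylates never count. Distributions
  are reported raw (unit-area histogram) and KDE-smoothed (Scott's
  bandwidth rule, overridable), smoothing being a presentation transform
  only.
- **Salt bridges** (`saltBridges`): a sodium bridges a (carbon,
  nearest-interchain-carbon) pair when it lies strictly within 0.5 nm of
  both carboxylate groups. The group reference point is the carboxylate
  **carbon** by default — consistent with the carbon-based neighbor
  analysis — with an oxygen-based variant (`site = "oxygen"`) since the
  convention is genuinely ambiguous. Fractions are pooled over frames
  (bridged records divided by qualifying records), with qualifying sets
  defined at 0.5 nm and 1.0 nm separately; because the sets differ, the
  0.5 nm fraction routinely *exceeds* the 1.0 nm one, and the
  implementation preserves that possibility rather than assuming
  monotonicity.
- **Condensation** (`condensedFraction`): the percentage of sodium ions
  strictly within 0.35 nm of any carboxylate oxygen.

## The synthetic generator

`generateMicelle()` emulates the *outcome* of micelle self-assembly, not
its physics: a compact DEC core inside an ellipsoid, hydrophilic residues
walking radially outward through a corona with realistic ~0.33 nm bead
steps, carboxylate side groups biased toward the outer surface
(`chargeSurfaceBias`, default 0.5 — charges prefer solvated positions),
one Na⁺ per carboxylate, and a 3-site explicit water shell filled by
rejection sampling with a hard 0.25 nm inter-bead floor (preventing
pathological RDF/SASA contacts; infeasible densities error out after
bounded retries). The representation is one bead per heavy group with
realistic group masses (backbone 57.05 amu, decyl 141.3, methoxyethyl
59.1; carboxylate carbon and oxygens as explicit beads; O + 2H waters),
because every analysis in scope keys on roles, masses and distances, not
bonded topology.

Planted ground truth drives validation:

- `naCondensationFraction` $f$: exactly $\operatorname{round}(f N_{Na})$
  sodium ions are placed at 0.25–0.32 nm of a carboxylate oxygen; all
  others are kept at least 0.45 nm from every carboxylate oxygen, so the
  detector must recover the planted fraction within one ion.
- `plantedSaltBridges` $k$: $k$ disjoint interchain carboxylate pairs are
  rebuilt with carbons 0.45 nm apart and a sodium ~0.39 nm from both
  carbons. Bridge sodiums are drawn from the condensation budget when it
  allows (the ion then also touches one oxygen at ~0.27 nm); otherwise
  the groups' oxygens are oriented away so the bridge ion stays
  uncondensed and the two plantings remain independent.

Defaults describe the reference study conditions: aggregation number 28
with a single chain-end charge (the `chain1` preset; presets `chain1`
through `chain8` carry the published aggregation numbers, with charge
positions marked approximate because they are only depicted graphically
in the source library), core radius 1.2 nm and corona 1.8 nm (micelle
$R_g$ of a few nm), water density 33.3 nm⁻³ (liquid water), condensation
fraction 0.1 (singly charged micelles keep ~90% of counterions
dispersed), and no planted bridges. Frames beyond the first add Gaussian
jitter (default 0.02 nm), emulating thermal fluctuation around a stable
structure — *not* conformational dynamics. Identical seeds give
byte-identical systems.

What the generator does **not** emulate: force-field energetics, chain
connectivity constraints beyond bead spacing, anisotropic corona density,
conformational transitions, or solvent structure beyond excluded volume.
Passing tests therefore demonstrate the correctness of the *measurement*
machinery on configurations with known answers, not the realism of any
particular micelle model.

`generateIdealBody()` supplies the analytic fixtures: uniform balls
($R_g/R \to \sqrt{3/5}$), rods ($\lambda_2 = \lambda_3 = 0$), flat discs
($\lambda_1 = \lambda_2$, $\lambda_3 = 0$) and ellipsoids.

## Reporting conventions

Per-frame series are summarized with a mean and a block-averaged standard
error (10 contiguous blocks by default; block averaging stays honest
under frame-to-frame correlation, and the error convention is stated
because a bare "±" is otherwise ambiguous). Quartiles and unit-area KDEs
support violin-style summaries. 2D joint densities (`jointDistribution`)
report their local maxima — candidate modes above 5% of the global
maximum, with maxima closer than one bandwidth merged, since a single
physical mode can split into adjacent grid maxima under KDE wiggle —
which is how bimodal conformational populations are detected. Pearson
correlations between $R_g$ and asphericity, shape and SASA quantify
whether size alone predicts shape. All statistics are computed on raw
values; KDE is presentation only.

`runPipeline()` chains the stages and writes a manifest (package version,
seeds, cutoffs, file list) sufficient to reproduce a run bit for bit;
stage timings go to the message log so that identical configurations
yield byte-identical outputs.

## Numerical choices and degenerate inputs

- Internal length unit is nm everywhere; PDB Å are converted on read.
  $Q$ is Å⁻¹ at the interface, converted internally.
- Residue and charge positions are 1-based in every user-facing
  structure and report, matching both R convention and chemical
  sequence numbering.
- Minimum-image distances support orthorhombic boxes only (the simulated
  boxes are cubic); triclinic cells are out of scope.
- All-zero eigenvalue spectra, all-zero weight sums, empty selections in
  a frame (reported with the frame index), missing vdW radii or
  scattering lengths (reported with the element), rMax beyond the
  half-box, and positive Guinier slopes are errors; an empty *selection
  result* is legal and only logged.
- Pair histograms use half-open bins $[lo, hi)$; a distance exactly at a
  cutoff is outside it (strict `<`).

## Problem sizes

The test suite and the benchmark script run on fixtures sized for
interactive use: spheres of $10^5$ points for the $R_g/R$ relation,
$10^5$ random spectra for the range properties, micelles of 4–8 chains
with thin hydration shells for the oracle-equivalence and
planted-recovery checks, and ~150–500-atom fixtures wherever an
exhaustive $O(n^2)$ oracle is compared bin by bin. These sizes keep the
full suite under a few minutes while leaving every check statistically
decisive.

## Known limitations

- GRO files carry no chain field; chains are recovered from per-chain
  residue-number resets, which round-trips files written by this package
  but may mis-group exotic externally produced numbering.
- The SASA rotation reproducibility floor (~0.1–0.3% at 960 points) is
  inherent to a fixed deterministic point set; raise `nSpherePoints` for
  tighter invariance.
- The scattering stage assumes an isotropic, orientationally averaged
  system; it does not model instrument resolution or absolute intensity.
- The generator plants structure geometrically; planted properties are
  guaranteed in frame 1 and preserved under the default jitter only in
  expectation for margins larger than a few jitter standard deviations.
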