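# MicelleMetrics

Structural characterization of self-assembled micelles of sequence-defined
charged peptoid block copolymers, from molecular configurations and
trajectories. The package targets the standard analysis battery applied to
ionic polypeptoid micelles — how charge number and placement along the chain
reshape a micelle — and ships a synthetic micelle generator with planted
ground truth so every stage is testable without running molecular dynamics.

## What it computes

**Shape.** The weighted gyration tensor
`T = Σᵢ wᵢ (rᵢ − c)(rᵢ − c)ᵀ / Σᵢ wᵢ` (masses or coherent neutron scattering
lengths as weights) with ordered eigenvalues λ₁ ≥ λ₂ ≥ λ₃ and
`Rg² = λ₁ + λ₂ + λ₃`. From the spectrum:

- asphericity `b = 1 − 3(λ₁λ₂ + λ₂λ₃ + λ₃λ₁)/(λ₁+λ₂+λ₃)²` — 0 for a sphere,
  1 for a rod;
- shape parameter `S = 27(λ₁−λ̄)(λ₂−λ̄)(λ₃−λ̄)/(λ₁+λ₂+λ₃)³` — bounded in
  [−0.25, 2]; −0.25 is a perfect oblate (disk, λ₁ = λ₂, λ₃ = 0), 2 a perfect
  prolate (rod), 0 a sphere.

Rg can be computed with or without the first hydration shell (water
molecules whose oxygen lies within 0.35 nm of the micelle), and with
scattering-length weighting (`Rgb`) for comparison against SANS.

**Scattering.** Partial radial distribution functions, their Faber–Ziman
neutron-weighted total
`g(r) = Σ c_α c_β b_α b_β g_αβ(r) / (Σ c_α b_α)²`, the static structure
factor `S(Q) = 1 + 4πρ ∫ r²(g−1) sinc(Qr) W(r) dr` (Lorch window by
default, Q in Å⁻¹), and Guinier-regime Rg extraction from the slope of
ln S versus Q² at Q ≤ 0.1 Å⁻¹.

**Surface.** Shrake–Rupley solvent-accessible surface area with a 1.4 Å
rolling probe, Bondi radii (overridable), deterministic golden-spiral test
points; total, per-atom and per-chain SASA, plus the SASA : Rg² ratio table
used as a sphericity diagnostic.

**Ionic structure.** Sodium and water coordination histograms of the
carboxylate groups (0.35 nm, strict `<`, either oxygen), nearest
interchain carboxylate-carbon distances, COO–Na–COO salt-bridge fractions
(sodium within 0.5 nm of both groups; qualifying sets at 0.5 and 1.0 nm),
and the condensed-counterion fraction.

**Synthetic data.** `generateMicelle()` builds coarse-grained micelles
(N chains of a 25-mer with a 5-residue hydrophobic block, one bead per
heavy group, 3-site waters, one Na⁺ per carboxylate) with a planted
condensation fraction and planted salt bridges; `generateIdealBody()`
supplies spheres, rods, disks and ellipsoids for analytic checks.

## Worked example

```r
library(MicelleMetrics)

preset <- chainPreset("chain6")            # triply charged, N = 18
spec <- SyntheticMicelleSpec(
  nChains = preset$nChains, sequence = preset$sequence,
  naCondensationFraction = 0.3, plantedSaltBridges = 2,
  nFrames = 5, waterShellThickness = 0.4, seed = 42)
sys <- generateMicelle(spec)

analyzeFrames(sys, rgb = TRUE)[, c("frame", "rg", "rgb", "asphericity", "shape")]
#>   frame     rg    rgb asphericity  shape
#> 1     1 1.9491 2.2042      0.0751 0.0186
#> 2     2 1.9489 2.2040      0.0746 0.0181
#> ...

saltBridges(sys)
#> SaltBridgeReport: 15 bridge record(s)
#>   bridged fraction (C-C_neighbor < 0.5 nm): 57.5%
#>   bridged fraction (C-C_neighbor < 1.0 nm): 17.8%
#>   condensed counterions (< 0.35 nm of COO- oxygen): 28.9%
```

The per-frame table gives the micelle radius of gyration (~1.95 nm for
this synthetic system), its scattering-length-weighted counterpart, and a
near-spherical spectrum (asphericity 0.075, shape slightly prolate). The
bridge report recovers the planted structure: the condensed fraction
(28.9%) matches the planted 0.3 within one ion, and both planted bridges
appear among the detected records.

A YAML-driven end-to-end run (`runPipeline("config.yaml", "out/")`) writes
`shape.csv`, `sasa.csv`, `rdf_total.csv`, `sq.csv`, coordination and
neighbor-distance tables, `salt_bridges.json`, block-averaged summaries,
correlations, and a `manifest.json` that reproduces the run bit for bit.
`inst/scripts/micelle-tools.R` exposes the same stages as shell
subcommands (`gen`, `shape`, `sasa`, `scatter`, `ions`, `run`).

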