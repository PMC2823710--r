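# perturbmap

Automatic, unbiased mapping of perturbed and unperturbed regions of a
protein from per-residue perturbation data and a 3D structure.

## The problem

When a protein binds a partner, a ligand, or partially unfolds, only part
of it is affected. NMR chemical shift perturbations (CSPs) from
¹H-¹⁵N HSQC spectra of the two states report on this per residue, but
turning a noisy, incomplete CSP profile into a clean set of perturbed
residues is usually done with ad-hoc cutoffs (mean + 1–2 SD), which are
subjective and ignore the structure: a residue with a small CSP sitting in
the middle of a strongly perturbed surface patch is almost certainly
perturbed too. `perturbmap` classifies every residue as **perturbed**,
**unperturbed** or **ambiguous** using both the data and the spatial
neighbourhood of each residue, with no user-chosen cutoff on the data
scale. It applies equally to protein–protein interfaces, ligand pockets
and partially unfolded states, and to any per-residue scalar (order
parameters, protection factors, ...), not just CSPs.

## The method

Each residue *i* with a datum CSPᵢ gets a confidence ρᵢ ∈ [−1, 1]
(+1 = certainly perturbed, −1 = certainly unperturbed) in four steps:

1. **Resampling attribution.** Random sub-ensembles of 15% of the data
   are drawn repeatedly; within each, the standardized score
   k = (CSPᵢ − μ)/σ of the residue's datum is mapped to an increment
   Γ(k) ∈ [−1, 1] and averaged over 100·N trials. The map Γ is clipped
   piecewise-linearly at thresholds k_high/k_low, themselves calibrated
   from ~1000·N sub-ensembles forced to contain the global extremes, so
   the largest datum gets ρ = 1 and the smallest ρ = −1 without letting
   outliers dominate the scale.
2. **Inference of missing residues.** Residues without data (prolines,
   missing assignments, exchange broadening) receive the
   inverse-distance-weighted mean of their measured neighbours' ρ within
   7.5 Å, weighted by a sigmoidal kernel
   φ(d) = 1/(1 + α_ε e^{λ(c)·d}) with φ(0) ≈ 1 and φ(c) ≈ 0; a residue
   with fewer than two measured neighbours is excluded (no decision).
   Distances are residue-barycenter distances, averaged over all models
   of an NMR-style ensemble.
3. **Homogenization.** Confidences are smoothed iteratively over the
   contact graph, each residue anchored to its own starting value:
   ρᵢ ← (ρᵢ⁽⁰⁾ + Σⱼ φ(dᵢⱼ) ρⱼ) / (1 + Σⱼ φ(dᵢⱼ)), until the RMSD between
   iterations is < 10⁻⁵. This creates spatially coherent blocks of
   similar confidence.
4. **Decision.** ρ > 0.05 → perturbed; ρ < −0.05 → unperturbed;
   in between → ambiguous. Before any of this, data whose relative
   standard deviation σ_R = σ/μ is below 25% are flagged as an
   unperturbed protein and no classification is made.

Accuracy against a reference (e.g. the crystallographic interface,
defined as residues with a backbone atom within 5 Å of the partner in at
least one model) is scored with the Matthews correlation coefficient
(MCC), and the package ships the two classical baselines (single-pass and
iterated mean + n·SD cutoffs) for comparison.

## Worked example

A synthetic 120-residue helix with a planted ~15-residue perturbed patch
(signal 5× the background noise, 10% of residues unmeasured):

```r
library(perturbmap)

ens <- syntheticStructure(nResidues = 120)          # ideal helix, 1 atom/residue
sim <- syntheticData(ens, seed = 42)                # data + ground truth
res <- mapPerturbations(ens, sim$data, mappingParams(seed = 42), verbose = TRUE)
#> sigmaR = 118.2%
#> calibration: kHigh = 1.2632, kLow = -0.4615
#> homogenization converged in 13 iterations
#> labels: ambiguous=1, perturbed=19, unperturbed=100

res
#> ClassificationResult
#>   sigmaR: 118.2%
#>   labels: 19 perturbed, 100 unperturbed, 1 ambiguous, 0 no-decision
#>   kHigh 1.2632, kLow -0.4615; 13 homogenization iterations

scorePrediction(res, sim$truth)
#> ConfusionCounts: tp=15 fp=4 tn=101 fn=0 (MCC 0.871)
```

σ_R = 118% ≫ 25%, so the data carry real signal and the guard lets the
run proceed. The calibration maps standardized scores ≥ 1.26 to full
positive confidence. All 15 truly perturbed residues are recovered
(fn = 0); the 4 false positives are residues whose background noise drew
unusually high values. `writeResults()` saves a per-residue TSV and
`writeConfidencePDB()` a copy of the structure with ρ in the B-factor
column for colouring in a molecular viewer.

Real data enter the same way: `readStructure("prot.pdb")` +
`readDataTable("csp.tsv")`, or two shift tables combined by
`computeCsp()`. A command-line front end is installed at
`system.file("scripts", "perturbmap.R", package = "perturbmap")`.

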