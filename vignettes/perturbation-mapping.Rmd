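---
title: "Mapping perturbed protein regions: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping perturbed protein regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbmap)
```

# The model

`perturbmap` answers one question: given a scalar per-residue measurement
that differs between two states of a protein (bound/unbound,
folded/partially unfolded) and the 3D structure of one state, which
residues are perturbed? The measurement is typically a chemical shift
perturbation, but nothing in the method is NMR-specific; any non-negative
per-residue scalar in which perturbed residues stand out as high values
works.

The central quantity is the per-residue confidence $\rho_i \in [-1, 1]$.
Its construction makes three assumptions worth stating explicitly:

* **Perturbation is one-sided.** High values indicate perturbation, low
  values its absence. The data must be magnitudes (the package rejects
  negative inputs).
* **Perturbation is spatially coherent.** Perturbed residues form patches
  on the structure, so a residue's neighbours carry information about it.
  This is what justifies both the inference of unmeasured residues and
  the homogenization step, and it is the assumption that fails for
  purely local effects (a single-residue chemical change).
* **The data distribution is informative but unknown.** No parametric
  form is assumed; significance is judged by resampling the empirical
  distribution itself.

## Step 1: resampling attribution

For residue $i$, repeatedly draw a sub-ensemble containing its datum plus
randomly chosen others (15% of the $N$ available data per draw), and
standardize: $k = (x_i - \mu)/\sigma$ over the sub-ensemble. The
increment
$$\Gamma(k) = \begin{cases} 1 & k \ge k_{high} \\ k/k_{high} & 0 \le k <
k_{high} \\ -k/k_{low} & k_{low} < k < 0 \\ -1 & k \le k_{low} \\ 0 &
\sigma = 0 \end{cases}$$
is accumulated over $100N$ trials and averaged, giving $\rho_i$. The
thresholds are calibrated first: over roughly $1000N$ runs, sub-ensembles
forced to contain the global maximum and minimum are drawn, and
$k_{high}$ ($k_{low}$) is the *lowest* (*highest*) standardized score the
maximum (minimum) attains. The extremes therefore map to $\pm 1$ by
construction, and because the thresholds are the least extreme scores the
true extremes ever show, outliers cannot stretch the scale for everyone
else. Sub-ensembles with zero spread are uninformative and contribute 0.

Two conventions are deliberate here. The standard deviation is the
population form ($1/n$, not $1/(n-1)$): the mean is computed from the
same small sub-ensemble, and the same convention is used everywhere else
in the package (the $\sigma_R$ guard, the baseline methods) for internal
consistency. And $\Gamma$ interpolates linearly between 0 and the
calibrated extremes — the minimal continuous choice that sends the
extremes to $\pm1$, intermediates strictly between, and degenerate draws
to 0. A step function (only $\pm1$/0) would discard the graded
information in intermediate scores.

Resampling makes $\rho$ invariant under positive affine rescaling of the
data (tested as a property), so the method needs no tuning to the data's
units — the reason there is no user-facing cutoff on the CSP scale.

## Step 2: inference of unmeasured residues

Missing data are the rule in real CSP sets (prolines, overlap, exchange
broadening). A missing residue $i$ receives
$$\rho_i = \frac{\sum_j \phi(d_{ij})\,\rho_j}{\sum_j \phi(d_{ij})}$$
over its *measured* neighbours $j$ within the cutoff $c$, where $d_{ij}$
is the distance between unweighted heavy-atom barycenters, averaged over
all models when an ensemble is supplied. The kernel
$$\phi(d) = \frac{1}{1 + \alpha_\varepsilon e^{\lambda(c)\,d}}, \qquad
\alpha_\varepsilon = \frac{\varepsilon}{1-\varepsilon}, \quad
\lambda(c) = \frac{2}{c}\ln\frac{1-\varepsilon}{\varepsilon}$$
satisfies $\phi(0) = 1-\varepsilon$, $\phi(c) = \varepsilon$ and
$\phi(c/2) = 1/2$ exactly — this algebraic form is fixed by requiring
both boundary conditions with the stated constant $\alpha_\varepsilon$
and a steepness depending only on $c$. With fewer than two measured
neighbours the interpolation would amount to copying a single residue, so
the residue is excluded and ends as "no-decision".

Inference is single-pass and uses only measured neighbours: letting
inferred values seed further inferences would make results depend on
visit order and let confidence propagate into data-free regions where
the method has nothing to say.

## Step 3: homogenization

$$\rho_i^{(t+1)} = \frac{\rho_i^{(0)} + \sum_j \phi(d_{ij})\,
\rho_j^{(t)}}{1 + \sum_j \phi(d_{ij})}$$
iterated synchronously (Jacobi-style, for order-independence) over all
non-excluded residues until the RMSD between consecutive iterates falls
below $10^{-5}$. Anchoring each residue to its *starting* confidence with
unit weight is essential: anchoring to the current value instead would
make the iteration converge to a single global consensus and erase the
very blocks the step is meant to create. With the anchor, the update is a
linear fixed-point iteration $\rho^{(t+1)} = D^{-1}(\rho^{(0)} + W
\rho^{(t)})$ whose iteration matrix $D^{-1}W$ has row sums $< 1$, so it
is a contraction: convergence is guaranteed, every iterate is bounded by
the starting extremes, and the limit equals the direct solution of
$(D - W)\rho = \rho^{(0)}$ (verified against `solve()` on small systems
to $10^{-6}$). The $10^5$-iteration cap exists only to catch a
misconfigured tolerance.

## Step 4: decision and the flat-data guard

Homogenized confidences above $+0.05$ are perturbed, below $-0.05$
unperturbed, the closed band $[-0.05, 0.05]$ ambiguous (boundary values
are ambiguous; the outer classes use strict inequalities). Ambiguous
residues typically flank perturbed regions.

Before anything runs, the relative standard deviation
$\sigma_R = \sigma/\mu$ of the measured data is checked. Below 25% the
data scatter around a common level — the signature of an unperturbed
protein — and any classification would amplify noise, so the run stops
with every residue at "no-decision". `force = TRUE` (the batch
replacement for an interactive "continue anyway?") overrides this; the
result then carries real labels and records the low $\sigma_R$, and its
`guardTriggered` flag stays `FALSE` because the flag means "the guard
stopped the run", keeping the invariant that a guard-stopped result is
all no-decision. All-zero data ($\mu = 0$) always stop the run. The
guard uses measured residues only — missing values cannot contribute to
a spread.

# Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `subsetFraction` | 0.15 | — | sub-ensemble size as a fraction of N |
| `minSubsetSize` | 3 | residues | floor so a subset can hold max + min + 1 random |
| `calibMultiplier` | 1000 | runs/datum | calibration sampling depth |
| `trialMultiplier` | 100 | trials/datum | attribution sampling depth |
| `neighborCutoff` | 7.5 | Å | barycenter distance defining neighbours |
| `epsilon` | 10⁻³ | — | sigmoid floor: φ(0)=1−ε, φ(c)=ε |
| `homogTol` | 10⁻⁵ | — | homogenization convergence RMSD |
| `decisionThreshold` | 0.05 | — | half-width of the ambiguous band |
| `sigmaRGuard` | 0.25 | — | relative-SD floor for classifiable data |
| `seed` | 1 | — | RNG seed; fixes the whole run bit-for-bit |

The defaults are the method's published operating point and are not
meant to be tuned per dataset — the resampling construction is exactly
what removes the need for dataset-specific cutoffs. The two multipliers
trade Monte-Carlo error against time: at $N \approx 100$ the defaults
mean $\sim 10^5$ calibration draws and $\sim 10^6$ attribution draws,
about half a second in the compiled core, with per-residue Monte-Carlo
error of order $1/\sqrt{100N} \approx 0.01$ — comfortably inside the
0.05 decision band.

For CSPs computed from shift tables, the spectral-width weights default
to $SW_N = 6.5$, $SW_{C\alpha} = SW_{CO} = 10$. These are typical
literature ratios, but they are a genuine sensitivity: different weights
change the CSP magnitudes and hence, mildly, the classification. They
are explicit arguments of `cspWeights()`, never hidden constants.

# The synthetic generator

`syntheticStructure()` builds an ideal α-helix (rise 1.5 Å, turn 100°,
radius 2.3 Å — consecutive-residue distance 3.83 Å, matching the real
Cα–Cα spacing) or a self-avoiding random coil (3.8 Å steps, 3.0 Å clash
floor), one pseudo-atom per residue so barycenters are fully controlled.
`syntheticData()` plants a patch: every residue within `patchRadius`
(default 12 Å) of a centre residue draws
`effectSize + |N(0, noiseScale)|`, the rest `|N(0, noiseScale)|`
(half-normal noise keeps values non-negative without truncation), and a
fraction of residues is hidden as missing. The flat control replaces all
of this with values around a unit baseline with SD `noiseScale`,
emulating an unperturbed protein; a pure half-normal with no effect
would have $\sigma_R \approx 76\%$ and could never exercise the 25%
guard, whereas noise around a common level is exactly what repeated
measurements of one state produce.

The default study conditions used throughout the tests and the
acceptance script are 120 residues, a ~15-residue patch, effect 5× the
noise scale, 10% missing data, and 20 seeded replicates — small enough
to run in seconds, large enough that patch, background and missing set
all have realistic extent.

What the generator does *not* emulate: correlated noise along the
sequence, the heavy right tail of real CSP distributions, conformational
changes that perturb residues far from the contact surface, ambiguous
assignment errors, and multi-chain complexes (interface extraction is
tested on hand-built coordinate fixtures instead). Passing the synthetic
studies therefore demonstrates the machinery — calibration, inference,
smoothing, decision — under clean, known truth; it does not certify
accuracy on any particular real system, where data quality and the
weight choice in the CSP combination dominate.

# Numerical choices and edge cases

* Residue identity is `chain:number` (insertion codes appended), so the
  data table and the structure must share author numbering; a key in the
  data absent from the structure is a hard error, not a silent drop.
* Altloc conformers resolve to highest occupancy, ties to first listed;
  hydrogens are excluded from barycenters (often absent from X-ray
  files) and from interface contacts; waters/HETATM are excluded unless
  whitelisted.
* Models of an ensemble that disagree in residue content are intersected
  (with a warning) so every model indexes the same residues.
* The neighbour test is a closed boundary ($d \le c$), making the stated
  cutoff attainable.
* Zero spread is detected as $\sigma \le 10^{-12}\max(1, |\mu|)$ — exact
  ties produce exact zeros, but rescaled data can leave rounding dust.
* Ties for the global extremes: one representative carries the extreme
  per calibration run; tied residues remain eligible as random members.
* The RMSD convergence test is evaluated after each full sweep; a
  uniform field converges in one iteration, isolated residues return
  their anchor exactly.

# Known limitations

* **Isolated high-noise residues can be selected.** A background residue
  drawing 2–3× the noise scale gets a moderately positive starting
  confidence; homogenization pulls it toward its neighbours but, with
  only ~1.2 total neighbour weight on a helix, occasionally leaves it
  just above the 0.05 cut while far from any true patch. The acceptance
  study reports this as the maximum distance of a false positive from
  the planted patch, and it is an inherent trait of the method: a
  residue whose datum is genuinely extreme *should* attract confidence
  even when spatially isolated, which is also why conformational changes
  remote from an interface are flagged on real systems. Consumers who
  want strictly patch-coherent output should post-filter perturbed
  residues by distance to the nearest other perturbed residue.
* The iterated baseline (method B) at 1σ collapses on clean synthetic
  data — successive rejection keeps lowering the threshold until much of
  the background is "perturbed" — which is precisely the bias the
  resampling construction avoids; this is visible in the benchmark MCCs
  the acceptance script writes.
* Single-pass inference leaves residues in data-free regions undecided
  by design; a structure region with no measurements anywhere stays
  blank rather than being extrapolated.
* The method assumes one data scale; mixing heterogeneous measurements
  (e.g. CSPs and protection factors) in one table is not supported.

# A minimal run

```{r example, eval = FALSE}
ens <- syntheticStructure(nResidues = 120)
sim <- syntheticData(ens, seed = 42)
res <- mapPerturbations(ens, sim$data, mappingParams(seed = 42))
table(residueLabels(res))
scorePrediction(res, sim$truth)
```
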