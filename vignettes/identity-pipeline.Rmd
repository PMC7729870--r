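---
title: "Biomolecular identification of historical remains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomolecular identification of historical remains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoid)
```

`osteoid` implements the independent biomolecular lines of evidence commonly
combined to assess the identity of historical human skeletal remains: bone
collagen quality control and dietary inference from stable isotopes,
reservoir-corrected radiocarbon calibration, ancient-DNA (aDNA)
authentication and mitochondrial consensus calling, mtDNA haplogroup
assignment, and maximum-parsimony phylogenetic placement. Each stage is an
ordinary R function; a thin orchestration layer runs them from one
configuration and emits a consolidated evidence report. This vignette
explains the models, the parameters that matter, the numerical choices, and
the limits of what the synthetic-data tests demonstrate.

## Collagen quality control and diet

Bone collagen degrades and picks up exogenous carbon (humic substances) in
the ground. The standard screen is the **atomic C/N ratio**,

$$\mathrm{C{:}N} = \frac{\%C / 12.011}{\%N / 14.007},$$

with 2.9–3.6 (boundaries inclusive) taken as the range of well-preserved
collagen. `collagen_qc()` applies this with a configurable range. A ratio
outside the range does not invalidate downstream measurements by itself, but
it must be reported alongside them, which is why the evidence report keeps
the flag rather than aborting.

The **marine dietary fraction** comes from two-endmember mixing of collagen
$\delta^{13}C$:

$$f = \frac{\delta^{13}C - \delta^{13}C_{terr}}{\delta^{13}C_{mar} - \delta^{13}C_{terr}},$$

clamped to $[0,1]$. The defaults $\delta^{13}C_{terr} = -21.0$‰ and
$\delta^{13}C_{mar} = -12.5$‰ follow the Arneborg-style convention for
human collagen; both are arguments of `diet_endmembers()`, never constants
inside the formula, because endmember choice is regionally contested and
shifts $f$ materially. Reporting rounds the ratio to one decimal and the
fraction to 0.1 percentage points, matching the precision such results are
conventionally quoted at. No trophic-level enrichment or multi-source
mixing model is attempted.

Whether a specimen "plots inside" a reference population's isotopic scatter
is usually judged by eye on a biplot. `cluster_distance()` makes the call
explicit with a **Mahalanobis distance** under the reference sample
covariance, calling the point inside when $d^2 \le \chi^2_{2}(0.95)$. This
statistic is this package's choice (a scatter plot has no formula to
reproduce) and is labelled as such in the report. It assumes an
approximately elliptical reference cloud; with $n \ge$ tens of reference
individuals the sample covariance is stable, and the test suite checks the
decision against an empirical quantile oracle.

## Radiocarbon calibration with a mixed curve

A conventional radiocarbon age $y \pm \sigma_y$ is mapped to calendar age
$\theta$ through a calibration curve $\mu(\theta) \pm \sigma_c(\theta)$,
tabulated in the standard `.14c` five-column format and interpolated
linearly in both mean and error (`read_curve()`, `curve_at()`; no
extrapolation beyond the tabulated domain).

Consumers of marine protein carry old carbon, so their effective curve is a
**diet-weighted mixture** of the atmospheric and marine curves. With marine
fraction $f$ and local reservoir offset $\Delta R \pm \sigma_{\Delta R}$:

$$\mu_{mix}(\theta) = (1-f)\,\mu_{atm}(\theta) + f\,(\mu_{mar}(\theta) + \Delta R),$$
$$\sigma_{mix}^2(\theta) = ((1-f)\,\sigma_{atm})^2 + (f\,\sigma_{mar})^2 + (f\,\sigma_{\Delta R})^2.$$

$\Delta R$ applies to the marine component only, the standard usage for the
modern marine curves. With $f = 0$ the mixture is bit-identical to the
atmospheric curve and the reservoir terms vanish exactly.

`calibrate()` evaluates, on a uniform calendar grid (default 1-year step),

$$L(\theta) \propto \frac{1}{\sqrt{\sigma_y^2 + \sigma_{mix}^2(\theta)}}
 \exp\!\left(-\frac{(y - \mu_{mix}(\theta))^2}{2(\sigma_y^2 + \sigma_{mix}^2(\theta))}\right),$$

under a flat prior on $\theta$, normalised to sum to one (checked to 1e-9).
The grid is trimmed to where $L$ exceeds $10^{-12}$ of its maximum; the
discarded tail mass is negligible by construction and trimming keeps grids
small on long curves.

The marine fraction enters as a point value by default. Because the
fraction itself is estimated, `mixed_curve_spec()` optionally takes
`marine_fraction_sigma`; the likelihood is then marginalised over
Gauss–Hermite nodes (Golub–Welsch, default 7 nodes, clamped to $[0,1]$) of
a Normal fraction distribution. This is off by default since reference
software treatments of fraction uncertainty vary and the point-value result
is the comparable one.

**HPD reporting.** `hpd_ranges()` selects grid points in decreasing density
order until the requested mass (conventionally 95.4%) is reached and merges
adjacent points into ranges, each reported with its own mass in calAD
($\mathrm{calAD} = 1950 - \mathrm{calBP}$). This greedy construction is
provably minimal-width on a grid and yields nested regions across levels;
both properties are verified by brute force in the tests. Endpoints are
reported to 1 calendar year and masses to 0.1%. Exact agreement with other
calibration programs' masses is not promised — binning and rounding differ
between implementations — and the acceptance check on the case-study date
therefore allows ±15 years on endpoints and ±1 percentage point on masses.
Whether published values were computed on a 1- or 5-year grid is typically
unstated; the tests verify that refining 5 → 1 years moves endpoints by at
most the coarse step.

The real IntCal20/Marine20 tables are not redistributable inside this
package; `analysis/02_calibration.R` uses them when the user downloads them
into `analysis/data/`, and otherwise demonstrates the engine on synthetic
curves whose posteriors have closed forms (a linear curve gives a
discretised Gaussian; a wiggly curve with a known number of likelihood
crossings gives a posterior with that number of HPD modes).

## Ancient-DNA processing

The pipeline consumes already-aligned reads in plain SAM text against a
single mitochondrial reference (read mapping, adapter trimming and duplicate
removal are upstream tools' jobs). CIGARs are resolved to per-base
`(reference position, read base)` pairs; inserted bases are dropped and
deleted positions contribute no counts, since indel consensus is out of
scope. Coordinates are 1-based; the reference is treated as linear, a
documented limitation for reads spanning the circular origin.

**Filtering** (`filter_reads()`) removes unmapped records and mapping
quality below 30 (the conventional aDNA threshold), drops reads on an
exclusion list — the pluggable stand-in for external contaminant screens
(BLASTN hits to non-human genomes, nuclear mtDNA copies) — and masks the
first and last 2 aligned bases of each read. Clipping is recorded per read
so the operation is idempotent.

**Damage profiling** (`damage_profile()`) must run *before* clipping, since
clipping removes exactly the positions being profiled. Post-mortem cytosine
deamination appears as C→T substitutions concentrated at the 5′ fragment
end, with the complementary G→A at the 3′ end in double-stranded libraries;
single-stranded libraries show C→T at both ends. For each offset from each
read end (orientation-aware: minus-strand reads are complemented and
reversed first) the profile records opportunities (reference C or G) and
hits, keeping cells with zero opportunities as undefined rather than zero.
`authenticate()` calls a library consistent with aDNA when the pooled
terminal rate at offsets 1–2 is at least 3× the pooled interior rate
(offsets 11–25, floored at a pseudo-rate of 0.005 so clean interiors do not
divide by zero) at both analysed ends, and returns *inconclusive* — not
"modern" — when terminal opportunities are scarcer than 50. The ends
analysed follow the declared library chemistry.

**Consensus** (`pileup()`, `consensus()`) runs after clipping: a position
is called with its modal base when depth ≥ 2 and the modal base holds ≥ 70%
of the depth; ties and everything else become N. The depth and fraction
thresholds are conservative defaults (tools differ and published pipelines
rarely state theirs) and are configurable. `coverage_stats()` reports
breadth (percent of positions at ≥ 1× by default, to one decimal) and mean
depth. The simulation tests verify the recovery chain: profiles match the
generator's per-offset damage probabilities within three binomial standard
errors; error-free reads reproduce the haplotype exactly at covered
positions; and 2-base clipping removes ≥ 95% of the consensus errors
attributable to terminal damage.

## Haplogroup assignment

`call_variants()` compares an rCRS-aligned consensus to the reference
position by position (substitutions only; N positions are recorded as
uncovered). The hypervariable control-region stretches whose length
polymorphisms carry no classification signal are masked by default: nps
303–315, 522–523 and 16180–16193 — keeping np 16189, a haplogroup-defining
site inside the masked stretch — plus np 16519. The mask is a data object
(`mask_policy()`), not hard-coded behaviour.

A haplogroup tree carries defining variants on its edges. For each node the
expected variant set is accumulated along the root path (later states
override earlier ones; a mutation back to the reference base removes the
site). The observed set is scored with the **Kulczynski measure**

$$s = \tfrac12\left(\frac{found}{expected} + \frac{found}{found + private}\right),$$

the published default of the standard haplogroup-calling tool; degenerate
0/0 ratios count as 1 so a reference-identical sequence scores 1 at the
root. No per-site mutation-rate weights are used — the weight-free score is
transparent and its failure modes (ties) are handled explicitly. Uncovered
positions shrink *expected* rather than counting as mismatches, the
aDNA-friendly choice: a site you could not observe is no evidence against a
clade. The consequence, verified in the tests, is that hiding a node's
distinguishing sites makes it tie with its parent; ties break toward the
deeper node, then lexicographically, so calls are reproducible. Imported
PhyloTree-style JSON trees may contain indels and back-mutation
annotations; these are dropped with a warning since only substitutions are
scored.

## Maximum parsimony

`fitch_score()` computes the minimum number of substitutions a topology
requires, summing the classic union/intersection counts over site patterns
(duplicate alignment columns are collapsed with weights). N and gaps act as
the full base set — missing data, never a fifth state. `mp_search()` offers
two modes: **exhaustive** enumeration of all $(2n-5)!!$ unrooted binary
topologies (refused above 9 taxa), with ties broken toward the
lexicographically smallest canonical newick so results are deterministic
without seeds; and **NNI**, which runs 5 random-addition stepwise starts
(orders drawn from the seed) and hill-climbs each with best-improvement
nearest-neighbour interchanges. Multiple starts matter: single-start NNI
stalls in local optima on a few percent of random panels, and the test
suite requires the heuristic to match the exhaustive optimum on ≥ 90% of
50 random six-taxon panels (it can never do better, also checked).
Alignment columns map to reference numbering through a designated reference
row (gap-aware cumulative position), so the hypervariable mask can be
applied to a panel before tree building. Bootstrap support and
likelihood/distance methods are out of scope.

## Synthetic data: what it emulates, and what it does not

The generators make every stage testable offline:

- `simulate_reference()` — uniform-composition stand-in for the 16,569-bp
  mitochondrial reference (the real reference is user-supplied).
- `fixture_haplogroup_tree()` — a fictional 24-node defining-variant tree
  whose positions are drawn outside the default mask and whose variants are
  transitions of the reference base, valid by construction on any supplied
  reference.
- `simulate_haplotype()` — applies a node's path variants plus private
  substitutions placed away from all defining sites and masked regions.
- `simulate_reads()` — truncated-normal fragment lengths (mean 60 bp,
  sd 15, minimum 25 — the typical aDNA size range), uniform start and
  strand, geometric terminal damage $p(k) = p_1 \cdot d^{\,k-1}$ (the
  simplest monotone model consistent with observed end-elevation; real
  damage curves are empirical), uniform base error, valid SAM output with
  match-only CIGARs, and a truth log of every injected event.
- `synth_curve()` / `synth_isotope_cluster()` — calibration curves with
  closed-form posteriors and bivariate-normal isotope reference clusters.

All generators are deterministic functions of their arguments and seed
(re-running with the same seed is byte-identical, which the tests assert).
They do **not** emulate: indels, mappability structure, duplicate reads,
base-quality profiles, empirical (non-geometric) damage decay, heteroplasmy
or contamination mixtures, or non-Gaussian isotope reference scatter.
Passing tests therefore demonstrate the correctness of the algorithms under
clean, known-truth conditions — not robustness to every artefact of real
ancient libraries.

## Problem sizes and defaults used by the shipped runs

The analysis scripts and tests use a 16,569-bp (scripts) or 2,000-bp
(tests) synthetic reference, 250–2,800 reads per simulation (mean depths
roughly 2–10×), 20 replicate seeds for statistical recovery properties, and
six-to-ten-taxon panels for tree search — sizes chosen so every stage's
behaviour is exercised at its real dimensionality or a faithful reduction
of it. The orchestration layer records every parameter a stage actually
used in the report's provenance blocks; reports rerun bit-identically apart
from the provenance timestamps.

## Known limitations

- The calibration engine covers single determinations only: no sequence or
  phase modelling, wiggle-matching, bomb-pulse or southern-hemisphere
  curves.
- The consensus caller is substitution-only, and the reference is treated
  as linear.
- Contamination-rate estimation and empirical damage-model fitting are not
  implemented; authentication is the terminal/interior rate comparison
  described above.
- The haplogroup caller's accuracy is bounded by the supplied
  defining-variant tree; the bundled tree is a small fictional fixture, and
  real classifications require a user-supplied PhyloTree-style file.
- Exhaustive parsimony search is exponential and deliberately refused above
  9 taxa; the NNI heuristic carries no optimality guarantee.
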