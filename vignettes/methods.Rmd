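---
title: "Methods: family-based variant prioritization and trajectory analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based variant prioritization and trajectory analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prioMD)
```

prioMD implements, as one tested pipeline, the two computational stages of a
family-based candidate-gene study in a dominant Mendelian disorder: exome
variant prioritization against a pedigree, and molecular-dynamics trajectory
analytics used to argue structural destabilization of the candidate protein.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic generators do and do
not emulate.

## Stage 1: variant prioritization

### Filtration cascade

For an autosomal-dominant model, `filterCandidates()` retains variants that
are simultaneously (a) non-synonymous, (b) heterozygous, (c) rare — minor
allele frequency at most `mafThreshold` (default 0.01, the conventional
cutoff for dominant disease alleles), where MAF is the folded frequency
min(f, 1-f) from an allele-count record, and a variant with *no* frequency
record is treated as novel and kept — and (d) carried by every member of the
`sharedIn` set, normally the exome-sequenced affecteds. The threshold is
inclusive (MAF = 0.01 passes). The cascade is idempotent and
order-preserving; `runPrioritize()` applies the same predicates one rule at
a time (synonymous, homozygous, common, non-shared, segregation) so its
decision log attributes each exclusion to the first rule that fired.

### Co-segregation with a phenocopy allowance

`assessCosegregation()` tallies, per variant, affected carriers, affected
non-carriers and unaffected carriers among typed members; individuals with
unknown affection or untyped calls contribute to no count. A variant passes
when affected non-carriers are at most `maxPhenocopies` (default 1) and
unaffected carriers at most `maxUnaffectedCarriers` (default 0). The
defaults encode the usual reading of a late-onset neurodegenerative
pedigree: one late-onset typical-presentation affected may be a phenocopy,
while any carrier among unaffecteds marks a likely polymorphism. Raising
`maxUnaffectedCarriers` models reduced penetrance; both budgets are
monotone, so loosening them can only grow the pass set.

In the packaged worked example (nine genotyped relatives, five variants),
these defaults pass four variants and fail the one carried by three
unaffected relatives; the strict setting (`maxPhenocopies = 0`) passes only
the variant carried by all five affecteds.

### Consensus deleteriousness

`classifyToolScore()` maps raw scores to each tool's own categorical
vocabulary:

| tool           | deleterious when | note                           |
|----------------|------------------|--------------------------------|
| SIFT           | score <= 0.05    | inclusive boundary             |
| PolyPhen-2     | score >= 0.447   | >= 0.909 "probably damaging" (HumDiv tiers) |
| MutationTaster | p >= 0.5         |                                |
| CADD (phred)   | score >= 15      | between the "top 10%" (10) and "top 1%" (20) tiers |
| Condel         | score >= 0.522   | published operating point      |
| GERP++         | score >= 2.0     | conservation flag, not a vote  |

The source tables never state the numeric cutoffs behind their printed
labels; the cutoffs above are community defaults chosen once, and they
reproduce every printed label in the packaged example. They are exposed
through `consensusThresholds()`. GERP++ is reported as a conservation flag
rather than a sixth vote because it measures evolutionary constraint, not
pathogenicity; its scores are validated against the published range
[-12.3, 6.17] at read time. A missing score votes non-deleterious but is
reported as `absent` rather than `benign`, and a variant with no scores at
all cannot be profiled.

`rankCandidates()` orders candidates by: segregation pass before fail, then
the lexicographic rank key (deleterious votes, conserved flag, CADD phred)
descending, then gene symbol alphabetically. The ordering is a total order,
so input permutation never changes the result. Expression evidence is
reduced to an optional local gene-to-tissue table join
(`annotateTissueExpression()`), producing a boolean report column; no web
lookups.

## Stage 2: trajectory analytics

Coordinates are in nanometres internally; PDB input (Angstrom) is converted
at the read boundary. Genomic and residue indices are 1-based.

### Observables

`kabschSuperpose()` computes the optimal rigid superposition via the SVD
construction, with the determinant correction that forbids reflections; the
test suite checks it against a brute-force search over rotation angles.
`rmsdSeries()` fits every frame to a fixed reference — frame 1 by default,
matching the common single-reference convention, with
`reference = "average"` available. `rmsfPerResidue()` superposes the
post-equilibration frames onto their time-average structure (computed by a
three-pass iterative fit, which converges immediately for near-rigid
motion), takes per-atom root-mean-square fluctuation about the mean, and
averages atoms within residues; fitting can be disabled for analytic tests.
`rgSeries()` implements the (optionally mass-weighted) radius of gyration.
`summarizeSeries()` reports mean and sample (n-1) standard deviation over
frames at time >= the equilibration cut, defaulting to half the trajectory —
mirroring the practice of analysing only the converged second half of a
production run.

`sasaStructure()` is a Shrake–Rupley implementation: test points on each
atom's probe-inflated sphere (water probe 0.14 nm), a point buried if inside
any other inflated sphere. Points come from the deterministic golden-spiral
construction, so results are bit-reproducible; 960 points per atom keeps the
isolated-sphere error well under 2% and agrees with a 3840-point evaluation
to under 1% on random clusters. Default per-element radii (N 0.155, C 0.17,
O 0.152, S 0.18 nm) are overridable.

### Essential dynamics

`buildCovariance()` removes rigid-body motion by superposing each retained
frame onto the average structure and accumulates the 3N x 3N positional
covariance with the population (1/n) normalization, so the PCA identity
"variance along PC i equals eigenvalue i" holds exactly for the projections
returned by `projectTrajectory()`. Mass-weighting multiplies coordinates by
sqrt(m). Selections are capped at 3N <= 3000 to keep the dense symmetric
eigendecomposition at desk scale; larger selections must be subset
explicitly. `principalComponents()` reports eigenvalues in descending order
and contributions as percent of the trace.

### Free-energy surface and metastable states

`freeEnergySurface()` bins two order parameters (by default Rg against
RMSD) into a `bins` x `bins` histogram (default 32, edges spanning the data
with 1e-9 padding) and Boltzmann-inverts it, dG = -kB T log(P/Pmax) with
kB = 0.0083144621 kJ/mol/K, so the most populated bin sits at zero and all
visited bins are non-negative. The normalization uses the *maximum*
probability as the reference — the only reading under which the surface has
minimum 0 — and unvisited bins are flagged NA rather than set to zero.

`countMinima()` operationalizes "number of metastable conformations", which
the source field usually judges visually: a visited bin is metastable when
it is a strict minimum over its visited 8-neighbourhood and no deeper bin
can be reached without climbing at least `depthThreshold` (default 1 kB T).
In the barrier flood, unvisited bins are treated as sitting at the visited
maximum: unsampled regions are high free energy, not impassable walls. This
drains isolated single-count outlier bins into the real basins while leaving
genuinely separated wells intact. The count is monotone non-increasing in
the depth threshold. With sparse sampling the count retains Poisson
histogram noise — a cluster split across bins can occasionally contribute an
extra shallow minimum — which is inherent to histogram-based landscapes at
a few hundred frames.

## Synthetic data

The generators exist so every stage is testable without external data, and
their defaults are fixed study conditions, not tuning knobs.

`generateFamilyDataset()` plants exactly one causal variant — heterozygous,
no frequency record (novel), carried by all affecteds except declared
phenocopies, absent from unaffecteds — among background variants whose
genotypes are Binomial(2, MAF) draws per individual, with MAF ~
Beta(0.6, 8) (a mix of rare and common polymorphisms that exercises the
frequency filter). Causal scores are drawn deleterious-side (SIFT ~
Beta(1,20), CADD ~ Normal(28,3) truncated at 0, GERP ~ Normal(5,0.5)
clipped to range, PolyPhen-2/MutationTaster ~ Beta(9,1), Condel ~
Beta(8,2)); background scores mirror them toward benign. The default family
(4 affected + 4 unaffected, 20 background variants) matches the scale of the
worked example. Scores are rounded to six decimals so TSV round-trips are
value-exact.

`generateTrajectory()` builds a random fixed-bond chain (0.38 nm, one
CA-like particle per residue) and animates it in four modes: `static`,
`harmonic` (independent Gaussian displacement with planted per-residue sd),
`hinge` (a terminal domain rotating about an axis through a pivot,
theta_t = A sin(2 pi t/T), plus isotropic noise sd 0.02 nm), and
`two_state` (switching between the compact chain and an extended
conformation — the mobile domain displaced 1 nm outward — with geometric
dwell times, emulating flexed/extended domain transitions). Each generator
consumes its own seed, and outputs are bit-reproducible.

What the generators do *not* emulate: linkage between variants, genotyping
error, population structure, and (for trajectories) bonded geometry under
motion, solvent, or realistic force-field energetics. Passing recovery
tests therefore demonstrates that the analytics extract planted statistical
structure correctly — not that the pipeline's conclusions transfer to any
particular empirical dataset.

## Problem sizes and verification

The shipped tests use 4-atom toys against the brute-force superposition
oracle, 5-atom/50-frame covariance oracles, 2000-frame harmonic
trajectories for RMSF amplitude recovery (Spearman > 0.9), 600-frame
two-state trajectories for landscape recovery across five seeds, and 20
seeded families for end-to-end planted-variant recovery. The worked-example
assertions (four co-segregating variants, one unanimous consensus candidate
ranked first, the folded control-population frequency 8.88e-5) run in well
under a second. `scripts/acceptance.R` recomputes all of these from the
installed package.

## Known limitations

- Published trajectory-level numbers from the motivating study (e.g. RMSD
  1.61 ± 0.26 nm, PC1 70%, covariance trace 237.82) depend on the authors'
  unreleased GROMACS trajectories and are not reproducible here; the
  package reproduces the printed variant tables and the algorithmic
  properties instead.
- The gene symbol RFT1 follows the printed tables; the source text also
  uses the spelling RTF1 in places.
- One genotyped relative with a borderline late examination is encoded as
  affected, as the printed genotype table lists her; with the default
  phenocopy budget this does not change the pass set.
- Genomic positions for four of the five packaged variants are synthetic
  placeholders (only gene/cDNA/protein labels are printed in the source
  tables); no computation consumes them.
- PED parsing supports the 6+1-column single-family layout; parental links
  are read but unused, since co-segregation here needs only affection and
  carrier status.
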