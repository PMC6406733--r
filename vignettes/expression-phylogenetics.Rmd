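---
title: "Phylogenetic clustering of expression time courses: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic clustering of expression time courses: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprphylo)
```

## Why a phylogeny for expression data

An expression time course is a trajectory: a population of cells starts in
one transcriptional state and moves, so later samples carry the accumulated
changes of earlier ones. Hierarchical clustering, the default view of such
data, is blind to this — it has no root and no direction. Phylogenetic
reconstruction, by contrast, is built around exactly this structure: an
outgroup fixes the ancestral state, branch lengths measure accumulated
change, and bootstrap support quantifies how firmly the data back each
grouping. `exprphylo` therefore treats samples as taxa and genes as
characters, and runs the three classical inference families — distance
(neighbor joining), parsimony, and likelihood — on the same matrix.

The package makes no claim that samples are literally related by descent
with splitting; the tree is a *clustering with a direction*. The validation
battery (below) asks the question that matters for that reading: does the
reconstructed tree recover orderings and groupings that are known to be in
the data?

## The three inference routes

**Neighbor joining** works directly on the continuous values. All genes
enter a sample-by-sample distance matrix (Euclidean by default; Manhattan
and 1 − Pearson are available). The implementation is the standard
Saitou–Nei agglomeration with the Studier–Keppler criterion; ties in the
join criterion are broken toward the lexicographically smallest index pair
so results are reproducible, and negative branch lengths — a known artifact
of NJ on non-additive data — are clamped to zero with the deficit moved to
the sibling edge, preserving the path length through the joined pair.
Euclidean distance was chosen as the default because it is the metric under
which the drift model below makes squared distance additive in time
separation, the regime in which NJ is provably consistent.

**Parsimony and likelihood** need discrete characters. Every non-outgroup
sample is expressed as a log2 ratio against the mean of the outgroup
replicates, and each gene becomes one three-state character: down
(ratio ≤ −τ), constant, up (ratio ≥ τ). Only characters in which at least
two states each occur in at least two taxa (parsimony-informative
characters) can distinguish topologies, so τ is selected to maximize their
number. The count is *not* monotone in τ — a gene pair constant at a low
threshold can become informative at a higher one — so the selection scans a
grid rather than bisecting; the default grid is 21 evenly spaced values
between the 50th and 99th percentile of |log2 ratio|, spanning "almost
nothing constant" to "almost everything constant". Ties go to the smallest
τ. The outgroup itself enters the character matrix as an all-constant taxon
(every gene is, by construction, unchanged relative to itself), which lets
the discrete trees be rooted the same way as the distance trees; the
informative-site count includes it by default and the search result records
the choice.

Parsimony scoring is Fitch's set-intersection algorithm, vectorized across
characters with bitmask state sets. Likelihood uses the symmetric
three-state Markov model — the k = 3 analogue of JC69, with stationary
frequencies 1/3, a single exchange rate, and branch lengths in expected
state changes per character, giving the closed form
P_same(b) = 1/3 + (2/3)·exp(−1.5·b) — evaluated by Felsenstein pruning
after aggregating identical character patterns. No rate heterogeneity is
modeled: with a single calibration-free threshold producing the states
there is no basis for a Gamma layer, and the model stays the clean
three-state analogue. Branch lengths are optimized coordinate-wise by
Brent's method on [0, 10] (tolerance 1e-6), sweeping all edges until a
sweep gains less than 1e-8 log-likelihood or 50 sweeps elapse; the upper
bound reflects saturation, since P_same(10) differs from 1/3 by under
3e-7 and longer branches are unidentifiable. Near-zero lengths are snapped
to exactly zero when that does not reduce the likelihood, so degenerate
edges are reported as hard zeros rather than optimizer dust.

**Tree search** for both discrete methods is either exhaustive enumeration
(≤ 9 taxa for parsimony's 135,135 topologies, ≤ 7 for likelihood where each
candidate is optimized) or nearest-neighbor-interchange hill climbing from
the NJ tree on Hamming distances. The hill climb is deterministic: it takes
the best strictly improving neighbor, and on score plateaus steps to the
first not-yet-visited equal-score neighbor (at most 20 sideways moves), a
cheap guard against the flat regions that plain NNI gets trapped in. The
likelihood search additionally climbs from the parsimony optimum and keeps
the better of the two ends — the two starts fail independently often enough
that the combination recovers the exhaustive optimum in almost all the
simulated cases the test suite checks.

## Support, ordering, and the clustering baseline

Branch support is the character bootstrap: genes (rows of the expression
matrix) or discretized characters are resampled with replacement, the tree
is re-inferred per pseudoreplicate, and each internal edge of the
point-estimate tree is annotated with the percentage of replicates whose
tree contains the same bipartition. Support is mapped onto the single
point-estimate tree rather than a consensus because that is how the trees
are read in practice — one topology with numbers above branches. 100
pseudoreplicates is the conventional default.

To compare against the field's default view, the package also builds
single- and complete-linkage dendrograms from the same distance matrix and
offers two comparison metrics: the Robinson–Foulds distance between
topologies, and a temporal-order score defined as the Kendall τ-b
correlation between each leaf's known time rank and the depth (in nodes
from the root) at which its lineage leaves the root path. A caterpillar
tree matching the time order scores 1, its reversal −1, and random
arrangements average 0. Replicates share a time rank; τ-b handles the ties,
but note the score's ceiling is below 1 whenever replicates exist, because
replicate leaves must branch at successive depths while holding one rank —
the 27-sample default simulation tops out at 0.927.

## Downstream: clades, genes, pathways

A rooted expression tree typically shows two large sister groups — in a
treatment time course, an "early" clade of not-yet-responding samples and a
well-resolved "late" clade. `split_major_clades()` takes the two children
of the root (after pruning the outgroup, which only serves to place the
root) as that split. Genes separating the clades are found either by
per-gene Welch t-tests with Benjamini–Hochberg correction (the default,
since the targeted designs carry replicates) or as synapomorphies —
genes whose discretized state is uniform within each clade and different
between them, the phylogenetically natural reading. The Welch mode needs at
least two samples per clade and suggests the synapomorphy mode otherwise.

Gene-set enrichment is deliberately simple and calibrated: the raw p per
set is the upper-tail hypergeometric probability of the observed overlap,
with the universe defaulting to the genes actually measured on the matrix
(not the union of the collection — the assay defines the background). The
adjusted p is family-wise by construction: the fraction of permuted queries
(uniform, same size, drawn from the universe) whose *minimum* raw p across
the whole collection is at least as extreme as the observed set's. Under a
null query this guarantees super-uniformity, which the test suite verifies
empirically (observed family-wise rate ≈ 3–4% at the 5% level over 500
trials).

## Drug-screen scoring

The screen module scores single-dose viability screens laid out on
384-well plates at two plating densities. The resistance score of a drug is
the ratio of mean viability signal under treatment to mean signal under
vehicle, computed per density and then averaged — densities are treated as
replicates, and a flag-free mean was preferred over requiring both
densities so a drug missing one density still gets a score. A ratio above 1
is a resistance call, below 1 a sensitization call; re-sensitization under
a knockdown arm is called when the knockdown fold change falls to 1 or
below, the mirror image of the resistance definition (a relative-drop rule
is provided for sensitivity analysis, since the symmetric rule is a design
choice, not a law). QC follows screening practice: ordinary least squares
of control-well (empty and DMSO) signal on the row-major well index pooled
across plates — any material R² flags a positional artifact — and Pearson
correlations of per-drug means between the two densities per condition. No
plate normalization is applied by default; an optional per-plate DMSO
scaling would cancel in the fold change anyway, which is the point of a
ratio score.

## What the simulators emulate — and what they do not

`simulate_time_course()` draws each gene's latent log2 trajectory as a
Gaussian random walk over the ordered time points (per-step drift SD 1 by
default), adds a late-onset shift of ±2 log2 units to a 10% subset of
"signal" genes at all ranks ≥ 4, and observes each of 3 replicates per rank
with i.i.d. Gaussian noise (SD 0.05). The random walk is the deliberate
choice: Brownian drift makes expected squared Euclidean distance grow
linearly with time separation, so the distance matrix is approximately
additive and NJ has a principled positive control. The defaults mirror a
nine-point, three-replicate treatment series of ~2000 informative probes
with a transcriptional switch midway — the design regime the method
targets. `simulate_screen()` builds well signals multiplicatively —
baseline × density factor × per-drug survival × condition multiplier ×
lognormal noise (CV 3%) — on a shared 384-well layout with scattered
empty/DMSO controls, one plate per arm/condition/density. Defaults plant
119 drugs, 71 of them resistant under treatment (multiplier 1.5 on top of
an overall 0.9 growth-slowing factor), 29 of those losing the multiplier
under knockdown, so the expected headline fractions are 60% and 41%.

What the generators do *not* emulate matters for reading the test results:
no probe-level intensity artifacts, batch effects, or missing values in the
time course; no dose–response structure, edge evaporation, or
liquid-handling streaks in the screen; and cleanly lognormal noise
throughout. Passing the validation battery therefore shows the algorithms
are correct and the workflow recovers truth *in the regime the method
assumes* — it does not certify performance on arrays with strong batch
structure or screens with systematic plate pathologies, which should be
inspected with the QC tools before trusting the calls.

## Numerical and degenerate-input conventions

Distance matrices must be symmetric to 1e-9 and are symmetrized exactly;
NJ requires ≥ 3 taxa, searches ≥ 4. All tie-breaks (NJ joins, threshold
selection, hill-climb neighbor order) are deterministic. Fold changes
refuse zero vehicle means; screens refuse negative signals at load. Genes
with zero variance in both clades get statistic 0 and p 1 rather than NaN.
Every stochastic function takes an explicit seed and restores the caller's
RNG state. Problem sizes in the test suite are chosen to keep the full
validation battery — including the 100-matrix brute-force oracle
comparisons and the 500-trial null calibration — in the low minutes on a
single core; the same checks scale up unchanged if stronger evidence is
wanted.

## Known limitations

The temporal-order score compares divergence depth, not branch lengths, so
it saturates on ladder-like trees and its ceiling depends on the replicate
structure. The three-state model ignores the magnitude of expression change
beyond the threshold, and the threshold is global — a per-gene adaptive
threshold is out of scope. NNI search is a local optimizer; the two-start
design reduces but cannot eliminate local optima, and exhaustive search is
limited to small taxon counts. Enrichment treats gene sets as flat lists
(no ontology structure, no ranked-list statistics). The screen module
scores single-dose data only; it fits no dose–response curves.
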