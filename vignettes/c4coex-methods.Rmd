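---
title: "Comparative leaf-gradient co-expression analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative leaf-gradient co-expression analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

C4 photosynthesis concentrates CO2 around Rubisco by splitting carbon
fixation between mesophyll and bundle-sheath cells. The enzymes of the core
C4 shuttle — carbonic anhydrase (CA), PEPC, NADP-MDH, NADP-ME, PPDK and the
PPDK regulatory protein — pre-exist in C3 species but are highly expressed
and tightly co-regulated only in C4 leaves, where their transcripts rise
steeply along the leaf developmental gradient from the basal sink tissue to
the photosynthetically mature tip. Genes that were recruited into the C4
pathway should therefore betray themselves through their co-expression
behaviour: they travel with the classic shuttle genes in C4 species and
behave differently (lower, reshaped, or absent) in a C3 relative.

`c4coex` implements this comparative strategy as a reusable pipeline over
per-species gene-by-section RPKM tables (several C4 grasses and one C3
reference, each leaf cut into ordered sections from base to tip), a syntenic
orthologue map, a classic-marker list and a MapMan-style functional
annotation. Because section counts differ between species, no unified
gradient is imposed; each species gets its own network, and species are
compared only through orthologue pairs and through profiles resampled onto a
common grid of relative leaf positions.

## Pipeline stages and their models

**Filtering and outliers.** A gene is kept when its RPKM exceeds 1 in
strictly more than 10% of sections. The strict inequality makes the minimum
qualifying section count equal to 2 for every gradient of 10–15 sections,
which keeps the filter consistent across species with different section
counts (`min_retained_sections()`). Sample outliers are then detected from
the section–section Pearson correlation of log2(RPKM+1) profiles: a section
whose best correlation to any other section falls below 0.6 (configurable)
is flagged and removed — the typical case being the basal-most section,
which is transcriptionally unlike the rest of the gradient. Filtering runs
once, on the full section set, and is not repeated after sections are
dropped.

**Unsigned weighted networks.** Within a species, gene similarity is the
Pearson correlation of log2(RPKM+1) profiles across sections (the log
transform is the package default; raw RPKM is available via
`transform = "none"`). The adjacency is `a_ij = |r_ij|^beta` with the
species-specific soft powers `M:10, G:12, S:18, R:16` as defaults;
`select_soft_power()` re-derives a power from the scale-free topology fit
when the defaults do not suit a new dataset. Clustering operates on the
topological overlap dissimilarity `1 - TOM`, which rewards shared weighted
neighbourhoods and suppresses single spurious correlations.

**Branch cutting.** Modules are branches of the average-linkage dendrogram,
selected by a deterministic top-down decomposition
(`min_module_size = 30` by default):

* a branch merging above the 99th percentile of all merge heights is split;
* a branch whose two children are both of module size and whose merge height
  exceeds the children's own heights by at least `min_gap = 0.15` is split
  (this separates distinct tight modules that join below the ceiling);
* otherwise the branch is accepted iff the **median of its pairwise
  dissimilarities** is at most `core_frac = 0.97` times the matrix-wide
  median — i.e. the branch is genuinely tighter than the bulk; rejected
  branches are explored further down;
* accepted branches are pruned: a member whose median dissimilarity to the
  rest of the branch lies beyond the midpoint between the branch's own
  median and the background level returns to the unassigned pool.

The decision to judge branches on pairwise dissimilarities rather than merge
heights is deliberate: average-linkage chains of unclustered genes start
from chance-tight pairs at low heights, so heights alone cannot distinguish
a chained background cluster from a real module, whereas the pairwise
medians separate the two regimes by a wide margin (about 0.5 versus well
above 0.99 of the background level on data of this shape). `core_frac` is
set to 0.97 because differential co-expression communities (below) are
genuinely weak in TOM units — their median dissimilarity sits around 0.93 of
the background level — while noise clusters stay above 0.996 in every regime
we generate; 0.97 leaves both sides a wide margin. Genes are ordered
lexicographically before clustering so dendrogram ties break reproducibly.
Unassigned genes carry the reserved label `grey`; modules are named by
colour in decreasing size order and prefixed with the species letter in all
reports (`M.turquoise`).

**Eigengenes and merging.** A module's eigengene is the first principal
component of its standardized member profiles, unit-norm, with its sign
oriented along the membership (mean correlation with members non-negative;
an exact tie falls back to a first-nonzero-positive rule). Modules whose
eigengenes correlate at or above 0.9 are merged greedily — always the
currently most-correlated pair, recomputing the merged eigengene each round;
ties prefer the larger combined module, then lexicographic order.

**Cross-species comparison.** Modules of two species are compared on the
universe of orthologue groups whose genes survived filtering in both
species; each group contributes at most one orthologue pair because the map
allows one gene per species per group. Overlaps are scored with the
one-sided hypergeometric upper tail (equivalently a one-sided Fisher exact
test for over-representation). Functional-bin enrichment of modules uses the
same tail against the expressed-gene universe of the species, with
Benjamini–Hochberg adjustment across all (module, bin) pairs;
photosynthesis-enriched ("PS") modules are those with q ≤ 0.05 for a PS bin.

**C4 modules.** Within each C4 species the C4 modules are the PS-enriched
modules that contain a classic marker gene or whose eigengene correlates at
least 0.9 with a marker-containing module's eigengene, and whose eigengene
rises from base to tip (positive Spearman correlation with the section
index) — the signature of the C4 shuttle.

**Differential co-expression.** For each C4 species versus the reference,
correlation matrices are built on the shared orthologue-group space and
combined into the change adjacency
`c_ij = (|sign(rA) rA^2 - sign(rB) rB^2| / 2)^(beta/2)` with `beta = 6`,
followed by the same TOM dissimilarity and branch cutter. An extra
sign-separation step splits each cluster by the sign of each gene's mean
correlation change summed over cluster members, so gain-of-correlation and
loss-of-correlation genes form separate modules (each sign group must still
reach the size floor). Retained modules need at least 30 genes and
`|rA - rB| > 0.7` in strictly more than 10% of within-module pairs; each
carries a direction, `higher_in_C4` or `lower_in_C4`, from the sign of the
mean pairwise change. The 10%-of-pairs rule is evaluated per module.

**Candidate typing.** The candidate pool is the set of orthologue groups
sitting in a C4 module of at least two C4 species. For each pool member the
supporting species' C4-module eigengenes, resampled onto 20 relative leaf
positions and weighted by module size, form the C4 reference pattern; the
reference species' own resampled log2 profile is correlated against it.

* **Type I** (level-shifted): pattern correlation ≥ 0.5 and tip-third mean
  expression (untransformed RPKM over the last `ceiling(n/3)` sections) at
  least 1.5-fold lower in the reference than in *each* supporting C4
  species.
* **Type II** (pattern-changed): pattern correlation < 0.5 and membership in
  retained differential modules in at least two of the three comparisons
  with the same direction. Only type II is gated on differential
  co-expression: a changed pattern should manifest as changed correlation,
  whereas a pure level shift (type I) leaves correlations untouched.
* **Type III** (reference-absent): present in all three C4 species but
  absent from the reference in the orthologue map. The classifier trusts
  the map; its evidence grade is recorded as `map-absent`, and independent
  syntenic verification is out of scope.

The types are mutually exclusive by construction (the pattern threshold
separates I from II; map absence pre-empts both). Pool members matching no
rule are reported `unclassified` with a reason; members whose reference gene
was filtered out of the expression matrix are `untestable`. There is no
manual curation step: the reviewable `unclassified`/`untestable` report
replaces it.

## The synthetic study design

`simulation_config()` encodes the four-species design the pipeline is
validated on: species M (15 sections), G (10), S (13) and the C3 reference R
(11); 2000 orthologue groups; five planted 100-gene modules at noise sd 0.3.
Latent module profiles are smooth curves over relative position t in [0, 1]:
a logistic rise (midpoint 0.6, scale 0.1) — the C4 pattern, hosting the six
markers — and Gaussian transients at centres 0.12/0.32/0.52/0.72 (width
0.08). The centres and widths were chosen so that no two module latents
exceed |r| ≈ 0.6 at these section counts; in an unsigned network a rising
and a falling latent are indistinguishable (|r| ≈ 0.97), so "falling" is
deliberately not a default module shape. A gene's log2 expression is its
group-level base (N(5, 1) for planted genes, N(3, 2) for background), plus a
small per-species jitter (sd 0.1, reflecting conserved orthologue
expression), plus amplitude times the latent, plus section-wise Gaussian
noise — i.e. multiplicative lognormal noise on RPKM, matching the log2
transform upstream.

Planted candidates sit inside the rising module: 20 type I genes whose
reference base level is divided by 2; 20 type II genes whose reference
latent is swapped to the falling shape (their pattern correlation with the
rising reference is ≈ −0.9, and their changed correlation to the conserved
rising-module genes is what the differential stage detects — an early design
with several alternative shapes was abandoned because shapes coinciding with
other planted modules' latents made the planted truth ambiguous); 10 type
III genes absent from the reference matrix and map. One differential block
per C4 species (60 genes for the first, 40 for the others) follows the
rising latent in its home species only and is plain noise elsewhere; these
blocks guarantee that every comparison carries a differential module large
enough to survive the 30-gene floor without entering the candidate pool
(they are co-expressed in only one C4 species). Orthologue coverage dropout
(10%) applies to background genes only — planted genes model conserved
photosynthesis machinery with full coverage, which also keeps background
dropouts from masquerading as type III absences. "PS" annotation is drawn at
rate 0.8 inside the rising module and 0.05 elsewhere.

`null_dataset()` destroys the named structure for type-I-error control:
independent per-gene section permutation (removes all co-expression) or
per-species orthologue permutation (removes cross-species correspondence).

**What the generator does not emulate.** Counts-level sampling noise and its
mean–variance relation, replicate structure, tandem duplicates and
many-to-many orthology, correlated module overlap (modules share no genes),
batch effects, and any bundle-sheath/mesophyll cell-type signal. Passing the
recovery tests therefore demonstrates that the pipeline's logic is correct
and well-calibrated on data of the assumed shape, not that real leaf
gradients will yield modules this clean; on real data the soft power,
minimum module size and the 0.6 outlier threshold deserve inspection before
trust.

## Numerical choices and degenerate inputs

* Correlations are clamped to [−1, 1] after `cor()` to absorb floating-point
  excursions; TOM is symmetrized explicitly.
* Zero-variance genes are an error in `build_correlation()` (they must be
  filtered first) but are excluded with a warning from eigengene
  computation; a constant section is flagged as a `degenerate` outlier.
* `resample_profile()` standardizes with the sample sd before linear
  interpolation, so ramps of different lengths agree up to the
  length-dependent standardization constant; constant profiles are an error
  surfaced as `untestable` in the classifier.
* An exactly zero mean correlation change is labelled `higher_in_C4` with a
  warning; eigengene sign ties break on the first nonzero component.
* All randomness lives in the generator and is fixed by `seed`; the pipeline
  itself is deterministic, and repeated runs are checksum-identical (run
  logs carry no timestamps).

## Validation problem sizes

The shipped checks run the default design (4 species × 2000 genes) once
end-to-end for module recovery (adjusted Rand index against planted truth,
planted genes only) and candidate precision/recall; the differential
recovery and its 20 section-shuffled null replicates use 1000 genes, the
scale at which a single 60-gene planted block is a realistic target; and
determinism is checked on an 800-gene configuration. These sizes were chosen
as the smallest at which all planted structure is comfortably above the
method's detection floors.

## Known limitations

Unsigned networks cannot distinguish activation from repression — a
deliberate scope decision, with the consequence noted above for falling
profiles. The branch cutter's background-level statistic assumes modules
occupy a minority of the network; a dataset that is mostly one tight module
would defeat it. The classifier applies the fold rule against each
supporting species (the strictest reading; a mean-based variant is a
documented alternative), and pattern similarity is a plain Pearson threshold
at 0.5 on the resampled grid — a declared constant, not a fitted one.
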