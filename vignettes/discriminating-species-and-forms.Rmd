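---
title: "Discriminating species and forms from multi-locus barcode alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating species and forms from multi-locus barcode alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodiag)
```

## The problem

Closely related planktonic copepods often differ in little besides body
size. The motivating system is the *Neocalanus* assemblage of the
Northwestern Pacific: three species (*N. cristatus*, *N. plumchrus*,
*N. flemingeri*) of which one, *N. flemingeri*, occurs as a large and a
small body-size form at a single locality. Whether such forms are
incipient species, isolated populations, or mere polymorphism is exactly
the kind of question DNA barcode data are collected to answer — and it has
to be answered twice over, because the two standard ways of reading
barcode data can disagree:

* **distance-based**: do the pairwise genetic distances between groups
  separate cleanly from the distances within groups (a "barcoding gap")?
* **character-based**: do particular alignment columns carry states fixed
  in one group and absent from the others (diagnostic characters)?

`barcodiag` implements both readings for any number of loci over a flat
set of groups (species, or species plus form), together with a simulator
that generates multi-locus datasets with a controlled divergence
hierarchy, so the whole pipeline can be exercised and power-checked
without any sequence download.

## Distances: uncorrected p with pairwise deletion

For two aligned sequences the statistic is the uncorrected proportion of
differing sites,

$$p = \frac{\#\{\text{retained columns where bases differ}\}}
           {\#\{\text{retained columns}\}},$$

where a column is *retained* for a pair only if both characters resolve to
exactly one base. Gaps and every IUPAC ambiguity code are excluded
pairwise, not alignment-wide: direct sequencing of mixed templates
(nuclear copies of mitochondrial genes, incompletely homogenised rDNA
arrays) produces sporadic double peaks that are coded as ambiguity
letters, and the safe treatment is to ignore the affected comparison
rather than to guess a base. A pair with no retained column gets an
*undefined* distance — propagated as `NA` and counted, never coerced to
zero.

```{r}
pairwise_p("ACGT", "ACGA")$p        # one mismatch over four columns
pairwise_p("ACRT", "ACGT")$n_compared  # the R column is dropped
```

Group-pair summaries (`group_summary()`, `all_group_summaries()`) report
the mean and standard deviation of p over the full Cartesian pair set for
two groups, or over all unordered pairs within a group. The SD defaults
to the sample estimator (n−1 denominator); a population-SD switch is
provided because published tables rarely state which was used. No
model correction (JC, K2P) is applied to empirical distances: at the
divergences where barcoding gaps matter (p below ~0.2) the correction is
smaller than the sampling noise, and the uncorrected statistic is the one
the field's tables print.

p-distances under pairwise deletion are not guaranteed to satisfy the
triangle inequality, because different pairs are compared over different
column sets. The package therefore never treats the matrix as a metric;
it is only ever reduced to per-category summaries and extremes.

## The barcoding gap

For a pair of groups, `barcoding_gap()` compares the largest within-group
distance (pooled over both groups — the question is whether *any*
intra-group comparison could be confused with an inter-group one) with
the smallest between-group distance:

$$\text{gap} = \min_{\text{inter}} p \;-\; \max_{\text{intra}} p,
\qquad \text{has\_gap} \iff \text{gap} > 0.$$

The decision is taken on raw distances; the histograms produced by
`mismatch_distribution()` (half-open bins $[kw, (k+1)w)$, default width
$w = 0.005$) are purely descriptive, and `has_gap` is invariant to the
binning. A value falling exactly on a bin edge belongs to the upper bin;
the implementation adds `1e-9` before flooring so that ratios like
`0.3/0.1` are not floored to the lower bin by floating-point error.

## Diagnostic characters: pure and private sites

Character-based diagnosis works on alignment columns after two filters:

1. **ambiguity filter** — any column where *any* individual carries an
   ambiguity code is deleted. A double peak in one individual makes the
   column's states uncertain for the comparison as a whole.
2. **variation filter** — a column is kept only if at least
   `min_variant_carriers` (default 2) individuals do not carry the
   column's modal base, gaps ignored. Variation seen in a single
   individual is indistinguishable from a sequencing error; requiring two
   carriers suppresses exactly that failure mode. When several bases tie
   for modal, any choice of modal base minimises the non-modal count, so
   the rule is well defined.

Each retained column is then classified per group from the set of bases
observed in that group (gaps contribute no state):

* **PURE** — the group is fixed for one base and no other group carries
  it. These are the open-box, identification-grade characters.
* **PRIVATE** — some base occurs only in this group, but not in all of
  its members.
* **NONE** — otherwise.

A group can never be both PURE and PRIVATE at one column (PURE requires
fixation, PRIVATE requires non-fixation). Column coordinates are 1-based
alignment positions, matching the way diagnostic sites are cited in
print.

`assign_specimen()` turns the PURE columns into an identifier: at every
column that is PURE for some group, the query's base votes for each group
whose diagnostic base it is compatible with (an `R` votes for a group
whose pure state is `A` *and* for one whose pure state is `G`). Gaps and
`N` span no information and cast no vote. Assignment requires a strict
plurality; ties and zero-vote queries return `UNASSIGNED` rather than a
guess. PRIVATE states are reported but never vote: they are not fixed in
the group, so their absence from a query is uninformative.

## The simulator

`simulate_dataset()` exists so that every stage above can be tested, at
the study's own scale, with known truth. `neocalanus_config()` encodes
the study design this package was built around:

* four groups on the fixed rooted topology
  `(cristatus, (plumchrus, (flem_large, flem_small)))` with sizes
  8/8/16/5 (37 specimens);
* four loci with strongly unequal divergence scales — COI (658 bp) ≫ 12S
  (500 bp) ≫ ITS (900 bp) ≈ 28S (400 bp) — whose between-group targets
  are the published mean p-distances for each group pair;
* low within-group diversity: 0.006 (COI), 0.003 (12S), 0.0005 (ITS) and
  0 (28S) expected substitutions/site. The published within-group bounds
  differ by marker (below 0.010, 0.005, 0.002 and exactly 0.000
  respectively), and the within value must also stay below the
  between-form target for the tree to be realizable, which pins the
  nuclear values near the low end of their bounds;
* sporadic two-fold IUPAC codes (R/Y/S/W/K/M) injected at 0.002 per base,
  emulating electropherogram double peaks. Double peaks are two-state
  events, so three- and four-fold codes are never injected.

### How targets become branch lengths

The six configured between-group expectations are first discounted for
the within-group contribution using the Jukes–Cantor composition rule
$p_1 \oplus p_2 = p_1 + p_2 - \tfrac{4}{3} p_1 p_2$ (each specimen sits
half its group's diversity away from the group ancestor), then decomposed
onto the five edges of the unrooted quartet by the standard three-point
formulas. Construction fails, naming the violated inequality, if the
targets are not additive on the topology, if any edge comes out negative
(e.g. forms configured deeper than the sibling-species split), or if a
between-group target is below the within-group diversity.

### Variance control

A naive per-site Bernoulli simulation realises each internal branch once
per dataset, so a recovered between-species mean distance would wobble
with standard deviation $\sqrt{p(1-p)/L}$ — about 0.014 at $p = 0.15$,
$L = 658$ — regardless of how many specimens are sampled. That noise
would swamp the fine structure the study design is about (e.g. the
0.0004 difference between two of the species pairs). The generator
therefore allocates to each internal edge its *expected* substitution
count (stochastically rounded, so expectations are exact), placed on
sites disjoint across the internal edges; specimen-level branches evolve
by unconstrained `evolve_jc()` in exact-count mode, where the number of
substitutions concentrates on the branch expectation but their placement
is free. Realised between-ancestor divergences then match the configured
targets up to rounding, while within-group variation, the mismatch
histograms and the filters still see ordinary stochastic data.
`evolve_jc()` retains a `"bernoulli"` mode for users who want the
literal independent-site process; the closed form
`jc_expected_p(d) = (3/4)(1 - e^{-4d/3})` and its inverse are exported
and serve as the recovery oracle in the tests.

### What the simulator does and does not emulate

It reproduces the divergence hierarchy, the group sizes, low intra-group
diversity on a star genealogy, and ambiguity contamination. It does not
simulate indels (gap handling is exercised with hand-built fixtures),
within-group coalescent structure, rate heterogeneity among sites,
introgression or paralogous (numt) sequences. Tests passing on simulated
data therefore demonstrate that the statistics recover a known generating
structure of this shape — not that any particular empirical dataset has
that structure.

## Numerical and design choices

* **Group keys** are `species` or `species|form` strings; all statistics
  treat them as opaque labels, so species-level analyses are just a
  relabelling (`species_level()`), not a second code path.
* **Gaps** are excluded pairwise in distances (the data are silent on
  whether a published pipeline treats them as missing or as a fifth
  state; missing is the conservative choice) and contribute no state in
  diagnostics, but a gap column is *not* deleted by the ambiguity filter
  — a deletion is not a double peak.
* **Undefined distances** propagate as `NA` with a skipped-pair count in
  every summary; they are never silently zero.
* **Assignment tie-break**: none. Anything short of a strict plurality is
  `UNASSIGNED`; a barcode identifier that guesses on ties is worse than
  one that abstains.
* **Within-group distances for the gap statistic** pool both groups, the
  stricter and more interpretable contrast; per-group histograms are
  still emitted separately by `mismatch_distribution()`.
* **Problem sizes in the test suite**: the simulation-based checks run
  the full 37-specimen, four-locus design across ten seeds, and the
  oracle comparisons use 1,000 random alignments (up to 12 sequences and
  30 columns) — sizes at which the brute-force oracles are exact and the
  whole suite completes in well under a minute.

## Limitations

* Groups are flat labels; no tree-aware (clade-hierarchical) diagnostic
  attributes, and no compound multi-column characters.
* No automatic threshold-based species delimitation (ABGD-style
  recursive partitioning); the package reports gap presence and size per
  declared grouping and stops there.
* Alignments are taken as given; nothing here aligns sequences or reads
  chromatograms. Double peaks must already be IUPAC-coded.
* Diagnostic-site coordinates are positions of the *input alignment*;
  reproducing site labels quoted from a publication requires knowing the
  primer-trimming convention behind them.
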