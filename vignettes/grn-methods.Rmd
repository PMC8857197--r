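---
title: "Methods: curation, inference and assessment of bacterial regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, inference and assessment of bacterial regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnforge)
```

`grnforge` implements a complete workflow for working with bacterial gene
regulatory networks (GRNs): assembling evidence-graded meta-curations from
heterogeneous interaction sources, inferring new interactions from
transcription-factor (TF) binding sites and from expression compendia,
integrating predictions into community networks, assessing them against gold
standards and by their structure, and classifying genes into system-level
components. This vignette explains the models behind each step, the
parameters that matter, and where the package makes a choice that the
literature leaves open.

## Evidence-graded curation

Curated interaction sources disagree in identifiers, redundancy and
reliability. The package's data model keys every interaction by the ordered
pair (regulator, target) of locus tags, compared case-insensitively, and
carries the set of supporting experiment types. Evidence is graded with a
two-level scheme: **strong** when at least one experiment demonstrates that
the TF binds the upstream region of the target (EMSA with purified protein,
in vitro transcription, DNase footprinting), **weak** when the evidence is a
hypothetical binding site (ChIP technologies) or a possibly indirect effect
(microarray, RNA-seq, RT-PCR, knockouts). `default_evidence_catalog()` ships
this mapping as a seed and is a plain named vector, so laboratories can
extend it; unknown experiment strings are an error rather than a silent
default, because mislabeled evidence contaminates the gold standard
downstream.

Merging (`merge_networks()`) unions genes and interactions; duplicate pairs
collapse to one record whose experiments and sources are unioned, whose
evidence takes the maximum grade, and whose effect resolves to `dual` when
sources disagree about activation versus repression. Merging is idempotent
and order-insensitive, and `filter_strong()` commutes with it, which the
test suite checks on randomized source families.

## The natural decomposition

The natural decomposition approach (NDA) classifies every gene of a GRN into
one of four structural classes — global regulators (GRs), modular genes,
intermodular genes and basal machinery — from topology alone.

Given a GR set, `nda_classify()` proceeds as follows. GRs and their edges
are removed; residual self-loops are discarded because self-regulation alone
creates no module structure. Genes isolated in the residual graph (regulated
only by GRs, or not at all) are basal machinery. The remaining structure is
anchored by the *regulator skeleton*: the residual subgraph induced on genes
that still regulate something. Weakly connected components of the skeleton
seed the modules; weak (not strong) connectivity is used because modules
contain non-TF targets reachable only along edge direction. Every pure
target then attaches to the components of its direct regulators: a target
regulated from a single component joins that module, while a target whose
regulators span two or more components is intermodular — its promoter
integrates the response of several modules and it belongs to none.
Anchoring components on the regulator skeleton rather than on the full
residual graph is essential: in the full graph an intermodular gene would
glue its modules into one weak component and the definition could never
fire.

Two published details of the original criterion are not available in
reproducible form, so the package substitutes documented stand-ins:

* **GR identification.** The default `elbow` strategy ranks regulators by
  out-degree and cuts at the point of maximum perpendicular distance
  between the rank–connectivity curve and its chord; the elbow point itself
  belongs to the tail. `fixed_set` injects a published GR list (the route to
  reproduce literature classifications exactly), and `threshold` applies a
  plain out-degree cutoff.
* **Submodules.** Within a module, genes that directly regulate an
  intermodular gene act as bridges; if removing them disconnects the
  module's residual subgraph, the parts are recorded as submodules. This
  captures the idea of a mega-module held together through intermodular
  genes without claiming to reproduce the unpublished derivation.

The four classes always partition the gene set, the result is deterministic,
and on synthetic scale-free networks the elbow GR set changes by at most one
element under 5% random edge removal in at least 90% of trials — all
enforced by tests.

## Binding-site inference

Regulon extension rebuilds a binding model for every trusted TF and scans
all upstream regions for further targets.

**Upstream regions** span −300 to +50 bp around the translation start
(1-based inclusive coordinates; the annotated gene start on the coding
strand), truncated so they never overlap the annotated extent of the nearest
upstream gene regardless of its strand, clipped at replicon ends, and
reverse-complemented for minus-strand genes.

**PWMs** require at least three known sites; column probabilities are
`(count + 0.1 * background) / (n + 0.1)`. The built-in motif discovery
(`discover_motif()`) is a deliberately simple information-content-maximizing
common-window search — seed words are refined by a few rescan-and-rebuild
rounds and the highest-information candidate wins. It is deterministic and
self-contained; matrices from dedicated discovery tools can be imported in
MEME minimal format (`read_meme()`) and used anywhere a PWM is accepted.

**Scanning** scores every offset of every region on both strands with
log2-odds against the background (0-order frequencies of the scanned
regions by default, switchable to uniform). The p-value of the best hit per
gene is exact under the background null: the score distribution of a random
word is computed by dynamic programming over integer-discretized scores
(granularity 10^-3 on the log-odds scale, which bounds the exactness), and
the reported p is the probability that a random word scores at least as
high. Tests verify the DP against exhaustive enumeration of all 4^w words
for widths up to 8, under uniform and skewed backgrounds. Hits pass at
p < 10^-4, the conventional single-motif threshold. Words containing
non-ACGT characters are skipped; regions shorter than the motif are skipped
with a log entry.

ChIP-supported weak interactions are statistically validated by
intersection with the motif hits (`chip_validate()`): an interaction seen by
both a ChIP experiment and an independent binding-site model is upgraded to
strong by the caller.

**Regulog transfer** (`regulogs_transfer()`) extrapolates a trusted network
across species: PWMs built from the source organism's regulons scan the
target organism's upstream regions, and predictions survive only when both
TF and target have a strict 1:1 ortholog; for redundant predictions the best
p-value wins, and the target's own strong interactions are listed ahead of
the transfers. `grn_wide_orthologs()` then restricts an ortholog map to
pairs present in both networks, the basis for cross-species comparison of
the NDA classes via the Simpson index.

## Expression-based inference

The mutual-information family is implemented natively with a TF constraint:
only TF-to-gene edges are ever emitted, because undirected dependence alone
cannot orient causality. Expression values are discretized per gene into
equal-frequency bins (`floor(sqrt(conditions))` by default, standard MI
practice) and pairwise MI is the maximum-likelihood plug-in estimate; the
estimate is invariant under any per-gene monotone transformation that
preserves discretization ranks, and constant genes get MI 0 with a warning.

* **CLR** scores a pair by how exceptional its MI is against both genes'
  backgrounds: per-gene z-scores (clipped at zero) combined as
  `sqrt(z_i^2 + z_j^2)`.
* **MRNET** selects regulators per target by greedy
  maximum-relevance/minimum-redundancy: the first pick maximizes MI with the
  target, later candidates are penalized by their mean MI with the already
  selected set, and selection stops when no candidate scores positive.

On the seeded 50-gene / 10-TF / 137-condition linear benchmark (below) both
methods reach a median AUROC of at least 0.7 over 20 seeds, and CLR's AUPR
exceeds three times the random expectation. External methods (tree
ensembles, regression with stability selection, and the like) are ingested
as rankings through `import_external_ranking()` rather than reimplemented.

## Community integration

Rank aggregation follows the wisdom-of-crowds recipe: each interaction's
community score is the mean of its 1-based rank positions across the input
lists, where a list of length L that misses the interaction contributes
L + 1. Ranks are taken after each list's own deterministic tie-breaking
(score descending, then lexicographic), making the output independent of
the order in which lists are supplied. A community of communities is just
`integrate_rankings()` applied to community lists — no special casing.
`prune_top()` truncates to the expected size of the complete network (for
the organism that motivated this package, 23,908 interactions as estimated
from network-completeness models).

## Assessment

`pr_curve()` and `roc_curve()` walk the ranked list grouping tied scores
into single curve points (no optimistic within-tie ordering) and integrate
by trapezoid. Predictions touching genes unknown to the gold standard are
removed first (`restrict_to_gold()`): the gold standard cannot judge them,
and counting them as false positives would only penalize discovery. The ROC
negative universe is every ordered TF-to-gene pair over the gold standard's
genes, where TF means a regulator *in the gold standard* — matching the
search space given to inference methods — with self-pairs included because
curated networks contain autoregulation; pairs absent from the ranking are
appended as one tied block. The resulting AUROC equals the Mann–Whitney
rank-sum statistic, which the tests verify exhaustively on all small
instances, as well as the brute-force step-function AUPR oracle.

GR predictions are scored as sets over a fixed gene universe with MCC,
precision and F1; MCC is defined as 0 whenever a table marginal is zero.
Class overlap between decompositions uses the Simpson index
`|A ∩ B| / min(|A|, |B|)`, which is 1 whenever one set contains the other —
the right behavior when comparing networks of very different completeness.

## Structural comparison

`structural_profile()` computes a fixed 15-property vector: regulator
percentage, interaction count, self-regulation percentage, maximum
out-connectivity percentage, density, weakly connected components, giant
component percentage, feed-forward circuits, complex feed-forward circuits,
3-gene feedback loops, average shortest path and diameter (undirected giant
component), average clustering coefficient (undirected simple graph), and
the adjusted R² of the P(k) and C(k) fits. Motif conventions: an FFC is an
ordered triple A→B, A→C, B→C of distinct genes; 3-feedback loops are
directed 3-cycles counted once per node set; self-loops are excluded from
motifs and clustering. "Complex FFC" has no published definition, so the
default counts FFCs with at least one reciprocated edge, behind a swappable
counter (`complex_ffc_counter`).

Degree-distribution fitting comes in two flavors. The regression route fits
a Huber-weighted robust line to the log–log complementary cumulative degree
distribution and reports `alpha = |slope| + 1` (the CCDF of `P(k) ~ k^-α`
falls with exponent α − 1). The point where the CCDF equals 1 is excluded
when at least three points remain: it equals 1 for every distribution, so it
carries no information and only bends the fit. Total (in+out) degree on the
simple graph is fitted by default, as the choice of degree is not fixed by
convention; the degree sequence is an explicit argument, so any variant can
be passed. The likelihood route (`fit_powerlaw_mle()`) fits the discrete
power law by maximum likelihood with the lower cutoff chosen by
Kolmogorov–Smirnov minimization, then compares alternatives (discrete
exponential, stretched exponential, lognormal, truncated power law) fitted
on the same tail, preferring the smallest KS distance. Scale-free GRNs are
expected to have α between 2 and 3 and, in the ultra-small-world regime,
average path lengths near `ln(ln(N))` (`ultra_small_world_reference()`).
Hierarchical modularity shows as `C(k) ~ k^-1` (`fit_ck_scaling()`).

Profiles are compared by pairwise Pearson correlation and clustered with
Ward's method on Euclidean distances between correlation rows, optionally
after min–max scaling each property (which removes the dominance of raw
size). `network_dissimilarity()` additionally implements a three-term graph
distance on the undirected simple projections: (1) the Jensen–Shannon
divergence between averaged node-distance distributions, (2) the difference
in network node dispersion (how heterogeneous each graph's own distance
distributions are), and (3) an alpha-centrality term computed on the graphs
and their complements, which discriminates size. The default weights
(0.45, 0.45, 0.1) give the size-sensitive term a small share. The measure is
0 on identical graphs, symmetric and bounded in [0, 1]; unreachable pairs
occupy a dedicated distance bin.

## The synthetic test bed

Every module is exercisable without downloads through `synth_config()` and
four generators, all pure functions of (config, seed):

* `sample_grn()` draws TF out-degrees from a discrete power law (default
  exponent 2.5, within the 2–3 scale-free band) and attaches targets
  preferentially, yielding fat-tailed degree structure; evidence labels are
  strong with configurable probability (default 0.3 so that regulons keep
  at least three strong members often enough to build PWMs).
* `simulate_expression()` is a linear structural-equation model: root genes
  draw standard-normal values, regulated genes sum signed weighted parental
  values (weights Uniform(0.5, 1.5), signs from the annotated effects) plus
  Gaussian noise (default SD 0.5). Incoming weights are scaled by
  1/sqrt(in-degree) and the coupling matrix is rescaled if its spectral
  radius reaches 0.95, so the stationary distribution exists even with
  feedback loops; the stationary system is solved directly, with damped
  fixed-point iteration retained as a fallback for near-singular systems.
  The default 137 conditions mirror the size of a typical one-organism
  public compendium.
* `plant_genome()` lays the genes on one replicon with 1200 bp spacing (so
  upstream windows are full-length), fills i.i.d. background at the
  configured GC content (default 0.5; set 0.72 for a high-GC actinomycete),
  builds one PWM per TF at the configured information content (default 1.5
  bits/column, the regime where single-genome motif discovery is expected
  to work), and embeds one sampled site per true target at a random offset
  and strand, recording the truth.
* `make_ortholog_pair()` deletes a random gene fraction from a relabelled
  copy and returns the surviving 1:1 map.

What the generators deliberately do **not** emulate: operon structure,
sigma-factor competition, condition-dependent regulation, overlapping genes
(so upstream truncation is exercised by dedicated unit fixtures instead),
and nonlinear kinetics. Passing tests on this bed demonstrate that the
machinery recovers known structure under the stated statistical model; they
do not certify performance on real compendia, where indirect effects,
batch structure and incomplete gold standards dominate.

## Problem sizes and determinism

The shipped validation suite uses networks of tens to a few hundred genes,
2000-observation degree sequences for fit recovery (20-seed medians), the
50-gene expression benchmark over 20 seeds, and 50 planted-motif replicates
— sizes at which every statistical property under test is already stable
and the whole suite runs in a couple of minutes. All randomness flows from
explicit seeds; pipeline recipes (`run_recipe()`) fan a single top-level
seed out per stage and re-running any recipe over unchanged inputs is
byte-identical.

## Known limitations

* The GR elbow criterion and the submodule rule are documented stand-ins;
  use `fixed_set` with a published GR list when reproducing literature
  classifications.
* Exact p-values are exact with respect to the 10^-3-discretized score, the
  0-order background, and a single-word null; very long motifs (beyond ~25
  columns) make the DP table large.
* The MI estimator is the plug-in estimate on equal-frequency bins; no
  bias correction is applied, which is harmless for ranking but biases
  absolute MI upward at small sample sizes.
* CLR/MRNET see only linear-model synthetic data in the tests; on real
  compendia their relative performance depends on normalization and batch
  structure, which are upstream of this package.
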