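---
title: "Consensus plastid-targeting prediction and gene-family conservation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus plastid-targeting prediction and gene-family conservation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidfam)
```

## The problem

Most plastid proteins are nuclear-encoded and reach the organelle through an
N-terminal chloroplast transit peptide (cTP) that is cleaved on import.
Whether a protein carries a cTP can be predicted from sequence, but
individual predictors disagree, their error rates differ between monocots
and eudicots, and experimental "truth" itself depends on the assay: GFP
fusions are specific but low-throughput, while mass-spectrometry organelle
proteomics is sensitive but contamination-prone. `plastidfam` implements a
workflow for working at genome scale despite this: benchmark predictors
against experimentally labelled proteins, combine them into k-of-n consensus
rules, apply the best consensus across whole proteomes, cluster the
proteomes into gene families, and ask in which families plastid targeting is
conserved across species, confined to a clade, or unique to a single species
(nascent plastid-targeted proteins, NPTPs).

## Classification statistics and their conventions

All evaluation is binary (plastid vs non-plastid). Four statistics are
computed from a confusion matrix $(tp, fp, tn, fn)$:

$$SE = \frac{tp}{tp+fn}, \qquad
  SP = \frac{tp}{tp+fp}, \qquad
  ACC = \frac{tp+tn}{tp+fp+tn+fn},$$

$$MCC = \frac{tp \cdot tn - fp \cdot fn}
  {\sqrt{(tp+fn)(tp+fp)(tn+fn)(tn+fp)}}.$$

Note the **specificity convention**: in the cTP-prediction literature
"specificity" is $tp/(tp+fp)$ — the positive predictive value — not the
conventional true-negative rate. `classification_stats()` reports this
quantity as `sp_precision` and also exposes the conventional $tn/(tn+fp)$ as
`sp_conventional`, so the two can never be silently confused. MCC is the
primary ranking statistic because the benchmark classes are heavily
imbalanced (a few hundred plastid proteins against thousands of
non-plastid ones).

Degenerate matrices arise constantly during exhaustive workflow sweeps
(e.g. a 5-of-5 rule that calls nothing positive). Rather than abort, any
statistic with a zero denominator is defined as 0 and the row is flagged
`degenerate`; this keeps sweeps total and the convention is visible in the
output.

## k-of-n consensus workflows

A workflow is a non-empty predictor subset $S$ with a threshold
$m \in 1..|S|$; a protein is called plastid-targeted when at least $m$
members of $S$ agree. `enumerate_workflows()` generates all
$n \cdot 2^{n-1}$ of them (80 for a five-predictor panel), and
`evaluate_workflows()` scores each against a label table and ranks by MCC,
with deterministic tie-breaking (accuracy, then sensitivity, then
enumeration order) so ranking tables are reproducible. Stratified
evaluation (monocot vs eudicot, GFP vs MS evidence) repeats the sweep per
stratum and appends difference rows for two-level stratifications.

```{r workflows}
wf <- enumerate_workflows(c("TargetP", "Localizer", "Multiloc2"))
nrow(wf)
head(wf, 4)
```

The genome-scale rule used downstream is the 2-of-2 TargetP + Localizer
consensus (`consensus_targeting()`), a workflow chosen for its combination
of precision and practicality: it is equivalent to
`apply_workflow(c("TargetP", "Localizer"), 2, calls)`.

## Reconstructing confusion matrices from printed statistics

Published evaluations often print only rounded SE, SP and class sizes.
`reconstruct_confusion()` inverts them: $tp = \mathrm{round}(SE \cdot
n_{pos})$, predicted positives $= \mathrm{round}(tp / SP)$, the rest by
subtraction, all half-up. Because the printed inputs are rounded, the point
estimate can miss the original matrix by a count or two, occasionally
flipping the last printed digit of MCC or ACC. With `envelope = TRUE` the
function therefore also enumerates *every* $(tp, tp+fp)$ pair consistent
with the printed SE/SP at the stated precision and returns the attainable
MCC and ACC ranges. This replaces a simpler $tp \pm 1$ probe, which we
found too narrow: for one published monocot/eudicot benchmark row the
printed MCC/ACC are attainable only at the edge of the rounding bands, a
case the envelope detects and the $\pm 1$ probe does not.

```{r reconstruct}
r <- reconstruct_confusion(0.62, 0.71, n_pos = 161, n_neg = 640,
                           envelope = TRUE)
r$cm
round(r$stats$mcc, 3)
round(r$mcc_range, 3)
```

## Gene-family clustering

Two deliberately different clustering methods are implemented; agreement
between them on the same proteomes is itself a useful robustness check.
Both allow many-to-many relationships — no Markov-clustering paralog
splitting — because polyploid plant genomes make one-to-one orthology the
wrong model.

### Modified reciprocal-best-hit clustering

1. **Inter-species edges**: for every ordered species pair, hits are
   filtered at identity and coverage *strictly above* 40% (the method keeps
   hits whose parameters *exceed* the threshold), each query's best
   surviving hit is taken (bit score, ties by identity, then lexicographic
   target id), and an edge is kept only for mutual best hits
   (`reciprocal_best_pairs()`).
2. **Intra-species edges**: each proteome against itself, keeping pairs at
   $\ge$ 90% identity and coverage that are reciprocal within each other's
   first 10 hits (`intra_species_better_pairs()`). This links recent
   paralogs without letting distant ones bridge families.
3. **Merging**: clusters are connected components of the union of both
   edge sets; untouched proteins become singletons (`merge_components()`).
4. **Trimming**: in clusters containing at least one plastid-predicted
   member, members lacking a hit at $\ge$ 40% identity and coverage to any
   plastid member are removed (`trim_cluster()`); clusters with no plastid
   member pass through unchanged, flagged.

Coverage is computed from alignment spans and sequence lengths (the
tabular hit format does not carry it); both query and target coverage are
computed and the filter applies to **both** by default, with a query-only
option, since the original method does not state which it used. The 40%
filters are strict inequalities ("exceeded 40%") while the 90% and
trimming filters are inclusive ("at least" / "exceeding ... 90%" read as
$\ge 90.0$); both are configurable.

### Greedy-centroid clustering with random reseeding

The greedy method scans sequences longest-first; each sequence joins the
first existing centroid it matches at the current thresholds, else founds
a new cluster (`greedy_pass()`; first-match is the documented behaviour of
the original tool, a best-identity mode is available). The initial pass
runs at 40% identity and 40% query coverage. Greedy scans fragment
families — a long outlier that becomes a centroid can capture part of a
family while the rest founds separate clusters — so the method is
iterated: each of `iterations` (100 by default; most healing happens
within about ten) reseeded passes draws one random member per initial
cluster, prepends the length-sorted seeds to the length-sorted full list,
and re-clusters at 90% identity with both coverages at 40% (the target
coverage bound stops short seeds from absorbing much longer sequences).
Clusters sharing any member across runs are merged by connected
components, so the merged cluster count is non-increasing in the number of
iterations, and merging is independent of run order. One global seed
drives all reseed draws (`iterative_cluster(..., seed = )`), making runs
bit-reproducible.

Pairwise similarity uses a semi-global (free-end-gap) alignment under a
fixed simple scheme — match +1, mismatch −1, gap open −2, gap extend −1 —
with identity defined as matching columns over alignment columns
(`pairwise_identity()`). A numerical consequence worth knowing: below
roughly 50% true identity the optimal alignment under this scheme
collapses to short high-scoring patches, so reported identity tracks true
identity faithfully only in the $\gtrsim$ 0.55 regime, and the coverage
thresholds are what reject dissimilar pairs. This is acceptable for
clustering (decisions near the 40% threshold are made on coverage as much
as identity) but it is why the package's clustering tests use families
separated well away from the threshold. Alignments are memoised across
reseeded passes, which is what makes 100 iterations affordable: after the
first expansion pass, subsequent passes are almost entirely cache hits.

## Conservation classification

After clustering, every protein carries a consensus plastid flag and each
cluster a per-species profile (`build_profile()`). Categories are assigned
in order (`classify_cluster()`):

1. **discarded_single_species** — clusters (including singletons) drawn
   from one species; likely gene-prediction artifacts.
2. **conserved** — at least 13 of 15 species present, at least one plastid
   member somewhere, and *every* present species either has a plastid
   member or carries at least 4 non-plastid members. The 4-member
   exemption compensates for the consensus predictor's ~39% false-negative
   rate: a species represented by several homologs of a conserved plastid
   protein that all lack a positive call is far more likely a prediction
   failure than a real loss of targeting.
3. **semi_conserved** — plastid targeting confined to one taxonomic group,
   assigned at the *smallest* qualifying level (family before subclade
   before clade): at least 2 species with plastid members inside the
   group, no plastid member outside it, and no outside species reaching
   the 4-member exemption (such clusters are conservatively removed, since
   the outside species may simply be under-predicted). The outgroup
   (Amborella), a single-species clade, instead requires at least 2
   plastid sequences.
4. **nptp** — at least 3 species present and exactly one with plastid
   members: a candidate recent transit-peptide gain.
5. **unclassified** otherwise.

All counts refer to the post-trimming cluster membership. The parameters
(13 species, 4-member exemption, 2 clade species, 3 NPTP species, 2
outgroup sequences) are exposed in `classification_params()`. Two
monotonicity properties are worth stating precisely, because the exemption
acts in opposite directions: raising the exemption count makes per-species
qualification *stricter*, so conserved counts are non-increasing in it,
while it weakens the outside-clade disqualifier, so semi-conserved counts
are non-decreasing. The conserved definition follows the "at least four"
reading of the rule (a "at least three additional" variant also appears in
the literature); the parameter is exposed for either.

## The synthetic-data generator

Real inputs for this workflow are fifteen proteomes, curated localization
databases and predictor binaries — none desk-scale. The generator
(`simulate_corpus()`, `simulate_calls()`, `simulate_hit_table()`) instead
produces data with exactly the statistical structure the pipeline assumes:

* **Families**: an ancestral sequence per family (length uniform on
  150–800, starting with methionine), per-species orthologs mutated to a
  target identity (substitutions only, count fixed by the target, so
  realised identity is within one substitution of it), and paralogs
  duplicated from the species ortholog at 97% identity.
* **Paralogy is scenario-dependent by default**: conserved families
  receive Poisson(6) extra copies per species, other scenarios none. This
  mirrors the observed structure of real angiosperm data — conserved
  plastid-targeted clusters are paralog-rich (on the order of a hundred
  sequences over fifteen species) while clade- and species-restricted
  multi-species clusters are small — and it is not incidental: the
  4-member false-negative exemption only functions as designed in
  paralog-rich families, and with a single global paralog intensity the
  exemption that rescues conserved families under realistic call error
  would equally misfile large clade-specific families as conserved. The
  default is a scientific statement about which regime the classifier is
  meant for, not a tuning knob.
* **Truth and calls**: targeting truth follows the scenario
  (conserved / clade-specific / species-unique / non-plastid); predictor
  calls are independent Bernoulli draws at given (SE, FPR). Published
  precision-style SP is converted to an FPR at a stated prevalence by
  `fpr_from_precision()`, since precision is not a generative parameter.
* **Hit tables**: within-family pairs at their realised Hamming identity
  with full coverage, bit scores monotone in identity × length, ranks
  consistent with scores, plus optional spurious cross-family hits at low
  identity.

What the generator deliberately does **not** emulate: insertions and
deletions (identities are realised by substitution only), transit-peptide
sequence composition (targeting exists only as a truth flag — the pipeline
consumes predictor *calls*, never the cTP sequence itself), amino-acid
compositional bias, correlated predictor errors, and cross-family homology
gradients. Tests passing on this generator therefore demonstrate
correctness of the algorithms under the stated statistical model, not
robustness to annotation noise, fragmented gene models, or predictors
whose errors are correlated — all of which real data have.

## Numerical choices and problem sizes

* Half-up rounding throughout `reconstruct_confusion()`.
* Strict `>` for the 40% RBH filter, inclusive `>=` for the 90% expansion
  and trimming filters; best-hit ties broken by bit score, then identity,
  then lexicographic id.
* Ambiguous residue X never counts as an alignment match.
* Zero-denominator statistics return 0 with a `degenerate` flag.
* Cluster ids are assigned by first-member order, so partitions are
  deterministic functions of their inputs.
* The test-suite and acceptance-script simulations are sized for a desk
  machine: corpora of 5–8 species and 6–12 families for alignment-based
  clustering (tens of sequences, lengths 120–250), 200 families over the
  full 15-species taxonomy for classification (about 6,000 sequences), 100
  randomized instances per brute-force cross-check, and 3,000 simulated
  proteins for the six-predictor workflow sweep. The reseeded clusterer is
  exercised at 3–10 iterations in tests; the 100-iteration default matches
  the reference protocol and remains practical at these scales thanks to
  alignment memoisation.

## Known limitations

* The greedy clusterer is a faithful desk-scale model of centroid
  clustering, not a re-implementation of the original tool's k-mer
  heuristics; it will not scale to hundreds of thousands of sequences.
* Identity from the fixed simple scoring scheme is distorted below ~50%
  (see above); thresholds in that region are effectively
  coverage-driven.
* The semi-conserved rules inherit the published method's asymmetry: a
  family whose plastid targeting is real in two clades but predicted in
  only one will be filed as semi-conserved, and paralog-rich
  clade-specific families are conservatively removed rather than
  reassigned.
* Evidence-class handling (GFP vs MS vs both) is a stratification of the
  label table; the package does not attempt to model assay error itself.
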