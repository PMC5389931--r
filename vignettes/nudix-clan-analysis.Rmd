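---
title: "Methods: confidence scoring, tree partitioning and function-on-phylogeny analysis for the Nudix clan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confidence scoring, tree partitioning and function-on-phylogeny analysis for the Nudix clan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nudixevol)
```

The Nudix homology clan is an old, functionally diverse superfamily:
hydrolases of nucleoside diphosphate derivatives, isopentenyl diphosphate
isomerases, A/G-specific adenine glycosylases and several non-enzymes share
a ~130-residue domain despite pairwise sequence identities that can fall
near 11%. Studying how function evolved across such a clan raises four
methodological problems that this package addresses: experimental evidence
of very unequal quality must be made comparable; phylogenies with tens of
thousands of leaves must be broken into alignable pieces; piecewise
alignments must be recombined without corrupting them; and statements such
as "this function is monophyletic" or "this function was plausibly present
in the last universal common ancestor" must be made operational on an
annotated tree. This vignette describes the models and procedures, the
parameters that matter, and the design decisions taken where more than one
reasonable choice existed.

## The confidence-score model

Each protein–function annotation is scored in [0, 1] from its experimental
records, split into a *genetic* category (knockout/knockdown phenotypes,
cross-species rescue) and a *biochemical* one (kcat/Km, substrate screens,
qualitative assays), reflecting the independence of physiological and
in-vitro measurements.

**Kinetic anchors.** kcat/Km values (M⁻¹s⁻¹) of 10³…10⁷ anchor scores
0.1, 0.2, 0.5, 0.85, 0.99; intermediate values interpolate linearly in
log10, so 5×10⁶ scores (log10(5×10⁶) − 6) × 0.14 + 0.85 = 0.948. Zero
activity scores 0.01. Pseudo-kcat/Km estimates — derived from a
relative-activity screen by scaling a reference substrate's measured
kcat/Km with the *squared* activity ratio, a deliberately conservative
nonlinearity — use a lower anchor set (0.05…0.7). Screens with no kinetic
reference score linearly from 0 to 0.1 at 100% relative activity.
Qualitative evidence uses fixed scores: gel electrophoresis for rarely
screened substrates 0.5, gel/HPLC for common substrates 0.05, an X-ray
structure with substrate for a binding reaction 0.5, with a turned-over
substrate 0.01, and bare positive-activity data 0.01.

**Combination.** Category scores are per-category maxima (the single
strongest experiment wins); the overall score is the noisy OR
`S_overall = 1 − (1 − S_genetic)(1 − S_biochem)`, and a missing category
contributes 0, so the overall score degrades gracefully to the other
category's score. Finally, each protein's set of overall scores is
Z-standardised and adjusted — `1 − (1 − S)/(1 + |Z|)` above the mean,
`S/(1 + |Z|)` below, unchanged at Z = 0 — so that one strong function among
many weak screens gains confidence. The adjustment is monotone in S, hence
rank-preserving.

**Decisions.** The published score table and the accompanying prose
disagree in two places: cross-species rescue is listed at 0.5 in the table
but 0.7 in the text, and the HPLC/X-ray qualitative scores are swapped
between the two. The consolidated table is taken as the default in both
cases, and every constant is overridable via `score_table()` or a YAML file
(`read_score_config()`), so either reading is available. The standard
deviation in the Z-score is the population SD (divide by n): the
adjustment is over the *complete* set of a protein's annotated functions,
not a sample from it, and population SD keeps the two-annotation case
stable; `sd_type = "sample"` is available. With SD = 0 (a single
annotation, or identical scores) all Z are defined as 0 and scores pass
through. Nonzero kcat/Km below 10³ clamps to the bottom anchor score (0.1)
and values above 10⁷ clamp to 0.99 — monotone and bounded without
inventing anchors the model never stated. Relative activities above 100%
(screens whose best substrate was redefined midway) are clamped to 100 with
a warning.

## The tree partitioner

To align a clan of tens of thousands of domains, the guide tree is
partitioned into tight clades that are aligned separately and then merged.
A subtree qualifies as tight when its mean pairwise (patristic) distance
falls below a percentile threshold of the whole-tree distance
distribution. Computing that distribution exactly is O(n²) in time and
memory; instead, one post-order pass computes for every node its leaf
count, the summed node-to-leaf distances, and from these the *exact* mean
distance over the leaf pairs whose most recent common ancestor is that
node. Since every leaf pair splits at exactly one node, the weighted
multiset of per-node (mean, pair-count) values is a linear-size summary of
the whole-tree distribution, and the threshold is its weighted percentile
(default 0.05, linear interpolation between weighted order statistics,
equivalent to a type-7 quantile on the expanded multiset).

The original formulation approximated per-clade distance distributions by
assuming equal branch lengths under a node; the recurrence used here gives
the exact means at the same linear cost, so the approximation is not
reproduced — this is a declared substitute, strictly dominating it and
testable against an O(n²) brute-force oracle. Pair-count weighting of the
percentile (rather than one vote per node) is likewise the only reading
under which each clade's "contribution to the whole-tree distribution" is
proportional to the pairs it contains.

Cluster selection is a pre-order descent that stops at the root-most nodes
with mean strictly below the threshold. Size bounds (defaults 400–4000
leaves, scaled down proportionally for smaller trees in all examples and
tests) are then enforced: oversized clades split at their root into all
children (polytomies split into all children, not two) until they fit;
undersized clades merge with their *adjacent* clade — the nearest other
clade by patristic distance between clade roots, preferring siblings, ties
broken by smaller clade then lexicographically smallest leaf label — when
the result stays within the maximum, and otherwise their leaves join a
single pooled "unclustered" group, as do leaves never covered by a
qualifying clade. Clade qualification uses strict inequality ("below" the
threshold); zero-length branches are legal and contribute zero. All steps
are deterministic: identical Newick input yields an identical partition.

## Scaffold-guided alignment merging

Subgroup alignments are produced by adding each subgroup's sequences to a
common core alignment, so all subgroups contain the core sequences with
identical ungapped content. Merging walks each subgroup's columns against
the core's: columns carrying core residues map 1:1 onto core columns (they
must appear in order, or the merge aborts naming the offending sequence);
columns that are all-gap across the core rows are subgroup-specific
inserts. The merged alignment interleaves the shared core columns with
each subgroup's insert blocks at their core positions, gap-padding the
blocks in all other rows — deliberately *not* aligning insert regions
between subgroups, because no homology statement connects them. When two
subgroups insert at the same core position, blocks appear in subgroup
input order (the merge is associative up to this documented ordering). Two
invariants are asserted throughout the tests: every row's ungapped sequence
survives exactly, and the output width equals core width plus total insert
width. A core alignment containing an all-gap column is rejected, since
such a column has no residue anchor and its position among inserts would be
ambiguous.

## Motifs: the Nudix box and the X-loop

The canonical Nudix box `GX5EX7REUXEEXGU` — with U a bulky aliphatic
residue (L/I/V by default, configurable) and X any residue — expands to a
fixed 23-position pattern, matched exhaustively (overlapping hits
included) on degapped sequences, with 1-based inclusive residue
coordinates; `ungapped_to_column()` maps hits back to alignment columns.
The substrate-specificity loop ("X-loop") is reported as a window starting
17 residues after the motif end: observed loops run 2–19 residues with
5–10 typical, so the default reported length is 10 (the upper end of the
typical range, for callers without structural knowledge), clamped to the
2–19 bounds and truncated at the sequence end; fewer than 2 remaining
residues yields a distinguished no-window result rather than an error.
Exact per-protein loop boundaries are structural knowledge the sequence
alone does not determine, which is why offset and length are parameters
rather than inferences.

## Function on phylogeny

Trees are midpoint rooted: the root is placed halfway along the longest
leaf-to-leaf path, so the two deepest root-to-leaf distances are equal
(checked to 1e-9 against a brute-force all-pairs diameter). Ties between
equally long paths are broken by the lexicographically smallest leaf-label
pair, making rooting deterministic; an all-zero-branch-length tree has no
midpoint and errors.

A leaf is *characterized* when it carries at least one function with
confidence ≥ 0.2 — the cutoff below which annotations are treated as
unlikely to reflect physiological activity (0.5, the "unreliable" line, is
a stricter preset). For a given function, the analysis finds the maximal
clades in which at least `coherence_fraction` of characterized leaves carry
it. The default is 1.0 (strict agreement): the looser "most proteins share
the function" reading is real but unquantified, so the fraction is an
explicit parameter rather than a hard-coded guess. Uncharacterized leaves
never break coherence — absence of evidence is not disagreement — so a
reported clade may legitimately include unannotated neighbors. Clades with
≥ 2 characterized leaves are reported with their domains of life;
*multi-domain* clades (≥ 2 of bacteria/archaea/eukaryota; viral leaves are
flagged but excluded from the count, since virus phylogeny does not place
them in the cellular tree) are the operational criterion for
candidate-ancestral functions — the package reports the criterion, not the
biological conclusion. The per-function count of maximal coherent clades,
with lone carriers counted as degenerate single-leaf clades (a lone carrier
elsewhere in the tree is evidence against monophyly), is the polyphyly
count: 1 means the characterized carriers are monophyletic, ≥ 2 means
homoplasy or loss.

## The synthetic-data generators

The generators emulate the statistical structure the analyses assume, with
recorded ground truth. `sim_tree()` grows a random binary topology by
uniform attachment with exponential branch lengths (default 100 leaves,
mean length 0.1). `sim_annotations()` plants each of 4 functions on
disjoint clades of 3–8 leaves (`origins_per_function` controls planted
homoplasy), gives planted leaves the function at confidence 0.7–0.99,
draws domains of life from a bacteria-dominated mix
(0.50/0.15/0.30/0.05 bacteria/archaea/eukaryota/virus) with within-clade
correlation 0.9, and characterizes leaves outside planted clades with
lineage-specific background functions at rate 0.6 (confidence 0.3–0.9) —
emulating a densely annotated reference phylogeny, and giving coherence
analysis the non-carrier evidence that separates independent origins. The
generator enforces its own ground truth: planted same-function clades must
be separable (a characterized non-carrier exists under every pairwise
MRCA), since otherwise the recorded origin count would overstate the
homoplasy actually present in the data. `sim_evidence()` draws
true-function kcat/Km with log10 uniform on [6, 7] plus Gaussian noise
(sd 0.3 log10 units — kinetics are lognormal because the scoring model is
linear in log10), decoy kinetics on [3, 4] for half the proteins, and a
knockout record for 10%; the ≥ 2-decade kinetic gap mirrors the >1000-fold
separation observed between physiological and non-physiological substrates
of well-studied Nudix hydrolases. One master seed fans out to independent
substreams per stage, so outputs are byte-identical under a fixed seed and
adding a stage never perturbs earlier ones.

What the generators do *not* emulate: sequence evolution (no substitution
model — motif scanning is tested on constructed sequences instead),
correlated or contradictory literature evidence, rate heterogeneity across
lineages, and annotation errors that are biased rather than random. Tests
passing on these data therefore show the algorithms implement their
definitions and recover planted structure under the stated noise; they do
not show robustness to the full messiness of curated literature data.

## Numerical choices and problem sizes

Interpolation is exact at anchors and clamped outside them; all scores are
bounded in [0, 1] by construction. Percentile computation interpolates
between weighted order statistics; the partitioner's qualification is a
strict inequality, so one-point distributions (a cherry) cluster at any
percentile. Midpoint rooting verifies the equal-depth property to 1e-9 and
returns an already-balanced tree unchanged. Test problem sizes — trees of
4–200 leaves (brute-force oracles up to 64), 100-replicate recovery sweeps
on 100-leaf trees, a 2000-leaf partition demonstration — were chosen so
that O(n²) oracles remain comfortably cheap while still exercising
non-trivial topology; the production size bounds (400–4000) appear only as
defaults, with tests and examples scaling them proportionally.

## Known limitations

Clade merging recomputes clade roots as MRCAs, so a merged "clade" need not
be a single node's leaf set (the merge rule itself guarantees this cannot
always hold); the partition reports leaf sets, not nodes. The partitioner
performs one pass — no iterative re-alignment loop. Coherence analysis
treats functions as unordered labels: it knows nothing of biochemical
similarity between functions, so two closely related activities count as
disagreement under strict coherence. Midpoint rooting assumes a roughly
clock-like tree; on strongly rate-heterogeneous trees the midpoint can fall
inside a fast-evolving clade, and no outgroup alternative is provided.
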