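---
title: "Origin-centred substitution analysis in rearranging bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Origin-centred substitution analysis in rearranging bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriscan)
library(dplyr)
```

## The problem

Bacterial chromosomes replicate bidirectionally from a single origin
(*oriC*): two forks proceed in opposite directions and meet near the
terminus, dividing a circular chromosome into two replichores.  Many
molecular properties — gene expression, essentiality, substitution rate —
have been reported to vary with distance from the origin.  Testing such
spatial trends across species is complicated by genome rearrangements: a
gene observed 2 Mb from *oriC* today may have spent most of its history
somewhere else.  `oriscan` implements an analysis that (i) re-indexes every
position as a distance from the origin along its own replichore, (ii)
reconstructs both ancestral nucleotides and ancestral genomic positions of
homologous blocks over a phylogeny, so each inferred substitution is mapped
to the genomic neighbourhood in which it actually occurred, and (iii)
summarises the result with per-site logistic regressions, windowed
densities, origin-shift permutations, taxon jackknives, and per-gene
dN/dS/&omega;.

A synthetic-genome simulator with complete truth logs accompanies the
pipeline so that every stage is testable by parameter recovery rather than
by eyeballing.

## The coordinate transform

`transform_position()` maps a raw 1-based position *p* on a circular
replicon with origin *o* and terminus *t* to

* `distance = (p − o) mod L` when *p* lies on the arc from origin to
  terminus in increasing-coordinate direction (the *right* replichore), and
* `distance = (o − p) mod L` otherwise (the *left* replichore).

The origin itself has distance 0 (when transformed coordinates are shown
1-based the origin is labelled 1; the `origin_label` attribute records
this).  The terminus belongs to both replichores: its two distances sum to
the replicon length.  On a 100-bp replicon with origin 20 and terminus 60,
position 40 maps to 20, position 80 maps to 40, and the terminus has
distances 40 (right) and 60 (left):

```{r transform}
rep100 <- replicon("demo", 100, "circular", origin = 20, terminus = 60)
transform_position(c(40, 80, 60), rep100)
replichore_lengths(rep100)
```

For circular replicons without an annotated terminus (for instance
secondary replicons), `terminus = "midpoint"` places it antipodal to the
origin, which is the assignment that equalises the two replichore lengths.
Linear chromosomes replicate from the origin out to both ends; positions
get signed coordinates (`signed = p − o`), regressions use the unsigned
distance, and the arm left of the origin is labelled `short_arm` by
convention (plots of linear chromosomes conventionally show it as the
shorter, negative arm).

Where the origin–terminus arcs are unequal, each position is assigned to
the replichore that physically contains it; positions beyond the terminus
on the shorter arc are *not* re-projected onto the longer arc.  This is a
deliberate choice: the alternative double-counts part of one replichore.

## Alignment hygiene

The pipeline consumes locally collinear blocks (LCBs) from a
rearrangement-aware aligner (XMFA input via `read_xmfa()`), and applies, in
order: universal-block selection (only blocks present in every taxon),
gap-fraction column trimming (`gap_fraction_trim()`, default threshold
0.2 — a deliberately simple, documented stand-in for heuristic alignment
trimmers), a codon-consistency filter (a column is kept only when every
taxon is inside an annotated gene at the identical codon position), and
run-splitting into gap-free, unambiguous segments of at least 100 bp that
start and end on complete codons.  Reverse-strand genes are
reverse-complemented into coding orientation; position maps always retain
forward-genome coordinates.  Ambiguity is defined as any character outside
`A/C/G/T`, and a column containing one is removed entirely.

Columns that are coding in all taxa but belong to different genes are kept
when their codon positions agree (dropping them would discard genuinely
alignable coding sequence; the codon filter already guarantees a shared
reading frame).  Genes crossing block boundaries are processed per block —
split genes are separate segments, never stitched.

## Joint ancestral reconstruction

**Nucleotides.** `reconstruct_nucleotides()` runs Felsenstein pruning under
HKY85 with empirical base frequencies and a transition/transversion ratio
fitted by one-dimensional likelihood maximisation (a single pooled kappa is
fitted per run; rate heterogeneity across sites is deliberately not
modelled).  The reported state at each internal node and column is the
maximum marginal posterior; posteriors equal to within 1e-9 are ties,
broken in the fixed order A &lt; C &lt; G &lt; T and flagged, so
reconstruction is deterministic.

**Positions.** Each block's placement in each taxon (genomic start plus
strand) is treated as one categorical character; `reconstruct_positions()`
assigns internal labels by Fitch small parsimony.  When the parsimony
solution is ambiguous, the tie is broken by marginal likelihood under a
simple rearrangement model in which a label change on a branch of length
*t* has probability 1 − exp(−&rho;t), spread uniformly over the other
observed labels; &rho; defaults to the Fitch change count divided by total
tree length.  &rho; only matters at ties, and residual exact ties fall to
the lexicographically smallest label.  Positions are reconstructed per
block — blocks move as units — and per-column ancestral positions follow
from the node's block label by column offset.  Reconstructing positions
per column independently would be enormously redundant and could fragment
within-block consistency; a config option to cluster nearby block labels
is available for sensitivity analysis but is not validated here.

**Events.** `extract_substitutions()` emits one event per branch and
column where the parent and child states differ; multiple hits at one site
on different branches are separate events.  Each event records the site's
genomic position at both the parent node (the *ancestral genomic
position*, used for spatial mapping) and the child node.  The
three-taxon worked example — `((a,b),c)` with the segment at positions 1–3 in *a*
and *b* (ending C) and 7–9 in *c* (ending A) — yields exactly one event,
on the lineage to *c*, with parent state C at position 3 and child
position 9:

```{r worked-example}
tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.2);")
blk <- aligned_block("blk", c(a = "TTC", b = "TTC", c = "TTA"),
                     start = c(a = 1, b = 1, c = 7),
                     end = c(a = 3, b = 3, c = 9),
                     strand = c(a = "+", b = "+", c = "+"))
seg <- gene_segment("blk.seg1", "blk", blk$seqs, blk$pos_map, 1:3)
nuc <- reconstruct_nucleotides(seg, tree, kappa = 2)
pos <- reconstruct_positions(
  tree, c(a = "1+", b = "1+", c = "7+"))
extract_substitutions(seg, nuc, pos,
                      list(`1+` = seg$pos_map$a, `7+` = seg$pos_map$c))
```

Mapping by the parent's position is the default because the event happened
on the branch above the child, in a genome whose arrangement is best
described by the parent's reconstruction; the child-side position is kept
in the output for sensitivity analyses.  No events are assigned above the
root, so input trees must be rooted.

## Spatial summaries and regressions

`build_site_table()` produces one row per analysed coding site with its
ancestral genomic position (the root-node placement of its block), the
transformed distance, the event count over branches, and a binary
indicator.  The logistic regression (`fit_logistic()`) models
logit P(&ge;1 substitution at the site) as linear in distance; the binary
indicator reconciles "binary data" with multiple-hit counting and is the
default response.  Windowed summaries (`window_aggregate()`) divide each
10-kb window's substitution total by its coding-site total; windowed OLS
runs at 10, 25, 50, 100, 200 and 400 kb.  Both replichores are pooled on
the shared distance axis.

Outliers are flagged on window densities with Tukey fences
(1.5 &times; IQR beyond the quartiles, linear-interpolation quartiles) and
excluded before fitting.  A literal "outside the interquartile range" mode
exists behind a switch, but it discards half the data by construction and
is not the default.  The same rule applied to &omega; values drives the
selection outlier filter.

`origin_shift_permutation()` refits the logistic model with the origin
moved in 10-kb steps out to &plusmn;100 kb (midpoint-rule termini are
recomputed), checking that the slope's sign and significance do not hinge
on the exact origin call.  `taxon_jackknife()` reruns block selection,
reconstruction and the regression with each taxon removed, flagging
removals of the outgroup or of the modal ancestral-position donor — the
two situations in which a sign flip is expected.

Significance defaults to 0.05 with no multiple-testing correction across
replicons (each replicon is analysed independently); full estimates, SEs,
p-values and n are always emitted rather than significance stars alone.

## Selection

`compute_dn_ds()` implements Nei–Gojobori (1986) codon counting with
Jukes–Cantor correction, averaged over all unordered taxon pairs.
Synonymous site counts are codon averages over the three possible changes
per position; differences average over mutation paths, excluding paths
through stop codons unless all are blocked; changes *to* stop codons count
as nonsynonymous, and codons containing a stop are skipped per pair.  A
pair whose proportion reaches 3/4 is saturated and excluded; &omega; is
undefined (not infinite) when dS = 0.  Counting is appropriate here
because the pipeline operates in a low-divergence regime where counting
and ML estimates of dN/dS effectively coincide; the estimator name is
stamped in the output.  Genome summaries are arithmetic averages weighted
by segment length; records with dS = 0 contribute to the dN and dS
averages but are removed from the weighted &omega;.  Per-segment distance
is the transformed midpoint in the reference taxon (first tree tip by
default) — some anchor taxon must be chosen and the choice is recorded in
the run parameters.

## The simulator

`simulate_genomes()` generates a root genome of non-overlapping
protein-coding genes laid out in equal-length rearrangeable blocks on a
circular (or linear) replicon, and evolves it along a clock-like tree.  On
each branch it first draws block rearrangements — a block moves to a
uniformly chosen slot and is inverted with probability `q`; counts are
Poisson with intensity proportional to branch length, scaled so the
tree-wide mean per branch is `rho` — and then per-site substitutions at
rate &mu;·exp(g·d)·t, where *d* is the distance from the origin *in the
genome as currently arranged*, so rearranged blocks acquire the rate of
their new neighbourhood: exactly the coupling the pipeline is designed to
detect.  The gradient is log-linear because that is the scale on which the
logistic model's linear predictor operates; a rate-doubling gradient
across a replichore means g = ln 2 / (L/2).  Proposals follow an HKY-like
kernel with uniform base frequencies (keeping the kernel strand-symmetric,
so inversions do not bias composition); nonsynonymous proposals are
accepted with probability `f`.

Default study conditions: 5 taxa, 500 kb, origin at 1 with antipodal
terminus, 400 genes (600–1200 bp) in 20 blocks (~72% coding), total tree
length 0.08 expected substitutions/site, kappa 3, f 0.2 (purifying),
rho 0.5 rearrangements/branch, q 0.5.  These sizes keep a full
simulate-and-analyse cycle in the tens of seconds while leaving tens of
thousands of substitutions for the regressions; module tests use a 60-kb
version of the same layout.

The simulator emits the exact block decomposition induced by the
rearrangement history as gap-free XMFA — no aligner is needed for tests —
plus per-taxon annotations, the tree, and complete truth logs
(`replay_truth()` reapplies them to the root and must reproduce every leaf
byte-exactly).  What it deliberately does not emulate: indels (gap
handling is exercised with hand-built fixtures), gene gain/loss, HGT from
outside the taxon set, compositional strand bias, and block-boundary
erosion.  Passing recovery tests therefore demonstrate correctness of the
inference machinery under the model's assumptions, not robustness to
alignment error or non-stationary composition in real data.

```{r demo, fig.width = 6, fig.height = 3}
sim <- simulate_genomes(sim_config(seed = 11, L = 60000, n_blocks = 6,
                                   n_genes = 60, tree_length = 0.06))
run <- suppressWarnings(run_full_analysis(sim))
glance(run)
autoplot(run)
```

The positive fitted slope recovers the simulated rate-doubling gradient;
`tidy(run$logistic)` exposes the full coefficient row, and
`run$selection_summary` the length-weighted dN/dS/&omega; averages, which
sit in the purifying regime (dS &gt; dN) that the simulator's
nonsynonymous rejection imposes.

## Numerical choices and degenerate inputs

* Logistic fits use IRLS (`stats::glm`) to convergence 1e-8 / 100
  iterations; separation (a single response class, or fitted probabilities
  collapsing to 0/1) is flagged in the result, never an error.
* Windowed fits require 3 usable windows, selection regressions 3 records
  and 2 distinct distances; otherwise they are skipped with a warning.
* Posterior and parsimony ties break deterministically (base order /
  lexicographic label order) and are flagged, so identical inputs always
  give identical outputs.
* Coordinates are 1-based inclusive in all inputs and outputs; internal
  modular arithmetic is 0-based.
* Empty blocks, zero-length segments, all-gap columns and mutation-free
  simulations flow through and yield empty tables or zero counts rather
  than errors.

## Known limitations

* Branch attribution of individual substitutions is noisy where branches
  are short: an event can be assigned to a neighbouring branch even when
  its site and position are correct.  Site-level spatial summaries are
  unaffected.
* A rearrangement on one of the two branches adjacent to the root is
  directionally ambiguous (both placements are equally parsimonious); the
  likelihood tie-break resolves it toward the longer branch, which is the
  more probable host when rearrangement propensity scales with branch
  length, but the truth contradicts it in a minority of histories.  When
  that happens, every event on the opposite root-adjacent branch in the
  displaced blocks receives a parent-side position that is off by the
  displacement.  In simulated recovery tests this is the dominant — in
  practice the only material — source of parent-side position error;
  child-side positions, anchored by observed leaf placements, are
  recovered essentially exactly under the same histories, and the
  site-level spatial regressions are unaffected because sites are keyed to
  the root-node block placement, not to per-event parent positions.
* Per-pair NG86 saturates above p = 3/4; deeply diverged segment pairs are
  flagged and excluded rather than rescued with a saturation-robust
  estimator.
* Tree inference, alignment computation, and topology congruence screening
  are upstream concerns: trees and LCBs are inputs (an exclusion list of
  block ids can mimic a congruence screen).
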