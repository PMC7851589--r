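# oriscan

Spatial analysis of nucleotide substitutions along bacterial replicons,
centred on the origin of replication and aware of genome rearrangements.

## What it is for

Bacterial chromosomes replicate bidirectionally from *oriC*: two forks run
in opposite directions and meet near the terminus, splitting a circular
replicon into two replichores.  A long-standing question in bacterial
comparative genomics is whether substitution rates rise with distance from
the origin.  Answering it honestly requires dealing with rearrangements —
a gene's present-day coordinate says little about where its substitutions
actually happened.  `oriscan` is for researchers who want to test spatial
substitution and selection trends across a set of closely related complete
genomes while reconstructing where each substitution occurred ancestrally.

The package provides, end to end:

* **Replicon geometry** — re-indexing of positions as distance from the
  origin along each position's own replichore
  (`replicon()`, `transform_position()`), with explicit or antipodal
  ("midpoint") termini and support for circular and linear chromosomes.
* **Alignment hygiene** — XMFA locally-collinear-block input
  (`read_xmfa()`), universal-block selection, gap-fraction trimming, a
  codon-consistency filter across taxa, and splitting into gap-free,
  codon-complete gene segments of ≥ 100 bp (`filter_blocks()`).
* **Joint ancestral reconstruction** — marginal maximum-likelihood
  nucleotide states under HKY85 (`reconstruct_nucleotides()`) and Fitch
  parsimony over block position labels with a likelihood tie-break in
  which a label change on a branch of length *t* has probability
  1 − exp(−ρt) (`reconstruct_positions()`); per-branch substitution events
  carry the genomic position of their site at both the parent and child
  node (`extract_substitutions()`).
* **Spatial statistics** — a per-site table (`build_site_table()`),
  logistic regression of logit P(substitution) = β₀ + β₁·distance
  (`fit_logistic()`), windowed densities and OLS trends at
  10–400 kb (`window_aggregate()`, `fit_window_regressions()`), Tukey
  outlier handling (`flag_outliers()`), origin-shift permutation tests
  (`origin_shift_permutation()`) and taxon jackknives
  (`taxon_jackknife()`).
* **Selection** — Nei–Gojobori codon-counting dN/dS with Jukes–Cantor
  correction per gene segment (`compute_dn_ds()`), ω-based outlier
  propagation, length-weighted genome averages and distance regressions.
* **A truth-logged simulator** — genomes evolved along a clock-like tree
  with a configurable log-linear rate gradient rate(d) = μ·exp(g·d),
  block translocations/inversions and purifying selection
  (`simulate_genomes()`, `replay_truth()`), so every stage is verified by
  parameter recovery.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and runs have `autoplot()`.

## Worked example

Simulate five genomes on a 60-kb circular replicon whose substitution rate
doubles across each replichore, with rearrangements, then run the full
analysis:

```r
library(oriscan)

sim <- simulate_genomes(sim_config(seed = 11, L = 60000, n_blocks = 6,
                                   n_genes = 60, tree_length = 0.06))
run <- run_full_analysis(sim)
run
#> <ori_run>
#>   replicon: sim (60000 bp, circular)
#>   blocks kept: 6; segments: 60; coding sites: 53481
#>   substitution events: 1969; subs/bp (outliers excluded): 0.03682
#>   logistic slope: 1.914e-05 per bp (p = 8.85e-13)
#>   weighted dS = 0.04251, dN = 0.006949, omega = 0.1712
```

The logistic slope is the change in log-odds of a site having substituted
per bp of distance from the origin: positive and highly significant, as it
should be for data generated with a rate-doubling gradient
(g = ln 2 / 30000 ≈ 2.3e-5 per bp; the fitted 1.9e-5 recovers it to well
within sampling error at this problem size).  The weighted dS > dN
reflects the simulator's purifying selection (nonsynonymous acceptance
0.2).  `tidy(run$logistic)` gives the full
coefficient row; `run$windows` the 10-kb density table behind
`autoplot(run)`; `run$selection` the per-segment dN/dS/ω records.

Sensitivity checks:

```r
origin_shift_permutation(run$site_table, run$replicon)  # ±100 kb, 10-kb steps
taxon_jackknife(sim$blocks, sim$annotations, sim$tree, sim$replicon)
```

On real data, start from `read_xmfa()`, `read_annotations()` (or
`read_gff_annotations()`), `ape::read.tree()`, and a `replicon()`
description, then call `run_full_analysis()` with those inputs.

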