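---
title: "Inferring clonal origins from sequenced microsatellite alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clonal origins from sequenced microsatellite alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatclone)
```

## The inference model

msatclone targets cohorts of hybrid parthenogens: every individual carries,
at each sequenced microsatellite locus, one allele inherited from each of
two sexual parental species, and reproduction is clonal. Two mutational
clocks run at very different speeds on each allele:

* repeat clusters (e.g. (GATA)n) gain or lose single repeat units by
  slippage — the stepwise mutation model (SMM) — on observable timescales;
* single nucleotide variants (SNVs) at fixed positions of the flanking
  sequence are effectively frozen, and their states segregate between the
  parental species.

The method rests on three assumptions, all of which the simulator encodes
and the tests exercise:

1. **Flank stability** — SMM changes repeat copy numbers only; an allele's
   SNV profile is invariant over the sampled history. Consequently the
   per-genotype combination of profiles (one unordered profile pair per
   locus) is inherited unchanged along a clonal lineage.
2. **Parental diagnosticity** — each profile (with the repeat-cluster
   signature as a tie-breaker, e.g. (AC)5 vs (AC)6) maps to at most one
   parental species at a locus. A catalog violating this is rejected at
   construction rather than silently producing arbitrary assignments.
3. **No recombination, no backcrossing** — clones differ within a founder
   class only by SMM steps. Differences between classes are founder
   differences and are never interpreted as mutations
   (`mutation_attribution()` refuses cross-class pairs).

Under these assumptions, the number of distinct SNV combinations is a
**lower bound** on the number of independent hybridization events: distinct
combinations require distinct events, while identical combinations cannot
exclude independent crossings of genetically identical parents. The fitted
object reports the bound and carries an explicit `lower_bound` flag rather
than a point estimate.

## Allele decomposition

`parse_repeat_structure()` reports maximal tandem runs of each configured
motif with at least `min_repeats` copies (default 3; two copies are
indistinguishable from chance in short flanks). Scanning anchors on the
**configured motif spelling** — the name the field prints, e.g. (GATA)n —
so a phase-shifted pure run is counted from its first full copy;
rotation-equivalent motif configurations are deduplicated via the
smallest-rotation class (`canonical_motif()`). Overlapping runs of
different motifs keep the longer run and report the conflict.

`extract_snv_profile()` reads the profile off an alignment in which repeat
clusters are first hard-masked (removed) from both allele and reference, so
repeat-length differences can never shift flank coordinates. The masked
sequences are aligned end-gap-free (Biostrings `pairwiseAlignment`, type
"overlap"); alignments below 70% identity (configurable) are rejected as
unalignable rather than yielding a wrong profile. A position deleted in the
allele yields the gap state `-`, which is a legal profile character
throughout (profiles, catalogs, network characters).

SNV positions are **configuration, not discovery**: they are fixed
empirically per locus and supplied as 0-based reference coordinates. This
keeps parsing deterministic and makes the locus config the single source of
coordinate truth. Coordinates are 0-based half-open everywhere.

## Genotypes, numbering and tabulation

Individuals with identical unordered allele pairs at every locus form one
multilocus genotype ("presumptive clone"). Ids are assigned in descending
order of count, ties broken by numeric-aware lexicographic order of the
composition, so identical cohorts always number identically. Published
tables of this kind do not follow a stated numbering rule, so ids here are
reproducible but not nominally comparable to any particular publication;
analyses that need to refer to a specific clone should anchor on its
composition string.

Genotypic diversity is 100·G/N with the convention that a monomorphic
population (G = 1) is reported as 0 — the convention used in the tables
this package mirrors, where a single-clone population is "1 (0)" regardless
of its size.

## Diversity statistics

`diversity_stats()` applies a filter stage first: listed genotypes are
dropped (by default in `run_pipeline()`, everything outside the largest
founder class, since rare independent lineages would otherwise dominate
within-lineage diversity), then populations under `min_pop_n = 2`
individuals are removed. The rarefaction size defaults to twice the
smallest retained population — 4 gene copies on the packaged fixture.

Per locus and population the package reports:

* `N`, the observed allele count over 2n gene copies;
* `R_S = Σ_i [1 − C(2n−N_i, g)/C(2n, g)]`, the expected allele count in a
  hypergeometric subsample of g copies (computed via `lchoose`, so large
  counts cannot overflow); `R_S` is non-decreasing in g and equals N at
  g = 2n, which is also why the pooled "Total" row — rarefied at its own
  full size — prints its allele count;
* `H_E = 2n/(2n−1)·(1 − Σ p_i²)`, Nei's gene diversity with the
  small-sample correction. The correction is the default because clonal
  cohorts are dominated by fixed heterozygosity, where H_E depends on n
  alone and the corrected form reproduces the reference tables' cells
  (0.51 at n = 21, 0.52 at n = 17, 0.67 at n = 2, ...); the uncorrected
  variant is available via `unbiased = FALSE`;
* `H_O`, the heterozygote fraction — 0 or 1 exactly for a single clone.

Rounding is applied only at the report layer (`report_diversity()`),
half-up to 2 decimals; all computation and testing uses unrounded values.

## Index of association

`index_of_association()` computes `I_A = V_O/V_E − 1` and `r̄_d` from
per-locus inter-individual mismatch distances (0/1/2 allele slots), with
significance from permuting per-locus genotype columns among individuals —
the scheme that preserves every single-locus distribution while destroying
between-locus association. An allele-level shuffle (`shuffle = "allele"`)
and clone correction are options. Cohorts with no variance return flagged
`NA` rather than a spurious statistic; seeds and permutation counts are
recorded in the result. In strictly clonal data a significant `r̄_d` is
expected; the statistic is most informative after clone correction or on
cohorts where lineage mixture is in question.

## Mutation networks

Genotypes are encoded per locus and allele slot (slots in canonical sorted
order): repeat counts as ordered integer characters (distance = |Δ|), SNV
states as unordered characters over A/C/G/T/- (distance 0/1). Alleles whose
cluster inventory is not homologous with the slot's modal inventory are
coded presence/absence (distance 1) with a warning.

`clone_network()` builds a minimum spanning network: candidate edges in
increasing step order, an edge joining two components is kept, and all
equally parsimonious alternatives at the joining level are retained (a
network, not an arbitrarily tie-broken tree — the semantics of statistical
parsimony). Edge processing order is deterministic: (steps, id pair).
Edges of s > 1 steps materialize s − 1 unsampled intermediate nodes, the
"computer-predicted" genotypes of parsimony graphs. Networks are built
**per founder class** by default with no step cap, because classes are the
biologically meaningful connection boundaries (cross-class differences are
not mutational paths); a numeric `connection_limit` is available and a
disconnected result is legal. The classical 95% parsimony connection
probability is not re-derived. `hub_statistics()` quantifies
star-likeness: in the fixture's major class the most frequent clone is the
unique maximum-degree hub and every clone lies within two steps of it.

## The simulator: what it emulates and what it does not

`simulate_cohort()` generates the study conditions the analysis assumes:
two parental species with species-diagnostic profile pools (four profiles
per species per locus by default — sexual parents are themselves
polymorphic in their flanks), F founder events each drawing one allele per
locus per parent, clonal propagation, and population sampling. Defaults
are fixed as the package's study conditions: F = 3 founders, four Du-like
loci (one carrying a secondary fixed (AC)n marker cluster), 100
generations, mu = 1e-3 per allele per generation (an order-of-magnitude
placeholder — no direct rate estimate exists for these loci), pool size 6,
three populations (20/10/10) with founder weights 0.8/0.1/0.1 emulating
one widespread clone and rare ones.

Mutation is single-step symmetric SMM on the primary motif only, matching
the observed single-repeat insertions/deletions at such loci; secondary
clusters are fixed species markers. Repeat counts reflect upward at
`min_copies = 3` (a downward step at the boundary is redirected up),
because shorter runs would fall below the detection threshold and break
cluster homology. Mutation event counts are therefore exactly
Binomial(generations, mu) per allele, which the tests verify against the
recorded ground truth. Each sampled individual descends independently from
its founder (star genealogy within a lineage); shared intra-lineage
genealogy, selection, drift in clone frequencies, backcrossing and
recombination are deliberately absent. Passing tests on simulated data
therefore demonstrate correctness of the inference chain under its own
assumptions — not robustness to recombination, null alleles, allele
dropout or scoring error in real data.

`emit_sequences()` renders every realized allele as flank + clusters +
flank with planted profile states, over random flanks that are generated
free of spurious motif runs and of full-motif junction copies, and verifies
the parse round trip; this is what lets the sequence-level pipeline be
tested end to end without any external data.

## Numerical and design choices

* Allele labels are opaque strings; when all labels at a locus parse as
  numbers they sort numerically ("10" after "9").
* Founder classes order by individuals covered (descending), then by
  signature string; genotype ids as above; network edge insertion by
  (steps, id pair) — every ordering in the package has a stated tie-break,
  so reruns are byte-identical (`run_pipeline()` outputs carry version,
  input hash and seed, and the determinism is tested).
* Frequencies in published tables of this kind are sometimes truncated
  rather than rounded (0.549 from 61/111 = 0.5495); the package never
  truncates — comparisons against such tables should use each cell's
  printed convention.
* Degenerate inputs have defined behavior: empty cohorts, missing locus
  calls, unknown populations, g exceeding 2n, identical-code genotypes in
  a network, and variance-free LD cohorts all produce informative errors
  or flagged results rather than wrong numbers.
* The packaged fixture reconstructs a published cohort; its allele
  sequences are synthetic backbones (flagged as such in the fixture
  metadata) carrying the reported cluster structure and SNV profiles, with
  invented flanks and coordinates. Repeat copy numbers for the allele
  series were chosen so that within-class allele ladders differ by single
  steps — consistent with the reported one-to-two-step derivation of rare
  clones — but the exact published fragment lengths are not encoded.
  Checks that depend only on composition, counts and profiles are
  therefore faithful; absolute step counts between specific allele pairs
  are fixture conventions.

## Problem sizes used by the test suite

The suite is sized for a single CPU: founder-recovery runs 200 simulated
cohorts of 32 individuals across F ∈ {1, 2, 3, 5} and mu ∈ {0, 0.01};
mutation-count calibration uses 200 cohorts of 2 individuals at
generations = 50, mu = 0.01; the Monte-Carlo rarefaction oracle draws
10^5 subsamples per fixture cell; the permutation-null uniformity check
runs 500 cohorts of 12 individuals with 99 permutations each. These sizes
give standard errors comfortably inside the asserted 3-SE bands.

## Known limitations

* The founder count is a lower bound by construction; lineages founded by
  genetically identical parental pairs are indistinguishable.
* Homoplasy: an SMM step can recreate an existing allele, merging two
  clones' compositions; at the fixture's scale this is negligible, but at
  high mu·generations the genotype count underestimates lineage history.
* The flank aligner is a simple global end-gap-free alignment; severely
  diverged flanks (below the identity threshold) are rejected, not
  rescued.
* `I_A`/`r̄_d` follow the classical multilocus definitions; no correction
  for clonal pseudo-replication beyond the clone-correct option.
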