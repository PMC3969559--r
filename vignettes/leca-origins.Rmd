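---
title: "Classifying the prokaryotic origins of LECA genes from single-gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the prokaryotic origins of LECA genes from single-gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lecatrace)
library(ape)
```

## The problem

Eukaryotic genomes are chimeric: genes present in the last eukaryotic
common ancestor (LECA) descend partly from the archaeal lineage that hosted
eukaryogenesis, partly from the alphaproteobacterial ancestor of
mitochondria via endosymbiotic gene transfer (EGT), and partly from other
prokaryotic donors. Reading those origins off single-gene trees is harder
than it looks. Each gene family gives one unrooted maximum-likelihood (ML)
tree in which a clade of eukaryotic sequences sits somewhere among
prokaryotes; the naive reading — "the origin is whatever the sister clade
is" — is routinely derailed by horizontal gene transfer (HGT) among
prokaryotes, incomplete taxon sampling, and phylogenetic noise. A single
recently transferred sequence sitting next to the eukaryotes is enough to
produce a confident, specific, and wrong assignment.

`lecatrace` implements a pipeline that addresses this with three ideas:

1. **Taxonomy-aware configurations.** A clade is assigned to a prokaryotic
   group only when it branches *inside* a clan of that group's sequences
   representing a minimum number of distinct species (a per-group threshold
   table); failing that, to a prokaryotic domain (at least 10 species);
   failing that, to a three-domain pattern; otherwise the tree is
   *unclear*. Trees where the eukaryotic representatives are not
   monophyletic are *paraphyletic*.
2. **Supports designed for a region, not a branch.** The position of a
   eukaryotic clade among prokaryotes is not carried by any single branch,
   so standard branch supports do not apply. The node bootstrap support
   (NBS) counts replicate trees containing the full tripartition at the
   base of the eukaryotic stem; the sister-group stability (SGS) measures
   how consistent the sister leaf *set* is across replicates.
3. **A calibratable decision rule.** On reference genes of known origin,
   the smallest SGS above which every clade is correctly assigned becomes
   the operating threshold for the rest of the data.

All trees are *unrooted*, so "monophyletic" is formalised as a *clan*: a
leaf set forming one side of some bipartition of the tree.

## Pipeline stages and their rules

### LECA clade detection

Maximal clans consisting purely of eukaryotic leaves are extracted from
each family tree. A clade is inferred to trace back to LECA when it
contains sequences from at least (R1) two Unikont species and two Plantae,
(R2) two Unikonts and two Chromalveolates, or (R3) two Plantae, two
Chromalveolates and one kinetoplastid. Counting *species*, not sequences,
means in-paralogs cannot inflate the evidence; requiring two supergroups
means an opisthokont-specific expansion never qualifies. Several LECA
clades can coexist in one family (ancient paralogy) and are analysed
independently.

Isolated prokaryotic sequences nested among diverse eukaryotes — the
signature of a recent eukaryote-to-prokaryote transfer — make the
eukaryotes look paraphyletic. Where the original analysis relied on manual
tree inspection, `flag_intruders()` is a declared, reproducible
approximation: it flags maximal prokaryote-only clans of at most
`max_intruder_size` leaves (default 2) whose removal merges two or more
eukaryotic clans jointly spanning at least two supergroups. Two points are
worth stating explicitly. First, the before/after comparison is made in a
rooted sense, holding the root at a reference prokaryote outside the
candidate: on unrooted trees, removing the candidate can otherwise make the
eukaryotes a "clan" merely because only one prokaryotic block remains (the
complement of any clan is a clan), reporting merges that do not reflect
nestedness. Second, the defaults are our quantification of "isolated" and
"diverse" — the source procedure was manual and gives no numbers — so all
flaggings are reported, and pruning is opt-in (`prune_intruders`).

### Representative sampling

Large clades are reduced to `k = 10` representatives before
classification, preserving sequence diversity while shedding the
longest-branched sequences. The clade subtree is rooted by the
least-squares criterion — the root is the point on any edge minimising the
sum of squared deviations of root-to-leaf path lengths from their mean,
solved in closed form per edge (the objective is quadratic in the position
along an edge) and scanned over edges. Leaves are then pruned one at a
time: remove the leaf deepest in edge count from the root; break ties by
path length; break residual ties by removing the lexicographically
greatest label (a determinism choice; the procedure itself does not specify
one). Depths are recomputed after every removal, because suppressing the
unary node left behind changes them. The selection is nested: the `k-1`
selection is always a subset of the `k` selection.

### Configuration classification

For a clade that is a clan of its (representative-restricted) tree, every
clan containing it is examined. A taxon X at a given level (group, then
domain) is *eligible* when some enclosing clan has all its prokaryotic
members in X and those members represent at least the threshold number of
distinct X species. Eligibility is existential — "does the clade branch
inside a sufficiently sampled clade of X sequences" — rather than being
tested on the smallest enclosing pure-X clan; pure-X clans containing a
fixed clade are nested, so this is the same as testing the largest one.
(Testing the smallest would, for instance, turn the classic
single-transferred-sister case into *unclear* instead of
bacterial-domain-related, defeating the design.)

If exactly one group is eligible the clade is group-related; if two taxa at
the same level are simultaneously eligible, the clade sits exactly
*between* two pure blocks rather than inside either, so no call is made at
that level and classification falls through — for domains, that situation
is precisely the three-domain topology, which is then tested explicitly
(all three domains clans, at least 10 species in each prokaryotic domain).

The thresholds (`group_thresholds()`) encode the reference sampling: an
integer minimum, `HALF` (at least half the sampled species, rounded up), or
`NEVER` for groups whose sampling is too sparse for any group-level call.
`domain_min` and `three_domain_min` both default to 10 species. The table
can be overridden from a TSV for other samplings.

Classification of bootstrap ensembles (`bootstrap_configuration_profile()`)
tabulates the label of every replicate; frequencies sum to one with
*paraphyletic* included. Modal-label ties are broken by specificity —
group-related over three-domain over domain-related over unclear over
paraphyletic, then alphabetically — so a tie never silently downgrades a
specific call.

### Support statistics

With `N` replicate trees and `G_i` the sister set of the clade in replicate
`i` (the smaller of the two subtrees flanking the clade's stem; ties go to
the lexicographically smaller label tuple):

- `NBS = 100/N * #{i : replicate i contains the ML tripartition}`;
- `SGS = 2/(N(N-1)) * sum_{i<j} s(G_i, G_j)` with `s` the Jaccard index
  `|intersection| / |union|`, and `s = 0` for any pair involving a
  replicate where the clade is paraphyletic or its attachment
  multifurcating.

SGS ranges from 0 (pairwise-disjoint sister sets) to 1 (identical sister
sets in every replicate, which requires monophyly in every replicate). The
similarity function is a pluggable argument of `sgs()`, so alternative
readings (overlap coefficient, comparison against the ML sister) can be
swapped without touching callers. One relation worth knowing: the `k`
replicates containing the ML tripartition share identical sister sets, so
`SGS >= k(k-1)/(N(N-1))` — approximately `(NBS/100)^2`, not `NBS/100`;
under strong instability SGS can legitimately sit well below NBS/100.

`calibrate_sgs_threshold()` takes reference clades of known origin and
returns the highest SGS among misclassified references (0 if none): above
that value, every reference is correctly assigned. If no reference is
correctly assigned above it, the threshold is flagged unusable.

`near_universal_filter()` marks families containing at least 90% (ceiling)
of the reference species of both Archaea and Bacteria; only such families
are informative about the domain-level relationship of eukaryotes to
archaea, which `summarize_universal()` reports as per-clade and mean
bootstrap supports for the monophyly of each prokaryotic domain.

### Orchestration

`run_pipeline()` ties the stages together over a directory of families (or
simulator output) and one taxonomy table. Clades whose representative-set
monophyly support is not *strictly above* 50% are discarded as ambiguous
(the boundary case is excluded on purpose; the retention threshold is
configurable). Every input family ends in exactly one of: a report row, the
no-LECA log, or the ambiguous log. Rows are sorted by configuration class
and decreasing NBS. The result is a classed object with `print()`,
`summary()` and `plot()` methods, and `write_leca_report()` emits TSVs.

## The simulator

Real inputs for this kind of study are thousands of externally inferred ML
trees plus bootstrap ensembles. To make the pipeline testable at desk
scale, `simulate_dataset()` generates data with the same statistical
structure, fully determined by one seed:

- a rooted species tree over a configurable design, groups and domains
  monophyletic, backbone `(Bacteria, (Archaea, Eukarya))`, exponential
  branch lengths. The default design reproduces the reference sampling (39
  archaeal and 144 bacterial species across 31 groups) plus a 19-species
  eukaryote panel spanning the four supergroups (6 Unikonts, 5 Plantae, 5
  Chromalveolates, 2 Kinetoplastids, 1 other) — enough species per
  supergroup for the LECA rules to be attainable yet breakable by loss;
- gene families derived from the species tree by per-species loss
  (`loss_prob`, default 0.1 — the patchy distributions typical of real
  families), an origin scenario (`EGT` re-attaches the eukaryote clan
  inside a donor group's clan; `VERTICAL_ARCHAEAL` inside or adjacent to
  the archaeal clan; `LUCA_THREE_DOMAIN` leaves all three domains
  monophyletic; `UNCLEAR_MIX` builds a ladder of alternately archaeal and
  bacterial transferred sequences around the eukaryote stem), and
  `Poisson(hgt_rate)` prokaryote-to-prokaryote transfers, each moving a
  recipient sequence next to a donor sequence. Every event is logged, and
  the log replays to the emitted topology;
- bootstrap ensembles emulated *topologically*: each replicate is the ML
  tree, except that with probability `q` the eukaryote clan is re-attached
  to an edge drawn from a kernel decaying geometrically with topological
  distance from the true edge (the true edge itself excluded), and with
  probability `r` one random internal edge is NNI-perturbed. Replicates are
  trees, which is all the pipeline consumes, and `q` gives direct analytic
  control: expected NBS is `100(1-q)`. No sequence evolution, alignment
  uncertainty, or long-branch attraction is simulated — passing tests
  demonstrate the correctness of the tree calculus and decision rules, not
  robustness to inference artifacts in real alignments.

`simulate_hgt_confound()` constructs the classic trap for the naive
criterion: one sequence of a recipient group is marooned inside another
group's region, and the eukaryote clan is attached directly to its branch.
The naive criterion names the recipient group; the configuration system
backs off to bacterial-domain-related.

## Numerical and scale choices

- Test-suite and acceptance-script problem sizes are chosen for desk-scale
  turnaround: oracle comparisons use exhaustive enumeration up to 10–12
  leaves; stability checks use 30–50 families of ~50–200 leaves with
  `N = 100` replicates; donor-recovery checks use 200 small families or 50
  full-design families. Statistical assertions use three-standard-deviation
  binomial bands around analytic expectations.
- Trees without branch lengths get unit lengths with a warning (only the
  rooting and pruning stages consume lengths; supports and topology queries
  do not).
- All-zero branch lengths make the least-squares criterion flat; the root
  falls back to the first edge midpoint, with a warning.
- Sister-group size ties and residual pruning ties are broken
  lexicographically; modal-label ties by specificity; all are documented
  determinism choices on questions the source procedure leaves open.
- Bootstrap supports are read from internal node labels (the common ML
  dialect); the bracket-comment dialect `):0.12[87]` is also parsed.

## Known limitations

- Intruder flagging approximates a manual curation step; its defaults are
  package choices, not measured from curated data.
- The exact printed forms of the SGS/NBS formulas in the source are images;
  the Jaccard-pair reading implemented here matches the printed anchors
  (range 0–1, "complete disjunction" to "absolute stability") and is
  swappable.
- The pipeline neither roots the eukaryote subtree nor infers the position
  of the eukaryote root; gene families are consumed as externally inferred
  trees, and no alignment-level analysis is performed.

## A small worked run

```{r worked, eval = FALSE}
cfg <- simulation_config(seed = 7, scenario = "EGT",
                         donor_group = "Alphaproteobacteria",
                         loss_prob = 0.1, n_replicates = 100,
                         q_instability = 0.05)
ds <- simulate_dataset(cfg, n_families = 10)
scan <- run_pipeline(ds)
summary(scan)
plot(scan)
```
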