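# lecatrace

Tracing the prokaryotic origins of ancestral eukaryotic (LECA) genes from
single-gene trees.

## What problem this solves, and for whom

Genes present in the last eukaryotic common ancestor (LECA) descend from
several prokaryotic sources: the archaeal host lineage, the
alphaproteobacterial mitochondrial endosymbiont (via endosymbiotic gene
transfer, EGT), and other bacterial donors. Phylogenomicists try to read
each gene's origin off its gene-family tree — an unrooted ML tree in which
a clade of eukaryotic sequences branches somewhere among prokaryotes. The
intuitive rule, "the origin is the sister clade", fails routinely: one
recently transferred prokaryotic sequence next to the eukaryotes produces a
confident and wrong group-level call, and horizontal gene transfer (HGT)
among prokaryotes plus patchy taxon sampling blur everything else.

`lecatrace` is for molecular evolution researchers who have per-family ML
trees with bootstrap replicate ensembles and a taxonomy of the sequences,
and want reproducible, support-aware origin calls. It provides:

- **LECA clade detection** on unrooted trees. Monophyly is formalised as
  the *clan* (one side of a bipartition). A eukaryotic clan traces back to
  LECA when it spans enough eukaryotic supergroups: at least two Unikont
  species and two Plantae, or two Unikonts and two Chromalveolates, or two
  Plantae, two Chromalveolates and a kinetoplastid — species counted, not
  sequences.
- **Representative sampling**: least-squares rooting of each clade subtree
  (root at the point minimising the variance of root-to-leaf distances)
  and iterative pruning of the deepest leaves down to k = 10.
- **Configuration classification.** A clade is *group-related* to a
  prokaryotic group X only when it branches inside a clan whose prokaryotic
  members are all X and represent at least a per-group threshold of
  distinct species (e.g. 5 of 10 sampled Alphaproteobacteria; sparsely
  sampled groups can never be assigned); else *bacterial-* or
  *archaeal-domain-related* (≥ 10 species); else *three-domain* when all
  three domains are monophyletic with ≥ 10 species per prokaryotic domain;
  else *unclear*; *paraphyletic* when the representatives are not a clan.
- **Support statistics for a region of the tree.** With N bootstrap trees
  and G_i the eukaryote sister set in replicate i:
  - NBS = 100/N x #{replicates containing the tripartition at the base of
    the eukaryotic stem};
  - SGS = 2/(N(N−1)) x Σ_{i<j} s(G_i, G_j), with s the Jaccard index and
    s = 0 for pairs involving a paraphyletic replicate. SGS runs from 0
    (disjoint sister sets) to 1 (absolute stability).
- **SGS threshold calibration** on reference genes of known origin
  (e.g. mitochondrion-encoded genes, which must trace to
  Alphaproteobacteria): the smallest SGS above which every reference is
  correctly assigned.
- **A gene-tree simulator** (species trees, gene loss, HGT/EGT, emulated
  bootstrap ensembles with controllable stability of the eukaryote
  attachment) so the whole pipeline is testable without external data.

## Worked example

Simulate ten gene families whose eukaryotic gene was acquired from
Alphaproteobacteria (10% per-species gene loss, 100 bootstrap replicates
per family, 5% probability that a replicate perturbs the eukaryote
attachment), then run the pipeline:

```r
library(lecatrace)

cfg <- simulation_config(seed = 7, scenario = "EGT",
                         donor_group = "Alphaproteobacteria",
                         loss_prob = 0.1, n_replicates = 100,
                         q_instability = 0.05)
ds   <- simulate_dataset(cfg, n_families = 10)
scan <- run_pipeline(ds)
summary(scan)
```

```
LECA origin scan
  retained clades:    10
  no-LECA families:   0
  ambiguous discards: 0
  intruder prunings:  0

ML configuration counts:

group:Alphaproteobacteria
                       10

Modal bootstrap configuration counts:

group:Alphaproteobacteria
                       10

Support: median NBS = 94 ; median SGS = 90.67173 %
```

All ten clades are traced to the donor group, in the ML tree and as the
modal configuration across their bootstrap ensembles. The per-clade table
carries the evidence:

```r
scan$clades[1:3, c("clade_id", "ml_config", "modal_config", "nbs", "sgs_percent")]
#>   clade_id                 ml_config              modal_config nbs sgs_percent
#> 1 fam001.1 group:Alphaproteobacteria group:Alphaproteobacteria  96    94.86566
#> 2 fam002.1 group:Alphaproteobacteria group:Alphaproteobacteria  95    91.46320
#> 3 fam006.1 group:Alphaproteobacteria group:Alphaproteobacteria  95    92.39646
```

NBS near 95 reflects the 5% replicate instability; SGS sits a little lower
because perturbed replicates also drag pairwise sister-set similarity down.
`write_leca_report(scan, "report/")` writes the clade table, configuration
counts and logs as TSV; `plot(scan)` draws the per-clade NBS/SGS bars
coloured by configuration.

A thin command-line front end over the same functions ships in
`inst/scripts/lecatrace.R` (subcommands `simulate`, `run-all`,
`calibrate`).

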