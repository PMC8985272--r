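---
title: "Synteny-aware pangenome graphs: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-aware pangenome graphs: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangraphr)
library(igraph)
```

## The problem

A bacterial species is poorly described by any single genome: strains gain
and lose genes through horizontal transfer, mobile elements and
recombination, and the union of all genes across a set of related genomes —
the pangenome — is the natural object of study. Most pangenome tools reduce
this to a gene presence/absence matrix. `pangraphr` keeps the *synteny*: it
represents the pangenome as a graph whose nodes are protein clusters and
whose edges record, genome by genome, which clusters are chromosomal
neighbours. On that graph, biologically meaningful structures — allelic
variants, rare insertions, segregating insertions/deletions, mobile
elements, contamination artefacts — become recognisable topological
patterns (bubbles, cycles, isolated nodes) instead of rows in a table.

## The pipeline, stage by stage

### Protein clustering: an iterative descending-identity cascade

All predicted proteins of the cohort are clustered greedily at 90%
sequence identity. Clusters that reach the retention rule — at least as
many members as there are input genomes, by default — are *frozen* at that
tier; everything else is re-clustered from scratch at 80%, then 75%, and
finally 70%, where all remaining clusters are kept. The cascade lets
well-conserved families form at high stringency while still uniting
divergent families before the 70% floor. Anything less than 70% identical
is, by construction, a different cluster — which is exactly what makes
allelic *variants* below that floor visible as parallel nodes later.

Identity between two proteins is computed from a global alignment (BLOSUM62
scores, affine gaps with open penalty 10 and extension penalty 1) as
*identical aligned residues divided by the length of the shorter sequence*.
The shorter-length denominator matches the behaviour of the greedy
clustering tools this cascade emulates, and means a truncated protein fully
contained in its full-length homolog counts as identical — deliberate,
since truncation variants should not fragment a family.

Two details of the cascade were genuinely open and were fixed as package
design choices:

* **Retention counting.** "At least the number of input genomes" can count
  proteins or distinct genomes; the readings differ exactly when a family
  has paralogs. Both are implemented (`retention = "protein_count"` is the
  default, `"genome_count"` the alternative).
* **Representative choice.** A uniformly random member is the documented
  representative choice, and `choose_representative()` implements it with a
  seeded stream keyed by `(seed, cluster_id)` so the pick is reproducible.
  The cluster objects, however, keep the greedy *founder* as the working
  representative: the founder is the only member that provably has identity
  at or above the cluster's tier to every other member, and downstream code
  (and the test suite's alignment oracle) relies on that bound. A random
  member carries no such guarantee once members sit at, say, 0.78 pairwise
  identity in a tier-0.80 cluster.

Greedy clustering processes sequences in decreasing length order with a
lexicographic tie-break, making results deterministic where incremental
clustering tools are input-order dependent. Exact duplicate sequences are
grouped before alignment; this is provably faithful to the sequential
scheme (duplicates always take the same first-match decision) and is what
makes cohorts of near-clonal genomes fast.

### Strain graphs and the pangenome graph

Each input GFF3 file is one *strain*. Its strain graph has one node per
CDS, adjacency edges between genes with consecutive ordinals on the same
contig, and paralogy edges forming a clique among same-cluster genes of the
genome. Adjacency is defined purely by order on the annotated sequence:
strand is stored but ignored, and contig breaks sever adjacency. Contigs
are linear by default; a per-contig circular flag closes the ring
(finished replicons), implemented only for contigs with at least three
genes so no duplicate edge can arise.

The pangenome graph has one node per cluster. An edge's weight is the
number of *genomes* in which the two clusters are adjacent — two
adjacencies of the same pair inside one genome still count once. Edges
with weight below `w_min` are dropped; nodes never are. The default
`w_min = 1` draws every observed adjacency; raising it to 2 removes
single-genome adjacencies, which is what isolates assembly artefacts and
free-floating mobile genes (see *orphans* below).

### Paralog splitting by genomic neighbourhood

A cluster with two or more members in one genome sits at several genomic
locations and would tangle the graph if kept as one node. The package
determines the minimal number of *unrelated neighbourhoods* of the cluster:
every occurrence (locus) across all genomes becomes a vertex of an
occurrence graph, two occurrences are connected when their flanking cluster
sets (clusters of the adjacent loci, window of one gene on each side by
default) intersect, and each connected component becomes one subcluster
(`c00017_1`, `c00017_2`, ...). This was the main algorithmic gap in the
method's description; connected components of the shared-flank graph are
the minimal grouping in which related contexts stay together, and the
window is configurable where one flank gene is not enough context.
Splitting runs on unfiltered adjacency information, and the pangenome graph
is then rebuilt, re-weighted and re-filtered, so rare contexts split
correctly even under `w_min > 1`. Tandem copies flank each other, so they
remain one neighbourhood and surface as a self-loop instead.

### Occupancy partitions

With `f` the fraction of genomes carrying a (sub)cluster, the partition is
`hard_core` if `f >= 0.99`, `soft_core` if `f >= 0.95`, `shell` if
`f >= 0.15`, and `cloud` otherwise. Each boundary uses `>=`, and fractions
are compared exactly — they are ratios of small integers, so no epsilon is
warranted. The hard/soft distinction absorbs occasional losses to
sequencing or assembly error; the shell holds lineage-discriminating
structure; the cloud holds rarities, recent transfers and artefacts.

### Chromosomization

Given finished *template* genomes whose contigs map to named replicons, a
subcluster is assigned the replicon of its template members: one distinct
label assigns it, conflicting labels give `undetermined`, no template
member gives `unknown`. Multiple templates aggregate by label-set union,
and any conflict — within or across templates — is `undetermined`.
Assignment happens at subcluster level, so a repeat split into
replicon-specific contexts resolves cleanly, while a repeat whose contexts
share a flank (an IS-element cassette present on both chromosomes) stays
one subcluster and is flagged `undetermined` — the classic signature of a
repeat-induced misassembly, worth visual inspection.

### Pattern detection

Five pattern classes are read off the filtered pangenome graph. Self-loops
and paralogy edges are excluded throughout.

* **Orphans** — nodes with no adjacency edge but present in two or more
  genomes: no consistent neighbourhood, i.e. contamination contigs,
  assembly artefacts, or small mobile elements. Detection runs after the
  `w_min` filter, so orphan calls depend on it by design: at `w_min = 1` a
  mobile gene still has its scattered weight-1 edges, at `w_min = 2` it
  stands alone.
* **Uniques** — nodes whose strain set has exactly one genome, regardless
  of connectivity.
* **Variants** — parallel alternatives in one genomic slot: nodes of degree
  one or two grouped by their *exact* neighbour set; a group of two or more
  internal nodes between the same anchors is a variant group. The
  exact-set grouping covers both the two-anchor and the dead-end case
  deterministically; subset semantics would make a degree-one node a
  member of every group containing its neighbour, which is why it was not
  used. Groups report shared strains so users can separate true alleles
  (disjoint carriers) from co-resident copies.
* **Insertions** — an anchor pair joined both directly (the ancestral
  adjacency) and by an alternative simple path of 1 to `max_insertion_len`
  (default 10) nodes, all of them shell or cloud. A core node on the
  bypass disqualifies it.
* **InDels** — cycles of more than four nodes, with no restriction on
  member frequency. Exhaustive simple-cycle enumeration is exponential, so
  the detector reports the cycles of a *minimum cycle basis*, computed
  Horton-style (per-vertex BFS candidate cycles, shortest-first greedy
  selection under GF(2) independence) with deterministic tie-breaking.
  Candidates are capped at `max_cycle_len` (default 100) nodes; because the
  greedy fills the basis shortest-first, the cap can only suppress basis
  cycles longer than the cap — cycles that would not be reported anyway.
  A full circular replicon is itself a cycle; at default scale it exceeds
  the cap, and on very small graphs the cap should be set below the ring
  size (the test suite uses 20 on its 85-gene cohorts).

One overlap is inherent to the definitions: an insertion of three or more
genes forms, together with its direct anchor edge, a cycle of more than
four nodes, so it is legitimately reported both as an insertion and as an
InDel. The synthetic truth manifests encode this double expectation rather
than pretending the classes are disjoint.

### Highlighting

`highlight_strains()` overlays a genome group: nodes and edges covered by
the group are marked `"orange"`; adjacencies the group carries that fell
below `w_min` are *added* and marked `"yellow"`, never silently mixed with
supported edges, and re-application is idempotent (a yellow element stays
yellow). `highlight_clades()` adds per-clade membership and
specifically-present/absent flags from two-column clade tables — a minimal
dialect of the tables produced by gene-history pipelines; gene-set IDs that
no longer exist after subcluster renaming warn rather than fail. Colours
are stored as plain attribute values so any GraphML viewer can style them.

## The synthetic cohort generator

`generate_cohort()` produces the package's test bed: GFF3 + protein FASTA
cohorts with a collinear core backbone over one or more (optionally
circular) replicons and planted structures, each recorded in a truth
manifest (member loci, carriers, expected partition, expected pattern
class, expected replicon class). The default configuration — 20 genomes,
a 400-gene circular backbone split 300/100 over two replicons, 5 uniques,
3 orphans with 5 carriers, 4 variant pairs split across cohort halves, 4
three-gene insertions in 4 carriers, 3 six-node InDel loops, 2 two-context
paralog families, 1 cross-replicon cassette, and 6 backbone families with
per-genome divergence at identity 0.98/0.93 — is the study condition for
the end-to-end validation, sized so a full run takes well under a minute
on one CPU.

What it emulates, and what it does not: backbone proteins are independent
random sequences (mutual identity far below the 0.70 clustering floor; the
planted variant allele pairs are explicitly verified below 0.70 during
generation and regenerated otherwise, while the backbone relies on the
astronomically small collision probability of random sequences rather than
an all-pairs scan). Family divergence is substitution-only by default, so
target identities are hit exactly within 1/(2L); an option for
length-changing mutations would exercise the shorter-length denominator
but is not needed by the planted structures. There is no phylogeny, no
codon structure, no gene-length or GC realism, no annotation error model.
Passing the recovery tests therefore demonstrates the graph machinery and
detectors are correct under controlled conditions — not that real cohorts,
with fragmented assemblies and annotation noise, will be as clean. On real
data the `w_min` filter and the orphan/unique reports are the tools for
exactly that noise.

The manifest's pattern expectations are defined under `w_min = 2`
(recorded as `analysis_w_min` in the configuration): weight-1 edges are
precisely what carries the unrelated neighbourhoods of orphans and the
private context of uniques, mirroring how the graph filter is meant to be
used on larger cohorts.

Everything is a deterministic function of the configuration and one seed:
the generator runs inside a scoped RNG (derived sub-seeds per genome,
slot and cluster), writers emit sorted, timestamp-free output, and two
runs with equal seeds are byte-identical — which is itself part of the
test suite and the acceptance checks.

## Numerical and degenerate-input choices

* Identity values are exact ratios from alignment match counts; partition
  fractions are compared without tolerance. The only tolerance in the
  system is the ±0.02 target band of `mutate_protein()`.
* Empty inputs are contracts, not errors: a header-only GFF3 yields an
  empty record table with a warning; an empty FASTA an empty protein set;
  an empty pattern report writes header-only files and empty subgraphs.
* Malformed inputs fail loudly and specifically: wrong column counts name
  the line, CDS without ID name the feature, duplicate IDs name the
  duplicate, configuration validation aggregates all violations into one
  message.
* Ties everywhere are broken lexicographically (greedy processing order,
  subcluster numbering by smallest member locus, cycle rotation starting at
  the smallest node toward its smaller neighbour), so no output depends on
  hash or insertion order.

## Sizes used by the validation suite

The test suite exercises the full default cohort once (20 genomes, ~8,400
proteins) and otherwise uses 6–8 genome cohorts with 85–110 gene backbones,
chosen so the complete suite, including the exhaustive-alignment oracle
sweeps, runs in a few minutes on one CPU. The acceptance script
(`scripts/acceptance.R`) regenerates its cohorts from its `--seed`
argument at the same sizes.

## Known limitations

* The minimum cycle basis is a deterministic, tractable stand-in for "all
  cycles": two InDels sharing edges can be reported as one basis
  combination, and structures longer than `max_cycle_len` are not
  reported.
* Insertion search enumerates simple paths within the shell/cloud
  subgraph; pathological dense accessory regions could make this slow, and
  `max_insertion_len` is the guard.
* Chromosomization trusts template annotations; a misassembled template
  contaminates assignments (the `undetermined` class is the safety valve).
* The clustering cascade is quadratic in the number of *distinct* new
  sequences per tier; cohorts of highly diverged genomes (little exact
  duplication) are the slow case. The implementation is not parallelised.

## A worked miniature

```{r miniature}
co <- generate_cohort(
  fixture_config(
    n_genomes = 6L,
    replicons = data.frame(label = c("chromosome_1", "chromosome_2"),
                           n_genes = c(60L, 25L), circular = c(TRUE, TRUE)),
    n_uniques = 2L, n_orphans = 1L, orphan_carriers = 3L,
    n_variant_pairs = 2L, n_insertions = 1L, insertion_carriers = 2L,
    indel_loop_lengths = 6L, n_paralog_families = 1L,
    n_cross_replicon_repeats = 1L, n_diverged_high = 1L,
    n_diverged_low = 1L, seed = 7L),
  file.path(tempdir(), "vignette_cohort"))

res <- run_all(validate_config(overrides = list(
  gff_dir = co$paths$gff_dir, proteins = co$paths$proteins,
  out_dir = file.path(tempdir(), "vignette_run"),
  w_min = 2L, templates = co$paths$templates,
  circular_contigs = co$paths$circular, max_cycle_len = 20L, seed = 7L)))

table(V(res$pangenome)$partition)
res$report
evaluate_recovery(co$manifest, res$pangenome, res$strain_graphs,
                  res$report, chromosomes = res$chromosomes)$classes
```
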