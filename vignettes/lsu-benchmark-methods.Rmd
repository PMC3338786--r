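---
title: "Benchmarking LSU rDNA amplicon classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking LSU rDNA amplicon classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsubench)
```

## The problem

Amplicon surveys of fungal communities increasingly target the nuclear
large-subunit (LSU, 25--28S) ribosomal RNA gene. Next-generation platforms
return short reads, so three experimental choices dominate the quality of the
taxonomic picture a survey produces: which primer the read starts from (and
hence which part of the gene it samples), how long the read is, and how much
per-base sequence error it carries. On top of that, the classification method
itself -- similarity search parsed by a lowest-common-ancestor (LCA)
consensus, a naive Bayesian k-mer classifier, or phylogenetic placement --
trades recovery against erroneous assignments in characteristic ways.

`lsubench` makes these trade-offs measurable without any external data: it
generates a reference database with the statistical structure the question
needs (rank-structured divergence, a mosaic of conserved and divergent
domains, embedded primer sites), simulates primer-anchored reads at chosen
lengths and error rates, classifies them with three classifiers, and scores
the results per taxonomic rank in complete and leave-one-out search
scenarios.

## Metrics

For a set of queries evaluated at one rank:

* **recovery** -- proportion of queries classified with the correct taxon;
* **erroneous recovery** -- proportion classified with a wrong taxon;
* **coverage** -- proportion classified at all, so
  coverage = recovery + erroneous recovery.

Queries whose true lineage does not name a rank are excluded from that rank's
denominator: a truth-side annotation gap is not a classifier error. In the
leave-one-out scenario the query's own record is removed from the searchable
set, so a correct species call needs a second conspecific record, a correct
genus call a second congeneric species, and so on -- the standard emulation
of an incomplete reference database.

## The synthetic reference database

`sim_config()` describes a balanced taxonomy (by default 2 phyla x 2 classes
x 2 orders x 2 families x 2 genera x 2 species = 64 species, one record
each) and a domain architecture of 3,396 bp with 12 divergent domains
interleaved with 13 conserved segments, echoing the classic divergent-domain
map of the eukaryote LSU gene. A root sequence is evolved down the taxonomy:
on each branch every position mutates independently with probability
(segment rate x rank multiplier). Substitutions only -- no indels -- so
primer coordinates and fragment arithmetic stay exact throughout.

Default rates are stand-ins chosen once, not measurements: conserved
segments mutate at 0.001 per site per branch, divergent domains at 0.02, and
primer-binding sites at 0.0005 (a primer site is, by construction, the most
conserved sequence around). Rank multipliers (4, 3, 2.5, 2, 1.5, 1.2, 1 from
kingdom down to species) make divergence accumulate toward the root so that
congeneric sequences stay cohesive (about 2% pairwise distance) while phyla
are clearly separated (tens of percent in divergent domains). These values
were chosen so that the generator satisfies its own stated properties --
primer sites findable at one mismatch in at least 95% of records,
within-genus identity above between-phylum identity, and neighbor joining
recovering the generating topology on small trees -- and they are not
revisited per experiment.

What the generator deliberately does **not** emulate: indel variation and
length heterogeneity of real expansion segments, rRNA secondary structure,
introns, chimeras, and PCR amplification bias. Passing benchmarks on this
material therefore demonstrates the correctness and relative behavior of the
classification machinery under controlled divergence, not absolute accuracy
figures for any real community.

## Reads, primers, and the error model

Twelve published LSU primers are bundled with their coordinates on the
*S. cerevisiae* 25S gene (`lsu_primers()`); the benchmark uses LR0R, LR3,
LR5, and LR7, which span the 5' region used in fungal phylogenetics.
Binding sites are located by scanning both strands with IUPAC-aware
matching, allowing one mismatch; ties go to the 5'-most forward-strand site,
deterministically. Reverse primers are matched as reverse complements --
their published ranges print descending coordinates because the range runs
5' to 3' of the primer itself.

Fragments of 50, 100, 200, and 400 bp are clipped in sequencing direction
starting at the primer's 5' end (the primer span is part of the read, as in
real amplicons; the choice is parameterized). Per-base errors are
independent substitutions at rate r, with the substituted base drawn from
the three alternatives, so the count of errors in a read of length L is
exactly Binomial(L, r); rates 0.01%, 0.1%, 1%, and 10% are the benchmark
grid. Indel and quality-profile error models are out of scope.

Reads from reverse primers are emitted in sequencing direction, i.e.
reverse-complemented relative to the reference strand. The classifiers
normalize orientation first (`orient_reads()`): a read is flipped when its
reverse complement shares more 11-mers with the reference database than the
read does -- the same strand handling any practical search or classification
pipeline performs. The vote is robust even at 10% per-base error, where
roughly 30% of a read's 11-mers still survive intact.

Mock communities hold one read per parent for every (primer, rate) cell,
restricted to parents on which all four primer sites are detectable, so all
communities share an identical parent set. The benchmark subsamples this
pool once to 33 parents -- equal-size communities of 33, the same community
size the metrics are designed around -- and reuses the same 33 parents for
every stage.

## The three classifiers

**Naive Bayesian k-mer classifier** (`nbc()`, `predict()`). Training records
the distinct 8-mers of each reference; for word *w*, the corpus prior is
P = (n(w) + 0.5) / (N + 1) and the genus conditional is
(m(w) + P) / (M + 1), where n(w) counts training sequences containing *w*,
m(w) those within the genus, N and M the corresponding sequence totals.
A query is placed at the genus maximizing the summed log conditionals over
its distinct words; higher ranks derive from the winning genus' lineage, and
species is never claimed. Confidence comes from 100 bootstrap replicates of
ceiling(W/8) words each; the recommended confidence cutoffs (50% below
250 bp, 80% otherwise) can be applied post hoc. Ties are broken uniformly at
random from the seeded stream. Words containing non-ACGT symbols are
skipped; duplicate words within one sequence count once. Leave-one-out
classification downdates the training counts exactly rather than retraining.

**Similarity + LCA** (`classify_lca()`). An affine-gap Smith--Waterman
search (match +2, mismatch -3, gap open 5, gap extend 2 -- blastn-like
rewards, raw score in place of a bit score) produces scored hit lists. The
MEGAN-style consensus retains hits at or above a minimum score (50 for 50 bp
reads, 100 otherwise -- thresholds on this package's raw-score scale), applies
the winscore floor when positive, keeps hits within top-percent (1%) of the
best, and assigns the lowest common ancestor of the retained subjects'
lineages. A minimum-support rule (default 1 = disabled) can push unsupported
taxa to ancestors. Naive Bayes output can be re-parsed through the same
stage with confidence-as-score (minimum score 50, top percent 100), which
reconciles classifier lineages against the reference taxonomy by collapsing
to the deepest shared ancestor.

**Neighbor-joining placement** (`classify_nj()`). A simplified
phylogeny-based classifier: candidates at >= 90% local-alignment identity
are compiled under diversity quotas (>= 1 phylum, 2 classes, 3 orders, 5
families, 10 genera; at most one record per species), p-distances are taken
from query-anchored pairwise global alignments, a neighbor-joining tree is
built and rooted at the non-query leaf most distant from the query, and the
assignment is the lineage LCA of the query's smallest enclosing non-trivial
clade. 100 bootstrap replicates resample alignment columns; the conventional
95% support cutoff can be enforced post hoc. This replaces the full
Bayesian machinery of phylogenetic assignment tools with a deterministic
distance-based rule -- an intentional simplification; its behavior (strong
on long queries, fragile on short ones, heavy recovery cost under the 95%
cutoff) is what the benchmark studies.

## Community comparison

Assignments are summarized at the order rank (coarse enough to damp
misclassification noise), profiles are rescaled to the smallest placed total
with largest-remainder rounding, and pairwise distances are computed with
two indices: Bray--Curtis on counts, and a simplified UniFrac on the
taxonomy tree with unit edge lengths -- the fraction of union path edges not
on any shared taxon's path (presence/absence; read counts do not weight
edges). Unplaced reads are excluded from both indices but reported so totals
reconcile. Ordination is Kruskal stress-1 NMDS in two dimensions, best of
ten starts (one classical-scaling start plus nine seeded random starts, each
run to convergence at relative tolerance 1e-8); zero distances between
distinct items are clamped to a tiny epsilon so monotone regression is well
defined.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere.
* Name matching is exact and case-sensitive after whitespace normalization;
  synonyms and anamorph names are not reconciled.
* The dedupe key for "non-redundant" filtering is the exact (sequence,
  species) pair, so identically sequenced sister species are both kept.
* The LCA of an empty retained-hit set is "unclassified", never the root.
* The Smith--Waterman raw score replaces a search engine's bit score; the
  50/100 minimum-score defaults are calibrated to this package's scale and
  are configurable.
* One root seed fans out to per-stage child seeds by stable label hashing
  (`derive_seed()`), so adding a stage never perturbs another stage's
  stream; reruns with the same configuration are bit-identical.
* Annotation degradation truncates lineages at a uniformly chosen rank at
  or above genus.

## Problem sizes

The bundled study conditions are a 64-species database (one record per
species, 3,396 bp), 33-parent mock communities, four primers, read lengths
50--400 bp, five error rates, and 100 bootstrap replicates per query --
sizes at which the complete grid (three classifiers, both scenarios) runs
end to end on a single CPU in well under half an hour. All of them scale
through `benchmark_config()`.

## Worked example

```{r example, eval = FALSE}
cfg <- benchmark_config(seed = 1)
res <- run_benchmark(cfg)

# genus-rank recovery by read length, mean over the four primers
g <- res$length_grid[res$length_grid$rank == "genus" &
                       res$length_grid$scenario == "leave_one_out", ]
aggregate_sem(g, "recovery", c("method", "L"))

# error-degradation deltas and community ordination
aggregate(delta ~ method + rate, res$error_tracking, mean)
res$community[["lca bray_curtis"]]$nmds$stress
```

## Known limitations

The generator's divergence rates are plausible stand-ins, not fitted to real
LSU alignments; absolute recovery numbers therefore should not be read as
predictions for field data. The LCA stage consumes this package's own
alignment scores, so its minimum-score settings are not interchangeable with
thresholds quoted for other search engines. The placement classifier is a
deliberate simplification of full statistical assignment. Finally, amplicon
biology that the simulator omits (amplification bias, chimeras, indels) can
dominate real surveys; the benchmark isolates classification behavior from
those factors rather than modelling them.
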