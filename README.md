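# lsubench

Simulation benchmark for taxonomic classification of nuclear large-subunit
(LSU, 25–28S) ribosomal DNA amplicons. Fungal amplicon surveys that target
LSU must choose a primer, a read length, and a classification method, and
must live with sequencing error; each choice changes both per-read
classification accuracy and the community composition the survey appears to
find. `lsubench` measures those effects end to end on synthetic data with
known truth, so no reference downloads are required.

The package provides:

* a **synthetic reference generator** — a balanced taxonomy over the seven
  ranks kingdom→species whose sequences evolve by substitution down the
  tree, with a mosaic of conserved cores and 12 divergent domains over
  ~3.4 kb and embedded binding sites for published LSU primers (LR0R, LR3,
  LR5, LR7, and eight more in `lsu_primers()`);
* a **read simulator** — IUPAC-aware primer-site location (one mismatch
  allowed, both strands), fixed-length clipping in sequencing direction
  (50/100/200/400 bp), an independent per-base substitution error model, and
  equal-size mock communities;
* three **classifiers** behind one assignment interface:
  * `nbc()` / `predict()` — naive Bayesian 8-mer classifier with
    word prior `(n(w)+0.5)/(N+1)`, genus conditional `(m(w)+P)/(M+1)`,
    100-replicate bootstrap confidence, and length-dependent confidence
    cutoffs (50% < 250 bp, else 80%);
  * `classify_lca()` — affine-gap Smith–Waterman search (+2/−3, gap 5+2k)
    parsed by a MEGAN-style lowest-common-ancestor consensus
    (min support / min score / top percent / winscore);
  * `classify_nj()` — simplified phylogenetic placement: ≥90%-identity
    homologs under diversity quotas, neighbor-joining on p-distances,
    bootstrap support with an optional 95% cutoff;
* an **evaluation harness** — recovery, erroneous recovery, and coverage per
  rank (recovery + erroneous = coverage), complete vs leave-one-out search
  scenarios, SEM aggregation across primers, and error-degradation tracking
  of the reads correct at zero error;
* **community comparison** — order-rank profiles, size normalization,
  Bray–Curtis (`Σ|p−q| / Σ(p+q)`) and a simplified taxonomy-based UniFrac
  (fraction of union path edges unique to one community), NMDS ordination,
  and primer pooling.

## Worked example

```r
library(lsubench)

cfg <- benchmark_config(seed = 1)   # 64-species db, 33-parent communities
res <- run_benchmark(cfg)

g <- res$length_grid[res$length_grid$rank == "genus" &
                     res$length_grid$scenario == "leave_one_out", ]
aggregate_sem(g, "recovery", c("method", "L"))
```

```
 method   L      mean        sem n_rep sem_defined
    lca  50 0.1818182 0.16224625     4        TRUE
    lca 100 0.4621212 0.18197594     4        TRUE
    lca 200 0.6893939 0.19220141     4        TRUE
    lca 400 0.9621212 0.03787879     4        TRUE
    nbc  50 0.1742424 0.15470135     4        TRUE
    nbc 100 0.4772727 0.19418190     4        TRUE
    nbc 200 0.7121212 0.18700514     4        TRUE
    nbc 400 0.9696970 0.02142748     4        TRUE
     nj  50 0.2500000 0.12018186     4        TRUE
     nj 100 0.5000000 0.17253223     4        TRUE
     nj 200 0.7500000 0.18028605     4        TRUE
     nj 400 1.0000000 0.00000000     4        TRUE
```

Each row is the mean (± standard error over the four primers) of the
proportion of reads whose genus was recovered in a leave-one-out search at
that read length: recovery grows with read length, and primers anchored next
to divergent domains (LR0R, LR3) outperform those in conserved sequence
(LR5, LR7), which is what drives the between-primer SEM. `res` also carries
the error-degradation table (`res$error_tracking`: change in recovery of the
zero-error-correct reads as the per-base error rate rises to 10%), the
full-length parent identity check (`res$parent_eval`), and community
distance matrices with their NMDS ordinations (`res$community`).

The numbers above are from the bundled default configuration; your exact
values depend on the seed. See the vignette
(`vignettes/lsu-benchmark-methods.Rmd`) for the model, parameter, and
design-choice documentation.

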