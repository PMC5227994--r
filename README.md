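# microprofiler

Taxonomic and functional profiling of microbial communities from 16S rRNA
data, as one reproducible R package. It takes per-sample read files —
16S amplicons, or shotgun metagenomes from which 16S fragments are first
extracted — plus a reference database (16S sequences, rooted phylogeny,
taxonomy, 16S copy numbers, KO traits, pathway map) and produces, with a
single command: calibrated OTU and taxonomy tables, predicted KO/pathway
profiles with NSTI reliability scores, alpha-diversity statistics and
rarefaction curves, a phylogeny-aware beta-diversity distance matrix with
PCoA/UPGMA and a permutation group test, biomarker rankings, and a
co-occurrence network with topology statistics.

It is aimed at method developers and teachers who need a *complete,
inspectable, deterministic* pipeline at desk scale: every stage is plain R
(alignment kernels in C++), every default is documented, and the package
ships a synthetic reference-database and read simulator so the whole
analysis is testable end to end without any external database.

## The methods in brief

- **16S detection** (shotgun mode): position-specific log-odds profile,
  scored on both strands by local alignment with affine gaps; the score
  threshold is calibrated on an empirical null of uniform-random reads.
- **OTU picking**: k-mer-prefiltered banded semi-global alignment; a read
  is assigned to its best reference at identity ≥ 0.97, where identity =
  matches / alignment columns spanning the read.
- **Copy-number calibration**: relative abundance
  `a_i = 100 · (n_i/k_i) / Σ_j (n_j/k_j)` with `k_i` the organism's 16S
  copies per genome — raw 16S counts over-represent high-copy organisms.
- **Functional prediction**: each OTU inherits the KO trait vector of its
  nearest individually sequenced taxon on the phylogeny;
  `ko[k] = Σ_i (a_i/100) · t_{nn(i),k}`. Reliability is the NSTI,
  `Σ a_i d_i / Σ a_i`, the abundance-weighted distance to those taxa.
- **Alpha diversity**: observed OTUs, Shannon (nats), Gini–Simpson,
  bias-corrected Chao1 `S_obs + F1(F1−1)/(2(F2+1))`; bootstrap rarefaction
  curves (B = 20) evaluated on the per-OTU mean of the bootstrap draws.
- **Beta diversity**: a tree-traversal similarity — shared abundance
  matches at the leaves, unmatched mass propagates rootward decaying by
  `exp(−β·branch length)` and can match deeper; distance `1 − S` feeds
  PCoA (classical scaling), UPGMA, and a PERMANOVA-style permutation test
  (exhaustive relabeling when feasible, Monte-Carlo otherwise).
- **Markers & network**: Wilcoxon/Kruskal–Wallis screening with BH
  correction, random-forest permutation-importance ranking; Spearman
  co-occurrence/co-exclusion edges (|rho| ≥ 0.6, q ≤ 0.05) and Freeman
  degree centralization, islands, density, diameter, radius.

The methods vignette (`vignettes/methods.Rmd`) derives each formula,
states every default with its rationale, and lists the generator's known
simplifications.

## Worked example

Simulate a ten-sample, nine-organism, two-group amplicon study against a
synthetic reference database and run the full pipeline:

```r
library(microprofiler)

ref <- make_reference_db(n_taxa = 9, seq_len = 250, seed = 1)
db  <- ref$db
des <- make_fig_design(db, seed = 5)          # 2 groups x 5 samples

dir.create("demo/reads", recursive = TRUE)
write_reference_db(db, "demo/refdb")
man <- data.frame(sample_id = des$sample_id,
                  path = file.path("demo/reads", paste0(des$sample_id, ".fasta")),
                  mode = "amplicon")
for (i in seq_len(nrow(des))) {
  p <- unlist(des[i, -(1:2)]); names(p) <- colnames(des)[-(1:2)]
  sim <- simulate_amplicon_reads(p, db, n_reads = 400, read_len = 100,
                                 err = 0.005, seed = 100 + i,
                                 sample_id = des$sample_id[i])
  write_sequences(sim$reads, man$path[i])
}
meta <- data.frame(group = des$group, row.names = des$sample_id)

res <- run_pipeline(man, meta, "demo/refdb", "demo/out", seed = 42)
```

What it prints (abridged):

```
> res$tables$genus
<abundance_table> 10 samples x 8 features (relative)
> round(res$tables$genus$values[c(1, 6), ], 1)
    g__T1 g__T14 g__T2 g__T5 g__T6 g__T7 g__T8 g__T9
S01   1.7   28.0  20.7   4.9   3.0  23.1  12.0   6.6
S06  16.4   11.1   0.5  22.1   2.2   0.5   2.9  44.2
> head(res$alpha, 3)
  sample_id observed_otus  shannon   simpson chao1
1       S01             9 1.964696 0.8382125     9
2       S02             9 2.135145 0.8743750     9
3       S03             9 2.001299 0.8541750     9
> res$permanova
PERMANOVA pseudo-F = 50.43, p = 0.0079 (252 relabelings, exact = TRUE)
> res$topology
  n_nodes n_islands   density diameter radius centralization
1       8         3 0.2857143        3      2      0.3809524
```

Reading it: the genus rows are copy-number-calibrated relative abundances
(0–100, rows sum to 100); the two displayed samples come from different
groups and show the designed disjoint dominant genera. The group test is
exact here — with two groups of five only 252 distinct relabelings exist,
and the observed between-group separation is exceeded by 2 of them
(p = 2/252 ≈ 0.0079). The genus co-occurrence network has 8 nodes in 3
islands; its largest island has diameter 3.

`demo/out/` additionally contains every table as TSV (`otu_table.tsv`,
`taxa.genus.tsv`, `ko_table.tsv`, `nsti.tsv`, `beta_distance.tsv`,
`pcoa.tsv`, `upgma.nwk`, `markers.tsv`, `network_edges.tsv`, …) and a
`pipeline.log` with one line per stage.

The same entry point is available from a shell:

```sh
exec/microprofiler run -i samples.tsv -m metadata.tsv -d refdb/ -o out/ \
    --mode shotgun --perms 10000 --seed 1
```

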