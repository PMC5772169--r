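# subtadr

Insulator-based chromatin sub-domain (subTAD) prediction and
domain-constrained enhancer-gene association, for regulatory genomics
analyses of the kind done around signal-dependent transcription factors
in macrophages: which enhancers does a factor repress or activate, and
which co-regulated genes share a chromatin compartment with them.

## What it computes

**Domain prediction** from CTCF and Cohesin ChIP-seq peak summits
collected across many samples:

1. *Consensus summits*: per chromosome, summits chained by single
   linkage at gaps `< 51` bp; clusters with `>= 2` members emit a
   consensus at the round-half-up mean position.
2. *Insulators*: consensus CTCF summits with a consensus Cohesin summit
   strictly closer than 51 bp; coverage of both proteins is averaged on
   the 100 bp window around the insulator.
3. *Orientation*: PWM scan of the ±100 bp neighbourhood on both strands
   (log-odds threshold 6); among competing hits, agreement with the
   CTCF/Cohesin binding layout outranks score. Insulators without a
   motif but with a clear binding direction inherit that orientation.
4. *Domains*: insulators above a per-protein coverage threshold
   (10⁻⁵ of the summed density, in both proteins) are paired — each
   forward insulator with its nearest downstream reverse insulator at
   distance in (1 kb, 1 Mb] — and kept when boundary coverage differs
   less than 2-fold for both proteins. Overlaps resolve greedily by
   boundary coverage; gaps between final convergent domains become
   "negative" domains.

**Enhancer classification**: replicate read counts over factor-bound
regions, RPKM-normalised, tested per region with a trend-moderated
t statistic (variance shrunk toward a loess mean-variance trend);
regions at `p <= 0.05` are *repressor* (fold < 1) or *activator*
(fold > 1), otherwise *neutral*. A paired region-set shift test
(`p < 1e-5` and mean fold `>= 1.15`) backs set-level claims.

**Expression clustering**: genes with `>= 1` FPKM in any sample enter a
per-gene two-way ANOVA (genotype × time) on `log2(FPKM + 1)` with Tukey
post hoc contrasts; genes with `p < 0.05` and fold `>= 2` at any time
are regulated. Induced genes split into 4 K-means trajectory clusters
(A-D) plus one repressed cluster (E); an LPS-pretreatment design splits
LPS-induced genes into attenuated / insensitive / increased clusters.

**Association matrix**: peaks (by summit) and genes (by TSS) are
assigned to domains; the class × cluster matrix counts co-domain pairs
and is column-standardised, connecting e.g. repressor enhancers with
the repressed gene cluster inside the same chromatin compartment.

A synthetic-data generator (`simulation_config()`, `simulate_study()`)
plants all of this — jittered summit samples, oriented motifs in a
generated genome, balanced convergent pairs plus divergent/unbalanced/
orphan decoys, negative-binomial counts with planted fold changes, and
archetype FPKM time courses with a non-responding knockout — so the
pipeline is fully testable offline.

## Worked example

```r
library(subtadr)

cfg <- simulation_config(seed = 42, chrom_lengths = c(chr1 = 4e6, chr2 = 4e6),
                         n_convergent_pairs = 12, n_divergent = 4,
                         n_unbalanced = 4, n_orphan = 2,
                         domain_len_range = c(5e3, 1e5), margin_bp = 1e5)
sim <- simulate_study(cfg, tempfile())

cs <- function(paths) consensus_summits(
  do.call(rbind, lapply(paths, read_summits, sample_id = "s")))
ins <- call_insulators(cs(sim$paths$ctcf_summits), cs(sim$paths$cohesin_summits))
ins <- quantify_insulators(ins, read_bedgraph(sim$paths$ctcf_bedgraph),
                           read_bedgraph(sim$paths$cohesin_bedgraph))
ins <- orient_insulators(ins, read_genome_fasta(sim$paths$genome),
                         read_pwm(sim$paths$pwm))
dom <- predict_domains(ins)
conv <- dom[dom$kind == "convergent", ]
head(conv[, c("chrom", "start", "end", "kind", "pair_coverage")], 3)
#>   chrom   start     end       kind pair_coverage
#> 1  chr1  461519  545937 convergent      192.7848
#> 3  chr1  801726  883779 convergent       39.5803
#> 5  chr1 1141416 1211516 convergent      174.3600

ev <- evaluate_domains(conv, sim$truth$domains)
sprintf("recall %.2f  precision %.2f", ev$recall, ev$precision)
#> recall 1.00  precision 1.00      # all 12 planted domains, no extras

rc <- read_counts_table(sim$paths$peak_counts, sim$paths$peak_design)
cls <- classify_peaks(rc)
table(cls$class)
#> activator   neutral repressor
#>        80       149        71
```

Of 100 planted repressor and 100 activator enhancers, 71 and 80 are
detected at the default dispersion (0.1) — the expected power of a
moderated test on 2-fold effects with three replicates — and every
detection carries the planted sign. Feeding the classified peaks and
the gene trajectory clusters into `assign_to_domains()` and
`association_scores()` yields the column-scaled association matrix:

```r
pk <- assign_to_domains(merge(read_narrowpeak(sim$paths$peaks), cls,
                              by.x = "name", by.y = "peak_id"), dom, "summit")
et <- expressed_genes(read_expression_table(sim$paths$expression))
calls <- call_regulated(et)
cl <- trajectory_clusters(fold_change_matrix(et)[calls$gene_id[calls$regulated], ],
                          seed = 42)
gn <- assign_to_domains(merge(read_bed(sim$paths$genes_bed),
                              cl[, c("gene_id", "cluster")],
                              by.x = "name", by.y = "gene_id"), dom, "tss")
print(association_scores(pk, gn))
#> column-scaled scores:
#>                A      B      C      D      E
#> activator  0.704  0.696  0.702  0.701 -1.147
#> neutral    0.441  0.450  0.443  0.444  0.688
#> repressor -1.145 -1.146 -1.145 -1.145  0.459
```

Repressor peaks are strongly depleted from the domains of induced gene
clusters A-D (scores ≈ −1.15) and co-occur only with the repressed
cluster E; activator peaks show the mirror image. Ubiquitous neutral
peaks dilute the E column when predicted (rather than planted) classes
are used — with planted labels the maxima sit exactly on the
(repressor, E) and (activator, A-D) cells.

The whole chain also runs as one call from a config
(`run_pipeline(config, out_dir)`), writing every stage output plus a
JSON run manifest, and reproducing outputs byte-for-byte under a fixed
seed. A thin command-line dispatcher over the same functions ships in
`inst/scripts/subtad.R`.

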