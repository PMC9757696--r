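# targetasm

Reference-guided recovery of target nuclear genes (Angiosperms353-style
loci) from high-throughput sequencing reads — genome skimming, RNA-seq, or
target enrichment — for phylogenomics. Reads covering each target locus are
a sparse fraction of such libraries, so `targetasm` works in two stages:

1. **k-mer read filtering.** All reference homologs are decomposed into
   length-*k* substrings held in an in-memory hash table; a read (or its
   reverse complement) sharing at least `min_hits` exact k-mers with a
   gene's references is binned to that gene. No mismatches are tolerated
   inside a k-mer; a `step` parameter strides the read's k-mers for speed.
   When either mate of a pair matches, both mates are recruited.
2. **Weighted de Bruijn graph assembly.** Each bin's reads (both
   orientations) become an `assembly_k`-mer graph; a greedy path is grown
   from the most abundant k-mer, visiting each node at most once. A
   candidate extension is scored by

   &nbsp;&nbsp;&nbsp;&nbsp;*W* = *count*<sup>(1 − *pos*)</sup>

   where *count* is the k-mer's abundance in the bin and *pos* the
   positional distance between candidate and current node on the gene's
   references (mean fractional positions; 1 when unreferenced). Abundance
   therefore dominates where the reference confirms the local order, and
   positional outliers decay to the weight floor.

Recovery is scored with the **T50** statistic (genes recovering ≥ 50% of
their target length, the mean reference length) and with alignment-based
**base-calling** and **indel error rates** against a gold standard. A
paired-end Illumina-like read simulator (per-base substitution errors,
diverged reference homologs) makes the whole pipeline verifiable with no
external data.

## Worked example

Simulate a 5-gene family with two congeneric-style references per gene (5%
divergence), sequence it at 20× with 0.5% base error, and run the pipeline:

```r
library(targetasm)

cfg <- sim_config(n_genes = 5, gene_length_range = c(400, 900),
                  depth = 20, seed = 7)
sim <- generate_gene_family(cfg)
d <- tempfile()
paths <- write_sim_truth(sim, d)          # reference/ dir + truth.fasta
simulate_reads(sim$truths, cfg,
               out1 = file.path(d, "r1.fq.gz"),
               out2 = file.path(d, "r2.fq.gz"))

res <- run_pipeline(paths$ref_dir,
                    file.path(d, "r1.fq.gz"), file.path(d, "r2.fq.gz"),
                    out_dir = file.path(d, "out"),
                    gold = paths$truth_fasta, quiet = TRUE)
print(res)
#> pipeline_result in /tmp/.../out
#>   5 genes | 498 reads recruited | 5 contigs
#> recovery_report: 5 genes | T50 = 5 | valid = 5
#>   aggregate base-calling error 0.02769% | indel error 0%
```

All 5 genes exceed half their target length (`T50 = 5`); contigs recover
93–99% of each gene, and across the 3611 aligned bases only one column
mismatches the truth (0.028% base-calling error, no indels). The output
directory holds the per-gene read bins (`filtered/`), per-gene and combined
contig FASTA files (`contigs/`), the per-gene recovery report, a JSON echo
of the configuration and a log.

A command-line front-end wrapping the same functions is installed at
`exec/targetasm` inside the package (subcommands `run`, `simulate`,
`evaluate`).

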