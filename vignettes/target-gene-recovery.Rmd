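---
title: "Reference-guided target-gene recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided target-gene recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetasm)
```

## The problem

Universal low-copy nuclear marker sets such as Angiosperms353 are recovered
from three kinds of high-throughput data — target enrichment, RNA-seq, and
genome skimming — in all of which the reads belonging to any one target
locus are a tiny, scattered fraction of the library. `targetasm` recovers
such loci in two reference-guided stages: reads are first *binned* per gene
by exact k-mer sharing with a reference database of homologs, and each bin
is then *assembled* on a weighted de Bruijn graph whose extension choices
are informed by where each k-mer sits on the reference. The package also
ships a read simulator and evaluation statistics so the whole pipeline can
be verified in silico.

## Read filtering

All reference sequences are decomposed into their length-*k* substrings,
which are stored in an in-memory hash table together with, per gene, the
occurrence count and the mean fractional position of each k-mer along the
gene's references. A read matches a gene when at least `min_hits` of its
k-mers (default 1) — sampled every `step` offsets (default 1) from the read
*and* from its reverse complement — occur in the table for that gene.
Matching is exact: a single mismatch anywhere in a k-mer breaks it, which
is what makes a long k-mer (default `filter_k = 31`) specific. `step > 1`
trades sensitivity for speed; the gene set found at a larger step is always
a subset of the step-1 result for the same read.

For paired input, a match by either mate recruits both mates into the bin
("pair rescue", default on): the unmatched mate often covers a flank the
reference does not, and extends the assembly. A read matching several genes
enters every matching bin, since bins are assembled independently.

The index stores the forward strand only, and reads are looked up in both
orientations. This keeps the positional statistics in reference
orientation, which the assembler's prior requires.

## Assembly on a weighted de Bruijn graph

Each bin is assembled independently at its own k-mer length
(`assembly_k = 41`, deliberately independent of — and here longer than —
the filter k, for specificity in the graph where repeats matter most).
Nodes are the N-free `assembly_k`-mers of the bin's reads and their reverse
complements, with abundances pooled per distinct k-mer string; a directed
edge joins two nodes that overlap by k−1 bases. Assembly seeks a path
visiting as many nodes as possible, each at most once.

The walk is greedy: the globally most abundant k-mer seeds the path
(lexicographic tie-break), which is extended rightwards and then leftwards
under one shared visited set. When several unvisited neighbors exist, each
candidate is scored

  W = count ^ (1 − pos),

where `count` is the candidate's abundance and `pos` the positional
distance between candidate and current node — the absolute difference of
their mean fractional positions on the gene's references. A candidate
adjacent to the current node on the reference (`pos` near 0) keeps its full
abundance weight; a positional outlier decays toward weight 1. Candidates
absent from the reference get `pos = 1`, the weight floor, so an
unreferenced k-mer never outranks a positionally consistent referenced one
of equal abundance, yet still carries the walk through unbranched regions
the references do not cover.

Weight ties are resolved by higher abundance, then by lexicographic order.
The abundance fallback is load-bearing: with congeneric references at ~5%
divergence, only a minority of 41-mers of the true sequence occur in the
references at all, so at a sequencing-error fork both branches frequently
sit at the weight floor. Falling back to abundance is exactly the consensus
decision — the error branch is supported by one read, the true branch by
the local coverage — and it is what makes the recovered error rate *drop*
as depth grows. The lexicographic last resort keeps assembly fully
deterministic: identical bins and parameters always give identical contigs.

If the seeded contig falls short of `min_length` (default
`assembly_k + 20`, suppressing trivial seed-only output), up to
`max_seed_retries = 4` further seeds — the next most abundant k-mers — are
tried and the contig visiting the most nodes is kept. Retries guard against
seeding inside a sequencing-error bubble. One contig is reported per gene;
scaffolding of disconnected components and paralog separation are out of
scope. `min_count` (node-abundance pruning) defaults to 1 — no pruning —
because recovery is expected to work down to 1× depth, where any pruning
destroys the signal.

A path of *n* nodes spells a contig of `n + assembly_k − 1` bases; the
contig may come out in either orientation, and evaluation handles that.

## Evaluation

Two statistics summarize a run against a gold standard:

* **T50** — the number of genes whose recovered length is at least 50% of
  the gene's *target length*, the mean length of its reference instances.
* **Error rates** — each contig is aligned to its truth sequence with an
  ends-free (overlap) pairwise alignment (match 1, mismatch −1, gap open 2,
  gap extend 1, via Biostrings), in whichever orientation scores higher.
  Ends-free alignment means truth overhang beyond a partial contig is not
  penalized and, symmetrically, contig overhang is not counted as indel
  error. Within the aligned span, the base-calling error rate is
  mismatching columns over both-base columns, and the indel error rate is
  gap columns over the span length. Rates are reported per gene and in
  aggregate (total mismatches over total aligned bases across genes); an
  alignment covering fewer than 20 bases yields no rates and the sequence
  is flagged invalid, as is any contig with a base-calling error rate above
  5%. The 5% validity cutoff is a documented, configurable choice
  (`max_base_error`) separating sequences usable for phylogenetics from
  assembly failures.

## The simulator, and what it does (not) emulate

`sim_config()` / `generate_gene_family()` / `simulate_reads()` emulate a
verification protocol in which truth sequences play the role of a sequenced
genome's coding sequences and diverged homologs play the role of a
congeneric reference database:

* truths are uniform random A/C/G/T strings, 400–2000 bases (the longest
  Angiosperms353 locus is no more than 2000 bp), 353 genes by default;
* each gene gets `n_homologs = 2` references derived from the truth by
  independent per-base substitution at `ref_divergence = 0.05`,
  approximating congeneric reference divergence; no reference indels;
* paired 150 bp reads are drawn from fragments with uniform starts and
  normal(350, 50) lengths clamped to `[read_length, gene length]`;
  `round(depth · L / (2 · read_length))` pairs per gene; per-base
  substitution sequencing errors at `base_error = 0.005` with uniform
  alternative bases; constant qualities.

Everything is reproducible bit-for-bit from the seed: the gene family is
drawn from `seed`, the reads from a fixed offset of it, so the same family
can be sequenced at several depths deterministically.

The model exercises the pipeline's real failure modes — missing k-mers at
low depth, false branch points from sequencing errors, reference–target
divergence breaking exact matches — but deliberately omits several features
of real libraries: empirical quality profiles and indel read errors
(substitution-only, so recovered indel error is expected to be ~0), PCR
duplicates, contamination and organellar background, paralogy, and
intron/exon structure (references and truths are both "coding-sequence
like"). Random sequences are also nearly repeat-free at k = 41, so graph
tangles from genuine repeats are underrepresented. Passing the simulated
checks therefore demonstrates the algorithmic machinery, not performance on
any particular empirical library.

## Numerical and degenerate-input choices

* Fractional k-mer position uses denominator `L − k`, spanning [0, 1]
  inclusive; a reference of length exactly k maps to position 0.
* k-mers containing any non-ACGT character are skipped everywhere (exact
  hashing needs a clean alphabet); lowercase input is uppercased on read.
* Positional statistics pool all homologs of a gene with equal weight per
  occurrence.
* Empty bins assemble to nothing (no error); genes without a contig score
  recovered length 0 and count against T50's denominator.
* `node_weight` clips `pos` into [0, 1] defensively (with a warning);
  upstream code never produces values outside it.
* Ties anywhere (seed choice, extension, orientation at equal alignment
  score) resolve deterministically, so reruns are byte-identical and
  multithreaded filtering returns exactly the single-thread bins.

## Verification at a glance

The packaged depth-gradient experiment
(`depth_gradient_experiment()`, 353 genes, depths 1/5/10/20/50×) is run by
the test suite and by `scripts/acceptance.R`. The qualitative pattern it
checks — aggregate base-calling and indel error rates non-increasing with
depth, valid-gene counts and T50 non-decreasing, and aggregate base error
under 1% from 10× up — is computed fresh on every run; the problem sizes
(353 genes at five depths, a few minutes of compute) were chosen as the
smallest faithful rendition of the protocol.
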