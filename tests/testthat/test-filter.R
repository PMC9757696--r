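test_that("kmerize enumerates stride-sampled windows and drops N windows", {
  expect_equal(kmerize("ACGTAC", 4, 1), c("ACGT", "CGTA", "GTAC"))
  expect_equal(kmerize("ACGTAC", 4, 2), c("ACGT", "GTAC"))
  expect_equal(kmerize("ACG", 4, 1), character(0))
  expect_equal(kmerize("ACNTACG", 3, 1), c("TAC", "ACG"))
  expect_equal(kmerize("acgt", 4, 1), "ACGT")
})

make_gene_set <- function(n_genes = 5, len = 400) {
  seqs <- lapply(seq_len(n_genes), function(i) {
    stats::setNames(rand_seq(len), paste0("hom", i))
  })
  names(seqs) <- paste0("g", seq_len(n_genes))
  seqs
}

test_that("classify_read recruits exact reference slices on both strands", {
  withr::local_seed(55)
  gene_seqs <- make_gene_set()
  k <- 31
  idx <- build_kmer_index(gene_seqs, k)
  fp <- filter_params(k = k)
  slice <- substr(gene_seqs$g3[[1]], 101, 250)
  expect_true("g3" %in% classify_read(slice, idx, fp))
  expect_equal(classify_read(slice, idx, fp),
               classify_read(bf_revcomp(slice), idx, fp))
})

test_that("classify_read equals the brute-force substring-sharing oracle", {
  withr::local_seed(66)
  gene_seqs <- make_gene_set(5, 400)
  k <- 21
  idx <- build_kmer_index(gene_seqs, k)
  fp <- filter_params(k = k)
  reads <- character(200)
  for (i in 1:200) {
    reads[i] <- switch(1 + (i %% 4),
      rand_seq(80),                                   # random, usually no hit
      substr(gene_seqs[[1 + (i %% 5)]][[1]], 1 + (i %% 300), 80 + (i %% 300)),
      bf_revcomp(substr(gene_seqs[[1 + (i %% 5)]][[1]], 50, 140)),
      paste0(rand_seq(40), substr(gene_seqs[[1 + (i %% 5)]][[1]], 200, 239))
    )
  }
  for (r in reads) {
    expect_setequal(classify_read(r, idx, fp), bf_classify(r, gene_seqs, k))
  }
})

test_that("min_hits counts k-mer occurrences over both strands", {
  withr::local_seed(77)
  gene_seqs <- make_gene_set(2, 200)
  k <- 31
  idx <- build_kmer_index(gene_seqs, k)
  # 30 forward k-mer starts hit; the slice's reverse-complement k-mers are
  # not on the reference's forward strand, so the total stays 30
  slice <- substr(gene_seqs$g1[[1]], 1, 60)
  expect_true("g1" %in% classify_read(slice, idx,
                                      filter_params(k, min_hits = 30)))
  expect_false("g1" %in% classify_read(slice, idx,
                                       filter_params(k, min_hits = 31)))
  # a read spliced with its own reverse complement hits on both strands
  both <- paste0(slice, "GGGGG", bf_revcomp(slice))
  expect_true("g1" %in% classify_read(both, idx,
                                      filter_params(k, min_hits = 60)))
})

test_that("stride weakens but never contradicts step=1 classification", {
  withr::local_seed(88)
  gene_seqs <- make_gene_set(4, 350)
  k <- 25
  idx <- build_kmer_index(gene_seqs, k)
  for (i in 1:40) {
    read <- substr(gene_seqs[[1 + (i %% 4)]][[1]], 1 + 7 * i, 90 + 7 * i)
    g1 <- classify_read(read, idx, filter_params(k, step = 1))
    for (s in c(2, 4, 8)) {
      gs <- classify_read(read, idx, filter_params(k, step = s))
      expect_true(all(gs %in% g1))
    }
  }
})

test_that("filter_reads rescues pairs, writes bins, and ignores order", {
  withr::local_seed(99)
  gene_seqs <- make_gene_set(3, 400)
  k <- 31
  idx <- build_kmer_index(gene_seqs, k)
  pairs <- data.frame(
    id = c("p1", "p2"),
    seq1 = c(substr(gene_seqs$g2[[1]], 1, 120), rand_seq(120)),
    seq2 = c(rand_seq(120), rand_seq(120)),
    stringsAsFactors = FALSE)
  out <- withr::local_tempdir()
  bins <- filter_reads(pairs, NULL, idx, filter_params(k), out_dir = out)
  # only r1 of p1 matches g2, yet both mates land in the bin
  expect_equal(length(bins$bins$g2), 2L)
  expect_setequal(names(bins$bins$g2), c("p1/1", "p1/2"))
  expect_equal(bins$summary$n_reads[bins$summary$gene_id == "g2"], 2L)
  expect_true(file.exists(file.path(out, "g2.fasta")))
  expect_equal(nrow(read_fasta(file.path(out, "g2.fasta"))), 2L)
  # non-matching genes produce no bin file
  expect_false(file.exists(file.path(out, "g1.fasta")))

  # without rescue, the unmatched mate stays out
  bins2 <- filter_reads(pairs, NULL, idx, filter_params(k),
                        pair_rescue = FALSE)
  expect_equal(names(bins2$bins$g2), "p1/1")

  # order invariance (bins as sets)
  bins_rev <- filter_reads(pairs[2:1, ], NULL, idx, filter_params(k))
  expect_setequal(names(bins_rev$bins$g2), names(bins$bins$g2))
})

test_that("filter_reads on zero input yields empty bins", {
  idx <- build_kmer_index(list(g = "ACGTACGTACGTACGTACGTACGTACGTACGTA"), 31)
  pairs <- data.frame(id = character(), seq1 = character(),
                      seq2 = character(), stringsAsFactors = FALSE)
  bins <- filter_reads(pairs, NULL, idx, filter_params(31))
  expect_equal(bins$n_scanned, 0L)
  expect_true(all(bins$summary$n_reads == 0L))
})

test_that("simulated bins are dominated by reads of their own gene", {
  withr::local_seed(101)
  cfg <- sim_config(n_genes = 5, gene_length_range = c(400, 800),
                    depth = 10, seed = 424243)
  sim <- generate_gene_family(cfg)
  rd <- simulate_reads(sim$truths, cfg)
  idx <- build_kmer_index(sim$references, 31)
  bins <- filter_reads(rd$reads[, c("id", "seq1", "seq2")], NULL, idx,
                       filter_params(31))
  origin <- stats::setNames(rd$provenance$gene_id, rd$provenance$read_id)
  for (g in names(bins$bins)) {
    expect_gt(length(bins$bins[[g]]), 0)
    from <- origin[sub("/[12]$", "", names(bins$bins[[g]]))]
    expect_gte(mean(from == g), 0.9)
  }
})
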