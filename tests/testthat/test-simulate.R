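test_that("zero divergence yields references identical to truths", {
  cfg <- sim_config(n_genes = 4, gene_length_range = c(300, 500),
                    ref_divergence = 0, seed = 9)
  sim <- generate_gene_family(cfg)
  for (g in names(sim$truths)) {
    expect_true(all(sim$references$genes[[g]] == sim$truths[[g]]))
  }
})

test_that("the generator is reproducible and respects length bounds", {
  cfg <- sim_config(n_genes = 20, gene_length_range = c(400, 2000),
                    seed = 19)
  sim1 <- generate_gene_family(cfg)
  sim2 <- generate_gene_family(cfg)
  expect_identical(sim1$truths, sim2$truths)
  expect_identical(sim1$references$genes, sim2$references$genes)
  lens <- nchar(sim1$truths)
  expect_true(all(lens >= 400 & lens <= 2000))
  expect_equal(length(sim1$truths), 20L)
  # divergence lands near the nominal 5% rate
  mm <- mapply(function(t, refs) {
    mean(vapply(refs, function(r) {
      mean(strsplit(t, "")[[1]] != strsplit(r, "")[[1]])
    }, numeric(1)))
  }, sim1$truths, sim1$references$genes)
  expect_gt(mean(mm), 0.03)
  expect_lt(mean(mm), 0.07)
})

test_that("pair counts follow round(depth * L / (2 * read_length))", {
  cfg <- sim_config(n_genes = 1, gene_length_range = c(1000, 1000),
                    read_length = 100, insert_mean = 300, depth = 20,
                    seed = 29)
  sim <- generate_gene_family(cfg)
  rd <- simulate_reads(sim$truths, cfg)
  expect_equal(nrow(rd$reads), 100L) # 20 * 1000 / (2 * 100)

  # depth rounding to zero pairs is allowed (1x sparsity regime)
  cfg0 <- sim_config(n_genes = 1, gene_length_range = c(400, 400),
                     read_length = 150, insert_mean = 300, depth = 0.3,
                     seed = 29)
  sim0 <- generate_gene_family(cfg0)
  rd0 <- simulate_reads(sim0$truths, cfg0)
  expect_equal(nrow(rd0$reads), 0L)
})

test_that("error-free reads are exact substrings of the truth", {
  cfg <- sim_config(n_genes = 1, gene_length_range = c(800, 800),
                    base_error = 0, depth = 10, seed = 39)
  sim <- generate_gene_family(cfg)
  rd <- simulate_reads(sim$truths, cfg)
  truth <- sim$truths[[1]]
  rc <- bf_revcomp(truth)
  expect_true(all(vapply(rd$reads$seq1, grepl, logical(1), x = truth,
                         fixed = TRUE)))
  expect_true(all(vapply(rd$reads$seq2, grepl, logical(1), x = rc,
                         fixed = TRUE)))
})

test_that("realized coverage tracks the requested depth within 10%", {
  cfg <- sim_config(n_genes = 10, gene_length_range = c(400, 1500),
                    seed = 49)
  sim <- generate_gene_family(cfg)
  total_truth <- sum(nchar(sim$truths))
  for (d in c(5, 20)) {
    rd <- simulate_reads(sim$truths, cfg, depth = d)
    emitted <- sum(nchar(rd$reads$seq1)) + sum(nchar(rd$reads$seq2))
    expect_lt(abs(emitted / total_truth - d) / d, 0.1)
  }
})

test_that("FASTQ output round-trips and provenance covers every read", {
  cfg <- sim_config(n_genes = 3, gene_length_range = c(400, 600),
                    depth = 5, seed = 59)
  sim <- generate_gene_family(cfg)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "r1.fq.gz")
  f2 <- file.path(d, "r2.fq.gz")
  rd <- simulate_reads(sim$truths, cfg, out1 = f1, out2 = f2)
  pairs <- read_fastq_pairs(f1, f2)
  expect_equal(pairs$id, rd$reads$id)
  expect_equal(pairs$seq1, rd$reads$seq1)
  expect_equal(pairs$seq2, rd$reads$seq2)
  expect_setequal(rd$provenance$read_id, rd$reads$id)
  # constant qualities of read length
  expect_true(all(pairs$qual1 == strrep("I", cfg$read_length)))

  # same seed, byte-identical files
  f1b <- file.path(d, "b1.fq.gz")
  f2b <- file.path(d, "b2.fq.gz")
  simulate_reads(sim$truths, cfg, out1 = f1b, out2 = f2b)
  expect_identical(readLines(f1), readLines(f1b))
  expect_identical(readLines(f2), readLines(f2b))
})

test_that("write_sim_truth lays out reference dir, truth FASTA and config", {
  cfg <- sim_config(n_genes = 3, gene_length_range = c(400, 500), seed = 69)
  sim <- generate_gene_family(cfg)
  d <- withr::local_tempdir()
  paths <- write_sim_truth(sim, d)
  expect_length(list.files(paths$ref_dir, pattern = "\\.fasta$"), 3L)
  truth <- read_fasta(paths$truth_fasta)
  expect_setequal(truth$id, names(sim$truths))
  cfg_back <- jsonlite::read_json(paths$config_json)
  expect_equal(cfg_back$n_genes, 3L)
  expect_equal(cfg_back$ref_divergence, cfg$ref_divergence)
})
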