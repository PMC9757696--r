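test_that("node_weight reproduces count^(1 - pos) with its identities", {
  grid <- expand.grid(count = c(1, 2, 3, 4, 7, 9, 50), pos = seq(0, 1, 0.125))
  expect_equal(node_weight(grid$count, grid$pos),
               grid$count^(1 - grid$pos))
  expect_equal(node_weight(1, 0.37), 1)
  expect_equal(node_weight(7, 0), 7)
  expect_equal(node_weight(4, 0.5), 2)
  expect_equal(node_weight(9, 1), 1)
  expect_warning(w <- node_weight(4, 1.5), "clipped")
  expect_equal(w, 1)
})

test_that("node_weight is monotone in count and pos", {
  counts <- 1:20
  expect_true(all(diff(node_weight(counts, 0.3)) >= 0))
  pos <- seq(0, 1, 0.05)
  expect_true(all(diff(node_weight(10, pos)) <= 0))
  expect_true(all(node_weight(counts, 1) == 1))
})

test_that("build_graph pools forward and reverse-complement k-mer counts", {
  reads <- c("ACGTA", "ACGTA")
  g <- build_graph(reads, k_asm = 4)
  expected <- bf_count_kmers(reads, 4)
  expect_setequal(g$nodes$kmer, names(expected))
  expect_equal(g$nodes$count[match(names(expected), g$nodes$kmer)],
               as.integer(expected))

  # min_count prunes singleton (error-like) nodes
  g2 <- build_graph(c("ACGTAACC", "ACGTAACC", "GGGTT"), k_asm = 5,
                    min_count = 2)
  expect_false(any(c("GGGTT", "AACCC") %in% g2$nodes$kmer))
  expect_true("ACGTA" %in% g2$nodes$kmer)

  expect_equal(nrow(build_graph(character(0), k_asm = 4)$nodes), 0L)
})

test_that("graph nodes carry reference positions when the reference has them", {
  withr::local_seed(7)
  ref <- rand_seq(60)
  g <- build_graph(ref, k_asm = 11, gene_refs = c(r = ref))
  on_ref <- bf_substrings(ref, 11)
  pos <- g$nodes$ref_pos[match(on_ref, g$nodes$kmer)]
  expect_true(all(!is.na(pos)))
  expect_true(all(pos >= 0 & pos <= 1))
  # reverse-complement nodes are absent from the forward-strand reference
  rc_only <- setdiff(g$nodes$kmer, on_ref)
  expect_true(all(is.na(g$nodes$ref_pos[match(rc_only, g$nodes$kmer)])))
})

test_that("extend_path follows a linear chain to its end", {
  withr::local_seed(17)
  s <- rand_seq(40)
  g <- build_graph(s, k_asm = 31) # k > L/2: no revcomp overlap branching
  start <- substr(s, 1, 31)
  path <- extend_path(g, start, "right")
  expect_equal(path_to_seq <- paste0(path[1],
                                     paste(substring(path[-1], 31, 31),
                                           collapse = "")), s)
  back <- extend_path(g, substr(s, 10, 40), "left")
  expect_equal(back[length(back)], start)
})

test_that("extend_path picks the candidate with the highest weight", {
  # fork: branch A count=10 at pos_delta 0.9 -> 10^0.1 ~ 1.2589
  #       branch B count=3  at pos_delta 0.1 -> 3^0.9  ~ 2.6879 -> B wins
  nodes <- data.frame(kmer = c("ACGT", "CGTA", "CGTC"),
                      count = c(5L, 10L, 3L),
                      ref_pos = c(0, 0.9, 0.1),
                      stringsAsFactors = FALSE)
  g <- structure(list(k = 4L, nodes = nodes), class = "assembly_graph")
  expect_gt(node_weight(3, 0.1), node_weight(10, 0.9))
  expect_equal(extend_path(g, "ACGT", "right"), c("ACGT", "CGTC"))

  # weight ties (both candidates unreferenced) fall back to abundance
  nodes2 <- data.frame(kmer = c("ACGT", "CGTA", "CGTC"),
                       count = c(5L, 2L, 30L),
                       ref_pos = c(NA, NA, NA),
                       stringsAsFactors = FALSE)
  g2 <- structure(list(k = 4L, nodes = nodes2), class = "assembly_graph")
  expect_equal(extend_path(g2, "ACGT", "right")[2], "CGTC")

  # full ties resolve lexicographically
  nodes3 <- data.frame(kmer = c("ACGT", "CGTT", "CGTC"),
                       count = c(5L, 2L, 2L),
                       ref_pos = c(NA, NA, NA),
                       stringsAsFactors = FALSE)
  g3 <- structure(list(k = 4L, nodes = nodes3), class = "assembly_graph")
  expect_equal(extend_path(g3, "ACGT", "right")[2], "CGTC")
})

test_that("extend_path terminates on cycles by visiting nodes at most once", {
  s <- "ACGTACGTACGT" # circular 4-mer structure
  g <- build_graph(s, k_asm = 4)
  path <- extend_path(g, "ACGT", "right")
  expect_lte(length(path), nrow(g$nodes))
  expect_equal(anyDuplicated(path), 0L)
})

test_that("error-free tiling reads reconstruct the truth exactly", {
  withr::local_seed(27)
  truth <- rand_seq(300)
  kmers <- c(bf_substrings(truth, 41), bf_substrings(bf_revcomp(truth), 41))
  expect_equal(anyDuplicated(kmers), 0L) # all-unique k-mer precondition
  reads <- tile_reads(truth, 100, 20)
  ref <- c(hom = bf_revcomp(truth)) # orientation of the reference is moot
  res <- assemble_gene(reads, ref, gene_id = "t", k_asm = 41)
  expect_false(is.null(res))
  expect_equal(res$n_nodes_visited + 41 - 1, nchar(res$seq))
  expect_true(res$seq == truth || res$seq == bf_revcomp(truth))
  expect_equal(res$recovered_fraction, 1)
})

test_that("assemble_gene handles empty and sub-minimum input", {
  expect_null(assemble_gene(character(0), k_asm = 41))
  expect_null(assemble_gene("ACGTACGTAC", k_asm = 5, min_length = 50))
})

test_that("assembly is deterministic for identical bins and parameters", {
  withr::local_seed(37)
  truth <- rand_seq(400)
  reads <- c(tile_reads(truth, 90, 6),
             vapply(tile_reads(truth, 90, 4), bf_revcomp, character(1)))
  a <- assemble_gene(reads, c(r = truth), k_asm = 31)
  b <- assemble_gene(sample(reads), c(r = truth), k_asm = 31)
  expect_identical(a$seq, b$seq)
  expect_identical(a$seed_kmer, b$seed_kmer)
})
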