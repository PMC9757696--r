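#' Simulation configuration
#'
#' Parameters of the synthetic verification protocol: per-gene truth
#' sequences, congeneric-style reference homologs diverged from the truth
#' by per-base substitution, and paired-end Illumina-like reads drawn from
#' the truth at a requested depth with per-base substitution errors.
#'
#' @param n_genes number of target genes.
#' @param gene_length_range integer pair, truth lengths drawn uniformly in
#'   this range (bases). Angiosperms353-style loci stay at or below 2000
#'   bases.
#' @param ref_divergence per-base substitution probability applied to the
#'   truth to create each reference homolog (0.05 mimics congeneric
#'   references).
#' @param n_homologs number of reference homologs per gene.
#' @param read_length read length in bases.
#' @param insert_mean,insert_sd fragment (insert) length distribution in
#'   bases; fragments are clamped to `[read_length, gene length]`.
#' @param depth requested sequencing depth (x); the number of pairs per
#'   gene is `round(depth * gene_length / (2 * read_length))`.
#' @param base_error per-base sequencing substitution error rate.
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 353L, gene_length_range = c(400L, 2000L),
                       ref_divergence = 0.05, n_homologs = 2L,
                       read_length = 150L, insert_mean = 350L,
                       insert_sd = 50, depth = 10, base_error = 0.005,
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(gene_length_range) == 2L,
            gene_length_range[1] <= gene_length_range[2],
            gene_length_range[1] >= read_length,
            ref_divergence >= 0, ref_divergence < 1,
            n_homologs >= 1, read_length >= 1,
            read_length <= insert_mean, insert_sd >= 0,
            depth > 0, base_error >= 0, base_error < 1)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 ref_divergence = ref_divergence,
                 n_homologs = as.integer(n_homologs),
                 read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = insert_sd, depth = depth,
                 base_error = base_error, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic gene family: truths plus diverged references
#'
#' Truth sequences are uniform random A/C/G/T strings with lengths uniform
#' in `gene_length_range`; each of the `n_homologs` reference homologs per
#' gene is derived from the truth by independent per-base substitution at
#' rate `ref_divergence` (no indels). Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sim_truth`: `truths` (named character
#'   vector, gene -> gold-standard sequence), `references` (a
#'   `reference_set` of the diverged homologs) and `config`.
#' @export
generate_gene_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  lengths <- sample.int(cfg$gene_length_range[2] - cfg$gene_length_range[1] +
                          1L, cfg$n_genes, replace = TRUE) +
    cfg$gene_length_range[1] - 1L
  truths <- stats::setNames(random_dna_cpp(lengths), gene_ids)
  genes <- lapply(gene_ids, function(g) {
    homs <- mutate_bases_cpp(rep(truths[[g]], cfg$n_homologs),
                             cfg$ref_divergence)
    stats::setNames(homs, paste0(g, "_ref", seq_len(cfg$n_homologs)))
  })
  names(genes) <- gene_ids
  structure(list(truths = truths, references = new_reference_set(genes),
                 config = cfg),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$truths), "genes;",
      x$config$n_homologs, "reference homolog(s)/gene at",
      sprintf("%.1f%%", 100 * x$config$ref_divergence), "divergence\n")
  invisible(x)
}

#' Simulate paired-end reads from truth sequences
#'
#' For each gene, `round(depth * L / (2 * read_length))` fragments are
#' drawn with uniform start and normal(insert_mean, insert_sd) length
#' (clamped to `[read_length, L]`); mate 1 is the fragment's 5' read and
#' mate 2 the reverse complement of its 3' read. Per-base substitution
#' errors are applied at `base_error` with a uniform alternative base.
#' Qualities are constant. The origin gene of every read is recorded in a
#' provenance table.
#'
#' The RNG seed used is `seed` (default `cfg$seed + 1000003`), so the read
#' stream is deterministic and distinct from the gene-family stream.
#'
#' @param truths named character vector of truth sequences (e.g.
#'   `sim_truth$truths`).
#' @param cfg a [sim_config()].
#' @param out1,out2 optional FASTQ output paths (`.gz` for compression).
#' @param depth sequencing depth, defaulting to `cfg$depth`.
#' @param seed RNG seed for the read stream.
#' @return A list of class `sim_reads`: `reads` data frame (`id`, `gene_id`,
#'   `seq1`, `seq2`), `provenance` data frame (`read_id`, `gene_id`), and
#'   the output paths when written.
#' @export
simulate_reads <- function(truths, cfg, out1 = NULL, out2 = NULL,
                           depth = cfg$depth, seed = cfg$seed + 1000003L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  rl <- cfg$read_length
  gene_ids <- names(truths)
  per_gene <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    truth <- truths[[g]]
    L <- nchar(truth)
    n_pairs <- round(depth * L / (2 * rl))
    if (n_pairs < 1L) next
    flen <- pmin(pmax(round(rnorm(n_pairs, cfg$insert_mean, cfg$insert_sd)),
                      rl), L)
    start <- 1L + floor(runif(n_pairs) * (L - flen + 1))
    frag <- substring(truth, start, start + flen - 1L)
    r1 <- substr(frag, 1L, rl)
    r2 <- revcomp_cpp(substring(frag, flen - rl + 1L, flen))
    if (cfg$base_error > 0) {
      r1 <- mutate_bases_cpp(r1, cfg$base_error)
      r2 <- mutate_bases_cpp(r2, cfg$base_error)
    }
    per_gene[[gi]] <- data.frame(
      id = sprintf("%s_p%06d", g, seq_len(n_pairs)),
      gene_id = g, seq1 = r1, seq2 = r2, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, per_gene)
  if (is.null(reads)) {
    reads <- data.frame(id = character(), gene_id = character(),
                        seq1 = character(), seq2 = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(reads) <- NULL
  qual <- strrep("I", rl)
  if (!is.null(out1)) {
    write_fastq(paste0(reads$id, "/1"), reads$seq1,
                rep(qual, nrow(reads)), out1)
  }
  if (!is.null(out2)) {
    write_fastq(paste0(reads$id, "/2"), reads$seq2,
                rep(qual, nrow(reads)), out2)
  }
  structure(list(reads = reads,
                 provenance = data.frame(read_id = reads$id,
                                         gene_id = reads$gene_id,
                                         stringsAsFactors = FALSE),
                 out1 = out1, out2 = out2, depth = depth, seed = seed),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$reads), "read pairs at depth", x$depth, "x\n")
  invisible(x)
}

#' Write a simulated gene family to disk
#'
#' Writes the per-gene reference FASTA directory and the truth (gold
#' standard) FASTA, plus a JSON echo of the configuration.
#'
#' @param sim a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return A list with `ref_dir`, `truth_fasta` and `config_json` paths.
#' @export
write_sim_truth <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_truth"))
  ref_dir <- file.path(dir, "reference")
  dir.create(ref_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$references$genes)) {
    write_fasta(sim$references$genes[[g]],
                file.path(ref_dir, paste0(g, ".fasta")))
  }
  truth_fasta <- file.path(dir, "truth.fasta")
  write_fasta(sim$truths, truth_fasta)
  config_json <- file.path(dir, "sim_config.json")
  jsonlite::write_json(unclass(sim$config), config_json, auto_unbox = TRUE,
                       digits = NA)
  list(ref_dir = ref_dir, truth_fasta = truth_fasta,
       config_json = config_json)
}
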