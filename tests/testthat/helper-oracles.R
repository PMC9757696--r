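# Brute-force oracles, written in plain R string code so they stay
# independent of the package's hashed implementations.

bases <- c("A", "C", "G", "T")

rand_seq <- function(n) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

bf_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# all length-k substrings (stride 1), keeping windows with N
bf_substrings <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

bf_kmers <- function(s, k, step = 1) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq(1, n - k + 1, by = step)
  out <- substring(toupper(s), starts, starts + k - 1)
  out[!grepl("[^ACGT]", out)]
}

# gene ids whose references share at least one exact length-k substring
# with the read or its reverse complement
bf_classify <- function(read, gene_seqs, k) {
  rk <- unique(c(bf_kmers(read, k), bf_kmers(bf_revcomp(read), k)))
  hit <- vapply(gene_seqs, function(refs) {
    ref_k <- unique(unlist(lapply(refs, bf_kmers, k = k)))
    any(rk %in% ref_k)
  }, logical(1))
  names(gene_seqs)[hit]
}

# k-mer abundance over reads and their reverse complements
bf_count_kmers <- function(reads, k) {
  all <- unlist(lapply(c(reads, vapply(reads, bf_revcomp, character(1))),
                       bf_kmers, k = k))
  table(all)
}

# error-free reads tiling a sequence at roughly the requested depth
tile_reads <- function(truth, read_len, depth) {
  L <- nchar(truth)
  n <- max(1, round(depth * L / read_len))
  starts <- round(seq(1, L - read_len + 1, length.out = n))
  substring(truth, starts, starts + read_len - 1)
}

write_ref_dir <- function(gene_seqs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(gene_seqs)) {
    write_fasta(gene_seqs[[g]], file.path(dir, paste0(g, ".fasta")))
  }
  dir
}
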