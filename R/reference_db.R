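#' Build a per-gene reference set
#'
#' A reference set maps each target gene to the homologous nucleotide
#' sequences available for it, plus the gene's target length (the arithmetic
#' mean of its reference lengths, the denominator of the T50 statistic).
#'
#' Two layouts are accepted:
#' * a directory with one FASTA file per gene (multi-FASTA of homologs
#'   inside); the gene id is the file's basename with the extension (and any
#'   `.gz`) stripped;
#' * a single combined FASTA (`combined = TRUE`) whose record ids encode the
#'   gene as the token after the last `-`, a common convention for
#'   Angiosperms353 reference releases.
#'
#' @param path directory of per-gene FASTA files, or a single FASTA file.
#' @param combined logical; treat `path` as a combined FASTA (see above).
#' @return An object of class `reference_set`: a list with `genes` (named
#'   list of named character vectors, homolog id -> sequence) and
#'   `target_length` (named numeric, mean reference length per gene).
#' @export
build_reference_set <- function(path, combined = !dir.exists(path)) {
  genes <- list()
  if (!combined) {
    if (!dir.exists(path)) {
      stop("reference directory not found: ", path, call. = FALSE)
    }
    files <- list.files(path,
                        pattern = "\\.(fa|fasta|fas|fna)(\\.gz)?$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (!length(files)) {
      stop("no FASTA files found in reference directory: ", path,
           call. = FALSE)
    }
    for (f in files) {
      gene <- sub("\\.(fa|fasta|fas|fna)(\\.gz)?$", "", basename(f),
                  ignore.case = TRUE)
      recs <- read_fasta(f)
      if (nrow(recs) == 0L) {
        warning("reference file '", f, "' contains no records; gene '",
                gene, "' skipped", call. = FALSE)
        next
      }
      genes[[gene]] <- stats::setNames(recs$seq, recs$id)
    }
  } else {
    recs <- read_fasta(path)
    if (nrow(recs) == 0L) {
      stop("combined reference FASTA '", path, "' contains no records",
           call. = FALSE)
    }
    gene_of <- sub("^.*-", "", recs$id)
    for (gene in sort(unique(gene_of))) {
      sel <- gene_of == gene
      genes[[gene]] <- stats::setNames(recs$seq[sel], recs$id[sel])
    }
  }
  if (!length(genes)) {
    stop("reference set is empty after reading '", path, "'", call. = FALSE)
  }
  new_reference_set(genes)
}

new_reference_set <- function(genes) {
  stopifnot(is.list(genes), length(genes) >= 1L)
  target_length <- vapply(genes, function(s) mean(nchar(s)), numeric(1))
  structure(list(genes = genes, target_length = target_length),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  n_seq <- sum(lengths(x$genes))
  cat("reference_set:", length(x$genes), "genes,", n_seq, "sequences\n")
  cat("  target length: ",
      round(min(x$target_length)), "-", round(max(x$target_length)),
      " bases (mean ", round(mean(x$target_length), 1), ")\n", sep = "")
  invisible(x)
}

#' Build the reference k-mer hash index
#'
#' Every N-free length-`k` substring of every reference sequence (forward
#' strand) is recorded in an in-memory hash table, keyed by k-mer, with one
#' entry per gene holding the occurrence count and the mean fractional start
#' position `start / (L - k)` over all occurrences in that gene's references
#' (`0` when `L == k`). These positional statistics are the reference priors
#' used both to recruit reads and to weight assembly-graph extensions.
#'
#' @param refs a `reference_set`, or a named list of named character vectors
#'   (gene -> homolog sequences).
#' @param k k-mer length, at least 2.
#' @return An object of class `kmer_index` wrapping the in-memory hash
#'   table; query it with [kmer_index_lookup()] or [kmer_index_table()].
#' @export
build_kmer_index <- function(refs, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("k must be a single integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  genes <- if (inherits(refs, "reference_set")) refs$genes else refs
  stopifnot(is.list(genes), length(genes) >= 1L)
  gene_ids <- names(genes)
  seqs <- unlist(unname(genes))
  gene_of <- rep.int(seq_along(genes), lengths(genes)) - 1L
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " reference sequence(s) shorter than k = ", k,
            " contribute no k-mers", call. = FALSE)
  }
  ptr <- kmer_index_build_cpp(as.character(seqs), gene_of, gene_ids, k)
  structure(list(ptr = ptr, k = k, gene_ids = gene_ids),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, "|", format(kmer_index_size_cpp(x$ptr)),
      "distinct k-mers |", length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Query a k-mer index
#'
#' @param index a `kmer_index`.
#' @param kmers character vector of k-mers to look up.
#' @return A data frame with one row per (found k-mer, gene) pair:
#'   `kmer`, `gene_id`, `count`, `mean_frac_pos`.
#' @export
kmer_index_lookup <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  kmer_index_lookup_cpp(index$ptr, as.character(kmers))
}

#' Dump the full (k-mer, gene) table of an index
#'
#' Intended for small indices (inspection and testing).
#'
#' @param index a `kmer_index`.
#' @return A data frame with columns `kmer`, `gene_id`, `count`,
#'   `mean_frac_pos`, sorted by k-mer then gene.
#' @export
kmer_index_table <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  kmer_index_dump_cpp(index$ptr)
}
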