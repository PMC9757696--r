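#' Read-filtering parameters
#'
#' @param k filter k-mer length (must match the index used).
#' @param step stride between successive k-mer start offsets when splitting
#'   a read; `1` inspects every offset, larger values trade sensitivity for
#'   speed.
#' @param min_hits number of shared k-mers (read plus reverse complement)
#'   required to assign a read to a gene.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(k = 31L, step = 1L, min_hits = 1L) {
  stopifnot(k >= 2, step >= 1, min_hits >= 1)
  structure(list(k = as.integer(k), step = as.integer(step),
                 min_hits = as.integer(min_hits)),
            class = "filter_params")
}

#' Split a sequence into stride-sampled k-mers
#'
#' Returns the substrings starting at offsets `0, step, 2*step, ...` that
#' fit within the sequence; windows containing a non-ACGT character are
#' dropped; the result is empty when the sequence is shorter than `k`.
#'
#' @param seq a single nucleotide string.
#' @param k k-mer length.
#' @param step stride between start offsets.
#' @return Character vector of k-mers.
#' @examples
#' kmerize("ACGTAC", 4, 1)
#' kmerize("ACGTAC", 4, 2)
#' @export
kmerize <- function(seq, k, step = 1L) {
  stopifnot(length(seq) == 1L, k >= 1, step >= 1)
  kmerize_cpp(as.character(seq), as.integer(k), as.integer(step))
}

#' Classify one read against the reference index
#'
#' A gene matches when the number of stride-sampled k-mers of the read plus
#' those of its reverse complement found in the hash table for that gene is
#' at least `min_hits`. Matching is exact: no mismatches are tolerated
#' anywhere in a k-mer.
#'
#' @param read a nucleotide string (or a length-1 named character vector).
#' @param index a `kmer_index` built at `params$k`.
#' @param params a [filter_params()] object.
#' @return Character vector of matching gene ids (possibly empty), in index
#'   order.
#' @export
classify_read <- function(read, index, params = filter_params(k = index$k)) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "filter_params"))
  if (params$k != index$k) {
    stop("filter k (", params$k, ") does not match index k (", index$k, ")",
         call. = FALSE)
  }
  hits <- classify_reads_cpp(index$ptr, as.character(read), params$step,
                             params$min_hits)[[1]]
  index$gene_ids[hits]
}

#' Filter reads into per-gene bins
#'
#' Streams single- or paired-end FASTQ, assigns each read to the genes it
#' shares k-mers with, and collects per-gene read bins. For paired input,
#' when either mate matches a gene both mates are recruited to that gene's
#' bin ("pair rescue", on by default). A read may enter several bins. Bins
#' are written as one FASTA per gene under `out_dir` along with a
#' tab-separated summary.
#'
#' @param path1,path2 FASTQ input (`path2 = NULL` for single-end), plain or
#'   gzipped. Alternatively `path1` may be a data frame as returned by
#'   [read_fastq_pairs()].
#' @param index a `kmer_index` over the reference set.
#' @param params a [filter_params()] object (`params$k` must equal
#'   `index$k`).
#' @param out_dir output directory for per-gene FASTA bins and
#'   `filter_summary.tsv`; `NULL` keeps bins in memory only.
#' @param pair_rescue logical; recruit both mates when either matches.
#' @param threads number of worker processes for classification (forked via
#'   \pkg{parallel}; results are identical to a single-threaded run).
#' @param chunk_size reads (pairs) per streamed chunk.
#' @return An object of class `read_bins`: list with `bins` (named list of
#'   named character vectors, read id -> sequence), `summary` (data frame
#'   `gene_id`, `n_reads`), `n_scanned`, `n_matched`.
#' @export
filter_reads <- function(path1, path2 = NULL, index, params = filter_params(),
                         out_dir = NULL, pair_rescue = TRUE, threads = 1L,
                         chunk_size = 20000L) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "filter_params"))
  if (params$k != index$k) {
    stop("filter k (", params$k, ") does not match index k (", index$k, ")",
         call. = FALSE)
  }
  if (is.data.frame(path1)) {
    chunks_in <- list(path1)
    stream <- local({
      i <- 0L
      function() {
        i <<- i + 1L
        if (i > length(chunks_in)) return(NULL)
        df <- chunks_in[[i]]
        if (nrow(df) == 0L) return(NULL)
        as.list(df)
      }
    })
  } else {
    stream <- fastq_pair_stream(path1, path2, chunk_size)
  }

  gene_ids <- index$gene_ids
  acc <- lapply(gene_ids, function(g) list())
  names(acc) <- gene_ids
  n_scanned <- 0L
  n_matched <- 0L

  classify_vec <- function(seqs) {
    if (threads > 1L && length(seqs) >= 2L * threads) {
      parts <- split(seq_along(seqs),
                     cut(seq_along(seqs), threads, labels = FALSE))
      res <- parallel::mclapply(parts, function(ix) {
        classify_reads_cpp(index$ptr, seqs[ix], params$step, params$min_hits)
      }, mc.cores = threads)
      do.call(c, unname(res))
    } else {
      classify_reads_cpp(index$ptr, seqs, params$step, params$min_hits)
    }
  }

  repeat {
    ch <- stream()
    if (is.null(ch)) break
    paired <- !is.null(ch$seq2)
    n <- length(ch$seq1)
    n_scanned <- n_scanned + n * (1L + paired)
    g1 <- classify_vec(ch$seq1)
    g2 <- if (paired) classify_vec(ch$seq2) else NULL

    add_reads <- function(gene_hits, ids, seqs) {
      # gene_hits: list of integer vectors (indices into gene_ids) per read
      len <- lengths(gene_hits)
      if (!any(len > 0L)) return(0L)
      read_i <- rep.int(seq_along(gene_hits), len)
      gene_i <- unlist(gene_hits, use.names = FALSE)
      by_gene <- split(read_i, gene_i)
      for (gi_chr in names(by_gene)) {
        gi <- as.integer(gi_chr)
        sel <- by_gene[[gi_chr]]
        g <- gene_ids[gi]
        acc[[g]][[length(acc[[g]]) + 1L]] <<-
          stats::setNames(seqs[sel], ids[sel])
      }
      sum(len > 0L)
    }

    if (paired && pair_rescue) {
      pair_hits <- mapply(function(a, b) sort(unique(c(a, b))), g1, g2,
                          SIMPLIFY = FALSE)
      m <- add_reads(pair_hits, paste0(ch$id, "/1"), ch$seq1)
      add_reads(pair_hits, paste0(ch$id, "/2"), ch$seq2)
      n_matched <- n_matched + 2L * m
    } else if (paired) {
      n_matched <- n_matched + add_reads(g1, paste0(ch$id, "/1"), ch$seq1)
      n_matched <- n_matched + add_reads(g2, paste0(ch$id, "/2"), ch$seq2)
    } else {
      n_matched <- n_matched + add_reads(g1, ch$id, ch$seq1)
    }
  }

  bins <- lapply(acc, function(parts) {
    if (!length(parts)) character(0) else do.call(c, parts)
  })
  summary <- data.frame(gene_id = gene_ids,
                        n_reads = vapply(bins, length, integer(1)),
                        stringsAsFactors = FALSE, row.names = NULL)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    for (g in gene_ids) {
      if (length(bins[[g]])) {
        write_fasta(bins[[g]], file.path(out_dir, paste0(g, ".fasta")))
      }
    }
    write.table(summary, file.path(out_dir, "filter_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(bins = bins, summary = summary, n_scanned = n_scanned,
                 n_matched = n_matched),
            class = "read_bins")
}

#' @export
print.read_bins <- function(x, ...) {
  cat("read_bins:", x$n_scanned, "reads scanned,", x$n_matched, "matched;",
      sum(x$summary$n_reads > 0L), "of", nrow(x$summary),
      "gene bins non-empty\n")
  invisible(x)
}
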