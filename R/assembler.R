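#' Node weight of an assembly-graph extension candidate
#'
#' The weight of a candidate node is `count ^ (1 - pos)`, where `count` is
#' the k-mer's abundance in the gene's read bin and `pos` the positional
#' distance to the current node on the reference (the absolute difference of
#' the two k-mers' mean fractional reference positions). A positionally
#' consistent candidate (`pos` near 0) keeps its full abundance weight; a
#' positional outlier (`pos` near 1) decays toward weight 1.
#'
#' @param count k-mer abundance, at least 1. Vectorized.
#' @param pos positional distance in `[0, 1]`; values outside are clipped
#'   (with a warning), as upstream code should already guarantee the range.
#' @return Numeric vector of weights.
#' @examples
#' node_weight(4, 0.5) # 2
#' node_weight(7, 0)   # 7
#' @export
node_weight <- function(count, pos) {
  stopifnot(all(count >= 1))
  if (any(pos < 0 | pos > 1)) {
    warning("pos outside [0, 1] clipped", call. = FALSE)
    pos <- pmin(pmax(pos, 0), 1)
  }
  count^(1 - pos)
}

#' Build the weighted de Bruijn graph of a read bin
#'
#' Every N-free length-`k_asm` substring of every read and of every read's
#' reverse complement becomes a node, with abundance pooled per distinct
#' k-mer string. Nodes are annotated with their mean fractional position on
#' the gene's reference sequences (`NA` when the k-mer does not occur in the
#' references). Edges are implicit: `u -> v` whenever the (k-1)-suffix of
#' `u` equals the (k-1)-prefix of `v`.
#'
#' @param reads character vector of read sequences (a gene's bin).
#' @param k_asm assembly k-mer length (independent of the filter k).
#' @param min_count nodes with abundance below this are dropped.
#' @param gene_refs named character vector of the gene's reference homologs
#'   (may be empty: all nodes then lack a reference position).
#' @return An object of class `assembly_graph`: list with `k` and `nodes`
#'   (data frame `kmer`, `count`, `ref_pos`, sorted by k-mer).
#' @export
build_graph <- function(reads, k_asm, min_count = 1L,
                        gene_refs = character(0)) {
  stopifnot(k_asm >= 2, min_count >= 1)
  k_asm <- as.integer(k_asm)
  nodes <- dbg_count_kmers_cpp(as.character(reads), k_asm)
  if (nrow(nodes) && min_count > 1L) {
    nodes <- nodes[nodes$count >= min_count, , drop = FALSE]
    rownames(nodes) <- NULL
  }
  if (nrow(nodes) && length(gene_refs)) {
    ref_idx <- build_kmer_index(list(gene = unname(gene_refs)), k_asm)
    nodes$ref_pos <- kmer_index_meanpos_cpp(ref_idx$ptr, nodes$kmer)
  } else {
    nodes$ref_pos <- rep(NA_real_, nrow(nodes))
  }
  structure(list(k = k_asm, nodes = nodes), class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("assembly_graph: k =", x$k, "|", nrow(x$nodes), "nodes\n")
  invisible(x)
}

#' Greedy weighted path extension
#'
#' Walks the graph from a seed node under a visit-once constraint. At each
#' step the unvisited successors (direction `"right"`) or predecessors
#' (`"left"`) are scored with [node_weight()], using as `pos` the absolute
#' difference of reference positions between candidate and current node
#' (1 when either lacks a reference position, the weight floor); the best
#' weight is taken, ties falling back to higher abundance and then to the
#' lexicographically smaller k-mer. The walk stops when no unvisited
#' neighbor exists.
#'
#' @param graph an `assembly_graph`.
#' @param seed a k-mer present in the graph.
#' @param direction `"right"` (successors) or `"left"` (predecessors).
#' @param visited optional character vector of k-mers to treat as already
#'   visited (used to keep the two half-extensions of a contig disjoint).
#' @return Character vector of visited k-mers in walk order, starting at
#'   the seed.
#' @export
extend_path <- function(graph, seed, direction = c("right", "left"),
                        visited = NULL) {
  stopifnot(inherits(graph, "assembly_graph"))
  direction <- match.arg(direction)
  nodes <- graph$nodes
  seed_i <- match(seed, nodes$kmer)
  if (is.na(seed_i)) stop("seed k-mer not present in graph", call. = FALSE)
  vis_i <- if (is.null(visited)) integer(0) else
    match(visited, nodes$kmer, nomatch = 0L)
  path <- dbg_extend_cpp(nodes$kmer, nodes$count, nodes$ref_pos,
                         seed_i, direction == "right",
                         vis_i[vis_i > 0L])
  nodes$kmer[path]
}

path_to_seq <- function(kmers, k) {
  if (!length(kmers)) return("")
  paste0(kmers[1], paste(substring(kmers[-1], k, k), collapse = ""))
}

#' Assemble one gene's read bin into a contig
#'
#' Builds the weighted de Bruijn graph of the bin, seeds at the most
#' frequent k-mer (ties broken lexicographically), extends right then left
#' (the two half-walks share one visited set, so each node is used at most
#' once), and concatenates the path into a contig of length
#' `n_nodes + k_asm - 1`. If the contig falls short of `min_length`, up to
#' `max_seed_retries` further seeds (next most frequent k-mers) are tried
#' and the contig visiting the most nodes is kept.
#'
#' @param reads character vector of read sequences (the gene's bin).
#' @param gene_refs named character vector of the gene's reference
#'   homologs, used for positional annotation.
#' @param gene_id gene identifier carried into the result.
#' @param k_asm assembly k-mer length.
#' @param min_count minimum node abundance (1 = no pruning, so that
#'   single-coverage data still assembles).
#' @param min_length minimum contig length; shorter assemblies are
#'   discarded. Default `k_asm + 20` suppresses trivial seed-only output.
#' @param max_seed_retries additional seeds tried when the first fails to
#'   reach `min_length`.
#' @param target_length optional target length (mean reference length) used
#'   to report the recovered fraction.
#' @return A list of class `contig_result` with `gene_id`, `seq`,
#'   `n_nodes_visited`, `seed_kmer`, `recovered_fraction`, or `NULL` when
#'   the graph is empty or no attempt reaches `min_length`.
#' @export
assemble_gene <- function(reads, gene_refs = character(0), gene_id = "gene",
                          k_asm = 41L, min_count = 1L,
                          min_length = k_asm + 20L, max_seed_retries = 4L,
                          target_length = NULL) {
  graph <- build_graph(reads, k_asm, min_count, gene_refs)
  nodes <- graph$nodes
  if (!nrow(nodes)) return(NULL)
  ord <- order(-nodes$count, nodes$kmer)
  seeds <- nodes$kmer[head(ord, 1L + max_seed_retries)]

  best <- NULL
  for (s in seeds) {
    right <- extend_path(graph, s, "right")
    left <- extend_path(graph, s, "left", visited = right)
    path <- c(rev(left[-1]), right)
    if (is.null(best) || length(path) > length(best$path)) {
      best <- list(path = path, seed = s)
    }
    if (length(best$path) + graph$k - 1L >= min_length) break
  }
  contig <- path_to_seq(best$path, graph$k)
  if (nchar(contig) < min_length) return(NULL)
  if (is.null(target_length)) {
    target_length <- if (length(gene_refs)) mean(nchar(gene_refs)) else NA_real_
  }
  structure(list(gene_id = gene_id, seq = contig,
                 n_nodes_visited = length(best$path),
                 seed_kmer = best$seed,
                 recovered_fraction = nchar(contig) / target_length),
            class = "contig_result")
}

#' @export
print.contig_result <- function(x, ...) {
  cat("contig_result: ", x$gene_id, " | ", nchar(x$seq), " bases (",
      x$n_nodes_visited, " nodes; recovered fraction ",
      round(x$recovered_fraction, 3), ")\n", sep = "")
  invisible(x)
}

#' Assemble every non-empty bin of a filtering result
#'
#' @param bins a `read_bins` object from [filter_reads()], or a named list
#'   of read vectors.
#' @param refs the `reference_set` the bins were filtered against.
#' @param out_dir optional directory: per-gene contig FASTA files
#'   (`<gene>.contig.fasta`), a combined `all_genes.fasta`, and
#'   `assembly_summary.tsv` are written there.
#' @inheritParams assemble_gene
#' @return A list of class `assembly_result`: `contigs` (named character
#'   vector, gene -> contig sequence) and `summary` (per-gene data frame).
#' @export
assemble_bins <- function(bins, refs, out_dir = NULL, k_asm = 41L,
                          min_count = 1L, min_length = k_asm + 20L,
                          max_seed_retries = 4L) {
  stopifnot(inherits(refs, "reference_set"))
  bin_list <- if (inherits(bins, "read_bins")) bins$bins else bins
  gene_ids <- sort(intersect(names(bin_list), names(refs$genes)))
  contigs <- character(0)
  rows <- vector("list", length(gene_ids))
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    res <- if (length(bin_list[[g]])) {
      assemble_gene(bin_list[[g]], refs$genes[[g]], gene_id = g,
                    k_asm = k_asm, min_count = min_count,
                    min_length = min_length,
                    max_seed_retries = max_seed_retries,
                    target_length = refs$target_length[[g]])
    } else NULL
    if (!is.null(res)) {
      contigs[[g]] <- res$seq
      rows[[i]] <- data.frame(gene_id = g, length = nchar(res$seq),
                              n_nodes = res$n_nodes_visited,
                              seed = res$seed_kmer,
                              recovered_fraction = res$recovered_fraction,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(gene_id = g, length = 0L, n_nodes = 0L,
                              seed = NA_character_,
                              recovered_fraction = 0,
                              stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  if (is.null(summary)) {
    summary <- data.frame(gene_id = character(), length = integer(),
                          n_nodes = integer(), seed = character(),
                          recovered_fraction = numeric(),
                          stringsAsFactors = FALSE)
  }
  rownames(summary) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    for (g in names(contigs)) {
      hdr <- sprintf("%s length=%d nodes=%d seed=%s", g,
                     nchar(contigs[[g]]),
                     summary$n_nodes[summary$gene_id == g],
                     summary$seed[summary$gene_id == g])
      write_fasta(data.frame(id = g,
                             desc = sub("^\\S+\\s*", "", hdr),
                             seq = contigs[[g]],
                             stringsAsFactors = FALSE),
                  file.path(out_dir, paste0(g, ".contig.fasta")))
    }
    if (length(contigs)) {
      write_fasta(contigs, file.path(out_dir, "all_genes.fasta"))
    } else {
      write_fasta(character(0), file.path(out_dir, "all_genes.fasta"))
    }
    write.table(summary, file.path(out_dir, "assembly_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(contigs = contigs, summary = summary),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("assembly_result:", length(x$contigs), "contigs over",
      nrow(x$summary), "genes\n")
  invisible(x)
}
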