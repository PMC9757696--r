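#' T50 recovery statistic
#'
#' The number of genes whose recovered sequence length is at least 50% of
#' the gene's target length (the mean length of its reference instances).
#' Genes absent from `recovered_lengths` count as length 0.
#'
#' @param recovered_lengths named numeric/integer vector, gene -> recovered
#'   contig length in bases.
#' @param target_lengths named numeric vector, gene -> target length; every
#'   recovered gene must appear here.
#' @return Integer count of genes at or above the 50% threshold.
#' @examples
#' t50(c(g1 = 60, g2 = 40, g3 = 50), c(g1 = 100, g2 = 100, g3 = 100)) # 2
#' @export
t50 <- function(recovered_lengths, target_lengths) {
  missing <- setdiff(names(recovered_lengths), names(target_lengths))
  if (length(missing)) {
    stop("recovered gene(s) absent from target lengths: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  rec <- recovered_lengths[names(target_lengths)]
  rec[is.na(rec)] <- 0
  sum(rec >= 0.5 * target_lengths)
}

align_overlap <- function(contig, truth, match = 1, mismatch = -1,
                          gap_opening = 2, gap_extension = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE,
                                                  type = "DNA")
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(contig),
    subject = Biostrings::DNAString(truth),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
}

#' Base-calling and indel error rates of a recovered sequence
#'
#' The contig is aligned to its gold-standard truth sequence with an
#' ends-free (semi-global) pairwise alignment, in the orientation (forward
#' or reverse complement) achieving the higher score; truth overhang beyond
#' a partial contig is therefore not counted as indel error. Within the
#' aligned span:
#' * base-calling error rate = mismatching columns / columns where both
#'   sequences have a base;
#' * indel error rate = gap columns / span length.
#'
#' @param contig recovered nucleotide string.
#' @param truth gold-standard nucleotide string.
#' @param min_cover minimum number of both-base aligned columns for the
#'   rates to be meaningful; below it the sequence is flagged invalid and
#'   the rates are `NA`.
#' @return A list: `base_error_rate`, `indel_error_rate`, `aligned_bases`
#'   (both-base columns), `span` (aligned columns incl. gaps),
#'   `n_mismatch`, `n_gap`, `orientation` (`"+"` or `"-"`), `valid_alignment`.
#' @export
error_rates <- function(contig, truth, min_cover = 20L) {
  stopifnot(nchar(contig) > 0, nchar(truth) > 0)
  aln_f <- align_overlap(contig, truth)
  aln_r <- align_overlap(revcomp(contig), truth)
  if (Biostrings::score(aln_f) >= Biostrings::score(aln_r)) {
    aln <- aln_f
    orientation <- "+"
  } else {
    aln <- aln_r
    orientation <- "-"
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- p != "-" & s != "-"
  aligned_bases <- sum(both)
  span <- length(p)
  n_gap <- sum(p == "-" | s == "-")
  n_mismatch <- sum(p[both] != s[both])
  if (aligned_bases < min_cover) {
    return(list(base_error_rate = NA_real_, indel_error_rate = NA_real_,
                aligned_bases = aligned_bases, span = span,
                n_mismatch = n_mismatch, n_gap = n_gap,
                orientation = orientation, valid_alignment = FALSE))
  }
  list(base_error_rate = n_mismatch / aligned_bases,
       indel_error_rate = n_gap / span,
       aligned_bases = aligned_bases, span = span,
       n_mismatch = n_mismatch, n_gap = n_gap,
       orientation = orientation, valid_alignment = TRUE)
}

#' Score recovered contigs against a gold standard
#'
#' Computes per-gene recovered lengths, T50, per-gene error rates, and the
#' aggregate error rates over the total aligned length (total mismatches /
#' total both-base columns, total gap columns / total span). A recovered
#' sequence is counted valid when its alignment covers at least `min_cover`
#' bases and its base-calling error rate does not exceed
#' `max_base_error`.
#'
#' @param contigs named character vector, gene -> recovered sequence
#'   (genes without a contig may simply be absent).
#' @param truths named character vector, gene -> gold-standard sequence.
#' @param target_lengths named numeric vector, gene -> target length;
#'   defaults to the truth lengths.
#' @param max_base_error validity threshold on the per-gene base-calling
#'   error rate.
#' @param min_cover minimum aligned coverage in bases.
#' @return An object of class `recovery_report`: `per_gene` data frame
#'   (`gene_id`, `recovered_length`, `target_length`, `recovered_fraction`,
#'   `base_error_rate`, `indel_error_rate`, `valid`) and `summary` list
#'   (`t50`, `n_valid`, `n_recovered`, `aggregate_base_error_rate`,
#'   `aggregate_indel_error_rate`).
#' @export
evaluate_recovery <- function(contigs, truths, target_lengths = NULL,
                              max_base_error = 0.05, min_cover = 20L) {
  if (is.null(target_lengths)) {
    target_lengths <- vapply(truths, nchar, numeric(1))
  }
  contigs <- as.list(contigs) # so genes without a contig index as NULL
  genes <- names(truths)
  rows <- vector("list", length(genes))
  tot_mm <- 0
  tot_bases <- 0
  tot_gap <- 0
  tot_span <- 0
  for (i in seq_along(genes)) {
    g <- genes[i]
    ctg <- contigs[[g]]
    if (is.null(ctg) || is.na(ctg) || !nzchar(ctg)) {
      rows[[i]] <- data.frame(gene_id = g, recovered_length = 0L,
                              target_length = target_lengths[[g]],
                              recovered_fraction = 0,
                              base_error_rate = NA_real_,
                              indel_error_rate = NA_real_, valid = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    er <- error_rates(ctg, truths[[g]], min_cover = min_cover)
    valid <- er$valid_alignment && er$base_error_rate <= max_base_error
    if (er$valid_alignment) {
      tot_mm <- tot_mm + er$n_mismatch
      tot_bases <- tot_bases + er$aligned_bases
      tot_gap <- tot_gap + er$n_gap
      tot_span <- tot_span + er$span
    }
    rows[[i]] <- data.frame(gene_id = g, recovered_length = nchar(ctg),
                            target_length = target_lengths[[g]],
                            recovered_fraction =
                              nchar(ctg) / target_lengths[[g]],
                            base_error_rate = er$base_error_rate,
                            indel_error_rate = er$indel_error_rate,
                            valid = valid, stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  rec_len <- stats::setNames(per_gene$recovered_length, per_gene$gene_id)
  summary <- list(
    t50 = t50(rec_len, target_lengths),
    n_valid = sum(per_gene$valid),
    n_recovered = sum(per_gene$recovered_length > 0L),
    aggregate_base_error_rate =
      if (tot_bases > 0) tot_mm / tot_bases else NA_real_,
    aggregate_indel_error_rate =
      if (tot_span > 0) tot_gap / tot_span else NA_real_)
  structure(list(per_gene = per_gene, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat("recovery_report: ", nrow(x$per_gene), " genes | T50 = ", s$t50,
      " | valid = ", s$n_valid, "\n", sep = "")
  cat(sprintf("  aggregate base-calling error %.4g%% | indel error %.4g%%\n",
              100 * s$aggregate_base_error_rate,
              100 * s$aggregate_indel_error_rate))
  invisible(x)
}

#' Write a recovery report to disk
#'
#' @param report a `recovery_report`.
#' @param path output TSV path for the per-gene table; a one-line summary
#'   is written next to it as `<path>.summary.tsv`.
#' @return `path`, invisibly.
#' @export
write_recovery_report <- function(report, path) {
  stopifnot(inherits(report, "recovery_report"))
  write.table(report$per_gene, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  s <- report$summary
  write.table(data.frame(t50 = s$t50, n_valid = s$n_valid,
                         n_recovered = s$n_recovered,
                         aggregate_base_error_rate =
                           s$aggregate_base_error_rate,
                         aggregate_indel_error_rate =
                           s$aggregate_indel_error_rate),
              paste0(path, ".summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
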