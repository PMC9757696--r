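#' Depth-gradient verification experiment
#'
#' Runs the whole pipeline on one synthetic gene family at a gradient of
#' sequencing depths and scores each run against the gold standard. The
#' gene family (truths and diverged references) is generated once from
#' `cfg$seed`; each depth gets its own deterministic read stream. This is
#' the in-silico analogue of validating a target-recovery tool on reads
#' simulated from a sequenced genome at increasing coverage.
#'
#' @param depths numeric vector of sequencing depths (x).
#' @param cfg a [sim_config()]; `cfg$depth` is ignored in favor of
#'   `depths`.
#' @param filter_k,step,min_hits,assembly_k,min_count,min_length,max_seed_retries
#'   pipeline parameters, as in [run_pipeline()].
#' @param max_base_error,min_cover validity thresholds, as in
#'   [evaluate_recovery()].
#' @param quiet suppress progress messages.
#' @return A list of class `depth_gradient`: `metrics` data frame with one
#'   row per depth (`depth`, `n_pairs`, `n_recovered`, `n_valid`, `t50`,
#'   `aggregate_base_error_pct`, `aggregate_indel_error_pct`), and
#'   `reports` (per-depth `recovery_report` objects, named by depth).
#' @export
depth_gradient_experiment <- function(depths = c(1, 5, 10, 20, 50),
                                      cfg = sim_config(),
                                      filter_k = 31L, step = 1L,
                                      min_hits = 1L, assembly_k = 41L,
                                      min_count = 1L,
                                      min_length = assembly_k + 20L,
                                      max_seed_retries = 4L,
                                      max_base_error = 0.05,
                                      min_cover = 20L, quiet = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), length(depths) >= 1)
  say <- function(...) if (!quiet) message(...)

  say("generating gene family (", cfg$n_genes, " genes)")
  sim <- generate_gene_family(cfg)
  index <- build_kmer_index(sim$references, filter_k)
  fp <- filter_params(filter_k, step, min_hits)

  rows <- vector("list", length(depths))
  reports <- vector("list", length(depths))
  for (di in seq_along(depths)) {
    d <- depths[di]
    say("depth ", d, "x: simulating reads")
    rd <- simulate_reads(sim$truths, cfg, depth = d,
                         seed = cfg$seed + 1000003L + di)
    pairs_df <- rd$reads[, c("id", "seq1", "seq2")]
    say("depth ", d, "x: filtering ", nrow(pairs_df), " pairs")
    bins <- filter_reads(pairs_df, NULL, index, fp)
    say("depth ", d, "x: assembling")
    assembly <- assemble_bins(bins, sim$references, k_asm = assembly_k,
                              min_count = min_count,
                              min_length = min_length,
                              max_seed_retries = max_seed_retries)
    report <- evaluate_recovery(assembly$contigs, sim$truths,
                                target_lengths =
                                  sim$references$target_length,
                                max_base_error = max_base_error,
                                min_cover = min_cover)
    s <- report$summary
    say(sprintf("depth %gx: T50 = %d, valid = %d, base err %.4g%%",
                d, s$t50, s$n_valid,
                100 * s$aggregate_base_error_rate))
    rows[[di]] <- data.frame(
      depth = d, n_pairs = nrow(pairs_df),
      n_recovered = s$n_recovered, n_valid = s$n_valid, t50 = s$t50,
      aggregate_base_error_pct = 100 * s$aggregate_base_error_rate,
      aggregate_indel_error_pct = 100 * s$aggregate_indel_error_rate,
      stringsAsFactors = FALSE)
    reports[[di]] <- report
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  names(reports) <- as.character(depths)
  structure(list(metrics = metrics, reports = reports, config = cfg),
            class = "depth_gradient")
}

#' @export
print.depth_gradient <- function(x, ...) {
  cat("depth_gradient over", nrow(x$metrics), "depths,",
      x$config$n_genes, "genes:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
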