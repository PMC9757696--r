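#' Read a FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file. Sequences are
#' uppercased and line wrapping is removed. The record id is the first
#' whitespace-delimited token of the header; the remainder (possibly empty)
#' is kept as the description.
#'
#' @param path path to a FASTA file, plain or gzip-compressed.
#' @return A data frame with columns `id`, `desc` and `seq`, one row per
#'   record, in file order. Zero rows for an empty file.
#' @seealso [write_fasta()], [read_fastq_pairs()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  dss <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("FASTA format error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(dss) == 0L) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  headers <- names(dss)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(dss))
  if (any(!nzchar(seqs))) {
    stop("FASTA format error in '", path, "': record with empty sequence",
         call. = FALSE)
  }
  data.frame(id = id, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x named character vector of sequences, or a data frame with
#'   columns `id` and `seq` (and optionally `desc`).
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param wrap positive integer, bases per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 60L) {
  stopifnot(wrap >= 1L)
  if (is.data.frame(x)) {
    seqs <- x$seq
    ids <- x$id
    if (!is.null(x$desc)) {
      ids <- ifelse(nzchar(x$desc), paste(ids, x$desc), ids)
    }
  } else {
    seqs <- as.character(x)
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs)) {
    chunks <- vapply(seqs, function(s) {
      n <- nchar(s)
      starts <- seq.int(1L, n, by = wrap)
      paste(substring(s, starts, pmin(starts + wrap - 1L, n)),
            collapse = "\n")
    }, character(1), USE.NAMES = FALSE)
    writeLines(paste0(">", ids, "\n", chunks), con, sep = "\n")
  }
  invisible(path)
}

strip_mate_suffix <- function(id) {
  sub("[/_][12]$", "", id)
}

parse_fastq_lines <- function(lines, path, offset) {
  n <- length(lines)
  if (n == 0L) {
    return(list(id = character(), seq = character(), qual = character()))
  }
  if (n %% 4L != 0L) {
    stop("FASTQ format error in '", path, "': truncated record near line ",
         offset + n, call. = FALSE)
  }
  h <- lines[seq.int(1L, n, by = 4L)]
  p <- lines[seq.int(3L, n, by = 4L)]
  bad <- which(!startsWith(h, "@") | !startsWith(p, "+"))
  if (length(bad)) {
    stop("FASTQ format error in '", path, "': malformed record at line ",
         offset + (bad[1] - 1L) * 4L + 1L, call. = FALSE)
  }
  seq <- toupper(lines[seq.int(2L, n, by = 4L)])
  qual <- lines[seq.int(4L, n, by = 4L)]
  if (any(nchar(qual) != nchar(seq))) {
    stop("FASTQ format error in '", path,
         "': quality length differs from sequence length", call. = FALSE)
  }
  header <- sub("^@", "", h)
  list(id = sub("\\s.*$", "", header), seq = seq, qual = qual)
}

#' Streaming reader over single- or paired-end FASTQ
#'
#' Returns a closure that yields successive chunks of reads so that memory
#' use is bounded by the chunk size, not the file size. Plain and
#' gzip-compressed files are both accepted (compression is detected from the
#' stream, not the file name).
#'
#' @param path1 FASTQ file with the first (or only) mates.
#' @param path2 optional FASTQ file with second mates.
#' @param chunk_size number of records (pairs) per chunk.
#' @return A function that, when called, returns either `NULL` (end of
#'   input) or a list with elements `id`, `seq1`, `qual1` and, for paired
#'   input, `seq2`, `qual2`. Mate identifiers are checked to agree after
#'   stripping a trailing mate suffix (`/1`, `/2`).
#' @seealso [read_fastq_pairs()] for a materialized data frame.
#' @export
fastq_pair_stream <- function(path1, path2 = NULL, chunk_size = 20000L) {
  for (p in c(path1, path2)) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
  }
  con1 <- gzfile(path1, "rt")
  con2 <- if (!is.null(path2)) gzfile(path2, "rt") else NULL
  off1 <- 0L
  off2 <- 0L
  done <- FALSE
  close_all <- function() {
    done <<- TRUE
    try(close(con1), silent = TRUE)
    if (!is.null(con2)) try(close(con2), silent = TRUE)
  }
  function() {
    if (done) {
      return(NULL)
    }
    on_error <- function(e) {
      close_all()
      stop(e)
    }
    tryCatch({
    l1 <- readLines(con1, n = chunk_size * 4L)
    r1 <- parse_fastq_lines(l1, path1, off1)
    off1 <<- off1 + length(l1)
    if (is.null(con2)) {
      if (length(l1) == 0L) {
        close_all()
        return(NULL)
      }
      return(list(id = strip_mate_suffix(r1$id), seq1 = r1$seq,
                  qual1 = r1$qual))
    }
    l2 <- readLines(con2, n = chunk_size * 4L)
    r2 <- parse_fastq_lines(l2, path2, off2)
    off2 <<- off2 + length(l2)
    if (length(l1) != length(l2)) {
      stop("read pairing error: '", path1, "' and '", path2,
           "' have different record counts", call. = FALSE)
    }
    if (length(l1) == 0L) {
      close_all()
      return(NULL)
    }
    id1 <- strip_mate_suffix(r1$id)
    id2 <- strip_mate_suffix(r2$id)
    bad <- which(id1 != id2)
    if (length(bad)) {
      stop("read pairing error: mate identifiers disagree ('", r1$id[bad[1]],
           "' vs '", r2$id[bad[1]], "')", call. = FALSE)
    }
    list(id = id1, seq1 = r1$seq, qual1 = r1$qual,
         seq2 = r2$seq, qual2 = r2$qual)
    }, error = on_error)
  }
}

#' Read single- or paired-end FASTQ into a data frame
#'
#' Convenience wrapper over [fastq_pair_stream()] that materializes all
#' read pairs.
#'
#' @inheritParams fastq_pair_stream
#' @return A data frame with columns `id`, `seq1`, `qual1` and, for paired
#'   input, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2 = NULL, chunk_size = 20000L) {
  stream <- fastq_pair_stream(path1, path2, chunk_size)
  chunks <- list()
  repeat {
    ch <- stream()
    if (is.null(ch)) break
    chunks[[length(chunks) + 1L]] <- as.data.frame(ch,
                                                   stringsAsFactors = FALSE)
  }
  if (!length(chunks)) {
    cols <- c("id", "seq1", "qual1", if (!is.null(path2)) c("seq2", "qual2"))
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                         cols), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

write_fastq <- function(id, seq, qual, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seq)) {
    writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
  }
  invisible(path)
}
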