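#' Classify reads by gapped k-mer coverage
#'
#' For each read, queries gapped k-mer windows in the index and accumulates
#' the set of covered base positions; a read is classified as host if at
#' least `threshold * read_length` bases are covered (inclusive: the
#' boundary counts as host).
#'
#' Modes:
#' * `"sensitive"`: every window offset is queried; a hit marks the
#'   significant positions of the window as covered.
#' * `"sampling"`: only offsets `0, s, 2s, ...` with `s = floor(w/2) + 1`
#'   are queried (the first window, then skipping the next `floor(w/2)`
#'   windows); a hit marks all `w` window positions as covered, so every
#'   base can be covered by up to two distinct queried windows.
#'
#' Windows containing non-ACGT characters count as queried but cannot hit
#' (the index holds only fully defined seeds). Reads shorter than the mask
#' width query nothing and are never classified as host.
#'
#' @param reads character vector of read sequences.
#' @param index a `cuckoo_index` with an attached mask (from
#'   [build_index()] or [load_index()]), or the list returned by
#'   [build_index()].
#' @param mode `"sensitive"` (default) or `"sampling"`.
#' @param threshold coverage threshold T in \[0, 1\] (default 0.5).
#' @return data.frame with one row per read: `read_length`,
#'   `windows_queried`, `windows_hit`, `covered_bases`, `is_host`.
#' @export
classify_reads <- function(reads, index, mode = c("sensitive", "sampling"),
                           threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.character(reads), threshold >= 0, threshold <= 1)
  index <- unwrap_index(index)
  info <- .store_info_cpp(index$ptr)
  if (!nzchar(info$mask))
    stop("index has no mask attached; build it with build_index()")
  mask <- parse_mask(info$mask)
  .classify_batch_cpp(index$ptr, reads, mask$kappa, mask$w,
                      if (mode == "sampling") 1L else 0L, threshold)
}

unwrap_index <- function(index) {
  if (is.list(index) && !inherits(index, "cuckoo_index") &&
      !is.null(index$index)) index <- index$index
  check_store(index)
}

#' @rdname classify_reads
#' @param read a single read sequence.
#' @export
classify_read <- function(read, index, mode = c("sensitive", "sampling"),
                          threshold = 0.5) {
  classify_reads(read, index, mode, threshold)
}

#' Classify a read pair
#'
#' Each end is classified independently; the pair is removed if at least
#' one end is classified as host.
#'
#' @param read1,read2 the two read sequences of the pair.
#' @inheritParams classify_reads
#' @return list with `remove_pair` (logical) and the per-end one-row
#'   data.frames `end1`, `end2`.
#' @export
classify_pair <- function(read1, read2, index,
                          mode = c("sensitive", "sampling"),
                          threshold = 0.5) {
  r1 <- classify_reads(read1, index, mode, threshold)
  r2 <- classify_reads(read2, index, mode, threshold)
  list(remove_pair = r1$is_host[1] || r2$is_host[1], end1 = r1, end2 = r2)
}

#' Filter FASTQ files against a host index
#'
#' Streams single-end or paired-end FASTQ input (gzip accepted), classifies
#' every read (pair), writes the retained (non-host) records to the output
#' files preserving order, record bytes and pairing, and optionally writes
#' the removed records to separate sinks. For paired input a pair is
#' removed if either end is host; summary counts are in pairs.
#'
#' @param reads input FASTQ path (read 1 for paired data).
#' @param out output FASTQ path for retained reads (read 1).
#' @param index index as in [classify_reads()].
#' @param reads2,out2 second-end input/output for paired data (both or
#'   neither).
#' @param removed,removed2 optional sinks for removed reads.
#' @param mode,threshold see [classify_reads()].
#' @param chunk_size records per streamed chunk.
#' @return list `summary`: `total`, `removed`, `retained` (units: reads, or
#'   pairs for paired input), plus `short_reads` (reads shorter than the
#'   mask width, always retained).
#' @export
filter_fastq <- function(reads, out, index, reads2 = NULL, out2 = NULL,
                         removed = NULL, removed2 = NULL,
                         mode = c("sensitive", "sampling"), threshold = 0.5,
                         chunk_size = 50000L) {
  mode <- match.arg(mode)
  paired <- !is.null(reads2)
  if (paired && is.null(out2))
    stop("paired input (reads2) requires a second output (out2)")
  if (!paired && !is.null(out2))
    stop("out2 given without reads2")
  index <- unwrap_index(index)
  info <- .store_info_cpp(index$ptr)
  if (!nzchar(info$mask)) stop("index has no mask attached")
  mask <- parse_mask(info$mask)

  in1 <- open_fastq_in(reads)
  on.exit(close(in1), add = TRUE)
  out1 <- open_fastq_out(out)
  on.exit(close(out1), add = TRUE)
  if (paired) {
    in2 <- open_fastq_in(reads2)
    on.exit(close(in2), add = TRUE)
    o2 <- open_fastq_out(out2)
    on.exit(close(o2), add = TRUE)
  }
  rem1 <- if (!is.null(removed)) open_fastq_out(removed)
  if (!is.null(rem1)) on.exit(close(rem1), add = TRUE)
  rem2 <- if (paired && !is.null(removed2)) open_fastq_out(removed2)
  if (!is.null(rem2)) on.exit(close(rem2), add = TRUE)

  total <- 0; n_removed <- 0; n_short <- 0
  mode_i <- if (mode == "sampling") 1L else 0L
  repeat {
    c1 <- read_fastq_chunk(in1, chunk_size)
    c2 <- if (paired) read_fastq_chunk(in2, chunk_size)
    if (is.null(c1)) {
      if (paired && !is.null(c2))
        stop("paired FASTQ inputs have unequal record counts")
      break
    }
    if (paired && (is.null(c2) || length(c2$seq) != length(c1$seq)))
      stop("paired FASTQ inputs have unequal record counts")
    r1 <- .classify_batch_cpp(index$ptr, c1$seq, mask$kappa, mask$w,
                              mode_i, threshold)
    host <- r1$is_host
    n_short <- n_short + sum(r1$read_length < mask$w)
    if (paired) {
      r2 <- .classify_batch_cpp(index$ptr, c2$seq, mask$kappa, mask$w,
                                mode_i, threshold)
      host <- host | r2$is_host
      n_short <- n_short + sum(r2$read_length < mask$w)
    }
    total <- total + length(host)
    n_removed <- n_removed + sum(host)
    write_fastq_chunk(out1, c1, which(!host))
    if (!is.null(rem1)) write_fastq_chunk(rem1, c1, which(host))
    if (paired) {
      write_fastq_chunk(o2, c2, which(!host))
      if (!is.null(rem2)) write_fastq_chunk(rem2, c2, which(host))
    }
  }
  list(total = total, removed = n_removed, retained = total - n_removed,
       short_reads = n_short, paired = paired, mode = mode,
       threshold = threshold)
}
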