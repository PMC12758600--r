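#' Read / write FASTQ files
#'
#' Minimal lossless FASTQ plumbing for the filtering pipeline: 4-line
#' records, gzip handled transparently on input (magic-byte detection via
#' the connection layer) and selected by a `.gz` suffix on output. Header
#' and separator lines, sequences and quality strings are passed through
#' byte-for-byte; record order is preserved.
#'
#' @param path FASTQ file path (`.gz` accepted).
#' @return `read_fastq` returns a data.frame with columns `header` (with
#'   leading `@`), `seq`, `plus`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- open_fastq_in(path)
  on.exit(close(con))
  out <- list()
  repeat {
    chunk <- read_fastq_chunk(con, 65536L)
    if (is.null(chunk)) break
    out[[length(out) + 1L]] <- chunk
  }
  if (!length(out))
    return(data.frame(header = character(), seq = character(),
                      plus = character(), qual = character()))
  do.call(rbind, lapply(out, as.data.frame))
}

#' @rdname read_fastq
#' @param records data.frame as returned by `read_fastq`, or with columns
#'   `id`, `seq`, `qual` (a `@` and a bare `+` are added).
#' @export
write_fastq <- function(records, path) {
  con <- open_fastq_out(path)
  on.exit(close(con))
  write_fastq_chunk(con, normalize_fastq_records(records))
  invisible(path)
}

normalize_fastq_records <- function(records) {
  if (!is.null(records$header)) return(records)
  list(header = paste0("@", records$id), seq = records$seq,
       plus = rep("+", length(records$seq)), qual = records$qual)
}

# gzfile() reads both gzip-compressed and plain text (autodetects by magic)
open_fastq_in <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  gzfile(path, "rt")
}
open_fastq_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

# Returns list(header, seq, plus, qual) of up to n records, or NULL at EOF.
read_fastq_chunk <- function(con, n) {
  lines <- readLines(con, n = n * 4L)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at end of file")
  idx <- seq(1L, length(lines), by = 4L)
  header <- lines[idx]
  seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(header, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record at record index ", bad[1])
  mis <- which(nchar(seq) != nchar(qual))
  if (length(mis))
    stop("sequence/quality length mismatch at record index ", mis[1])
  list(header = header, seq = seq, plus = plus, qual = qual)
}

write_fastq_chunk <- function(con, chunk, sel = NULL) {
  if (!is.null(sel)) chunk <- lapply(chunk, `[`, sel)
  n <- length(chunk$header)
  if (n == 0L) return(invisible())
  out <- character(4L * n)
  out[seq(1L, 4L * n, by = 4L)] <- chunk$header
  out[seq(2L, 4L * n, by = 4L)] <- chunk$seq
  out[seq(3L, 4L * n, by = 4L)] <- chunk$plus
  out[seq(4L, 4L * n, by = 4L)] <- chunk$qual
  writeLines(out, con)
  invisible()
}
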