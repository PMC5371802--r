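#' Quality-control parameters for amplicon reads
#'
#' The QC recipe for HiSeq amplicon surveys: hard-trim the first and last 10
#' bases (primer/low-quality ends), then keep a read only if more than 95% of
#' its remaining positions were called at Phred quality 20 or better. The
#' retention rule uses a strict inequality — exactly 95% fails.
#'
#' @param trim_head,trim_tail Bases removed from the start / end of each read.
#' @param min_fraction Minimum fraction (exclusive) of positions at or above
#'   `q_threshold`.
#' @param q_threshold Phred score counted as a good call (`Q >= q_threshold`).
#' @param min_length Reads shorter than this after trimming are dropped and
#'   tallied as length-dropped.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(trim_head = 10, trim_tail = 10, min_fraction = 0.95,
                      q_threshold = 20, min_length = 1) {
  stopifnot(trim_head >= 0, trim_tail >= 0,
            min_fraction >= 0, min_fraction <= 1, min_length >= 1)
  structure(list(trim_head = as.integer(trim_head),
                 trim_tail = as.integer(trim_tail),
                 min_fraction = min_fraction,
                 q_threshold = as.integer(q_threshold),
                 min_length = as.integer(min_length)),
            class = "qc_params")
}

#' Trim fixed-length head and tail off reads
#'
#' @param reads A read tibble (`id`, `bases`, `quals`) as from [read_fastq()].
#' @param params A [qc_params()] object.
#' @return The read tibble with trimmed `bases` and `quals`; reads shorter
#'   than `trim_head + trim_tail` become empty (zero-length) reads.
#' @export
trim_reads <- function(reads, params = qc_params()) {
  len <- nchar(reads$bases)
  from <- pmin(params$trim_head + 1L, len + 1L)
  to <- pmax(len - params$trim_tail, from - 1L)
  reads$bases <- substr(reads$bases, from, to)
  reads$quals <- lapply(seq_len(nrow(reads)), function(i) {
    q <- reads$quals[[i]]
    if (from[i] > to[i]) integer(0) else q[from[i]:to[i]]
  })
  reads
}

#' Does a read pass the fraction-of-good-bases rule?
#'
#' @param quals Integer vector of Phred scores for one read.
#' @param params A [qc_params()] object.
#' @return `TRUE` iff the fraction of positions with `Q >= q_threshold`
#'   strictly exceeds `min_fraction`. Empty reads are an error; route them to
#'   the length-dropped tally first.
#' @export
passes_quality <- function(quals, params = qc_params()) {
  if (length(quals) == 0) {
    abort("passes_quality() on an empty read; drop short reads first")
  }
  mean(quals >= params$q_threshold) > params$min_fraction
}

#' Trim and quality-filter a batch of reads
#'
#' Applies [trim_reads()] then the strict fraction-at-Q rule, preserving read
#' order. Reads falling below `min_length` after trimming are tallied as
#' length-dropped; reads failing the quality rule as quality-dropped.
#'
#' @inheritParams trim_reads
#' @return An object of class `qc_result`: a list with `reads` (the kept,
#'   trimmed tibble) and `stats` (a one-row tibble: `reads_in`, `reads_kept`,
#'   `reads_dropped_quality`, `reads_dropped_length`). `tidy()` returns the
#'   kept reads, `glance()` the stats row.
#' @examples
#' fq <- simulate_fastq(50, length = 100, p_good_base = 0.97, seed = 1)
#' res <- qc_reads(read_fastq(fq))
#' glance(res)
#' @export
qc_reads <- function(reads, params = qc_params()) {
  n_in <- nrow(reads)
  trimmed <- trim_reads(reads, params)
  len <- nchar(trimmed$bases)
  long_enough <- len >= params$min_length
  pass <- logical(n_in)
  pass[long_enough] <- vapply(which(long_enough), function(i) {
    passes_quality(trimmed$quals[[i]], params)
  }, logical(1))
  stats <- tibble::tibble(
    reads_in = n_in,
    reads_kept = sum(pass),
    reads_dropped_quality = sum(long_enough & !pass),
    reads_dropped_length = sum(!long_enough)
  )
  structure(list(reads = trimmed[pass, ], stats = stats, params = params),
            class = "qc_result")
}

#' @export
tidy.qc_result <- function(x, ...) x$reads

#' @export
glance.qc_result <- function(x, ...) x$stats

#' @export
print.qc_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<qc_result> %d reads in, %d kept (%d quality-dropped, %d length-dropped)\n",
              s$reads_in, s$reads_kept, s$reads_dropped_quality, s$reads_dropped_length))
  invisible(x)
}
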