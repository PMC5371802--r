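#' Read and write FASTQ (Phred+33)
#'
#' Reads a 4-line-per-record FASTQ file into a tibble with one row per read.
#' Quality characters are decoded to integer Phred scores assuming the +33
#' offset used by modern Illumina pipelines; other encodings are rejected by
#' the score-range check rather than guessed.
#'
#' @param path Path to a FASTQ file, or a character vector of its lines.
#' @return A tibble with columns `id` (text after `@`), `bases` (nucleotide
#'   string) and `quals` (list-column of integer Phred scores, one per base).
#' @examples
#' fq <- c("@r1", "ACGT", "+", "IIII")
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  # trailing blank lines are tolerated; blanks elsewhere are truncation
  while (length(lines) > 0 && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (record %d is incomplete)",
                  length(lines), length(lines) %/% 4 + 1))
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    return(tibble::tibble(id = character(), bases = character(), quals = list()))
  }
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ: record %d header does not start with '@'", bad[1]))
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ: record %d has %d bases but %d quality characters",
                  bad[1], nchar(seqs[bad[1]]), nchar(quals[bad[1]])))
  }
  qlist <- lapply(quals, function(q) as.integer(utf8ToInt(q)) - 33L)
  rng <- range(c(0L, unlist(qlist, use.names = FALSE)))
  if (rng[1] < 0 || rng[2] > 60) {
    abort("quality scores outside [0, 60]: input is not Phred+33")
  }
  tibble::tibble(id = sub("^@", "", hdr), bases = seqs, quals = qlist)
}

#' @rdname read_fastq
#' @param reads A tibble as returned by `read_fastq()`.
#' @param path Output path; when `NULL` the FASTQ text is returned as a
#'   character vector of lines.
#' @export
write_fastq <- function(reads, path = NULL) {
  stopifnot(all(c("id", "bases", "quals") %in% names(reads)))
  if (nrow(reads) > 0 &&
      any(nchar(reads$bases) != lengths(reads$quals))) {
    abort("bases and quals disagree in length")
  }
  qstr <- vapply(reads$quals, function(q) intToUtf8(as.integer(q) + 33L), character(1))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", qstr))
  if (nrow(reads) == 0) lines <- character(0)
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(path)
}
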