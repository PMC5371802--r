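#' Replicate (count) columns of an OTU or phylotype table
#'
#' Tables are tibbles with one numeric column per PCR replicate; every other
#' column (ids, lineages, membership list-columns) is metadata. This helper
#' names the count columns, in table order.
#'
#' @param tbl An OTU or phylotype tibble.
#' @return Character vector of column names.
#' @export
replicate_cols <- function(tbl) {
  names(tbl)[vapply(tbl, is.numeric, logical(1))]
}

count_matrix <- function(tbl) {
  reps <- replicate_cols(tbl)
  m <- as.matrix(tbl[reps])
  if (is.null(dim(m)) || length(reps) == 0) {
    m <- matrix(numeric(0), nrow = nrow(tbl), ncol = length(reps))
  }
  colnames(m) <- reps
  m
}

#' Read an OTU count table and its lineage map
#'
#' The count table is tab-separated with a header row of replicate names and a
#' first column of OTU ids. The taxonomy map is tab-separated `otu_id TAB
#' lineage`, the lineage being a semicolon-joined label path. OTUs missing
#' from the map get the unknown (empty) lineage and are reported via a
#' message; counts must be non-negative integers and OTU ids unique.
#'
#' @param table_path Path to the tab-separated count table.
#' @param taxonomy_path Optional path to the tab-separated lineage map.
#' @return A tibble with `otu_id`, one integer column per replicate, and
#'   `lineage`.
#' @export
read_otu_table <- function(table_path, taxonomy_path = NULL) {
  tbl <- readr::read_tsv(table_path, col_types = readr::cols(
    .default = readr::col_character()), show_col_types = FALSE)
  names(tbl)[1] <- "otu_id"
  reps <- setdiff(names(tbl), "otu_id")
  if (anyDuplicated(tbl$otu_id)) {
    abort(paste0("duplicate OTU id: ", tbl$otu_id[duplicated(tbl$otu_id)][1]))
  }
  if (nrow(tbl) > 0) {
    ok <- vapply(tbl[reps], function(col) grepl("^[0-9]+$", col),
                 logical(nrow(tbl)))
    ok <- matrix(ok, nrow = nrow(tbl))
    bad <- which(rowSums(!ok) > 0)
    if (length(bad)) {
      abort(paste0("negative or non-integer count in row '", tbl$otu_id[bad[1]], "'"))
    }
  }
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::all_of(reps), as.integer))
  tax <- if (is.null(taxonomy_path)) {
    tibble::tibble(otu_id = character(), lineage = character())
  } else {
    readr::read_tsv(taxonomy_path,
                    col_names = c("otu_id", "lineage"),
                    col_types = "cc", show_col_types = FALSE)
  }
  out <- dplyr::left_join(tbl, tax, by = "otu_id")
  missing <- is.na(out$lineage)
  if (any(missing)) {
    message(sum(missing), " OTU(s) missing from the taxonomy map; assigned the unknown lineage")
    out$lineage[missing] <- ""
  }
  out$lineage <- lineage_join(lineage_split(out$lineage))
  out
}

#' @rdname read_otu_table
#' @param tbl An OTU tibble as returned by `read_otu_table()`.
#' @param table_path,taxonomy_path Output paths (taxonomy optional).
#' @export
write_otu_table <- function(tbl, table_path, taxonomy_path = NULL) {
  reps <- replicate_cols(tbl)
  readr::write_tsv(tbl[c("otu_id", reps)], table_path)
  if (!is.null(taxonomy_path)) {
    readr::write_tsv(tbl[c("otu_id", "lineage")], taxonomy_path, col_names = FALSE)
  }
  invisible(table_path)
}

blast_col_names <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore")

#' Read BLAST tabular output (outfmt 6) with an e-value gate
#'
#' Parses the standard 12-column tab-separated BLAST output and drops hits at
#' or above the expectation-value threshold (the survey convention is to keep
#' e-values below 1e-5). The number of gated-out records is attached as the
#' `"discarded"` attribute.
#'
#' @param path Path to a BLAST tabular file, or a character vector of lines.
#' @param max_evalue Hits with `evalue < max_evalue` are kept. Use `Inf` to
#'   keep every syntactically valid record.
#' @return A tibble with the 12 standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`) and attribute `discarded`.
#' @export
read_blast_tabular <- function(path, max_evalue = 1e-5) {
  stopifnot(max_evalue > 0)
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    out <- tibble::as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), blast_col_names))
    attr(out, "discarded") <- 0L
    return(out)
  }
  nfield <- stringr::str_count(lines, "\t") + 1L
  bad <- which(nfield != 12L)
  if (length(bad)) {
    abort(sprintf("line %d has %d columns; 12-column BLAST tabular expected",
                  bad[1], nfield[bad[1]]))
  }
  hits <- readr::read_tsv(I(lines), col_names = blast_col_names,
                          col_types = "ccdddddddddd", show_col_types = FALSE)
  if (any(hits$evalue < 0) || any(!is.finite(hits$bitscore))) {
    abort("invalid BLAST record: negative e-value or non-finite bit-score")
  }
  keep <- hits$evalue < max_evalue
  out <- hits[keep, ]
  attr(out, "discarded") <- sum(!keep)
  out
}

#' Write lineage counts in Krona text-import format
#'
#' Emits one line per entry: the count, a TAB, then the lineage labels
#' TAB-separated from most general to most specific — the dialect consumed by
#' `ktImportText`. Total count mass is conserved exactly.
#'
#' @param counts Numeric vector of non-negative counts.
#' @param lineage Character vector of semicolon-joined lineages, parallel to
#'   `counts`. Unknown lineages are emitted under the single label
#'   `"unknown"`.
#' @param path Output path; when `NULL` the lines are returned.
#' @return The lines (invisibly, when written to `path`).
#' @examples
#' write_krona_text(7, "Bacteria;Cyanobacteria;Synechococcus")
#' @export
write_krona_text <- function(counts, lineage, path = NULL) {
  if (length(counts) != length(lineage)) {
    abort("counts and lineage must have the same length")
  }
  if (any(counts < 0)) {
    abort("negative count in Krona export")
  }
  labs <- lineage_split(lineage)
  labs <- lapply(labs, function(l) if (length(l)) l else "unknown")
  lines <- vapply(seq_along(counts), function(i) {
    paste(c(format(counts[i], scientific = FALSE, trim = TRUE), labs[[i]]),
          collapse = "\t")
  }, character(1))
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}
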