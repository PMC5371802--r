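#' Best hit per query
#'
#' Selects, for every query, the hit with the maximal bit-score; ties break by
#' minimal e-value, then by input order (first wins). Queries tied across
#' subjects with *different* lineages are resolved the same way; callers can
#' count such ambiguities from the returned table.
#'
#' @param hits A BLAST hit tibble as from [read_blast_tabular()], already
#'   e-value gated.
#' @return A tibble with one row per `qseqid`, in order of first appearance.
#' @export
top_hit_per_query <- function(hits) {
  hits$.ord <- seq_len(nrow(hits))
  out <- hits |>
    dplyr::arrange(.data$qseqid, dplyr::desc(.data$bitscore), .data$evalue, .data$.ord) |>
    dplyr::distinct(.data$qseqid, .keep_all = TRUE)
  out <- dplyr::arrange(out, match(.data$qseqid, unique(hits$qseqid)))
  out$.ord <- NULL
  out
}

#' Assign taxonomy to top hits via a subject-lineage map
#'
#' Each query inherits the lineage of its top hit's subject. Subjects absent
#' from the map are kept with the unknown lineage and flagged; queries with no
#' gated hit at all (supply the full query universe via `queries`) are listed
#' separately as unannotated.
#'
#' @param tophits One-row-per-query hit tibble from [top_hit_per_query()].
#' @param taxmap A tibble `subject_id`, `lineage` (semicolon-joined); no
#'   subject may map to two lineages.
#' @param queries Optional character vector of all query ids submitted, used
#'   to identify unannotated queries.
#' @return An object of class `annotation_set`: a tibble `query_id`,
#'   `subject_id`, `lineage`, `mapped` (logical) plus the hit columns, with
#'   attribute `unannotated` (character vector). `tidy()` returns the tibble.
#' @export
annotate_hits <- function(tophits, taxmap, queries = NULL) {
  if (anyDuplicated(taxmap$subject_id)) {
    abort("taxonomy map assigns two lineages to one subject")
  }
  out <- tibble::tibble(
    query_id = tophits$qseqid,
    subject_id = tophits$sseqid,
    lineage = taxmap$lineage[match(tophits$sseqid, taxmap$subject_id)],
    evalue = tophits$evalue,
    bitscore = tophits$bitscore
  )
  out$mapped <- !is.na(out$lineage)
  out$lineage[!out$mapped] <- ""
  out$lineage <- lineage_join(lineage_split(out$lineage))
  unannotated <- if (is.null(queries)) character(0) else setdiff(queries, out$query_id)
  structure(out, unannotated = unannotated,
            class = c("annotation_set", class(out)))
}

#' @export
tidy.annotation_set <- function(x, ...) tibble::as_tibble(x)

#' Superkingdom composition of an annotation set
#'
#' Percentage of annotated queries per top-level category (Bacteria, Archaea,
#' Eukaryota, Viruses, unknown), to two decimals; categories absent from the
#' data are omitted and the percentages sum to 100 within rounding.
#'
#' @param annotations An [annotate_hits()] result, or any tibble with a
#'   `lineage` column.
#' @return A tibble `superkingdom`, `n`, `pct`, sorted by decreasing `pct`.
#' @export
superkingdom_profile <- function(annotations) {
  if (nrow(annotations) == 0) {
    return(tibble::tibble(superkingdom = character(), n = integer(), pct = numeric()))
  }
  tibble::tibble(superkingdom = superkingdom_of(annotations$lineage)) |>
    dplyr::count(.data$superkingdom, name = "n") |>
    dplyr::mutate(pct = round_away(100 * .data$n / sum(.data$n), 2)) |>
    dplyr::arrange(dplyr::desc(.data$pct))
}

#' Deterministic uniform subsampling
#'
#' Library-size normalisation by drawing `n` items uniformly without
#' replacement under an explicit seed, so a run is reproducible from its
#' recorded metadata. When `n` is at least the number of items, everything is
#' returned in original order.
#'
#' @param items A vector (or list) to sample from.
#' @param n Target sample size.
#' @param seed Integer seed; identical `(items, n, seed)` gives an identical
#'   result.
#' @return The sampled items, with attribute `seed`.
#' @export
subsample <- function(items, n, seed) {
  stopifnot(n >= 0)
  size <- if (is.data.frame(items)) nrow(items) else length(items)
  if (n >= size) {
    out <- items
  } else {
    idx <- withr::with_seed(as.integer(seed), sample.int(size, n))
    out <- if (is.data.frame(items)) items[idx, ] else items[idx]
  }
  attr(out, "seed") <- as.integer(seed)
  out
}
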