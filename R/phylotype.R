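#' Collapse OTUs into phylotypes at the lowest assigned rank
#'
#' OTUs whose lineages share the same lowest assigned taxon merge into one
#' phylotype; counts are summed per replicate and member OTU ids recorded.
#' Unassigned OTUs collapse into the single `"unknown"` phylotype. Identical
#' labels reached through *different* lineage paths (e.g. one genus under two
#' conflicting families) are kept as separate phylotypes and the conflict is
#' reported with a message — merging across inconsistent paths would hide a
#' reference-database disagreement.
#'
#' @param tbl An OTU tibble (`otu_id`, count columns, `lineage`).
#' @param rank_order Rank names, most general first.
#' @return A phylotype tibble: `phylotype` (label), `rank`, `lineage`,
#'   `members` (list of OTU ids), and one count column per replicate. Count
#'   mass is conserved exactly per replicate.
#' @export
aggregate_phylotypes <- function(tbl, rank_order = rank_order_cellular()) {
  reps <- replicate_cols(tbl)
  lab <- phylotype_label(tbl$lineage, rank_order)
  key <- lab$lineage  # full path: homonym labels under distinct paths stay apart
  key[lab$depth == 0] <- ""
  homonyms <- dplyr::distinct(tibble::tibble(label = lab$label, rank = lab$rank, key = key))
  homonyms <- dplyr::count(homonyms, .data$label, .data$rank)
  homonyms <- dplyr::filter(homonyms, .data$n > 1)
  if (nrow(homonyms) > 0) {
    message(nrow(homonyms), " phylotype label(s) occur under conflicting lineage paths; kept separate")
  }
  grouped <- tibble::tibble(key = key, label = lab$label, rank = lab$rank,
                            otu_id = tbl$otu_id)
  grouped <- dplyr::bind_cols(grouped, tbl[reps])
  out <- dplyr::summarise(
    dplyr::group_by(grouped, .data$key, .data$label, .data$rank),
    members = list(.data$otu_id),
    dplyr::across(dplyr::all_of(reps), sum),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$key)
  tibble::tibble(
    phylotype = out$label,
    rank = out$rank,
    lineage = out$key,
    members = out$members
  ) |>
    dplyr::bind_cols(out[reps])
}
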