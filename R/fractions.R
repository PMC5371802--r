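#' Presence-absence comparison of size fractions
#'
#' Compares what was seen in the small (<0.45 um) metagenome fraction against
#' the prokaryote and eukaryote amplicon fractions at one stringency level.
#' All three datasets are projected to genus — or, where the genus is not
#' assigned, the most specific rank available ([project_to_rank()]) — and the
#' resulting label sets are partitioned into Venn regions with pairwise
#' shared percentages (union denominator). The metagenome set is conventionally
#' held at its unfiltered annotation while the amplicon stringency varies.
#'
#' @param meta An [annotate_hits()] result (or tibble with `lineage`) for the
#'   metagenome fraction.
#' @param prok,euk Phylotype tibbles (with `lineage`) for the amplicon
#'   fractions, already filtered at the requested level.
#' @param level The [stringency_level()] the amplicon tables were filtered at
#'   (recorded in the report; not re-applied).
#' @param rank Projection rank (default `"genus"`).
#' @param rank_order Rank names, most general first.
#' @return An object of class `fraction_report`: list with `level`, `sets`
#'   (named list: metagenome, prokaryote, eukaryote), `venn`
#'   (a [venn_partition()]) and `pairwise` (tibble of [method_overlap()] rows
#'   per pair). `tidy()` returns the pairwise table.
#' @export
compare_fractions <- function(meta, prok, euk, level = stringency_level("T0"),
                              rank = "genus", rank_order = rank_order_cellular()) {
  proj <- function(lineage) {
    if (length(lineage) == 0) return(character(0))
    p <- project_to_rank(lineage, rank, rank_order)
    unique(p$label[p$label != "unknown"])
  }
  sets <- list(
    metagenome = proj(meta$lineage),
    prokaryote = proj(prok$lineage),
    eukaryote = proj(euk$lineage)
  )
  if (length(sets$prokaryote) == 0 && length(sets$eukaryote) == 0) {
    warn("both amplicon sets are empty after filtering; regions are zeroed")
  }
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- dplyr::bind_rows(lapply(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    row <- if (length(a) == 0 && length(b) == 0) {
      tibble::tibble(n_shared = 0L, n_a_only = 0L, n_b_only = 0L, shared_pct = NA_real_)
    } else {
      method_overlap(a, b)
    }
    dplyr::bind_cols(tibble::tibble(set_a = p[1], set_b = p[2]), row)
  }))
  structure(list(level = level$name, sets = sets,
                 venn = venn_partition(sets), pairwise = pairwise),
            class = "fraction_report")
}

#' @export
tidy.fraction_report <- function(x, ...) x$pairwise

#' @export
glance.fraction_report <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    n_metagenome = length(x$sets$metagenome),
    n_prokaryote = length(x$sets$prokaryote),
    n_eukaryote = length(x$sets$eukaryote),
    n_all_shared = sum(x$venn$size[lengths(x$venn$sets) == 3])
  )
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf("<fraction_report> amplicon level %s\n", x$level))
  print(x$pairwise)
  invisible(x)
}
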