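#' Taxonomic rank orders
#'
#' Lineages are semicolon-joined label paths read from most general to most
#' specific; the rank of each label is positional, taken from a configured
#' rank order. Two presets are shipped: a SILVA-style order for cellular
#' organisms and an ICTV-style order for viruses (superkingdom "Viruses",
#' then order/family/subfamily/genus/species).
#'
#' @return Character vector of rank names, most general first.
#' @examples
#' rank_order_cellular()
#' rank_order_viral()
#' @export
rank_order_cellular <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' @rdname rank_order_cellular
#' @export
rank_order_viral <- function() {
  c("superkingdom", "order", "family", "subfamily", "genus", "species")
}

#' Split and join semicolon-delimited lineages
#'
#' A lineage is stored as a single string such as
#' `"Bacteria;Cyanobacteria;Synechococcus"`. The empty string is the unknown
#' lineage. Labels are whitespace-normalised on parsing; truncation is only
#' allowed at the tail, so an empty label inside an assigned prefix is an
#' error.
#'
#' @param lineage Character vector of semicolon-joined lineages.
#' @return `lineage_split()`: a list of character vectors (one per lineage,
#'   `character(0)` for unknown). `lineage_join()`: a character vector.
#' @examples
#' lineage_split(c("Bacteria;Cyanobacteria", ""))
#' @export
lineage_split <- function(lineage) {
  lineage <- as.character(lineage)
  lineage[is.na(lineage)] <- ""
  out <- stringr::str_split(lineage, ";")
  out <- lapply(out, function(labs) {
    labs <- stringr::str_squish(labs)
    # drop trailing empties (truncation), then validate the prefix
    while (length(labs) > 0 && labs[length(labs)] == "") {
      labs <- labs[-length(labs)]
    }
    if (any(labs == "")) {
      abort("lineage has an empty label inside its assigned prefix")
    }
    labs
  })
  out
}

#' @rdname lineage_split
#' @param labels A list of character vectors as produced by `lineage_split()`.
#' @export
lineage_join <- function(labels) {
  vapply(labels, paste, character(1), collapse = ";")
}

#' Label of the most specific assigned rank
#'
#' A phylotype is defined operationally as the lowest taxonomic rank assigned
#' to a lineage: species where the lineage reaches species, a class label when
#' assignment stops at class, and the literal `"unknown"` when no taxonomy was
#' assigned at all.
#'
#' @param lineage Character vector of semicolon-joined lineages.
#' @param rank_order Character vector giving rank names positionally, most
#'   general first.
#' @return A tibble with one row per input: `lineage`, `label` (phylotype
#'   label), `rank` (rank name, `NA` for unknown), `depth` (number of assigned
#'   ranks).
#' @examples
#' phylotype_label(c("Eukaryota;Dinoflagellata;Noctilucales;Noctilucaceae;Noctiluca;Noctiluca scintillans", ""),
#'                 rank_order = c("superkingdom", "phylum", "order", "family", "genus", "species"))
#' @export
phylotype_label <- function(lineage, rank_order = rank_order_cellular()) {
  labs <- lineage_split(lineage)
  depth <- lengths(labs)
  if (any(depth > length(rank_order))) {
    abort("lineage is deeper than the configured rank order")
  }
  tibble::tibble(
    lineage = lineage_join(labs),
    label = ifelse(depth == 0, "unknown",
                   vapply(labs, function(l) if (length(l)) l[length(l)] else "", character(1))),
    rank = ifelse(depth == 0, NA_character_, rank_order[pmax(depth, 1L)]),
    depth = depth
  )
}

#' Project a lineage onto a fixed rank, falling back to the lowest assigned
#'
#' Projects each lineage to the label at `rank`. When the lineage is truncated
#' above that rank the most specific assigned label is returned instead and
#' flagged as a fallback — the convention used when comparing datasets "at the
#' genus level or, failing that, at the lowest level available". Unknown
#' lineages project to `"unknown"`.
#'
#' @inheritParams phylotype_label
#' @param rank A single rank name present in `rank_order`.
#' @return A tibble with `lineage`, `label`, `rank` (rank actually used),
#'   `fallback` (logical).
#' @examples
#' project_to_rank("Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Erythrobacteraceae;Erythrobacter",
#'                 "genus")
#' @export
project_to_rank <- function(lineage, rank, rank_order = rank_order_cellular()) {
  pos <- match(rank, rank_order)
  if (is.na(pos)) {
    abort(paste0("rank '", rank, "' is not in the configured rank order"))
  }
  labs <- lineage_split(lineage)
  depth <- lengths(labs)
  label <- character(length(labs))
  used <- character(length(labs))
  fallback <- logical(length(labs))
  for (i in seq_along(labs)) {
    if (depth[i] == 0) {
      label[i] <- "unknown"
      used[i] <- NA_character_
      fallback[i] <- FALSE
    } else if (depth[i] >= pos) {
      label[i] <- labs[[i]][pos]
      used[i] <- rank
      fallback[i] <- FALSE
    } else {
      label[i] <- labs[[i]][depth[i]]
      used[i] <- rank_order[depth[i]]
      fallback[i] <- TRUE
    }
  }
  tibble::tibble(lineage = lineage_join(labs), label = label,
                 rank = used, fallback = fallback)
}

#' Superkingdom of a lineage
#'
#' Returns the first (most general) label of each lineage when it is one of
#' Bacteria, Archaea, Eukaryota or Viruses, and `"unknown"` otherwise
#' (including the empty lineage).
#'
#' @inheritParams phylotype_label
#' @return Character vector.
#' @export
superkingdom_of <- function(lineage) {
  labs <- lineage_split(lineage)
  top <- vapply(labs, function(l) if (length(l)) l[1] else "unknown", character(1))
  ifelse(top %in% c("Bacteria", "Archaea", "Eukaryota", "Viruses"), top, "unknown")
}
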