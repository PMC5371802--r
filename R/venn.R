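#' Partition named sets into disjoint Venn regions
#'
#' For 2 or 3 (or more) named sets, assigns every member of the union to
#' exactly one region keyed by the subset of sets containing it. Region sizes
#' therefore sum to the union cardinality — the bookkeeping behind a Venn
#' diagram of presence-absence overlap.
#'
#' @param sets Named list of character vectors; names must be unique.
#' @return An object of class `venn_partition`: a tibble with `region` (set
#'   names joined by `"&"`), `sets` (list of the names), `members` (list),
#'   `size`; the input set names in attribute `set_names`. Only non-empty
#'   regions are listed. `tidy()` returns the tibble.
#' @examples
#' venn_partition(list(A = c("x", "y"), B = c("y", "z")))
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets))) {
    abort("sets must have unique, non-empty names")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(sets)))
  if (length(universe) == 0) {
    out <- tibble::tibble(region = character(), sets = list(),
                          members = list(), size = integer())
  } else {
    key <- apply(membership, 1, function(m) paste(names(sets)[m], collapse = "&"))
    split_members <- split(universe, key)
    out <- tibble::tibble(
      region = names(split_members),
      sets = strsplit(names(split_members), "&", fixed = TRUE),
      members = unname(split_members),
      size = unname(lengths(split_members))
    )
  }
  structure(dplyr::arrange(out, lengths(.data$sets), .data$region),
            set_names = names(sets), class = c("venn_partition", class(out)))
}

#' @export
tidy.venn_partition <- function(x, ...) {
  tibble::as_tibble(x[c("region", "size", "members")])
}

#' Shared fraction of two label sets
#'
#' Presence-absence overlap between two annotation methods or fractions:
#' `100 * |A intersect B| / |A union B|`, to two decimals — the union
#' denominator is the only one under which "common across the two methods" is
#' symmetric. Alternative denominators (`"a"`, `"b"`) are exposed since
#' published overlap figures do not always state theirs.
#'
#' @param set_a,set_b Character vectors of labels produced at a common rank.
#' @param denominator `"union"` (default), `"a"` or `"b"`.
#' @return A one-row tibble: `n_shared`, `n_a_only`, `n_b_only`,
#'   `shared_pct`.
#' @examples
#' method_overlap(c("x", "y"), c("y", "z"))  # 33.33% shared
#' @export
method_overlap <- function(set_a, set_b, denominator = c("union", "a", "b")) {
  denominator <- match.arg(denominator)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 && length(set_b) == 0) {
    abort("method_overlap() on two empty sets")
  }
  shared <- intersect(set_a, set_b)
  denom <- switch(denominator,
                  union = length(union(set_a, set_b)),
                  a = length(set_a), b = length(set_b))
  tibble::tibble(
    n_shared = length(shared),
    n_a_only = length(setdiff(set_a, set_b)),
    n_b_only = length(setdiff(set_b, set_a)),
    shared_pct = round_away(100 * length(shared) / denom, 2)
  )
}
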