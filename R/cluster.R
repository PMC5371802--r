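#' Global alignment identity between two sequences
#'
#' Optimal Needleman-Wunsch global alignment (match +1, mismatch -1, gap -1)
#' with deterministic traceback (diagonal preferred, then a gap in the second
#' sequence, then a gap in the first). Identity is the number of identical
#' aligned columns divided by the alignment length *including* gap columns —
#' a fixed, reproducible convention rather than the many identity definitions
#' aligners offer.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param alignment If `TRUE`, return the full alignment record (score,
#'   matches, columns, identity, aligned strings) instead of the identity.
#' @return The identity as a proportion in `[0, 1]`, or a list when
#'   `alignment = TRUE`.
#' @examples
#' global_identity("ACGT", "ACGA")  # 0.75
#' global_identity("ACGT", "AGT")   # 3 matches over 4 columns: 0.75
#' @export
global_identity <- function(a, b, alignment = FALSE) {
  res <- .nw_align(a, b)
  if (alignment) res else res$identity
}

#' Greedy abundance-sorted centroid clustering
#'
#' A minimal, exactly testable stand-in for 97%-identity OTU clustering so
#' that synthetic pipelines need no external tool: records are visited in
#' decreasing abundance (ties by id, lexicographically) and each joins the
#' first existing centroid, in founding order, whose [global_identity()] to it
#' reaches the threshold; otherwise it founds a new cluster. Intended for
#' synthetic data at the scale of thousands of sequences, not for production
#' OTU picking.
#'
#' @param records A tibble with columns `id`, `bases`, `abundance` (positive
#'   integer dereplicated copy count) and `replicate`.
#' @param threshold Identity threshold in `(0, 1]` (default 0.97).
#' @return A list with `clusters` — a tibble of `otu_id` (centroid id),
#'   `centroid` (bases) and `members` (list of member id vectors) — and
#'   `otu_table`, an OTU tibble keyed by centroid id with one count column per
#'   replicate (member abundances summed) and an empty `lineage`.
#' @export
greedy_cluster <- function(records, threshold = 0.97) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(records) == 0) {
    abort("greedy_cluster() requires at least one record")
  }
  if (any(records$abundance < 1)) {
    abort("abundances must be >= 1")
  }
  ord <- order(-records$abundance, records$id, method = "radix")
  records <- records[ord, ]
  centroid_id <- character(0)
  centroid_seq <- character(0)
  assignment <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    hit <- 0L
    for (k in seq_along(centroid_seq)) {
      if (global_identity(records$bases[i], centroid_seq[k]) >= threshold) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      centroid_id <- c(centroid_id, records$id[i])
      centroid_seq <- c(centroid_seq, records$bases[i])
      hit <- length(centroid_id)
    }
    assignment[i] <- hit
  }
  reps <- sort(unique(records$replicate))
  counts <- matrix(0L, nrow = length(centroid_id), ncol = length(reps),
                   dimnames = list(centroid_id, reps))
  for (i in seq_len(nrow(records))) {
    r <- match(records$replicate[i], reps)
    counts[assignment[i], r] <- counts[assignment[i], r] + as.integer(records$abundance[i])
  }
  clusters <- tibble::tibble(
    otu_id = centroid_id,
    centroid = centroid_seq,
    members = lapply(seq_along(centroid_id), function(k) records$id[assignment == k])
  )
  otu_table <- tibble::as_tibble(cbind(
    tibble::tibble(otu_id = centroid_id),
    tibble::as_tibble(counts)
  ))
  otu_table$lineage <- ""
  list(clusters = clusters, otu_table = otu_table)
}
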