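#' Stringency levels for replicate-aware filtering
#'
#' The five-level cascade used to separate genuine community members from
#' PCR/sequencing artefacts in replicated amplicon surveys:
#'
#' * **T0** — no filter: every phylotype with a nonzero count anywhere.
#' * **T1** — singletons (cells equal to exactly 1) zeroed independently in
#'   each replicate at OTU level, then re-aggregated.
#' * **T10** — at least `min_count = 10` copies of the phylotype in any one
#'   replicate.
#' * **T10-R1** — at least 10 copies in any two replicates.
#' * **T10-R2** — at least 10 copies in all replicates.
#'
#' The named levels are the triplicate-PCR defaults; the parameterised form
#' (`min_count`, `min_replicates`, `singleton_removal`) generalises to any
#' replicate count.
#'
#' @param name One of `"T0"`, `"T1"`, `"T10"`, `"T10-R1"`, `"T10-R2"`
#'   (underscores accepted), or `NULL` when giving parameters directly.
#' @param min_count Minimum copies a phylotype must reach in a replicate for
#'   that replicate to count.
#' @param min_replicates Number of replicates that must reach `min_count`.
#' @param singleton_removal Zero count-1 cells per replicate at OTU level
#'   before aggregation?
#' @param n_replicates Replicate count used to resolve `"T10-R2"` ("all
#'   replicates") in `stringency_level()` and `stringency_levels()`.
#' @return `stringency_level()`: a list of class `stringency_level`.
#'   `stringency_levels()`: a named list of the five canonical levels.
#' @examples
#' stringency_level("T10-R1")
#' stringency_levels(n_replicates = 3)
#' @export
stringency_level <- function(name = NULL, min_count = 1, min_replicates = 1,
                             singleton_removal = FALSE, n_replicates = 3) {
  if (!is.null(name)) {
    canon <- gsub("_", "-", toupper(name))
    params <- switch(canon,
      "T0" = list(1, 1, FALSE),
      "T1" = list(1, 1, TRUE),
      "T10" = list(10, 1, FALSE),
      "T10-R1" = list(10, 2, FALSE),
      "T10-R2" = list(10, n_replicates, FALSE),
      abort(paste0("unknown stringency level '", name, "'"))
    )
    min_count <- params[[1]]; min_replicates <- params[[2]]
    singleton_removal <- params[[3]]
  } else {
    canon <- sprintf("T%d-R%d%s", min_count, min_replicates,
                     if (singleton_removal) "-S" else "")
  }
  stopifnot(min_count >= 1, min_replicates >= 1)
  structure(list(name = canon, min_count = as.integer(min_count),
                 min_replicates = as.integer(min_replicates),
                 singleton_removal = isTRUE(singleton_removal)),
            class = "stringency_level")
}

#' @rdname stringency_level
#' @export
stringency_levels <- function(n_replicates = 3) {
  nm <- c("T0", "T1", "T10", "T10-R1", "T10-R2")
  setNames(lapply(nm, stringency_level, n_replicates = n_replicates), nm)
}

#' @export
print.stringency_level <- function(x, ...) {
  cat(sprintf("<stringency_level %s> min_count=%d in >=%d replicate(s)%s\n",
              x$name, x$min_count, x$min_replicates,
              if (x$singleton_removal) ", singletons removed per replicate" else ""))
  invisible(x)
}

#' Zero per-replicate singletons at OTU level
#'
#' Every cell equal to exactly 1 is set to 0, independently in each replicate
#' — a count of 1 in one replicate is indistinguishable from a PCR or
#' sequencing artefact, whereas the same OTU supported elsewhere keeps its
#' other counts. Rows left with all-zero counts are dropped. Exactly
#' (number of cells equal to 1) units of count mass are removed.
#'
#' @param tbl An OTU (or phylotype) tibble with numeric count columns.
#' @return The filtered tibble.
#' @export
remove_singletons <- function(tbl) {
  reps <- replicate_cols(tbl)
  out <- dplyr::mutate(tbl, dplyr::across(dplyr::all_of(reps),
                                          ~ ifelse(.x == 1, 0L, .x)))
  keep <- rowSums(count_matrix(out)) > 0
  out[keep, ]
}

#' Apply one stringency level to a phylotype table
#'
#' T0 keeps phylotypes with any nonzero count. T1 re-runs the aggregation on
#' the singleton-zeroed OTU table (`source_otus`), because singleton removal
#' acts *below* phylotype level — OTU counts drop under T1 even where their
#' phylotype survives. The T10 family keeps phylotypes whose per-replicate
#' counts reach `min_count` in at least `min_replicates` replicates, evaluated
#' on raw counts (equivalent on singleton-zeroed counts for thresholds >= 2,
#' and available via `after_singletons = TRUE` for the cumulative reading).
#'
#' @param ptable A phylotype tibble as from [aggregate_phylotypes()], the T0
#'   aggregation of `source_otus`.
#' @param level A [stringency_level()].
#' @param source_otus The OTU tibble `ptable` was aggregated from; required
#'   when `level` (or `after_singletons`) involves singleton removal.
#' @param rank_order Rank names used when re-aggregating.
#' @param after_singletons Evaluate count thresholds on the singleton-zeroed
#'   table instead of raw counts.
#' @return The filtered phylotype tibble.
#' @export
apply_stringency <- function(ptable, level, source_otus = NULL,
                             rank_order = rank_order_cellular(),
                             after_singletons = FALSE) {
  stopifnot(inherits(level, "stringency_level"))
  reps <- replicate_cols(ptable)
  if (level$min_replicates > length(reps)) {
    abort(sprintf("level %s needs %d replicates but the table has %d",
                  level$name, level$min_replicates, length(reps)))
  }
  tab <- ptable
  if (level$singleton_removal || after_singletons) {
    if (is.null(source_otus)) {
      abort("singleton removal requires the source OTU table")
    }
    tab <- aggregate_phylotypes(remove_singletons(source_otus), rank_order)
  }
  cnt <- count_matrix(tab)
  keep <- rowSums(cnt >= level$min_count) >= level$min_replicates &
    rowSums(cnt) > 0
  tab[keep, ]
}

retention_pct <- function(n, n0, digits = 2) {
  if (n0 == 0) return(NA_real_)
  round_away(100 * n / n0, digits)
}

#' Retention report across stringency levels
#'
#' For each filtered table: phylotype count, OTU count (distinct member OTUs),
#' read (count-mass) total, and percentages retained versus the baseline,
#' rounded to two decimals (the convention in which 834 of 1409 phylotypes is
#' reported as 59.19%).
#'
#' @param tables Named list of phylotype tibbles, one per level.
#' @param baseline Name of the baseline level (default the first), whose
#'   retention is 100% by construction.
#' @return A tibble with columns `level`, `phylotypes`, `otus`, `reads`,
#'   `pct_phylotypes`, `pct_reads`.
#' @export
retention_report <- function(tables, baseline = names(tables)[1]) {
  stopifnot(baseline %in% names(tables))
  if (nrow(tables[[baseline]]) == 0) {
    abort("baseline table is empty")
  }
  one <- function(tab) {
    tibble::tibble(
      phylotypes = nrow(tab),
      otus = if ("members" %in% names(tab)) {
        length(unique(unlist(tab$members)))
      } else NA_integer_,
      reads = sum(count_matrix(tab))
    )
  }
  out <- dplyr::bind_rows(lapply(tables, one), .id = "level")
  base <- out[out$level == baseline, ]
  out$pct_phylotypes <- vapply(out$phylotypes, retention_pct, numeric(1),
                               n0 = base$phylotypes)
  out$pct_reads <- vapply(out$reads, retention_pct, numeric(1), n0 = base$reads)
  tibble::as_tibble(out)
}

#' Mean per-replicate retention as a whole percent
#'
#' Given per-replicate phylotype counts before and after a filter, returns the
#' per-replicate percentages (two decimals) and their mean rounded half away
#' from zero to the nearest whole percent — the convention in which
#' 882->561, 1077->697, 767->505 is reported as "on average 65%".
#'
#' @param before,after Parallel numeric vectors of per-replicate counts.
#' @return A list with `per_replicate` (named numeric) and `mean_pct`.
#' @export
replicate_retention <- function(before, after) {
  stopifnot(length(before) == length(after), all(before > 0))
  pct <- round_away(100 * after / before, 2)
  list(per_replicate = pct, mean_pct = round_away(mean(100 * after / before), 0))
}

#' Phylotypes common to every stringency level
#'
#' Intersection of the phylotype identities across all supplied levels — the
#' "core" community robust to every filter choice.
#'
#' @param sets Named list (length >= 2) of character vectors of phylotype
#'   identities (labels or lineage keys).
#' @return Character vector, the intersection.
#' @export
core_across_levels <- function(sets) {
  if (length(sets) < 2) {
    abort("core_across_levels() needs at least two levels")
  }
  Reduce(intersect, sets)
}

phylotype_ids <- function(ptab) ptab$lineage

#' Run the full stringency cascade on an OTU table
#'
#' Aggregates the OTU table into phylotypes, applies every level of the
#' cascade, and assembles the retention report plus the cross-level core set.
#' The T10-family thresholds are additionally evaluated after singleton
#' removal (`report_post_t1`): the surviving *sets* are identical by the
#' nesting property, but the OTU tallies differ and both readings are
#' reported.
#'
#' @param otus An OTU tibble (`otu_id`, count columns, `lineage`).
#' @param levels Named list of [stringency_level()]s; defaults to the five
#'   canonical levels at the table's replicate count.
#' @param rank_order Rank names, most general first.
#' @return An object of class `filter_report`: list with `tables` (filtered
#'   phylotype tibbles per level), `report` (retention tibble vs T0 on raw
#'   counts), `report_post_t1` (T10-family tallies evaluated after singleton
#'   zeroing), `core` (phylotype lineage keys common to all levels), `levels`.
#'   `tidy()` returns the report, `glance()` a one-row summary, and
#'   `autoplot()` draws the retention profile.
#' @examples
#' com <- sample_community(20, seed = 1)
#' sim <- simulate_otu_tables(com, seed = 1)
#' fc <- filter_cascade(sim$otu_table)
#' tidy(fc)
#' @export
filter_cascade <- function(otus, levels = NULL, rank_order = rank_order_cellular()) {
  reps <- replicate_cols(otus)
  if (is.null(levels)) levels <- stringency_levels(n_replicates = length(reps))
  baseline <- aggregate_phylotypes(otus, rank_order)
  tables <- lapply(levels, function(lv) {
    apply_stringency(baseline, lv, source_otus = otus, rank_order = rank_order)
  })
  report <- retention_report(tables, baseline = names(tables)[1])
  post <- lapply(names(levels), function(nm) {
    lv <- levels[[nm]]
    if (lv$singleton_removal || lv$min_count < 2) return(tables[[nm]])
    apply_stringency(baseline, lv, source_otus = otus, rank_order = rank_order,
                     after_singletons = TRUE)
  })
  names(post) <- names(levels)
  report_post_t1 <- retention_report(post, baseline = names(post)[1])
  core <- core_across_levels(lapply(tables, phylotype_ids))
  structure(list(tables = tables, report = report,
                 report_post_t1 = report_post_t1,
                 core = core, levels = levels),
            class = "filter_report")
}

#' @export
tidy.filter_report <- function(x, ...) x$report

#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(
    n_levels = length(x$levels),
    phylotypes_t0 = x$report$phylotypes[1],
    phylotypes_final = x$report$phylotypes[nrow(x$report)],
    core_size = length(x$core)
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$report)
  cat(sprintf("core across all levels: %d phylotypes\n", length(x$core)))
  invisible(x)
}

#' Per-replicate stringency analysis
#'
#' Applies a level to each replicate in isolation (`min_replicates` forced to
#' 1; singleton removal uses only that replicate's counts) and partitions the
#' surviving phylotype sets into Venn regions — the replicate-concordance
#' view of a filter.
#'
#' @inheritParams filter_cascade
#' @param level A [stringency_level()].
#' @return A list with `sets` (named list of phylotype lineage keys per
#'   replicate), `counts` (tibble of per-replicate phylotype counts) and
#'   `venn` (a [venn_partition()]).
#' @export
per_replicate_analysis <- function(otus, level, rank_order = rank_order_cellular()) {
  reps <- replicate_cols(otus)
  sets <- lapply(reps, function(r) {
    sub <- otus[c("otu_id", r, "lineage")]
    lv1 <- stringency_level(min_count = level$min_count, min_replicates = 1,
                            singleton_removal = level$singleton_removal)
    ptab <- aggregate_phylotypes(sub, rank_order)
    phylotype_ids(apply_stringency(ptab, lv1, source_otus = sub, rank_order = rank_order))
  })
  names(sets) <- reps
  list(sets = sets,
       counts = tibble::tibble(replicate = reps,
                               phylotypes = lengths(sets)),
       venn = venn_partition(sets))
}
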