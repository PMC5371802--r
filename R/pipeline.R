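#' Run the whole analysis pipeline from a config
#'
#' One-call orchestration of the survey analysis: (synthetic data or on-disk
#' inputs) -> read QC -> phylotype aggregation -> stringency cascade ->
#' metagenome annotation -> annotation-method comparison -> cross-fraction
#' comparison, with Krona exports and a provenance block. Every stage reads
#' and writes the package's plain-text formats, so any stage can instead be
#' fed the output of external tools (QIIME/Swarm/BLAST) for real data.
#' Identical config and inputs give identical outputs.
#'
#' The config is a named list (or path to a JSON file) with elements:
#' * `seed` — integer, drives every stochastic stage (default 1).
#' * `simulate` — `TRUE` or a list of overrides for the synthetic stage
#'   (`n_taxa_prok`, `n_taxa_euk`, `depth`, `spurious_rate`, `n_queries`,
#'   `overlap_fraction`, `n_reads`, `p_good_base`); mutually exclusive with
#'   `inputs`.
#' * `inputs` — paths: `prok_table`, `prok_taxonomy`, `euk_table`,
#'   `euk_taxonomy`, `hits`, `taxmap`, and optionally `fastq`. All referenced
#'   paths must exist; a missing one aborts before anything is written.
#' * `qc` — list of [qc_params()] overrides, or `FALSE` to skip the stage.
#' * `filter` — list with `levels` (subset of the canonical names).
#' * `annotate` — list with `max_evalue` (default 1e-5), or `FALSE` to skip.
#' * `compare` — list with `rank` (default `"genus"`), or `FALSE` to skip.
#' * `out_dir` — optional directory for the report bundle on disk.
#'
#' @param config Named list or path to a JSON config.
#' @return An object of class `pipeline_result`: list with (depending on the
#'   stages run) `qc`, `cascades` (per fraction), `annotation`, `profile`,
#'   `method_comparison`, `fraction_reports` (per level), `krona` and
#'   `provenance` (config hash, seed, stage tallies).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  # the hash identifies the analysis, not where its outputs land
  provenance <- list(config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
                     seed = seed, stages = list())
  inputs <- config$inputs
  if (!is.null(inputs)) {
    paths <- unlist(inputs, use.names = TRUE)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(paste0("input path does not exist: ", missing[1]))
    }
  }

  fastq <- NULL; otu_tables <- list()
  hits <- NULL; taxmap <- NULL; hits2 <- NULL; taxmap2 <- NULL
  if (isTRUE(config$simulate) || is.list(config$simulate)) {
    sim <- if (is.list(config$simulate)) config$simulate else list()
    prok_com <- sample_community(sim$n_taxa_prok %||% 50, domain = "Bacteria",
                                 prefix = "prok", seed = seed)
    euk_com <- sample_community(sim$n_taxa_euk %||% 30, domain = "Eukaryota",
                                prefix = "euk", seed = seed + 1L)
    otu_tables$prokaryote <- simulate_otu_tables(
      prok_com, depth = sim$depth %||% 1e4,
      spurious_rate = sim$spurious_rate %||% 0.005, seed = seed)$otu_table
    otu_tables$eukaryote <- simulate_otu_tables(
      euk_com, depth = sim$depth %||% 1e4,
      spurious_rate = sim$spurious_rate %||% 0.005, seed = seed + 1L)$otu_table
    meta <- simulate_metagenome_hits(
      prok_com, n_queries = sim$n_queries %||% 500,
      overlap_fraction = sim$overlap_fraction %||% 0.1, seed = seed)
    hits <- meta$hits; taxmap <- meta$taxmap
    # a second, independently sampled annotation input standing in for the
    # read-level (vs contig-level) method
    meta2 <- simulate_metagenome_hits(
      prok_com, n_queries = sim$n_queries %||% 500,
      overlap_fraction = sim$overlap_fraction %||% 0.1, seed = seed + 2L)
    hits2 <- meta2$hits; taxmap2 <- meta2$taxmap
    fastq <- simulate_fastq(sim$n_reads %||% 200,
                            p_good_base = sim$p_good_base %||% 0.97,
                            seed = seed)
    provenance$stages$simulate <- list(
      prok_taxa = nrow(prok_com), euk_taxa = nrow(euk_com),
      queries = length(unique(hits$qseqid)))
  } else if (!is.null(inputs)) {
    otu_tables$prokaryote <- read_otu_table(inputs$prok_table, inputs$prok_taxonomy)
    if (!is.null(inputs$euk_table)) {
      otu_tables$eukaryote <- read_otu_table(inputs$euk_table, inputs$euk_taxonomy)
    }
    if (!is.null(inputs$hits)) {
      hits <- read_blast_tabular(inputs$hits,
                                 config$annotate$max_evalue %||% 1e-5)
      taxmap <- readr::read_tsv(inputs$taxmap,
                                col_names = c("subject_id", "lineage"),
                                col_types = "cc", show_col_types = FALSE)
    }
    if (!is.null(inputs$hits2)) {
      hits2 <- read_blast_tabular(inputs$hits2,
                                  config$annotate$max_evalue %||% 1e-5)
      taxmap2 <- readr::read_tsv(inputs$taxmap2 %||% inputs$taxmap,
                                 col_names = c("subject_id", "lineage"),
                                 col_types = "cc", show_col_types = FALSE)
    }
    if (!is.null(inputs$fastq)) fastq <- read_fastq(inputs$fastq)
  } else {
    abort("config must supply either 'simulate' or 'inputs'")
  }

  out <- list(provenance = provenance)

  if (!is.null(fastq) && !isFALSE(config$qc)) {
    reads <- if (is.data.frame(fastq)) fastq else read_fastq(fastq)
    qp <- do.call(qc_params, as.list(config$qc %||% list()))
    out$qc <- qc_reads(reads, qp)
    out$provenance$stages$qc <- as.list(glance(out$qc))
  }

  level_names <- config$filter$levels %||% c("T0", "T1", "T10", "T10-R1", "T10-R2")
  out$cascades <- lapply(otu_tables, function(tbl) {
    lv <- stringency_levels(n_replicates = length(replicate_cols(tbl)))
    filter_cascade(tbl, levels = lv[level_names])
  })
  out$provenance$stages$filter <- lapply(out$cascades, function(fc) {
    as.list(glance(fc))
  })

  if (!is.null(hits) && !isFALSE(config$annotate)) {
    gated <- hits
    if (is.null(attr(hits, "discarded"))) {
      keep <- hits$evalue < (config$annotate$max_evalue %||% 1e-5)
      gated <- hits[keep, ]
      attr(gated, "discarded") <- sum(!keep)
    }
    top <- top_hit_per_query(gated)
    out$annotation <- annotate_hits(top, taxmap,
                                    queries = unique(hits$qseqid))
    out$profile <- superkingdom_profile(out$annotation)
    out$krona <- write_krona_text(rep(1, nrow(out$annotation)),
                                  out$annotation$lineage)
    out$provenance$stages$annotate <- list(
      queries = nrow(out$annotation),
      unannotated = length(attr(out$annotation, "unannotated")),
      discarded_by_evalue = attr(gated, "discarded"))
  }

  if (!is.null(out$annotation) && !is.null(hits2) && !isFALSE(config$compare)) {
    rank <- config$compare$rank %||% "genus"
    top2 <- top_hit_per_query(hits2)
    ann2 <- annotate_hits(top2, taxmap2, queries = unique(hits2$qseqid))
    labels_at <- function(ann, how) {
      lab <- if (how == "lowest") {
        phylotype_label(ann$lineage)$label
      } else {
        project_to_rank(ann$lineage, how)$label
      }
      unique(lab[lab != "unknown"])
    }
    out$method_comparison <- dplyr::bind_cols(
      tibble::tibble(rank = c("lowest", rank)),
      dplyr::bind_rows(
        method_overlap(labels_at(out$annotation, "lowest"), labels_at(ann2, "lowest")),
        method_overlap(labels_at(out$annotation, rank), labels_at(ann2, rank))
      )
    )
    out$provenance$stages$compare_methods <- list(rank = rank)
  }

  if (!is.null(out$annotation) && !isFALSE(config$compare)) {
    rank <- config$compare$rank %||% "genus"
    out$fraction_reports <- lapply(names(out$cascades[[1]]$tables), function(nm) {
      compare_fractions(
        out$annotation,
        prok = out$cascades$prokaryote$tables[[nm]],
        euk = if (!is.null(out$cascades$eukaryote)) {
          out$cascades$eukaryote$tables[[nm]]
        } else out$cascades$prokaryote$tables[[nm]][0, ],
        level = stringency_level(nm, n_replicates = 3),
        rank = rank
      )
    })
    names(out$fraction_reports) <- names(out$cascades[[1]]$tables)
    out$provenance$stages$compare_fractions <- list(
      levels = names(out$fraction_reports), rank = rank)
  }

  if (!is.null(config$out_dir)) {
    write_pipeline_bundle(out, config$out_dir)
  }
  class(out) <- "pipeline_result"
  out
}

write_pipeline_bundle <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out$cascades)) {
    readr::write_tsv(out$cascades[[nm]]$report,
                     file.path(dir, paste0("retention_", nm, ".tsv")))
  }
  if (!is.null(out$profile)) {
    readr::write_tsv(out$profile, file.path(dir, "superkingdom_profile.tsv"))
  }
  if (!is.null(out$krona)) {
    writeLines(out$krona, file.path(dir, "annotation.krona.txt"))
  }
  if (!is.null(out$fraction_reports)) {
    fr <- dplyr::bind_rows(lapply(out$fraction_reports, tidy), .id = "level")
    readr::write_tsv(fr, file.path(dir, "fraction_overlap.tsv"))
  }
  jsonlite::write_json(out$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(" stages run:", paste(names(x$provenance$stages), collapse = ", "), "\n")
  for (nm in names(x$cascades)) {
    cat(" --", nm, "cascade --\n")
    print(x$cascades[[nm]]$report)
  }
  invisible(x)
}
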