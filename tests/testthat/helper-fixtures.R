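# Fixtures are built in code: small OTU tables with a shared lineage pool so
# that aggregation actually merges rows, plus random-table generators used by
# the property suites.

`%||%` <- function(x, y) if (is.null(x)) y else x

lineage_pool <- function() {
  c(
    "Bacteria;Cyanobacteria;Synechococcales;Synechococcaceae;Synechococcus;Synechococcus sp1",
    "Bacteria;Cyanobacteria;Synechococcales;Synechococcaceae;Synechococcus;Synechococcus sp2",
    "Bacteria;Cyanobacteria;Prochlorales;Prochloraceae;Prochlorococcus",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Erythrobacteraceae;Erythrobacter",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales",
    "Eukaryota;Alveolata;Dinophyceae;Noctilucales;Noctilucaceae;Noctiluca;Noctiluca scintillans",
    "Eukaryota;Alveolata;Syndiniales",
    ""
  )
}

make_otu_tbl <- function(counts, lineage = NULL, otu_id = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  colnames(counts) <- paste0("rep", seq_len(ncol(counts)))
  tibble::tibble(
    otu_id = otu_id %||% sprintf("otu%03d", seq_len(n)),
    !!!tibble::as_tibble(counts),
    lineage = lineage %||% rep_len(lineage_pool()[1], n)
  )
}

random_otu_tbl <- function(n_otus, n_reps = 3, max_count = 30, seed = 1,
                           pool = lineage_pool()) {
  withr::with_seed(seed, {
    counts <- matrix(sample(0:max_count, n_otus * n_reps, replace = TRUE,
                            prob = c(5, 5, rep(1, max_count - 1))),
                     nrow = n_otus)
    make_otu_tbl(counts, lineage = sample(pool, n_otus, replace = TRUE))
  })
}

random_read <- function(len, seed = NULL) {
  bases <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  tibble::tibble(id = paste0("r", sample.int(1e6, 1)),
                 bases = bases,
                 quals = list(sample(0:41, len, replace = TRUE)))
}

# independent rule-by-rule evaluation of the stringency cascade, written as a
# literal set comprehension over phylotype rows (the oracle the fast path is
# checked against)
brute_force_stringency <- function(otus, level_name, rank_order = rank_order_cellular()) {
  reps <- replicate_cols(otus)
  tab <- otus
  if (level_name == "T1") {
    for (r in reps) tab[[r]][tab[[r]] == 1] <- 0L
  }
  ptab <- aggregate_phylotypes(tab, rank_order)
  keep <- logical(nrow(ptab))
  for (i in seq_len(nrow(ptab))) {
    cnt <- as.numeric(ptab[i, reps])
    keep[i] <- switch(level_name,
      "T0" = any(cnt > 0),
      "T1" = any(cnt > 0),
      "T10" = sum(cnt >= 10) >= 1,
      "T10-R1" = sum(cnt >= 10) >= 2,
      "T10-R2" = sum(cnt >= 10) >= length(reps)
    )
  }
  sort(ptab$lineage[keep])
}
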