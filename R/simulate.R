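#' Sample a synthetic true community
#'
#' Draws a mock community with lognormal relative abundances — the standard
#' species-abundance assumption for microbial surveys — over a synthetic,
#' internally consistent taxonomy (each label implies a unique parent path).
#' A configurable fraction of lineages is truncated before species, mimicking
#' incomplete reference assignment.
#'
#' Abundances are floored at `min_abundance` (and renormalised): a mock
#' community built for *exact* recovery contracts must sit above the survey's
#' effective detection floor, since a taxon expected at fewer than a couple of
#' copies per replicate is statistically indistinguishable from a singleton
#' artefact. Set `min_abundance = 0` for an untruncated lognormal.
#'
#' @param n_taxa Number of taxa.
#' @param meanlog,sdlog Lognormal abundance parameters (defaults 0, 1).
#' @param min_abundance Lower truncation for relative abundances (default
#'   1e-3, i.e. an expected 10 copies per 1e4-read replicate).
#' @param domain Top label of every lineage (e.g. `"Bacteria"`,
#'   `"Eukaryota"`).
#' @param truncation_probs Probability that a lineage ends at each rank of
#'   [rank_order_cellular()] (length 7, sums to 1); the default leaves 80% of
#'   lineages assigned to species.
#' @param prefix Label prefix separating e.g. prokaryote from eukaryote
#'   namespaces.
#' @param seed Integer seed; the draw is bit-reproducible.
#' @return A tibble `taxon_id`, `lineage`, `abundance` (sums to 1), with a
#'   `provenance` attribute recording the spec and seed.
#' @examples
#' sample_community(5, seed = 42)
#' @export
sample_community <- function(n_taxa, meanlog = 0, sdlog = 1,
                             min_abundance = 1e-3,
                             domain = "Bacteria",
                             truncation_probs = c(0, 0, 0.02, 0.03, 0.05, 0.10, 0.80),
                             prefix = "tax", seed = 1) {
  stopifnot(n_taxa >= 0, length(truncation_probs) == length(rank_order_cellular()),
            abs(sum(truncation_probs) - 1) < 1e-8,
            min_abundance >= 0, min_abundance * n_taxa < 1)
  if (n_taxa == 0) {
    out <- tibble::tibble(taxon_id = character(), lineage = character(),
                          abundance = numeric())
    attr(out, "provenance") <- list(n_taxa = 0, seed = seed)
    return(out)
  }
  withr::with_seed(as.integer(seed), {
    x <- rlnorm(n_taxa, meanlog, sdlog)
    x <- floor_abundances(x / sum(x), min_abundance)
    # hierarchical indices: a child label embeds its parent's, so equal labels
    # always sit on equal paths
    n_phy <- max(2L, min(6L, n_taxa))
    phy <- sample.int(n_phy, n_taxa, replace = TRUE)
    cla <- paste0(phy, ".", sample.int(2, n_taxa, replace = TRUE))
    ord <- paste0(cla, ".", sample.int(2, n_taxa, replace = TRUE))
    fam <- paste0(ord, ".", sample.int(2, n_taxa, replace = TRUE))
    gen <- paste0(fam, ".", sample.int(3, n_taxa, replace = TRUE))
    depth <- sample.int(length(truncation_probs), n_taxa, replace = TRUE,
                        prob = truncation_probs)
    lineage <- vapply(seq_len(n_taxa), function(i) {
      labs <- c(domain,
                sprintf("%s_phy%s", prefix, phy[i]),
                sprintf("%s_cla%s", prefix, cla[i]),
                sprintf("%s_ord%s", prefix, ord[i]),
                sprintf("%s_fam%s", prefix, fam[i]),
                sprintf("%s_gen%s", prefix, gen[i]),
                sprintf("%s_sp%04d", prefix, i))
      paste(labs[seq_len(depth[i])], collapse = ";")
    }, character(1))
    out <- tibble::tibble(
      taxon_id = sprintf("%s_%04d", prefix, seq_len(n_taxa)),
      lineage = lineage,
      abundance = x / sum(x)
    )
  })
  attr(out, "provenance") <- list(n_taxa = n_taxa, meanlog = meanlog,
                                  sdlog = sdlog, domain = domain,
                                  truncation_probs = truncation_probs,
                                  prefix = prefix, seed = as.integer(seed))
  out
}

#' Default terrestrial contaminant spikes
#'
#' Lineages of land plants that have no business in seawater — the classic
#' signature of lab or reagent contamination — spiked at count 1 so that
#' per-replicate singleton removal eliminates them.
#'
#' @return A tibble `lineage`, `count`.
#' @export
default_contaminants <- function() {
  tibble::tibble(
    lineage = c(
      "Eukaryota;Streptophyta;Magnoliopsida;Fabales;Fabaceae;Cicer;Cicer arietinum",
      "Eukaryota;Streptophyta;Magnoliopsida;Lamiales;Pedaliaceae;Sesamum;Sesamum indicum",
      "Eukaryota;Streptophyta;Magnoliopsida;Solanales;Solanaceae;Nicotiana;Nicotiana sylvestris"
    ),
    count = c(1L, 1L, 1L)
  )
}

#' Simulate replicated OTU count tables with artefacts and contaminants
#'
#' Emulates triplicate-PCR amplicon sequencing of a known community: per
#' replicate, counts are drawn multinomially at the given depth over the true
#' taxa; spurious OTUs (PCR/sequencing artefacts) are appended with count 1 in
#' exactly one replicate and a perturbed, unique lineage; contaminants are
#' appended with their spike counts in one random replicate. The ground-truth
#' record says which OTU is which, making the singleton filter's contract
#' exactly testable.
#'
#' @param community A [sample_community()] tibble.
#' @param n_replicates Number of PCR replicates (default 3).
#' @param depth Reads per replicate (default 1e4).
#' @param spurious_rate Expected artefact OTUs per true read (default 0.005,
#'   i.e. ~50 artefact OTUs per 1e4-read replicate).
#' @param contaminants Tibble `lineage`, `count` of contaminant spikes;
#'   [default_contaminants()] spikes three land plants at count 1.
#' @param messy If `TRUE`, artefact counts are geometric (>= 1) instead of
#'   exactly 1; recovery by the singleton filter is then only statistical.
#' @param seed Integer seed.
#' @return A list with `otu_table` (tibble `otu_id`, `rep1..repR`, `lineage`),
#'   `truth` (tibble `otu_id`, `lineage`, `origin` in
#'   {true, artefact, contaminant}) and `provenance`.
#' @export
simulate_otu_tables <- function(community, n_replicates = 3, depth = 1e4,
                                spurious_rate = 0.005,
                                contaminants = default_contaminants(),
                                messy = FALSE, seed = 1) {
  stopifnot(n_replicates >= 1, depth >= 0, spurious_rate >= 0)
  if (depth == 0 && spurious_rate > 0) {
    abort("depth 0 with a nonzero spurious rate: no read mass to scale artefacts")
  }
  reps <- paste0("rep", seq_len(n_replicates))
  withr::with_seed(as.integer(seed), {
    if (nrow(community) > 0 && depth > 0) {
      cnt <- rmultinom(n_replicates, depth, community$abundance)
    } else {
      cnt <- matrix(0L, nrow = nrow(community), ncol = n_replicates)
    }
    colnames(cnt) <- reps
    true_tbl <- dplyr::bind_cols(
      tibble::tibble(otu_id = paste0("otu_", community$taxon_id)),
      tibble::as_tibble(cnt),
      tibble::tibble(lineage = community$lineage)
    )
    n_art <- if (spurious_rate > 0) {
      stats::rpois(1, spurious_rate * depth * n_replicates)
    } else 0L
    art_tbl <- NULL
    if (n_art > 0) {
      src <- sample.int(max(nrow(community), 1), n_art, replace = TRUE)
      art_lineage <- vapply(seq_len(n_art), function(k) {
        base <- if (nrow(community)) lineage_split(community$lineage[src[k]])[[1]] else "Bacteria"
        keep <- sample.int(length(base), 1)  # truncate at a random rank ...
        paste(c(base[seq_len(keep)][-length(base[seq_len(keep)])],
                sprintf("art%04d_%s", k, base[keep])), collapse = ";")
      }, character(1))  # ... and perturb the last kept label to a novel one
      art_rep <- sample.int(n_replicates, n_art, replace = TRUE)
      art_cnt <- matrix(0L, nrow = n_art, ncol = n_replicates,
                        dimnames = list(NULL, reps))
      art_val <- if (messy) stats::rgeom(n_art, 0.6) + 1L else rep(1L, n_art)
      art_cnt[cbind(seq_len(n_art), art_rep)] <- art_val
      art_tbl <- dplyr::bind_cols(
        tibble::tibble(otu_id = sprintf("art_%04d", seq_len(n_art))),
        tibble::as_tibble(art_cnt),
        tibble::tibble(lineage = art_lineage)
      )
    }
    con_tbl <- NULL
    if (!is.null(contaminants) && nrow(contaminants) > 0) {
      con_rep <- sample.int(n_replicates, nrow(contaminants), replace = TRUE)
      con_cnt <- matrix(0L, nrow = nrow(contaminants), ncol = n_replicates,
                        dimnames = list(NULL, reps))
      con_cnt[cbind(seq_len(nrow(contaminants)), con_rep)] <- as.integer(contaminants$count)
      con_tbl <- dplyr::bind_cols(
        tibble::tibble(otu_id = sprintf("cont_%02d", seq_len(nrow(contaminants)))),
        tibble::as_tibble(con_cnt),
        tibble::tibble(lineage = contaminants$lineage)
      )
    }
  })
  otu_table <- dplyr::bind_rows(true_tbl, art_tbl, con_tbl)
  truth <- tibble::tibble(
    otu_id = otu_table$otu_id,
    lineage = otu_table$lineage,
    origin = c(rep("true", nrow(true_tbl)),
               rep("artefact", if (is.null(art_tbl)) 0 else nrow(art_tbl)),
               rep("contaminant", if (is.null(con_tbl)) 0 else nrow(con_tbl)))
  )
  list(otu_table = otu_table, truth = truth,
       provenance = list(n_replicates = n_replicates, depth = depth,
                         spurious_rate = spurious_rate, messy = messy,
                         seed = as.integer(seed)))
}

# water-filling truncation: members below the floor are pinned to it and the
# rest renormalised, repeated until stable
floor_abundances <- function(a, floor_val) {
  if (floor_val <= 0) return(a / sum(a))
  repeat {
    low <- a <= floor_val
    if (all(low)) return(rep(1 / length(a), length(a)))
    b <- a
    b[low] <- floor_val
    b[!low] <- a[!low] * (1 - floor_val * sum(low)) / sum(a[!low])
    if (all(b[!low] >= floor_val - 1e-15)) return(b / sum(b))
    a <- b
  }
}

viral_lineage_pool <- function() {
  c(
    "Viruses;Caudovirales;Myoviridae;Myo_subfam1;Cyanophage_gen1;Cyanophage_sp1",
    "Viruses;Caudovirales;Myoviridae;Myo_subfam1;Cyanophage_gen1;Cyanophage_sp2",
    "Viruses;Caudovirales;Siphoviridae;Sipho_subfam1;Sipho_gen1;Sipho_sp1",
    "Viruses;Caudovirales;Podoviridae;Podo_subfam1;Podo_gen1;Podo_sp1",
    "Viruses;Megavirales;Phycodnaviridae;Phycodna_subfam1;Phycodna_gen1;Phycodna_sp1",
    "Viruses;Megavirales;Mimiviridae;Mimi_subfam1;Mimi_gen1;Mimi_sp1"
  )
}

#' Simulate metagenome BLAST hits and their taxonomy map
#'
#' Emulates the annotation input for the small size fraction: `n_queries`
#' queries, each with 1-5 gated hits whose top hit maps, through the emitted
#' taxonomy map, to a lineage drawn from a category mixture over
#' {Bacteria, Archaea, Eukaryota, Viruses, unknown}. A configurable fraction
#' of the cellular lineages reuses genera of the supplied amplicon community
#' (`overlap_fraction`), so the expected cross-fraction overlap is known by
#' construction. "unknown" queries hit subjects deliberately missing from the
#' map. The default mixture matches a contig-level marine profile dominated by
#' Bacteria with ~11% unknown.
#'
#' @param community Amplicon community ([sample_community()]), source of
#'   shareable genera.
#' @param n_queries Number of queries (default 500).
#' @param mixture Named probabilities over the five categories (sums to 1).
#' @param overlap_fraction Probability that a cellular query whose category
#'   matches the community's domain draws its genus from the community.
#' @param seed Integer seed.
#' @return A list with `hits` (12-column BLAST tibble), `taxmap` (tibble
#'   `subject_id`, `lineage`), `truth` (tibble `query_id`, `category`,
#'   `lineage`) and `provenance`.
#' @export
simulate_metagenome_hits <- function(community, n_queries = 500,
                                     mixture = c(Bacteria = 0.8685, unknown = 0.1103,
                                                 Eukaryota = 0.0135, Viruses = 0.0075,
                                                 Archaea = 0.0002),
                                     overlap_fraction = 0.1, seed = 1) {
  stopifnot(abs(sum(mixture) - 1) < 1e-6,
            overlap_fraction >= 0, overlap_fraction <= 1)
  com_genus <- character(0)
  com_domain <- character(0)
  if (nrow(community) > 0) {
    pr <- project_to_rank(community$lineage, "genus")
    ok <- !pr$fallback & pr$label != "unknown"
    com_genus <- unique(community$lineage[ok])
    com_genus <- vapply(lineage_split(com_genus),
                        function(l) paste(l[1:6], collapse = ";"), character(1))
    com_genus <- unique(com_genus)
    com_domain <- unique(superkingdom_of(community$lineage))
  }
  withr::with_seed(as.integer(seed), {
    category <- sample(names(mixture), n_queries, replace = TRUE, prob = mixture)
    lineage <- vapply(seq_len(n_queries), function(i) {
      cat_i <- category[i]
      if (cat_i == "unknown") return("")
      if (cat_i == "Viruses") return(sample(viral_lineage_pool(), 1))
      if (cat_i %in% com_domain && length(com_genus) > 0 &&
          runif(1) < overlap_fraction) {
        return(sample(com_genus, 1))
      }
      paste(c(cat_i, sprintf("meta_%s_%s%d", tolower(substr(cat_i, 1, 3)),
                             c("phy", "cla", "ord", "fam", "gen"), i)),
            collapse = ";")
    }, character(1))
    subject <- sprintf("subj_%05d", seq_len(n_queries))
    taxmap <- tibble::tibble(subject_id = subject[category != "unknown"],
                             lineage = lineage[category != "unknown"])
    hits <- dplyr::bind_rows(lapply(seq_len(n_queries), function(i) {
      k <- sample.int(5, 1)
      bits <- sort(runif(k, 50, 500), decreasing = TRUE)
      tibble::tibble(
        qseqid = sprintf("query_%05d", i),
        sseqid = c(subject[i],
                   if (k > 1) sprintf("decoy_%05d_%d", i, seq_len(k - 1)) else character(0)),
        pident = round(runif(k, 70, 100), 2),
        length = sample(30:100, k, replace = TRUE),
        mismatch = sample(0:10, k, replace = TRUE),
        gapopen = sample(0:2, k, replace = TRUE),
        qstart = 1, qend = 100,
        sstart = 1, send = 100,
        evalue = 10^(-runif(k, 6, 50)),
        bitscore = bits
      )
    }))
    truth <- tibble::tibble(query_id = sprintf("query_%05d", seq_len(n_queries)),
                            category = category, lineage = lineage)
  })
  list(hits = hits, taxmap = taxmap, truth = truth,
       provenance = list(n_queries = n_queries, mixture = mixture,
                         overlap_fraction = overlap_fraction,
                         seed = as.integer(seed)))
}

#' Simulate FASTQ reads with i.i.d. per-base quality
#'
#' Each base is called "good" (Phred 20-40) with probability `p_good_base`
#' and "bad" (Phred 2-19) otherwise, so the fraction of reads surviving the
#' fraction-at-Q20 rule has a closed-form binomial-tail expectation.
#'
#' @param n_reads Number of reads.
#' @param length Read length in bases (default 100).
#' @param p_good_base Probability a base is called at Q >= 20.
#' @param seed Integer seed.
#' @return FASTQ text as a character vector of lines (4 per read), parseable
#'   by [read_fastq()].
#' @export
simulate_fastq <- function(n_reads, length = 100, p_good_base = 0.97, seed = 1) {
  stopifnot(p_good_base >= 0, p_good_base <= 1, length >= 1)
  withr::with_seed(as.integer(seed), {
    lines <- character(4 * n_reads)
    for (i in seq_len(n_reads)) {
      bases <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                     collapse = "")
      good <- runif(length) < p_good_base
      q <- ifelse(good, sample(20:40, length, replace = TRUE),
                  sample(2:19, length, replace = TRUE))
      lines[4 * i - 3] <- sprintf("@sim_%06d", i)
      lines[4 * i - 2] <- bases
      lines[4 * i - 1] <- "+"
      lines[4 * i] <- intToUtf8(q + 33L)
    }
    lines
  })
}
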