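hit_row <- function(q, s, evalue = 1e-20, bitscore = 100) {
  tibble::tibble(qseqid = q, sseqid = s, pident = 99, length = 50,
                 mismatch = 0, gapopen = 0, qstart = 1, qend = 50,
                 sstart = 1, send = 50, evalue = evalue, bitscore = bitscore)
}

test_that("top-hit selection maximises bit-score with documented tie-breaks", {
  hits <- dplyr::bind_rows(
    hit_row("q1", "sA", bitscore = 100),
    hit_row("q1", "sB", bitscore = 90),
    hit_row("q2", "sC", evalue = 1e-20, bitscore = 80),
    hit_row("q2", "sD", evalue = 1e-30, bitscore = 80),  # tie: smaller e-value
    hit_row("q3", "sE", evalue = 1e-10, bitscore = 70),
    hit_row("q3", "sF", evalue = 1e-10, bitscore = 70),  # full tie: input order
    hit_row("q4", "sG")
  )
  top <- top_hit_per_query(hits)
  expect_equal(top$sseqid[top$qseqid == "q1"], "sA")
  expect_equal(top$sseqid[top$qseqid == "q2"], "sD")
  expect_equal(top$sseqid[top$qseqid == "q3"], "sE")
  expect_equal(top$sseqid[top$qseqid == "q4"], "sG")
})

test_that("top-hit selection is invariant to shuffling when scores are tie-free", {
  withr::with_seed(51, {
    hits <- dplyr::bind_rows(lapply(1:20, function(i) {
      dplyr::bind_rows(lapply(1:4, function(j) {
        hit_row(paste0("q", i), sprintf("s%d_%d", i, j),
                bitscore = sample.int(1000, 1))
      }))
    }))
    hits <- dplyr::distinct(hits, bitscore, .keep_all = TRUE)
    shuffled <- hits[sample.int(nrow(hits)), ]
  })
  a <- top_hit_per_query(hits)
  b <- top_hit_per_query(shuffled)
  b <- b[match(a$qseqid, b$qseqid), ]
  expect_equal(a$sseqid, b$sseqid)
})

test_that("annotation assigns lineages, flags unmapped subjects, lists no-hit queries", {
  top <- dplyr::bind_rows(hit_row("q1", "sA"), hit_row("q2", "sB"),
                          hit_row("q3", "sC"), hit_row("q4", "sZ"))
  taxmap <- tibble::tibble(
    subject_id = c("sA", "sB", "sC"),
    lineage = c("Bacteria;Cyanobacteria", "Bacteria;Proteobacteria", "Eukaryota;Alveolata")
  )
  ann <- annotate_hits(top, taxmap, queries = paste0("q", 1:5))
  expect_equal(ann$lineage[ann$query_id == "q1"], "Bacteria;Cyanobacteria")
  expect_equal(ann$lineage[ann$query_id == "q4"], "")
  expect_false(ann$mapped[ann$query_id == "q4"])
  expect_equal(attr(ann, "unannotated"), "q5")

  prof <- superkingdom_profile(ann)
  expect_equal(prof$pct[prof$superkingdom == "Bacteria"], 50)
  expect_equal(prof$pct[prof$superkingdom == "unknown"], 25)

  expect_error(annotate_hits(top, dplyr::bind_rows(taxmap, taxmap[1, ])),
               "two lineages")
})

test_that("superkingdom percentages sum to 100 within rounding", {
  prof3 <- superkingdom_profile(tibble::tibble(
    lineage = c("Bacteria;A", "Bacteria;B", "Bacteria;C", "")))
  expect_equal(prof3$pct, c(75, 25))
  one <- superkingdom_profile(tibble::tibble(lineage = rep("Viruses;X", 5)))
  expect_equal(one$pct, 100)
  expect_equal(nrow(superkingdom_profile(tibble::tibble(lineage = character()))), 0)

  for (seed in 1:10) {
    withr::with_seed(seed, {
      lin <- sample(c("Bacteria;A", "Archaea;B", "Eukaryota;C", "Viruses;D", ""),
                    sample(3:200, 1), replace = TRUE)
    })
    expect_lte(abs(sum(superkingdom_profile(tibble::tibble(lineage = lin))$pct) - 100),
               0.05)
  }
})

test_that("subsampling is deterministic, saturating and uniform", {
  items <- letters[1:10]
  expect_equal(subsample(items, 20, seed = 1), structure(items, seed = 1L))
  expect_equal(subsample(items, 4, seed = 9), subsample(items, 4, seed = 9))

  freq <- c(a = 0, b = 0, c = 0)
  for (s in 1:10000) {
    pick <- subsample(c("a", "b", "c"), 1, seed = s)
    freq[pick] <- freq[pick] + 1
  }
  expect_true(all(abs(freq / 10000 - 1 / 3) < 0.02))
})

test_that("method overlap uses the union denominator", {
  ov <- method_overlap(c("x", "y"), c("y", "z"))
  expect_equal(ov$shared_pct, 33.33)
  expect_equal(ov[c("n_shared", "n_a_only", "n_b_only")],
               tibble::tibble(n_shared = 1L, n_a_only = 1L, n_b_only = 1L))
  expect_equal(method_overlap(c("x", "y"), c("y", "x"))$shared_pct, 100)
  expect_equal(method_overlap("x", "y")$shared_pct, 0)
  expect_error(method_overlap(character(0), character(0)), "empty")
  expect_equal(method_overlap(c("x", "y"), "y", denominator = "a")$shared_pct, 50)
})

test_that("coarsening the rank never decreases the shared percentage", {
  # two annotation sets over lineages whose genus projection is total
  withr::with_seed(52, {
    pool <- sprintf("Bacteria;P%d;C%d;O%d;F%d;G%d;S%d",
                    rep(1:4, each = 10), rep(1:4, each = 10),
                    rep(1:4, each = 10), rep(1:4, each = 10),
                    rep(1:8, 5), 1:40)
    for (k in 1:5) {
      a <- sample(pool, 25); b <- sample(pool, 25)
      sp_a <- phylotype_label(a)$label; sp_b <- phylotype_label(b)$label
      ge_a <- project_to_rank(a, "genus")$label
      ge_b <- project_to_rank(b, "genus")$label
      expect_gte(method_overlap(ge_a, ge_b)$shared_pct,
                 method_overlap(sp_a, sp_b)$shared_pct)
    }
  })
})
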