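# exhaustive enumeration of all global alignments of two short sequences:
# returns the optimal score and every identity achievable at that score
enumerate_alignments <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf; best$identities <- numeric(0)
  recurse <- function(i, j, score, matches, cols) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score) {
        best$score <- score
        best$identities <- matches / cols
      } else if (score == best$score) {
        best$identities <- unique(c(best$identities, matches / cols))
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) 1 else -1
      recurse(i + 1, j + 1, score + s, matches + (a[i] == b[j]), cols + 1)
    }
    if (i <= length(a)) recurse(i + 1, j, score - 1, matches, cols + 1)
    if (j <= length(b)) recurse(i, j + 1, score - 1, matches, cols + 1)
  }
  recurse(1, 1, 0, 0, 0)
  list(score = best$score, identities = best$identities)
}

test_that("global identity matches hand-checked and enumerated alignments", {
  expect_equal(global_identity("ACGT", "ACGT"), 1.0)
  expect_equal(global_identity("ACGT", "ACGA"), 0.75)
  expect_equal(global_identity("ACGT", "AGT"), 0.75)  # one gap column, 3 matches / 4
  expect_error(global_identity("", "ACGT"), "non-empty")

  withr::with_seed(31, {
    for (k in 1:12) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE), collapse = "")
      oracle <- enumerate_alignments(a, b)
      aln <- global_identity(a, b, alignment = TRUE)
      expect_equal(aln$score, oracle$score)
      expect_true(aln$identity %in% oracle$identities)
    }
  })
})

test_that("alignment score agrees with an independent aligner", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  withr::with_seed(32, {
    for (k in 1:8) {
      a <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(30:50, 1), replace = TRUE), collapse = "")
      ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 0, gapExtension = 1)
      expect_equal(global_identity(a, b, alignment = TRUE)$score,
                   Biostrings::score(ref))
    }
  })
})

mutate_bases <- function(bases, n_mut, seed) {
  withr::with_seed(seed, {
    v <- strsplit(bases, "")[[1]]
    pos <- sample(seq_along(v), n_mut)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  })
}

test_that("greedy clustering merges by identity threshold", {
  base <- withr::with_seed(33, paste(sample(c("A", "C", "G", "T"), 100,
                                            replace = TRUE), collapse = ""))
  rec1 <- tibble::tibble(id = "s1", bases = base, abundance = 10L, replicate = "rep1")

  single <- greedy_cluster(rec1)
  expect_equal(nrow(single$clusters), 1)
  expect_equal(single$clusters$members[[1]], "s1")

  near <- dplyr::bind_rows(rec1, tibble::tibble(
    id = "s2", bases = mutate_bases(base, 1, 34), abundance = 3L, replicate = "rep2"))
  expect_equal(nrow(greedy_cluster(near, 0.97)$clusters), 1)

  far <- dplyr::bind_rows(rec1, tibble::tibble(
    id = "s3", bases = mutate_bases(base, 10, 35), abundance = 3L, replicate = "rep2"))
  expect_equal(nrow(greedy_cluster(far, 0.97)$clusters), 2)
})

count_matrix_of <- function(tbl) as.matrix(tbl[replicate_cols(tbl)])

test_that("cluster counts respect the threshold ordering and conserve mass", {
  withr::with_seed(36, {
    base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    records <- dplyr::bind_rows(lapply(1:12, function(i) {
      tibble::tibble(id = sprintf("s%02d", i),
                     bases = mutate_bases(base, sample(0:12, 1), 100 + i),
                     abundance = sample(1:20, 1),
                     replicate = sample(paste0("rep", 1:3), 1))
    }))
  })
  res_lo <- greedy_cluster(records, 0.80)
  res_hi <- greedy_cluster(records, 0.97)
  expect_lte(nrow(res_lo$clusters), nrow(res_hi$clusters))
  for (res in list(res_lo, res_hi)) {
    expect_equal(sum(count_matrix_of(res$otu_table)), sum(records$abundance))
  }
})

test_that("greedy assignment verifies against a brute-force re-check", {
  # <= 6 short sequences: every member meets the threshold to its centroid and
  # each record was compared against centroids in founding order
  withr::with_seed(37, {
    for (case in 1:6) {
      base <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
      n <- sample(3:6, 1)
      records <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        tibble::tibble(id = sprintf("q%02d", i),
                       bases = mutate_bases(base, sample(0:8, 1), 200 * case + i),
                       abundance = sample(1:9, 1),
                       replicate = "rep1")
      }))
      threshold <- 0.9
      res <- greedy_cluster(records, threshold)

      ord <- order(-records$abundance, records$id)
      visited <- records[ord, ]
      centroids <- character(0)
      for (i in seq_len(nrow(visited))) {
        ids <- vapply(centroids, function(cb) global_identity(visited$bases[i], cb),
                      numeric(1))
        expected_centroid <- if (any(ids >= threshold)) {
          centroids[which(ids >= threshold)[1]]
        } else {
          centroids <- c(centroids, visited$bases[i])
          visited$bases[i]
        }
        got <- res$clusters$centroid[vapply(res$clusters$members,
                                            function(m) visited$id[i] %in% m,
                                            logical(1))]
        expect_equal(got, expected_centroid)
        expect_gte(global_identity(visited$bases[i], got), threshold)
      }
    }
  })
})
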