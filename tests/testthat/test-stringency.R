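test_that("named levels carry the canonical parameters", {
  lv <- stringency_levels(n_replicates = 3)
  expect_equal(lv[["T0"]][c("min_count", "min_replicates", "singleton_removal")],
               list(min_count = 1L, min_replicates = 1L, singleton_removal = FALSE))
  expect_equal(lv[["T1"]]$singleton_removal, TRUE)
  expect_equal(lv[["T10"]]$min_count, 10L)
  expect_equal(lv[["T10-R1"]]$min_replicates, 2L)
  expect_equal(lv[["T10-R2"]]$min_replicates, 3L)
  expect_equal(stringency_level("T10_R2", n_replicates = 5)$min_replicates, 5L)
})

test_that("singleton removal zeroes count-1 cells per replicate", {
  tbl <- make_otu_tbl(rbind(c(1, 1, 1), c(5, 1, 0), c(0, 3, 2)),
                      lineage = c("Bacteria;A", "Bacteria;B", "Bacteria;C"))
  out <- remove_singletons(tbl)
  expect_equal(out$otu_id, c("otu002", "otu003"))             # (1,1,1) dropped
  expect_equal(unname(unlist(out[1, c("rep1", "rep2", "rep3")])), c(5L, 0L, 0L))

  empty <- tbl[0, ]
  expect_equal(nrow(remove_singletons(empty)), 0)
})

test_that("singleton removal removes exactly the count-1 mass", {
  for (seed in 1:10) {
    tbl <- random_otu_tbl(30, max_count = 4, seed = seed)
    cnt <- as.matrix(tbl[replicate_cols(tbl)])
    out <- remove_singletons(tbl)
    expect_equal(sum(cnt) - sum(as.matrix(out[replicate_cols(out)])),
                 sum(cnt == 1))
  }
})

test_that("threshold rules keep and drop phylotypes as enumerated", {
  tbl <- make_otu_tbl(rbind(c(10, 0, 0), c(10, 12, 9), c(1, 1, 1)),
                      lineage = c("Bacteria;A", "Bacteria;B", "Bacteria;C"))
  ptab <- aggregate_phylotypes(tbl)
  kept <- function(level) {
    apply_stringency(ptab, stringency_level(level), source_otus = tbl)$phylotype
  }
  expect_setequal(kept("T0"), c("A", "B", "C"))
  expect_setequal(kept("T1"), c("A", "B"))
  expect_setequal(kept("T10"), c("A", "B"))
  expect_setequal(kept("T10-R1"), "B")
  expect_equal(kept("T10-R2"), character(0))

  expect_error(
    apply_stringency(ptab, stringency_level(min_count = 1, min_replicates = 4)),
    "4 replicates"
  )
})

test_that("retention reporting rounds to two decimals and flags empty baselines", {
  tbl <- random_otu_tbl(20, seed = 3)
  ptab <- aggregate_phylotypes(tbl)
  rep_identical <- retention_report(list(T0 = ptab, again = ptab))
  expect_equal(rep_identical$pct_phylotypes, c(100, 100))
  expect_equal(rep_identical$pct_reads, c(100, 100))
  expect_error(retention_report(list(T0 = ptab[0, ], T1 = ptab)), "empty")
})

test_that("cross-level cores are intersections", {
  expect_equal(core_across_levels(list(a = c("a", "b", "c"), b = c("a", "b"),
                                       c = "a")), "a")
  expect_equal(core_across_levels(list(a = "x", b = "y")), character(0))
  expect_error(core_across_levels(list(a = "x")), "at least two")
  withr::with_seed(41, {
    full <- sample(letters, 20)
    nested <- lapply(c(20, 12, 7, 3), function(n) full[seq_len(n)])
    names(nested) <- paste0("L", 1:4)
    expect_setequal(core_across_levels(nested), nested[[4]])
  })
})

test_that("per-replicate analysis filters each replicate in isolation", {
  tbl <- make_otu_tbl(matrix(c(1, 5), ncol = 1),
                      lineage = c("Bacteria;A", "Bacteria;B"))
  pra <- per_replicate_analysis(tbl, stringency_level("T1"))
  expect_equal(pra$sets$rep1, "Bacteria;B")

  sym <- make_otu_tbl(rbind(c(4, 4, 4), c(7, 7, 7)),
                      lineage = c("Bacteria;A", "Bacteria;B"))
  pra <- per_replicate_analysis(sym, stringency_level("T1"))
  expect_equal(tidy(pra$venn)$region, "rep1&rep2&rep3")
  expect_equal(tidy(pra$venn)$size, 2)

  for (seed in 5:8) {
    tbl <- random_otu_tbl(25, seed = seed)
    pra <- per_replicate_analysis(tbl, stringency_level("T10"))
    expect_equal(sum(pra$venn$size), length(unique(unlist(pra$sets))))
  }
})

test_that("replicate retention reports per-replicate and mean percentages", {
  rr <- replicate_retention(c(r1 = 200, r2 = 100), c(r1 = 100, r2 = 80))
  expect_equal(unname(rr$per_replicate), c(50, 80))
  expect_equal(rr$mean_pct, 65)
  expect_equal(replicate_retention(10, 10)$mean_pct, 100)
})

test_that("filter cascade nests and matches the brute-force rules", {
  for (seed in 1:25) {
    tbl <- random_otu_tbl(sample(5:50, 1), seed = seed)
    fc <- filter_cascade(tbl)
    sets <- lapply(fc$tables, function(t) t$lineage)
    # nesting T10-R2 subset T10-R1 subset T10 subset T1 subset T0
    for (k in 2:5) {
      expect_true(all(sets[[k]] %in% sets[[k - 1]]),
                  info = paste("nesting at seed", seed, "level", k))
    }
    # rule-by-rule oracle
    for (nm in names(sets)) {
      expect_equal(sort(sets[[nm]]), brute_force_stringency(tbl, nm),
                   info = paste("oracle at seed", seed, nm))
    }
    # core of a nested family is its smallest set
    expect_setequal(fc$core, sets[["T10-R2"]])
  }
})

test_that("raw and post-singleton baselines keep the same phylotype sets", {
  for (seed in 30:34) {
    tbl <- random_otu_tbl(30, seed = seed)
    fc <- filter_cascade(tbl)
    expect_equal(fc$report$phylotypes[3:5], fc$report_post_t1$phylotypes[3:5])
  }
})
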