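test_that("orientation merging reverse-complements and sums identical ASVs", {
  fwd <- tibble::tibble(
    asv_id = "f1", sequence = "AAGG", replicate_id = "s1_r1",
    sample_id = "s1", role = "sample", count = 5
  )
  rev <- tibble::tibble(
    asv_id = "r1", sequence = "CCTT", replicate_id = "s1_r1",
    sample_id = "s1", role = "sample", count = 3
  )
  merged <- merge_orientations(fwd, rev)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$sequence, "AAGG")  # revcomp("CCTT") == "AAGG"
  expect_identical(merged$asv_id, "f1")
  expect_identical(merged$count, 8)

  # empty reverse table: identity
  expect_identical(merge_orientations(fwd, rev[0, ])$count, 5)

  # reverse-only sequences pass through under their own id
  rev2 <- dplyr::mutate(rev, sequence = "GGGG", asv_id = "r9")
  m2 <- merge_orientations(fwd, rev2)
  expect_identical(sort(m2$asv_id), c("f1", "r9"))
  expect_identical(m2$sequence[m2$asv_id == "r9"], "CCCC")
})

test_that("orientation merging conserves total counts on random tables", {
  for (seed in 1:3) {
    rec <- simulate_record(small_config(seed = seed))
    mb <- emit_metabarcoding(rec)
    merged <- merge_orientations(mb$forward, mb$reverse)
    expect_equal(sum(merged$count),
                 sum(mb$forward$count) + sum(mb$reverse$count))
    # every reverse-oriented taxon collapses back onto its forward ASV
    expect_false(any(grepl("_rc$", merged$asv_id)))
  }
})

test_that("singleton removal zeroes exactly the one-read observations", {
  counts <- matrix(c(0, 1, 2, 1, 7, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("a1", "a2"),
                                   c("s1_r1", "s1_r2", "s1_r3")))
  tbl <- long_table(counts, roles = c(s1_r1 = "sample", s1_r2 = "sample",
                                      s1_r3 = "sample"))
  out <- remove_singletons(tbl)
  expect_identical(wide_table(out, rownames(counts), colnames(counts)),
                   matrix(c(0, 0, 2, 0, 7, 0), nrow = 2, byrow = TRUE,
                          dimnames = dimnames(counts)))
  expect_identical(remove_singletons(out), out)  # idempotent
})

test_that("negative floor applies the per-ASV strict-below rule", {
  # spec'd hand case: negatives {0,3,1}, samples {2,3,10} -> {0,3,10}
  counts <- matrix(c(2, 3, 10, 0, 3, 1), nrow = 1,
                   dimnames = list("a1", c("s1_r1", "s1_r2", "s1_r3",
                                           "n1", "n2", "n3")))
  roles <- c(s1_r1 = "sample", s1_r2 = "sample", s1_r3 = "sample",
             n1 = "extraction_negative", n2 = "pcr_negative",
             n3 = "library_negative")
  out <- negative_floor_filter(long_table(counts, roles))
  expect_identical(
    wide_table(out, "a1", c("s1_r1", "s1_r2", "s1_r3")),
    matrix(c(0, 3, 10), nrow = 1,
           dimnames = list("a1", c("s1_r1", "s1_r2", "s1_r3")))
  )
  # no control columns survive
  expect_true(all(out$role == "sample"))
})

test_that("negative floor matches the cell-wise oracle on random tables", {
  withr::with_seed(14, {
    for (i in 1:5) {
      n_asv <- 8; n_rep <- 10
      counts <- matrix(rpois(n_asv * n_rep, 4), n_asv, n_rep,
                       dimnames = list(paste0("a", 1:n_asv),
                                       c(paste0("s1_r", 1:7),
                                         paste0("n", 1:3))))
      roles <- stats::setNames(
        c(rep("sample", 7), rep("pcr_negative", 3)), colnames(counts))
      tbl <- long_table(counts, roles)
      out <- negative_floor_filter(tbl)
      expect_identical(
        wide_table(out, rownames(counts), paste0("s1_r", 1:7)),
        oracle_negative_floor(counts, paste0("n", 1:3))
      )
      # row/column order invariance
      shuf <- tbl[sample(nrow(tbl)), ]
      expect_identical(
        wide_table(negative_floor_filter(shuf), rownames(counts),
                   paste0("s1_r", 1:7)),
        wide_table(out, rownames(counts), paste0("s1_r", 1:7))
      )
      # idempotent once controls are gone
      expect_identical(
        wide_table(negative_floor_filter(out), rownames(counts),
                   paste0("s1_r", 1:7)),
        wide_table(out, rownames(counts), paste0("s1_r", 1:7))
      )
    }
  })
  # no negatives at all: pass-through
  counts <- matrix(c(5, 2), 1, dimnames = list("a1", c("s1_r1", "s1_r2")))
  tbl <- long_table(counts, c(s1_r1 = "sample", s1_r2 = "sample"))
  expect_identical(negative_floor_filter(tbl), tbl)
})

test_that("length filter keeps the inclusive 75-150 bp window", {
  seqs <- stats::setNames(
    vapply(c(74, 75, 150, 151), function(l) {
      paste(rep("A", l), collapse = "")
    }, ""),
    paste0("a", 1:4)
  )
  counts <- matrix(5, 4, 1, dimnames = list(names(seqs), "s1_r1"))
  tbl <- long_table(counts, c(s1_r1 = "sample"), sequences = seqs)
  out <- length_filter(tbl, 75, 150)
  expect_identical(sort(unique(out$asv_id)), c("a2", "a3"))
  # 12S-style window
  expect_identical(sort(unique(length_filter(tbl, 75, 140)$asv_id)), "a2")
  # all-in-range: unchanged
  expect_identical(length_filter(out, 75, 150), out)
})

test_that("rarefaction drops shallow replicates and hits the exact depth", {
  counts <- matrix(c(
    60, 40,   # s1_r1 total 100 -> subsampled
    5, 4,     # s1_r2 total 9   -> dropped (below depth)
    80, 0     # s1_r3 total 80  -> only a1 -> forced 10
  ), nrow = 2, dimnames = list(c("a1", "a2"), c("s1_r1", "s1_r2", "s1_r3")))
  roles <- stats::setNames(rep("sample", 3), colnames(counts))
  out <- rarefy(long_table(counts, roles), depth = 10, seed = 2)
  sums <- tapply(out$count, out$replicate_id, sum)
  expect_identical(sort(names(sums)), c("s1_r1", "s1_r3"))
  expect_true(all(sums == 10))
  expect_equal(out$count[out$replicate_id == "s1_r3"], 10)
  # reproducible under the same seed
  expect_identical(rarefy(long_table(counts, roles), depth = 10, seed = 2),
                   out)
  expect_error(rarefy(long_table(counts, roles), depth = 0), "positive")
})

test_that("rarefaction is unbiased: per-ASV mean matches the expectation", {
  counts <- matrix(c(30, 70), 2, 1, dimnames = list(c("a1", "a2"), "s1_r1"))
  tbl <- long_table(counts, c(s1_r1 = "sample"))
  draws <- vapply(1:200, function(s) {
    out <- rarefy(tbl, depth = 50, seed = s)
    sum(out$count[out$asv_id == "a1"])
  }, 0)
  # hypergeometric: mean 15, var = 50 * .3 * .7 * (100-50)/(100-1)
  se <- sqrt(50 * 0.3 * 0.7 * 50 / 99 / 200)
  expect_lt(abs(mean(draws) - 15), 3 * se)
})

test_that("cumulative sum scaling follows the quantile-sum convention", {
  # counts (1,2,3,4), p = 0.5: interpolated median 2.5, s_j = 1 + 2 = 3
  counts <- matrix(c(1, 2, 3, 4,
                     1, 2, 3, 4,
                     2, 4, 6, 8), nrow = 4,
                   dimnames = list(paste0("a", 1:4),
                                   c("s1_r1", "s1_r2", "s1_r3")))
  roles <- stats::setNames(rep("sample", 3), colnames(counts))
  tbl <- long_table(counts, roles)
  out <- css_normalize(tbl, quantile_mode = "fixed", p = 0.5)
  expect_identical(unname(attr(out, "css_factors")),
                   c(3, 3, 6))
  # scale invariance: the doubled replicate normalises to the same values
  w <- wide_table(dplyr::mutate(out, count = .data$norm),
                  paste0("a", 1:4), colnames(counts))
  expect_equal(w[, "s1_r3"], w[, "s1_r1"])
  # identical replicates share a scaling factor, so norm is proportional
  expect_equal(w[, "s1_r1"], w[, "s1_r2"])

  # a replicate with no positive counts is rejected
  expect_error(
    css_normalize(dplyr::mutate(tbl, count = ifelse(
      .data$replicate_id == "s1_r2", 0, .data$count))),
    "no positive counts"
  )
})

test_that("ASV assignment filters to the top band then takes the LCA", {
  tax <- example_taxonomy()
  hits <- tibble::tibble(
    asv_id = c("x", "y", "y", "z", "z"),
    taxid = c(101L, 101L, 102L, 101L, 301L),
    identity = c(1.0, 1.0, 1.0, 1.0, 0.95),
    coverage = 1.0
  )
  out <- assign_asvs(hits, tax)
  expect_identical(out$taxid[out$asv_id == "x"], 101L)  # single hit
  expect_identical(out$taxid[out$asv_id == "y"], 100L)  # congeneric -> genus
  # z's second hit is 5% below the best: outside the 1% band
  expect_identical(out$taxid[out$asv_id == "z"], 101L)
  expect_false(any(out$low_quality))

  lowq <- assign_asvs(tibble::tibble(
    asv_id = "w", taxid = 101L, identity = 0.9, coverage = 0.5
  ), tax)
  expect_true(lowq$low_quality)

  # random hit sets against the brute-force oracle
  withr::with_seed(77, {
    species <- tax$nodes$taxid[tax$nodes$rank == "species"]
    for (i in 1:30) {
      ids <- sample(species, sample(2:5, 1))
      idn <- round(stats::runif(length(ids), 0.97, 1), 3)
      h <- tibble::tibble(asv_id = "q", taxid = ids, identity = idn,
                          coverage = 1)
      keep <- ids[idn >= max(idn) * 0.99]
      expect_identical(assign_asvs(h, tax)$taxid, oracle_lca(tax, keep))
    }
  })
})

test_that("positive replicate counts match brute force", {
  counts <- matrix(c(0, 5, 2, 0, 0, 0, 0, 0,
                     1, 1, 1, 1, 1, 1, 1, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("a1", "a2"), paste0("s1_r", 1:8)))
  roles <- stats::setNames(rep("sample", 8), colnames(counts))
  out <- positive_replicates(long_table(counts, roles))
  expect_identical(out$n_positive[out$asv_id == "a1"], 2L)
  expect_identical(out$n_positive[out$asv_id == "a2"], 8L)

  withr::with_seed(31, {
    m <- matrix(rpois(60, 0.7), 6, 10,
                dimnames = list(paste0("a", 1:6),
                                c(paste0("s1_r", 1:5), paste0("s2_r", 1:5))))
    tbl <- long_table(m, stats::setNames(rep("sample", 10), colnames(m)))
    out <- positive_replicates(tbl)
    for (j in seq_len(nrow(out))) {
      cols <- grep(paste0("^", out$sample_id[j], "_"), colnames(m))
      expect_identical(out$n_positive[j],
                       sum(m[out$asv_id[j], cols] > 0))
    }
  })
})

test_that("replicate tables round-trip through TSV", {
  rec <- simulate_record(small_config(seed = 2))
  mb <- emit_metabarcoding(rec)
  path <- tempfile(fileext = ".tsv")
  write_replicate_table(mb$forward, path)
  back <- read_replicate_table(path)
  expect_equal(as.data.frame(back), as.data.frame(mb$forward))
})
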