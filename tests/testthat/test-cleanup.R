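test_that("prefilter applies the 100-read and ambiguous-base rules", {
  counts <- make_counts(list(
    "AAAAA" = c(50, 49),     # 99 reads: out
    "CCCCC" = c(50, 50),     # exactly 100: kept
    "GGGNG" = c(5e5, 5e5),   # N: out regardless of abundance
    "TTTTT" = c(1e4, 1e4)
  ))
  pf <- prefilter(counts)
  expect_setequal(pf$kept$barcode, c("CCCCC", "TTTTT"))
  expect_equal(pf$removed$reason[pf$removed$barcode == "AAAAA"], "low-reads")
  expect_equal(pf$removed$reason[pf$removed$barcode == "GGGNG"], "contains-N")
})

test_that("evaluate_pair applies the three criteria in order", {
  m <- c(1e5, 2e5, 3e5)

  # distance 5 fails even if frequencies are perfect
  ev <- evaluate_pair(m, round(0.001 * m), "AAAAAAAAAA", "CCCCCAAAAA")
  expect_equal(ev$distance, 5L)
  expect_equal(ev$verdict, "not-daughter")
  expect_equal(ev$reason, "distance")

  # ratio 0.10 fails at distance 1
  ev <- evaluate_pair(m, round(0.10 * m), "AAAAAAAAAA", "AAAAAAAAAC")
  expect_equal(ev$reason, "ratio")

  # the constant-rate daughter at distance 1 is accepted, with its score
  # above the threshold line at 600 total reads
  ev <- evaluate_pair(m, round(0.001 * m), "AAAAAAAAAA", "AAAAAAAAAC")
  expect_equal(ev$verdict, "daughter")
  expect_gt(ev$loglik, -2 * log10(600) - 1)

  expect_error(evaluate_pair(c(1, 1), c(5, 5), "AAAA", "AAAC"), "prevalent")
})

test_that("an undefined score can never be accepted", {
  # both sequences similar and rare: no sample reaches 200 reads
  ev <- evaluate_pair(c(150, 180), c(5, 6), "AAAAAAAAAA", "AAAAAAAAAC",
                      cleanup_params(min_total_reads = 1))
  expect_equal(ev$n_qualifying, 0L)
  expect_true(is.na(ev$loglik))
  expect_equal(ev$verdict, "not-daughter")
  expect_equal(ev$reason, "score")
})

test_that("clean_lane handles degenerate tables", {
  one <- make_counts(list("AAAAAAAAAA" = c(500, 500)))
  res <- clean_lane(one)
  expect_equal(res$retained$barcode, "AAAAAAAAAA")

  empty <- one[0, ]
  res <- clean_lane(empty)
  expect_equal(nrow(res$retained), 0)
  expect_equal(nrow(res$pairs), 0)
})

test_that("unrelated abundant barcodes are both retained", {
  counts <- make_counts(list(
    "AAAAAAAAAAAAAAA" = c(1e5, 2e5),
    "GGGGCCCCTTTTGGG" = c(5e4, 1e5)
  ))
  res <- clean_lane(counts)
  expect_setequal(res$retained$barcode, counts$barcode)
  expect_equal(res$pairs$reason, "distance")
})

test_that("the greedy loop removes daughters and granddaughters correctly", {
  mother <- "AAAAAAAAAAAAAAA"
  daughter <- "CAAAAAAAAAAAAAA"     # d=1 from mother
  grand <- "CCAAAAAAAAAAAAA"        # d=1 from daughter, d=2 from mother
  m <- c(2e5, 1e5, 3e5, 2e5)
  counts <- make_counts(setNames(list(
    m,
    round(0.01 * m),        # constant 1% of the mother
    round(0.03 * 0.01 * m)  # constant 3% of the daughter: 240 reads total
  ), c(mother, daughter, grand)))
  res <- clean_lane(counts)
  # both generations are gone
  expect_setequal(res$retained$barcode, mother)
  # the daughter was claimed by the mother and never acted as a mother, so
  # the granddaughter was claimed transitively by the mother itself (its
  # counts track the mother's at rate 3e-4)
  rd <- res$removed_as_daughter
  expect_equal(rd$mother[rd$daughter == daughter], mother)
  expect_equal(rd$mother[rd$daughter == grand], mother)
  expect_false(daughter %in% res$pairs$mother)
  expect_false(grand %in% res$pairs$mother)
})

test_that("cleaning is deterministic and row-order independent", {
  sim <- simulate_experiment(simulation_config(seed = 5, noise_tail_count = 200L))
  counts <- sim$lanes$lane1$counts
  res1 <- clean_lane(counts)
  res2 <- clean_lane(counts)
  expect_identical(res1$retained, res2$retained)
  expect_identical(res1$pairs, res2$pairs)

  set.seed(99)
  shuffled <- counts[sample(nrow(counts)), ]
  res3 <- clean_lane(shuffled)
  expect_identical(res1$retained, res3$retained)
  expect_setequal(res1$prefiltered$barcode, res3$prefiltered$barcode)
})

test_that("retained barcodes keep their original counts bit-identically", {
  sim <- simulate_experiment(simulation_config(seed = 6, noise_tail_count = 100L))
  counts <- sim$lanes$lane1$counts
  res <- clean_lane(counts)
  orig <- counts[match(res$retained$barcode, counts$barcode), ]
  expect_identical(
    as.matrix(orig[setdiff(names(orig), "barcode")]),
    as.matrix(res$retained[setdiff(names(res$retained), "barcode")]),
    ignore_attr = TRUE
  )
})

test_that("no retained barcode sits in a more prevalent retained barcode's acceptance region", {
  sim <- simulate_experiment(simulation_config(seed = 7, noise_tail_count = 200L))
  counts <- sim$lanes$lane1$counts
  res <- clean_lane(counts)
  ret <- res$retained
  mat <- as.matrix(ret[setdiff(names(ret), "barcode")])
  totals <- rowSums(mat)
  for (i in seq_len(nrow(ret))) {
    for (j in seq_len(nrow(ret))) {
      if (i == j || totals[i] < totals[j]) next
      ev <- evaluate_pair(mat[i, ], mat[j, ], ret$barcode[i], ret$barcode[j])
      expect_equal(ev$verdict, "not-daughter")
    }
  }
})

test_that("the tidy/glance accessors partition the input barcodes", {
  sim <- simulate_experiment(simulation_config(seed = 8, noise_tail_count = 100L))
  counts <- sim$lanes$lane1$counts
  res <- clean_lane(counts)
  td <- tidy(res)
  expect_setequal(td$barcode, counts$barcode)
  expect_equal(nrow(td), nrow(counts))
  g <- glance(res)
  expect_equal(g$prefiltered + g$removed_as_daughter + g$retained,
               g$barcodes_in)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("read_threshold_filter retains by lane total with a closed boundary", {
  counts <- make_counts(list(a = c(49, 50), b = c(50, 50), c = c(51, 50)))
  counts$barcode <- c("AAAAA", "CCCCC", "GGGGG")
  expect_equal(read_threshold_filter(counts, 1), counts$barcode)
  expect_setequal(read_threshold_filter(counts, 100), c("CCCCC", "GGGGG"))
  expect_error(read_threshold_filter(counts, 0))
})
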