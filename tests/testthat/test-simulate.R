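test_that("single-substitution variants are enumerated exactly", {
  expect_setequal(enumerate_snv_variants("A"), c("C", "G", "T"))
  v100 <- enumerate_snv_variants(strrep("ACGT", 25))
  expect_equal(length(v100), 300)
  bc <- "ACGTACGTACGTACG"
  v <- enumerate_snv_variants(bc)
  expect_equal(length(v), 45)
  expect_false(bc %in% v)
  expect_true(all(levenshtein(bc, v) == 1L))
  expect_error(enumerate_snv_variants("ACGN"), "A/C/G/T")
})

test_that("correct read fraction follows the per-base error arithmetic", {
  expect_equal(correct_read_fraction(0.001, 100), 0.999^100)
  expect_equal(round(correct_read_fraction(0.001, 100), 2), 0.90)
  expect_equal(correct_read_fraction(0, 12345), 1)
  expect_equal(correct_read_fraction(0.01, 15), 0.99^15)
  expect_error(correct_read_fraction(1, 10))
})

test_that("a clean world contains exactly the mother barcodes", {
  cfg <- simulation_config(errors_per_mother = 0L, pcr_error_rate = 0,
                           contaminant_count = 0L, noise_tail_count = 0L,
                           seed = 51)
  sim <- simulate_experiment(cfg)
  counts <- sim$lanes$lane1$counts
  expect_setequal(counts$barcode, sim$truth$mothers$barcode)
  expect_equal(nrow(counts), 20)
})

test_that("simulation is bit-reproducible from its seed", {
  a <- simulate_experiment(simulation_config(seed = 52, noise_tail_count = 100L))
  b <- simulate_experiment(simulation_config(seed = 52, noise_tail_count = 100L))
  expect_identical(a$lanes$lane1$counts, b$lanes$lane1$counts)
  expect_identical(a$truth, b$truth)
})

test_that("the clone series and sequence spacing match the design", {
  sim <- simulate_experiment(simulation_config(seed = 53, noise_tail_count = 0L))
  sizes <- sim$truth$mothers$cells_base
  expect_equal(max(sizes) / min(sizes), 2^19)
  mo <- sim$truth$mothers$barcode
  for (i in seq_along(mo)) {
    others <- mo[-i]
    expect_true(all(levenshtein_to_many(mo[i], others) > 4))
  }
  # daughters sit within their recorded distance of their mother
  dg <- sim$truth$error_daughters
  expect_true(all(levenshtein(dg$mother, dg$barcode) == dg$distance))
  expect_true(all(dg$distance >= 1 & dg$distance <= 4))
  expect_false(anyDuplicated(c(mo, dg$barcode)) > 0)
})

test_that("per-lane rates respect the configured range and vary between lanes", {
  cfg <- simulation_config(seed = 54, n_lanes = 4, noise_tail_count = 0L)
  sim <- simulate_experiment(cfg)
  rates <- sim$truth$error_rates
  expect_true(all(rates$rate >= 10^cfg$error_rate_log10_range[1]))
  expect_true(all(rates$rate <= 10^cfg$error_rate_log10_range[2]))
  spread <- tapply(rates$rate, rates$barcode, function(r) max(r) / min(r))
  expect_true(all(spread <= cfg$between_lane_rate_factor + 1e-9))
  expect_gt(mean(spread), 1.05)  # lanes genuinely differ
})

test_that("daughter counts track rate * mother reads with overdispersion", {
  cfg <- simulation_config(seed = 55, n_replicate_groups = 30L,
                           errors_per_mother = 2L, pcr_error_rate = 0,
                           contaminant_count = 0L, noise_tail_count = 0L)
  sim <- simulate_experiment(cfg)
  counts <- sim$lanes$lane1$counts
  cols <- setdiff(names(counts), "barcode")
  mat <- as.matrix(counts[cols])
  rownames(mat) <- counts$barcode
  rates <- sim$truth$error_rates
  dg <- sim$truth$error_daughters
  checked <- 0
  for (k in seq_len(nrow(dg))) {
    if (!dg$barcode[k] %in% rownames(mat)) next  # never observed
    e <- rates$rate[rates$barcode == dg$barcode[k]]
    m <- mat[dg$mother[k], ]
    c <- mat[dg$barcode[k], ]
    big <- m >= 2e4
    if (e < 1e-3 || sum(big) < 20) next
    obs <- c[big] / m[big]
    # mean ratio near the lane rate
    expect_lt(abs(mean(obs) - e) / e, 0.5)
    # dispersion clearly above binomial: beta-binomial variance is
    # m*mu*(1-mu)*(1+(m-1)*rho); at these depths the rho term dominates
    v_bin <- mean(e * (1 - e) / m[big])
    expect_gt(stats::var(obs), 3 * v_bin)
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(abundance_ratio = 1))
  expect_error(simulation_config(error_rate_log10_range = c(-3, 0)))
  expect_error(
    simulate_experiment(simulation_config(barcode_length = 2L,
                                          n_mothers = 40L, seed = 1)),
    "sequence space|spacing")
})
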