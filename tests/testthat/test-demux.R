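demo_spec <- function() {
  extraction_spec(
    primer_constant = "GATCTGACGT",
    index_offset = 0L, index_length = 4L,
    barcode_offset = 4L, barcode_length = 15L,
    index_to_sample = c(AACC = "s1", GGTT = "s2")
  )
}

make_read <- function(index, barcode, prefix = "TT",
                      primer = "GATCTGACGT") {
  paste0(prefix, primer, index, barcode)
}

write_fastq <- function(seqs, path) {
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    c(sprintf("@r%d", i), seqs[i], "+", strrep("F", nchar(seqs[i])))
  }))
  writeLines(lines, path)
  path
}

test_that("a single well-formed read lands in its one cell", {
  bc <- "ACGTACGTACGTACG"
  res <- extract_barcodes(make_read("AACC", bc), demo_spec())
  expect_equal(res$counts$barcode, bc)
  expect_equal(res$counts$s1, 1L)
  expect_equal(res$counts$s2, 0L)
  expect_equal(sum(res$discarded$n), 0L)
})

test_that("reads are discarded with the right tallies", {
  bc <- "ACGTACGTACGTACG"
  reads <- c(
    make_read("AACC", bc),                      # counted
    make_read("AACG", bc),                      # index off by one base
    paste0("TTTT", "CCCCCCCCCC", "AACC", bc),   # no primer anywhere
    make_read("GGTT", "ACGT")                   # barcode window truncated
  )
  res <- extract_barcodes(reads, demo_spec())
  d <- setNames(res$discarded$n, res$discarded$reason)
  expect_equal(unname(d["unknown-index"]), 1L)
  expect_equal(unname(d["no-primer"]), 1L)
  expect_equal(unname(d["truncated"]), 1L)
  # conservation: counted + discarded = input reads
  expect_equal(sum(as.matrix(res$counts[c("s1", "s2")])) + sum(res$discarded$n),
               length(reads))
})

test_that("extraction is order independent and anchored leftmost", {
  bc1 <- "ACGTACGTACGTACG"
  bc2 <- "TTTTACGTACGTACG"
  reads <- c(make_read("AACC", bc1), make_read("GGTT", bc2),
             make_read("AACC", bc1), make_read("AACC", bc2))
  a <- extract_barcodes(reads, demo_spec())
  b <- extract_barcodes(rev(reads), demo_spec())
  expect_identical(a$counts, b$counts)

  # duplicated primer: leftmost match defines the anchor
  double <- paste0("GATCTGACGT", "AACC", bc1, "GATCTGACGT")
  res <- extract_barcodes(double, demo_spec())
  expect_equal(res$counts$barcode, bc1)
})

test_that("empty input and FASTQ files round-trip", {
  res <- extract_barcodes(character(0), demo_spec())
  expect_equal(nrow(res$counts), 0)
  expect_equal(sum(res$discarded$n), 0L)

  f <- withr::local_tempfile(fileext = ".fastq")
  bc <- "ACGTACGTACGTACG"
  write_fastq(c(make_read("AACC", bc), make_read("GGTT", bc)), f)
  res <- extract_barcodes(f, demo_spec())
  expect_equal(res$counts$s1, 1L)
  expect_equal(res$counts$s2, 1L)
})

test_that("malformed FASTQ is reported with its record number", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "FFFF",
               "@r2", "ACGT", "BROKEN", "FFFF"), f)
  expect_error(extract_barcodes(f, demo_spec()), "record 2")
})

test_that("extraction specs validate and round-trip through YAML", {
  expect_error(extraction_spec("GANC", 0, 4, 4, 15, c(AAAA = "s1")), "A/C/G/T")
  expect_error(extraction_spec("GATC", 0, 4, 4, 15, c(AAAA = "s1", AAAA = "s2")),
               "unique")
  expect_error(extraction_spec("GATC", 0, 4, 4, 15, c(AAA = "s1", GGGG = "s2")),
               "length")
  f <- withr::local_tempfile(fileext = ".yaml")
  spec <- demo_spec()
  write_extraction_spec(spec, f)
  spec2 <- read_extraction_spec(f)
  expect_equal(spec2$primer_constant, spec$primer_constant)
  expect_equal(spec2$index_to_sample, spec$index_to_sample)
})

test_that("simulated FASTQ demultiplexes back to the source table", {
  counts <- make_counts(list(
    "ACGTACGTACGTACG" = c(5, 3),
    "TACGTACGTACGTAC" = c(0, 7)
  ), sample_ids = c("s1", "s2"))
  f <- withr::local_tempfile(fileext = ".fastq")
  simulate_fastq(counts, demo_spec(), f)
  res <- extract_barcodes(f, demo_spec())
  back <- res$counts[match(counts$barcode, res$counts$barcode), ]
  expect_equal(back$s1, counts$s1, ignore_attr = TRUE)
  expect_equal(back$s2, counts$s2, ignore_attr = TRUE)
  expect_equal(sum(res$discarded$n), 0L)
})
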