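#' Barcode-by-sample count tables
#'
#' The quantitative input to the clean-up method is a plain tibble with a
#' character column `barcode` followed by one non-negative integer column per
#' sample; every sample column is one technical replicate of a multiplexed
#' sequencing lane. Sample metadata travel in a second tibble with columns
#' `sample_id`, `lane_id`, `replicate_group` and optionally `index_sequence`
#' (a replicate group is the biological sample of which a column is one of
#' two technical replicates).
#'
#' `validate_counts()` checks the invariants (unique equal-length barcodes,
#' integer counts >= 0) and returns the table invisibly; the other functions
#' read and write the TSV dialect used throughout (tab-separated, header row,
#' no quoting, barcodes upper-case).
#'
#' @param counts A barcode-by-sample count tibble.
#' @param path File path.
#' @param meta A sample-metadata tibble.
#' @name count_table
NULL

#' @rdname count_table
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts) || !"barcode" %in% names(counts)) {
    abort("`counts` must be a data frame with a `barcode` column.")
  }
  bc <- counts$barcode
  if (anyDuplicated(bc)) abort("Barcode sequences must be unique.")
  if (nrow(counts) > 0 && length(unique(nchar(bc))) > 1) {
    abort("All barcodes must have equal length.")
  }
  num <- counts[setdiff(names(counts), "barcode")]
  if (ncol(num) == 0) abort("`counts` must have at least one sample column.")
  ok <- vapply(num, function(x) {
    is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == round(x))
  }, logical(1))
  if (!all(ok)) {
    abort(paste0("Sample column(s) not non-negative integers: ",
                 paste(names(num)[!ok], collapse = ", ")))
  }
  invisible(counts)
}

sample_cols <- function(counts) setdiff(names(counts), "barcode")

count_matrix <- function(counts) {
  m <- as.matrix(counts[sample_cols(counts)])
  rownames(m) <- counts$barcode
  storage.mode(m) <- "double"
  m
}

lane_totals <- function(counts) {
  rowSums(count_matrix(counts))
}

#' @rdname count_table
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  counts$barcode <- toupper(counts$barcode)
  validate_counts(counts)
  counts
}

#' @rdname count_table
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' @rdname count_table
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_meta(meta)
  meta
}

#' @rdname count_table
#' @export
write_sample_meta <- function(meta, path) {
  validate_sample_meta(meta)
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' @rdname count_table
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "lane_id", "replicate_group")
  if (!is.data.frame(meta) || !all(need %in% names(meta))) {
    abort(paste0("Sample metadata needs columns: ", paste(need, collapse = ", ")))
  }
  dup <- duplicated(meta[c("lane_id", "sample_id")])
  if (any(dup)) abort("`sample_id` must be unique within a lane.")
  too_big <- meta %>%
    dplyr::count(.data$lane_id, .data$replicate_group) %>%
    filter(.data$n > 2)
  if (nrow(too_big) > 0) {
    abort("A replicate group may contain at most two samples.")
  }
  invisible(meta)
}

#' Check that a count table and its metadata describe the same samples
#'
#' @param counts A count tibble.
#' @param meta A sample-metadata tibble.
#' @return Invisibly `TRUE`; errors naming the first mismatched sample.
#' @export
check_counts_meta <- function(counts, meta) {
  validate_counts(counts)
  validate_sample_meta(meta)
  cols <- sample_cols(counts)
  missing_meta <- setdiff(cols, meta$sample_id)
  missing_counts <- setdiff(meta$sample_id, cols)
  if (length(missing_meta) > 0) {
    abort(paste0("Sample in counts but not metadata: ", missing_meta[1]))
  }
  if (length(missing_counts) > 0) {
    abort(paste0("Sample in metadata but not counts: ", missing_counts[1]))
  }
  invisible(TRUE)
}
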