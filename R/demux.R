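#' Specification for barcode extraction from raw reads
#'
#' Reads are anchored by an exact match to a constant part of the sequenced
#' primer region; the sample index and the barcode are then extracted at
#' fixed offsets relative to the position immediately after the primer match
#' (0-based). Reads without the primer constant, with an index not exactly
#' matching a listed index, or too short to cover the extraction windows are
#' discarded and tallied.
#'
#' @param primer_constant Non-empty A/C/G/T string matched exactly; the
#'   leftmost occurrence anchors the read.
#' @param index_offset,index_length Position and length of the sample index
#'   window after the primer (0-based offset).
#' @param barcode_offset Position of the barcode window after the primer
#'   (0-based offset).
#' @param barcode_length Barcode length (default 15).
#' @param index_to_sample Named character vector mapping index sequences
#'   (names) to sample identifiers (values). Index sequences must be unique
#'   and of length `index_length`.
#' @return An `extraction_spec` object.
#' @export
extraction_spec <- function(primer_constant,
                            index_offset,
                            index_length,
                            barcode_offset,
                            barcode_length = 15L,
                            index_to_sample) {
  if (!is.character(primer_constant) || length(primer_constant) != 1 ||
      !nzchar(primer_constant) || !grepl("^[ACGT]+$", primer_constant)) {
    abort("`primer_constant` must be a non-empty A/C/G/T string.")
  }
  if (barcode_length < 1) abort("`barcode_length` must be >= 1.")
  if (index_offset < 0 || barcode_offset < 0) {
    abort("Offsets are 0-based and must be >= 0.")
  }
  idx <- names(index_to_sample)
  if (is.null(idx) || any(!nzchar(idx))) {
    abort("`index_to_sample` must be a named vector (names are index sequences).")
  }
  if (anyDuplicated(idx)) abort("Index sequences must be unique.")
  if (length(unique(nchar(idx))) != 1 || nchar(idx[1]) != index_length) {
    abort("All index sequences must have length `index_length`.")
  }
  structure(
    list(
      primer_constant = primer_constant,
      index_offset = as.integer(index_offset),
      index_length = as.integer(index_length),
      barcode_offset = as.integer(barcode_offset),
      barcode_length = as.integer(barcode_length),
      index_to_sample = index_to_sample
    ),
    class = "extraction_spec"
  )
}

#' Read or write an extraction spec as YAML
#'
#' Flat keys matching the arguments of [extraction_spec()];
#' `index_to_sample` is a mapping of index sequence to sample id.
#'
#' @param path File path.
#' @param spec An `extraction_spec` object.
#' @export
read_extraction_spec <- function(path) {
  v <- yaml::read_yaml(path)
  extraction_spec(
    primer_constant = v$primer_constant,
    index_offset = v$index_offset,
    index_length = v$index_length,
    barcode_offset = v$barcode_offset,
    barcode_length = if (is.null(v$barcode_length)) 15L else v$barcode_length,
    index_to_sample = unlist(v$index_to_sample)
  )
}

#' @rdname read_extraction_spec
#' @export
write_extraction_spec <- function(spec, path) {
  stopifnot(inherits(spec, "extraction_spec"))
  v <- unclass(spec)
  v$index_to_sample <- as.list(spec$index_to_sample)
  yaml::write_yaml(v, path)
  invisible(path)
}

#' Extract a barcode-by-sample count table from FASTQ reads
#'
#' For every read with (i) an exact leftmost match of the primer constant,
#' (ii) an index window exactly equal to one of the listed indices, and
#' (iii) a fully covered barcode window, one count is added to the
#' (barcode, sample) cell. Discarded reads are tallied by reason
#' (`no-primer`, `truncated`, `unknown-index`). Quality scores are ignored.
#'
#' @param fastq Path to a FASTQ file (plain or gzip), or a character vector
#'   of read sequences.
#' @param spec An [extraction_spec()].
#' @return A `barcode_extraction` object: list with `counts` (tibble with a
#'   column per sample in `index_to_sample`, including all-zero samples),
#'   `discarded` (tibble `reason`, `n`) and `n_reads`.
#' @export
extract_barcodes <- function(fastq, spec) {
  stopifnot(inherits(spec, "extraction_spec"))
  reads <- if (is.character(fastq) && length(fastq) == 1 &&
               file.exists(fastq)) {
    read_fastq_sequences(fastq)
  } else if (is.character(fastq)) {
    toupper(fastq)
  } else {
    abort("`fastq` must be a file path or a character vector of sequences.")
  }

  samples <- unique(unname(spec$index_to_sample))
  tallies <- c("no-primer" = 0L, "truncated" = 0L, "unknown-index" = 0L)
  n_reads <- length(reads)

  counts_tbl <- tibble(barcode = character(0))
  for (s in samples) counts_tbl[[s]] <- integer(0)

  if (n_reads > 0) {
    pos <- regexpr(spec$primer_constant, reads, fixed = TRUE)
    no_primer <- pos < 0
    tallies["no-primer"] <- sum(no_primer)

    anchor <- pos + nchar(spec$primer_constant)   # first base after primer
    need <- anchor - 1 + max(spec$index_offset + spec$index_length,
                             spec$barcode_offset + spec$barcode_length)
    truncated <- !no_primer & nchar(reads) < need
    tallies["truncated"] <- sum(truncated)

    usable <- !no_primer & !truncated
    idx <- substr(reads, anchor + spec$index_offset,
                  anchor + spec$index_offset + spec$index_length - 1)
    known <- usable & idx %in% names(spec$index_to_sample)
    tallies["unknown-index"] <- sum(usable & !known)

    if (any(known)) {
      bc <- substr(reads[known], anchor[known] + spec$barcode_offset,
                   anchor[known] + spec$barcode_offset + spec$barcode_length - 1)
      smp <- unname(spec$index_to_sample[idx[known]])
      tab <- table(bc, factor(smp, levels = samples))
      counts_tbl <- dplyr::bind_cols(
        tibble(barcode = rownames(tab)),
        as_tibble(`rownames<-`(unclass(tab), NULL))
      )
      counts_tbl <- counts_tbl[order(counts_tbl$barcode), , drop = FALSE]
    }
  }

  structure(
    list(
      counts = counts_tbl,
      discarded = tibble(reason = names(tallies), n = unname(tallies)),
      n_reads = n_reads
    ),
    class = "barcode_extraction"
  )
}

#' @export
print.barcode_extraction <- function(x, ...) {
  cat(sprintf(
    "Barcode extraction: %d reads; %d barcodes counted; discarded: %s\n",
    x$n_reads, nrow(x$counts),
    paste(sprintf("%s=%d", x$discarded$reason, x$discarded$n), collapse = ", ")))
  invisible(x)
}

read_fastq_sequences <- function(path) {
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    bad <- diagnose_fastq(path)
    if (!is.na(bad)) {
      abort(sprintf("Malformed FASTQ in %s at record %d.", path, bad))
    }
    abort(sprintf("Could not read FASTQ %s: %s", path, conditionMessage(res)))
  }
  toupper(as.character(res))
}

# structural scan used only to name the offending record when the FASTQ
# reader rejects a file: returns the 1-based record number or NA
diagnose_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
  if (length(lines) == 0) return(NA_integer_)
  n_rec <- ceiling(length(lines) / 4)
  for (r in seq_len(n_rec)) {
    chunk <- lines[((r - 1) * 4 + 1):min(r * 4, length(lines))]
    if (length(chunk) < 4 ||
        !startsWith(chunk[1], "@") ||
        !startsWith(chunk[3], "+") ||
        nchar(chunk[2]) != nchar(chunk[4]) ||
        grepl("[^A-Za-z]", chunk[2])) {
      return(r)
    }
  }
  NA_integer_
}
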