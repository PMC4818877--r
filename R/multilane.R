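#' Build an in silico barcode reference library from cleaned lanes
#'
#' Joins all barcodes that survived cleaning in at least one lane into a
#' reference library, recording per barcode the lanes it survived in. The
#' library plays the role of an independently sequenced reference library
#' when none exists.
#'
#' @param results A named list of `barcode_cleanup` objects (names are lane
#'   ids; unnamed lists get `lane1`, `lane2`, ...).
#' @return A `barcode_library` tibble: `barcode`, `n_lanes`, `lanes`
#'   (comma-separated lane ids).
#' @export
build_insilico_library <- function(results) {
  if (length(results) < 1) abort("Need at least one cleaned lane.")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("lane", seq_along(results))
  }
  long <- purrr::imap(results, function(res, id) {
    stopifnot(inherits(res, "barcode_cleanup"))
    tibble(barcode = res$retained$barcode, lane_id = id)
  }) %>% bind_rows()
  lib <- long %>%
    group_by(.data$barcode) %>%
    summarise(n_lanes = dplyr::n_distinct(.data$lane_id),
              lanes = paste(sort(unique(.data$lane_id)), collapse = ","),
              .groups = "drop") %>%
    arrange(desc(.data$n_lanes), .data$barcode)
  class(lib) <- c("barcode_library", class(lib))
  lib
}

#' Rescue barcodes using a reference library
#'
#' A true barcode wrongly removed as a daughter in one lane may survive
#' cleaning in another lane; the multi-lane library can then "fish" it back.
#' Any barcode of the lane's table that passes the prefilter (lane total
#' >= `min_total_reads`, no ambiguous bases) and whose sequence is in the
#' library is moved to the retained set, keeping its original counts. Rescue
#' never removes a barcode.
#'
#' @param counts The lane's original count tibble.
#' @param result The `barcode_cleanup` produced from `counts`.
#' @param library A `barcode_library` (or any data frame with a `barcode`
#'   column, or a plain character vector of sequences).
#' @param params The [cleanup_params()] used.
#' @return An updated `barcode_cleanup` with rescued barcodes in `retained`
#'   and listed in `$rescued`.
#' @export
rescue_with_library <- function(counts, result, library,
                                params = cleanup_params()) {
  stopifnot(inherits(result, "barcode_cleanup"))
  lib_seqs <- library_sequences(library)
  pf <- prefilter(counts, params)
  eligible <- intersect(pf$kept$barcode, lib_seqs)
  add <- setdiff(eligible, result$retained$barcode)
  if (length(add) == 0) return(result)

  extra <- counts[match(add, counts$barcode), , drop = FALSE]
  retained <- bind_rows(result$retained, extra)
  retained <- retained[order(-lane_totals(retained), retained$barcode), ,
                       drop = FALSE]
  result$retained <- retained
  result$rescued <- union(result$rescued, add)
  result$removed_as_daughter <- result$removed_as_daughter[
    !result$removed_as_daughter$daughter %in% add, , drop = FALSE]
  result$summary$retained <- nrow(retained)
  result$summary$removed_as_daughter <-
    result$summary$removed_as_daughter - length(add)
  result
}

#' Filter a count table against a reference library
#'
#' The gold-standard procedure: retain exactly those barcodes whose sequence
#' occurs in an (independently obtained) reference library, by exact match.
#'
#' @param counts A barcode-by-sample count tibble.
#' @param reference A `barcode_library`, data frame with a `barcode` column,
#'   or character vector of sequences.
#' @return Character vector of retained barcode sequences.
#' @export
filter_by_reference <- function(counts, reference) {
  validate_counts(counts)
  counts$barcode[counts$barcode %in% library_sequences(reference)]
}

library_sequences <- function(library) {
  if (is.data.frame(library)) {
    if (!"barcode" %in% names(library)) {
      abort("Library data frame needs a `barcode` column.")
    }
    library$barcode
  } else if (is.character(library)) {
    library
  } else {
    abort("`library` must be a data frame with a `barcode` column or a character vector.")
  }
}

#' Read or write a barcode library file
#'
#' Plain text, one barcode per line; an optional second tab-separated column
#' carries comma-separated provenance lane ids.
#'
#' @param path File path.
#' @param library A `barcode_library` tibble (or data frame with `barcode`
#'   and optionally `lanes` columns).
#' @return `read_library()` returns a `barcode_library` tibble.
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lib <- tibble(
    barcode = toupper(vapply(parts, `[`, character(1), 1)),
    lanes = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                   character(1))
  )
  lib$n_lanes <- ifelse(is.na(lib$lanes), NA_integer_,
                        lengths(strsplit(lib$lanes, ",", fixed = TRUE)))
  lib <- lib[c("barcode", "n_lanes", "lanes")]
  class(lib) <- c("barcode_library", class(lib))
  lib
}

#' @rdname read_library
#' @export
write_library <- function(library, path) {
  seqs <- library_sequences(library)
  lanes <- if (is.data.frame(library) && "lanes" %in% names(library)) {
    library$lanes
  } else {
    rep(NA_character_, length(seqs))
  }
  lines <- ifelse(is.na(lanes), seqs, paste(seqs, lanes, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
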