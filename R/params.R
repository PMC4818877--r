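#' Clean-up parameters
#'
#' Bundles every cutoff of the barcode clean-up method. The defaults are the
#' published operating point of the method: a candidate daughter must lie
#' within `max_dist` edits of its mother, carry at most `max_ratio` of the
#' mother's lane-total reads, and its log-likelihood score must exceed the
#' line `slope_a * log10(total daughter reads) + offset_b`. Barcodes with
#' fewer than `min_total_reads` reads in the whole lane (or containing `N`)
#' are excluded before any pairing; only samples where mother or daughter has
#' at least `min_sample_reads` reads contribute to the score; the
#' beta-binomial overdispersion is fixed to `ratio / rho_divisor`.
#'
#' @param max_dist Maximum Levenshtein distance between mother and daughter
#'   (edits; default 4).
#' @param max_ratio Maximum daughter/mother lane-total read ratio
#'   (dimensionless, in (0,1); default 0.05).
#' @param slope_a,offset_b Slope and offset of the score threshold line
#'   (default -2 and -1).
#' @param min_total_reads Lane-total read prefilter (reads; default 100).
#' @param min_sample_reads Per-sample read requirement for a sample to
#'   contribute to the score (reads; default 200).
#' @param rho_divisor Overdispersion is fixed to `ratio / rho_divisor`
#'   (default 10).
#'
#' @return An object of class `cleanup_params` (a named list).
#' @examples
#' cleanup_params()
#' cleanup_params(max_dist = 3)
#' @export
cleanup_params <- function(max_dist = 4L,
                           max_ratio = 0.05,
                           slope_a = -2,
                           offset_b = -1,
                           min_total_reads = 100L,
                           min_sample_reads = 200L,
                           rho_divisor = 10) {
  p <- list(
    max_dist = as.integer(max_dist),
    max_ratio = as.numeric(max_ratio),
    slope_a = as.numeric(slope_a),
    offset_b = as.numeric(offset_b),
    min_total_reads = as.integer(min_total_reads),
    min_sample_reads = as.integer(min_sample_reads),
    rho_divisor = as.numeric(rho_divisor)
  )
  validate_cleanup_params(p)
  structure(p, class = "cleanup_params")
}

validate_cleanup_params <- function(p) {
  stopifnot(
    p$max_dist >= 1L,
    p$max_ratio > 0, p$max_ratio < 1,
    p$min_total_reads >= 1L,
    p$min_sample_reads >= 1L,
    p$rho_divisor > 1
  )
  invisible(p)
}

#' @export
print.cleanup_params <- function(x, ...) {
  cat("Barcode clean-up parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write clean-up parameters as a YAML config
#'
#' A flat key-value YAML file; unknown keys are rejected, missing keys take
#' their defaults.
#'
#' @param path File path.
#' @param params A [cleanup_params()] object.
#' @return `read_params()` returns a `cleanup_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cleanup_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown parameter(s) in ", path, ": ", paste(bad, collapse = ", ")))
  }
  do.call(cleanup_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cleanup_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
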