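#' Confusion counts and performance metrics against a gold standard
#'
#' Over a stated universe of barcodes, compares a predicted-true set with a
#' gold-standard true set: sensitivity is the probability of correctly
#' identifying a true barcode (tp / (tp + fn)), specificity of correctly
#' identifying a spurious one (tn / (tn + fp)), and precision the fraction
#' of correct barcodes among all barcodes left after filtering
#' (tp / (tp + fp)). A metric whose denominator is zero is reported as `NA`,
#' never as 0 or 1.
#'
#' @param predicted_true,gold_true Character vectors (subsets of `universe`).
#' @param universe Character vector: all barcodes under consideration.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision`.
#' @examples
#' evaluate_detection(c("A", "B"), c("A", "C"), c("A", "B", "C", "D"))
#' @export
evaluate_detection <- function(predicted_true, gold_true, universe) {
  predicted_true <- unique(predicted_true)
  gold_true <- unique(gold_true)
  universe <- unique(universe)
  if (!all(predicted_true %in% universe)) {
    abort("`predicted_true` must be a subset of `universe`.")
  }
  if (!all(gold_true %in% universe)) {
    abort("`gold_true` must be a subset of `universe`.")
  }
  tp <- length(intersect(predicted_true, gold_true))
  fp <- length(setdiff(predicted_true, gold_true))
  fn <- length(setdiff(gold_true, predicted_true))
  tn <- length(universe) - tp - fp - fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp)
  )
}

#' Randomization control: destroy mother-daughter structure
#'
#' First randomly swaps the barcode sequence labels across rows, then, for
#' each row independently, assigns the per-sample read numbers to random
#' samples. Row totals and the multiset of sequences are preserved, but the
#' frequency and sequence-similarity relationships between mothers and
#' daughters — the basis of the clean-up — are lost. Cleaning randomized
#' data measures how much agreement with a gold standard arises by chance.
#'
#' @param counts A barcode-by-sample count tibble.
#' @param seed Integer seed.
#' @return A count tibble of the same shape.
#' @export
randomize_table <- function(counts, seed) {
  validate_counts(counts)
  set.seed(seed)
  mat <- count_matrix(counts)
  out_barcodes <- sample(counts$barcode)
  for (i in seq_len(nrow(mat))) {
    mat[i, ] <- mat[i, sample(ncol(mat))]
  }
  rownames(mat) <- NULL
  dplyr::bind_cols(tibble(barcode = out_barcodes), as_tibble(mat))
}

#' Subsample the columns of a lane
#'
#' Keeps a uniform random subset of `n_samples` sample columns and rescales
#' every remaining count by (original lane grand total) / (kept grand
#' total), rounding to the nearest integer (round-half-to-even), so the lane
#' total is preserved. Used to ask how many multiplexed samples the clean-up
#' needs.
#'
#' @param counts A barcode-by-sample count tibble.
#' @param n_samples Number of columns to keep (1 to all).
#' @param seed Integer seed.
#' @return A count tibble with `n_samples` sample columns.
#' @export
subsample_lane <- function(counts, n_samples, seed) {
  validate_counts(counts)
  cols <- sample_cols(counts)
  if (n_samples < 1 || n_samples > length(cols)) {
    abort("`n_samples` must be between 1 and the number of samples.")
  }
  set.seed(seed)
  keep <- sort(sample(length(cols), n_samples))
  sub <- counts[c("barcode", cols[keep])]
  grand <- sum(count_matrix(counts))
  kept_total <- sum(count_matrix(sub))
  if (kept_total > 0) {
    scale <- grand / kept_total
    for (cn in cols[keep]) sub[[cn]] <- round(sub[[cn]] * scale)
  }
  sub
}

#' Sweep the read-threshold baseline against a gold standard
#'
#' Applies [read_threshold_filter()] at each threshold and computes the
#' metrics of [evaluate_detection()] over the given universe.
#'
#' @param counts A barcode-by-sample count tibble.
#' @param thresholds Integer vector of read thresholds.
#' @param gold_true Character vector of gold-standard true barcodes.
#' @param universe Universe of barcodes for the metrics; defaults to the
#'   prefilter-passing barcodes of `counts` so that baseline and clean-up
#'   are compared on the same set.
#' @param params [cleanup_params()] defining the default universe.
#' @return A tibble with one row per threshold and the metric columns.
#' @export
threshold_sweep <- function(counts, thresholds, gold_true,
                            universe = NULL, params = cleanup_params()) {
  validate_counts(counts)
  if (is.null(universe)) {
    universe <- prefilter(counts, params)$kept$barcode
  }
  gold_true <- intersect(gold_true, universe)
  purrr::map_dfr(thresholds, function(th) {
    kept <- intersect(read_threshold_filter(counts, th), universe)
    dplyr::bind_cols(tibble(threshold = th),
                     evaluate_detection(kept, gold_true, universe))
  })
}
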