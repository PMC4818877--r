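#' Beta-binomial shape from mean and overdispersion
#'
#' The error model for daughter read counts is a beta-binomial distribution
#' re-parameterized by a mean `mu = alpha / (alpha + beta)` and an
#' overdispersion `rho = 1 / (1 + alpha + beta)`. In the clean-up method
#' `mu` is fixed to the daughter/mother total-read ratio `r` and `rho` to
#' `r / 10`, which yields a unimodal mass with its peak at the expected
#' daughter read count `r * m_i`.
#'
#' @param mu Mean, in (0, 1).
#' @param rho Overdispersion, in (0, 1).
#' @return A `bb_shape` object: list with `alpha`, `beta`, `mu`, `rho`.
#' @examples
#' bb_shape(0.5, 1/3) # alpha = beta = 1
#' @export
bb_shape <- function(mu, rho) {
  if (!is.numeric(mu) || !is.numeric(rho) ||
      any(mu <= 0 | mu >= 1) || any(rho <= 0 | rho >= 1)) {
    abort("`mu` and `rho` must lie strictly in (0, 1).")
  }
  s <- 1 / rho - 1            # alpha + beta
  structure(
    list(alpha = mu * s, beta = (1 - mu) * s, mu = mu, rho = rho),
    class = "bb_shape"
  )
}

#' @export
print.bb_shape <- function(x, ...) {
  cat(sprintf("Beta-binomial shape: alpha = %g, beta = %g (mu = %g, rho = %g)\n",
              x$alpha, x$beta, x$mu, x$rho))
  invisible(x)
}

# log-mass floor standing in for zero-probability observations (c > n, or a
# positive count with zero trials): keeps the mean score finite while still
# letting one anomalous sample destroy a pair's score.
bb_floor_log <- log(1e-300)

#' Log density of the beta-binomial distribution
#'
#' Natural log of the beta-binomial probability mass of `x` successes in
#' `size` trials, computed through `lchoose`/`lbeta` for numerical stability.
#' Observations with zero mass (`x > size`) are floored at `log(1e-300)`
#' rather than `-Inf` so that means over samples stay finite.
#'
#' @param x Non-negative integer count(s).
#' @param size Non-negative integer trial count(s).
#' @param shape A [bb_shape()] object.
#' @return Numeric vector of log masses.
#' @examples
#' dbetabinom_log(1, 2, bb_shape(0.5, 1/3)) # log(1/3)
#' @export
dbetabinom_log <- function(x, size, shape) {
  if (!inherits(shape, "bb_shape")) abort("`shape` must be a bb_shape object.")
  if (any(x < 0) || any(size < 0)) abort("`x` and `size` must be non-negative.")
  n <- max(length(x), length(size))
  x <- rep_len(as.numeric(x), n)
  size <- rep_len(as.numeric(size), n)
  out <- rep(bb_floor_log, n)
  ok <- x <= size
  if (any(ok)) {
    out[ok] <- lchoose(size[ok], x[ok]) +
      lbeta(x[ok] + shape$alpha, size[ok] - x[ok] + shape$beta) -
      lbeta(shape$alpha, shape$beta)
  }
  pmax(out, bb_floor_log)
}

#' Expected daughter reads in one sample
#'
#' Given the lane-wide daughter/mother total-read ratio `r`, the expected
#' daughter read count in a sample where the mother has `m_i` reads is
#' `r * m_i` (e.g. a ratio of 0.001 and 100,000 mother reads predict 100
#' daughter reads).
#'
#' @param ratio Lane-wide total-read ratio (>= 0).
#' @param mother_reads Mother read count(s) in the sample(s).
#' @return `ratio * mother_reads`.
#' @export
expected_daughter_reads <- function(ratio, mother_reads) {
  if (any(ratio < 0)) abort("`ratio` must be non-negative.")
  ratio * mother_reads
}

#' Score threshold line
#'
#' The acceptance threshold for the log-likelihood score depends on the
#' daughter's lane-total read count: `slope_a * log10(total) + offset_b`.
#' Scores above this line (together with the distance and ratio criteria)
#' qualify a pair as mother-daughter.
#'
#' @param total_daughter_reads Positive lane-total daughter read count(s).
#' @param params A [cleanup_params()] object.
#' @return Numeric threshold value(s).
#' @examples
#' score_threshold(100) # -5 at the default slope/offset
#' @export
score_threshold <- function(total_daughter_reads, params = cleanup_params()) {
  if (any(total_daughter_reads < 1)) {
    abort("`total_daughter_reads` must be >= 1.")
  }
  params$slope_a * log10(total_daughter_reads) + params$offset_b
}

#' Cross-sample predictability score for a candidate mother-daughter pair
#'
#' The central statistic of the clean-up method. With `c_i` and `m_i` the
#' daughter and mother read counts in sample `i`, the lane-wide ratio
#' `r = sum(c) / sum(m)` predicts `r * m_i` daughter reads per sample; the
#' score is the mean natural-log beta-binomial mass of the observed `c_i`
#' (trials `m_i`, mean `r`, overdispersion `r / rho_divisor`) over the
#' qualifying samples — those where mother or daughter has at least
#' `min_sample_reads` reads. With no qualifying sample (or a degenerate
#' ratio of 0 or >= 1) the score is undefined (`NA`) and the pair can never
#' be accepted.
#'
#' @param daughter_counts,mother_counts Equal-length integer vectors aligned
#'   to the same sample order.
#' @param params A [cleanup_params()] object.
#' @return A one-row tibble: `total_daughter`, `total_mother`, `ratio`,
#'   `n_qualifying`, `loglik`, `threshold`.
#' @examples
#' loglik_score(c(100, 200), c(100000, 200000))
#' @export
loglik_score <- function(daughter_counts, mother_counts,
                         params = cleanup_params()) {
  if (length(daughter_counts) != length(mother_counts) ||
      length(mother_counts) < 1) {
    abort("Count vectors must have equal length >= 1.")
  }
  if (any(daughter_counts < 0) || any(mother_counts < 0)) {
    abort("Counts must be non-negative.")
  }
  sm <- sum(mother_counts)
  sc <- sum(daughter_counts)
  if (sm == 0) abort("Mother has zero total reads.")
  ratio <- sc / sm
  qual <- mother_counts >= params$min_sample_reads |
    daughter_counts >= params$min_sample_reads
  nq <- sum(qual)
  loglik <- NA_real_
  if (nq >= 1 && ratio > 0 && ratio < 1) {
    shape <- bb_shape(ratio, ratio / params$rho_divisor)
    loglik <- mean(dbetabinom_log(daughter_counts[qual], mother_counts[qual],
                                  shape))
  }
  tibble(
    total_daughter = sc,
    total_mother = sm,
    ratio = ratio,
    n_qualifying = nq,
    loglik = loglik,
    threshold = if (sc >= 1) score_threshold(sc, params) else NA_real_
  )
}
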