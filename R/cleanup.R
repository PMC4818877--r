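#' Abundance and sequence prefilter
#'
#' Before any mother-daughter evaluation, barcodes with fewer than
#' `min_total_reads` reads summed over all samples of the lane are excluded
#' (at such depths the per-sample counts are too small to discriminate
#' correct from incorrect pairs), as are barcodes containing any character
#' outside A/C/G/T (ambiguous base calls).
#'
#' @param counts A barcode-by-sample count tibble (see [validate_counts()]).
#' @param params A [cleanup_params()] object.
#' @return A list with `kept` (the filtered count tibble) and `removed`
#'   (tibble with `barcode`, `total_reads`, `reason` in
#'   `"low-reads"`/`"contains-N"`).
#' @export
prefilter <- function(counts, params = cleanup_params()) {
  validate_counts(counts)
  totals <- lane_totals(counts)
  has_n <- !grepl("^[ACGT]+$", counts$barcode)
  low <- totals < params$min_total_reads
  drop <- has_n | low
  removed <- tibble(
    barcode = counts$barcode[drop],
    total_reads = unname(totals[drop]),
    # ambiguous bases take precedence as the reported reason
    reason = ifelse(has_n[drop], "contains-N", "low-reads")
  )
  list(kept = counts[!drop, , drop = FALSE], removed = removed)
}

#' Evaluate one candidate mother-daughter pair
#'
#' Computes the three criteria of the method for a single ordered pair: the
#' Levenshtein distance between the sequences, the daughter/mother lane-total
#' read ratio, and the cross-sample log-likelihood score with its threshold.
#' The verdict is `"daughter"` iff distance <= `max_dist`, ratio <=
#' `max_ratio`, and the score is defined and exceeds its threshold;
#' otherwise `reason` names the first failing criterion in the order
#' distance, ratio, score.
#'
#' @param mother_counts,daughter_counts Aligned integer count vectors; the
#'   mother must be at least as prevalent in total.
#' @param mother_seq,daughter_seq Barcode sequences.
#' @param params A [cleanup_params()] object.
#' @return A one-row tibble: `mother`, `daughter`, `distance`, `ratio`,
#'   `n_qualifying`, `loglik`, `threshold`, `verdict`, `reason`.
#' @export
evaluate_pair <- function(mother_counts, daughter_counts,
                          mother_seq, daughter_seq,
                          params = cleanup_params()) {
  if (sum(mother_counts) < sum(daughter_counts)) {
    abort("Mother must be at least as prevalent as daughter; reorder the pair.")
  }
  d <- levenshtein(mother_seq, daughter_seq)
  sc <- loglik_score(daughter_counts, mother_counts, params)
  verdict_row(mother_seq, daughter_seq, d, sc, params)
}

verdict_row <- function(mother_seq, daughter_seq, d, sc, params) {
  score_ok <- !is.na(sc$loglik) && sc$loglik > sc$threshold
  if (d > params$max_dist) {
    verdict <- "not-daughter"; reason <- "distance"
  } else if (sc$ratio > params$max_ratio) {
    verdict <- "not-daughter"; reason <- "ratio"
  } else if (!score_ok) {
    verdict <- "not-daughter"; reason <- "score"
  } else {
    verdict <- "daughter"; reason <- NA_character_
  }
  tibble(
    mother = mother_seq, daughter = daughter_seq, distance = as.integer(d),
    total_daughter = sc$total_daughter, total_mother = sc$total_mother,
    ratio = sc$ratio, n_qualifying = sc$n_qualifying,
    loglik = sc$loglik, threshold = sc$threshold,
    verdict = verdict, reason = reason
  )
}

#' Clean one sequencing lane
#'
#' The greedy prevalence-ordered clean-up. After the [prefilter()], barcodes
#' are sorted by lane-total reads (descending, ties broken lexicographically
#' by sequence). The most prevalent unprocessed barcode is fixed as a
#' potential mother and compared against every remaining less prevalent
#' barcode; all barcodes with verdict `"daughter"` are removed from further
#' consideration (they are never later considered as mothers). The loop
#' continues until every barcode is either removed as a daughter or retained
#' as true. Retained barcodes keep their original counts unchanged — reads
#' from spurious barcodes are removed, never merged into the mother.
#'
#' Pair evaluations are lazy: the Levenshtein distance prunes most pairs, and
#' the ratio and score are only computed within `max_dist`. Pairs pruned on
#' distance are recorded with `NA` score fields.
#'
#' @param counts A barcode-by-sample count tibble for a single lane.
#' @param params A [cleanup_params()] object.
#' @return A `barcode_cleanup` object: list with `retained` (count tibble),
#'   `pairs` (all evaluated pairs), `removed_as_daughter` (the verdict-
#'   daughter subset), `prefiltered`, `params`, and per-lane `summary`.
#'   Use [tidy()] for one row per input barcode, [glance()] for the summary,
#'   [autoplot()] for the score-vs-reads plot.
#' @examples
#' sim <- simulate_experiment(simulation_config(seed = 1))
#' res <- clean_lane(sim$lanes[[1]]$counts)
#' glance(res)
#' @export
clean_lane <- function(counts, params = cleanup_params()) {
  t0 <- proc.time()[["elapsed"]]
  validate_counts(counts)
  pf <- prefilter(counts, params)
  kept <- pf$kept

  seqs <- kept$barcode
  mat <- count_matrix(kept)
  totals <- rowSums(mat)
  ord <- order(-totals, seqs)
  seqs <- seqs[ord]
  mat <- mat[ord, , drop = FALSE]
  totals <- totals[ord]

  nb <- length(seqs)
  active <- rep(TRUE, nb)
  claimed_by <- rep(NA_character_, nb)
  pair_rows <- list()

  for (i in seq_len(nb)) {
    if (!active[i]) next               # removed daughters never become mothers
    cand <- which(active & seq_len(nb) > i)
    if (length(cand) == 0) next
    d <- levenshtein_to_many(seqs[i], seqs[cand])
    near <- d <= params$max_dist
    if (any(!near)) {
      pair_rows[[length(pair_rows) + 1]] <- tibble(
        mother = seqs[i], daughter = seqs[cand[!near]],
        distance = d[!near],
        total_daughter = totals[cand[!near]], total_mother = totals[i],
        ratio = NA_real_, n_qualifying = NA_integer_,
        loglik = NA_real_, threshold = NA_real_,
        verdict = "not-daughter", reason = "distance"
      )
    }
    for (k in which(near)) {
      j <- cand[k]
      sc <- loglik_score(mat[j, ], mat[i, ], params)
      row <- verdict_row(seqs[i], seqs[j], d[k], sc, params)
      pair_rows[[length(pair_rows) + 1]] <- row
      if (row$verdict == "daughter") {
        active[j] <- FALSE
        claimed_by[j] <- seqs[i]
      }
    }
  }

  pairs <- if (length(pair_rows) > 0) bind_rows(pair_rows) else tibble(
    mother = character(), daughter = character(), distance = integer(),
    total_daughter = numeric(), total_mother = numeric(),
    ratio = numeric(), n_qualifying = integer(), loglik = numeric(),
    threshold = numeric(), verdict = character(), reason = character()
  )

  retained_seqs <- seqs[active]
  retained <- kept[match(retained_seqs, kept$barcode), , drop = FALSE]
  retained <- retained[order(-lane_totals(retained), retained$barcode), ,
                       drop = FALSE]

  res <- structure(
    list(
      retained = retained,
      pairs = pairs,
      removed_as_daughter = pairs[pairs$verdict == "daughter", , drop = FALSE],
      prefiltered = pf$removed,
      rescued = character(0),
      params = params,
      summary = tibble(
        barcodes_in = nrow(counts),
        prefiltered = nrow(pf$removed),
        removed_as_daughter = sum(!active),
        retained = sum(active),
        elapsed_s = proc.time()[["elapsed"]] - t0
      )
    ),
    class = "barcode_cleanup"
  )
  res
}

#' Fixed read-threshold baseline filter
#'
#' The conventional alternative the clean-up is compared against: retain
#' every barcode whose lane-total read count is at least `threshold`, with no
#' use of sequence similarity or cross-sample structure.
#'
#' @param counts A barcode-by-sample count tibble.
#' @param threshold Positive integer read threshold.
#' @return Character vector of retained barcode sequences.
#' @export
read_threshold_filter <- function(counts, threshold) {
  validate_counts(counts)
  if (threshold < 1) abort("`threshold` must be >= 1.")
  counts$barcode[lane_totals(counts) >= threshold]
}

#' @export
print.barcode_cleanup <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "Barcode clean-up: %d barcodes in; %d prefiltered, %d removed as ",
    "daughters, %d retained (%.2fs)\n"),
    s$barcodes_in, s$prefiltered, s$removed_as_daughter, s$retained,
    s$elapsed_s))
  if (length(x$rescued) > 0) {
    cat(sprintf("  incl. %d rescued via reference library\n", length(x$rescued)))
  }
  invisible(x)
}

#' Tidy a clean-up result into one row per input barcode
#'
#' @param x A `barcode_cleanup` object.
#' @param ... Unused.
#' @return A tibble with `barcode`, `total_reads`, `status` (one of
#'   `retained`, `daughter`, `prefiltered`, `rescued`), `mother` (claiming
#'   mother for daughters) and `reason` (prefilter reason).
#' @method tidy barcode_cleanup
#' @export
tidy.barcode_cleanup <- function(x, ...) {
  ret <- tibble(
    barcode = x$retained$barcode,
    total_reads = unname(lane_totals(x$retained)),
    status = ifelse(x$retained$barcode %in% x$rescued, "rescued", "retained"),
    mother = NA_character_, reason = NA_character_
  )
  dght <- x$removed_as_daughter
  dau <- tibble(
    barcode = dght$daughter,
    total_reads = dght$total_daughter,
    status = "daughter", mother = dght$mother, reason = NA_character_
  )
  pre <- tibble(
    barcode = x$prefiltered$barcode,
    total_reads = x$prefiltered$total_reads,
    status = "prefiltered", mother = NA_character_,
    reason = x$prefiltered$reason
  )
  bind_rows(ret, dau, pre)
}

#' Summarize a clean-up result in one row
#'
#' @param x A `barcode_cleanup` object.
#' @param ... Unused.
#' @return The per-lane summary tibble (counts in/out and wall time).
#' @method glance barcode_cleanup
#' @export
glance.barcode_cleanup <- function(x, ...) {
  x$summary
}

#' Plot pair scores against daughter read totals
#'
#' Scatter of the log-likelihood score of every scored pair against the
#' log10 lane-total reads of the candidate daughter, with the acceptance
#' threshold line; accepted pairs lie above the line.
#'
#' @param object A `barcode_cleanup` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot barcode_cleanup
#' @export
autoplot.barcode_cleanup <- function(object, ...) {
  pr <- object$pairs
  pr <- pr[!is.na(pr$loglik), , drop = FALSE]
  ggplot2::ggplot(pr, ggplot2::aes(x = log10(.data$total_daughter),
                                   y = .data$loglik,
                                   colour = .data$verdict)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$params$slope_a,
                         intercept = object$params$offset_b,
                         linetype = "dashed") +
    ggplot2::labs(x = "log10 total daughter reads",
                  y = "log-likelihood score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
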