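#' Configuration for the synthetic barcoding experiment
#'
#' The generator emulates the training design used to develop the clean-up
#' method: `n_mothers` clones carrying distinct barcodes are mixed in a
#' geometric abundance series (two-fold steps by default, spanning roughly a
#' 5e5-fold range at the defaults), in two base mixes — the series and its
#' reverse — so that every clone is abundant in one of the two mixes. Each
#' replicate group (a biological sample) draws cells from one mix at a total
#' in a dilution series, splits them binomially into two technical
#' replicates, and is sequenced to `reads_per_sample` reads per replicate.
#' Each mother spawns `errors_per_mother` distinct error daughters whose
#' per-error rate `e` is log-uniform on `10^error_rate_log10_range`,
#' constant across samples within a lane but jittered by up to
#' `between_lane_rate_factor`-fold between lanes; daughter counts are drawn
#' beta-binomially with trials `m_i`, mean `e` and overdispersion
#' `e / overdispersion_divisor`. Replicate-specific early-PCR artifacts and
#' rare physical contaminants are injected into single replicates only.
#'
#' @param n_mothers Number of true clones (default 20).
#' @param abundance_ratio Step of the geometric clone-size series (default 2).
#' @param smallest_clone Cells of the smallest clone in the base mix
#'   (default 10).
#' @param n_replicate_groups Biological samples per lane; each contributes
#'   two technical-replicate columns (default 10, i.e. 20 samples).
#' @param n_lanes Number of sequencing lanes (default 1).
#' @param barcode_length Barcode length in nucleotides (default 15).
#' @param errors_per_mother Distinct error daughters per mother (default 10).
#' @param error_rate_log10_range Range of log10 per-error rates within a
#'   lane (default `c(-5, log10(0.05))`: error rates above ~5% are rare in
#'   practice). Each error's geometric-mean rate is log-uniform on this
#'   range shrunk by the jitter half-width, so realized lane rates always
#'   respect the bounds.
#' @param between_lane_rate_factor Maximum between-lane fold-change of a
#'   given error's rate (default 10).
#' @param overdispersion_divisor Daughter-count overdispersion is
#'   `e / overdispersion_divisor` (default 10).
#' @param pcr_error_rate Probability that a given (mother, replicate) pair
#'   acquires an early-PCR artifact barcode (default 0.01; early-PCR errors
#'   are rare).
#' @param contaminant_count Physical contaminant barcodes per lane
#'   (default 3).
#' @param noise_tail_count Distinct rare error sequences per lane (default
#'   2000): the background of multi-error reads at a handful of reads each.
#'   In raw barcoding data the vast majority of distinct sequences are such
#'   rare spurious variants; they dominate the row count of the raw table
#'   while contributing almost no reads.
#' @param reads_per_sample Sequencing depth per technical replicate
#'   (default 1e5).
#' @param sample_cells_range Range of total cells per replicate group; group
#'   totals are log-spaced across this range, emulating a dilution series
#'   (default `c(1e3, 2.1e5)`).
#' @param error_distance_probs Probabilities of an error daughter lying at
#'   substitution distance 1..4 from its mother (default
#'   `c(0.75, 0.15, 0.06, 0.04)`, mean ~1.4).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A `simulation_config` object (named list).
#' @export
simulation_config <- function(n_mothers = 20L,
                              abundance_ratio = 2,
                              smallest_clone = 10,
                              n_replicate_groups = 10L,
                              n_lanes = 1L,
                              barcode_length = 15L,
                              errors_per_mother = 10L,
                              error_rate_log10_range = c(-5, log10(0.05)),
                              between_lane_rate_factor = 10,
                              overdispersion_divisor = 10,
                              pcr_error_rate = 0.01,
                              contaminant_count = 3L,
                              noise_tail_count = 2000L,
                              reads_per_sample = 1e5,
                              sample_cells_range = c(1e3, 2.1e5),
                              error_distance_probs = c(0.75, 0.15, 0.06, 0.04),
                              seed = NULL) {
  cfg <- list(
    n_mothers = as.integer(n_mothers),
    abundance_ratio = abundance_ratio,
    smallest_clone = smallest_clone,
    n_replicate_groups = as.integer(n_replicate_groups),
    n_lanes = as.integer(n_lanes),
    barcode_length = as.integer(barcode_length),
    errors_per_mother = as.integer(errors_per_mother),
    error_rate_log10_range = error_rate_log10_range,
    between_lane_rate_factor = between_lane_rate_factor,
    overdispersion_divisor = overdispersion_divisor,
    pcr_error_rate = pcr_error_rate,
    contaminant_count = as.integer(contaminant_count),
    noise_tail_count = as.integer(noise_tail_count),
    reads_per_sample = reads_per_sample,
    sample_cells_range = sample_cells_range,
    error_distance_probs = error_distance_probs,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  stopifnot(
    cfg$n_mothers >= 1, cfg$abundance_ratio > 1, cfg$smallest_clone >= 1,
    cfg$n_replicate_groups >= 1, cfg$n_lanes >= 1, cfg$barcode_length >= 1,
    cfg$errors_per_mother >= 0,
    length(cfg$error_rate_log10_range) == 2,
    diff(cfg$error_rate_log10_range) >= 0,
    10^cfg$error_rate_log10_range[2] < 1,
    cfg$between_lane_rate_factor >= 1,
    cfg$overdispersion_divisor > 1,
    cfg$pcr_error_rate >= 0, cfg$pcr_error_rate < 1,
    cfg$contaminant_count >= 0, cfg$noise_tail_count >= 0,
    cfg$reads_per_sample >= 1,
    length(cfg$sample_cells_range) == 2,
    all(cfg$sample_cells_range >= 1),
    length(cfg$error_distance_probs) >= 1,
    all(cfg$error_distance_probs >= 0), sum(cfg$error_distance_probs) > 0
  )
  structure(cfg, class = "simulation_config")
}

#' All single-substitution variants of a sequence
#'
#' Every sequence obtainable by exactly one base substitution: `3 * nchar(seq)`
#' variants (a 100-mer has 300), the original excluded. This is the
#' combinatorial reason most detected sequences are spurious even at a low
#' per-base error rate.
#'
#' @param seq A non-empty A/C/G/T string.
#' @return Character vector of variants.
#' @examples
#' enumerate_snv_variants("A")
#' length(enumerate_snv_variants(strrep("A", 100))) # 300
#' @export
enumerate_snv_variants <- function(seq) {
  if (length(seq) != 1 || is.na(seq) || !nzchar(seq) ||
      !grepl("^[ACGT]+$", seq)) {
    abort("`seq` must be a non-empty A/C/G/T string.")
  }
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (i in seq_along(chars)) {
    for (b in setdiff(bases, chars[i])) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  unique(out)
}

#' Expected fraction of error-free reads
#'
#' With a uniform per-base error rate `e`, a stretch of `length` bases is
#' read without error with probability `(1 - e)^length` (about 0.90 for
#' e = 0.001 over 100 bases).
#'
#' @param per_base_error Per-base error probability in `[0, 1)`.
#' @param length Number of bases (>= 0).
#' @return `(1 - per_base_error)^length`.
#' @export
correct_read_fraction <- function(per_base_error, length) {
  if (any(per_base_error < 0) || any(per_base_error >= 1)) {
    abort("`per_base_error` must be in [0, 1).")
  }
  if (any(length < 0)) abort("`length` must be >= 0.")
  (1 - per_base_error)^length
}

#' Draw beta-binomial counts
#'
#' @param n Number of draws.
#' @param size Trial count(s), recycled.
#' @param shape A [bb_shape()] object.
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(n, size, shape) {
  stopifnot(inherits(shape, "bb_shape"))
  p <- rbeta(n, shape$alpha, shape$beta)
  rbinom(n, rep_len(size, n), p)
}

random_sequences <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# n sequences pairwise (and vs `avoid`) at Levenshtein distance > min_gap
spaced_sequences <- function(n, len, min_gap, avoid = character(0),
                             max_tries = 1000 * n) {
  if (4^min(len, 30) < n + length(avoid)) {
    abort("Sequence space too small for the requested number of barcodes.")
  }
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort("Could not place barcodes at the requested spacing; sequence space exhausted.")
    }
    cand <- random_sequences(1, len)
    ref <- c(out, avoid)
    if (length(ref) == 0 || all(levenshtein_to_many(cand, ref) > min_gap)) {
      out <- c(out, cand)
    }
  }
  out
}

substitute_at_distance <- function(seq, d) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), d)
  for (i in pos) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a multi-lane cellular barcoding experiment
#'
#' Generates per-lane barcode-by-sample count tables with the statistical
#' structure the clean-up method assumes, together with full ground truth.
#' See [simulation_config()] for the generative model. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [simulation_config()] object.
#' @return A `barcode_sim` object: list with `lanes` (named list of
#'   `list(counts, meta)` per lane), `truth` (tibbles `mothers`,
#'   `error_daughters`, `error_rates`, `pcr_artifacts`, `contaminants`) and
#'   `config`.
#' @examples
#' sim <- simulate_experiment(simulation_config(seed = 42))
#' sim$lanes$lane1$counts
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config

  needed <- cfg$n_mothers * (1 + cfg$errors_per_mother) +
    cfg$n_lanes * (cfg$contaminant_count + cfg$noise_tail_count)
  if (needed > 4^min(cfg$barcode_length, 30)) {
    abort("Config demands more unique sequences than the sequence space holds.")
  }

  # mothers spaced > max usable daughter distance apart so no true barcode can
  # sit inside another's acceptance region
  mothers <- spaced_sequences(cfg$n_mothers, cfg$barcode_length, min_gap = 4L)
  clone_sizes <- cfg$smallest_clone *
    cfg$abundance_ratio^(seq_len(cfg$n_mothers) - 1)

  # error daughters: sequence, target substitution distance, base rate.
  # The geometric-mean rate is drawn from the configured range shrunk by the
  # between-lane jitter half-width, so every lane's realized rate stays
  # within `error_rate_log10_range`.
  half_jitter <- log10(cfg$between_lane_rate_factor) / 2
  rng <- cfg$error_rate_log10_range
  base_rng <- c(rng[1] + half_jitter, rng[2] - half_jitter)
  if (base_rng[1] > base_rng[2]) base_rng <- rep(mean(rng), 2)
  all_seqs <- mothers
  daughters <- vector("list", cfg$n_mothers)
  dprobs <- cfg$error_distance_probs / sum(cfg$error_distance_probs)
  for (j in seq_len(cfg$n_mothers)) {
    if (cfg$errors_per_mother == 0) {
      daughters[[j]] <- tibble(mother = character(), barcode = character(),
                               distance = integer(), base_rate = numeric())
      next
    }
    seqs <- character(cfg$errors_per_mother)
    dists <- integer(cfg$errors_per_mother)
    for (k in seq_len(cfg$errors_per_mother)) {
      repeat {
        d <- sample.int(length(dprobs), 1, prob = dprobs)
        cand <- substitute_at_distance(mothers[j], min(d, cfg$barcode_length))
        if (!cand %in% all_seqs) break
      }
      seqs[k] <- cand
      dists[k] <- levenshtein(mothers[j], cand)
      all_seqs <- c(all_seqs, cand)
    }
    daughters[[j]] <- tibble(
      mother = mothers[j], barcode = seqs, distance = dists,
      base_rate = 10^runif(cfg$errors_per_mother, base_rng[1], base_rng[2])
    )
  }
  daughters <- bind_rows(daughters)

  # replicate-group design: alternate forward / reversed mixes, dilution series
  G <- cfg$n_replicate_groups
  mix_forward <- clone_sizes / sum(clone_sizes)
  mix_reverse <- rev(clone_sizes) / sum(clone_sizes)
  group_cells <- exp(seq(log(cfg$sample_cells_range[1]),
                         log(cfg$sample_cells_range[2]), length.out = G))

  lanes <- list()
  rate_rows <- list()
  pcr_rows <- list()
  cont_rows <- list()
  tail_rows <- list()
  f <- cfg$between_lane_rate_factor

  for (l in seq_len(cfg$n_lanes)) {
    lane_id <- sprintf("lane%d", l)
    jitter <- 10^runif(nrow(daughters), -half_jitter, half_jitter)
    lane_rates <- daughters$base_rate * jitter
    if (nrow(daughters) > 0) {
      rate_rows[[l]] <- tibble(lane_id = lane_id,
                               barcode = daughters$barcode,
                               mother = daughters$mother,
                               rate = lane_rates)
    }

    n_samp <- 2 * G
    sample_ids <- as.vector(t(outer(seq_len(G), c("r1", "r2"),
                                    function(g, r) sprintf("%s_g%02d_%s", lane_id, g, r))))
    rep_groups <- rep(sprintf("%s_g%02d", lane_id, seq_len(G)), each = 2)

    # mother reads: Poisson cells per clone, binomial replicate split,
    # multinomial sequencing to fixed depth
    M <- matrix(0, nrow = cfg$n_mothers, ncol = n_samp,
                dimnames = list(mothers, sample_ids))
    for (g in seq_len(G)) {
      mix <- if (g %% 2 == 1) mix_forward else mix_reverse
      cells <- rpois(cfg$n_mothers, mix * group_cells[g])
      r1 <- rbinom(cfg$n_mothers, cells, 0.5)
      r2 <- cells - r1
      for (rr in 1:2) {
        cc <- if (rr == 1) r1 else r2
        col <- (g - 1) * 2 + rr
        if (sum(cc) > 0) {
          M[, col] <- rmultinom(1, cfg$reads_per_sample, prob = cc)
        }
      }
    }

    # error-daughter reads: beta-binomial around rate * mother reads
    D <- matrix(0, nrow = nrow(daughters), ncol = n_samp,
                dimnames = list(daughters$barcode, sample_ids))
    if (nrow(daughters) > 0) {
      mi <- match(daughters$mother, mothers)
      for (k in seq_len(nrow(daughters))) {
        e <- lane_rates[k]
        shape <- bb_shape(e, e / cfg$overdispersion_divisor)
        D[k, ] <- rbetabinom(n_samp, M[mi[k], ], shape)
      }
    }

    # early-PCR artifacts: one replicate only, small fraction of the mother
    pcr <- list()
    if (cfg$pcr_error_rate > 0) {
      hit <- which(matrix(runif(cfg$n_mothers * n_samp) < cfg$pcr_error_rate,
                          nrow = cfg$n_mothers), arr.ind = TRUE)
      for (h in seq_len(nrow(hit))) {
        j <- hit[h, 1]; s <- hit[h, 2]
        reads <- round(runif(1, 0.001, 0.02) * M[j, s])
        if (reads < 1) next
        repeat {
          cand <- substitute_at_distance(mothers[j], 1)
          if (!cand %in% all_seqs) break
        }
        all_seqs <- c(all_seqs, cand)
        pcr[[length(pcr) + 1]] <- tibble(
          lane_id = lane_id, sample_id = sample_ids[s],
          mother = mothers[j], barcode = cand, reads = reads
        )
      }
    }
    pcr <- if (length(pcr) > 0) bind_rows(pcr) else tibble(
      lane_id = character(), sample_id = character(), mother = character(),
      barcode = character(), reads = numeric())
    pcr_rows[[l]] <- pcr

    # physical contaminants: real but foreign barcodes, one replicate only
    cont <- tibble(lane_id = character(), sample_id = character(),
                   barcode = character(), reads = numeric())
    if (cfg$contaminant_count > 0) {
      cseqs <- spaced_sequences(cfg$contaminant_count, cfg$barcode_length,
                                min_gap = 4L, avoid = all_seqs)
      all_seqs <- c(all_seqs, cseqs)
      cont <- tibble(
        lane_id = lane_id,
        sample_id = sample(sample_ids, cfg$contaminant_count, replace = TRUE),
        barcode = cseqs,
        reads = rnbinom(cfg$contaminant_count, mu = 400, size = 2)
      )
      cont <- cont[cont$reads > 0, , drop = FALSE]
    }
    cont_rows[[l]] <- cont

    # rare multi-error background: many distinct sequences, a few reads each,
    # derived from abundant mothers (read-weighted) at distances 1-4
    tail_tbl <- tibble(sample_id = character(), barcode = character(),
                       reads = numeric(), mother = character(),
                       distance = integer())
    if (cfg$noise_tail_count > 0) {
      mother_w <- rowSums(M) + 1
      src <- sample(cfg$n_mothers, ceiling(1.2 * cfg$noise_tail_count),
                    replace = TRUE, prob = mother_w)
      dd <- sample(1:4, length(src), replace = TRUE,
                   prob = c(0.35, 0.3, 0.2, 0.15))
      cand <- vapply(seq_along(src), function(h) {
        substitute_at_distance(mothers[src[h]],
                               min(dd[h], cfg$barcode_length))
      }, character(1))
      keep <- !duplicated(cand) & !cand %in% all_seqs
      cand <- cand[keep][seq_len(min(cfg$noise_tail_count, sum(keep)))]
      src <- src[keep][seq_along(cand)]
      dd <- dd[keep][seq_along(cand)]
      all_seqs <- c(all_seqs, cand)
      tail_tbl <- tibble(
        sample_id = sample(sample_ids, length(cand), replace = TRUE),
        barcode = cand,
        reads = 1 + rpois(length(cand), 0.7),
        mother = mothers[src],
        distance = dd
      )
    }
    tail_rows[[l]] <- dplyr::bind_cols(tibble(lane_id = lane_id),
                                       tail_tbl[c("barcode", "mother",
                                                  "distance", "reads",
                                                  "sample_id")])

    # assemble the lane table: mothers always present, daughters if observed
    extra <- bind_rows(
      pcr[c("sample_id", "barcode", "reads")],
      cont[c("sample_id", "barcode", "reads")],
      tail_tbl[c("sample_id", "barcode", "reads")]
    )
    X <- matrix(0, nrow = length(all_seqs_lane <- c(mothers, daughters$barcode,
                                                    unique(extra$barcode))),
                ncol = n_samp, dimnames = list(all_seqs_lane, sample_ids))
    X[mothers, ] <- M
    if (nrow(daughters) > 0) X[daughters$barcode, ] <- D
    for (h in seq_len(nrow(extra))) {
      X[extra$barcode[h], extra$sample_id[h]] <-
        X[extra$barcode[h], extra$sample_id[h]] + extra$reads[h]
    }
    observed <- rownames(X) %in% mothers | rowSums(X) > 0
    X <- X[observed, , drop = FALSE]

    counts <- dplyr::bind_cols(tibble(barcode = rownames(X)),
                               as_tibble(`rownames<-`(X, NULL)))
    meta <- tibble(
      sample_id = sample_ids, lane_id = lane_id,
      replicate_group = rep_groups,
      index_sequence = random_index_set(n_samp)
    )
    lanes[[lane_id]] <- list(counts = counts, meta = meta)
  }

  structure(
    list(
      lanes = lanes,
      truth = list(
        mothers = tibble(barcode = mothers, clone = seq_len(cfg$n_mothers),
                         cells_base = clone_sizes),
        error_daughters = daughters,
        error_rates = bind_rows(rate_rows),
        pcr_artifacts = bind_rows(pcr_rows),
        contaminants = bind_rows(cont_rows),
        noise_tail = bind_rows(tail_rows)
      ),
      config = cfg
    ),
    class = "barcode_sim"
  )
}

# unique index sequences for one lane (8-mers, pairwise distinct)
random_index_set <- function(n, len = 8L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_sequences(n - length(out), len)
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Ground-truth barcode sets of a simulated lane
#'
#' `sim_true_barcodes()` returns the sequences genuinely present as
#' molecules in the lane: the mother clones plus any physical contaminants
#' (in a real experiment, contaminants are true barcodes from elsewhere and
#' would sit in the reference library). `sim_spurious_barcodes()` returns
#' the error-derived sequences: beta-binomial error daughters and early-PCR
#' artifacts.
#'
#' @param sim A `barcode_sim` object.
#' @param lane_id Lane identifier (default first lane).
#' @return Character vector of barcode sequences.
#' @export
sim_true_barcodes <- function(sim, lane_id = names(sim$lanes)[1]) {
  stopifnot(inherits(sim, "barcode_sim"))
  cont <- sim$truth$contaminants
  c(sim$truth$mothers$barcode,
    cont$barcode[cont$lane_id == lane_id])
}

#' @rdname sim_true_barcodes
#' @export
sim_spurious_barcodes <- function(sim, lane_id = names(sim$lanes)[1]) {
  stopifnot(inherits(sim, "barcode_sim"))
  pcr <- sim$truth$pcr_artifacts
  tl <- sim$truth$noise_tail
  c(sim$truth$error_daughters$barcode,
    pcr$barcode[pcr$lane_id == lane_id],
    tl$barcode[tl$lane_id == lane_id])
}

#' @export
print.barcode_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated barcoding experiment: %d lane(s), %d mothers, %d error daughters\n",
    length(x$lanes), nrow(x$truth$mothers), nrow(x$truth$error_daughters)))
  invisible(x)
}

#' Emit a simulated count table as FASTQ
#'
#' Wraps each barcode of a lane in a configurable primer + index scaffold so
#' the demultiplexing stage can be exercised end-to-end: each read is
#' `filler | primer_constant | post-primer window` with the sample index and
#' barcode placed at the spec's offsets, repeated once per counted read.
#' No additional errors are injected. Counts should be small; one FASTQ
#' record is written per read.
#'
#' @param counts A barcode-by-sample count tibble.
#' @param spec An [extraction_spec()] whose `index_to_sample` covers every
#'   sample column of `counts`.
#' @param path Output FASTQ path (plain text; `.gz` gets gzip-compressed).
#' @param filler_length Bases of A-filler before the primer (default 4).
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(counts, spec, path, filler_length = 4L) {
  validate_counts(counts)
  stopifnot(inherits(spec, "extraction_spec"))
  samples <- sample_cols(counts)
  idx_of <- setNames(names(spec$index_to_sample), spec$index_to_sample)
  missing <- setdiff(samples, names(idx_of))
  if (length(missing) > 0) {
    abort(paste0("No index for sample(s): ", paste(missing, collapse = ", ")))
  }
  post_len <- max(spec$index_offset + spec$index_length,
                  spec$barcode_offset + spec$barcode_length)
  lines <- character(0)
  read_no <- 0
  for (s in samples) {
    idx <- idx_of[[s]]
    for (i in seq_len(nrow(counts))) {
      nread <- counts[[s]][i]
      if (nread == 0) next
      post <- strrep("A", post_len)
      substr(post, spec$index_offset + 1,
             spec$index_offset + spec$index_length) <- idx
      substr(post, spec$barcode_offset + 1,
             spec$barcode_offset + spec$barcode_length) <- counts$barcode[i]
      seq <- paste0(strrep("A", filler_length), spec$primer_constant, post)
      for (r in seq_len(nread)) {
        read_no <- read_no + 1
        lines <- c(lines, sprintf("@read%d", read_no), seq, "+",
                   strrep("I", nchar(seq)))
      }
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
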