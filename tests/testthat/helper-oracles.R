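# Independent oracles used to cross-check the implementation.

# Full dynamic-programming Levenshtein table, O(nm), no shortcuts.
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(
        D[i, j + 1] + 1L,
        D[i + 1, j] + 1L,
        D[i, j] + (x[i] != y[j])
      )
    }
  }
  D[n + 1, m + 1]
}

# Beta-binomial log mass by direct term-wise products of the ascending
# factorials (independent of the lchoose/lbeta route used in the package):
# P(c | n) = C(n,c) * prod_{j<c}(a+j) * prod_{j<n-c}(b+j) / prod_{j<n}(a+b+j)
bb_log_oracle <- function(c, n, alpha, beta) {
  if (c > n) return(-Inf)
  term <- function(z, k) if (k == 0) 0 else sum(log(z + 0:(k - 1)))
  lchoose(n, c) + term(alpha, c) + term(beta, n - c) - term(alpha + beta, n)
}

# Pair score recomputed from scratch with the oracle density.
loglik_oracle <- function(dc, mc, params = cleanup_params()) {
  r <- sum(dc) / sum(mc)
  s <- 1 / (r / params$rho_divisor) - 1
  alpha <- r * s
  beta <- (1 - r) * s
  qual <- mc >= params$min_sample_reads | dc >= params$min_sample_reads
  vals <- mapply(function(c, n) {
    max(bb_log_oracle(c, n, alpha, beta), log(1e-300))
  }, dc[qual], mc[qual])
  mean(vals)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Hand-sized count table: barcodes x samples from a named list of count rows.
make_counts <- function(rows, sample_ids = NULL) {
  n <- length(rows[[1]])
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  out <- tibble::tibble(barcode = names(rows))
  for (k in seq_len(n)) out[[sample_ids[k]]] <- vapply(rows, `[`, numeric(1), k)
  out
}
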