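# Small in-code fixtures shared across test files.

# deterministic probe x sample expression_matrix
tiny_matrix <- function(n_probes = 6, n_samples = 4, seed = 1, log2 = TRUE,
                        detection = FALSE, slide_size = 2) {
  set.seed(seed)
  v <- matrix(rnorm(n_probes * n_samples, 8, 1), n_probes,
              dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_samples))))
  dp <- if (detection) matrix(runif(n_probes * n_samples, 0, 0.009),
                              n_probes, dimnames = dimnames(v)) else NULL
  expression_matrix(v, gene_symbols = sprintf("G%03d", seq_len(n_probes)),
                    detection_p = dp,
                    slide = sprintf("sl%d", (seq_len(n_samples) - 1) %/% slide_size + 1),
                    log2 = log2)
}

tiny_annotation <- function(sample_ids, ethnicity = NULL, stage = NULL) {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             patient_id = sprintf("PT%02d", seq_len(n)),
             ethnicity = ethnicity %||% rep(c("AA", "EA"), length.out = n),
             stage = stage %||% rep(1:2, length.out = n),
             nodal = rep(c("pos", "neg"), length.out = n),
             age = 50 + seq_len(n),
             tissue_site = "primary",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive enumeration oracle: P(longest undetectable run >= k) for n
# Bernoulli trials with detect probability det_rate
run_pvalue_enum <- function(n, k, det_rate) {
  total <- 0
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]  # 1 = undetectable
    r <- rle(bits)
    longest <- if (any(r$values == 1)) max(r$lengths[r$values == 1]) else 0
    if (longest >= k)
      total <- total + (1 - det_rate)^sum(bits) * det_rate^(n - sum(bits))
  }
  total
}

# brute-force one-sided hypergeometric over-representation oracle:
# enumerate all selections of the given size from the universe
hyper_enum <- function(overlap, set_size, universe_size, selection_size) {
  sets <- utils::combn(universe_size, selection_size)
  in_set <- seq_len(set_size)  # wlog the set is the first set_size genes
  hits <- colSums(matrix(sets %in% in_set, nrow = selection_size))
  mean(hits >= overlap)
}

# brute-force BH: adj_i = min over j with p_(j) >= p_(i) of m * p_(j) / j
bh_enum <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(ord == i)  # rank of p[i]
    cand <- sapply(ri:m, function(j) m * p[ord[j]] / j)
    adj[i] <- min(1, min(cand))
  }
  adj
}
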