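#' QC report for the preprocessing pipeline
#'
#' Records, per filtering step, the probe/sample dimensions in and out plus
#' step-specific details (per-sample detectable fractions, probes removed by
#' the batch-run filter with their run p-values, outlier cell counts).
#' Step counts telescope: each step's input dims equal the previous step's
#' output dims.
#'
#' @param steps data.frame with columns step, n_samples_in, n_probes_in,
#'   n_samples_out, n_probes_out.
#' @param details named list of step-specific payloads.
#' @return a `qc_report`.
#' @export
qc_report <- function(steps, details = list()) {
  structure(list(steps = steps, details = details), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Combine QC reports from consecutive steps
#' @param ... `qc_report` objects in pipeline order.
#' @return a single `qc_report`.
#' @export
combine_qc <- function(...) {
  reps <- list(...)
  qc_report(do.call(rbind, lapply(reps, `[[`, "steps")),
            do.call(c, lapply(reps, `[[`, "details")))
}

step_row <- function(step, em_in, em_out) {
  data.frame(step = step,
             n_samples_in = ncol(em_in$values), n_probes_in = nrow(em_in$values),
             n_samples_out = ncol(em_out$values), n_probes_out = nrow(em_out$values),
             stringsAsFactors = FALSE)
}

#' Keep the best sample per patient
#'
#' Drops samples taken from sites other than the primary tumor, then, for
#' patients with several remaining samples, keeps the one with the highest
#' detectable-probe fraction (ties broken by sample id order).
#'
#' @param x an `expression_matrix` with detection p-values.
#' @param annotation annotation data.frame covering the samples
#'   (see [read_annotation()]).
#' @param detect_threshold detection p-value cut-off for "detectable".
#' @return an `expression_matrix` with one primary-site sample per patient.
#' @export
select_best_sample <- function(x, annotation, detect_threshold = 0.01) {
  if (is.null(x$detection_p))
    stop("select_best_sample needs detection p-values (quality score undefined)")
  ann <- annotation[match(colnames(x$values), annotation$sample_id), ]
  if (any(is.na(ann$sample_id)))
    stop("annotation missing for samples: ",
         paste(setdiff(colnames(x$values), annotation$sample_id), collapse = ", "))
  primary <- ann$tissue_site == "primary"
  det_frac <- colMeans(detectable_mask(x, detect_threshold))
  keep <- logical(ncol(x$values))
  for (p in unique(ann$patient_id[primary])) {
    idx <- which(primary & ann$patient_id == p)
    idx <- idx[order(-det_frac[idx], colnames(x$values)[idx])]
    keep[idx[1]] <- TRUE
  }
  x[, keep]
}

#' Detection-based sample and probe filter
#'
#' Removes samples with less than `sample_min` detectable probes first,
#' then probes detectable in less than `probe_min` of the remaining
#' samples (both strict "less than" at the stated fractions).
#'
#' @param x an `expression_matrix` with detection p-values.
#' @param sample_min minimum detectable-probe fraction per sample (default 0.30).
#' @param probe_min minimum fraction of samples a probe must be detected in
#'   (default 0.10).
#' @param detect_threshold detection p-value cut-off.
#' @return list with `matrix` (filtered `expression_matrix`) and `report`
#'   (a [qc_report()] with per-sample detectable fractions).
#' @export
detection_filter <- function(x, sample_min = 0.30, probe_min = 0.10,
                             detect_threshold = 0.01) {
  if (is.null(x$detection_p)) stop("detection_filter needs detection p-values")
  det <- detectable_mask(x, detect_threshold)
  samp_frac <- colMeans(det)
  keep_s <- samp_frac >= sample_min
  if (!any(keep_s)) stop("all samples removed by the detection filter")
  x1 <- x[, keep_s]
  probe_frac <- rowMeans(detectable_mask(x1, detect_threshold))
  keep_p <- probe_frac >= probe_min
  out <- x1[keep_p, ]
  rep <- qc_report(step_row("detection_filter", x, out),
                   list(detection_filter = list(
                     sample_detectable_fraction = samp_frac,
                     samples_removed = colnames(x$values)[!keep_s],
                     probes_removed = rownames(x1$values)[!keep_p])))
  list(matrix = out, report = rep)
}

#' Longest-run tail probability for Bernoulli detection calls
#'
#' Exact probability that the longest run of consecutive *undetectable*
#' outcomes is at least `k` among `n` independent calls that are each
#' detectable with probability `det_rate`. Computed by dynamic programming
#' over the trailing-run length, exact to machine precision; degenerate
#' rates return the analytic limit.
#'
#' @param n number of Bernoulli calls.
#' @param k run length of interest, `1 <= k <= n`.
#' @param det_rate per-call probability of a detectable outcome.
#' @return `P(longest undetectable run >= k)`.
#' @export
run_pvalue <- function(n, k, det_rate) {
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n")
  if (det_rate < 0 || det_rate > 1) stop("det_rate must lie in [0, 1]")
  if (det_rate == 0) return(1)  # all undetectable: run of n is certain
  if (det_rate == 1) return(0)
  q <- 1 - det_rate
  # state j in 0..k-1: P(no run >= k yet, trailing undetectable run = j)
  s <- c(1, numeric(k - 1))
  for (i in seq_len(n)) {
    s_new <- numeric(k)
    s_new[1] <- det_rate * sum(s)
    if (k > 1) s_new[2:k] <- q * s[1:(k - 1)]
    s <- s_new
  }
  max(0, min(1, 1 - sum(s)))
}

#' Filter probes with slide-clustered dropout
#'
#' WG-DASL slides carry batches of consecutive samples; a probe whose
#' undetectable calls cluster as a long consecutive run within one slide is
#' a batch artifact rather than biology. For each probe, the overall
#' detectable fraction is taken as the null detection rate; within each
#' slide, the longest observed run of undetectable samples gives an exact
#' tail probability via [run_pvalue()]; the probe's p-value is the smallest
#' per-slide tail probability Bonferroni-multiplied by the number of
#' slides. Probes with p < `alpha` are removed.
#'
#' @param x an `expression_matrix` with detection p-values and slide labels.
#' @param alpha removal threshold on the per-probe p-value (default 1e-4).
#' @param detect_threshold detection p-value cut-off.
#' @return list with `matrix` and `report`; the report details name each
#'   removed probe with its run p-value.
#' @export
batch_run_filter <- function(x, alpha = 1e-4, detect_threshold = 0.01) {
  if (is.null(x$detection_p)) stop("batch_run_filter needs detection p-values")
  if (is.null(x$slide)) stop("batch_run_filter needs slide labels")
  det <- detectable_mask(x, detect_threshold)
  slides <- unique(x$slide)
  n_slides <- length(slides)
  n_samp <- ncol(det)
  det_count <- rowSums(det)
  # longest undetectable run per probe per slide (samples in load order)
  run_tab <- new.env(parent = emptyenv())  # memoized run_pvalue lookups
  pv <- rep(1, nrow(det))
  for (s in slides) {
    cols <- which(x$slide == s)
    sub <- !det[, cols, drop = FALSE]
    ns <- length(cols)
    kmax <- apply(sub, 1, function(u) {
      r <- rle(u)
      m <- r$lengths[r$values]
      if (length(m)) max(m) else 0L
    })
    idx <- which(kmax > 0)
    for (i in idx) {
      key <- paste(ns, kmax[i], det_count[i], sep = "_")
      p <- run_tab[[key]]
      if (is.null(p)) {
        p <- run_pvalue(ns, kmax[i], det_count[i] / n_samp)
        run_tab[[key]] <- p
      }
      if (p < pv[i]) pv[i] <- p
    }
  }
  pv <- pmin(1, pv * n_slides)
  keep <- pv >= alpha
  out <- x[keep, ]
  rep <- qc_report(step_row("batch_run_filter", x, out),
                   list(batch_run_filter = list(
                     probes_removed = rownames(x$values)[!keep],
                     run_pvalues = pv[!keep])))
  list(matrix = out, report = rep)
}

#' Log2 transform, outlier masking and quantile normalization
#'
#' Raw intensities are log2-transformed (a matrix already flagged log2 is
#' not re-transformed). Per sample, values more than `outlier_sd` standard
#' deviations from the sample mean are masked as missing. The matrix is
#' then quantile-normalized over non-missing values: each sample's values
#' are replaced by the across-sample mean quantile function evaluated at
#' their within-sample ranks. Masked cells are imputed to the target
#' quantile of their within-sample rank (computed on the pre-masking
#' values) so downstream steps see a complete matrix; imputed cells are
#' flagged in the `imputed` slot. A matrix already flagged as normalized is
#' returned unchanged: outlier distance is defined relative to the
#' pre-normalization sample distributions, so the map is idempotent.
#'
#' @param x an `expression_matrix`.
#' @param outlier_sd per-sample outlier distance in SD units (default 3).
#' @return list with `matrix` (log2, normalized, complete) and `report`.
#' @export
normalize_expression <- function(x, outlier_sd = 3.0) {
  if (x$normalized) {
    return(list(matrix = x,
                report = qc_report(step_row("normalize", x, x),
                                   list(normalize = list(note = "already normalized")))))
  }
  v <- x$values
  if (!x$log2) {
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-positive raw intensity at probe '%s', sample '%s'",
                   rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
    v <- log2(v)
  }
  n <- nrow(v)
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  out_mask <- sweep(abs(sweep(v, 2, mu)), 2, ifelse(sdv > 0, outlier_sd * sdv, Inf), ">")
  miss <- out_mask | x$missing_mask
  # target quantile function on the common grid p_i = (i - 0.5)/n
  p_grid <- (seq_len(n) - 0.5) / n
  qs <- vapply(seq_len(ncol(v)), function(j) {
    vj <- sort(v[!miss[, j], j])
    m <- length(vj)
    if (m == 0) stop("sample '", colnames(v)[j], "' has no usable values")
    if (m == n) vj else
      stats::approx((seq_len(m) - 0.5) / m, vj, xout = p_grid, rule = 2)$y
  }, numeric(n))
  target <- rowMeans(qs)
  # assign every cell (masked cells included, via their pre-masking value)
  # the target quantile of its within-sample rank; masked cells are thereby
  # imputed and every sample carries the same value multiset afterwards
  norm <- v
  for (j in seq_len(ncol(v))) {
    r_full <- rank(v[, j], ties.method = "average")
    norm[, j] <- stats::approx(p_grid, target, xout = (r_full - 0.5) / n,
                               rule = 2)$y
  }
  out <- x
  out$values <- norm
  out$log2 <- TRUE
  out$normalized <- TRUE
  out$imputed <- miss
  rep <- qc_report(step_row("normalize", x, out),
                   list(normalize = list(
                     outlier_cells_per_sample = colSums(out_mask),
                     outlier_sd = outlier_sd,
                     outlier_scope = "per-sample")))
  list(matrix = out, report = rep)
}

#' Full preprocessing pipeline
#'
#' Fixed order: [select_best_sample()] (primary-site, best per patient) ->
#' [detection_filter()] -> [batch_run_filter()] -> [normalize_expression()].
#' The combined QC report's step counts telescope exactly.
#'
#' @param x an `expression_matrix` with detection p-values and slide labels.
#' @param annotation annotation data.frame.
#' @param sample_min,probe_min detection-filter fractions.
#' @param alpha batch-run filter threshold.
#' @param outlier_sd normalization outlier distance.
#' @param detect_threshold detection p-value cut-off.
#' @return list with `matrix` and combined `report`.
#' @export
preprocess_pipeline <- function(x, annotation, sample_min = 0.30, probe_min = 0.10,
                                alpha = 1e-4, outlier_sd = 3.0,
                                detect_threshold = 0.01) {
  best <- select_best_sample(x, annotation, detect_threshold)
  rep0 <- qc_report(step_row("select_best_sample", x, best))
  df <- detection_filter(best, sample_min, probe_min, detect_threshold)
  bf <- batch_run_filter(df$matrix, alpha, detect_threshold)
  nm <- normalize_expression(bf$matrix, outlier_sd)
  list(matrix = nm$matrix,
       report = combine_qc(rep0, df$report, bf$report, nm$report))
}

#' Log-transform a count matrix
#'
#' `log2(count + pseudocount)`, marking the result as log-scale so the
#' Pearson-correlation scoring path treats RNA-seq counts like normalized
#' microarray intensities.
#'
#' @param counts non-negative gene x sample count matrix, or an
#'   `expression_matrix` holding counts.
#' @param pseudocount added before the log (default 1).
#' @return same shape as the input, log2 scale; an `expression_matrix` in,
#'   an `expression_matrix` (flagged log2) out.
#' @export
log_transform_counts <- function(counts, pseudocount = 1) {
  v <- if (inherits(counts, "expression_matrix")) counts$values else counts
  if (any(v < 0)) stop("negative count")
  lv <- log2(v + pseudocount)
  if (inherits(counts, "expression_matrix")) {
    counts$values <- lv
    counts$log2 <- TRUE
    counts
  } else {
    attr(lv, "log2") <- TRUE
    lv
  }
}
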