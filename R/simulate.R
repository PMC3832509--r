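#' Synthetic stand-in gene signatures
#'
#' Builds disjoint synthetic signatures over the generator's gene universe
#' (symbols `G00001`, `G00002`, ...). These are stand-ins with the same
#' shape as published subtype/profile signatures — real-valued centroid
#' weights for subtype-like signatures, +/-1 for directional lists — not
#' the published gene lists, which are inputs to the pipeline.
#'
#' @param sizes named integer vector: signature name -> gene count.
#' @param weighted named logical (same names): TRUE for centroid weights
#'   drawn N(0, 1), FALSE for +/-1 directional weights. Defaults to
#'   centroid weights for all.
#' @param n_genes size of the gene universe the signatures index into.
#' @param seed integer seed.
#' @return named list of [gene_signature()] objects.
#' @export
synthetic_signatures <- function(sizes = c(basal = 100, lar = 80, msc = 80,
                                           vegf = 13),
                                 weighted = NULL, n_genes = 2000, seed = 1) {
  if (sum(sizes) > n_genes)
    stop("gene universe too small for the requested signatures")
  if (is.null(weighted))
    weighted <- stats::setNames(rep(TRUE, length(sizes)), names(sizes))
  set.seed(seed)
  offs <- cumsum(c(0, utils::head(sizes, -1)))
  sigs <- lapply(seq_along(sizes), function(i) {
    idx <- offs[i] + seq_len(sizes[i])
    genes <- sprintf("G%05d", idx)
    w <- if (weighted[names(sizes)[i]])
      stats::rnorm(length(genes))
    else
      sample(c(-1, 1), length(genes), replace = TRUE)
    if (length(unique(w)) < 2) w[1] <- w[1] + 1   # guard degenerate draw
    gene_signature(names(sizes)[i], genes, w)
  })
  stats::setNames(sigs, names(sizes))
}

#' Simulate a WG-DASL-style FFPE expression cohort with known truth
#'
#' Emulates the structure of a degraded-FFPE TNBC microarray cohort:
#' log-normal background intensities (log2 values are Normal with
#' probe-specific mean and SD), samples loaded on slides in consecutive
#' batches, two ethnicity groups with optional planted differential
#' signature activation, group-stage confounding, FFPE-style detection
#' dropout, planted contiguous-run batch artifacts, and an optional
#' planted LAR-high subpopulation. All planted truth is recorded so every
#' downstream inference can be scored.
#'
#' Effects are additive on the log2 scale: a group (or stage) effect of
#' size e shifts each signature gene by `e * sd_g * w_g` in the affected
#' samples, where `sd_g` is the probe's own SD and `w_g` the standardized
#' signature weight — i.e. an effect of 1 moves the signature axis by one
#' per-gene SD.
#'
#' @param n_samples samples (default 90).
#' @param n_probes probes (default 18345); ~3% of probes duplicate a gene
#'   symbol to exercise many-to-one probe mapping.
#' @param signatures named list of [gene_signature()]s over the generator's
#'   gene universe (see [synthetic_signatures()]).
#' @param effect_sizes named numeric: signature -> log2-scale effect added
#'   to AA samples. Unknown signature names error.
#' @param stage_effects named numeric: signature -> effect added to samples
#'   with stage >= 2 (drives stage confounding scenarios).
#' @param stage_confounding odds multiplier linking the AA group to
#'   stage >= 2 (1 = no confounding).
#' @param detect_rate expected detectable fraction of cells (default 0.7);
#'   detection p-values are U(0, 0.01) for detected and U(0.05, 1) for
#'   undetected cells, with the detectable call at p < 0.01.
#' @param slide_size samples per slide (default 8; must be >= 2).
#' @param n_batch_probes probes given a planted undetectable run within one
#'   slide (default 0).
#' @param batch_run_length length of each planted run (default `slide_size`).
#' @param lar_signature optional signature name driving a planted LAR-high
#'   subset.
#' @param lar_high_frac fraction of samples planted LAR-high (default 0.12).
#' @param lar_effect LAR planting effect size in per-gene SD units (default 3).
#' @param frac_stage_unknown fraction of samples with unknown stage
#'   (default 0.03).
#' @param seed integer seed; same seed gives bit-identical output.
#' @return list with `matrix` (raw-scale `expression_matrix` with detection
#'   p-values and slide labels), `annotation` (data.frame), `truth` (list:
#'   planted effects, ethnicity/stage design, batch runs, LAR-high ids).
#' @export
simulate_cohort <- function(n_samples = 90, n_probes = 18345,
                            signatures = synthetic_signatures(),
                            effect_sizes = NULL, stage_effects = NULL,
                            stage_confounding = 1, detect_rate = 0.7,
                            slide_size = 8, n_batch_probes = 0,
                            batch_run_length = slide_size,
                            lar_signature = NULL, lar_high_frac = 0.12,
                            lar_effect = 3, frac_stage_unknown = 0.03,
                            seed = NULL) {
  if (slide_size < 2) stop("slide_size must be >= 2")
  if (batch_run_length > slide_size) stop("batch_run_length exceeds slide_size")
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  for (nm in names(effect_sizes)) if (!nm %in% names(signatures))
    stop("effect size given for unknown signature: ", nm)
  for (nm in names(stage_effects)) if (!nm %in% names(signatures))
    stop("stage effect given for unknown signature: ", nm)
  if (!is.null(lar_signature) && !lar_signature %in% names(signatures))
    stop("unknown LAR signature: ", lar_signature)
  if (!is.null(seed)) set.seed(seed)

  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  probe_ids <- sprintf("P%06d", seq_len(n_probes))
  n_genes <- max(max(1, round(0.97 * n_probes)),
                 max(0, suppressWarnings(max(c(0, unlist(lapply(signatures, function(s)
                   as.integer(sub("^G", "", s$genes)))))))))
  gene_idx <- c(seq_len(min(n_genes, n_probes)),
                if (n_probes > n_genes) seq_len(n_probes - n_genes))
  gene_symbols <- sprintf("G%05d", gene_idx)
  slide <- sprintf("slide%02d", (seq_len(n_samples) - 1) %/% slide_size + 1)

  # clinical design
  ethnicity <- sample(c("AA", "EA"), n_samples, replace = TRUE)
  base_odds <- 1                      # P(stage >= 2) = 0.5 for EA
  odds <- ifelse(ethnicity == "AA", base_odds * stage_confounding, base_odds)
  adv <- stats::runif(n_samples) < odds / (1 + odds)
  stage <- ifelse(adv, sample(2:4, n_samples, replace = TRUE,
                              prob = c(0.7, 0.2, 0.1)), 1L)
  stage[sample.int(n_samples, round(frac_stage_unknown * n_samples))] <- NA
  nodal <- ifelse(!is.na(stage) & stage >= 2,
                  ifelse(stats::runif(n_samples) < 0.7, "pos", "neg"),
                  ifelse(stats::runif(n_samples) < 0.25, "pos", "neg"))
  annotation <- data.frame(sample_id = sample_ids,
                           patient_id = sprintf("PT%03d", seq_len(n_samples)),
                           ethnicity = ethnicity, stage = stage, nodal = nodal,
                           age = round(stats::rnorm(n_samples, 52, 10)),
                           tissue_site = "primary", stringsAsFactors = FALSE)

  # background log2 intensities
  mu <- stats::rnorm(n_probes, 8, 1.5)
  sd_p <- stats::runif(n_probes, 0.3, 1.2)
  x <- mu + sd_p * matrix(stats::rnorm(n_probes * n_samples), n_probes)
  dimnames(x) <- list(probe_ids, sample_ids)

  add_effect <- function(x, sig, cols, e) {
    w <- as.vector(scale(unname(sig$weights)))
    rows <- which(gene_symbols %in% sig$genes)
    wr <- w[match(gene_symbols[rows], sig$genes)]
    x[rows, cols] <- x[rows, cols] + e * sd_p[rows] * wr
    x
  }
  for (nm in names(effect_sizes))
    x <- add_effect(x, signatures[[nm]], ethnicity == "AA", effect_sizes[[nm]])
  for (nm in names(stage_effects))
    x <- add_effect(x, signatures[[nm]], !is.na(stage) & stage >= 2,
                    stage_effects[[nm]])
  lar_ids <- character(0)
  if (!is.null(lar_signature)) {
    k <- max(1, round(lar_high_frac * n_samples))
    lar_ids <- sort(sample(sample_ids, k))
    x <- add_effect(x, signatures[[lar_signature]],
                    sample_ids %in% lar_ids, lar_effect)
  }

  # detection calls and planted batch runs
  det <- matrix(stats::runif(n_probes * n_samples) < detect_rate, n_probes)
  batch_runs <- NULL
  if (n_batch_probes > 0) {
    bp <- sample.int(n_probes, n_batch_probes)
    # only slides long enough to hold the planted run (the last slide of a
    # cohort that is not a multiple of slide_size may be shorter)
    slides <- names(which(table(slide) >= batch_run_length))
    batch_runs <- data.frame(probe = probe_ids[bp],
                             slide = sample(slides, n_batch_probes, replace = TRUE),
                             start = NA_integer_, length = batch_run_length,
                             stringsAsFactors = FALSE)
    for (i in seq_len(n_batch_probes)) {
      # a batch artifact is a probe that behaves well everywhere except one
      # slide: detectable off-slide, undetectable in a contiguous run
      det[bp[i], ] <- TRUE
      cols <- which(slide == batch_runs$slide[i])
      start <- sample.int(length(cols) - batch_run_length + 1, 1)
      batch_runs$start[i] <- start
      det[bp[i], cols[start:(start + batch_run_length - 1)]] <- FALSE
    }
  }
  detection_p <- matrix(NA_real_, n_probes, n_samples)
  detection_p[det] <- stats::runif(sum(det), 0, 0.01)
  detection_p[!det] <- stats::runif(sum(!det), 0.05, 1)

  em <- expression_matrix(2^x, gene_symbols = gene_symbols,
                          detection_p = detection_p, slide = slide,
                          log2 = FALSE)
  truth <- list(effect_sizes = effect_sizes, stage_effects = stage_effects,
                stage_confounding = stage_confounding,
                detect_rate = detect_rate, ethnicity = ethnicity,
                stage = stage, batch_runs = batch_runs,
                lar_high_ids = lar_ids, signatures = names(signatures))
  list(matrix = em, annotation = annotation, truth = truth)
}

#' Simulate an RNA-seq-style count cohort
#'
#' Negative-binomial counts with log-scale signature effects, exercising
#' the count path (log transform, then Pearson activation scoring).
#'
#' @param n_samples,n_genes cohort size; `n_genes` must be positive.
#' @param signatures,effect_sizes as in [simulate_cohort()] (effects added
#'   to AA samples on the log2 mean).
#' @param lar_signature,lar_high_frac,lar_effect optional planted LAR-high
#'   subset, as in [simulate_cohort()].
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param seed integer seed.
#' @return list with `counts` (gene x sample integer matrix), `annotation`,
#'   `truth`.
#' @export
simulate_counts <- function(n_samples = 73, n_genes = 2000,
                            signatures = synthetic_signatures(),
                            effect_sizes = NULL, lar_signature = NULL,
                            lar_high_frac = 0.12, lar_effect = 3,
                            dispersion = 0.2, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  for (nm in names(effect_sizes)) if (!nm %in% names(signatures))
    stop("effect size given for unknown signature: ", nm)
  if (!is.null(seed)) set.seed(seed)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  genes <- sprintf("G%05d", seq_len(n_genes))
  ethnicity <- sample(c("AA", "EA"), n_samples, replace = TRUE)
  stage <- sample(1:4, n_samples, replace = TRUE, prob = c(0.45, 0.35, 0.15, 0.05))
  log_mu <- stats::rnorm(n_genes, 6, 1.5)
  lm <- matrix(log_mu, n_genes, n_samples)
  sd_g <- rep(1, n_genes)
  add <- function(lm, sig, cols, e) {
    w <- as.vector(scale(unname(sig$weights)))
    rows <- which(genes %in% sig$genes)
    wr <- w[match(genes[rows], sig$genes)]
    lm[rows, cols] <- lm[rows, cols] + e * sd_g[rows] * wr
    lm
  }
  for (nm in names(effect_sizes))
    lm <- add(lm, signatures[[nm]], ethnicity == "AA", effect_sizes[[nm]])
  lar_ids <- character(0)
  if (!is.null(lar_signature)) {
    if (!lar_signature %in% names(signatures))
      stop("unknown LAR signature: ", lar_signature)
    k <- max(1, round(lar_high_frac * n_samples))
    lar_ids <- sort(sample(sample_ids, k))
    lm <- add(lm, signatures[[lar_signature]], sample_ids %in% lar_ids, lar_effect)
  }
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = 2^lm,
                                  size = 1 / dispersion),
                   n_genes, dimnames = list(genes, sample_ids))
  annotation <- data.frame(sample_id = sample_ids,
                           patient_id = sprintf("PT%03d", seq_len(n_samples)),
                           ethnicity = ethnicity, stage = stage,
                           nodal = sample(c("pos", "neg"), n_samples, TRUE),
                           age = round(stats::rnorm(n_samples, 55, 11)),
                           tissue_site = "primary", stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation,
       truth = list(effect_sizes = effect_sizes, ethnicity = ethnicity,
                    lar_high_ids = lar_ids))
}

#' Simulate a multi-channel histospot with known pixel truth
#'
#' Renders a blob-shaped tumor region covering approximately
#' `tumor_fraction` of the image in the cytokeratin channel, speckled
#' nuclei in the DAPI channel, and curvilinear CD31-positive vessels inside
#' the tumor covering `vessel_fraction` of the tumor pixels. Gaussian noise
#' is added to every channel. The recorded truth is computed from the
#' rendered ground-truth masks (exact pixel counts, not the target
#' fractions).
#'
#' @param size_px image side length (default 192; must be >= 32 when
#'   vessels are requested).
#' @param tumor_fraction target tumor pixel fraction of the image, in \[0,1\].
#' @param vessel_fraction target vessel fraction of tumor pixels, in \[0,0.2\].
#' @param n_vessels number of vessel curves (default 6).
#' @param noise_sd Gaussian channel noise SD (default 0.05).
#' @param nuclei_frac target nuclear fraction of tumor pixels (default 0.2).
#' @param spot_id spot identifier.
#' @param seed integer seed.
#' @return list with `spot` (a [histospot()]) and `truth` (list:
#'   `vessel_fraction` of tumor, `tumor_fraction` of image, and the
#'   rendered `tumor_mask`, `nuclear_mask`, `vessel_mask`).
#' @export
simulate_histospot <- function(size_px = 192, tumor_fraction = 0.5,
                               vessel_fraction = 0.02, n_vessels = 6,
                               noise_sd = 0.05, nuclei_frac = 0.2,
                               spot_id = "spot", seed = NULL) {
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0, 1]")
  if (vessel_fraction < 0 || vessel_fraction > 0.2)
    stop("vessel_fraction must lie in [0, 0.2]")
  if (size_px < 32 && vessel_fraction > 0 && n_vessels > 0)
    stop("image too small to place the requested vessels")
  if (!is.null(seed)) set.seed(seed)
  n <- size_px
  xs <- matrix(seq_len(n), n, n)
  ys <- matrix(seq_len(n), n, n, byrow = TRUE)
  cx <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  cy <- n / 2 + stats::runif(1, -0.05, 0.05) * n

  tumor <- matrix(FALSE, n, n)
  if (tumor_fraction > 0) {
    r0 <- n * sqrt(tumor_fraction / pi)
    amp <- stats::runif(3, 0, 0.12)
    phs <- stats::runif(3, 0, 2 * pi)
    theta <- atan2(ys - cy, xs - cx)
    rmax <- r0 * (1 + amp[1] * cos(2 * theta + phs[1]) +
                    amp[2] * cos(3 * theta + phs[2]) +
                    amp[3] * cos(4 * theta + phs[3]))
    tumor <- sqrt((xs - cx)^2 + (ys - cy)^2) <= rmax
  }
  tumor_px <- sum(tumor)

  stamp <- function(mask, x0, y0, r) {
    xr <- max(1, round(x0 - r)):min(n, round(x0 + r))
    yr <- max(1, round(y0 - r)):min(n, round(y0 + r))
    for (i in xr) for (j in yr)
      if ((i - x0)^2 + (j - y0)^2 <= r^2) mask[i, j] <- TRUE
    mask
  }

  nuclear <- matrix(FALSE, n, n)
  if (tumor_px > 0 && nuclei_frac > 0) {
    tgt <- nuclei_frac * tumor_px
    inside <- which(tumor)
    guard <- 0
    while (sum(nuclear & tumor) < tgt && guard < 20000) {
      p <- inside[sample.int(length(inside), 1)]
      nuclear <- stamp(nuclear, (p - 1) %% n + 1, (p - 1) %/% n + 1,
                       stats::runif(1, 1.5, 3))
      guard <- guard + 1
    }
    nuclear <- nuclear & tumor
  }

  vessel <- matrix(FALSE, n, n)
  if (tumor_px > 0 && vessel_fraction > 0 && n_vessels > 0) {
    budget <- round(vessel_fraction * tumor_px)
    inside <- which(tumor)
    guard <- 0
    while (sum(vessel) < budget && guard < 200) {
      p <- inside[sample.int(length(inside), 1)]
      x0 <- (p - 1) %% n + 1
      y0 <- (p - 1) %/% n + 1
      dir <- stats::runif(1, 0, 2 * pi)
      steps <- 0
      while (sum(vessel) < budget && steps < 4 * n) {
        if (tumor[round(min(max(x0, 1), n)), round(min(max(y0, 1), n))])
          vessel <- stamp(vessel, x0, y0, 1.3)
        dir <- dir + stats::rnorm(1, 0, 0.25)
        x0 <- x0 + cos(dir); y0 <- y0 + sin(dir)
        if (x0 < 2 || x0 > n - 1 || y0 < 2 || y0 > n - 1) break
        steps <- steps + 1
      }
      guard <- guard + 1
    }
    vessel <- vessel & tumor
  }

  noise <- function() matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  clamp <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
  spot <- histospot(
    cytokeratin = clamp(0.15 + 0.75 * tumor + noise()),
    dapi = clamp(0.10 + 0.70 * nuclear + noise()),
    cd31 = clamp(0.10 + 0.80 * vessel + noise()),
    spot_id = spot_id)
  truth <- list(
    vessel_fraction = if (tumor_px > 0) sum(vessel) / tumor_px else 0,
    tumor_fraction = tumor_px / (n * n),
    nuclear_fraction = if (tumor_px > 0) sum(nuclear) / tumor_px else 0,
    tumor_mask = tumor, nuclear_mask = nuclear, vessel_mask = vessel)
  list(spot = spot, truth = truth)
}
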