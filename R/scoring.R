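# Welch two-sample t on plain numeric vectors; returns c(t, df, p).
# Zero-variance guards: equal means -> t = 0, p = 1; unequal -> |t| = Inf, p = 0.
welch_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mx == my) return(c(t = 0, df = nx + ny - 2, p = 1))
    return(c(t = sign(mx - my) * Inf, df = nx + ny - 2, p = 0))
  }
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  if (!is.finite(df) || df <= 0) df <- nx + ny - 2
  c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Signature activation score
#'
#' Activation of a gene signature in a sample is the Pearson correlation
#' between the signature's weight vector and the sample's expression
#' profile over the signature genes. Correlating across many genes is
#' robust to the per-probe noise of degraded FFPE material: coordinated
#' expression of the whole signature is required for a high score.
#' Gene matching is case-insensitive; multiple probes per gene are
#' averaged first. With fewer than 3 matched genes the signature is
#' unscorable and all scores are NA (flagged, never silently zero);
#' a zero-variance sample sub-profile gives an NA score for that sample.
#'
#' @param x an `expression_matrix` with gene symbols (log2 scale expected).
#' @param signature a [gene_signature()].
#' @param exclude_imputed if TRUE, cells imputed during normalization are
#'   dropped from each sample's profile before correlating (default FALSE:
#'   imputed cells included).
#' @return numeric per-sample score vector with attributes `n_genes_used`,
#'   `genes_used` and `unscorable`.
#' @export
activation_score <- function(x, signature, exclude_imputed = FALSE) {
  gm <- collapse_to_genes(x)
  hit <- match(signature$genes, rownames(gm))
  used <- which(!is.na(hit))
  out <- stats::setNames(rep(NA_real_, ncol(gm)), colnames(gm))
  if (length(used) < 3) {
    attr(out, "n_genes_used") <- length(used)
    attr(out, "genes_used") <- signature$genes[used]
    attr(out, "unscorable") <- TRUE
    return(out)
  }
  w <- unname(signature$weights[used])
  sub <- gm[hit[used], , drop = FALSE]
  if (exclude_imputed && !is.null(x$imputed)) {
    imp_g <- rowsum(x$imputed[!is.na(x$gene_symbols) & nzchar(x$gene_symbols), ,
                              drop = FALSE] + 0,
                    factor(x$gene_symbols[!is.na(x$gene_symbols) &
                                            nzchar(x$gene_symbols)],
                           levels = unique(x$gene_symbols[!is.na(x$gene_symbols) &
                                                            nzchar(x$gene_symbols)])),
                    reorder = FALSE) > 0
    sub[imp_g[match(rownames(sub), rownames(imp_g)), , drop = FALSE]] <- NA
  }
  for (j in seq_len(ncol(sub))) {
    prof <- sub[, j]
    ok <- !is.na(prof)
    if (sum(ok) < 3 || stats::sd(prof[ok]) == 0 || stats::sd(w[ok]) == 0) next
    out[j] <- stats::cor(w[ok], prof[ok])
  }
  attr(out, "n_genes_used") <- length(used)
  attr(out, "genes_used") <- signature$genes[used]
  attr(out, "unscorable") <- FALSE
  out
}

#' Score a list of signatures into an activation table
#'
#' @param x an `expression_matrix`.
#' @param signatures list of [gene_signature()] objects.
#' @param exclude_imputed see [activation_score()].
#' @return an `activation_table`: sample x signature matrix of Pearson r
#'   with attributes `n_genes_used` and `unscorable` per signature.
#' @export
score_signatures <- function(x, signatures, exclude_imputed = FALSE) {
  if (is.null(names(signatures)) || any(!nzchar(names(signatures))))
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  cols <- lapply(signatures, function(s) activation_score(x, s, exclude_imputed))
  tab <- do.call(cbind, lapply(cols, as.vector))
  dimnames(tab) <- list(names(cols[[1]]), names(signatures))
  structure(tab,
            n_genes_used = vapply(cols, attr, 0L, "n_genes_used"),
            unscorable = vapply(cols, attr, TRUE, "unscorable"),
            class = c("activation_table", "matrix"))
}

#' @export
print.activation_table <- function(x, ...) {
  cat(sprintf("activation_table: %d samples x %d signatures\n", nrow(x), ncol(x)))
  info <- data.frame(signature = colnames(x),
                     n_genes_used = attr(x, "n_genes_used"),
                     unscorable = attr(x, "unscorable"))
  print(info, row.names = FALSE)
  invisible(x)
}

#' Differential signature activation between two groups
#'
#' Two-tailed Welch t-test on the per-sample activation scores of two
#' groups; direction is reported as the difference of group means
#' (first level minus second).
#'
#' @param scores numeric per-sample activation scores.
#' @param groups two-level factor/character vector parallel to `scores`.
#' @return list with `t`, `df`, `p`, `means` (named), `mean_diff`, `n` (named).
#' @export
differential_activation <- function(scores, groups) {
  ok <- !is.na(scores) & !is.na(groups)
  lev <- if (is.factor(groups)) levels(droplevels(groups[ok]))
         else sort(unique(as.character(groups)[ok]))
  scores <- scores[ok]; groups <- as.character(groups)[ok]
  if (length(lev) != 2) stop("exactly two groups required")
  x <- scores[groups == lev[1]]; y <- scores[groups == lev[2]]
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 samples")
  w <- welch_stat(x, y)
  list(t = unname(w["t"]), df = unname(w["df"]), p = unname(w["p"]),
       means = stats::setNames(c(mean(x), mean(y)), lev),
       mean_diff = mean(x) - mean(y),
       n = stats::setNames(c(length(x), length(y)), lev))
}

#' Stage-stratified permutation p-value for a group difference
#'
#' Controls for a confounder (tumor stage) by permuting the group labels
#' independently within each stratum, preserving the stratum-group counts
#' and any stratum-outcome association. The statistic is the absolute
#' Welch t between groups; the empirical two-sided p-value is
#' `(1 + #permuted |t| >= observed |t|) / (n_resamples + 1)`. Samples with
#' missing scores, group or stratum are excluded; a stratum containing
#' only one group contributes no permutation variability (a warning is
#' issued). Deterministic under `seed`.
#'
#' @param scores numeric per-sample scores.
#' @param groups two-level group labels parallel to `scores`.
#' @param strata stratum label per sample (NA = excluded).
#' @param n_resamples number of label permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with `p`, `t_obs`, `n_resamples`, `n_used`, `seed`.
#' @export
stage_adjusted_p <- function(scores, groups, strata, n_resamples = 1000,
                             seed = NULL) {
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  ok <- !is.na(scores) & !is.na(groups) & !is.na(strata)
  scores <- scores[ok]
  groups <- as.character(groups)[ok]
  strata <- as.character(strata)[ok]
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (!is.null(seed)) set.seed(seed)
  str_idx <- split(seq_along(scores), strata)
  single <- vapply(str_idx, function(i) length(unique(groups[i])) < 2, TRUE)
  if (any(single))
    warning(sum(single), " stratum/strata contain only one group and add no ",
            "permutation variability")
  g1 <- groups == lev[1]
  t_obs <- unname(welch_stat(scores[g1], scores[!g1])["t"])
  count <- 0L
  perm <- groups
  for (r in seq_len(n_resamples)) {
    for (i in str_idx) perm[i] <- groups[i][sample.int(length(i))]
    p1 <- perm == lev[1]
    t_star <- welch_stat(scores[p1], scores[!p1])["t"]
    if (abs(t_star) >= abs(t_obs)) count <- count + 1L
  }
  list(p = (1 + count) / (n_resamples + 1), t_obs = t_obs,
       n_resamples = n_resamples, n_used = length(scores), seed = seed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone after sorting and
#' capped at 1. Empty input gives empty output.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Group inference for every signature in an activation table
#'
#' For each signature: two-tailed Welch t-test between the groups (raw p),
#' stage-stratified permutation p ([stage_adjusted_p()]), and
#' Benjamini-Hochberg FDR across signatures applied to the stage-adjusted
#' p-values. Samples with unknown stage are excluded from the adjusted
#' test but kept in the raw test.
#'
#' @param act an `activation_table` from [score_signatures()].
#' @param annotation annotation data.frame.
#' @param group_col annotation column holding the two-level grouping
#'   (default "ethnicity"); levels beyond the two most frequent are dropped.
#' @param strata_col stratification column (default "stage").
#' @param n_resamples permutations for the adjusted p (default 1000).
#' @param seed integer seed for the permutations.
#' @return data.frame: signature, per-group means and n, t, p_raw,
#'   stage_adjusted_p, fdr, n_resamples.
#' @export
test_activation <- function(act, annotation, group_col = "ethnicity",
                            strata_col = "stage", n_resamples = 1000,
                            seed = NULL) {
  ann <- annotation[match(rownames(act), annotation$sample_id), ]
  grp <- as.character(ann[[group_col]])
  grp[grp == "unknown"] <- NA
  lev <- sort(names(sort(table(grp), decreasing = TRUE))[1:2])
  grp[!grp %in% lev] <- NA
  strata <- ann[[strata_col]]
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(colnames(act), function(sig) {
    sc <- act[, sig]
    if (isTRUE(attr(act, "unscorable")[sig]) || all(is.na(sc)))
      return(data.frame(signature = sig, mean_1 = NA, mean_2 = NA,
                        n_1 = NA, n_2 = NA, t = NA, p_raw = NA,
                        stage_adjusted_p = NA, fdr = NA,
                        n_resamples = n_resamples, stringsAsFactors = FALSE))
    da <- differential_activation(sc, grp)
    ap <- stage_adjusted_p(sc, grp, strata, n_resamples, seed = NULL)
    data.frame(signature = sig,
               mean_1 = unname(da$means[lev[1]]), mean_2 = unname(da$means[lev[2]]),
               n_1 = unname(da$n[lev[1]]), n_2 = unname(da$n[lev[2]]),
               t = da$t, p_raw = da$p, stage_adjusted_p = ap$p, fdr = NA_real_,
               n_resamples = n_resamples, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) %in% c("mean_1", "mean_2", "n_1", "n_2")] <-
    c(paste0("mean_", lev), paste0("n_", lev))
  ok <- !is.na(out$stage_adjusted_p)
  out$fdr[ok] <- fdr_adjust(out$stage_adjusted_p[ok])
  out
}

#' Detect a LAR-high cluster from AR expression and LAR activation
#'
#' The luminal androgen receptor (LAR) subtype forms a small, distinct
#' cluster with high androgen-receptor expression and high LAR-signature
#' activation. Both features are z-standardized and partitioned by k-means
#' with k = 2 (best of `restarts` random starts by total within-cluster sum
#' of squares); the cluster with the greater mean LAR activation is
#' labelled LAR-high.
#'
#' @param ar_expression per-sample AR expression (named).
#' @param lar_scores per-sample LAR-signature activation (same samples).
#' @param seed integer seed for the k-means starts.
#' @param restarts random restarts (default 50).
#' @return list with `assignments` (factor "LAR-high"/"other" per sample),
#'   `lar_high_ids`, `sizes`, `centers` (on the z scale), `tot_withinss`.
#' @export
lar_cluster <- function(ar_expression, lar_scores, seed = NULL, restarts = 50) {
  if (length(ar_expression) != length(lar_scores))
    stop("feature vectors differ in length")
  if (length(ar_expression) < 4) stop("at least 4 samples required")
  feats <- cbind(ar = as.vector(scale(ar_expression)),
                 lar = as.vector(scale(lar_scores)))
  if (anyNA(feats)) stop("constant or missing feature; cannot standardize")
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(feats, centers = 2, nstart = restarts)
  high <- which.max(tapply(lar_scores, km$cluster, mean))
  ids <- names(ar_expression)
  if (is.null(ids)) ids <- seq_along(ar_expression)
  assign <- factor(ifelse(km$cluster == high, "LAR-high", "other"),
                   levels = c("LAR-high", "other"))
  names(assign) <- ids
  list(assignments = assign,
       lar_high_ids = ids[km$cluster == high],
       sizes = table(assign),
       centers = km$centers,
       tot_withinss = km$tot.withinss)
}

#' Spearman correlation between component scores and signature activation
#'
#' Rank correlation (average ranks for ties) over the samples common to
#' both vectors; used to tie PCA components to signature activation
#' patterns. Returns NA (with a warning) for constant input.
#'
#' @param pc_scores named per-sample component scores.
#' @param activation_scores named per-sample activation scores.
#' @return Spearman's rho (numeric scalar, attribute `n`).
#' @export
spearman_pc_signature <- function(pc_scores, activation_scores) {
  if (!is.null(names(pc_scores)) && !is.null(names(activation_scores))) {
    common <- intersect(names(pc_scores), names(activation_scores))
    pc_scores <- pc_scores[common]
    activation_scores <- activation_scores[common]
  }
  ok <- !is.na(pc_scores) & !is.na(activation_scores)
  x <- pc_scores[ok]; y <- activation_scores[ok]
  if (length(x) < 3) stop("at least 3 paired samples required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(structure(NA_real_, n = length(x)))
  }
  structure(stats::cor(x, y, method = "spearman"), n = length(x))
}
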