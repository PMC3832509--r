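#' Multi-channel tissue-microarray histospot
#'
#' One TMA core's image: a cytokeratin channel delineating tumor, a DAPI
#' channel marking nuclei and a CD31 channel marking endothelium. Masks
#' (tumor, nuclear, vessel) are derived by the mask operators and stored
#' alongside the channels.
#'
#' @param cytokeratin,dapi,cd31 non-negative numeric matrices of equal shape.
#' @param spot_id spot identifier.
#' @return a `histospot`.
#' @export
histospot <- function(cytokeratin, dapi, cd31, spot_id = "spot") {
  chans <- list(cytokeratin = cytokeratin, dapi = dapi, cd31 = cd31)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) stop(nm, " must be a numeric matrix")
    if (any(ch < 0)) stop(nm, " has negative pixel values")
  }
  if (!identical(dim(cytokeratin), dim(dapi)) || !identical(dim(cytokeratin), dim(cd31)))
    stop("channel dimensions differ")
  structure(list(cytokeratin = cytokeratin, dapi = dapi, cd31 = cd31,
                 spot_id = spot_id, tumor = NULL, nuclear = NULL,
                 non_nuclear = NULL, vessel = NULL,
                 excluded = FALSE, exclusion_reason = NULL),
            class = "histospot")
}

#' @export
print.histospot <- function(x, ...) {
  cat(sprintf("histospot '%s': %d x %d px", x$spot_id,
              nrow(x$cytokeratin), ncol(x$cytokeratin)))
  if (x$excluded) cat(" [excluded: ", x$exclusion_reason, "]", sep = "")
  else if (!is.null(x$tumor))
    cat(sprintf(", tumor %.1f%%", 100 * mean(x$tumor)))
  if (!is.null(x$vessel))
    cat(sprintf(", vessel %.2f%% of tumor", 100 * sum(x$vessel) / sum(x$tumor)))
  cat("\n")
  invisible(x)
}

# Otsu threshold over a pixel subset with a separability guard.
# Returns the threshold, or NA when the channel shows no genuine signal:
# the foreground/background contrast (mu_fg - mu_bg over pooled within-class
# SD) of pure Gaussian noise is ~2.65 regardless of scale, while a genuine
# two-level channel scores far higher; min_contrast = 4 separates the two.
# Scale-invariant: thresholds, means and SDs all scale with the data.
otsu_threshold <- function(v, min_contrast = 4) {
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  th <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)), range = rng,
                      levels = 256L)
  fg <- v > th
  if (sum(fg) < 2 || sum(!fg) < 2) return(NA_real_)
  sp <- sqrt(((sum(fg) - 1) * stats::var(v[fg]) +
                (sum(!fg) - 1) * stats::var(v[!fg])) / (length(v) - 2))
  if (sp == 0) return(th)
  if ((mean(v[fg]) - mean(v[!fg])) / sp < min_contrast) return(NA_real_)
  th
}

# Drop connected components smaller than min_px (8-connectivity).
prune_small <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask + 0))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
}

#' Derive the binary tumor mask of a histospot
#'
#' Otsu threshold on the cytokeratin channel (with a no-signal separability
#' guard), morphological closing with a disc of radius `close_radius`, and
#' removal of connected components below `min_component` pixels. Spots whose
#' tumor mask covers less than `min_tumor_frac` of the image — and spots
#' with a blank or signal-free cytokeratin channel — are excluded with a
#' recorded reason.
#'
#' @param spot a [histospot()].
#' @param min_tumor_frac minimum tumor pixel fraction (default 0.05).
#' @param close_radius closing radius in px (default 2).
#' @param min_component minimum tumor component size in px (default 50).
#' @return the histospot with `tumor` set, or flagged `excluded` with
#'   `exclusion_reason`.
#' @export
tumor_mask <- function(spot, min_tumor_frac = 0.05, close_radius = 2,
                       min_component = 50) {
  ck <- spot$cytokeratin
  th <- otsu_threshold(as.vector(ck))
  if (is.na(th)) {
    spot$excluded <- TRUE
    spot$exclusion_reason <- "no signal in cytokeratin channel"
    return(spot)
  }
  m <- ck > th
  brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
  m <- EBImage::closing(EBImage::Image(m + 0), brush) > 0.5
  m <- prune_small(matrix(m, nrow(ck), ncol(ck)), min_component)
  frac <- mean(m)
  if (frac < min_tumor_frac) {
    spot$excluded <- TRUE
    spot$exclusion_reason <- sprintf("tumor content %.1f%% below %.0f%%",
                                     100 * frac, 100 * min_tumor_frac)
    return(spot)
  }
  spot$tumor <- m
  spot
}

#' Partition the tumor mask into nuclear and non-nuclear compartments
#'
#' The DAPI channel is Otsu-thresholded (no-signal guard as in
#' [tumor_mask()]); nuclear = DAPI mask within tumor, non-nuclear = the
#' rest of the tumor mask. The two compartments are disjoint and their
#' union is exactly the tumor mask. A blank DAPI channel yields an empty
#' nuclear compartment.
#'
#' @param spot a histospot with a tumor mask.
#' @return the histospot with `nuclear` and `non_nuclear` set.
#' @export
compartment_masks <- function(spot) {
  if (is.null(spot$tumor)) stop("tumor mask not set; call tumor_mask() first")
  th <- otsu_threshold(as.vector(spot$dapi))
  nuc <- if (is.na(th)) matrix(FALSE, nrow(spot$dapi), ncol(spot$dapi))
         else spot$dapi > th
  spot$nuclear <- nuc & spot$tumor
  spot$non_nuclear <- spot$tumor & !spot$nuclear
  spot
}

#' Microvessel area of a histospot
#'
#' The CD31 channel is thresholded by Otsu *within the tumor mask* (so that
#' sparse vessels still dominate the between-class variance), small
#' components below `min_component` px are removed, and the microvessel
#' area is the vessel pixel count as a percentage of the tumor pixel count.
#' Spots are called MVA-high above `threshold_pct` (default 0.6%, the
#' normalized cut-off separating clinically meaningful groups).
#'
#' @param spot a histospot with a tumor mask (not excluded).
#' @param threshold_pct MVA-high dichotomization threshold in percent.
#' @param min_component minimum vessel component size in px (default 10).
#' @return an `mva_result`: list with spot_id, tumor_fraction, mva_percent,
#'   high_mva, excluded, reason, and the tumor/vessel masks.
#' @export
microvessel_area <- function(spot, threshold_pct = 0.6, min_component = 10) {
  if (spot$excluded)
    stop("spot '", spot$spot_id, "' is excluded: ", spot$exclusion_reason)
  if (is.null(spot$tumor)) stop("tumor mask not set; call tumor_mask() first")
  v <- spot$cd31[spot$tumor]
  th <- otsu_threshold(v)
  vessel <- matrix(FALSE, nrow(spot$cd31), ncol(spot$cd31))
  if (!is.na(th)) {
    vessel <- (spot$cd31 > th) & spot$tumor
    vessel <- prune_small(vessel, min_component) & spot$tumor
  }
  mva <- 100 * sum(vessel) / sum(spot$tumor)
  structure(list(spot_id = spot$spot_id,
                 tumor_fraction = mean(spot$tumor),
                 mva_percent = mva,
                 high_mva = mva > threshold_pct,
                 excluded = FALSE, reason = NULL,
                 tumor = spot$tumor, vessel = vessel),
            class = "mva_result")
}

#' Quantify one histospot end to end
#'
#' [tumor_mask()] then [microvessel_area()]; an excluded spot yields an
#' `mva_result` with `excluded = TRUE`, the exclusion reason and no MVA.
#'
#' @param spot a [histospot()].
#' @param min_tumor_frac,threshold_pct see the mask operators.
#' @return an `mva_result`.
#' @export
quantify_spot <- function(spot, min_tumor_frac = 0.05, threshold_pct = 0.6) {
  spot <- tumor_mask(spot, min_tumor_frac)
  if (spot$excluded)
    return(structure(list(spot_id = spot$spot_id, tumor_fraction = NA_real_,
                          mva_percent = NA_real_, high_mva = NA,
                          excluded = TRUE, reason = spot$exclusion_reason,
                          tumor = NULL, vessel = NULL),
                     class = "mva_result"))
  microvessel_area(spot, threshold_pct)
}

#' @export
print.mva_result <- function(x, ...) {
  if (x$excluded)
    cat(sprintf("mva_result '%s': excluded (%s)\n", x$spot_id, x$reason))
  else
    cat(sprintf("mva_result '%s': tumor %.1f%%, MVA %.2f%%%s\n", x$spot_id,
                100 * x$tumor_fraction, x$mva_percent,
                if (x$high_mva) " [high]" else ""))
  invisible(x)
}

#' Combined VEGF profile score from expression ranks
#'
#' For each profile gene present in the matrix, samples are ranked by
#' expression (ascending, average ranks for ties); a sample's score is its
#' mean rank across the available genes. Rank aggregation is robust to
#' per-gene scale differences in degraded material.
#'
#' @param x an `expression_matrix` with gene symbols.
#' @param vegf_genes character profile gene symbols.
#' @return named per-sample score vector with attribute `genes_used`.
#' @export
vegf_rank_score <- function(x, vegf_genes) {
  gm <- collapse_to_genes(x)
  present <- intersect(toupper(vegf_genes), rownames(gm))
  if (length(present) == 0) stop("no VEGF profile genes present in the matrix")
  ranks <- t(apply(gm[present, , drop = FALSE], 1, rank, ties.method = "average"))
  if (length(present) == 1)
    ranks <- matrix(ranks, nrow = 1, dimnames = list(present, colnames(gm)))
  structure(colMeans(ranks), genes_used = present)
}

#' Per-gene group comparison with Bonferroni control
#'
#' Welch two-tailed t-test per gene on expression between two groups;
#' Bonferroni-adjusted p is `min(1, m * p)` with m the number of genes
#' actually tested. Genes absent from the matrix are skipped with a note.
#'
#' @param x an `expression_matrix` with gene symbols.
#' @param genes character gene symbols to test.
#' @param groups two-level group labels parallel to the samples.
#' @return data.frame: gene, mean_diff, t, p, bonferroni_p, note.
#' @export
per_gene_group_test <- function(x, genes, groups) {
  gm <- collapse_to_genes(x)
  groups <- as.character(groups)
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) != 2) stop("exactly two groups required")
  if (min(table(factor(groups, levels = lev))) < 2)
    stop("each group needs at least 2 samples")
  rows <- lapply(toupper(genes), function(g) {
    if (!g %in% rownames(gm))
      return(data.frame(gene = g, mean_diff = NA_real_, t = NA_real_,
                        p = NA_real_, bonferroni_p = NA_real_,
                        note = "skipped: gene absent", stringsAsFactors = FALSE))
    e <- gm[g, ]
    ok <- !is.na(groups)
    w <- welch_stat(e[ok & groups == lev[1]], e[ok & groups == lev[2]])
    data.frame(gene = g,
               mean_diff = mean(e[ok & groups == lev[1]]) -
                 mean(e[ok & groups == lev[2]]),
               t = unname(w["t"]), p = unname(w["p"]),
               bonferroni_p = NA_real_, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(is.na(out$note) | out$note == "")
  out$bonferroni_p <- pmin(1, m * out$p)
  out
}

#' Associate microvessel area with a clinical covariate
#'
#' Spot-level MVA results are aggregated to patients (mean `mva_percent`
#' over each patient's non-excluded spots; patients with only excluded
#' spots are dropped with a note). Two tests are reported side by side:
#' Fisher's exact test of the high/low dichotomization (patient mean above
#' `threshold_pct`) against the two-level covariate, and a Welch t-test of
#' the numeric patient MVA. Optionally a stage-stratified permutation p for
#' the numeric test via [stage_adjusted_p()].
#'
#' @param mva_results list of `mva_result` objects (or a data.frame with
#'   columns spot_id, mva_percent, excluded).
#' @param patients patient id per spot, parallel to `mva_results`.
#' @param annotation patient-level annotation: data.frame with columns
#'   `patient_id`, the covariate, and optionally the strata column.
#' @param covariate two-level covariate column name (e.g. "nodal").
#' @param threshold_pct dichotomization threshold (default 0.6).
#' @param strata_col optional stratification column for a permutation p.
#' @param n_resamples,seed permutation settings.
#' @return list with `patient_mva` (data.frame), `tests` (data.frame:
#'   test, statistic, p), `dropped_patients`.
#' @export
mva_association <- function(mva_results, patients, annotation, covariate = "nodal",
                            threshold_pct = 0.6, strata_col = NULL,
                            n_resamples = 1000, seed = NULL) {
  if (is.data.frame(mva_results)) {
    tab <- mva_results
  } else {
    tab <- data.frame(spot_id = vapply(mva_results, `[[`, "", "spot_id"),
                      mva_percent = vapply(mva_results, function(r)
                        if (r$excluded) NA_real_ else r$mva_percent, 0),
                      excluded = vapply(mva_results, `[[`, TRUE, "excluded"),
                      stringsAsFactors = FALSE)
  }
  tab$patient_id <- patients
  usable <- !tab$excluded
  dropped <- setdiff(unique(tab$patient_id), unique(tab$patient_id[usable]))
  pm <- stats::aggregate(mva_percent ~ patient_id, data = tab[usable, ], FUN = mean)
  pm$high_mva <- pm$mva_percent > threshold_pct
  ann <- annotation[match(pm$patient_id, annotation$patient_id), ]
  cv <- as.character(ann[[covariate]])
  cv[cv == "unknown"] <- NA
  ok <- !is.na(cv)
  lev <- unique(cv[ok])
  if (length(lev) != 2) stop("covariate must have exactly two observed levels")
  ft <- stats::fisher.test(table(factor(pm$high_mva[ok], levels = c(FALSE, TRUE)),
                                 factor(cv[ok], levels = lev)))
  w <- welch_stat(pm$mva_percent[ok & cv == lev[1]],
                  pm$mva_percent[ok & cv == lev[2]])
  tests <- data.frame(test = c("fisher_threshold", "welch_numeric"),
                      statistic = c(unname(ft$estimate), unname(w["t"])),
                      p = c(ft$p.value, unname(w["p"])),
                      stringsAsFactors = FALSE)
  if (!is.null(strata_col)) {
    ap <- stage_adjusted_p(pm$mva_percent[ok], cv[ok],
                           ann[[strata_col]][ok], n_resamples, seed)
    tests <- rbind(tests, data.frame(test = "stage_adjusted_numeric",
                                     statistic = ap$t_obs, p = ap$p))
  }
  list(patient_mva = pm, tests = tests, dropped_patients = dropped)
}
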