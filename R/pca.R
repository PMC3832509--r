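#' Principal component analysis of an expression matrix
#'
#' Probes are centered across samples and the centered matrix decomposed by
#' SVD. Loadings ("projection scores") are per-probe, scores per-sample,
#' and variance fractions are squared singular values over their total.
#' Each component is oriented so that its largest-magnitude probe loading
#' is positive, making component signs reproducible.
#'
#' @param x an `expression_matrix` (complete; impute upstream) or a numeric
#'   probe x sample matrix.
#' @return a `pca_result`: list with `loadings` (probe x component),
#'   `scores` (sample x component), `variance_fraction`, `center`
#'   (per-probe means).
#' @export
run_pca <- function(x) {
  v <- if (inherits(x, "expression_matrix")) x$values else x
  if (ncol(v) < 2) stop("PCA needs at least 2 samples")
  if (anyNA(v)) stop("PCA input contains missing values; impute upstream")
  ctr <- rowMeans(v)
  vc <- v - ctr
  sv <- svd(vc)
  flip <- vapply(seq_along(sv$d), function(c) {
    i <- which.max(abs(sv$u[, c]))
    sign(sv$u[i, c])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$u, 2, flip, `*`)
  scores <- sweep(sv$v %*% diag(sv$d, length(sv$d)), 2, flip, `*`)
  cn <- paste0("PC", seq_along(sv$d))
  dimnames(loadings) <- list(rownames(v), cn)
  dimnames(scores) <- list(colnames(v), cn)
  tot <- sum(sv$d^2)
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = stats::setNames(sv$d^2 / tot, cn),
                 center = ctr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(8, length(x$variance_fraction))
  cat(sprintf("pca_result: %d probes, %d samples\n",
              nrow(x$loadings), nrow(x$scores)))
  cat("  variance fractions:",
      paste(sprintf("%s %.1f%%", names(x$variance_fraction)[1:k],
                    100 * x$variance_fraction[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the extreme-loading probes of a component
#'
#' Probes are ranked by signed loading on the chosen component; the `n`
#' highest (`tail = "top"`) or lowest (`tail = "bottom"`) are returned.
#' Ties are broken by probe id. The default n = 250 matches the module
#' size used for component-interpretation enrichment.
#'
#' @param pca a `pca_result`.
#' @param component component index or name (e.g. 4 or "PC4").
#' @param n number of probes to return.
#' @param tail `"top"` or `"bottom"`.
#' @return character vector of probe ids, most extreme first.
#' @export
top_probes <- function(pca, component, n = 250, tail = c("bottom", "top")) {
  tail <- match.arg(tail)
  if (is.character(component)) component <- match(component, colnames(pca$loadings))
  if (is.na(component) || component < 1 || component > ncol(pca$loadings))
    stop("component out of range")
  if (n > nrow(pca$loadings)) stop("n exceeds the number of probes")
  ld <- pca$loadings[, component]
  ids <- rownames(pca$loadings)
  ord <- if (tail == "top") order(-ld, ids) else order(ld, ids)
  ids[ord][seq_len(n)]
}

#' Associate a principal component with clinical covariates
#'
#' For each covariate: a nominal variable with exactly two observed levels
#' is tested by a two-tailed Welch t-test on the component scores; a
#' numeric variable by Pearson correlation with a two-tailed p-value.
#' Unknown/missing values are excluded per covariate; covariates with
#' fewer than two observed levels are skipped with a note.
#'
#' @param pca a `pca_result`.
#' @param annotation annotation data.frame with a `sample_id` column.
#' @param component component index or name.
#' @param covariates columns to test (default: all but sample/patient ids).
#' @return data.frame with covariate, type, statistic, estimate, p, n, note.
#' @export
associate_component <- function(pca, annotation, component,
                                covariates = setdiff(names(annotation),
                                                     c("sample_id", "patient_id"))) {
  if (is.character(component)) component <- match(component, colnames(pca$scores))
  if (is.na(component) || component < 1 || component > ncol(pca$scores))
    stop("component out of range")
  sc <- pca$scores[, component]
  ann <- annotation[match(rownames(pca$scores), annotation$sample_id), ]
  res <- lapply(covariates, function(cv) {
    v <- ann[[cv]]
    row <- data.frame(covariate = cv, type = NA_character_,
                      statistic = NA_real_, estimate = NA_real_,
                      p = NA_real_, n = NA_integer_, note = "",
                      stringsAsFactors = FALSE)
    if (is.numeric(v)) {
      ok <- !is.na(v)
      if (sum(ok) < 3 || stats::sd(v[ok]) == 0 || stats::sd(sc[ok]) == 0) {
        row$note <- "skipped: too few observations or constant"
        return(row)
      }
      ct <- stats::cor.test(sc[ok], v[ok])
      row$type <- "pearson"; row$statistic <- unname(ct$statistic)
      row$estimate <- unname(ct$estimate); row$p <- ct$p.value; row$n <- sum(ok)
    } else {
      v <- as.character(v)
      ok <- !is.na(v) & v != "unknown"
      lev <- unique(v[ok])
      if (length(lev) != 2) {
        row$note <- sprintf("skipped: %d observed level(s)", length(lev))
        return(row)
      }
      g1 <- sc[ok & v == lev[1]]; g2 <- sc[ok & v == lev[2]]
      if (length(g1) < 2 || length(g2) < 2) {
        row$note <- "skipped: group with fewer than 2 samples"
        return(row)
      }
      tt <- stats::t.test(g1, g2)
      row$type <- "welch_t"; row$statistic <- unname(tt$statistic)
      row$estimate <- mean(g1) - mean(g2); row$p <- tt$p.value
      row$n <- sum(ok)
      row$note <- paste(lev, collapse = " vs ")
    }
    row
  })
  do.call(rbind, res)
}
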