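#' Probe-by-sample expression container
#'
#' Lightweight container for WG-DASL-style microarray data: an intensity
#' matrix (raw or log2 scale), optional per-cell detection p-values, a
#' probe-to-gene-symbol map and a sample-to-slide (batch) assignment.
#' Detection p-values drive all "detectable" calls downstream; the
#' detection threshold defaults to p < 0.01 and is configurable wherever
#' it is used.
#'
#' @param values numeric probe x sample matrix. Rownames are probe ids,
#'   colnames sample ids; both are required and must be unique.
#' @param gene_symbols character vector of per-probe gene symbols (NA where
#'   unannotated). Uppercased on construction; signatures are symbol-keyed.
#' @param detection_p optional probe x sample matrix of detection p-values
#'   in \[0, 1\].
#' @param slide optional character vector naming the slide (batch) of each
#'   sample, in sample order or named by sample id.
#' @param log2 logical; TRUE if `values` are already on the log2 scale.
#' @param missing_mask optional logical probe x sample matrix marking cells
#'   with no usable measurement.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_symbols`, `detection_p`, `slide`, `log2`, `normalized`,
#'   `missing_mask`, `imputed`.
#' @export
expression_matrix <- function(values, gene_symbols = NULL, detection_p = NULL,
                              slide = NULL, log2 = FALSE, missing_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id")
  if (!is.null(gene_symbols)) {
    if (length(gene_symbols) != nrow(values))
      stop("gene_symbols length must equal number of probes")
    gene_symbols <- toupper(as.character(gene_symbols))
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values)))
      stop("detection_p dimensions must match values")
    rng <- range(detection_p, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("detection p-values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  if (!is.null(slide)) {
    if (!is.null(names(slide))) {
      if (!all(colnames(values) %in% names(slide)))
        stop("slide assignment missing for some samples")
      slide <- slide[colnames(values)]
    } else if (length(slide) != ncol(values)) {
      stop("slide length must equal number of samples")
    } else {
      names(slide) <- colnames(values)
    }
    slide <- as.character(slide)
    names(slide) <- colnames(values)
  }
  if (is.null(missing_mask)) {
    missing_mask <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  } else if (!identical(dim(missing_mask), dim(values))) {
    stop("missing_mask dimensions must match values")
  } else {
    dimnames(missing_mask) <- dimnames(values)
  }
  structure(list(values = values, gene_symbols = gene_symbols,
                 detection_p = detection_p, slide = slide,
                 log2 = isTRUE(log2), normalized = FALSE,
                 missing_mask = missing_mask, imputed = NULL),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "raw",
              if (x$normalized) ", quantile-normalized" else ""))
  cat(sprintf("  detection p-values: %s; slide labels: %s\n",
              if (is.null(x$detection_p)) "absent" else "present",
              if (is.null(x$slide)) "absent" else
                paste0(length(unique(x$slide)), " slides")))
  if (!is.null(x$gene_symbols))
    cat(sprintf("  gene symbols: %d annotated\n", sum(!is.na(x$gene_symbols))))
  invisible(x)
}

#' Subset an expression matrix by probes and/or samples
#'
#' @param x an `expression_matrix`.
#' @param i probe index (integer, logical or probe-id character).
#' @param j sample index (integer, logical or sample-id character).
#' @param ... ignored.
#' @return an `expression_matrix` with all parallel slots subset consistently.
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  if (!is.null(x$gene_symbols)) {
    names(x$gene_symbols) <- rownames(x$values)
    out$gene_symbols <- unname(x$gene_symbols[rownames(out$values)])
  }
  if (!is.null(x$detection_p)) out$detection_p <- x$detection_p[i, j, drop = FALSE]
  if (!is.null(x$slide)) out$slide <- x$slide[colnames(out$values)]
  out$missing_mask <- x$missing_mask[i, j, drop = FALSE]
  if (!is.null(x$imputed)) out$imputed <- x$imputed[i, j, drop = FALSE]
  out
}

#' Detectable-call mask
#'
#' A cell is "detectable" when its detection p-value is below `threshold`.
#'
#' @param x an `expression_matrix` with detection p-values.
#' @param threshold detection p-value cut-off (default 0.01).
#' @return logical probe x sample matrix.
#' @export
detectable_mask <- function(x, threshold = 0.01) {
  if (is.null(x$detection_p))
    stop("no detection p-values in this expression matrix")
  x$detection_p < threshold
}

#' Collapse probes to gene symbols
#'
#' Averages the rows of all probes mapping to the same (uppercased) gene
#' symbol; unannotated probes are dropped. Used before symbol-keyed scoring.
#'
#' @param x an `expression_matrix` with gene symbols.
#' @return numeric gene x sample matrix with symbol rownames.
#' @export
collapse_to_genes <- function(x) {
  if (is.null(x$gene_symbols)) stop("no gene symbols in this expression matrix")
  keep <- !is.na(x$gene_symbols) & nzchar(x$gene_symbols)
  v <- x$values[keep, , drop = FALSE]
  sym <- x$gene_symbols[keep]
  grp <- factor(sym, levels = unique(sym))
  out <- rowsum(v, grp, reorder = FALSE) / as.vector(table(grp))
  rownames(out) <- levels(grp)
  out
}

#' Gene signature: symbols with per-gene weights
#'
#' A named gene list with a real-valued weight per gene: +/-1 for
#' directional up/down lists, real centroid values for subtype signatures.
#' A constant weight vector is rejected: Pearson activation scoring against
#' it is undefined.
#'
#' @param name signature name.
#' @param genes character gene symbols (uppercased on construction).
#' @param weights numeric, one per gene.
#' @return a `gene_signature` object.
#' @export
gene_signature <- function(name, genes, weights) {
  genes <- toupper(as.character(genes))
  weights <- as.numeric(weights)
  if (length(genes) != length(weights))
    stop("signature '", name, "': genes and weights differ in length")
  if (length(genes) == 0) stop("signature '", name, "' is empty")
  if (anyDuplicated(genes)) stop("signature '", name, "': duplicate gene symbols")
  if (any(is.na(weights))) stop("signature '", name, "': NA weight")
  if (length(unique(weights)) < 2)
    stop("signature '", name, "': degenerate (constant) weight vector")
  structure(list(name = name, genes = genes, weights = stats::setNames(weights, genes)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes, weights in [%.3g, %.3g]\n",
              x$name, length(x$genes), min(x$weights), max(x$weights)))
  invisible(x)
}
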