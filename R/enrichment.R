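#' One-sided hypergeometric over-representation test
#'
#' P(overlap >= observed) for drawing `selection_size` genes from a
#' universe containing `set_size` set members.
#' @keywords internal
hyper_p <- function(overlap, set_size, universe_size, selection_size) {
  stats::phyper(overlap - 1, set_size, universe_size - set_size,
                selection_size, lower.tail = FALSE)
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Tests each set in a collection for over-representation in a gene
#' selection (e.g. the genes behind a component's extreme-loading probes),
#' by the one-sided (upper tail) hypergeometric probability — identical to
#' a one-sided Fisher's exact test on the 2x2 membership table. Gene
#' symbols are deduplicated and uppercased; each set is first intersected
#' with the universe, and sets disjoint from the universe are skipped with
#' a note. P-values are Benjamini-Hochberg adjusted across the collection.
#'
#' @param selection character gene symbols (will be intersected with the
#'   universe and deduplicated).
#' @param collection a `gene_set_collection` (named list of symbol vectors).
#' @param universe character vector of all testable gene symbols.
#' @return data.frame: set, universe_size, set_size, selection_size,
#'   overlap, expected, odds_ratio, p, fdr, note.
#' @export
fisher_enrichment <- function(selection, collection, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty universe")
  selection <- intersect(unique(toupper(selection)), universe)
  U <- length(universe); S <- length(selection)
  res <- lapply(names(collection), function(nm) {
    set_u <- intersect(unique(toupper(collection[[nm]])), universe)
    m <- length(set_u)
    if (m == 0)
      return(data.frame(set = nm, universe_size = U, set_size = 0L,
                        selection_size = S, overlap = 0L, expected = NA_real_,
                        odds_ratio = NA_real_, p = NA_real_, fdr = NA_real_,
                        note = "skipped: set disjoint from universe",
                        stringsAsFactors = FALSE))
    k <- length(intersect(selection, set_u))
    a <- k; b <- S - k; c <- m - k; d <- U - S - m + k
    data.frame(set = nm, universe_size = U, set_size = m,
               selection_size = S, overlap = k,
               expected = S * m / U,
               odds_ratio = (a * d) / max(1e-12, b * c),
               p = hyper_p(k, m, U, S), fdr = NA_real_, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$p)
  out$fdr[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out[order(out$p), ]
}

#' GO enrichment with the elim decorrelation procedure
#'
#' Tests every DAG term for over-representation of the selection by the
#' one-sided hypergeometric test, reporting both the classic p-value
#' (full propagated annotation) and the elim p-value. Terms are processed
#' children-before-parents (reverse topological order); whenever a term's
#' elim p-value falls below `elim_threshold`, all genes annotated to it
#' (as currently seen by the elim pass) are removed from every ancestor's
#' annotation set before the ancestors are tested, decorrelating nested
#' terms. With `elim_threshold = 0` (or a flat DAG) elim reduces exactly
#' to classic. FDR (Benjamini-Hochberg) is reported on the elim p-values.
#'
#' @param selection character gene symbols.
#' @param dag a [go_dag()] with propagated annotations.
#' @param universe character vector of testable gene symbols.
#' @param elim_threshold significance threshold triggering elimination
#'   (default 0.01).
#' @return data.frame: term, name, universe_size, set_size, set_size_elim,
#'   overlap, overlap_elim, p_classic, p_elim, fdr, note.
#' @export
go_elim_enrichment <- function(selection, dag, universe, elim_threshold = 0.01) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty universe")
  selection <- intersect(unique(toupper(selection)), universe)
  U <- length(universe); S <- length(selection)
  # ancestors closure
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in dag$order) {            # parents before children
    anc[[t]] <- unique(c(unlist(anc[dag$parents[[t]]]), dag$parents[[t]]))
  }
  removed <- stats::setNames(replicate(length(dag$terms), character(0),
                                       simplify = FALSE), dag$terms)
  rows <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in rev(dag$order)) {       # children before parents
    ann_full <- intersect(dag$genes[[t]], universe)
    ann_elim <- setdiff(ann_full, removed[[t]])
    m_c <- length(ann_full); m_e <- length(ann_elim)
    k_c <- length(intersect(selection, ann_full))
    k_e <- length(intersect(selection, ann_elim))
    p_c <- if (m_c > 0) hyper_p(k_c, m_c, U, S) else NA_real_
    p_e <- if (m_e > 0) hyper_p(k_e, m_e, U, S) else NA_real_
    if (!is.na(p_e) && elim_threshold > 0 && p_e < elim_threshold) {
      for (a in anc[[t]]) removed[[a]] <- union(removed[[a]], ann_elim)
    }
    rows[[t]] <- data.frame(term = t, name = unname(dag$names[t]),
                            universe_size = U, set_size = m_c,
                            set_size_elim = m_e, overlap = k_c,
                            overlap_elim = k_e, p_classic = p_c, p_elim = p_e,
                            fdr = NA_real_,
                            note = if (m_c == 0) "skipped: no annotated genes in universe" else "",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[dag$terms])
  ok <- !is.na(out$p_elim)
  out$fdr[ok] <- stats::p.adjust(out$p_elim[ok], method = "BH")
  rownames(out) <- NULL
  out[order(out$p_elim), ]
}

#' Map selected probes to unique gene symbols
#'
#' Collapses a probe selection (e.g. from [top_probes()]) to the set of
#' unique gene symbols, counting each gene once however many of its probes
#' were selected. Unannotated probes are dropped.
#'
#' @param probes character probe ids.
#' @param x the `expression_matrix` the probes came from.
#' @return character vector of unique gene symbols.
#' @export
probes_to_genes <- function(probes, x) {
  if (is.null(x$gene_symbols)) stop("no gene symbols in this expression matrix")
  sym <- x$gene_symbols[match(probes, rownames(x$values))]
  unique(sym[!is.na(sym) & nzchar(sym)])
}
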