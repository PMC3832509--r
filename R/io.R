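#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect is: optional `#!` metadata lines (`#! scale=log2|raw`,
#' `#! slides=<comma-separated slide per sample>`), then a header
#' `probe_id<TAB>gene_symbol<TAB><sample ids...>` and one row per probe.
#' Detection p-values, if present, live in a parallel file
#' `<path minus .tsv>.detection.tsv` with the same probe/sample layout,
#' which is picked up automatically. GCT (version 1.2: `#1.2` line, a
#' dimensions line, then Name/Description columns) is accepted without
#' detection values; GCT intensities are taken as raw scale.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") return(read_gct(path))
  lines <- readLines(path)
  meta_idx <- grep("^#!", lines)
  meta <- list(scale = "raw", slides = NULL)
  for (m in lines[meta_idx]) {
    kv <- strsplit(sub("^#!\\s*", "", m), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(body)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "probe_id" || header[2] != "gene_symbol")
    stop("malformed header at line ", meta_idx_offset(lines, body[1]),
         ": expected 'probe_id<TAB>gene_symbol<TAB>samples...'")
  samples <- header[-(1:2)]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("malformed row at line ", meta_idx_offset(lines, body[-1][bad[1]]),
         ": expected ", length(header), " fields")
  probe_ids <- vapply(rows, `[[`, "", 1L)
  gene_symbols <- vapply(rows, `[[`, "", 2L)
  gene_symbols[gene_symbols %in% c("", "NA")] <- NA_character_
  values <- matrix(as.numeric(unlist(lapply(rows, `[`, -(1:2)))),
                   nrow = length(rows), byrow = TRUE,
                   dimnames = list(probe_ids, samples))
  detection_p <- NULL
  dpath <- paste0(sub("\\.tsv$", "", path), ".detection.tsv")
  if (file.exists(dpath)) {
    dtab <- utils::read.delim(dpath, check.names = FALSE, row.names = 1)
    detection_p <- as.matrix(dtab)[probe_ids, samples, drop = FALSE]
  }
  slides <- NULL
  if (!is.null(meta$slides)) {
    slides <- trimws(strsplit(meta$slides, ",", fixed = TRUE)[[1]])
    if (length(slides) != length(samples))
      stop("slides metadata lists ", length(slides), " entries for ",
           length(samples), " samples")
  }
  em <- expression_matrix(values, gene_symbols = gene_symbols,
                          detection_p = detection_p, slide = slides,
                          log2 = identical(meta$scale, "log2"))
  em
}

meta_idx_offset <- function(lines, line) which(lines == line)[1]

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !grepl("^#1\\.2", lines[1]))
    stop("malformed header at line 1: expected GCT version line '#1.2'")
  dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][1:2])
  if (any(is.na(dims)))
    stop("malformed header at line 2: expected '<n_probes><TAB><n_samples>'")
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:2)]
  if (anyDuplicated(samples)) stop("duplicate sample id in GCT header")
  if (length(samples) != dims[2])
    stop("GCT dimensions line declares ", dims[2], " samples but header has ",
         length(samples))
  rows <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != dims[1])
    stop("GCT dimensions line declares ", dims[1], " probes but file has ",
         length(rows))
  probe_ids <- vapply(rows, `[[`, "", 1L)
  gene_symbols <- vapply(rows, `[[`, "", 2L)
  gene_symbols[gene_symbols %in% c("", "NA", "na")] <- NA_character_
  values <- matrix(as.numeric(unlist(lapply(rows, `[`, -(1:2)))),
                   nrow = length(rows), byrow = TRUE,
                   dimnames = list(probe_ids, samples))
  expression_matrix(values, gene_symbols = gene_symbols, log2 = FALSE)
}

#' Write an expression matrix as TSV (with detection companion)
#'
#' Inverse of [read_expression()]: writes `#!` metadata (scale, slides),
#' the probe table, and — when detection p-values are present — the
#' parallel `<path minus .tsv>.detection.tsv`.
#'
#' @param x an `expression_matrix`.
#' @param path output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#! scale=", if (x$log2) "log2" else "raw"), con)
  if (!is.null(x$slide))
    writeLines(paste0("#! slides=", paste(x$slide, collapse = ",")), con)
  gs <- if (is.null(x$gene_symbols)) rep(NA_character_, nrow(x$values)) else x$gene_symbols
  writeLines(paste(c("probe_id", "gene_symbol", colnames(x$values)), collapse = "\t"), con)
  body <- cbind(rownames(x$values), ifelse(is.na(gs), "NA", gs),
                format(x$values, trim = TRUE, digits = 15))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  if (!is.null(x$detection_p)) {
    dpath <- paste0(sub("\\.tsv$", "", path), ".detection.tsv")
    dtab <- data.frame(probe_id = rownames(x$values),
                       x$detection_p, check.names = FALSE)
    utils::write.table(dtab, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Symbols are uppercased; empty sets and duplicate set names are rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("gene set '", fields[[short[1]]][1], "' has an empty gene list")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Read a weighted signature TSV
#'
#' Two tab-separated columns, `gene` and `weight`, with a header line.
#'
#' @param path file path.
#' @param name signature name; defaults to the file name without extension.
#' @return a [gene_signature()].
#' @export
read_signature <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(tab)))
    stop("signature file must have 'gene' and 'weight' columns")
  gene_signature(name, tab$gene, tab$weight)
}

#' @rdname read_signature
#' @param x a `gene_signature`.
#' @export
write_signature <- function(x, path) {
  utils::write.table(data.frame(gene = x$genes, weight = unname(x$weights)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample annotation CSV
#'
#' Expected columns: `sample_id`, `patient_id`, `ethnicity` (AA, EA,
#' Hispanic or unknown), `stage` (1-4 or unknown), `nodal` (pos, neg,
#' unknown), `age` (years), `tissue_site` (primary or other). Stage is
#' coded numerically; "unknown" becomes NA and such samples are retained
#' but excluded from stage-stratified computations.
#'
#' @param path CSV path.
#' @return a `data.frame`, one row per sample.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "ethnicity", "stage", "nodal", "age", "tissue_site")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in annotation")
  tab$stage <- suppressWarnings(as.integer(ifelse(tab$stage %in% c("unknown", ""),
                                                  NA, tab$stage)))
  if (any(!is.na(tab$stage) & (tab$stage < 1 | tab$stage > 4)))
    stop("stage must be 1-4 or unknown")
  tab
}

#' @rdname read_annotation
#' @param annotation annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  out <- annotation
  out$stage <- ifelse(is.na(out$stage), "unknown", out$stage)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OBO-lite GO DAG from TSV
#'
#' Tab-separated columns `term_id`, `name`, `parents` (pipe-separated,
#' empty for roots) and `genes` (pipe-separated direct annotations).
#' The graph must be acyclic; on load, gene annotations are propagated
#' to all ancestors (true-path rule).
#'
#' @param path TSV path.
#' @return a `go_dag`: list with `terms` (per-term name/parents/genes,
#'   annotations propagated), and `order` (a topological order, leaves last).
#' @export
read_go_dag <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("term_id", "name", "parents", "genes")
  if (!all(req %in% names(tab)))
    stop("GO DAG file must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(tab$term_id)) stop("duplicate term_id in DAG")
  split_pipe <- function(s) {
    out <- strsplit(s, "|", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  parents <- split_pipe(tab$parents)
  genes <- lapply(split_pipe(tab$genes), toupper)
  names(parents) <- names(genes) <- tab$term_id
  unknown <- setdiff(unlist(parents), tab$term_id)
  if (length(unknown))
    stop("parent term not defined: ", paste(unknown, collapse = ", "))
  go_dag(tab$term_id, stats::setNames(tab$name, tab$term_id), parents, genes)
}

#' Construct a GO-style DAG
#'
#' @param term_ids character term ids.
#' @param term_names named character, term id -> display name.
#' @param parents named list, term id -> character vector of parent ids.
#' @param genes named list, term id -> directly annotated gene symbols.
#' @return a `go_dag` with annotations propagated to ancestors.
#' @export
go_dag <- function(term_ids, term_names, parents, genes) {
  order <- topo_sort(term_ids, parents)           # parents before children
  # propagate annotations upward: visit children-first (reverse order)
  ann <- lapply(genes[term_ids], function(g) unique(toupper(g)))
  names(ann) <- term_ids
  for (t in rev(order)) {
    for (p in parents[[t]]) ann[[p]] <- union(ann[[p]], ann[[t]])
  }
  structure(list(terms = term_ids,
                 names = term_names[term_ids],
                 parents = parents[term_ids],
                 direct_genes = lapply(genes[term_ids],
                                       function(g) unique(toupper(g))),
                 genes = ann,
                 order = order),
            class = "go_dag")
}

# Kahn topological sort; errors on cycles.
topo_sort <- function(term_ids, parents) {
  indeg <- stats::setNames(lengths(parents[term_ids]), term_ids)
  children <- stats::setNames(vector("list", length(term_ids)), term_ids)
  for (t in term_ids) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  queue <- names(indeg)[indeg == 0]
  out <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    out <- c(out, t)
    for (ch in children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(term_ids))
    stop("cycle detected in GO DAG involving: ",
         paste(setdiff(term_ids, out), collapse = ", "))
  out
}

#' Filter samples on clinical annotation
#'
#' Applies equality/membership and threshold conditions to the annotation
#' table and returns the surviving sample ids. Conditions are given as a
#' named list: a plain field name means membership in the given values
#' (e.g. `list(ethnicity = c("AA", "EA"))`); a numeric field suffixed
#' `_min`/`_max` is an inclusive threshold (e.g. `list(age_min = 18)`).
#' With `per_patient = TRUE`, only the first surviving sample (by sample id
#' order) of each patient is kept. Idempotent by construction.
#'
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @param conditions named list of conditions; unknown field names error.
#' @param per_patient keep one sample per patient?
#' @return character vector of sample ids.
#' @export
filter_clinical <- function(annotation, conditions = list(), per_patient = FALSE) {
  if (nrow(annotation) == 0) return(character(0))
  keep <- rep(TRUE, nrow(annotation))
  for (nm in names(conditions)) {
    field <- sub("_(min|max)$", "", nm)
    if (!field %in% names(annotation))
      stop("unknown annotation field: ", field)
    v <- annotation[[field]]
    cond <- conditions[[nm]]
    if (grepl("_min$", nm)) keep <- keep & !is.na(v) & v >= cond
    else if (grepl("_max$", nm)) keep <- keep & !is.na(v) & v <= cond
    else keep <- keep & !is.na(v) & v %in% cond
  }
  ids <- annotation$sample_id[keep]
  if (per_patient) {
    pat <- annotation$patient_id[keep]
    ord <- order(ids)
    ids <- ids[ord][!duplicated(pat[ord])]
    ids <- sort(ids)
  }
  ids
}
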