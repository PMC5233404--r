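#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, then member genes.
#'
#' @param path File path.
#' @return Named list of character vectors, with per-set descriptions in
#'   the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("GMT file is empty.")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(parts))
  descs <- character(length(parts))
  nms <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) {
      abort(sprintf("GMT line %d: set '%s' has no member genes.", i,
                    if (length(p)) p[[1]] else ""))
    }
    nms[i] <- p[[1]]
    descs[i] <- p[[2]]
    sets[[i]] <- unique(p[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    abort(sprintf("Duplicate gene-set name(s): %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  names(sets) <- nms
  structure(sets, descriptions = setNames(descs, nms))
}

#' Write a GMT gene-set file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(gene_sets)))
  descs <- descriptions %||% attr(gene_sets, "descriptions") %||%
    setNames(rep("na", length(gene_sets)), names(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CLS phenotype-label file
#'
#' Standard categorical CLS: line 1 `n_samples n_classes 1`, line 2
#' `# class names`, line 3 space-separated per-sample labels (either the
#' class names or 0-based indices).
#'
#' @param path File path.
#' @return Character vector of per-sample class labels, with class names in
#'   the `classes` attribute.
#' @export
read_cls <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort("CLS file must have 3 lines.")
  hdr <- scan(text = lines[[1]], what = integer(), quiet = TRUE)
  if (length(hdr) < 2L) abort("CLS line 1: expected 'n_samples n_classes 1'.")
  classes <- scan(text = sub("^#\\s*", "", lines[[2]]), what = character(), quiet = TRUE)
  if (length(classes) != hdr[[2]]) {
    abort(sprintf("CLS line 2: %d class name(s) but header declares %d.",
                  length(classes), hdr[[2]]))
  }
  labels <- scan(text = lines[[3]], what = character(), quiet = TRUE)
  if (length(labels) != hdr[[1]]) {
    abort(sprintf("CLS line 3: %d label(s) but header declares %d samples.",
                  length(labels), hdr[[1]]))
  }
  if (all(labels %in% as.character(seq_along(classes) - 1L))) {
    labels <- classes[as.integer(labels) + 1L]
  } else if (!all(labels %in% classes)) {
    bad <- setdiff(unique(labels), classes)
    abort(sprintf("CLS line 3: unknown sample label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  structure(labels, classes = classes)
}

#' Write a CLS phenotype-label file
#'
#' @param labels Character vector of per-sample class labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(labels, path) {
  classes <- unique(labels)
  writeLines(c(
    paste(length(labels), length(classes), 1),
    paste("#", paste(classes, collapse = " ")),
    paste(labels, collapse = " ")
  ), path)
  invisible(path)
}

#' Read an expression matrix (TSV or GCT v1.2)
#'
#' TSV: header of sample ids, first column gene/probe ids. GCT v1.2: the
#' standard `#1.2` header, dimensions line, then `Name`/`Description`
#' columns before the samples.
#'
#' @param path File path; format detected from a leading `#1.2` line.
#' @return Numeric matrix with gene/probe rownames and sample colnames.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "#1.2")) {
    dims <- scan(text = readLines(path, n = 2L, warn = FALSE)[2], quiet = TRUE)
    tbl <- readr::read_tsv(path, skip = 2L, show_col_types = FALSE,
                           progress = FALSE)
    if (nrow(tbl) != dims[1] || ncol(tbl) - 2L != dims[2]) {
      abort(sprintf("GCT declares %d x %d but body is %d x %d.",
                    dims[1], dims[2], nrow(tbl), ncol(tbl) - 2L))
    }
    m <- as.matrix(tbl[, -(1:2)])
    rownames(m) <- tbl[[1]]
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(m) <- tbl[[1]]
  }
  if (!is.numeric(m)) abort("Expression values are not numeric.")
  if (anyDuplicated(rownames(m))) abort("Duplicate row ids in expression matrix.")
  m
}

#' Write an expression matrix as TSV
#'
#' @param values Numeric matrix with rownames.
#' @param path Output path.
#' @param id_column Name for the first (id) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path, id_column = "gene") {
  tbl <- tibble::as_tibble(values, rownames = id_column)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read / write a pathway-drug enrichment-score matrix (TSV)
#'
#' Rows are pathways (first column `pathway`), remaining columns one drug
#' each. Numeric values round-trip at full double precision.
#'
#' @param path File path.
#' @return A `pathway_drug_matrix`.
#' @export
read_es_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  if (!is.numeric(m)) abort("ES matrix values are not numeric.")
  structure(m, class = c("pathway_drug_matrix", "matrix", "array"))
}

#' @rdname read_es_matrix
#' @param m A `pathway_drug_matrix` (or named numeric matrix).
#' @export
write_es_matrix <- function(m, path) {
  tbl <- tibble::as_tibble(unclass(m), rownames = "pathway")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read / write validation-network edge lists (TSV)
#'
#' Columns `node_a`, `node_b`, `edge_type`, `weight`.
#'
#' @param path File path.
#' @return Tibble of edges.
#' @export
read_edge_list <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("node_a", "node_b", "edge_type", "weight")
  if (!all(req %in% names(tbl))) {
    abort(paste0("Edge list needs columns: ", paste(req, collapse = ", ")))
  }
  tbl
}

#' @rdname read_edge_list
#' @param edges Tibble of edges.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Read / write a drug score table (TSV)
#'
#' @param path File path.
#' @return A `drug_score_table` tibble.
#' @export
read_score_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(tbl) <- c("drug_score_table", class(tbl))
  tbl
}

#' @rdname read_score_table
#' @param scores A [score_drugs()] table.
#' @export
write_score_table <- function(scores, path) {
  readr::write_tsv(tibble::as_tibble(scores), path)
  invisible(path)
}

#' Write per-dataset enrichment results (TSV)
#'
#' Fixed column order: pathway, es, nes, p, n_matched.
#'
#' @param result An [enrich_dataset()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  readr::write_tsv(result[, c("pathway", "es", "nes", "p", "n_matched")], path)
  invisible(path)
}

#' Read a plain list of drug ids (one per line)
#'
#' @param path File path.
#' @return Character vector (comment and blank lines skipped).
#' @export
read_drug_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
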