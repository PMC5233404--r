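#' Assemble the pathway-drug enrichment matrix
#'
#' Collects per-drug pathway enrichment scores into a pathways-by-drugs
#' matrix. Input is either a named list of enrichment tibbles (one per drug,
#' as from [enrich_dataset()] on the drug-vs-vehicle contrast) or a long
#' tibble with columns `drug`, `pathway`, `es`. Pathway/drug combinations
#' with no reported ES are filled with 0 (a warning reports how many).
#'
#' @param enrichments Named list of tibbles with columns `pathway` and `es`,
#'   or a single long tibble with columns `drug`, `pathway`, `es`.
#' @return A numeric matrix (class `pathway_drug_matrix`), pathways in rows,
#'   drugs in columns, entries in `[-1, 1]`.
#' @export
build_pathway_drug_matrix <- function(enrichments) {
  if (is.data.frame(enrichments)) {
    stopifnot(all(c("drug", "pathway", "es") %in% names(enrichments)))
    long <- tibble::as_tibble(enrichments)[, c("drug", "pathway", "es")]
  } else {
    if (is.null(names(enrichments)) || anyDuplicated(names(enrichments))) {
      abort("Per-drug enrichment lists must have unique drug names.")
    }
    long <- purrr::imap_dfr(enrichments, function(tbl, nm) {
      tibble::tibble(drug = nm, pathway = tbl$pathway, es = tbl$es)
    })
  }
  if (anyDuplicated(long[, c("drug", "pathway")])) {
    abort("Duplicate (drug, pathway) enrichment entries.")
  }
  if (!all(is.finite(long$es))) abort("Enrichment scores must be finite.")
  pathways <- sort(unique(long$pathway))
  drugs <- sort(unique(long$drug))
  m <- matrix(0, length(pathways), length(drugs),
              dimnames = list(pathways, drugs))
  m[cbind(match(long$pathway, pathways), match(long$drug, drugs))] <- long$es
  n_missing <- length(m) - nrow(long)
  if (n_missing > 0L) {
    warn(sprintf("%d pathway-drug cell(s) had no enrichment result; filled with 0.",
                 n_missing))
  }
  structure(m, class = c("pathway_drug_matrix", "matrix", "array"))
}

#' Long-format view of a pathway-drug matrix
#'
#' @param x A `pathway_drug_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `pathway`, `drug`, `es`.
#' @method tidy pathway_drug_matrix
#' @export
tidy.pathway_drug_matrix <- function(x, ...) {
  tibble::tibble(
    pathway = rep(rownames(x), times = ncol(x)),
    drug = rep(colnames(x), each = nrow(x)),
    es = as.vector(unclass(x))
  )
}

#' Build the weighted pathway-drug bipartite graph
#'
#' Converts the enrichment matrix into a bipartite graph with pathway nodes
#' `U`, drug nodes `V`, and edge weights derived from the enrichment scores.
#' Two weight conventions are supported: `"abs"` (default) keeps `|ES|`,
#' treating strong enrichment in either direction as evidence of
#' association; `"positive"` keeps only positive scores. Entries at or below
#' `threshold` are dropped, and nodes left without any edge are removed with
#' a warning (the normalization is undefined at degree zero).
#'
#' @param m A `pathway_drug_matrix` (or plain named numeric matrix,
#'   pathways x drugs).
#' @param weight_transform `"abs"` or `"positive"`.
#' @param threshold Sparsification cutoff `tau >= 0`; an edge is kept when
#'   its transformed weight exceeds it strictly. Default 0 keeps every
#'   nonzero association (the network is dense, as in the source enrichment
#'   matrix).
#' @return An object of class `bipartite_graph`: list with `w` (weight
#'   matrix, retained pathways x retained drugs), `pathways`, `drugs`, and
#'   `dropped` (names of isolated nodes removed).
#' @export
build_bipartite <- function(m, weight_transform = c("abs", "positive"),
                            threshold = 0) {
  weight_transform <- match.arg(weight_transform)
  stopifnot(is.matrix(m), is.numeric(m), threshold >= 0)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("Matrix must carry pathway rownames and drug colnames.")
  }
  w <- if (weight_transform == "abs") abs(unclass(m)) else pmax(unclass(m), 0)
  w[w <= threshold] <- 0
  keep_u <- rowSums(w) > 0
  keep_v <- colSums(w) > 0
  dropped <- c(rownames(w)[!keep_u], colnames(w)[!keep_v])
  if (length(dropped)) {
    warn(sprintf("Dropped %d isolated node(s) (no edge above threshold).",
                 length(dropped)))
  }
  w <- w[keep_u, keep_v, drop = FALSE]
  if (sum(w > 0) == 0L) abort("Bipartite graph has no edges after thresholding.")
  structure(
    list(w = w, pathways = rownames(w), drugs = colnames(w), dropped = dropped),
    class = "bipartite_graph"
  )
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %d pathways x %d drugs, %d edges\n",
              length(x$pathways), length(x$drugs), sum(x$w > 0)))
  invisible(x)
}

#' Edge list of a bipartite graph
#'
#' @param x A `bipartite_graph`.
#' @param ... Unused.
#' @return Tibble with columns `pathway`, `drug`, `weight` (positive edges
#'   only).
#' @method tidy bipartite_graph
#' @export
tidy.bipartite_graph <- function(x, ...) {
  ij <- which(x$w > 0, arr.ind = TRUE)
  tibble::tibble(
    pathway = rownames(x$w)[ij[, 1L]],
    drug = colnames(x$w)[ij[, 2L]],
    weight = x$w[ij]
  ) |>
    dplyr::arrange(.data$pathway, .data$drug)
}

#' @method glance bipartite_graph
#' @export
glance.bipartite_graph <- function(x, ...) {
  tibble::tibble(
    n_pathways = length(x$pathways), n_drugs = length(x$drugs),
    n_edges = sum(x$w > 0), n_dropped = length(x$dropped)
  )
}

#' Symmetric degree normalization of a bipartite graph
#'
#' Computes `B = D_u^{-1/2} W D_v^{-1/2}`, where `W` is the weight matrix
#' and `D_u`, `D_v` are diagonal matrices of weighted node degrees
#' (`d(u) = sum_v w(u,v)` and vice versa). The largest singular value of `B`
#' is at most 1, which guarantees convergence of the label-propagation
#' iteration for any damping below 1.
#'
#' @param g A [build_bipartite()] graph.
#' @return An object of class `normalized_bipartite`: list with `b` (the
#'   normalized matrix, pathways x drugs), `pathways`, `drugs`.
#' @export
symmetric_normalize <- function(g) {
  stopifnot(inherits(g, "bipartite_graph"))
  du <- rowSums(g$w)
  dv <- colSums(g$w)
  if (any(du <= 0) || any(dv <= 0)) {
    abort("Zero-degree node encountered; rebuild the graph with `build_bipartite()`.")
  }
  b <- g$w / (sqrt(du) %o% sqrt(dv))
  structure(
    list(b = b, pathways = g$pathways, drugs = g$drugs),
    class = "normalized_bipartite"
  )
}

#' @export
print.normalized_bipartite <- function(x, ...) {
  cat(sprintf("<normalized_bipartite> %d pathways x %d drugs\n",
              length(x$pathways), length(x$drugs)))
  invisible(x)
}
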