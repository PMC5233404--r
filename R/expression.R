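#' Construct a case/control expression dataset
#'
#' Bundles a genes-by-samples matrix of (log-scale) expression values with a
#' binary phenotype for each sample. This is the unit of input for pathway
#' enrichment: one object per study, several objects when integrating across
#' studies.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene
#'   symbols), samples in columns.
#' @param sample_labels Character or factor of length `ncol(values)`; each
#'   entry must be one of `case`/`control`.
#' @param case,control The label values denoting the two classes.
#' @param na_action What to do with genes containing missing values:
#'   `"omit"` drops the rows (with a warning), `"impute"` replaces each
#'   missing value with the row mean.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix) and `is_case` (logical per sample).
#' @export
#' @examples
#' x <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
#' ds <- expression_dataset(x, c("case", "case", "case", "control", "control"))
#' ds
expression_dataset <- function(values, sample_labels,
                               case = "case", control = "control",
                               na_action = c("omit", "impute")) {
  na_action <- match.arg(na_action)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values))) abort("`values` must have gene symbols as rownames.")
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate gene ids in `values`; collapse probes first (see `collapse_probes()`).")
  }
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) != ncol(values)) {
    abort("`sample_labels` must have one entry per sample column.")
  }
  bad <- setdiff(unique(sample_labels), c(case, control))
  if (length(bad)) {
    abort(paste0("Unknown sample label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(values)) {
    na_rows <- rowSums(is.na(values)) > 0
    if (na_action == "omit") {
      warn(sprintf("Dropping %d gene(s) with missing values.", sum(na_rows)))
      values <- values[!na_rows, , drop = FALSE]
      if (nrow(values) == 0L) abort("All genes had missing values.")
    } else {
      rm_ <- rowMeans(values, na.rm = TRUE)
      idx <- which(is.na(values), arr.ind = TRUE)
      values[idx] <- rm_[idx[, 1L]]
    }
  }
  structure(
    list(values = values, is_case = sample_labels == case,
         case = case, control = control),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples (%d %s / %d %s)\n",
    nrow(x$values), ncol(x$values),
    sum(x$is_case), x$case, sum(!x$is_case), x$control
  ))
  invisible(x)
}

#' Collapse probe-level expression to gene level
#'
#' Maps probe ids to gene symbols and averages the expression of probes that
#' share a symbol. Probes without a mapped symbol are discarded.
#'
#' @param probe_values Numeric matrix, probes in rows (unique rownames =
#'   probe ids), samples in columns.
#' @param mapping Data frame whose first two columns are probe id and gene
#'   symbol. The mapping may be partial.
#'
#' @return A genes-by-samples numeric matrix with unique gene rownames.
#'   Attribute `n_dropped` records how many probes had no mapping.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 4, 4), 2, 2, byrow = TRUE,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' collapse_probes(m, data.frame(probe = c("P1", "P2"), gene = c("G", "G")))
collapse_probes <- function(probe_values, mapping) {
  if (!is.matrix(probe_values) || is.null(rownames(probe_values))) {
    abort("`probe_values` must be a matrix with probe-id rownames.")
  }
  if (anyDuplicated(rownames(probe_values))) abort("Probe ids must be unique.")
  mapping <- as.data.frame(mapping)[, 1:2]
  names(mapping) <- c("probe", "gene")
  mapping <- mapping[!is.na(mapping$gene) & nzchar(mapping$gene), , drop = FALSE]
  gene <- mapping$gene[match(rownames(probe_values), mapping$probe)]
  keep <- !is.na(gene)
  n_dropped <- sum(!keep)
  if (!any(keep)) abort("No probe mapped to a gene symbol; mapping unusable.")
  out <- rowsum(probe_values[keep, , drop = FALSE], group = gene[keep])
  cnt <- as.vector(table(gene[keep])[rownames(out)])
  out <- out / cnt
  structure(out, n_dropped = n_dropped)
}

#' Rank genes by the signal-to-noise statistic
#'
#' Computes, per gene, (mean_case - mean_control) / (sd_case + sd_control),
#' with each class standard deviation floored at `0.2 * |class mean|` (and a
#' small absolute floor) so that low-variance genes do not dominate. Genes
#' are returned sorted by the statistic, descending; ties are broken by gene
#' symbol so the ordering is fully deterministic.
#'
#' @param ds An [expression_dataset()].
#' @return A tibble with columns `gene` and `metric`, one row per gene, in
#'   ranking order.
#' @export
rank_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  for (cls in c(TRUE, FALSE)) {
    n <- sum(ds$is_case == cls)
    if (n < 2L) {
      abort(sprintf("Class '%s' has %d sample(s); at least 2 are required.",
                    if (cls) ds$case else ds$control, n))
    }
  }
  metric <- unname(signal_to_noise(ds$values, ds$is_case))
  ord <- order(-metric, rownames(ds$values), method = "radix")
  tibble::tibble(gene = rownames(ds$values)[ord], metric = metric[ord])
}

# Vectorized signal-to-noise with GSEA-style sd floor.
signal_to_noise <- function(values, is_case, sd_floor_frac = 0.2, eps = 1e-8) {
  xc <- values[, is_case, drop = FALSE]
  xn <- values[, !is_case, drop = FALSE]
  mc <- rowMeans(xc); mn <- rowMeans(xn)
  sc <- apply(xc, 1L, stats::sd); sn <- apply(xn, 1L, stats::sd)
  sc <- pmax(sc, sd_floor_frac * abs(mc), eps)
  sn <- pmax(sn, sd_floor_frac * abs(mn), eps)
  (mc - mn) / (sc + sn)
}

# Signal-to-noise for many label permutations at once.
# values: G x S; case_mat: S x B 0/1 membership of the case class per
# permutation. Returns G x B metric matrix.
signal_to_noise_perm <- function(values, case_mat, sd_floor_frac = 0.2, eps = 1e-8) {
  ctrl_mat <- 1 - case_mat
  nc <- colSums(case_mat); nn <- colSums(ctrl_mat)
  s1c <- values %*% case_mat
  s1n <- values %*% ctrl_mat
  v2 <- values^2
  s2c <- v2 %*% case_mat
  s2n_ <- v2 %*% ctrl_mat
  mc <- sweep(s1c, 2L, nc, "/")
  mn <- sweep(s1n, 2L, nn, "/")
  varc <- sweep(s2c - sweep(mc^2, 2L, nc, "*"), 2L, nc - 1, "/")
  varn <- sweep(s2n_ - sweep(mn^2, 2L, nn, "*"), 2L, nn - 1, "/")
  sc <- pmax(sqrt(pmax(varc, 0)), sd_floor_frac * abs(mc), eps)
  sn <- pmax(sqrt(pmax(varn, 0)), sd_floor_frac * abs(mn), eps)
  (mc - mn) / (sc + sn)
}
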