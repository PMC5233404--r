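#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list: each gene in `gene_set` ("hit") advances a
#' running sum by its weighted metric `|r|^p` (normalized so the hits sum to
#' one), every other gene ("miss") retreats it by `1/(N - k)`. The enrichment
#' score is the running-sum value of maximal absolute deviation from zero,
#' keeping its sign, and always lies in `[-1, 1]`.
#'
#' Genes in the set that are absent from the ranking are ignored; their count
#' is `length(gene_set) - attr(result, "n_matched")`.
#'
#' @param ranked A tibble as returned by [rank_genes()] (columns `gene`,
#'   `metric`, already in ranking order).
#' @param gene_set Character vector of gene symbols.
#' @param weight_exponent Non-negative exponent `p` applied to `|metric|` for
#'   hit increments. `0` gives the classic unweighted KS statistic; the
#'   default `1` weights hits by their ranking metric.
#' @return A length-one numeric (the ES) with attribute `n_matched`.
#' @export
#' @examples
#' ranked <- tibble::tibble(gene = paste0("g", 1:4), metric = c(2, 1, -1, -2))
#' enrichment_score(ranked, c("g1", "g3"), weight_exponent = 0)  # 0.5
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(is.data.frame(ranked), weight_exponent >= 0)
  pos <- which(ranked$gene %in% gene_set)
  if (length(pos) == 0L) {
    abort("`gene_set` has no overlap with the ranked gene list.")
  }
  absr <- abs(ranked$metric)^weight_exponent
  es <- es_from_positions(pos, absr, nrow(ranked))
  structure(es, n_matched = length(pos))
}

# Core ES computation from sorted-or-not hit positions.
# absr: |metric|^p for every position of the ranking (length N).
es_from_positions <- function(pos, absr, n) {
  k <- length(pos)
  if (k == n) return(1)
  pos <- sort.int(pos)
  hw <- absr[pos]
  nr <- sum(hw)
  # All hit weights zero (flat metric with p > 0): fall back to equal steps,
  # which is the p = 0 statistic.
  if (nr == 0) hw <- rep.int(1 / k, k) else hw <- hw / nr
  miss_step <- 1 / (n - k)
  tops <- cumsum(hw) - (pos - seq_len(k)) * miss_step
  bottoms <- tops - hw
  mx <- max(tops)
  mn <- min(bottoms)
  if (mx >= -mn) mx else mn
}

#' Permutation p-value and normalized enrichment score for one pathway
#'
#' Estimates the significance of an enrichment score against a permutation
#' null. By default the phenotype labels are permuted and the whole ranking
#' recomputed per permutation; when either class has fewer than 7 samples the
#' null falls back to gene-set permutation (random sets of the same size
#' drawn from the ranking). The p-value uses the add-one estimator
#' `(1 + extreme) / (1 + same_sign)` over permutations whose ES has the same
#' sign as the observed one, so it is never exactly zero. The normalized
#' enrichment score (NES) divides the observed ES by the mean `|ES|` of the
#' same-sign permutations and is `NA` when no permutation lands on the same
#' sign.
#'
#' @inheritParams enrichment_score
#' @param ds An [expression_dataset()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; required, so that results are reproducible.
#' @param perm_type `"auto"` (default: phenotype permutation, gene-set
#'   fallback below 7 samples/class), `"phenotype"`, or `"geneset"`.
#' @return A one-row tibble: `es`, `nes`, `p`, `n_matched`, `n_same_sign`,
#'   `perm_type`.
#' @export
nominal_p <- function(ds, gene_set, n_perm = 1000, seed,
                      weight_exponent = 1, perm_type = c("auto", "phenotype", "geneset")) {
  res <- enrich_dataset(ds, list(pathway = gene_set),
                        n_perm = n_perm, seed = seed,
                        weight_exponent = weight_exponent,
                        perm_type = perm_type, min_overlap = 1L)
  res[, c("es", "nes", "p", "n_matched", "n_same_sign", "perm_type")]
}

#' Pathway enrichment of one dataset against a gene-set collection
#'
#' Runs the weighted KS enrichment for every pathway with at least
#' `min_overlap` genes present in the dataset, sharing one set of
#' permutations across pathways.
#'
#' @inheritParams nominal_p
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param min_overlap Minimum number of pathway genes present in the dataset
#'   for a pathway to be scored (default 5).
#' @return A tibble with one row per scored pathway: `pathway`, `es`, `nes`,
#'   `p`, `n_matched`, `n_same_sign`, `perm_type`, sorted by `p`. Pathways
#'   skipped for insufficient overlap are recorded in the `skipped`
#'   attribute.
#' @export
enrich_dataset <- function(ds, gene_sets, n_perm = 1000, seed,
                           weight_exponent = 1,
                           perm_type = c("auto", "phenotype", "geneset"),
                           min_overlap = 5L) {
  stopifnot(inherits(ds, "expression_dataset"))
  perm_type <- match.arg(perm_type)
  if (missing(seed)) abort("`seed` is required for reproducible permutation p-values.")
  if (n_perm < 1L) abort("`n_perm` must be at least 1.")
  if (!length(gene_sets)) abort("`gene_sets` is empty.")
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets))) {
    abort("`gene_sets` must be a uniquely named list.")
  }

  genes_ds <- rownames(ds$values)
  n <- length(genes_ds)
  row_index <- setNames(seq_len(n), genes_ds)
  # secondary sort key: rank of the gene symbol, for deterministic ties
  tie <- integer(n)
  tie[order(genes_ds, method = "radix")] <- seq_len(n)

  idx <- purrr::map(gene_sets, ~ unname(row_index[intersect(unique(.x), genes_ds)]))
  overlap <- lengths(idx)
  keep <- overlap >= min_overlap
  skipped <- tibble::tibble(pathway = names(gene_sets)[!keep],
                            n_matched = overlap[!keep])
  if (!any(keep)) abort("No pathway meets `min_overlap` in this dataset.")
  idx <- idx[keep]
  idx0 <- lapply(idx, function(i) i - 1L)

  metric_obs <- signal_to_noise(ds$values, ds$is_case)
  es_obs <- drop(perm_es_matrix(matrix(metric_obs, ncol = 1L), tie, idx0,
                                weight_exponent))
  names(es_obs) <- names(idx)

  min_class <- min(sum(ds$is_case), sum(!ds$is_case))
  used <- if (perm_type == "auto") {
    if (min_class < 7L) "geneset" else "phenotype"
  } else perm_type

  es_null <- withr::with_seed(seed, {
    if (used == "phenotype") {
      phenotype_null(ds, idx0, tie, n_perm, weight_exponent)
    } else {
      ord <- order(-metric_obs, tie, method = "radix")
      absr <- abs(metric_obs[ord])^weight_exponent
      geneset_null(absr, lengths(idx), n_perm, n, names(idx))
    }
  })

  stats_tbl <- purrr::imap_dfr(idx, function(ii, nm) {
    null_i <- es_null[[nm]]
    obs <- es_obs[[nm]]
    sgn <- if (obs >= 0) 1 else -1
    same <- null_i[sign(null_i) == sgn]
    n_same <- length(same)
    if (n_same == 0L) {
      tibble::tibble(pathway = nm, es = obs, nes = NA_real_,
                     p = 1 / (1 + n_perm), n_matched = length(ii),
                     n_same_sign = 0L)
    } else {
      tibble::tibble(
        pathway = nm, es = obs,
        nes = obs / mean(abs(same)),
        p = (1 + sum(abs(same) >= abs(obs))) / (1 + n_same),
        n_matched = length(ii), n_same_sign = n_same
      )
    }
  })
  out <- dplyr::arrange(stats_tbl, .data$p, .data$pathway)
  out$perm_type <- used
  attr(out, "skipped") <- skipped
  attr(out, "n_perm") <- n_perm
  out
}

# Phenotype-permutation null: permute class labels, re-rank, recompute ES for
# every set (ranking + running sums in C++). Returns a named list of
# length-n_perm numeric vectors.
phenotype_null <- function(ds, idx0, tie, n_perm, weight_exponent) {
  s <- length(ds$is_case)
  n_case <- sum(ds$is_case)
  case_mat <- matrix(0, s, n_perm)
  for (b in seq_len(n_perm)) case_mat[sample.int(s, n_case), b] <- 1
  metrics <- signal_to_noise_perm(ds$values, case_mat)
  es <- perm_es_matrix(metrics, tie, idx0, weight_exponent)
  setNames(lapply(seq_along(idx0), function(j) es[, j]), names(idx0))
}

# Gene-set permutation null: random position sets of matching size on the
# observed ranking. Sets of equal size share the same null draws.
geneset_null <- function(absr, sizes, n_perm, n, set_names) {
  by_size <- new.env(parent = emptyenv())
  out <- vector("list", length(sizes))
  names(out) <- set_names
  for (j in seq_along(sizes)) {
    key <- as.character(sizes[[j]])
    if (is.null(by_size[[key]])) {
      by_size[[key]] <- vapply(seq_len(n_perm), function(b) {
        es_from_positions(sample.int(n, sizes[[j]]), absr, n)
      }, numeric(1))
    }
    out[[j]] <- by_size[[key]]
  }
  out
}

#' Integrate per-dataset enrichment results into disease-specific pathways
#'
#' Selects, for each dataset, the pathways with nominal p below
#' `p_threshold`, and returns their union with provenance (which datasets
#' each pathway was significant in).
#'
#' @param results Named list of enrichment tibbles (one per dataset, as
#'   returned by [enrich_dataset()]).
#' @param p_threshold Nominal p-value cutoff (default 0.01).
#' @return A tibble with columns `pathway`, `n_datasets`, `datasets`
#'   (list-column of dataset names), `min_p`, sorted by `n_datasets`
#'   descending then pathway. Zero rows (with a warning) when nothing is
#'   selected.
#' @export
integrate_disease_pathways <- function(results, p_threshold = 0.01) {
  if (!length(results)) abort("`results` must contain at least one dataset's enrichment table.")
  if (is.null(names(results))) names(results) <- paste0("dataset", seq_along(results))
  long <- purrr::imap_dfr(results, function(tbl, nm) {
    sel <- dplyr::filter(tbl, .data$p < p_threshold)
    if (nrow(sel) == 0L) return(tibble::tibble(pathway = character(), dataset = character(), p = numeric()))
    tibble::tibble(pathway = sel$pathway, dataset = nm, p = sel$p)
  })
  if (nrow(long) == 0L) {
    warn("No pathway passed the threshold in any dataset; empty union.")
    return(tibble::tibble(pathway = character(), n_datasets = integer(),
                          datasets = list(), min_p = numeric()))
  }
  long |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(n_datasets = dplyr::n_distinct(.data$dataset),
                     datasets = list(sort(unique(.data$dataset))),
                     min_p = min(.data$p), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_datasets), .data$pathway)
}
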