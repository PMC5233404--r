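#' Define a synthetic-data scenario
#'
#' Fixes the sizes, effect strengths and noise levels of the synthetic
#' inputs used to exercise the full repositioning pipeline without external
#' downloads. All generation downstream is fully determined by `seed`.
#'
#' The defaults are sized as a scaled-down analogue of a multi-study
#' case/control compendium: four independent expression datasets of 2000
#' genes and 30 + 30 samples, 200 pathways of 15-40 genes of which 10 carry
#' a planted case shift of 2 standard deviations, and 1000 drugs of which 5
#' are planted repositioning candidates and 5 are known treatment drugs.
#' The planted drugs (1% of the library, mirroring the sparse hit rate of a
#' real drug-repositioning screen) carry near-saturated enrichment (mean
#' |ES| 0.9) on the planted disease pathways over a weak background
#' (noise sd 0.04), the regime in which drugs treating the same phenotype
#' visibly target the same pathways.
#'
#' @param n_genes Genes per dataset.
#' @param n_samples_per_class Samples per class (case and control each).
#' @param n_pathways Number of pathways in the collection.
#' @param pathway_size_range Length-2 integer range of pathway sizes.
#' @param n_datasets Number of independent expression datasets.
#' @param n_disease_pathways Number of planted disease pathways.
#' @param effect_size Case-minus-control shift, in sd units, applied to
#'   genes of planted pathways.
#' @param n_drugs Number of drugs in the enrichment matrix.
#' @param n_candidate_drugs Planted (unlabeled) repositioning candidates.
#' @param n_known_drugs Planted known treatment drugs (labeled positives).
#' @param es_signal_mean Mean |ES| of planted drug-pathway associations
#'   (must be <= 1).
#' @param es_signal_sd Spread of the planted |ES| values.
#' @param es_noise_sd Sd of the background enrichment noise.
#' @param n_validation_genes Gene nodes in the synthetic validation network.
#' @param n_hub_drugs Planted hub drugs in the validation network.
#' @param bg_edge_prob Background edge probability of the validation
#'   network (weights Uniform(0.2, 0.6), so a 0.4 weight filter removes
#'   about half of them).
#' @param seed Integer seed governing all generation.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_genes = 2000, n_samples_per_class = 30,
                                n_pathways = 200, pathway_size_range = c(15, 40),
                                n_datasets = 4, n_disease_pathways = 10,
                                effect_size = 2,
                                n_drugs = 1000, n_candidate_drugs = 5,
                                n_known_drugs = 5,
                                es_signal_mean = 0.9, es_signal_sd = 0.1,
                                es_noise_sd = 0.04,
                                n_validation_genes = 40, n_hub_drugs = 1,
                                bg_edge_prob = 0.1, seed = 1) {
  sc <- as.list(environment())
  if (sc$n_disease_pathways > sc$n_pathways) abort("More planted pathways than pathways.")
  if (sc$n_candidate_drugs + sc$n_known_drugs > sc$n_drugs) {
    abort("Planted drug counts exceed the number of drugs.")
  }
  if (max(sc$pathway_size_range) > sc$n_genes) {
    abort("Pathway sizes exceed the number of genes.")
  }
  if (sc$effect_size < 0) abort("`effect_size` must be non-negative.")
  if (sc$es_signal_mean > 1) abort("`es_signal_mean` must not exceed 1 (ES scale).")
  structure(sc, class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<simulation_scenario> %d datasets x %d genes, %d pathways (%d planted, delta=%g), %d drugs (%d candidates + %d known), seed %d\n",
    x$n_datasets, x$n_genes, x$n_pathways, x$n_disease_pathways, x$effect_size,
    x$n_drugs, x$n_candidate_drugs, x$n_known_drugs, x$seed
  ))
  invisible(x)
}

sim_gene_names <- function(sc) sprintf("G%04d", seq_len(sc$n_genes))
sim_drug_names <- function(sc) sprintf("drug%04d", seq_len(sc$n_drugs))
sim_pathway_names <- function(sc) sprintf("PATHWAY_%03d", seq_len(sc$n_pathways))

# Pathway membership shared by all generators; drawn from its own seed
# stream so expression and drug-matrix generation see identical sets.
sim_gene_sets <- function(sc) {
  withr::with_seed(sc$seed, {
    genes <- sim_gene_names(sc)
    sizes <- sample(seq(sc$pathway_size_range[1], sc$pathway_size_range[2]),
                    sc$n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sim_pathway_names(sc)
    sets
  })
}

#' Simulate case/control expression datasets with planted pathways
#'
#' Control expression is standard normal per gene; genes belonging to the
#' planted disease pathways are shifted by `effect_size` standard deviations
#' in case samples. Noise is drawn independently per dataset, so integrating
#' the per-dataset enrichment results is meaningful.
#'
#' @param sc A [simulation_scenario()].
#' @return List with `datasets` (named list of [expression_dataset()]),
#'   `gene_sets` (named list of gene vectors), and `truth` (tibble
#'   `pathway`, `planted`).
#' @export
simulate_expression_datasets <- function(sc) {
  stopifnot(inherits(sc, "simulation_scenario"))
  gene_sets <- sim_gene_sets(sc)
  planted <- names(gene_sets)[seq_len(sc$n_disease_pathways)]
  shifted_genes <- unique(unlist(gene_sets[planted], use.names = FALSE))
  genes <- sim_gene_names(sc)
  n <- sc$n_samples_per_class
  labels <- rep(c("case", "control"), each = n)
  datasets <- withr::with_seed(sc$seed + 1L, {
    lapply(seq_len(sc$n_datasets), function(d) {
      x <- matrix(rnorm(sc$n_genes * 2 * n), sc$n_genes, 2 * n,
                  dimnames = list(genes, sprintf("d%d_s%02d", d, seq_len(2 * n))))
      x[shifted_genes, seq_len(n)] <- x[shifted_genes, seq_len(n)] + sc$effect_size
      expression_dataset(x, labels)
    })
  })
  names(datasets) <- sprintf("dataset%d", seq_len(sc$n_datasets))
  list(
    datasets = datasets,
    gene_sets = gene_sets,
    truth = tibble::tibble(pathway = names(gene_sets),
                           planted = names(gene_sets) %in% planted)
  )
}

#' Simulate the pathway-drug enrichment matrix with planted candidates
#'
#' Background entries are Gaussian noise truncated to `[-1, 1]`. Known
#' drugs and planted candidate drugs receive boosted-|ES| entries (random
#' sign, magnitude around `es_signal_mean`) on the planted disease
#' pathways, emulating the premise that drugs treating the same phenotype
#' target the same pathways. Known drugs are a labeled subset of the
#' planted-signal drugs; candidates carry the same signal but no label.
#'
#' @param sc A [simulation_scenario()].
#' @return List with `matrix` (a `pathway_drug_matrix`), `truth` (tibble
#'   `drug`, `role` in background/known/candidate), `known_drugs`, and
#'   `candidate_drugs`.
#' @export
simulate_drug_phenotype_matrix <- function(sc) {
  stopifnot(inherits(sc, "simulation_scenario"))
  drugs <- sim_drug_names(sc)
  pathways <- sim_pathway_names(sc)
  planted_paths <- pathways[seq_len(sc$n_disease_pathways)]
  known <- drugs[seq_len(sc$n_known_drugs)]
  candidates <- drugs[sc$n_known_drugs + seq_len(sc$n_candidate_drugs)]
  m <- withr::with_seed(sc$seed + 2L, {
    m <- matrix(rnorm(sc$n_pathways * sc$n_drugs, 0, sc$es_noise_sd),
                sc$n_pathways, sc$n_drugs, dimnames = list(pathways, drugs))
    m <- pmin(pmax(m, -1), 1)
    for (d in c(known, candidates)) {
      mag <- pmin(pmax(rnorm(length(planted_paths), sc$es_signal_mean,
                             sc$es_signal_sd), 0), 1)
      m[planted_paths, d] <- mag * sample(c(-1, 1), length(planted_paths),
                                          replace = TRUE)
    }
    m
  })
  list(
    matrix = structure(m, class = c("pathway_drug_matrix", "matrix", "array")),
    truth = tibble::tibble(
      drug = drugs,
      role = dplyr::case_when(drugs %in% known ~ "known",
                              drugs %in% candidates ~ "candidate",
                              TRUE ~ "background")
    ),
    known_drugs = known,
    candidate_drugs = candidates
  )
}

#' Simulate a heterogeneous validation network with planted hub drugs
#'
#' Drug nodes are the scenario's known and candidate drugs; gene nodes are
#' synthetic. Background edges are Erdos-Renyi with weights
#' Uniform(0.2, 0.6) (so a weight filter at 0.4 removes about half of
#' them); planted hub drugs connect to every known drug and to a majority
#' of genes with strong weights Uniform(0.7, 0.99).
#'
#' @param sc A [simulation_scenario()].
#' @return List with `edges` (tibble ready for
#'   [assemble_validation_network()]) and `hubs` (planted hub drug ids).
#' @export
simulate_validation_network <- function(sc) {
  stopifnot(inherits(sc, "simulation_scenario"))
  drugs <- sim_drug_names(sc)
  known <- drugs[seq_len(sc$n_known_drugs)]
  candidates <- drugs[sc$n_known_drugs + seq_len(sc$n_candidate_drugs)]
  hubs <- candidates[seq_len(min(sc$n_hub_drugs, length(candidates)))]
  net_drugs <- c(known, candidates)
  genes <- sprintf("VGENE%03d", seq_len(sc$n_validation_genes))
  nodes <- c(net_drugs, genes)
  kind <- setNames(rep(c("drug", "gene"), c(length(net_drugs), length(genes))), nodes)
  withr::with_seed(sc$seed + 3L, {
    pairs <- utils::combn(nodes, 2)
    take <- runif(ncol(pairs)) < sc$bg_edge_prob
    bg <- tibble::tibble(node_a = pairs[1, take], node_b = pairs[2, take],
                         weight = runif(sum(take), 0.2, 0.6))
    hub_edges <- purrr::map_dfr(hubs, function(h) {
      gene_nb <- sample(genes, ceiling(0.6 * length(genes)))
      nb <- c(setdiff(known, h), gene_nb)
      tibble::tibble(node_a = h, node_b = nb,
                     weight = runif(length(nb), 0.7, 0.99))
    })
    edges <- dplyr::bind_rows(bg, hub_edges)
    # drug-gene rows must carry the drug in node_a
    swap <- kind[edges$node_a] == "gene" & kind[edges$node_b] == "drug"
    tmp <- edges$node_a[swap]
    edges$node_a[swap] <- edges$node_b[swap]
    edges$node_b[swap] <- tmp
    edges$edge_type <- dplyr::case_when(
      kind[edges$node_a] == "drug" & kind[edges$node_b] == "drug" ~ "drug-drug",
      kind[edges$node_a] == "drug" & kind[edges$node_b] == "gene" ~ "drug-gene",
      TRUE ~ "gene-gene"
    )
    # duplicates (background + hub) resolve later to max weight; keep as is
    list(edges = edges[, c("node_a", "node_b", "edge_type", "weight")],
         hubs = hubs)
  })
}

#' Rank-based recovery AUC of planted candidates
#'
#' Probability that a randomly chosen planted candidate outranks a randomly
#' chosen background drug (known drugs are excluded from the comparison, as
#' they carry the propagation seed labels).
#'
#' @param scores A [score_drugs()] table.
#' @param truth Tibble `drug`, `role` as returned by
#'   [simulate_drug_phenotype_matrix()].
#' @return AUC in `[0, 1]`.
#' @export
recovery_auc <- function(scores, truth) {
  tbl <- dplyr::inner_join(scores, truth, by = "drug") |>
    dplyr::filter(.data$role != "known")
  pos <- tbl$z[tbl$role == "candidate"]
  neg <- tbl$z[tbl$role == "background"]
  if (!length(pos) || !length(neg)) abort("Need both candidate and background drugs.")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
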