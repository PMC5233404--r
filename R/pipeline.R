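#' End-to-end drug repositioning pipeline
#'
#' Runs the full chain: per-dataset pathway enrichment, integration of the
#' significant pathways into the disease-specific set, bipartite network
#' construction from the pathway-drug enrichment matrix, label
#' initialization from disease pathways and known drugs, semisupervised
#' propagation, and Z-score candidate selection.
#'
#' @param datasets Named list of [expression_dataset()] objects.
#' @param gene_sets Named list of gene-symbol vectors (the pathway
#'   collection).
#' @param pd_matrix A `pathway_drug_matrix` of per-drug pathway enrichment
#'   scores.
#' @param known_drugs Character vector of known treatment drugs.
#' @param n_perm Permutations per dataset for the enrichment nulls.
#' @param seed Integer seed; dataset `i` uses `seed + i - 1`.
#' @param p_pathway Per-dataset pathway significance cutoff (default 0.01).
#' @param p_candidate Candidate significance cutoff (default 0.001).
#' @param weight_transform,threshold Passed to [build_bipartite()].
#' @param alpha,tol,max_iter Passed to [propagate()].
#' @param min_overlap Passed to [enrich_dataset()].
#' @return List with `enrichments` (per-dataset tibbles),
#'   `disease_pathways` (integration tibble), `graph`, `labels`,
#'   `propagation`, `scores` (a `drug_score_table`) and `candidates` (the
#'   [select_candidates()] split).
#' @export
reposition_drugs <- function(datasets, gene_sets, pd_matrix, known_drugs,
                             n_perm = 1000, seed,
                             p_pathway = 0.01, p_candidate = 0.001,
                             weight_transform = "abs", threshold = 0,
                             alpha = 0.8, tol = 1e-6, max_iter = 1000L,
                             min_overlap = 5L) {
  if (missing(seed)) abort("`seed` is required.")
  enrichments <- purrr::imap(datasets, function(ds, nm) {
    i <- match(nm, names(datasets))
    enrich_dataset(ds, gene_sets, n_perm = n_perm, seed = seed + i - 1L,
                   min_overlap = min_overlap)
  })
  disease_pathways <- integrate_disease_pathways(enrichments, p_threshold = p_pathway)
  graph <- build_bipartite(pd_matrix, weight_transform = weight_transform,
                           threshold = threshold)
  labels <- initialize_labels(graph, disease_pathways, known_drugs)
  nb <- symmetric_normalize(graph)
  prop <- propagate(nb, labels, alpha = alpha, tol = tol, max_iter = max_iter)
  scores <- score_drugs(prop, known_drugs = known_drugs,
                        p_threshold = p_candidate)
  list(
    enrichments = enrichments,
    disease_pathways = disease_pathways,
    graph = graph,
    labels = labels,
    propagation = prop,
    scores = scores,
    candidates = select_candidates(scores, p_threshold = p_candidate)
  )
}
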