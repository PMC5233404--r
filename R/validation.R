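#' Assemble the heterogeneous drug-gene validation network
#'
#' Builds an undirected weighted network with drug and gene nodes from edge
#' lists of the three relationship types (drug-drug chemical similarity,
#' drug-gene interaction, gene-gene interaction). Filtering mirrors the
#' triage protocol for candidate drugs:
#'
#' 1. optional rescaling of raw database scores into `[0, 1]` (interaction
#'    databases often score 0-900 or 0-1000; any weight above 1 without a
#'    `rescale_divisor` is an error),
#' 2. duplicate edges collapse to their maximum weight,
#' 3. edges with weight `<= weight_min` are dropped (strict inequality:
#'    `weight_min = 0.4` keeps only `r > 0.4`),
#' 4. each drug node keeps at most `neighbor_cap` incident edges, the
#'    strongest by weight (ties broken by neighbor id); an edge between two
#'    drugs must rank within the cap for both,
#' 5. gene-gene edges survive only when both endpoint genes are still
#'    connected to the drug layer.
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `edge_type`
#'   (one of `drug-drug`, `drug-gene`, `gene-gene`; for `drug-gene` rows
#'   `node_a` is the drug) and `weight`. Several edge lists may be passed as
#'   a list and are concatenated.
#' @param weight_min Minimum retained weight, exclusive (default 0.4).
#' @param neighbor_cap Maximum neighbors retained per drug node (default 40).
#' @param rescale_divisor Optional divisor applied to all weights before
#'   filtering (e.g. 1000 for 0-900 interaction scores).
#' @return An object of class `heterogeneous_network`: list with `nodes`
#'   (tibble `node`, `kind`) and `edges` (tibble `node_a`, `node_b`,
#'   `edge_type`, `weight`).
#' @export
assemble_validation_network <- function(edges, weight_min = 0.4,
                                        neighbor_cap = 40L,
                                        rescale_divisor = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) edges <- dplyr::bind_rows(edges)
  edges <- tibble::as_tibble(edges)
  req <- c("node_a", "node_b", "edge_type", "weight")
  if (!all(req %in% names(edges))) {
    abort(paste0("Edge list needs columns: ", paste(req, collapse = ", ")))
  }
  ok_types <- c("drug-drug", "drug-gene", "gene-gene")
  if (!all(edges$edge_type %in% ok_types)) {
    abort(paste0("`edge_type` must be one of: ", paste(ok_types, collapse = ", ")))
  }
  if (any(edges$node_a == edges$node_b)) abort("Self-loops are not allowed.")
  if (!is.null(rescale_divisor)) edges$weight <- edges$weight / rescale_divisor
  if (any(edges$weight > 1)) {
    abort("Edge weights exceed 1; supply `rescale_divisor` to bring scores into [0, 1].")
  }
  if (any(edges$weight < 0)) abort("Edge weights must be non-negative.")

  kinds <- node_kinds(edges)
  kind_of <- setNames(kinds$kind, kinds$node)

  # canonical endpoint order (same-kind edges sorted lexicographically;
  # drug-gene edges keep the drug in node_a), then dedup keeping max weight
  swap <- unname(kind_of[edges$node_a] == kind_of[edges$node_b]) &
    edges$node_a > edges$node_b
  a <- ifelse(swap, edges$node_b, edges$node_a)
  b <- ifelse(swap, edges$node_a, edges$node_b)
  edges <- tibble::tibble(node_a = a, node_b = b,
                          edge_type = edges$edge_type, weight = edges$weight) |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(edge_type = .data$edge_type[which.max(.data$weight)],
                     weight = max(.data$weight), .groups = "drop")

  edges <- dplyr::filter(edges, .data$weight > weight_min)

  # per-drug neighbor cap: an edge is kept iff it ranks within the cap for
  # every drug endpoint
  drug_edges <- edges$edge_type != "gene-gene"
  keep <- rep(TRUE, nrow(edges))
  for (d in kinds$node[kinds$kind == "drug"]) {
    inc <- which((edges$node_a == d | edges$node_b == d) & drug_edges)
    if (length(inc) > neighbor_cap) {
      other <- ifelse(edges$node_a[inc] == d, edges$node_b[inc], edges$node_a[inc])
      ord <- order(-edges$weight[inc], other, method = "radix")
      keep[inc[ord[-seq_len(neighbor_cap)]]] <- FALSE
    }
  }
  edges <- edges[keep, , drop = FALSE]

  # genes survive through their connection to the drug layer
  attached <- unique(c(edges$node_a[edges$edge_type != "gene-gene"],
                       edges$node_b[edges$edge_type != "gene-gene"]))
  gg <- edges$edge_type == "gene-gene"
  edges <- edges[!gg | (edges$node_a %in% attached & edges$node_b %in% attached), ,
                 drop = FALSE]

  if (nrow(edges) == 0L) abort("Validation network is empty after filtering.")
  nodes <- dplyr::filter(kinds, .data$node %in% unique(c(edges$node_a, edges$node_b))) |>
    dplyr::arrange(.data$kind, .data$node)
  structure(list(nodes = nodes, edges = edges), class = "heterogeneous_network")
}

# Infer node kinds from edge types; error on contradictions.
node_kinds <- function(edges) {
  with_kind <- dplyr::bind_rows(
    tibble::tibble(node = edges$node_a[edges$edge_type == "drug-drug"], kind = "drug"),
    tibble::tibble(node = edges$node_b[edges$edge_type == "drug-drug"], kind = "drug"),
    tibble::tibble(node = edges$node_a[edges$edge_type == "drug-gene"], kind = "drug"),
    tibble::tibble(node = edges$node_b[edges$edge_type == "drug-gene"], kind = "gene"),
    tibble::tibble(node = edges$node_a[edges$edge_type == "gene-gene"], kind = "gene"),
    tibble::tibble(node = edges$node_b[edges$edge_type == "gene-gene"], kind = "gene")
  ) |> dplyr::distinct()
  conflict <- with_kind$node[duplicated(with_kind$node)]
  if (length(conflict)) {
    abort(paste0("Node(s) appear as both drug and gene: ",
                 paste(unique(conflict), collapse = ", ")))
  }
  with_kind
}

#' @export
print.heterogeneous_network <- function(x, ...) {
  cat(sprintf("<heterogeneous_network> %d nodes (%d drugs, %d genes), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "drug"),
              sum(x$nodes$kind == "gene"), nrow(x$edges)))
  invisible(x)
}

#' @method glance heterogeneous_network
#' @export
glance.heterogeneous_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_drugs = sum(x$nodes$kind == "drug"),
    n_genes = sum(x$nodes$kind == "gene"),
    n_edges = nrow(x$edges),
    n_drug_drug = sum(x$edges$edge_type == "drug-drug"),
    n_drug_gene = sum(x$edges$edge_type == "drug-gene"),
    n_gene_gene = sum(x$edges$edge_type == "gene-gene")
  )
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b", "weight", "edge_type")],
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Degree centrality of validation-network nodes
#'
#' Unweighted degree divided by `n - 1`, so a node connected to every other
#' node scores 1.
#'
#' @param net A [assemble_validation_network()] result.
#' @return Tibble `node`, `kind`, `degree`, `degree_centrality`, sorted by
#'   centrality descending.
#' @export
degree_centrality <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2L) abort("Degree centrality needs at least 2 nodes.")
  deg <- igraph::degree(g)
  tibble::tibble(
    node = names(deg), kind = net$nodes$kind[match(names(deg), net$nodes$node)],
    degree = as.integer(deg), degree_centrality = as.numeric(deg) / (n - 1)
  ) |>
    dplyr::arrange(dplyr::desc(.data$degree_centrality), .data$node)
}

#' Betweenness of validation-network nodes
#'
#' Unnormalized shortest-path betweenness on the unweighted undirected
#' graph: each unordered node pair contributes 1, split fractionally among
#' equal-length shortest paths through the node.
#'
#' @inheritParams degree_centrality
#' @return Tibble `node`, `kind`, `betweenness`, sorted descending.
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  tibble::tibble(
    node = names(btw), kind = net$nodes$kind[match(names(btw), net$nodes$node)],
    betweenness = as.numeric(btw)
  ) |>
    dplyr::arrange(dplyr::desc(.data$betweenness), .data$node)
}

#' Weighted PageRank of validation-network nodes
#'
#' Damped random-walk stationary scores on the undirected weighted graph
#' (each edge acts as two directed arcs with transition probability
#' proportional to its weight). Raw scores sum to 1; `pagerank_scaled`
#' rescales them min-max into `[0, 1]` across all nodes, and is `NA` (with a
#' warning) when every node scores equally.
#'
#' @inheritParams degree_centrality
#' @param damping Damping factor in (0,1); default 0.85.
#' @return Tibble `node`, `kind`, `pagerank_raw`, `pagerank_scaled`, sorted
#'   by raw score descending.
#' @export
pagerank_centrality <- function(net, damping = 0.85) {
  if (!(damping > 0 && damping < 1)) abort("`damping` must lie in (0,1).")
  g <- as_igraph(net)
  pr <- igraph::page_rank(g, damping = damping,
                          weights = igraph::E(g)$weight)$vector
  rng <- range(pr)
  scaled <- if (rng[2] > rng[1]) {
    (pr - rng[1]) / (rng[2] - rng[1])
  } else {
    warn("All PageRank scores equal; min-max scaling undefined (NA).")
    rep(NA_real_, length(pr))
  }
  tibble::tibble(
    node = names(pr), kind = net$nodes$kind[match(names(pr), net$nodes$node)],
    pagerank_raw = as.numeric(pr), pagerank_scaled = as.numeric(scaled)
  ) |>
    dplyr::arrange(dplyr::desc(.data$pagerank_raw), .data$node)
}

#' All topology metrics of the validation network
#'
#' Joins [degree_centrality()], [betweenness_centrality()] and
#' [pagerank_centrality()] into one per-node table, typically filtered to
#' `kind == "drug"` when triaging candidates.
#'
#' @inheritParams pagerank_centrality
#' @return Tibble with one row per node and all metric columns, sorted by
#'   degree centrality descending.
#' @export
topology_metrics <- function(net, damping = 0.85) {
  degree_centrality(net) |>
    dplyr::left_join(betweenness_centrality(net), by = c("node", "kind")) |>
    dplyr::left_join(pagerank_centrality(net, damping), by = c("node", "kind")) |>
    dplyr::arrange(dplyr::desc(.data$degree_centrality), .data$node)
}
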