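# Independent reference implementations used as oracles. These deliberately
# use the most literal formulation of each quantity (full running-sum walk,
# all-pairs BFS, dense power iteration) and share no code with the package
# internals they check.

# Weighted KS enrichment score by walking the whole ranking.
es_bruteforce <- function(metric_ranked, hit, p = 1) {
  n <- length(metric_ranked)
  stopifnot(length(hit) == n, any(hit), !all(hit))
  w <- abs(metric_ranked)^p
  nr <- sum(w[hit])
  inc <- if (nr == 0) ifelse(hit, 1 / sum(hit), 0) else ifelse(hit, w / nr, 0)
  dec <- ifelse(hit, 0, 1 / (n - sum(hit)))
  rs <- cumsum(inc - dec)
  rs[which.max(abs(rs))]
}

# Random weighted bipartite graph wrapped in the package's constructor.
random_bipartite <- function(nu, nv, density = 0.4) {
  repeat {
    m <- matrix(stats::rbinom(nu * nv, 1, density) * stats::runif(nu * nv),
                nu, nv,
                dimnames = list(sprintf("P%03d", seq_len(nu)),
                                sprintf("D%03d", seq_len(nv))))
    if (sum(m > 0) > 0) {
      return(suppressWarnings(build_bipartite(m)))
    }
  }
}

# Random label assignment over a bipartite graph (at least one pathway hit).
random_labels <- function(g, p1 = 0.3) {
  n_p <- max(1L, stats::rbinom(1L, length(g$pathways), p1))
  n_d <- stats::rbinom(1L, length(g$drugs), p1)
  suppressMessages(suppressWarnings(initialize_labels(
    g,
    disease_pathways = sample(g$pathways, n_p),
    known_drugs = if (n_d > 0) sample(g$drugs, n_d) else character()
  )))
}

# All-pairs-BFS betweenness accumulation (unordered pairs, fractional
# credit over equal-length shortest paths).
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  bfs <- function(s) {
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s; d <- 0
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ])) {
          if (is.infinite(dist[u])) {
            dist[u] <- d + 1
            nxt <- c(nxt, u)
          }
          if (dist[u] == d + 1) sigma[u] <- sigma[u] + sigma[v]
        }
      }
      frontier <- unique(nxt)
      d <- d + 1
    }
    list(dist = dist, sigma = sigma)
  }
  all_bfs <- lapply(seq_len(n), bfs)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ds <- all_bfs[[s]]; dt <- all_bfs[[t]]
      if (is.infinite(ds$dist[t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(ds$dist[v]) && is.finite(dt$dist[v]) &&
            ds$dist[v] + dt$dist[v] == ds$dist[t]) {
          btw[v] <- btw[v] + ds$sigma[v] * dt$sigma[v] / ds$sigma[t]
        }
      }
    }
  }
  btw
}

# Dense power-iteration PageRank on an undirected weighted graph given as a
# symmetric weight matrix (every node assumed to have positive strength).
pagerank_oracle <- function(w, damping = 0.85, tol = 1e-13) {
  n <- nrow(w)
  p_trans <- w / rowSums(w)
  x <- rep(1 / n, n)
  repeat {
    x_new <- (1 - damping) / n + damping * drop(crossprod(p_trans, x))
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
}

# Random heterogeneous edge list with consistent node kinds.
random_validation_edges <- function(n_drugs = 6, n_genes = 12, p_edge = 0.35,
                                    w_min = 0.05, w_max = 1) {
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  kind <- setNames(rep(c("drug", "gene"), c(n_drugs, n_genes)), c(drugs, genes))
  pairs <- utils::combn(c(drugs, genes), 2)
  take <- stats::runif(ncol(pairs)) < p_edge
  a <- pairs[1, take]; b <- pairs[2, take]
  swap <- kind[a] == "gene" & kind[b] == "drug"
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  tibble::tibble(
    node_a = a, node_b = b,
    edge_type = paste0(kind[a], "-", kind[b]),
    weight = stats::runif(length(a), w_min, w_max)
  ) |>
    dplyr::mutate(edge_type = sub("gene-drug", "drug-gene", .data$edge_type))
}

# Tiny deterministic expression dataset with an optional planted set.
small_dataset <- function(n_genes = 120, n_per_class = 10, shift_genes = NULL,
                          delta = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * 2 * n_per_class), n_genes,
                2 * n_per_class,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), NULL))
    if (!is.null(shift_genes)) {
      x[shift_genes, seq_len(n_per_class)] <-
        x[shift_genes, seq_len(n_per_class)] + delta
    }
    expression_dataset(x, rep(c("case", "control"), each = n_per_class))
  })
}
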