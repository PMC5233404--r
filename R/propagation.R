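#' Initialize node labels on the pathway-drug graph
#'
#' Marks disease-specific pathways (on the pathway side) and known treatment
#' drugs (on the drug side) with label 1; every other node gets 0. Name
#' matching is exact string equality, by default after lower-casing both
#' sides; identifiers that fail to match any node are reported, since
#' mapping loss between drug vocabularies is common and must be visible.
#'
#' @param g A [build_bipartite()] graph (or a `normalized_bipartite`).
#' @param disease_pathways Character vector of pathway names (or a tibble
#'   with a `pathway` column, e.g. from [integrate_disease_pathways()]).
#' @param known_drugs Character vector of known treatment drug ids (may be
#'   empty, with a warning).
#' @param ignore_case Lower-case both sides before matching (default TRUE).
#' @return An object of class `label_assignment`: list with named 0/1
#'   vectors `y_u` (pathways), `y_v` (drugs), and character vectors
#'   `unmatched_pathways`, `unmatched_drugs`.
#' @export
initialize_labels <- function(g, disease_pathways, known_drugs = character(),
                              ignore_case = TRUE) {
  stopifnot(inherits(g, c("bipartite_graph", "normalized_bipartite")))
  if (is.data.frame(disease_pathways)) disease_pathways <- disease_pathways$pathway
  disease_pathways <- unique(as.character(disease_pathways))
  known_drugs <- unique(as.character(known_drugs))
  norm <- if (ignore_case) tolower else identity
  y_u <- setNames(as.numeric(norm(g$pathways) %in% norm(disease_pathways)), g$pathways)
  y_v <- setNames(as.numeric(norm(g$drugs) %in% norm(known_drugs)), g$drugs)
  unmatched_p <- disease_pathways[!norm(disease_pathways) %in% norm(g$pathways)]
  unmatched_d <- known_drugs[!norm(known_drugs) %in% norm(g$drugs)]
  if (sum(y_u) + sum(y_v) == 0) {
    abort("No pathway and no drug matched a network node; check identifiers.")
  }
  if (length(known_drugs) == 0L) {
    warn("No known drugs supplied; propagation is seeded from pathways only.")
  }
  if (length(unmatched_p) || length(unmatched_d)) {
    inform(sprintf(
      "Label mapping: %d/%d pathways and %d/%d drugs matched (%d pathway, %d drug id(s) unmatched).",
      sum(y_u), length(disease_pathways), sum(y_v), length(known_drugs),
      length(unmatched_p), length(unmatched_d)
    ))
  }
  structure(
    list(y_u = y_u, y_v = y_v,
         unmatched_pathways = unmatched_p, unmatched_drugs = unmatched_d),
    class = "label_assignment"
  )
}

#' @export
print.label_assignment <- function(x, ...) {
  cat(sprintf("<label_assignment> %d/%d pathways and %d/%d drugs labeled 1\n",
              sum(x$y_u), length(x$y_u), sum(x$y_v), length(x$y_v)))
  invisible(x)
}

#' Semisupervised label propagation over the normalized bipartite graph
#'
#' Iterates the coupled updates
#' \deqn{f_v^t = (1-\alpha) y_v + \alpha \sum_u B_{uv} f_u^{t-1}, \qquad
#'       f_u^t = (1-\alpha) y_u + \alpha \sum_v B_{uv} f_v^{t-1},}
#' where both sides read the previous iteration's values (Jacobi updates),
#' starting from \eqn{f^0 = y}. The damping \eqn{\alpha \in (0,1)} balances
#' the initial labels against the diffused signal. Because the spectral norm
#' of `B` is at most 1, the iteration contracts and converges to the unique
#' fixed point for any \eqn{\alpha < 1}; iteration stops when the maximum
#' absolute change falls below `tol`.
#'
#' @param nb A [symmetric_normalize()] result.
#' @param labels A [initialize_labels()] result (names must cover the
#'   network's nodes).
#' @param alpha Damping in [0, 1); default 0.8. At 0 the scores reduce
#'   to the initial labels.
#' @param tol Convergence tolerance on the max absolute change (default 1e-6).
#' @param max_iter Iteration cap (default 1000). Non-convergence returns the
#'   last iterate with `converged = FALSE` and a warning.
#' @return An object of class `propagation_result`: list with named score
#'   vectors `f_u`, `f_v`, the inputs' labels, `alpha`, `n_iter`,
#'   `converged`, `residual`, and `method = "iterative"`.
#' @export
propagate <- function(nb, labels, alpha = 0.8, tol = 1e-6, max_iter = 1000L) {
  y <- check_propagation_inputs(nb, labels, alpha)
  if (tol <= 0 || max_iter < 1L) abort("`tol` must be positive and `max_iter` >= 1.")
  b <- nb$b
  f_u <- y$y_u
  f_v <- y$y_v
  converged <- FALSE
  residual <- Inf
  n_iter <- 0L
  for (t in seq_len(max_iter)) {
    f_v_new <- (1 - alpha) * y$y_v + alpha * drop(crossprod(b, f_u))
    f_u_new <- (1 - alpha) * y$y_u + alpha * drop(b %*% f_v)
    residual <- max(abs(c(f_u_new - f_u, f_v_new - f_v)))
    f_u <- f_u_new
    f_v <- f_v_new
    n_iter <- t
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("Propagation did not converge in %d iterations (residual %.3g).",
                 max_iter, residual))
  }
  new_propagation_result(nb, y, f_u, f_v, alpha,
                         n_iter = n_iter, converged = converged,
                         residual = residual, method = "iterative")
}

#' Closed-form fixed point of the propagation iteration
#'
#' Solves the linear system whose fixed point the iteration approaches:
#' \eqn{f = (1-\alpha)(I - \alpha M)^{-1} y}, with `M` the symmetric block
#' matrix `[[0, B], [B', 0]]`. Useful as an exact reference for the
#' iterative solver and for small networks.
#'
#' @inheritParams propagate
#' @return A `propagation_result` with `method = "closed_form"`, `n_iter = 0`.
#' @export
propagate_closed_form <- function(nb, labels, alpha = 0.8) {
  y <- check_propagation_inputs(nb, labels, alpha)
  b <- nb$b
  nu <- nrow(b)
  nv <- ncol(b)
  m <- rbind(cbind(matrix(0, nu, nu), b),
             cbind(t(b), matrix(0, nv, nv)))
  f <- (1 - alpha) * solve(diag(nu + nv) - alpha * m, c(y$y_u, y$y_v))
  new_propagation_result(nb, y, f[seq_len(nu)], f[nu + seq_len(nv)], alpha,
                         n_iter = 0L, converged = TRUE, residual = 0,
                         method = "closed_form")
}

check_propagation_inputs <- function(nb, labels, alpha) {
  stopifnot(inherits(nb, "normalized_bipartite"), inherits(labels, "label_assignment"))
  if (!(alpha >= 0 && alpha < 1)) abort("`alpha` must lie in [0, 1).")
  if (!all(is.finite(nb$b))) abort("Normalized matrix contains non-finite values.")
  if (!all(nb$pathways %in% names(labels$y_u)) ||
      !all(nb$drugs %in% names(labels$y_v))) {
    abort("Labels do not cover every network node.")
  }
  list(y_u = labels$y_u[nb$pathways], y_v = labels$y_v[nb$drugs])
}

new_propagation_result <- function(nb, y, f_u, f_v, alpha, n_iter, converged,
                                   residual, method) {
  structure(
    list(
      f_u = setNames(as.numeric(f_u), nb$pathways),
      f_v = setNames(as.numeric(f_v), nb$drugs),
      y_u = y$y_u, y_v = y$y_v,
      alpha = alpha, n_iter = n_iter, converged = converged,
      residual = residual, method = method
    ),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "<propagation_result> %s, alpha = %g, %d pathway + %d drug scores (%s after %d iterations)\n",
    x$method, x$alpha, length(x$f_u), length(x$f_v),
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  invisible(x)
}

#' Per-node propagation scores
#'
#' @param x A `propagation_result`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `kind` (pathway/drug), `label`
#'   (initial 0/1) and `score` (final propagated value), drugs first,
#'   sorted by score descending.
#' @method tidy propagation_result
#' @export
tidy.propagation_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(node = names(x$f_v), kind = "drug",
                   label = unname(x$y_v), score = unname(x$f_v)),
    tibble::tibble(node = names(x$f_u), kind = "pathway",
                   label = unname(x$y_u), score = unname(x$f_u))
  ) |>
    dplyr::arrange(.data$kind, dplyr::desc(.data$score), .data$node)
}

#' @method glance propagation_result
#' @export
glance.propagation_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, alpha = x$alpha, n_iter = x$n_iter,
    converged = x$converged, residual = x$residual,
    n_pathways = length(x$f_u), n_drugs = length(x$f_v),
    n_labeled = sum(x$y_u) + sum(x$y_v)
  )
}
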