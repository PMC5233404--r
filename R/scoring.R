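#' Z-score normalization (population standard deviation)
#'
#' Centers and scales a score vector: `z_i = (x_i - mean(x)) / sd_pop(x)`,
#' where `sd_pop` divides by `n`. The result has mean 0 and population
#' standard deviation 1.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Numeric vector of Z-scores (names preserved).
#' @export
#' @examples
#' zscore_normalize(c(1, 2, 3))  # -1.2247, 0, 1.2247
zscore_normalize <- function(x) {
  if (length(x) < 2L) abort("Need at least 2 scores to Z-normalize.")
  if (!all(is.finite(x))) abort("Scores must be finite.")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) abort("Scores have zero variance; Z-scores are undefined.")
  (x - mean(x)) / s
}

#' Upper-tail Gaussian p-value of a Z-score
#'
#' `p = P(Z >= z)` for standard normal `Z`, evaluated with the exact
#' complementary-distribution routine (no series truncation). One-sided:
#' only unusually *high* propagation scores count as evidence.
#'
#' @param z Numeric vector of Z-scores.
#' @return Numeric vector of p-values in (0, 1).
#' @export
#' @examples
#' gaussian_p(0)      # 0.5
#' gaussian_p(3.452)  # ~0.000278
gaussian_p <- function(z) {
  stopifnot(all(is.finite(z)))
  pnorm(z, lower.tail = FALSE)
}

#' Drug score table from propagation results
#'
#' Converts final drug label scores into Z-scores (population sd) and
#' one-sided Gaussian p-values, flags known drugs and repositioning
#' candidates at the chosen significance threshold, and sorts by Z
#' descending (ties by drug id).
#'
#' @param prop A [propagate()] / [propagate_closed_form()] result, or a
#'   named numeric vector of drug scores.
#' @param known_drugs Character vector of known treatment drugs (matched
#'   case-insensitively against drug ids).
#' @param p_threshold Candidate significance cutoff (default 0.001).
#' @return A tibble of class `drug_score_table`: `drug`, `score`, `z`, `p`,
#'   `known`, `candidate` (`p < p_threshold`).
#' @export
score_drugs <- function(prop, known_drugs = character(), p_threshold = 0.001) {
  scores <- if (inherits(prop, "propagation_result")) prop$f_v else prop
  if (is.null(names(scores))) abort("Drug scores must be named by drug id.")
  if (!(p_threshold > 0 && p_threshold <= 1)) abort("`p_threshold` must be in (0, 1].")
  z <- zscore_normalize(scores)
  p <- gaussian_p(z)
  out <- tibble::tibble(
    drug = names(scores),
    score = unname(scores),
    z = unname(z),
    p = unname(p),
    known = tolower(names(scores)) %in% tolower(known_drugs),
    candidate = unname(p < p_threshold)
  ) |>
    dplyr::arrange(dplyr::desc(.data$z), .data$drug)
  class(out) <- c("drug_score_table", class(out))
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Select repositioning candidates from a drug score table
#'
#' Applies the significance rule `p < p_threshold` and splits the selection
#' into already-known drugs and novel repositioning candidates.
#'
#' @param scores A [score_drugs()] table (or any tibble with `drug`, `z`,
#'   `p` columns).
#' @param p_threshold Significance cutoff (default 0.001).
#' @param known_drugs Known treatment drugs; defaults to the table's `known`
#'   flag when present.
#' @return List with tibbles `selected` (all drugs with `p < p_threshold`,
#'   sorted by `z` descending, ties by drug id) and `novel` (`selected`
#'   minus known drugs). Empty selections are allowed (with a warning).
#' @export
select_candidates <- function(scores, p_threshold = 0.001, known_drugs = NULL) {
  stopifnot(is.data.frame(scores), all(c("drug", "z", "p") %in% names(scores)))
  if (!(p_threshold > 0 && p_threshold <= 1)) abort("`p_threshold` must be in (0, 1].")
  known <- if (!is.null(known_drugs)) {
    tolower(scores$drug) %in% tolower(known_drugs)
  } else if ("known" %in% names(scores)) {
    scores$known
  } else {
    rep(FALSE, nrow(scores))
  }
  known_by_drug <- setNames(known, scores$drug)
  sel <- scores[scores$p < p_threshold, , drop = FALSE]
  sel <- dplyr::arrange(tibble::as_tibble(sel), dplyr::desc(.data$z), .data$drug)
  novel <- sel[!known_by_drug[sel$drug], , drop = FALSE]
  if (nrow(sel) == 0L) warn("No drug passed the significance threshold.")
  list(selected = sel, novel = novel)
}

#' @method glance drug_score_table
#' @export
glance.drug_score_table <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x),
    n_known = sum(x$known),
    n_candidates = sum(x$candidate),
    n_novel = sum(x$candidate & !x$known),
    p_threshold = attr(x, "p_threshold") %||% NA_real_
  )
}
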