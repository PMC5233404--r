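test_that("label initialization matches by configured normalization", {
  m <- matrix(runif(6, 0.1, 1), 2, 3,
              dimnames = list(c("PATH_A", "PATH_B"), c("Tamoxifen", "dB", "dC")))
  g <- build_bipartite(m)
  lab <- initialize_labels(g, "path_a", "TAMOXIFEN")
  expect_equal(unname(lab$y_u), c(1, 0))
  expect_equal(unname(lab$y_v), c(1, 0, 0))
  # exact matching misses the case-mangled ids
  expect_message(
    lab2 <- initialize_labels(g, c("PATH_A"), "TAMOXIFEN", ignore_case = FALSE),
    "unmatched"
  )
  expect_equal(sum(lab2$y_v), 0)
  expect_equal(lab2$unmatched_drugs, "TAMOXIFEN")
  # one-sided initialization is allowed but flagged
  expect_warning(lab3 <- initialize_labels(g, "PATH_B"), "No known drugs")
  expect_equal(sum(lab3$y_u), 1)
  expect_error(suppressWarnings(initialize_labels(g, "nope", "nope2")),
               "No pathway and no drug")
})

test_that("propagation reaches the hand-solved fixed point", {
  # single edge, y_v = 1, y_u = 0: f_v = 1/(1+a), f_u = a/(1+a)
  g <- build_bipartite(matrix(4, 1, 1, dimnames = list("p", "d")))
  nb <- symmetric_normalize(g)
  lab <- suppressWarnings(initialize_labels(g, character(), "d"))
  a <- 0.8
  pr <- propagate(nb, lab, alpha = a, tol = 1e-9)
  expect_true(pr$converged)
  expect_equal(unname(pr$f_v), 1 / (1 + a), tolerance = 1e-6)
  expect_equal(unname(pr$f_u), a / (1 + a), tolerance = 1e-6)
  cf <- propagate_closed_form(nb, lab, alpha = a)
  expect_equal(unname(cf$f_v), 1 / (1 + a), tolerance = 1e-12)
  expect_equal(unname(cf$f_u), a / (1 + a), tolerance = 1e-12)

  # alpha = 0 collapses to the initial labels after one iteration
  pr0 <- propagate(nb, lab, alpha = 0)
  expect_equal(unname(pr0$f_v), 1)
  expect_equal(unname(pr0$f_u), 0)
  expect_equal(unname(propagate_closed_form(nb, lab, alpha = 0)$f_v), 1)
})

test_that("iterative and closed-form propagation agree on random graphs", {
  withr::with_seed(52, {
    for (i in 1:25) {
      g <- random_bipartite(sample(5:40, 1), sample(5:40, 1))
      nb <- symmetric_normalize(g)
      lab <- random_labels(g)
      for (a in c(0.1, 0.5, 0.9)) {
        it <- propagate(nb, lab, alpha = a, tol = 1e-8, max_iter = 5000)
        cf <- propagate_closed_form(nb, lab, alpha = a)
        expect_true(it$converged)
        expect_lt(max(abs(c(it$f_u - cf$f_u, it$f_v - cf$f_v))), 1e-5)
        # nonnegative scores, energy bounded by the labels
        expect_true(all(c(cf$f_u, cf$f_v) >= -1e-12))
        expect_lte(sqrt(sum(c(cf$f_u, cf$f_v)^2)),
                   sqrt(sum(c(lab$y_u, lab$y_v)^2)) + 1e-9)
      }
    }
  })
})

test_that("scores are monotone in the labels and equivariant to node order", {
  withr::with_seed(53, {
    g <- random_bipartite(12, 15)
    nb <- symmetric_normalize(g)
    lab <- random_labels(g)
    base <- propagate_closed_form(nb, lab, 0.7)
    # adding one more positive label never decreases any score
    off <- names(lab$y_v)[lab$y_v == 0]
    lab2 <- lab
    lab2$y_v[off[1]] <- 1
    more <- propagate_closed_form(nb, lab2, 0.7)
    expect_true(all(more$f_u >= base$f_u - 1e-12))
    expect_true(all(more$f_v >= base$f_v - 1e-12))

    # permuting rows and columns permutes the scores identically
    pu <- sample(g$pathways); pv <- sample(g$drugs)
    gp <- build_bipartite(g$w[pu, pv])
    labp <- initialize_labels(gp,
                              names(lab$y_u)[lab$y_u == 1],
                              names(lab$y_v)[lab$y_v == 1])
    prp <- propagate_closed_form(symmetric_normalize(gp), labp, 0.7)
    expect_equal(prp$f_u[g$pathways], base$f_u, tolerance = 1e-12)
    expect_equal(prp$f_v[g$drugs], base$f_v, tolerance = 1e-12)
  })
})

test_that("residuals contract and non-convergence is reported honestly", {
  withr::with_seed(54, {
    g <- random_bipartite(20, 25)
    nb <- symmetric_normalize(g)
    lab <- random_labels(g)
    a <- 0.9
    # replay the Jacobi iteration, tracking the l2 change per sweep
    fu <- lab$y_u[nb$pathways]; fv <- lab$y_v[nb$drugs]
    res <- numeric(30)
    for (t in 1:30) {
      fv_new <- (1 - a) * lab$y_v[nb$drugs] + a * drop(crossprod(nb$b, fu))
      fu_new <- (1 - a) * lab$y_u[nb$pathways] + a * drop(nb$b %*% fv)
      res[t] <- sqrt(sum((fu_new - fu)^2) + sum((fv_new - fv)^2))
      fu <- fu_new; fv <- fv_new
    }
    expect_true(all(diff(res[2:30]) <= 1e-12))

    expect_warning(pr <- propagate(nb, lab, alpha = a, tol = 1e-12, max_iter = 2),
                   "did not converge")
    expect_false(pr$converged)
    expect_equal(pr$n_iter, 2L)
  })
})

test_that("propagation tidiers expose scores and convergence metadata", {
  g <- build_bipartite(matrix(c(1, 0.5), 1, 2, dimnames = list("p", c("d1", "d2"))))
  lab <- suppressWarnings(initialize_labels(g, "p"))
  pr <- propagate(symmetric_normalize(g), lab)
  td <- tidy(pr)
  expect_named(td, c("node", "kind", "label", "score"))
  expect_equal(nrow(td), 3L)
  gl <- glance(pr)
  expect_true(gl$converged)
  expect_equal(gl$n_drugs, 2L)
  expect_equal(gl$n_labeled, 1)
})
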