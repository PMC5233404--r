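test_that("enrichment score reproduces closed-form cases", {
  ranked <- tibble::tibble(gene = paste0("g", 1:4), metric = c(2, 1, -1, -2))
  # set occupying the top positions scores 1 for any weight exponent
  for (p in c(0, 1, 1.5, 2)) {
    expect_equal(as.numeric(enrichment_score(ranked, c("g1", "g2"), p)), 1)
  }
  # alternating set, unweighted: running sum +0.5, 0, +0.5, 0
  expect_equal(as.numeric(enrichment_score(ranked, c("g1", "g3"), 0)), 0.5)
  expect_equal(attr(enrichment_score(ranked, c("g1", "g3"), 0), "n_matched"), 2L)
  # genes absent from the ranking are ignored, not an error
  expect_equal(as.numeric(enrichment_score(ranked, c("g1", "g2", "nope"), 0)), 1)
  # no overlap is an error, not ES = 0
  expect_error(enrichment_score(ranked, c("x", "y")), "no overlap")
})

test_that("enrichment score agrees with the brute-force running sum", {
  withr::with_seed(71, {
    for (i in 1:100) {
      n <- sample(20:80, 1)
      metric <- sort(rnorm(n, sd = sample(c(0.2, 1, 5), 1)), decreasing = TRUE)
      k <- sample(2:(n %/% 2), 1)
      hit_pos <- sort(sample(n, k))
      ranked <- tibble::tibble(gene = sprintf("g%03d", seq_len(n)), metric = metric)
      set <- ranked$gene[hit_pos]
      p <- sample(c(0, 1, 2), 1)
      es <- as.numeric(enrichment_score(ranked, set, p))
      expect_equal(es, es_bruteforce(metric, seq_len(n) %in% hit_pos, p),
                   tolerance = 1e-12)
      expect_true(es >= -1 && es <= 1)
    }
  })
})

test_that("unweighted enrichment depends on ranks only", {
  withr::with_seed(5, {
    n <- 60
    metric <- sort(rnorm(n), decreasing = TRUE)
    ranked <- tibble::tibble(gene = sprintf("g%02d", 1:n), metric = metric)
    set <- sample(ranked$gene, 12)
    base <- as.numeric(enrichment_score(ranked, set, 0))
    for (f in list(function(x) 3 * x + 7, function(x) exp(x), function(x) x^3)) {
      tr <- dplyr::mutate(ranked, metric = f(.data$metric))
      expect_equal(as.numeric(enrichment_score(tr, set, 0)), base)
    }
  })
})

test_that("enrichment score matches the fgsea reference implementation", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(30:100, 1)
      stats <- sort(rnorm(n), decreasing = TRUE)
      names(stats) <- sprintf("g%03d", seq_len(n))
      sel <- sort(sample(n, sample(3:10, 1)))
      ranked <- tibble::tibble(gene = names(stats), metric = unname(stats))
      expect_equal(
        as.numeric(enrichment_score(ranked, names(stats)[sel], 1)),
        fgsea::calcGseaStat(stats, selectedStats = sel, gseaParam = 1),
        tolerance = 1e-10
      )
    }
  })
})

test_that("permutation p-values are deterministic, add-one and sign-aware", {
  ds <- small_dataset(150, 10, shift_genes = 1:15, delta = 2, seed = 21)
  set <- sprintf("g%03d", 1:15)
  r1 <- nominal_p(ds, set, n_perm = 300, seed = 99)
  r2 <- nominal_p(ds, set, n_perm = 300, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$perm_type, "phenotype")
  expect_true(r1$p > 0 && r1$p <= 1)
  # planted shift is as extreme as the null allows: add-one minimum
  expect_equal(r1$p, 1 / (1 + r1$n_same_sign))
  expect_gt(r1$nes, 1)
  # small classes fall back to gene-set permutation
  ds_small <- small_dataset(150, 5, shift_genes = 1:15, delta = 2, seed = 22)
  r3 <- nominal_p(ds_small, set, n_perm = 200, seed = 1)
  expect_equal(r3$perm_type, "geneset")
})

test_that("dataset-level enrichment ranks planted pathways first", {
  ds <- small_dataset(400, 12, shift_genes = 1:60, delta = 2, seed = 13)
  genes <- sprintf("g%03d", 1:400)
  sets <- withr::with_seed(14, c(
    setNames(lapply(1:3, function(i) genes[((i - 1) * 20 + 1):(i * 20)]),
             paste0("planted", 1:3)),
    setNames(replicate(30, sample(genes[61:400], 20), simplify = FALSE),
             paste0("null", 1:30))
  ))
  res <- enrich_dataset(ds, sets, n_perm = 500, seed = 8)
  expect_setequal(head(res$pathway, 3), paste0("planted", 1:3))
  expect_true(all(res$p > 0 & res$p <= 1))
  # a pathway with no measured genes is skipped and reported
  sets2 <- c(sets, list(absent = c("zz1", "zz2", "zz3", "zz4", "zz5")))
  res2 <- enrich_dataset(ds, sets2, n_perm = 50, seed = 8)
  expect_false("absent" %in% res2$pathway)
  expect_true("absent" %in% attr(res2, "skipped")$pathway)
  expect_error(enrich_dataset(ds, list(), n_perm = 10, seed = 1), "empty")
  expect_error(enrich_dataset(ds, sets, n_perm = 10), "seed")
})

test_that("disease-pathway integration takes the union with provenance", {
  mk <- function(pw, p) tibble::tibble(pathway = pw, es = 0.5, nes = 1,
                                       p = p, n_matched = 10L)
  res <- list(d1 = mk(c("A", "B", "C"), c(0.001, 0.005, 0.5)),
              d2 = mk(c("B", "C", "D"), c(0.002, 0.3, 0.004)))
  uni <- integrate_disease_pathways(res, p_threshold = 0.01)
  expect_setequal(uni$pathway, c("A", "B", "D"))
  expect_equal(uni$n_datasets[uni$pathway == "B"], 2L)
  expect_equal(uni$datasets[uni$pathway == "B"][[1]], c("d1", "d2"))
  # single dataset: union equals its own selection
  uni1 <- integrate_disease_pathways(res["d1"], p_threshold = 0.01)
  expect_setequal(uni1$pathway, c("A", "B"))
  # union bounded by the sum of per-dataset selections and contains each
  expect_lte(nrow(uni), 2 + 2)
  expect_true(all(c("A", "B") %in% uni$pathway))
  expect_warning(out <- integrate_disease_pathways(res, p_threshold = 1e-6),
                 "empty union")
  expect_equal(nrow(out), 0L)
})
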