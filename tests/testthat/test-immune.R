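toy_expr <- function(values, genes, samples) {
  expression_matrix(matrix(values, length(genes), length(samples),
                           dimnames = list(genes, samples)), "linear")
}

test_that("CYT score is the geometric mean with symmetry and scale properties", {
  E <- toy_expr(c(4, 9, 2, 8, 0, 0), c("GZMA", "PRF1"),
                c("s1", "s2", "s3"))
  s <- cyt_score(E, offset = 0)
  expect_equal(unname(s), c(6, 4, 0))
  expect_equal(unname(cyt_score(E, offset = 0.01))[3], 0.01)
  # symmetric in the two genes
  expect_equal(unname(cyt_score(E, "PRF1", "GZMA", offset = 0)), unname(s))
  # scale equivariance at offset 0
  E10 <- toy_expr(10 * c(4, 9, 2, 8, 0, 0), c("GZMA", "PRF1"),
                  c("s1", "s2", "s3"))
  expect_equal(unname(cyt_score(E10, offset = 0)), 10 * unname(s))
  expect_error(cyt_score(E, gzma_id = "NOPE"), class = "ptc_lookup")
})

test_that("mean-z signature scores behave on degenerate and single-gene sets", {
  m <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  Econst <- log_transform(expression_matrix(m, "linear"))
  expect_equal(unname(signature_score(Econst, c("g1", "g2"))), c(0, 0, 0))
  set.seed(20)
  m2 <- matrix(rexp(12), 4, 3, dimnames = dimnames(m))
  E2 <- log_transform(expression_matrix(m2, "linear"))
  z1 <- as.vector(scale(E2$values["g1", ]))
  expect_equal(unname(signature_score(E2, "g1")), z1)
  expect_error(signature_score(E2, c("absent1", "absent2")),
               class = "ptc_scoring")
})

test_that("immune-set scores track the planted immune activity", {
  co <- small_cohort(noise = 0.2, seed = 23)
  sc <- signature_score(log_transform(co$expression),
                        co$config$immune_gene_ids)
  expect_gt(cor(sc, co$true_activity["signature2", ]), 0.5)
})

make_reference <- function(n_genes = 60, n_types = 5, seed = 30) {
  set.seed(seed)
  profiles <- matrix(rexp(n_genes * n_types, 0.2), n_genes, n_types,
                     dimnames = list(sprintf("g%03d", 1:n_genes),
                                     paste0("cell", 1:n_types)))
  reference_profile(profiles)
}

test_that("NNLS deconvolution recovers exact and pure mixtures", {
  R <- make_reference()
  e <- 0.3 * R$profiles[, 1] + 0.7 * R$profiles[, 2]
  est <- nnls_cell_fractions(e, R)
  expect_equal(unname(est$fractions[, 1]), c(0.3, 0.7, 0, 0, 0),
               tolerance = 1e-6)
  expect_equal(sum(est$fractions), 1, tolerance = 1e-9)
  pure <- nnls_cell_fractions(R$profiles[, 3], R)
  expect_equal(unname(pure$fractions[, 1]), c(0, 0, 1, 0, 0), tolerance = 1e-6)
  # scale invariance of the sample vector
  est2 <- nnls_cell_fractions(17 * e, R)
  expect_equal(est2$fractions, est$fractions, tolerance = 1e-9)
})

test_that("NNLS fraction errors stay small under mild noise", {
  R <- make_reference()
  set.seed(31)
  errs <- replicate(100, {
    f <- rexp(5); f <- f / sum(f)
    e <- (R$profiles %*% f)[, 1]
    e <- e * exp(rnorm(length(e), sd = 0.01))
    est <- nnls_cell_fractions(e, R)
    mean(abs(est$fractions[, 1] - f))
  })
  expect_lt(mean(errs), 0.02)
})

test_that("feature-signature correlations hit exact and planted targets", {
  co <- small_cohort(noise = 0.2, seed = 42)
  H <- metagene_activity(co$true_activity)
  feats <- data.frame(sample_id = colnames(co$true_activity),
                      same = co$true_activity["signature1", ],
                      neg = -co$true_activity["signature2", ],
                      flat = 1)
  expect_warning(r <- feature_signature_correlation(H, feats), "zero variance")
  expect_equal(r["signature1", "same"], 1)
  expect_equal(r["signature2", "neg"], -1)
  expect_true(is.na(r["signature1", "flat"]))
})

test_that("enrichment score matches brute force and honors the p floor", {
  set.seed(33)
  w <- sort(runif(50, 0.1, 5), decreasing = TRUE)
  names(w) <- sprintf("g%02d", 1:50)
  # top-m set: positive ES, maximal over all contiguous placements
  top <- names(w)[1:8]
  res <- preranked_enrichment(w, top, n_perm = 200, seed = 1)
  expect_gt(res$es, 0)
  placements <- vapply(1:(50 - 8 + 1), function(start)
    es_bruteforce(w, names(w)[start:(start + 7)]), numeric(1))
  expect_equal(res$es, max(placements), tolerance = 1e-12)
  expect_equal(res$es, es_bruteforce(w, top), tolerance = 1e-12)
  # set = all genes: running sum has nothing to contrast against
  expect_equal(preranked_enrichment(w, names(w), n_perm = 100, seed = 1)$es, 0)
  # plus-one estimator floor
  expect_gte(res$p, 1 / 201)
  # deterministic under a fixed seed
  res2 <- preranked_enrichment(w, top, n_perm = 200, seed = 1)
  expect_identical(res, res2)
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(34)
  w <- rnorm(80)
  names(w) <- sprintf("g%02d", 1:80)
  set_genes <- sample(names(w), 12)
  mine <- preranked_enrichment(w, set_genes, n_perm = 100, seed = 1)$es
  ref <- suppressWarnings(
    fgsea::calcGseaStat(sort(w, decreasing = TRUE),
                        which(names(sort(w, decreasing = TRUE)) %in% set_genes),
                        gseaParam = 1))
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("per-cluster ANOVA matches the textbook F computation", {
  y <- c(1, 2, 3, 10, 11, 12, 20, 22, 24)
  g <- rep(c("a", "b", "c"), each = 3)
  feats <- data.frame(sample_id = paste0("s", 1:9), y = y)
  tab <- cluster_feature_summary(feats, setNames(g, feats$sample_id))
  # hand computation of one-way ANOVA
  gm <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - rep(tapply(y, g, mean), each = 3))^2)
  F_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(tab$F[tab$feature == "y"], F_hand, tolerance = 1e-10)
  expect_true(tab$flagged[tab$feature == "y"])

  feats$const <- 5
  feats$index <- as.numeric(factor(g))
  tab2 <- cluster_feature_summary(feats, setNames(g, feats$sample_id))
  expect_equal(tab2$F[tab2$feature == "const"], 0)
  expect_false(tab2$flagged[tab2$feature == "const"])
  expect_lt(tab2$p[tab2$feature == "index"], 1e-10)
})

test_that("the immune feature table assembles expression and external columns", {
  co <- generate_cohort(synthetic_config(n_genes = 200, n_samples = 40,
                                         seed = 35))
  feats <- build_immune_features(co$expression,
                                 gene_sets = list(immune = co$config$immune_gene_ids),
                                 external = co$features)
  expect_s3_class(feats, "ImmuneFeatureTable")
  expect_equal(feats$sample_id, sample_ids(co$expression))
  expect_true(all(c("cyt_score", "immune_score", "PDL1", "CTLA4",
                    "leukocyte_fraction", "tumor_purity") %in% names(feats)))
  expect_true(all(feats$cyt_score > 0))
})
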