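# shared fixture: a medium cohort with its factorization
cls_cohort <- small_cohort(noise = 0.2, seed = 42)
cls_fit <- nmf_factorize(log_transform(cls_cohort$expression), 3, seed = 7,
                         max_iter = 1500, tol = 1e-7)
cls_ann <- annotate_signatures(cls_fit$activity, cls_cohort$driver_label,
                               cyt_score(cls_cohort$expression))

test_that("hierarchical clustering of activities recovers the four archetypes", {
  co <- generate_cohort(synthetic_config(n_genes = 200, n_samples = 80,
                                         noise_sd = 0, seed = 13))
  raw <- cluster_samples(metagene_activity(co$true_activity))
  expect_equal(ari(raw, as.integer(co$true_cluster)), 1.0)
})

test_that("clustering is stable under duplication and sample permutation", {
  H <- cls_fit$activity$levels
  # duplicated samples land in the same cluster as their originals
  Hd <- cbind(H, H)
  colnames(Hd) <- c(colnames(H), paste0(colnames(H), "_dup"))
  rawd <- cluster_samples(Hd)
  n <- ncol(H)
  expect_equal(unname(rawd[1:n]), unname(rawd[(n + 1):(2 * n)]))
  # permuting sample order permutes the partition identically
  raw <- cluster_samples(H)
  p <- sample(ncol(H))
  rawp <- cluster_samples(H[, p])
  expect_equal(ari(rawp, raw[p]), 1.0)
})

test_that("signature annotation recovers roles and is symmetric in drivers", {
  A <- metagene_activity(cls_cohort$true_activity)
  marker <- cyt_score(cls_cohort$expression)
  ann <- annotate_signatures(A, cls_cohort$driver_label, marker)
  expect_equal(unname(ann$roles), c("RAS", "Immune", "BRAF"))
  # swapping driver labels swaps RAS/BRAF, leaves Immune fixed
  swapped <- cls_cohort$driver_label
  swapped[cls_cohort$driver_label == "RAS-like"] <- "BRAF-like"
  swapped[cls_cohort$driver_label == "BRAF-like"] <- "RAS-like"
  ann2 <- annotate_signatures(A, swapped, marker)
  expect_equal(unname(ann2$roles), c("BRAF", "Immune", "RAS"))
  # the immune signature correlates best with the cytolytic marker
  expect_equal(which.max(ann$marker_correlation), c(signature2 = 2L))
})

test_that("cluster labeling reproduces the planted NMF1-4 semantics", {
  A <- metagene_activity(cls_cohort$true_activity)
  ann <- annotate_signatures(A, cls_cohort$driver_label,
                             cyt_score(cls_cohort$expression))
  raw <- as.integer(cls_cohort$true_cluster)
  asg <- label_clusters(raw, ann, A)
  expect_equal(as.character(asg$cluster), as.character(cls_cohort$true_cluster))
  expect_equal(as.character(asg$label[asg$cluster == "NMF3"])[1], "BRAF-IR")
  # shifting all Immune activities by a constant does not change labels
  A2 <- A$levels
  A2["signature2", ] <- A2["signature2", ] + 5
  asg2 <- label_clusters(raw, ann, metagene_activity(A2))
  expect_equal(asg2$label, asg$label)
})

test_that("labeling is invariant to signature column permutation", {
  A <- cls_cohort$true_activity
  perm <- c(3, 1, 2)
  Ap <- A[perm, ]
  rownames(Ap) <- rownames(A)[perm]
  annp <- annotate_signatures(metagene_activity(Ap), cls_cohort$driver_label,
                              cyt_score(cls_cohort$expression))
  asgp <- label_clusters(as.integer(cls_cohort$true_cluster), annp,
                         metagene_activity(Ap))
  expect_equal(as.character(asgp$cluster),
               as.character(cls_cohort$true_cluster))
})

test_that("degenerate side splits and immune ties are reported", {
  ann <- cls_ann
  # four clusters all on one driver side
  H1 <- rbind(signature1 = rep(c(8, 9, 10, 11), each = 5) + runif(20),
              signature2 = runif(20), signature3 = runif(20) * 0.1)
  colnames(H1) <- paste0("s", 1:20)
  rownames(H1) <- names(ann$roles)
  expect_error(label_clusters(rep(1:4, each = 5), ann, metagene_activity(H1)),
               class = "ptc_labeling")
  # tied immune means within a side pair
  H2 <- rbind(signature1 = rep(c(8, 8, 0.1, 0.1), each = 5),
              signature2 = rep(c(2, 2, 5, 1), each = 5),
              signature3 = rep(c(0.1, 0.1, 8, 8), each = 5))
  colnames(H2) <- paste0("s", 1:20)
  expect_error(label_clusters(rep(1:4, each = 5), ann, metagene_activity(H2)),
               class = "ptc_labeling")
})

test_that("pseudoinverse projection inverts exact mixtures", {
  set.seed(15)
  W <- matrix(rexp(60 * 3), 60, 3,
              dimnames = list(sprintf("g%02d", 1:60), paste0("signature", 1:3)))
  H_true <- matrix(rexp(3 * 10), 3, 10,
                   dimnames = list(paste0("signature", 1:3), paste0("s", 1:10)))
  V <- W %*% H_true
  H_new <- project_metagenes(metagene_basis(W), V, min_overlap_genes = 10)
  expect_equal(H_new$levels, H_true, tolerance = 1e-8)
  expect_equal(attr(H_new, "overlap_fraction"), 1.0)
})

test_that("identity basis projection returns clamped expression rows", {
  W <- diag(3)
  dimnames(W) <- list(c("A", "B", "C"), paste0("signature", 1:3))
  V <- matrix(c(1, -2, 3, 4, 5, -6), 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  H <- project_metagenes(metagene_basis(W), V, min_overlap_genes = 3)
  expect_equal(unname(H$levels), unname(pmax(V, 0)))
})

test_that("projection is linear before clamping and enforces overlap", {
  set.seed(16)
  W <- metagene_basis(matrix(rexp(90), 30, 3,
                             dimnames = list(sprintf("g%02d", 1:30),
                                             paste0("signature", 1:3))))
  V1 <- matrix(rexp(60), 30, 2, dimnames = list(sprintf("g%02d", 1:30),
                                                c("s1", "s2")))
  V2 <- matrix(rexp(60), 30, 2, dimnames = dimnames(V1))
  pr <- function(V) project_metagenes(W, V, min_overlap_genes = 5,
                                      clamp_negative = FALSE)$levels
  expect_equal(pr(2 * V1 + 3 * V2), 2 * pr(V1) + 3 * pr(V2),
               tolerance = 1e-9)
  # no shared genes at all
  V3 <- V1; rownames(V3) <- paste0("x", 1:30)
  expect_error(project_metagenes(W, V3, min_overlap_genes = 5),
               class = "ptc_projection")
  # insufficient overlap fraction
  V4 <- V1[1:6, , drop = FALSE]
  expect_error(project_metagenes(W, V4, min_overlap_frac = 0.5,
                                 min_overlap_genes = 5),
               class = "ptc_projection")
})

test_that("external classification is self-consistent on the training cohort", {
  raw <- cluster_samples(cls_fit$activity)
  own <- label_clusters(raw, cls_ann, cls_fit$activity)
  ext <- classify_external(cls_fit$basis, cls_ann,
                           log_transform(cls_cohort$expression),
                           min_overlap_genes = 100)
  agree <- mean(as.character(ext$label) == as.character(own$label))
  expect_gte(agree, 0.95)
})

test_that("a one-sided external cohort falls back to per-sample labels", {
  # pure cluster-2 archetype samples (RAS-side, immune-low)
  co <- cls_cohort
  keep <- co$true_cluster == "NMF2"
  E2 <- expression_matrix(co$expression$values[, keep], "linear")
  ext <- classify_external(cls_fit$basis, cls_ann, log_transform(E2),
                           min_overlap_genes = 100)
  expect_true(all(as.character(ext$label) == "RAS-ID"))
  expect_true(all(as.character(ext$cluster) == "NMF2"))
})
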