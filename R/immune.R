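#' Cytolytic activity (CYT) score
#'
#' Geometric mean of GZMA and PRF1 expression per sample,
#' `sqrt((GZMA + offset) * (PRF1 + offset))`, on linear-scale values. The
#' small offset keeps the score positive at zero expression.
#'
#' @param E linear-scale `ExpressionMatrix`.
#' @param gzma_id,prf1_id gene IDs of the two cytolytic effectors.
#' @param offset additive offset in linear expression units (default 0.01).
#' @return named numeric vector of per-sample scores.
#' @export
cyt_score <- function(E, gzma_id = "GZMA", prf1_id = "PRF1", offset = 0.01) {
  E <- as_expression(E)
  if (E$scale != "linear")
    stop_ptc("ptc_validation", "cyt_score requires a linear-scale matrix")
  for (g in c(gzma_id, prf1_id))
    if (!g %in% gene_ids(E))
      stop_ptc("ptc_lookup", "gene '%s' not found in the expression matrix", g)
  sqrt((E$values[gzma_id, ] + offset) * (E$values[prf1_id, ] + offset))
}

#' Mean-z signature score
#'
#' A simple single-sample score for a gene set: each set gene is z-scored
#' across samples (on the log scale) and the per-sample mean over the present
#' set genes is returned. This is a transparent surrogate for heavier
#' immune/stromal scoring algorithms and is labelled as such in reports.
#'
#' @param E log-scale `ExpressionMatrix`.
#' @param gene_set character vector of gene IDs.
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(E, gene_set) {
  E <- as_expression(E)
  if (E$scale != "log2p1")
    stop_ptc("ptc_validation", "signature_score expects a log-scale matrix")
  present <- intersect(unique(gene_set), gene_ids(E))
  if (length(present) == 0L)
    stop_ptc("ptc_scoring", "no gene of the set is present in the matrix")
  ptc_log("signature_score: %d/%d set genes present", length(present),
          length(unique(gene_set)))
  sub <- E$values[present, , drop = FALSE]
  z <- t(apply(sub, 1L, function(row) {
    s <- sd(row)
    if (s < 1e-12) rep(0, length(row)) else (row - mean(row)) / s
  }))
  colMeans(z)
}

#' Reference expression profiles for cell-fraction estimation
#'
#' @param profiles genes x cell-types non-negative matrix (linear scale) with
#'   gene rownames and cell-type colnames.
#' @return a `ReferenceProfile` object.
#' @export
reference_profile <- function(profiles) {
  if (!is.matrix(profiles) || any(profiles < 0) || anyNA(profiles))
    stop_ptc("ptc_validation", "reference profiles must be a complete non-negative matrix")
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    stop_ptc("ptc_validation", "reference profiles need gene and cell-type names")
  if (any(colSums(profiles) == 0))
    stop_ptc("ptc_validation", "reference has an all-zero cell-type column")
  if (anyDuplicated(rownames(profiles)))
    stop_ptc("ptc_validation", "duplicate gene ids in reference")
  structure(list(profiles = profiles), class = "ReferenceProfile")
}

#' Estimate immune cell fractions by non-negative least squares
#'
#' For each sample, solves `min || R f - e ||_2, f >= 0` on the genes shared
#' with the reference, after scaling every reference column and every sample
#' to a common library size; fractions are renormalized to sum to 1. This is
#' a transparent NNLS variant of reference-based deconvolution (not a
#' support-vector regression) and is labelled as such in reports.
#'
#' @param E linear-scale `ExpressionMatrix` (or a named per-gene vector for a
#'   single sample).
#' @param R a [reference_profile()].
#' @param min_genes minimum shared genes (default 50).
#' @return A `CellFractionEstimate` list: `fractions` (cell-types x samples,
#'   columns sum to 1), `residual_norm` (per sample), `n_shared_genes`.
#' @export
nnls_cell_fractions <- function(E, R, min_genes = 50L) {
  if (!inherits(R, "ReferenceProfile"))
    stop_ptc("ptc_validation", "R must be a ReferenceProfile")
  v <- if (inherits(E, "ExpressionMatrix")) {
    if (E$scale != "linear")
      stop_ptc("ptc_validation", "nnls_cell_fractions requires linear scale")
    E$values
  } else if (is.matrix(E)) E else matrix(E, ncol = 1,
                                         dimnames = list(names(E), "sample1"))
  shared <- intersect(rownames(R$profiles), rownames(v))
  if (length(shared) < min_genes)
    stop_ptc("ptc_overlap", "only %d genes shared with the reference (need %d)",
             length(shared), min_genes)
  ref <- R$profiles[shared, , drop = FALSE]
  obs <- v[shared, , drop = FALSE]
  # equalize library sizes for conditioning; the solution is mapped back to
  # the original reference scale before fractions are formed
  target <- mean(colSums(ref))
  col_scale <- colSums(ref) / target
  ref <- sweep(ref, 2L, col_scale, "/")
  fr <- matrix(NA_real_, ncol(ref), ncol(obs),
               dimnames = list(colnames(ref), colnames(obs)))
  resid <- setNames(numeric(ncol(obs)), colnames(obs))
  for (j in seq_len(ncol(obs))) {
    e <- obs[, j]
    if (sum(e) <= 0)
      stop_ptc("ptc_validation", "all-zero sample '%s'", colnames(obs)[j])
    e <- e * target / sum(e)
    sol <- pracma::lsqnonneg(ref, e)
    f <- sol$x / col_scale   # back to the original reference column scale
    if (sum(f) <= 0) stop_ptc("ptc_numerical", "degenerate NNLS solution")
    fr[, j] <- f / sum(f)
    resid[j] <- sqrt(sum((ref %*% sol$x - e)^2))
  }
  structure(list(fractions = fr, residual_norm = resid,
                 n_shared_genes = length(shared)),
            class = "CellFractionEstimate")
}

#' Assemble the per-sample immune feature table
#'
#' Combines the CYT score, optional immune/stromal mean-z signature scores,
#' log-scale checkpoint gene expression (PD-L1/CD274 and CTLA4 by default) and
#' any external numeric columns (tumor purity, leukocyte fraction, TCR
#' richness, mutation burden) keyed by `sample_id`.
#'
#' @param E linear-scale `ExpressionMatrix`.
#' @param gene_sets optional named list with elements `immune` / `stromal`.
#' @param external optional data frame with a `sample_id` column.
#' @param checkpoint_genes named character vector of checkpoint gene IDs.
#' @param offset CYT offset, see [cyt_score()].
#' @return An `ImmuneFeatureTable` data frame keyed by `sample_id`.
#' @export
build_immune_features <- function(E, gene_sets = NULL, external = NULL,
                                  checkpoint_genes = c(PDL1 = "CD274",
                                                       CTLA4 = "CTLA4"),
                                  offset = 0.01) {
  E <- as_expression(E)
  logE <- log_transform(E)
  out <- data.frame(sample_id = sample_ids(E),
                    cyt_score = unname(cyt_score(E, offset = offset)),
                    stringsAsFactors = FALSE)
  if (!is.null(gene_sets$immune))
    out$immune_score <- unname(signature_score(logE, gene_sets$immune))
  if (!is.null(gene_sets$stromal))
    out$stromal_score <- unname(signature_score(logE, gene_sets$stromal))
  for (nm in names(checkpoint_genes)) {
    g <- checkpoint_genes[[nm]]
    if (g %in% gene_ids(E)) {
      out[[nm]] <- unname(logE$values[g, ])
    } else {
      warn_ptc("checkpoint gene '%s' absent; column '%s' skipped", g, nm)
    }
  }
  if (!is.null(external)) {
    if (!"sample_id" %in% names(external))
      stop_ptc("ptc_validation", "external features need a sample_id column")
    out <- merge(out, external, by = "sample_id", all.x = TRUE, sort = FALSE)
    out <- out[match(sample_ids(E), out$sample_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("ImmuneFeatureTable", "data.frame")
  out
}

#' Correlate metagene activities with immune features
#'
#' Pearson correlation for every (signature, feature) pair over the shared
#' samples, pairwise-complete for missing feature values. Zero-variance
#' columns yield `NA` with a warning.
#'
#' @param H [metagene_activity()].
#' @param features an [build_immune_features()] table (or any data frame with
#'   `sample_id` and numeric columns).
#' @return matrix of correlations (signatures x features) with the per-pair
#'   sample counts as attribute `n`.
#' @export
feature_signature_correlation <- function(H, features) {
  h <- if (inherits(H, "MetageneActivity")) H$levels else H
  shared <- intersect(colnames(h), features$sample_id)
  if (length(shared) < 3L)
    stop_ptc("ptc_validation", "need at least 3 shared samples")
  h <- h[, shared, drop = FALSE]
  feats <- features[match(shared, features$sample_id), , drop = FALSE]
  num_cols <- names(feats)[vapply(feats, is.numeric, TRUE)]
  r <- matrix(NA_real_, nrow(h), length(num_cols),
              dimnames = list(rownames(h), num_cols))
  n <- r
  for (f in num_cols) {
    y <- feats[[f]]
    ok <- !is.na(y)
    if (sum(ok) < 3L || sd(y[ok]) < 1e-12 ) {
      warn_ptc("feature '%s' has too few values or zero variance; r undefined", f)
      n[, f] <- sum(ok)
      next
    }
    for (s in rownames(h)) {
      x <- h[s, ]
      r[s, f] <- if (sd(x[ok]) < 1e-12) NA_real_ else cor(x[ok], y[ok])
      n[s, f] <- sum(ok)
    }
  }
  attr(r, "n") <- n
  r
}

# weighted Kolmogorov-Smirnov running-sum enrichment score (weight exponent 1)
# for a logical membership vector over a ranking; extremum of the running sum
es_running <- function(w_ranked, in_set) {
  N <- length(w_ranked)
  m <- sum(in_set)
  if (m == 0L) stop_ptc("ptc_validation", "gene set does not overlap the ranking")
  if (m == N) return(0)  # vacuous set: no misses to contrast against
  hw <- abs(w_ranked)
  denom_hit <- sum(hw[in_set])
  if (denom_hit <= 0) {
    # all set genes carry zero weight: equal hit increments
    incr <- ifelse(in_set, 1 / m, -1 / (N - m))
  } else {
    incr <- ifelse(in_set, hw / denom_hit, -1 / (N - m))
  }
  run <- cumsum(incr)
  run[which.max(abs(run))]
}

#' Pre-ranked gene set enrichment score with permutation p-value
#'
#' Genes are ranked by decreasing weight (e.g. metagene signature loadings);
#' the enrichment score is the extremum of the weighted Kolmogorov-Smirnov
#' running sum (weight exponent 1). The p-value is estimated by permuting
#' gene-set membership, with the plus-one estimator
#' `(1 + #(|ES*| >= |ES|)) / (n_perm + 1)`.
#'
#' @param weights named numeric vector of per-gene weights.
#' @param gene_set character vector of gene IDs.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; results are deterministic for a fixed seed.
#' @return list with `es`, `p`, `n_set` (set genes in the ranking), `n_perm`.
#' @export
preranked_enrichment <- function(weights, gene_set, n_perm = 1000L, seed = 1L) {
  if (is.null(names(weights)))
    stop_ptc("ptc_validation", "weights must be named by gene")
  if (n_perm < 100L) stop_ptc("ptc_validation", "n_perm must be >= 100")
  ord <- order(-weights, names(weights), method = "radix")
  w <- weights[ord]
  in_set <- names(w) %in% gene_set
  es <- es_running(w, in_set)
  m <- sum(in_set)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- logical(length(w))
    perm[sample.int(length(w), m)] <- TRUE
    if (abs(es_running(w, perm)) >= abs(es)) exceed <- exceed + 1L
  }
  list(es = es, p = (1 + exceed) / (n_perm + 1), n_set = m, n_perm = n_perm)
}

#' Per-cluster feature summary with one-way ANOVA
#'
#' For each numeric feature, computes per-cluster means and a one-way ANOVA F
#' test across the cluster assignment; features with `p < alpha` are flagged
#' for display.
#'
#' @param features an [build_immune_features()] table.
#' @param assignment a `ClusterAssignment` (or factor named by sample).
#' @param alpha display threshold (default 0.05).
#' @return data frame with `feature`, `F`, `p`, `flagged`, and the
#'   per-cluster means as attribute `means`.
#' @export
cluster_feature_summary <- function(features, assignment, alpha = 0.05) {
  cl <- if (inherits(assignment, "ClusterAssignment")) {
    setNames(as.character(assignment$cluster), assignment$sample_id)
  } else setNames(as.character(assignment), names(assignment))
  shared <- intersect(features$sample_id, names(cl))
  feats <- features[match(shared, features$sample_id), , drop = FALSE]
  g <- factor(cl[shared])
  if (sum(table(g) >= 2L) < 2L)
    stop_ptc("ptc_validation", "need >= 2 clusters with >= 2 samples")
  num_cols <- setdiff(names(feats)[vapply(feats, is.numeric, TRUE)], "sample_id")
  res <- list(); means <- list()
  for (f in num_cols) {
    y <- feats[[f]]
    ok <- !is.na(y)
    if (sum(ok) < 3L || length(unique(g[ok])) < 2L) {
      warn_ptc("feature '%s' degenerate across clusters; skipped", f)
      next
    }
    if (sd(y[ok]) < 1e-12) {
      res[[f]] <- data.frame(feature = f, F = 0, p = 1, flagged = FALSE)
    } else {
      fit <- summary(aov(y[ok] ~ g[ok]))[[1]]
      res[[f]] <- data.frame(feature = f, F = fit[1, "F value"],
                             p = fit[1, "Pr(>F)"],
                             flagged = fit[1, "Pr(>F)"] < alpha)
    }
    means[[f]] <- tapply(y[ok], g[ok], mean)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "means") <- do.call(rbind, means)
  out
}
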