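#' Configuration for the synthetic thyroid cohort generator
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' a rank-3 non-negative signature structure (RAS, Immune, BRAF) expressed in
#' four sample clusters, cluster proportions of roughly 13/19/32/36 percent,
#' per-cluster recurrence rates of 5.8/5.8/13.1/5.8 percent, and immune marker
#' genes (GZMA, PRF1, CD274, CTLA4, CCL19, CCL21) loaded on the Immune
#' signature.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param k number of planted signatures; the four-cluster layout requires 3.
#' @param cluster_proportions length-4 proportions summing to 1 for clusters
#'   NMF1-NMF4.
#' @param signature_sparsity fraction of genes in each signature's dominant
#'   block (blocks are disjoint).
#' @param noise_sd standard deviation of multiplicative log-normal noise
#'   (log scale; 0 disables noise).
#' @param immune_gene_ids gene IDs given strong Immune-signature loadings.
#' @param recurrence_rate_by_cluster length-4 Bernoulli recurrence rates.
#' @param censoring_rate fraction of non-recurrent samples whose follow-up is
#'   curtailed (uniformly over the window) rather than complete.
#' @param followup_months administrative follow-up window, months.
#' @param normal_fraction_cluster1 fraction of cluster-1 samples labelled as
#'   normal thyroid rather than RAS-like tumor.
#' @param feature_cors named correlations used to plant the external immune
#'   features against the (standardized, log-scale) Immune activity.
#' @param seed integer RNG seed; regeneration with the same seed is
#'   bit-identical.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_samples = 400L,
                             k = 3L,
                             cluster_proportions = c(0.13, 0.19, 0.32, 0.36),
                             signature_sparsity = 0.12,
                             noise_sd = 0.2,
                             immune_gene_ids = c("GZMA", "PRF1", "CD274",
                                                 "CTLA4", "CCL19", "CCL21"),
                             recurrence_rate_by_cluster = c(0.058, 0.058,
                                                            0.131, 0.058),
                             censoring_rate = 0.3,
                             followup_months = 180,
                             normal_fraction_cluster1 = 0.3,
                             feature_cors = c(leukocyte_fraction = 0.8,
                                              tcr_richness = 0.73,
                                              tumor_purity = -0.71),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              k = as.integer(k), cluster_proportions = cluster_proportions,
              signature_sparsity = signature_sparsity, noise_sd = noise_sd,
              immune_gene_ids = immune_gene_ids,
              recurrence_rate_by_cluster = recurrence_rate_by_cluster,
              censoring_rate = censoring_rate,
              followup_months = followup_months,
              normal_fraction_cluster1 = normal_fraction_cluster1,
              feature_cors = feature_cors, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "SyntheticConfig")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$k != 3L)
    stop_ptc("ptc_config", "the four-cluster layout requires k = 3 signatures")
  if (length(cfg$cluster_proportions) != 4L ||
      abs(sum(cfg$cluster_proportions) - 1) > 1e-8)
    stop_ptc("ptc_config", "cluster_proportions must be 4 values summing to 1")
  rates <- c(cfg$recurrence_rate_by_cluster, cfg$censoring_rate)
  if (any(rates < 0 | rates > 1))
    stop_ptc("ptc_config", "rates must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop_ptc("ptc_config", "noise_sd must be >= 0")
  if (cfg$n_genes < 10L * cfg$k || cfg$n_samples < 8L)
    stop_ptc("ptc_config", "cohort too small for the planted design")
  invisible(cfg)
}

# Median activity levels per cluster (signatures x clusters), linear scale.
# Cluster 1 is RAS-side immune-high (normal-enriched, moderate RAS drive),
# 2 RAS-side immune-low, 3 BRAF-side immune-high, 4 BRAF-side immune-low.
# Driver activities vary multiplicatively with CV ~ 0.2 (gamma); the immune
# activity is a graded log-normal continuum (sdlog below), high in the IR
# clusters and low in the ID clusters, mirroring the relative nature of the
# immunoreactive/immunodeficient distinction.
cluster_archetypes <- function() {
  matrix(c(1.5, 5.0, 0.3,   # NMF1: RAS-IR
           8.0, 0.8, 0.3,   # NMF2: RAS-ID
           0.3, 4.0, 9.0,   # NMF3: BRAF-IR
           0.3, 0.8, 9.0),  # NMF4: BRAF-ID
         nrow = 3, ncol = 4,
         dimnames = list(c("signature1", "signature2", "signature3"),
                         paste0("NMF", 1:4)))
}

immune_sdlog <- c(NMF1 = 0.25, NMF2 = 0.30, NMF3 = 0.25, NMF4 = 0.30)

# exact cluster counts by largest-remainder apportionment
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic thyroid expression cohort with ground truth
#'
#' Draws a sparse non-negative basis (one dominant, disjoint gene block per
#' signature, immune marker genes on signature 2), per-sample activities around
#' the four cluster archetypes, and expression `basis %*% activity` under
#' multiplicative log-normal noise. Clinical covariates, Bernoulli recurrence
#' with cluster-specific rates, and censored exponential follow-up times are
#' attached, along with external immune features planted at configured
#' correlations with the Immune activity.
#'
#' @param config a [synthetic_config()].
#' @return A `SyntheticCohort` list: `expression` (linear
#'   [expression_matrix()]), `true_basis`, `true_activity`, `true_cluster`,
#'   `driver_label`, `clinical` (data frame), `features` (data frame of
#'   external immune features), `config`, `seed`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples; k <- config$k

  genes <- sprintf("G%05d", seq_len(ng))
  block_size <- max(length(config$immune_gene_ids),
                    round(config$signature_sparsity * ng))
  blocks <- lapply(seq_len(k), function(s) seq_len(block_size) + (s - 1L) * block_size)
  # immune marker genes live at the head of the signature-2 block
  genes[blocks[[2]][seq_along(config$immune_gene_ids)]] <- config$immune_gene_ids

  W <- matrix(rgamma(ng * k, shape = 0.3, rate = 10), nrow = ng,
              dimnames = list(genes, paste0("signature", seq_len(k))))
  for (s in seq_len(k))
    W[blocks[[s]], s] <- rgamma(block_size, shape = 2, rate = 0.5)
  W[config$immune_gene_ids, 2] <- rgamma(length(config$immune_gene_ids),
                                         shape = 6, rate = 0.75)

  counts <- apportion(ns, config$cluster_proportions)
  cl <- sample(rep.int(1:4, counts))
  arche <- cluster_archetypes()
  A <- arche[, cl, drop = FALSE]
  # driver activities: gamma multipliers with CV ~ 0.2
  A[1L, ] <- A[1L, ] * rgamma(ns, shape = 25, rate = 25)
  A[3L, ] <- A[3L, ] * rgamma(ns, shape = 25, rate = 25)
  # immune activity: graded log-normal continuum within IR and ID levels
  A[2L, ] <- A[2L, ] * exp(rnorm(ns, sd = immune_sdlog[cl]))
  samples <- sprintf("S%04d", seq_len(ns))
  dimnames(A) <- list(paste0("signature", seq_len(k)), samples)

  # canonical form (matching nmf_factorize output): unit-L1 basis columns,
  # scaling absorbed into the activity rows
  l1 <- colSums(W)
  W <- sweep(W, 2L, l1, "/")
  A <- A * l1

  V <- W %*% A
  if (config$noise_sd > 0)
    V <- V * exp(matrix(rnorm(ng * ns, sd = config$noise_sd), nrow = ng))
  dimnames(V) <- list(genes, samples)

  driver <- ifelse(cl <= 2L, "RAS-like", "BRAF-like")
  in_c1 <- which(cl == 1L)
  n_norm <- round(config$normal_fraction_cluster1 * length(in_c1))
  if (n_norm > 0) driver[sample(in_c1, n_norm)] <- "normal"

  clinical <- simulate_clinical(samples, cl, driver, config)
  features <- simulate_external_features(samples, A[2L, ], clinical, config)

  structure(list(
    expression = expression_matrix(V, "linear"),
    true_basis = W, true_activity = A,
    true_cluster = factor(paste0("NMF", cl), levels = paste0("NMF", 1:4)),
    driver_label = driver, clinical = clinical, features = features,
    config = config, seed = config$seed), class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d genes x %d samples, clusters %s (seed %d)\n",
              nrow(x$true_basis), ncol(x$true_activity),
              paste(table(x$true_cluster), collapse = "/"), x$seed))
  invisible(x)
}

# cluster-conditional covariate probabilities loosely following the TCGA-like
# marginal structure (aggressive histology, nodal disease and advanced T stage
# concentrate on the BRAF side)
simulate_clinical <- function(samples, cl, driver, config) {
  ns <- length(samples)
  p_variant <- rbind(NMF1 = c(0.50, 0.44, 0.01, 0.05),
                     NMF2 = c(0.39, 0.59, 0.01, 0.01),
                     NMF3 = c(0.70, 0.04, 0.21, 0.05),
                     NMF4 = c(0.84, 0.08, 0.05, 0.03))
  variants <- c("classic", "follicular variant", "tall cell variant", "other")
  p_ete <- c(0.09, 0.10, 0.42, 0.28)
  p_pt <- rbind(c(0.44, 0.31, 0.24, 0.01), c(0.32, 0.44, 0.23, 0.01),
                c(0.26, 0.24, 0.44, 0.06), c(0.24, 0.39, 0.32, 0.05))
  p_pn1 <- c(0.19, 0.13, 0.54, 0.52)
  p_stage <- rbind(c(0.68, 0.16, 0.16, 0.00), c(0.54, 0.20, 0.19, 0.07),
                   c(0.54, 0.03, 0.28, 0.15), c(0.56, 0.10, 0.20, 0.14))

  age <- pmin(90, pmax(15, round(rnorm(ns, 47, 15))))
  sex <- sample(c("Female", "Male"), ns, replace = TRUE, prob = c(0.73, 0.27))
  variant <- vapply(cl, function(c4)
    sample(variants, 1L, prob = p_variant[c4, ]), character(1))
  variant[driver == "normal"] <- "normal thyroid"
  ete <- ifelse(runif(ns) < p_ete[cl], "Present", "Absent")
  pt <- vapply(cl, function(c4)
    sample(paste0("pT", 1:4), 1L, prob = p_pt[c4, ]), character(1))
  pn <- ifelse(runif(ns) < p_pn1[cl], "pN1", "pN0/NX")
  stage <- vapply(cl, function(c4)
    sample(paste0("stage", 1:4), 1L, prob = p_stage[c4, ]), character(1))
  mutations <- rpois(ns, lambda = 11)

  p_rec <- config$recurrence_rate_by_cluster[cl]
  recurrence <- as.integer(runif(ns) < p_rec)
  FU <- config$followup_months
  # hazard chosen so P(event time <= window) equals the cluster recurrence
  # rate; recurrent samples get a window-truncated exponential event time
  lambda <- -log(1 - config$recurrence_rate_by_cluster) / FU
  t_obs <- numeric(ns)
  for (i in seq_len(ns)) {
    if (recurrence[i] == 1L) {
      u <- runif(1)
      t_obs[i] <- -log(1 - u * p_rec[i]) / lambda[cl[i]]
    } else {
      t_obs[i] <- if (runif(1) < config$censoring_rate)
        runif(1, 0.1 * FU, FU) else FU
    }
  }

  data.frame(sample_id = samples,
             cluster = factor(paste0("NMF", cl), levels = paste0("NMF", 1:4)),
             driver_class = driver, age_years = age, sex = sex,
             histologic_variant = variant, extrathyroidal_extension = ete,
             pT = pt, pN = pn, stage = stage, mutation_count = mutations,
             recurrence = recurrence, followup_months = pmax(t_obs, 1e-3),
             event = recurrence, stringsAsFactors = FALSE)
}

# external per-sample features planted at fixed Pearson correlations with the
# standardized log-scale Immune activity (affine maps only, so the planted
# correlation is preserved exactly in expectation)
simulate_external_features <- function(samples, immune_activity, clinical,
                                       config) {
  z <- as.vector(scale(log2(1 + immune_activity)))
  ns <- length(samples)
  plant <- function(r) r * z + sqrt(1 - r^2) * rnorm(ns)
  rs <- config$feature_cors
  data.frame(sample_id = samples,
             leukocyte_fraction = 0.20 + 0.08 * plant(rs[["leukocyte_fraction"]]),
             tcr_richness = 1500 + 600 * plant(rs[["tcr_richness"]]),
             tumor_purity = 0.72 + 0.08 * plant(rs[["tumor_purity"]]),
             mutation_burden = clinical$mutation_count,
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Emits `expression.tsv`, `clinical.csv`, `features.csv`, the ground-truth
#' files `true_basis.csv`, `true_activity.csv`, `true_labels.csv`, and a
#' `manifest.json` recording the seed and configuration.
#'
#' @param cohort a `SyntheticCohort`.
#' @param directory output directory.
#' @param overwrite overwrite an existing directory? Default `FALSE`.
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  if (!inherits(cohort, "SyntheticCohort"))
    stop_ptc("ptc_validation", "expected a SyntheticCohort")
  if (dir.exists(directory) && !overwrite)
    stop_ptc("ptc_io", "directory exists (use overwrite = TRUE): %s", directory)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$expression, file.path(directory, "expression.tsv"))
  utils::write.csv(cohort$clinical, file.path(directory, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$features, file.path(directory, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(gene_id = rownames(cohort$true_basis),
                              cohort$true_basis, check.names = FALSE),
                   file.path(directory, "true_basis.csv"), row.names = FALSE)
  utils::write.csv(data.frame(signature = rownames(cohort$true_activity),
                              cohort$true_activity, check.names = FALSE),
                   file.path(directory, "true_activity.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = colnames(cohort$true_activity),
                              true_cluster = as.character(cohort$true_cluster),
                              driver_label = cohort$driver_label),
                   file.path(directory, "true_labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = cohort$seed,
                            config = unclass(cohort$config)),
                       file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}
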