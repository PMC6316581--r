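#' Metagene basis and activity containers
#'
#' `metagene_basis` wraps the non-negative genes x k weight matrix W (the
#' "metagene signatures"); `metagene_activity` wraps the k x samples activity
#' matrix H ("metagene expression profiles"). The factorization is made
#' canonical by scaling W columns to unit L1 norm, with the inverse scaling
#' absorbed into H.
#'
#' @param weights genes x k non-negative matrix with gene rownames.
#' @param signature_names optional column names (default `signature1..k`).
#' @return `MetageneBasis` / `MetageneActivity` objects.
#' @export
metagene_basis <- function(weights, signature_names = NULL) {
  if (!is.matrix(weights) || any(weights < 0))
    stop_ptc("ptc_validation", "basis weights must be a non-negative matrix")
  if (any(colSums(weights) == 0))
    stop_ptc("ptc_validation", "basis has an all-zero signature column")
  if (is.null(signature_names))
    signature_names <- colnames(weights) %||% paste0("signature", seq_len(ncol(weights)))
  colnames(weights) <- signature_names
  structure(list(weights = weights, k = ncol(weights),
                 signature_names = signature_names), class = "MetageneBasis")
}

#' @rdname metagene_basis
#' @param levels k x samples non-negative matrix with sample colnames.
#' @export
metagene_activity <- function(levels, signature_names = NULL) {
  if (!is.matrix(levels) || any(levels < 0))
    stop_ptc("ptc_validation", "activity levels must be a non-negative matrix")
  if (is.null(signature_names))
    signature_names <- rownames(levels) %||% paste0("signature", seq_len(nrow(levels)))
  rownames(levels) <- signature_names
  structure(list(levels = levels, k = nrow(levels),
                 signature_names = signature_names), class = "MetageneActivity")
}

#' @export
print.MetageneBasis <- function(x, ...) {
  cat(sprintf("MetageneBasis: %d genes x %d signatures\n", nrow(x$weights), x$k))
  invisible(x)
}

#' @export
print.MetageneActivity <- function(x, ...) {
  cat(sprintf("MetageneActivity: %d signatures x %d samples\n", x$k,
              ncol(x$levels)))
  invisible(x)
}

# Extract a plain non-negative matrix for factorization. Log-scale matrices
# with negative entries (possible after projection preprocessing) are shifted
# so their minimum is zero, as NMF requires non-negative input.
nmf_input_matrix <- function(V) {
  if (inherits(V, "ExpressionMatrix")) {
    v <- V$values
    if (V$scale == "log2p1" && min(v) < 0) {
      ptc_log("nmf: shifting log-scale matrix up by %.4f", -min(v))
      v <- v - min(v)
    }
  } else if (is.matrix(V) && is.numeric(V)) {
    v <- V
  } else stop_ptc("ptc_validation", "V must be an ExpressionMatrix or numeric matrix")
  if (any(v < 0))
    stop_ptc("ptc_internal", "negative entries remain after shift")
  if (anyNA(v)) stop_ptc("ptc_validation", "V contains missing values")
  v
}

#' Factorize an expression matrix into metagene signatures
#'
#' Non-negative matrix factorization `V ~ W H` minimizing the generalized
#' Kullback-Leibler divergence via multiplicative updates from seeded random
#' uniform initialization. Iteration stops at `max_iter` or when the relative
#' divergence decrease over a `check_every`-iteration window falls below
#' `tol`. The returned factors are canonical: W columns have unit L1 norm.
#'
#' @param V `ExpressionMatrix` (log-scale matrices are shifted to min 0) or a
#'   non-negative numeric matrix.
#' @param k number of signatures, `1 <= k < min(dim(V))`.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum iterations (default 2000).
#' @param tol relative divergence-decrease tolerance (default 1e-6).
#' @param check_every convergence-check window in iterations (default 10).
#' @return An `nmf_fit` list: `basis` ([metagene_basis()]), `activity`
#'   ([metagene_activity()]), `divergence` (trace at every check point),
#'   `iterations`, `converged`, `seed`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          check_every = 10L) {
  v <- nmf_input_matrix(V)
  if (k < 1L || k >= min(dim(v)))
    stop_ptc("ptc_bounds", "k=%d out of range for a %d x %d matrix", k,
             nrow(v), ncol(v))
  set.seed(seed)
  sc <- sqrt(max(mean(v), .Machine$double.eps))
  W0 <- matrix(runif(nrow(v) * k), nrow(v), k) * sc
  H0 <- matrix(runif(k * ncol(v)), k, ncol(v)) * sc
  res <- nmf_kl_cpp(v, W0, H0, as.integer(max_iter), tol,
                    as.integer(check_every))
  W <- res$W; H <- res$H
  l1 <- colSums(W)
  if (any(l1 <= 0)) stop_ptc("ptc_numerical", "collapsed basis column in NMF")
  W <- sweep(W, 2L, l1, "/")
  H <- H * l1   # column scales recycle down rows of H (k x n)
  dimnames(W) <- list(rownames(v), paste0("signature", seq_len(k)))
  dimnames(H) <- list(paste0("signature", seq_len(k)), colnames(v))
  structure(list(basis = metagene_basis(W), activity = metagene_activity(H),
                 divergence = res$divergence, iterations = res$iterations,
                 converged = res$converged, seed = seed), class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: k=%d, %d iterations (converged=%s), final D=%.6g\n",
              x$basis$k, x$iterations, x$converged,
              x$divergence[length(x$divergence)]))
  invisible(x)
}

#' Generalized Kullback-Leibler divergence D(V || WH)
#'
#' `sum(V * log(V / WH) - V + WH)` with the `0 log 0 = 0` convention and an
#' epsilon guard inside the logarithm.
#'
#' @param V,W,H conformable numeric matrices (or the package containers).
#' @return non-negative scalar.
#' @export
kl_divergence <- function(V, W, H) {
  if (inherits(V, "ExpressionMatrix")) V <- V$values
  if (inherits(W, "MetageneBasis")) W <- W$weights
  if (inherits(H, "MetageneActivity")) H <- H$levels
  if (ncol(W) != nrow(H) || nrow(W) != nrow(V) || ncol(H) != ncol(V))
    stop_ptc("ptc_bounds", "non-conformable shapes in kl_divergence")
  WH <- W %*% H
  pos <- V > 0
  sum(V[pos] * log(V[pos] / (WH[pos] + 1e-12))) - sum(V) + sum(WH)
}

# dominant-signature assignment: max of per-sample L1-normalized activity,
# ties broken by lowest signature index (which.max's behaviour)
dominant_signature <- function(H) {
  if (inherits(H, "MetageneActivity")) H <- H$levels
  Hn <- sweep(H, 2L, pmax(colSums(H), 1e-12), "/")
  apply(Hn, 2L, which.max)
}

#' Consensus matrix over repeated NMF runs
#'
#' For each of `n_runs` seeded factorizations, samples are assigned to their
#' maximal-activity signature; the consensus is the mean over runs of the
#' co-assignment indicator.
#'
#' @inheritParams nmf_factorize
#' @param n_runs number of restarts (>= 2 for a meaningful consensus; 1 is
#'   allowed and yields a 0/1 connectivity matrix).
#' @param base_seed run r uses seed `base_seed + r - 1`.
#' @param ... passed to [nmf_factorize()].
#' @return samples x samples symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
consensus_matrix <- function(V, k, n_runs = 30L, base_seed = 1L, ...) {
  v <- nmf_input_matrix(V)
  ns <- ncol(v)
  acc <- matrix(0, ns, ns)
  ok <- 0L
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(nmf_factorize(v, k, seed = base_seed + r - 1L, ...),
                    error = function(e) {
                      warn_ptc("consensus run %d failed: %s", r, conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    a <- dominant_signature(fit$activity)
    acc <- acc + outer(a, a, "==")
    ok <- ok + 1L
  }
  if (ok == 0L) stop_ptc("ptc_numerical", "all consensus runs failed")
  C <- acc / ok
  dimnames(C) <- list(colnames(v), colnames(v))
  C
}

#' Cophenetic correlation of a consensus matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - C`;
#' returns the Pearson correlation between the dendrogram's cophenetic
#' distances and the original dissimilarities (upper triangle). A perfectly
#' block-diagonal consensus gives 1.
#'
#' @param C consensus matrix (symmetric, unit diagonal).
#' @return scalar in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(C) {
  if (!isSymmetric(unname(C), tol = 1e-8))
    stop_ptc("ptc_validation", "consensus matrix must be symmetric")
  d <- as.dist(1 - C)
  if (sd(d) < 1e-12) {
    ptc_log("cophenetic_coefficient: constant dissimilarities, returning 1")
    return(1)
  }
  hc <- hclust(d, method = "average")
  cor(as.vector(cophenetic(hc)), as.vector(d))
}

#' Survey factorization ranks by consensus stability
#'
#' Computes a consensus matrix and its cophenetic correlation for each rank in
#' `rank_range`, the standard stability criterion for choosing the number of
#' metagene signatures.
#'
#' @inheritParams consensus_matrix
#' @param rank_range ascending integer ranks, e.g. `2:10`.
#' @return A `RankSurvey` list: `ranks`, `cophenetic` (named numeric),
#'   `consensus` (list of matrices), `runs_per_rank`, `seeds`.
#' @export
rank_survey <- function(V, rank_range = 2:10, n_runs = 30L, base_seed = 1L,
                        ...) {
  if (length(rank_range) < 1L) stop_ptc("ptc_bounds", "empty rank range")
  if (is.unsorted(rank_range, strictly = TRUE))
    stop_ptc("ptc_validation", "rank_range must be strictly ascending")
  seeds <- vapply(seq_along(rank_range),
                  function(i) derive_seed(base_seed, i), integer(1))
  cons <- vector("list", length(rank_range))
  coph <- numeric(length(rank_range))
  for (i in seq_along(rank_range)) {
    cons[[i]] <- consensus_matrix(V, rank_range[i], n_runs = n_runs,
                                  base_seed = seeds[i], ...)
    coph[i] <- cophenetic_coefficient(cons[[i]])
    ptc_log("rank_survey: k=%d cophenetic=%.4f", rank_range[i], coph[i])
  }
  names(coph) <- names(cons) <- paste0("k", rank_range)
  structure(list(ranks = rank_range, cophenetic = coph, consensus = cons,
                 runs_per_rank = n_runs, seeds = seeds), class = "RankSurvey")
}

#' @export
print.RankSurvey <- function(x, ...) {
  cat("RankSurvey:\n")
  print(round(x$cophenetic, 4))
  invisible(x)
}

#' Select the number of signatures from a rank survey
#'
#' Returns the largest rank `k` whose cophenetic coefficient drops by at least
#' `drop_threshold` going to `k + 1` while still lying on the stability
#' plateau (within `plateau_tolerance` of every earlier coefficient). If no
#' such drop exists, the arg-max rank is returned with a warning.
#'
#' @param survey a [rank_survey()] result.
#' @param drop_threshold minimum stability drop (default 0.01: cophenetic
#'   coefficients sit on a plateau within a small fraction of a percent of 1
#'   up to the supported rank, so a drop of a percent or more is already
#'   decisive).
#' @param plateau_tolerance how far below the earlier maximum a rank may sit
#'   and still count as on-plateau (default `min(drop_threshold / 2, 0.01)`).
#'   Kept tighter than the drop threshold so that partial stability rebounds
#'   *after* the first decisive drop cannot re-qualify.
#' @return selected rank (integer).
#' @export
select_rank <- function(survey, drop_threshold = 0.01,
                        plateau_tolerance = min(drop_threshold / 2, 0.01)) {
  if (!inherits(survey, "RankSurvey") || length(survey$ranks) < 2L)
    stop_ptc("ptc_validation", "need a RankSurvey with at least 2 ranks")
  co <- survey$cophenetic
  n <- length(co)
  chosen <- NA_integer_
  for (i in seq_len(n - 1L)) {
    drop_ok <- (co[i] - co[i + 1L]) >= drop_threshold
    high_ok <- i == 1L || co[i] >= max(co[seq_len(i - 1L)]) - plateau_tolerance
    if (drop_ok && high_ok) chosen <- i
  }
  if (is.na(chosen)) {
    warn_ptc("select_rank: no stability drop >= %.3f; returning arg-max rank",
             drop_threshold)
    chosen <- which.max(co)
  }
  k <- survey$ranks[chosen]
  ptc_log("select_rank: chose k=%d (cophenetic %s)", k,
          paste(sprintf("%d:%.3f", survey$ranks, co), collapse = " "))
  as.integer(k)
}
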