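# shared fixtures and independent oracles used across test files

# small/medium cohorts reused by several files (helpers run once per suite)
small_cohort <- function(noise = 0.2, seed = 42, n_genes = 600, n_samples = 150) {
  generate_cohort(synthetic_config(n_genes = n_genes, n_samples = n_samples,
                                   noise_sd = noise, seed = seed))
}

# adjusted Rand index between two partitions (direct formula)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# best accuracy over all relabelings of `pred` onto `truth`
best_match_accuracy <- function(pred, truth) {
  pl <- unique(pred)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  tl <- unique(c(as.character(truth), as.character(pred)))
  best <- 0
  for (p in perms(tl)) {
    map <- setNames(p, tl)
    best <- max(best, mean(map[as.character(pred)] == as.character(truth)))
  }
  best
}

# truth groups for consensus at k = 3: samples grouped by the dominant
# (L1-normalized) planted activity
true_dominant_groups <- function(cohort) {
  A <- cohort$true_activity
  An <- sweep(A, 2, colSums(A), "/")
  apply(An, 2, which.max)
}

# brute-force weighted KS enrichment score (independent re-derivation used as
# oracle against the package implementation)
es_bruteforce <- function(weights, set_genes) {
  ord <- order(-weights, names(weights), method = "radix")
  w <- weights[ord]
  hit <- names(w) %in% set_genes
  N <- length(w); m <- sum(hit)
  denom <- sum(abs(w[hit]))
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(w[i]) / denom else -1 / (N - m)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# written-out Cox partial log-likelihood for a single covariate, no ties
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables (same margins) no more probable than observed
fisher_enumerate <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
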