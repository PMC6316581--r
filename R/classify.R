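#' Hierarchically cluster samples on metagene activities
#'
#' Activities are standardized per signature (z-score across samples), then
#' samples are clustered with Ward linkage on Euclidean distance and the tree
#' is cut at `n_clusters`. Deterministic for fixed input.
#'
#' @param H [metagene_activity()] or a k x samples matrix.
#' @param n_clusters number of clusters to cut (default 4).
#' @param linkage `hclust` method (default `"ward.D2"`, i.e. Ward on
#'   Euclidean distances).
#' @return named integer vector of raw cluster ids (1..n_clusters) per sample.
#' @export
cluster_samples <- function(H, n_clusters = 4L, linkage = "ward.D2") {
  h <- if (inherits(H, "MetageneActivity")) H$levels else H
  if (n_clusters > ncol(h))
    stop_ptc("ptc_bounds", "n_clusters=%d exceeds %d samples", n_clusters, ncol(h))
  hz <- t(apply(h, 1L, function(row) {
    s <- sd(row)
    if (s < 1e-12) rep(0, length(row)) else (row - mean(row)) / s
  }))
  hc <- hclust(dist(t(hz)), method = linkage)
  cutree(hc, k = n_clusters)
}

#' Annotate signatures as RAS, Immune and BRAF
#'
#' The RAS role goes to the signature with the largest mean-activity contrast
#' (RAS-like minus BRAF-like samples), the BRAF role to the largest reverse
#' contrast, and the remaining signature is the Immune signature. Its activity
#' is expected to correlate best with `immune_marker_score` (e.g. the
#' cytolytic score); if not, a warning is raised.
#'
#' @param H [metagene_activity()] with k = 3.
#' @param driver_label per-sample labels in `{RAS-like, BRAF-like, normal}`.
#' @param immune_marker_score per-sample numeric immune marker (e.g.
#'   [cyt_score()]).
#' @return A `SignatureAnnotation`: list with `roles` (named character,
#'   signature -> role) and `evidence` (mean activity by driver class).
#' @export
annotate_signatures <- function(H, driver_label, immune_marker_score) {
  h <- if (inherits(H, "MetageneActivity")) H$levels else H
  if (nrow(h) != 3L)
    stop_ptc("ptc_validation", "signature annotation requires k = 3")
  if (length(driver_label) != ncol(h))
    stop_ptc("ptc_validation", "driver_label length mismatch")
  ras <- driver_label == "RAS-like"
  braf <- driver_label == "BRAF-like"
  if (!any(ras) || !any(braf))
    stop_ptc("ptc_validation", "both RAS-like and BRAF-like samples required")
  contrast <- rowMeans(h[, ras, drop = FALSE]) -
    rowMeans(h[, braf, drop = FALSE])
  ras_sig <- which.max(contrast)
  braf_sig <- which.min(contrast)
  if (ras_sig == braf_sig)
    stop_ptc("ptc_annotation", "ambiguous driver contrast between signatures")
  imm_sig <- setdiff(seq_len(3L), c(ras_sig, braf_sig))
  roles <- character(3L)
  roles[c(ras_sig, imm_sig, braf_sig)] <- c("RAS", "Immune", "BRAF")
  names(roles) <- rownames(h)
  cors <- suppressWarnings(apply(h, 1L, cor, y = immune_marker_score))
  if (!is.na(cors[imm_sig]) && which.max(cors) != imm_sig)
    warn_ptc("immune marker correlates best with signature %d, not the Immune signature %d",
             which.max(cors), imm_sig)
  classes <- unique(driver_label)
  evidence <- sapply(classes, function(cl)
    rowMeans(h[, driver_label == cl, drop = FALSE]))
  structure(list(roles = roles, evidence = evidence,
                 marker_correlation = cors), class = "SignatureAnnotation")
}

#' @export
print.SignatureAnnotation <- function(x, ...) {
  cat("SignatureAnnotation:",
      paste(names(x$roles), x$roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

role_row <- function(annotation, role) {
  which(annotation$roles == role)
}

#' Label four raw clusters as RAS-IR / RAS-ID / BRAF-IR / BRAF-ID
#'
#' Clusters are split into a RAS side (positive mean RAS-minus-BRAF signature
#' contrast) and a BRAF side (negative contrast); a split other than 2 + 2 is
#' an error, reported as a degenerate cohort. Within each side the
#' cluster with the higher mean Immune activity is immunoreactive (IR), the
#' other immunodeficient (ID). The fixed correspondence NMF1 = RAS-IR,
#' NMF2 = RAS-ID, NMF3 = BRAF-IR, NMF4 = BRAF-ID is emitted.
#'
#' @param raw_clusters integer cluster ids from [cluster_samples()] (exactly 4
#'   distinct values).
#' @param annotation a [annotate_signatures()] result.
#' @param H the matching [metagene_activity()].
#' @return A `ClusterAssignment` data frame: `sample_id`, `cluster`
#'   (NMF1-NMF4), `label` (RAS-IR/RAS-ID/BRAF-IR/BRAF-ID), with the raw ->
#'   NMF mapping as attribute `mapping`.
#' @export
label_clusters <- function(raw_clusters, annotation, H) {
  h <- if (inherits(H, "MetageneActivity")) H$levels else H
  ids <- sort(unique(raw_clusters))
  if (length(ids) != 4L)
    stop_ptc("ptc_labeling", "expected exactly 4 raw clusters, got %d", length(ids))
  r_ras <- role_row(annotation, "RAS"); r_braf <- role_row(annotation, "BRAF")
  r_imm <- role_row(annotation, "Immune")
  m_ras <- vapply(ids, function(g) mean(h[r_ras, raw_clusters == g]), 0)
  m_braf <- vapply(ids, function(g) mean(h[r_braf, raw_clusters == g]), 0)
  m_imm <- vapply(ids, function(g) mean(h[r_imm, raw_clusters == g]), 0)
  side_score <- m_ras - m_braf
  if (sum(side_score > 0) != 2L)
    stop_ptc("ptc_labeling",
             "degenerate RAS/BRAF side split (%d of 4 clusters on the RAS side)",
             sum(side_score > 0))
  ras_side <- ids[side_score > 0]; braf_side <- ids[side_score <= 0]
  pair_label <- function(pair, prefix) {
    imm <- m_imm[match(pair, ids)]
    if (imm[1] == imm[2])
      stop_ptc("ptc_labeling", "tied Immune activity within the %s side pair",
               prefix)
    lab <- setNames(paste0(prefix, c("-ID", "-ID")), pair)
    lab[as.character(pair[which.max(imm)])] <- paste0(prefix, "-IR")
    lab
  }
  labels_by_raw <- c(pair_label(ras_side, "RAS"), pair_label(braf_side, "BRAF"))
  nmf_by_label <- c("RAS-IR" = "NMF1", "RAS-ID" = "NMF2",
                    "BRAF-IR" = "NMF3", "BRAF-ID" = "NMF4")
  lab <- labels_by_raw[as.character(raw_clusters)]
  out <- data.frame(sample_id = colnames(h),
                    cluster = factor(nmf_by_label[lab],
                                     levels = paste0("NMF", 1:4)),
                    label = factor(lab, levels = names(nmf_by_label)),
                    stringsAsFactors = FALSE)
  attr(out, "mapping") <- labels_by_raw
  class(out) <- c("ClusterAssignment", "data.frame")
  out
}

#' Project new expression profiles onto a fixed metagene basis
#'
#' Aligns the new matrix to the basis genes and solves `H = pinv(W) V` with
#' the Moore-Penrose generalized pseudoinverse; negative activities are
#' clamped to zero by default so samples remain positive combinations of the
#' signatures. An exact non-negative least-squares mode is available instead
#' of clamping.
#'
#' @param W [metagene_basis()] learned on the model cohort.
#' @param E_new `ExpressionMatrix` preprocessed like the model cohort
#'   (log-transformed; any negative log values are shifted to min 0).
#' @param min_overlap_frac minimum shared fraction of the basis genes
#'   (default 0.5).
#' @param min_overlap_genes hard floor on shared genes (default 200, capped at
#'   the basis size).
#' @param method `"pinv"` (pseudoinverse + clamp) or `"nnls"`.
#' @param clamp_negative clamp negative pseudoinverse solutions at 0
#'   (default TRUE; ignored for `"nnls"`).
#' @return [metagene_activity()] for the new samples, with attribute
#'   `overlap_fraction`.
#' @export
project_metagenes <- function(W, E_new, min_overlap_frac = 0.5,
                              min_overlap_genes = 200L,
                              method = c("pinv", "nnls"),
                              clamp_negative = TRUE) {
  method <- match.arg(method)
  w <- if (inherits(W, "MetageneBasis")) W$weights else W
  v_raw <- if (inherits(E_new, "ExpressionMatrix")) {
    nmf_input_matrix(E_new)
  } else E_new
  shared <- intersect(rownames(w), rownames(v_raw))
  required <- max(ceiling(min_overlap_frac * nrow(w)),
                  min(min_overlap_genes, nrow(w)))
  if (length(shared) < required)
    stop_ptc("ptc_projection",
             "gene overlap %d below required %d (basis %d genes)",
             length(shared), required, nrow(w))
  frac <- length(shared) / nrow(w)
  ptc_log("project_metagenes: %d/%d basis genes shared (%.1f%%)",
          length(shared), nrow(w), 100 * frac)
  ws <- w[shared, , drop = FALSE]
  vs <- v_raw[shared, , drop = FALSE]
  if (qr(ws)$rank < ncol(ws))
    warn_ptc("rank-deficient basis on the shared genes; least-norm solution used")
  if (method == "pinv") {
    Hn <- MASS::ginv(ws) %*% vs
    if (clamp_negative) {
      n_neg <- sum(Hn < 0)
      if (n_neg > 0) ptc_log("project_metagenes: clamped %d negative activities", n_neg)
      Hn[Hn < 0] <- 0
    }
  } else {
    Hn <- apply(vs, 2L, function(col) pracma::lsqnonneg(ws, col)$x)
    Hn <- matrix(Hn, nrow = ncol(ws))
  }
  dimnames(Hn) <- list(colnames(ws), colnames(vs))
  out <- if (clamp_negative || method == "nnls") {
    metagene_activity(Hn)
  } else {
    # unclamped solutions may be negative; bypass the non-negativity check
    structure(list(levels = Hn, k = nrow(Hn),
                   signature_names = rownames(Hn)), class = "MetageneActivity")
  }
  attr(out, "overlap_fraction") <- frac
  out
}

# per-sample fallback labeling used when an external cohort does not span the
# four clusters: side by RAS vs BRAF activity, IR when the Immune activity
# exceeds the mean of the two driver activities
label_samples_directly <- function(H, annotation) {
  h <- if (inherits(H, "MetageneActivity")) H$levels else H
  a_ras <- h[role_row(annotation, "RAS"), ]
  a_braf <- h[role_row(annotation, "BRAF"), ]
  a_imm <- h[role_row(annotation, "Immune"), ]
  side <- ifelse(a_ras >= a_braf, "RAS", "BRAF")
  ir <- a_imm > (a_ras + a_braf) / 2
  lab <- paste0(side, ifelse(ir, "-IR", "-ID"))
  nmf_by_label <- c("RAS-IR" = "NMF1", "RAS-ID" = "NMF2",
                    "BRAF-IR" = "NMF3", "BRAF-ID" = "NMF4")
  out <- data.frame(sample_id = colnames(h),
                    cluster = factor(nmf_by_label[lab],
                                     levels = paste0("NMF", 1:4)),
                    label = factor(lab, levels = names(nmf_by_label)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ClusterAssignment", "data.frame")
  out
}

#' Classify an external cohort with a fitted metagene model
#'
#' Projects the new cohort onto the basis, clusters the projected activities
#' and labels the clusters. If the external cohort does not support a 2 + 2
#' RAS/BRAF side split (e.g. it contains only one subtype), a per-sample
#' rule is used instead: side by dominant driver signature, IR when the
#' Immune activity exceeds the mean of the two driver activities.
#'
#' @inheritParams project_metagenes
#' @param annotation [annotate_signatures()] from the model cohort.
#' @param n_clusters clusters to cut (default 4).
#' @param ... passed to [project_metagenes()].
#' @return A `ClusterAssignment` data frame (see [label_clusters()]).
#' @export
classify_external <- function(W, annotation, E_new, n_clusters = 4L, ...) {
  Hn <- project_metagenes(W, E_new, ...)
  out <- tryCatch({
    raw <- cluster_samples(Hn, n_clusters = n_clusters)
    label_clusters(raw, annotation, Hn)
  }, ptc_labeling = function(e) {
    ptc_log("classify_external: %s; falling back to per-sample labeling",
            conditionMessage(e))
    label_samples_directly(Hn, annotation)
  })
  attr(out, "activity") <- Hn
  out
}
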