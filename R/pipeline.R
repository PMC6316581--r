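pipeline_defaults <- function() {
  list(
    seed = NULL,
    stages = c("preprocess", "nmf", "classify", "immune", "assoc"),
    paths = list(expression = NULL, clinical = NULL, features = NULL,
                 gmt = NULL, reference = NULL, outdir = NULL),
    preprocess = list(pseudocount = 1, n_variable_genes = 5000L),
    nmf = list(ranks = 2:6, runs = 10L, rank = NULL, tol = 1e-5,
               max_iter = 500L),
    classify = list(linkage = "ward.D2", min_overlap_frac = 0.5,
                    min_overlap_genes = 200L),
    report = list(alpha = 0.05, p_enter = 0.25, digits = 2L))
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop_ptc("ptc_config", "unknown config key%s: %s",
             if (length(unknown) > 1) "s" else "",
             paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop_ptc("ptc_config", "config key '%s%s' must be a section", path, nm)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads YAML or JSON (by file extension), fills documented defaults, rejects
#' unknown keys, and checks that a seed is present and referenced input paths
#' exist.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @return normalized `PipelineConfig` list.
#' @export
validate_config <- function(config) {
  user <- if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_ptc("ptc_io", "config file not found: %s", config)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) config else
    stop_ptc("ptc_config", "config must be a path or a named list")
  cfg <- merge_config(pipeline_defaults(), user)
  if (is.null(cfg$seed)) stop_ptc("ptc_config", "config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg$stages <- match.arg(cfg$stages, pipeline_defaults()$stages,
                          several.ok = TRUE)
  for (nm in c("expression", "clinical", "features", "gmt", "reference")) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop_ptc("ptc_config", "paths.%s does not exist: %s", nm, p)
  }
  if ("assoc" %in% cfg$stages && is.null(cfg$paths$clinical))
    stop_ptc("ptc_config", "assoc stage requires paths.clinical")
  if (is.null(cfg$paths$expression))
    stop_ptc("ptc_config", "paths.expression is required")
  if (is.null(cfg$paths$outdir))
    stop_ptc("ptc_config", "paths.outdir is required")
  structure(cfg, class = "PipelineConfig")
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the end-to-end metagene analysis pipeline
#'
#' Stages: `preprocess` (read expression, variable-gene filter, log
#' transform), `nmf` (rank survey, rank selection, final factorization),
#' `classify` (signature annotation from driver labels, four-cluster
#' labeling), `immune` (feature table, signature-feature correlations,
#' per-cluster ANOVA), `assoc` (recurrence odds-ratio/logistic tables, Cox
#' tables, Kaplan-Meier curves and log-rank test by cluster). Each stage
#' writes its outputs under `paths.outdir` and later stages can restart from
#' those files; a `manifest.json` records the package version, seed, input
#' checksums and key results. Fixed config + seed gives identical outputs.
#'
#' @param config a [validate_config()] result (or path/list accepted by it).
#' @param stages optional subset of stages to run (default from config).
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, stages = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config else validate_config(config)
  stages <- stages %||% cfg$stages
  outdir <- cfg$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  manifest <- list(package = as.character(packageVersion("ptcnmf")),
                   seed = cfg$seed, stages = stages, warnings = list(),
                   inputs = list(), results = list())
  for (nm in c("expression", "clinical", "features", "gmt")) {
    p <- cfg$paths[[nm]]
    if (!is.null(p)) manifest$inputs[[nm]] <- unname(tools::md5sum(p))
  }
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    ptc_log("pipeline stage: %s", name)
    withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        stop_ptc("ptc_stage", "stage '%s' failed: %s", name,
                 conditionMessage(e))
      }),
      warning = function(w) {
        manifest$warnings[[length(manifest$warnings) + 1L]] <<-
          paste0(name, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  run_stage("preprocess", function() {
    E <- read_expression_tsv(cfg$paths$expression)
    nv <- min(cfg$preprocess$n_variable_genes %||% nrow(E$values),
              nrow(E$values))
    state$E_linear <<- E
    Ef <- if (nv < nrow(E$values)) select_variable_genes(E, nv) else E
    state$E_log <<- log_transform(Ef, cfg$preprocess$pseudocount)
    manifest$results$n_genes_used <<- nrow(state$E_log$values)
  })

  run_stage("nmf", function() {
    if (is.null(state$E_log)) {
      E <- read_expression_tsv(cfg$paths$expression)
      nv <- min(cfg$preprocess$n_variable_genes %||% nrow(E$values),
                nrow(E$values))
      state$E_linear <<- E
      Ef <- if (nv < nrow(E$values)) select_variable_genes(E, nv) else E
      state$E_log <<- log_transform(Ef, cfg$preprocess$pseudocount)
    }
    k <- cfg$nmf$rank
    if (is.null(k)) {
      survey <- rank_survey(state$E_log, rank_range = cfg$nmf$ranks,
                            n_runs = cfg$nmf$runs,
                            base_seed = derive_seed(cfg$seed, 1L),
                            max_iter = cfg$nmf$max_iter, tol = cfg$nmf$tol)
      k <- select_rank(survey)
      utils::write.csv(data.frame(rank = survey$ranks,
                                  cophenetic = unname(survey$cophenetic)),
                       file.path(outdir, "survey.csv"), row.names = FALSE)
      write_matrix_tsv(survey$consensus[[paste0("k", k)]],
                       file.path(outdir, sprintf("consensus_%d.tsv", k)),
                       "sample_id")
      state$survey <<- survey
    }
    fit <- nmf_factorize(state$E_log, k, seed = derive_seed(cfg$seed, 2L),
                         max_iter = max(cfg$nmf$max_iter, 2000L),
                         tol = cfg$nmf$tol)
    write_matrix_tsv(fit$basis$weights, file.path(outdir, "W.tsv"), "gene_id")
    write_matrix_tsv(fit$activity$levels, file.path(outdir, "H.tsv"),
                     "signature")
    state$fit <<- fit
    manifest$results$selected_rank <<- k
    manifest$results$final_divergence <<-
      fit$divergence[length(fit$divergence)]
  })

  run_stage("classify", function() {
    if (is.null(state$fit)) {
      W <- read_matrix_tsv(file.path(outdir, "W.tsv"))
      H <- read_matrix_tsv(file.path(outdir, "H.tsv"))
      state$fit <<- list(basis = metagene_basis(W),
                         activity = metagene_activity(H))
    }
    if (is.null(state$E_linear))
      state$E_linear <<- read_expression_tsv(cfg$paths$expression)
    clinical <- utils::read.csv(cfg$paths$clinical, stringsAsFactors = FALSE)
    idx <- match(colnames(state$fit$activity$levels), clinical$sample_id)
    marker <- cyt_score(state$E_linear)
    ann <- annotate_signatures(state$fit$activity,
                               clinical$driver_class[idx],
                               marker[colnames(state$fit$activity$levels)])
    raw <- cluster_samples(state$fit$activity,
                           linkage = cfg$classify$linkage)
    assignment <- label_clusters(raw, ann, state$fit$activity)
    roles <- ann$roles
    hl <- state$fit$activity$levels
    lab_df <- data.frame(assignment,
                         sig_RAS = hl[role_row(ann, "RAS"), ],
                         sig_Immune = hl[role_row(ann, "Immune"), ],
                         sig_BRAF = hl[role_row(ann, "BRAF"), ])
    utils::write.csv(lab_df, file.path(outdir, "labels.csv"),
                     row.names = FALSE)
    state$annotation <<- ann
    state$assignment <<- assignment
    manifest$results$signature_roles <<- as.list(roles)
    manifest$results$cluster_sizes <<-
      as.list(table(as.character(assignment$cluster)))
  })

  run_stage("immune", function() {
    if (is.null(state$E_linear))
      state$E_linear <<- read_expression_tsv(cfg$paths$expression)
    gene_sets <- NULL
    if (!is.null(cfg$paths$gmt)) {
      gmt <- read_gmt(cfg$paths$gmt)
      gene_sets <- list(immune = gmt[["immune"]], stromal = gmt[["stromal"]])
    }
    external <- if (!is.null(cfg$paths$features))
      utils::read.csv(cfg$paths$features, stringsAsFactors = FALSE) else NULL
    features <- build_immune_features(state$E_linear, gene_sets = gene_sets,
                                      external = external)
    utils::write.csv(features, file.path(outdir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(state$fit)) {
      r <- feature_signature_correlation(state$fit$activity, features)
      write_matrix_tsv(r, file.path(outdir, "correlations.tsv"), "signature")
    }
    if (!is.null(state$assignment)) {
      anova_tab <- cluster_feature_summary(features, state$assignment,
                                           alpha = cfg$report$alpha)
      utils::write.csv(anova_tab, file.path(outdir, "feature_anova.csv"),
                       row.names = FALSE)
    }
    state$features <<- features
  })

  run_stage("assoc", function() {
    clinical <- utils::read.csv(cfg$paths$clinical, stringsAsFactors = FALSE)
    if (!is.null(state$assignment)) {
      # recurrence statistics are computed against the pipeline's own labels
      idx <- match(clinical$sample_id, state$assignment$sample_id)
      clinical$cluster <- as.character(state$assignment$cluster)[idx]
    }
    t2 <- build_table2(clinical, p_enter = cfg$report$p_enter,
                       alpha = cfg$report$alpha)
    utils::write.csv(t2$univariate, file.path(outdir, "table2.csv"),
                     row.names = FALSE)
    if (!is.null(t2$multivariate))
      utils::write.csv(t2$multivariate,
                       file.path(outdir, "table2_multivariate.csv"),
                       row.names = FALSE)
    t3 <- build_table3(clinical, p_enter = cfg$report$p_enter,
                       alpha = cfg$report$alpha)
    utils::write.csv(t3$univariate, file.path(outdir, "table3.csv"),
                     row.names = FALSE)
    ok <- !is.na(clinical$followup_months) & !is.na(clinical$event) &
      !is.na(clinical$cluster)
    km <- km_estimate(clinical$followup_months[ok], clinical$event[ok],
                      clinical$cluster[ok])
    utils::write.csv(km$curves, file.path(outdir, "km_curves.csv"),
                     row.names = FALSE)
    lr <- logrank_test(clinical$followup_months[ok], clinical$event[ok],
                       clinical$cluster[ok])
    state$table2 <<- t2; state$table3 <<- t3; state$km <<- km
    manifest$results$logrank_p <<- lr$p
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(state, list(manifest = manifest, config = cfg)))
}
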