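#' Pipeline configuration with study defaults
#'
#' Collects every tunable parameter of the end-to-end analysis in one
#' place, pre-filled with the published values: normalization pseudocount
#' 1; elastic-net mixing and penalty 0.1 with MYC cutoff 0.5; consensus
#' clustering with 200 replicates at 80% subsampling over k = 2..9; immune
#' ratio cutoff -0.278958829. Every random stage derives its seed from
#' `seed`.
#'
#' @param cohort a [cohort_config()] for the synthetic stage.
#' @param pseudocount added before the log2 step of normalization.
#' @param myc list: `alpha`, `penalty`, `cutoff`.
#' @param consensus list: `n_reps`, `fraction`, `k_range`.
#' @param immune_cutoff immune-ratio classification cutoff.
#' @param stages character vector of stages to run, a subset of
#'   `c("myc", "consensus", "immune")` (normalization and integration
#'   always run).
#' @param seed master seed.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            pseudocount = 1,
                            myc = list(alpha = 0.1, penalty = 0.1, cutoff = 0.5),
                            consensus = list(n_reps = 200, fraction = 0.8,
                                             k_range = 2:9),
                            immune_cutoff = -0.278958829,
                            stages = c("myc", "consensus", "immune"),
                            seed = 1L) {
  structure(
    list(cohort = cohort, pseudocount = pseudocount, myc = myc,
         consensus = consensus, immune_cutoff = immune_cutoff,
         stages = stages, seed = as.integer(seed)),
    class = "run_config"
  )
}

# Consensus-clustering stage: per-algorithm matrices over the k range,
# k selection (CDF-area rule for HC/SOM, BIC for PC), final per-algorithm
# labelings from the consensus matrices, alignment, meta-consensus and
# naive-Bayes extension, then cluster naming by host-response gene level.
run_consensus_stage <- function(norm, panel, cfg, seed) {
  monti_genes <- panel_genes(panel, c("oxphos", "bcr_prolif", "hr"))
  Zg <- zscale_genes(norm)[monti_genes, , drop = FALSE]
  # Per-sample median centering over the clustering gene set: residual
  # normalization error shifts all genes of a sample jointly, a rank-1
  # technical axis that would otherwise look like stable substructure to
  # the resampling procedure.
  Zg <- sweep(Zg, 2, apply(Zg, 2, stats::median), `-`)
  Z <- t(Zg)
  ks <- cfg$k_range
  algorithms <- c("HC", "SOM", "PC")

  matrices <- lapply(algorithms, function(alg) {
    ms <- lapply(ks, function(k) {
      consensus_matrix(Z, alg, k, n_reps = cfg$n_reps,
                       fraction = cfg$fraction,
                       seed = child_seed(seed, k * 100 + match(alg, algorithms)))
    })
    names(ms) <- ks
    ms
  })
  names(matrices) <- algorithms

  # BIC per k on the full data for the probabilistic route. The candidate
  # covariance families are evaluated jointly so the reported BIC is the
  # best of the same family set at every k (per-k fallbacks to different
  # families would make BIC values incomparable across k).
  pc_bic <- vapply(ks, function(k) {
    fit <- with_seed(child_seed(seed, 9000 + k), tryCatch(
      mclust::Mclust(Z, G = k, modelNames = c("EEI", "EII", "VII"),
                     verbose = FALSE),
      error = function(e) NULL
    ))
    if (is.null(fit)) NA_real_ else as.numeric(fit$bic)
  }, 0)
  names(pc_bic) <- ks

  selection <- list(
    HC = select_k(matrices$HC),
    SOM = select_k(matrices$SOM),
    PC = select_k(matrices$PC, bic = pc_bic)
  )
  chosen <- vapply(selection, `[[`, 0L, "k")
  # Common k: majority vote, smallest k on ties.
  tab <- table(chosen)
  k_final <- min(as.integer(names(tab)[tab == max(tab)]))

  labelings <- lapply(algorithms, function(alg) {
    cm <- matrices[[alg]][[as.character(k_final)]]
    hc <- stats::hclust(stats::as.dist(1 - cm$values), method = "average")
    unname(stats::cutree(hc, k = k_final))
  })
  names(labelings) <- algorithms
  aligned <- list(
    HC = labelings$HC,
    SOM = align_labels(labelings$HC, labelings$SOM),
    PC = align_labels(labelings$HC, labelings$PC)
  )
  meta <- meta_consensus(aligned)
  full <- tryCatch(extend_with_naive_bayes(Z, meta), error = function(e) {
    # Degenerate meta-consensus (e.g. agreement confined to one cluster):
    # fall back to a per-sample majority vote across the aligned labelings,
    # ties resolved by the hierarchical labeling.
    votes <- do.call(cbind, aligned)
    labels <- apply(votes, 1, function(v) {
      tb <- table(v)
      winners <- as.integer(names(tb)[tb == max(tb)])
      if (length(winners) == 1) winners else v[1]
    })
    list(labels = labels,
         source = ifelse(is.na(meta$labels), "vote", "meta"),
         nb_model = NULL)
  })

  # Name the cluster with the highest mean host-response expression "HR".
  hr_genes <- panel_genes(panel, "hr")
  hr_z <- colMeans(zscale_genes(norm)[hr_genes, , drop = FALSE])
  cluster_means <- tapply(hr_z, full$labels, mean)
  hr_id <- as.integer(names(cluster_means)[which.max(cluster_means)])
  calls <- ifelse(full$labels == hr_id, "HR", "non-HR")

  list(k = k_final, per_algorithm_k = chosen, selection = selection,
       matrices = matrices, labelings = aligned, meta = meta,
       labels = full$labels, source = full$source, calls = calls)
}

#' Run the full signature pipeline
#'
#' Stages, in order: synthetic cohort generation (unless a cohort is
#' supplied), normalization of the cohort and training counts, MYC
#' elastic-net training / LOOCV / scoring / IHC concordance, consensus
#' clustering with meta-consensus and naive-Bayes extension, immune ratio,
#' and integration: per-sample signature calls, the six-group table,
#' association tests and survival models. Rerunning with the same config
#' reproduces the outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-built `synthetic_cohort` (or compatible
#'   list with `counts`, `annotations`, `panel`, `training`); when `NULL`
#'   the synthetic stage generates one from `config$cohort`.
#' @return A list of class `pipeline_result` with elements `cohort`,
#'   `normalized`, `myc`, `consensus`, `immune`, `calls` (per-sample table)
#'   and `stats`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort)
  }
  panel <- cohort$panel
  ann <- cohort$annotations
  n <- nrow(ann)

  norm <- normalize_counts(cohort$counts, panel, config$pseudocount)

  calls <- data.frame(sample_id = ann$sample_id, coo = ann$coo,
                      stringsAsFactors = FALSE)

  myc_res <- NULL
  if ("myc" %in% config$stages) {
    tr_norm <- normalize_counts(cohort$training$counts, panel,
                                config$pseudocount)
    myc_panel <- panel_genes(panel, "myc_panel")
    model <- myc_train(tr_norm, cohort$training$labels, genes = myc_panel,
                       alpha = config$myc$alpha, penalty = config$myc$penalty,
                       cutoff = config$myc$cutoff)
    loocv <- myc_loocv(tr_norm, cohort$training$labels, genes = myc_panel,
                       alpha = config$myc$alpha, penalty = config$myc$penalty,
                       cutoff = config$myc$cutoff)
    scored <- myc_score(model, norm)
    conc <- ihc_concordance(scored$score, scored$class, ann$myc_ihc)
    myc_res <- list(model = model, loocv_accuracy = loocv, scores = scored,
                    importance = gene_importance(model), concordance = conc)
    calls$myc_score <- scored$score
    calls$myc_class <- scored$class
  } else {
    calls$myc_score <- NA_real_
    calls$myc_class <- NA_character_
  }

  consensus_res <- NULL
  if ("consensus" %in% config$stages) {
    consensus_res <- run_consensus_stage(norm, panel, config$consensus,
                                         seed = child_seed(config$seed, 42))
    calls$monti <- consensus_res$calls
    calls$monti_source <- consensus_res$source
  } else {
    calls$monti <- NA_character_
    calls$monti_source <- NA_character_
  }

  immune_res <- NULL
  if ("immune" %in% config$stages) {
    immune_res <- immune_ratio(norm, cutoff = config$immune_cutoff)
    calls$immune_score <- immune_res$score
    calls$immune_class <- immune_res$class
  } else {
    calls$immune_score <- NA_real_
    calls$immune_class <- NA_character_
  }

  # IHC decision rules from the annotations.
  calls$hans <- hans_classify(ann$cd10_ihc, ann$bcl6_ihc, ann$mum1_ihc)
  calls$de <- double_expressor(ann$myc_ihc, ann$bcl2_ihc)
  calls$myc_ihc_class <- myc_ihc_class(ann$myc_ihc)
  calls$dh <- classify_dh(ann$fish_pos, ann$sv_pos)
  calls$six_group <- assign_six_groups(calls$coo, calls$myc_class, calls$monti)

  stats_res <- list(six_groups = six_group_table(calls$six_group))
  both <- calls$coo %in% c("GCB", "ABC")
  if (!anyNA(calls$myc_class) && any(both)) {
    tab <- table(myc = factor(calls$myc_class[both], c("High", "Low")),
                 coo = factor(calls$coo[both], c("ABC", "GCB")))
    stats_res$myc_vs_coo <- fisher_exact(tab)
  }
  if (!anyNA(calls$monti) && !anyNA(calls$immune_class)) {
    tab <- table(immune = factor(calls$immune_class, c("high", "low")),
                 monti = factor(calls$monti, c("HR", "non-HR")))
    stats_res$immune_vs_hr <- fisher_exact(tab)
  }
  if (n > 0 && sum(ann$event) >= 2) {
    stats_res$km_overall <- km_estimate(ann$time, ann$event)
    covs <- data.frame(
      aaipi_high = ann$aaipi >= 2,
      age_over_60 = ann$age > 60
    )
    if (!anyNA(calls$myc_class)) covs$myc_high <- calls$myc_class == "High"
    gc_ab <- calls$coo %in% c("GCB", "ABC")
    if (any(gc_ab)) {
      covs$abc <- ifelse(gc_ab, calls$coo == "ABC", NA)
    }
    stats_res$cox_univariate <- cox_fit(ann$time, ann$event, covs,
                                        mode = "univariate")
    ok <- stats::complete.cases(covs)
    if (sum(ann$event[ok]) >= 2) {
      stats_res$cox_multivariate <- cox_fit(ann$time[ok], ann$event[ok],
                                            covs[ok, , drop = FALSE],
                                            mode = "multivariate")
    }
  }

  structure(
    list(cohort = cohort, normalized = norm, myc = myc_res,
         consensus = consensus_res, immune = immune_res, calls = calls,
         stats = stats_res, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Signature pipeline result:", nrow(x$calls), "samples\n")
  if (!is.null(x$myc)) {
    cat("  MYC: LOOCV accuracy", round(x$myc$loocv_accuracy, 3),
        "| High calls:", sum(x$calls$myc_class == "High"), "\n")
  }
  if (!is.null(x$consensus)) {
    cat("  Consensus: k =", x$consensus$k, "| HR calls:",
        sum(x$calls$monti == "HR"), "\n")
  }
  if (!is.null(x$immune)) {
    cat("  Immune-low calls:", sum(x$calls$immune_class == "low"), "\n")
  }
  cat("\nSix-group table:\n")
  print(x$stats$six_groups, row.names = FALSE)
  invisible(x)
}

#' Validate input files/tables against the assay contract
#'
#' Checks gene/sample agreement between a counts table and annotations,
#' panel role completeness, and annotation ranges.
#'
#' @param counts genes x samples matrix (rownames = gene ids).
#' @param annotations data frame with at least `sample_id`.
#' @param panel a [panel_definition()].
#' @return Character vector of violations (empty when everything checks
#'   out).
#' @export
validate_inputs <- function(counts, annotations, panel) {
  violations <- character(0)
  if (!setequal(rownames(counts), panel$gene_id)) {
    violations <- c(violations,
                    "counts rows do not match the panel gene identifiers")
  }
  if (sum(panel$role == "housekeeping") != 6L) {
    violations <- c(violations,
                    "panel must contain exactly 6 housekeeping genes")
  }
  for (role in c("pos_control", "neg_control")) {
    if (!any(panel$role == role)) {
      violations <- c(violations, paste("panel has no", role, "probes"))
    }
  }
  extra <- setdiff(annotations$sample_id, colnames(counts))
  if (length(extra) > 0) {
    violations <- c(violations,
                    paste("annotation sample(s) absent from counts:",
                          paste(extra, collapse = ", ")))
  }
  for (col in intersect(c("myc_ihc", "bcl2_ihc", "cd10_ihc", "bcl6_ihc",
                          "mum1_ihc"), names(annotations))) {
    v <- annotations[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      violations <- c(violations, paste(col, "outside [0,100]"))
    }
  }
  if ("time" %in% names(annotations) &&
      any(!is.na(annotations$time) & annotations$time < 0)) {
    violations <- c(violations, "negative survival times")
  }
  violations
}

#' Write per-sample calls and summary tables of a pipeline result
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls_path <- file.path(dir, "signature_calls.csv")
  groups_path <- file.path(dir, "six_groups.csv")
  utils::write.csv(result$calls, calls_path, row.names = FALSE)
  utils::write.csv(result$stats$six_groups, groups_path, row.names = FALSE)
  paths <- c(calls = calls_path, groups = groups_path)
  if (!is.null(result$myc)) {
    p <- file.path(dir, "myc_importance.csv")
    utils::write.csv(result$myc$importance, p, row.names = FALSE)
    paths <- c(paths, importance = p)
  }
  invisible(paths)
}
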