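# End-to-end pipeline: preprocess -> embed -> cluster search -> profiles ->
# classifiers -> consensus -> screening, with a reproducible run manifest.

#' Run configuration
#'
#' One object holding every stage's settings plus the master seed, from which
#' each stochastic stage derives a deterministic child seed.
#'
#' @param output_dir Directory for stage reports and the manifest.
#' @param cohort_dir Optional cohort directory to read (see
#'   [read_cohort_tables()]); when `NULL` a synthetic cohort is generated.
#' @param n_subjects,separation,missing_rate Synthetic-cohort settings.
#' @param signal A [signal_config()].
#' @param reducer A [reducer_config()].
#' @param gate A [gate_config()].
#' @param conditions Clustering condition grid (see [cluster_conditions()]).
#' @param lambda Fusion weight for the waveform-plus-basic dissimilarity.
#' @param mds_dim MDS embedding dimension.
#' @param grids Classifier grids (default [compact_model_grids()]).
#' @param consensus_n_models Use all `"four"` models in the Borda consensus
#'   or only the `"three"` tree-based ones.
#' @param fixed_cutoff Conventional TUG screening cutoff in seconds.
#' @param min_class_per_phenotype Minimum members of each fall class a
#'   phenotype needs for the classifier stage (smaller phenotypes are
#'   skipped with a note).
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("phenogait_run_"),
                       cohort_dir = NULL,
                       n_subjects = 146L, separation = 1, missing_rate = 0,
                       signal = signal_config(), reducer = reducer_config(),
                       gate = gate_config(), conditions = cluster_conditions(),
                       lambda = 1, mds_dim = 5L,
                       grids = compact_model_grids(),
                       consensus_n_models = c("four", "three"),
                       fixed_cutoff = 13.50,
                       min_class_per_phenotype = 5L,
                       seed = 7L) {
  structure(list(output_dir = output_dir, cohort_dir = cohort_dir,
                 n_subjects = n_subjects, separation = separation,
                 missing_rate = missing_rate, signal = signal,
                 reducer = reducer, gate = gate, conditions = conditions,
                 lambda = lambda, mds_dim = as.integer(mds_dim), grids = grids,
                 consensus_n_models = match.arg(consensus_n_models),
                 fixed_cutoff = fixed_cutoff,
                 min_class_per_phenotype = as.integer(min_class_per_phenotype),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the whole pipeline
#'
#' Executes preprocess, dissimilarity + embedding, cluster-method search,
#' phenotype profiles, per-phenotype faller classifiers, attribution-based
#' Borda consensus and TUG screening, writing one CSV report per stage plus
#' a JSON manifest. A rerun with the same configuration reproduces all
#' outputs.
#'
#' @param config A [run_config()].
#' @param cohort Optionally, an in-memory `gait_cohort` (overrides
#'   `config$cohort_dir` and the synthetic default).
#' @return List with the cohort, stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  # A: input
  cohort <- stage("input", {
    if (!is.null(cohort)) cohort
    else if (!is.null(config$cohort_dir)) read_cohort_tables(config$cohort_dir)
    else generate_cohort(default_archetypes(config$separation),
                         n_subjects = config$n_subjects,
                         signal = config$signal,
                         seed = child_seed(config$seed, "cohort"),
                         missing_rate = config$missing_rate)
  })
  subjects <- cohort$subjects

  # B: representative curves and reduction
  reduced <- stage("preprocess", {
    curves <- cohort_representative_curves(cohort, config$signal)
    reduce_channels(curves, config$reducer)
  })

  # C: dissimilarities and embeddings per mode
  modes <- unique(as.character(config$conditions$mode))
  dissimilarities <- list(); embeddings <- list()
  stage("embedding", {
    for (mode in modes) {
      dissimilarities[[mode]] <- pairwise_dissimilarity(
        reduced$series, basic = subjects[, c("age", "height")],
        mode = mode, lambda = config$lambda)
      embeddings[[mode]] <- mds_embed(dissimilarities[[mode]],
                                       d = config$mds_dim,
                                       seed = child_seed(config$seed, mode))
    }
  })

  # D: cluster-method search
  for (mode in modes) {
    write.csv(dissimilarities[[mode]]$D,
              file.path(config$output_dir, paste0("dissimilarity_", mode, ".csv")))
    emb <- embeddings[[mode]]$coordinates
    colnames(emb) <- paste0("dim_", seq_len(ncol(emb)))
    write.csv(data.frame(subject_id = subjects$id, emb),
              file.path(config$output_dir, paste0("embedding_", mode, ".csv")),
              row.names = FALSE)
  }

  search <- stage("cluster_search", {
    evaluate_conditions(subjects, dissimilarities, embeddings,
                        conditions = config$conditions, gate = config$gate,
                        seed = child_seed(config$seed, "search"))
  })
  labels <- search$best$solution$labels
  write.csv(search$table, file.path(config$output_dir, "method_evaluation.csv"),
            row.names = FALSE)

  # E: phenotype profiles
  profiles <- stage("profiles", cluster_summary(subjects, labels))
  write.csv(profiles$table, file.path(config$output_dir, "phenotype_profiles.csv"),
            row.names = FALSE)

  # F: per-phenotype classifiers + consensus
  consensus <- list()
  screening <- list()
  for (cl in sort(unique(labels))) {
    sub <- subjects[labels == cl, , drop = FALSE]
    tab <- table(factor(sub$fell, levels = 0:1))
    if (min(tab) < config$min_class_per_phenotype) {
      message(sprintf("phenotype %d skipped in classifier stage (class counts %d/%d)",
                      cl, tab[1], tab[2]))
      next
    }
    cons <- stage(paste0("classify_phenotype_", cl), {
      phenotype_consensus(sub, grids = config$grids,
                          seed = child_seed(config$seed, paste0("models", cl)))
    })
    if (config$consensus_n_models == "three") {
      keep <- setdiff(model_families, "feedforward_nn")
      R <- vapply(cons$attributions[keep],
                  function(a) rank_with_ties(a$global_importance),
                  numeric(length(gait_feature_names())))
      rownames(R) <- gait_feature_names()
      cons$borda <- weighted_borda(R, cons$weights[keep])
    }
    consensus[[as.character(cl)]] <- cons
    scr <- stage(paste0("screen_phenotype_", cl), {
      roc <- youden_threshold(sub$tug_s, sub$fell)
      list(roc = roc,
           report = screening_report(sub$tug_s, sub$fell, roc$chosen_cutoff,
                                     config$fixed_cutoff))
    })
    screening[[as.character(cl)]] <- scr
  }
  if (length(consensus) > 0) {
    borda_tab <- do.call(rbind, lapply(names(consensus), function(cl) {
      b <- utils::head(consensus[[cl]]$borda, 10)
      cbind(phenotype = cl, b)
    }))
    write.csv(borda_tab, file.path(config$output_dir, "borda_consensus.csv"),
              row.names = FALSE)
    metr_tab <- do.call(rbind, lapply(names(consensus), function(cl) {
      do.call(rbind, lapply(consensus[[cl]]$models, function(m) {
        cbind(phenotype = cl, family = m$family, m$metrics)
      }))
    }))
    write.csv(metr_tab, file.path(config$output_dir, "model_metrics.csv"),
              row.names = FALSE)
    screen_tab <- do.call(rbind, lapply(names(screening), function(cl) {
      cbind(phenotype = cl, screening[[cl]]$report)
    }))
    write.csv(screen_tab, file.path(config$output_dir, "tug_screening.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenogait")),
    seed = config$seed,
    n_subjects = nrow(subjects),
    separation = config$separation,
    selected_condition = as.list(search$best$condition),
    selected_composite = search$best$composite,
    cluster_sizes = search$best$solution$sizes,
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, reduced = reduced,
                 dissimilarities = dissimilarities, embeddings = embeddings,
                 search = search, labels = labels, profiles = profiles,
                 consensus = consensus, screening = screening,
                 manifest = manifest))
}
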