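#' Configuration for the end-to-end off-target discovery pipeline
#'
#' Bundles every stage's hyperparameters with one master seed. Stages can be
#' disabled individually; the candidate report then ranks on the remaining
#' evidence.
#'
#' @param seed Master RNG seed; each stage derives its own stream from it.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("metabolomics", "classify", "rescue", "structure")`.
#' @param synth Synthetic-data settings: a [synth_config()] for the drug
#'   panel.
#' @param score_threshold Annotation-score filter cutoff.
#' @param inhibition_fraction Flux fraction retained by pathway caps.
#' @param supplement_rate In-silico supplementation rate (mmol/gDW/hr).
#' @param drain_rate Enforced cofactor drain rate (`NULL`: half the
#'   reference charging flux).
#' @param eps,min_samples DBSCAN parameters on the 2-D embedding.
#' @param n_neighbors Embedding neighborhood size.
#' @param k_pockets Pockets retained per protein.
#' @param experimental_rescue Tibble `metabolite`, `growth_rate` of observed
#'   supplementation rescue (default [toy_rescue_pattern()]).
#' @param query_class Mechanism class used to build the synthetic query
#'   compound and to anchor the residual signature.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42,
                            stages = c("metabolomics", "classify", "rescue", "structure"),
                            synth = synth_config(seed = seed, drugs_per_class = 3),
                            score_threshold = 50,
                            inhibition_fraction = 0.9,
                            supplement_rate = 0.1,
                            drain_rate = NULL,
                            eps = 0.5, min_samples = 5,
                            n_neighbors = 14,
                            k_pockets = 5,
                            experimental_rescue = toy_rescue_pattern(),
                            query_class = "antifolate") {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(
      seed = as.integer(seed), stages = stages, synth = synth,
      score_threshold = score_threshold,
      inhibition_fraction = inhibition_fraction,
      supplement_rate = supplement_rate, drain_rate = drain_rate,
      eps = eps, min_samples = min_samples, n_neighbors = n_neighbors,
      k_pockets = k_pockets, experimental_rescue = experimental_rescue,
      query_class = query_class
    ),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[sort(names(config))])
}

#' Run the five-stage off-target discovery workflow on synthetic inputs
#'
#' Executes, in order: differential metabolomics of the query compound;
#' mechanism-of-action classification (filtering, training, leave-one-out
#' evaluation, query prediction, residual signature, embedding + clustering,
#' correlation matrix); constraint-based supplementation-rescue analysis on
#' the toy folate network (folate scenarios vs exhaustive knockout null);
#' and structural candidate ranking. Evidence is combined into a ranked
#' candidate table by rank-sum of pocket similarity and membership in the
#' pathway implicated by the best rescue scenario.
#'
#' @param config A [pipeline_config()].
#' @return A `candidate_report`: list with per-stage results, the combined
#'   `candidates` tibble and a provenance block (config hash, seed, package
#'   version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  stages <- config$stages
  report <- list(
    provenance = list(
      config_hash = config_hash(unclass(config)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("metarescue")),
      stages = stages
    )
  )

  # ---- stage 1: metabolomics --------------------------------------------
  abundance <- NULL
  if ("metabolomics" %in% stages || "classify" %in% stages) {
    abundance <- simulate_metabolomics(config$synth)
    query <- simulate_metabolomics(
      synth_config(
        seed = config$seed + 1L,
        n_replicates = config$synth$n_replicates,
        noise_sd = config$synth$noise_sd,
        effect_size = config$synth$effect_size,
        class_labels = config$query_class,
        drugs_per_class = 1,
        n_metabolites = config$synth$n_metabolites,
        time_points = config$synth$time_points,
        low_score_fraction = config$synth$low_score_fraction
      ),
      signature_map = with_seed(
        config$synth$seed,
        default_signature_map(config$synth)
      )[config$query_class]
    ) |>
      dplyr::mutate(
        drug = ifelse(.data$drug == "control", "control", "query_drug"),
        condition = ifelse(.data$condition == "control", "control", "query_drug")
      )
    report$query_abundance <- query
  }
  if ("metabolomics" %in% stages) {
    report$differential <- differential_table(
      report$query_abundance,
      contrast = c("query_drug", "control")
    )
  }

  # ---- stage 2: mechanism classification --------------------------------
  if ("classify" %in% stages) {
    panel_long <- drug_profiles(abundance)
    profiles <- filter_profiles(panel_long, score_threshold = config$score_threshold)
    query_long <- drug_profiles(report$query_abundance)
    query_profile <- filter_profiles(
      query_long,
      score_threshold = config$score_threshold,
      shared_ids = profile_feature_names(profiles)
    )
    shared <- intersect(profile_feature_names(profiles), profile_feature_names(query_profile))
    profiles <- profiles[, c("drug", "mechanism", shared)]
    query_profile <- query_profile[, c("drug", "mechanism", shared)]
    model <- train_mechanism_model(profiles)
    loocv <- evaluate_loocv(profiles)
    pred <- predict_mechanism(model, query_profile)
    top_class <- model$classes[which.max(as.numeric(pred[1, model$classes]))]
    residual <- residual_signature(model, query_profile, top_class)
    emb <- embed_2d(
      dplyr::bind_rows(profiles, query_profile),
      n_neighbors = min(config$n_neighbors, nrow(profiles) - 1)
    )
    emb$cluster <- dbscan_cluster(emb, eps = config$eps, min_samples = config$min_samples)
    report$classification <- list(
      profiles = profiles, model = model, loocv = loocv,
      query_prediction = pred, top_class = top_class,
      residual = residual, embedding = emb,
      correlation = drug_correlation_matrix(profiles),
      importance = feature_importance(model, top_class)
    )
  }

  # ---- stage 3: supplementation-rescue modelling ------------------------
  if ("rescue" %in% stages) {
    model0 <- make_toy_model()
    spec <- attr(model0, "spec")
    wt <- close_spontaneous(apply_expression_shutoff(
      model0, spec$unexpressed_genes,
      scope = "global"
    ))
    supplements <- config$experimental_rescue$metabolite
    scen <- folate_scenarios(
      fraction = config$inhibition_fraction,
      drain_rate = config$drain_rate
    )
    benefits <- benefit_table(wt, scen, supplements, rate = config$supplement_rate)
    combined <- benefits |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::summarise(benefit = mean(.data$benefit), .groups = "drop") |>
      dplyr::mutate(scenario = "folate_combined")
    null_tab <- random_inhibition_null(
      wt, supplements,
      seed = config$seed, rate = config$supplement_rate
    )
    ranking <- rank_scenarios(
      dplyr::bind_rows(combined, benefits, null_tab),
      config$experimental_rescue
    )
    report$rescue <- list(
      benefits = benefits, combined = combined, null = null_tab,
      ranking = ranking,
      best_scenario = ranking$scenario[1],
      implicated_pathway = if (grepl("^folate", ranking$scenario[1])) "folate" else "other"
    )
  }

  # ---- stage 4: structural candidate ranking ----------------------------
  if ("structure" %in% stages) {
    structs <- simulate_structures(seed = config$seed)
    pathway_members <- c("folK_like", "prot01", "prot02")
    ranked <- rank_candidates(
      structs$pockets,
      reference = "ref", k = config$k_pockets,
      pathway = pathway_members
    )
    report$structure <- list(
      properties = structs$properties,
      global_similarity = global_similarity_matrix(structs$properties),
      ranking = ranked,
      pathway = pathway_members
    )
  }

  # ---- combine evidence --------------------------------------------------
  report$candidates <- combine_evidence(report)
  class(report) <- "candidate_report"
  report
}

# Rank-sum combination: pocket-similarity rank plus pathway-evidence rank
# (members of the pathway implicated by the best rescue scenario rank ahead
# of non-members). Deterministic ties by protein id.
combine_evidence <- function(report) {
  if (is.null(report$structure)) {
    return(tibble(
      protein = character(0), pocket_rank = integer(0),
      pathway_rank = integer(0), rank_sum = numeric(0), rank = integer(0)
    ))
  }
  ranked <- report$structure$ranking
  pathway_supported <- !is.null(report$rescue) &&
    identical(report$rescue$implicated_pathway, "folate")
  out <- ranked |>
    dplyr::mutate(
      pocket_rank = dplyr::row_number(),
      pathway_rank = if (pathway_supported) {
        dplyr::dense_rank(!.data$in_pathway)
      } else {
        1L
      },
      rank_sum = .data$pocket_rank + .data$pathway_rank
    ) |>
    dplyr::arrange(.data$rank_sum, .data$protein) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(
      "protein", "score", "in_pathway", "pocket_rank",
      "pathway_rank", "rank_sum", "rank"
    )
  if (!is.null(report$classification)) {
    out$mechanism_class <- report$classification$top_class
  }
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("<candidate_report>\n")
  cat(" stages:", paste(x$provenance$stages, collapse = ", "), "\n")
  cat(" config hash:", x$provenance$config_hash, "\n")
  if (!is.null(x$rescue)) cat(" best rescue scenario:", x$rescue$best_scenario, "\n")
  if (nrow(x$candidates) > 0) {
    cat(" top candidate:", x$candidates$protein[1], "\n")
  }
  invisible(x)
}

#' Write a candidate report to disk
#'
#' Exports every numeric backing of the workflow as TSV (differential table,
#' confusion matrix, feature importance, embedding, benefit and ranking
#' tables, candidate table) plus a human-readable `summary.txt` containing
#' the provenance block. Output is deterministic: identical configurations
#' produce byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param format Only `"tsv"` is supported.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, dir, format = "tsv") {
  if (!identical(format, "tsv")) {
    stop_metarescue(paste0("unknown report format: ", format), "metarescue_unknown_format")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(df, p)
    paths <<- c(paths, p)
  }
  emit(report$candidates, "candidates")
  if (!is.null(report$differential)) emit(report$differential, "differential")
  if (!is.null(report$classification)) {
    conf <- as_tibble(report$classification$loocv$confusion, rownames = "truth")
    emit(conf, "confusion")
    emit(report$classification$importance, "importance")
    emit(report$classification$embedding, "embedding")
    emit(report$classification$query_prediction, "query_prediction")
    emit(
      as_tibble(report$classification$correlation, rownames = "drug"),
      "correlation"
    )
  }
  if (!is.null(report$rescue)) {
    emit(report$rescue$benefits, "benefits")
    emit(report$rescue$ranking, "scenario_ranking")
  }
  if (!is.null(report$structure)) {
    emit(
      as_tibble(report$structure$global_similarity, rownames = "protein"),
      "global_similarity"
    )
    emit(report$structure$ranking, "pocket_ranking")
  }
  summary_path <- file.path(dir, "summary.txt")
  lines <- c(
    "metarescue candidate report",
    paste0("config hash: ", report$provenance$config_hash),
    paste0("seed: ", report$provenance$seed),
    paste0("stages: ", paste(report$provenance$stages, collapse = ", ")),
    if (!is.null(report$rescue)) {
      paste0("best rescue scenario: ", report$rescue$best_scenario)
    },
    if (!is.null(report$classification)) {
      paste0("query mechanism class: ", report$classification$top_class)
    },
    if (nrow(report$candidates) > 0) {
      paste0(
        "top candidate: ", report$candidates$protein[1],
        " (rank-sum ", report$candidates$rank_sum[1], ")"
      )
    }
  )
  writeLines(lines, summary_path)
  invisible(c(paths, summary_path))
}
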