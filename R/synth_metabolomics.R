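#' Configuration for the synthetic metabolomics generator
#'
#' Captures the statistical structure the generators emulate: per-class
#' perturbation signatures on a shared metabolite namespace, multiplicative
#' log-normal measurement noise, biological replicates, time points, and a
#' fraction of features with low annotation confidence to exercise the
#' annotation-score filter.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @param n_replicates Biological replicates per drug and time point.
#' @param noise_sd Log2-scale standard deviation of the multiplicative
#'   log-normal intensity noise (>= 0).
#' @param effect_size Log2 fold-change magnitude of class signature effects
#'   (>= 0).
#' @param class_labels Mechanism-of-action class names.
#' @param drugs_per_class Number of distinct compounds per class.
#' @param n_metabolites Size of the shared metabolite namespace.
#' @param time_points Sampling times (hours); time 0 carries no treatment
#'   effect.
#' @param low_score_fraction Fraction of metabolites assigned annotation
#'   score <= 50 (filtered out downstream).
#' @param signature_fraction Fraction of metabolites perturbed by each class
#'   signature.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_replicates = 3, noise_sd = 0.2,
                         effect_size = 2,
                         class_labels = c(
                           "antifolate", "cell_wall", "dna_synthesis",
                           "translation", "oxidative_stress"
                         ),
                         drugs_per_class = 2, n_metabolites = 40,
                         time_points = c(0, 4, 8),
                         low_score_fraction = 0.2,
                         signature_fraction = 0.25) {
  assert_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(is_number(effect_size) && effect_size >= 0, "effect_size must be >= 0")
  assert_that(is_count(n_replicates), "n_replicates must be a positive integer")
  assert_that(length(class_labels) >= 1, "at least one class label required")
  structure(
    list(
      seed = as.integer(seed), n_replicates = n_replicates, noise_sd = noise_sd,
      effect_size = effect_size, class_labels = class_labels,
      drugs_per_class = drugs_per_class, n_metabolites = n_metabolites,
      time_points = time_points, low_score_fraction = low_score_fraction,
      signature_fraction = signature_fraction
    ),
    class = "synth_config"
  )
}

# Default per-class signatures: a random subset of metabolites perturbed by
# +/- effect_size log2 units per class.
default_signature_map <- function(config) {
  mets <- metabolite_ids(config$n_metabolites)
  n_hit <- max(1L, round(config$signature_fraction * config$n_metabolites))
  out <- lapply(config$class_labels, function(cl) {
    hit <- sample(mets, n_hit)
    setNames(sample(c(-1, 1), n_hit, replace = TRUE) * config$effect_size, hit)
  })
  setNames(out, config$class_labels)
}

metabolite_ids <- function(n) sprintf("C%05d", seq_len(n))

#' Simulate a labeled drug-panel metabolomics dataset
#'
#' Generates per-sample metabolite intensities for a panel of compounds with
#' known mechanism classes plus untreated controls. Each treated sample is
#' `baseline * 2^(class effect) * 2^noise` with log-normal noise on the log2
#' scale; the class effect is absent at time zero. Metabolite annotation
#' scores are drawn so a configurable fraction falls at or below 50.
#'
#' @param config A [synth_config()].
#' @param signature_map Named list, class -> named numeric vector of log2
#'   effects over metabolites. `NULL` draws random signatures of magnitude
#'   `config$effect_size`.
#' @return An abundance table: tibble with columns `sample_id`, `drug`,
#'   `condition` (mechanism class or `"control"`), `time_point`, `replicate`,
#'   `metabolite`, `intensity`, `annotation_score`.
#' @examples
#' tab <- simulate_metabolomics(synth_config(seed = 7, n_metabolites = 10))
#' dplyr::count(tab, condition)
#' @export
simulate_metabolomics <- function(config = synth_config(), signature_map = NULL) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  assert_that(length(config$class_labels) >= 1, "empty class set")
  with_seed(config$seed, {
    if (is.null(signature_map)) signature_map <- default_signature_map(config)
    assert_that(length(signature_map) >= 1, "empty class set")
    mets <- metabolite_ids(config$n_metabolites)
    extra <- setdiff(unique(unlist(lapply(signature_map, names))), mets)
    mets <- c(mets, extra)
    baseline <- setNames(2^rnorm(length(mets), mean = 20, sd = 1.5), mets)
    n_low <- round(config$low_score_fraction * length(mets))
    low <- sample(mets, n_low)
    score <- setNames(runif(length(mets), 51, 100), mets)
    score[low] <- runif(n_low, 0, 50)

    drugs <- purrr::map_dfr(names(signature_map), function(cl) {
      tibble(
        drug = paste0(cl, "_d", seq_len(config$drugs_per_class)),
        condition = cl
      )
    })
    drugs <- dplyr::bind_rows(drugs, tibble(drug = "control", condition = "control"))

    grid <- tidyr::expand_grid(
      drugs,
      time_point = config$time_points,
      replicate = seq_len(config$n_replicates)
    )
    out <- purrr::pmap_dfr(grid, function(drug, condition, time_point, replicate) {
      effect <- rep(0, length(mets))
      names(effect) <- mets
      if (condition != "control" && time_point > 0) {
        sig <- signature_map[[condition]]
        effect[names(sig)] <- sig
      }
      noise <- rnorm(length(mets), 0, config$noise_sd)
      tibble(
        sample_id = paste(drug, time_point, replicate, sep = "_"),
        drug = drug, condition = condition,
        time_point = time_point, replicate = replicate,
        metabolite = mets,
        intensity = baseline * 2^(effect + noise),
        annotation_score = unname(score[mets])
      )
    })
    out
  })
}

#' Per-drug log fold-change profiles from an abundance table
#'
#' Computes, for each drug, time point and metabolite, the log2 ratio of the
#' mean treated intensity over the mean control intensity at the same time
#' point. This long profile table is the input of [filter_profiles()].
#'
#' @param abundance Output of [simulate_metabolomics()] (or a table with the
#'   same columns).
#' @param control Condition label of the untreated reference samples.
#' @param pseudocount Added to both means before the ratio (see
#'   [log_fold_change()]).
#' @return Tibble `drug`, `mechanism`, `time_point`, `metabolite`, `lfc`,
#'   `annotation_score`.
#' @export
drug_profiles <- function(abundance, control = "control", pseudocount = 0) {
  assert_that(control %in% abundance$condition, "control condition not present")
  ctrl <- abundance |>
    dplyr::filter(.data$condition == control) |>
    dplyr::group_by(.data$time_point, .data$metabolite) |>
    dplyr::summarise(control_mean = mean(.data$intensity), .groups = "drop")
  abundance |>
    dplyr::filter(.data$condition != control) |>
    dplyr::group_by(
      .data$drug, .data$condition, .data$time_point,
      .data$metabolite, .data$annotation_score
    ) |>
    dplyr::summarise(treated_mean = mean(.data$intensity), .groups = "drop") |>
    dplyr::inner_join(ctrl, by = c("time_point", "metabolite")) |>
    dplyr::mutate(
      lfc = log2((.data$treated_mean + pseudocount) / (.data$control_mean + pseudocount))
    ) |>
    dplyr::select(
      drug = "drug", mechanism = "condition", "time_point",
      "metabolite", "lfc", "annotation_score"
    )
}
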