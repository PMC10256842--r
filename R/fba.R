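#' Flux balance analysis with parsimonious flux selection
#'
#' Maximizes the objective (biomass) flux subject to steady state
#' (`S v = 0`) and the reaction bounds. Among the typically degenerate
#' optima, a secondary linear program minimizes total absolute flux
#' (parsimonious FBA) so that the returned flux distribution is a unique,
#' reproducible reference.
#'
#' @param model A [metabolic_model()].
#' @param parsimonious If `TRUE` (default) run the secondary
#'   total-flux-minimization step; `FALSE` returns an arbitrary optimal
#'   vertex (faster, objective value identical).
#' @return An object of class `flux_solution`: a list with `objective`
#'   (the growth rate, 1/hr), `fluxes` (tibble `reaction`, `flux`) and
#'   `status` (`"optimal"`, `"infeasible"`, ...).
#' @examples
#' sol <- fba(make_toy_model())
#' sol$objective
#' @export
fba <- function(model, parsimonious = TRUE) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  obj <- model$reactions$objective_coefficient
  res <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(
      list(
        objective = NA_real_,
        fluxes = tibble(reaction = model$reactions$id, flux = NA_real_),
        status = res$status
      ),
      class = "flux_solution"
    ))
  }
  v <- res$v
  if (parsimonious) {
    p <- lp_min_total_flux(S, lb, ub, obj, res$objective)
    if (p$status == "optimal") v <- p$v
  }
  structure(
    list(
      objective = res$objective,
      fluxes = tibble(reaction = model$reactions$id, flux = v),
      status = "optimal"
    ),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution>  status: %s, objective: %s\n", x$status, format(x$objective)))
  invisible(x)
}

#' @export
tidy.flux_solution <- function(x, ...) x$fluxes

#' @export
glance.flux_solution <- function(x, ...) {
  tibble(
    objective = x$objective, status = x$status,
    total_flux = sum(abs(x$fluxes$flux)),
    n_active = sum(abs(x$fluxes$flux) > 1e-9)
  )
}

# -- expression shutoff ------------------------------------------------------

#' Close reactions not expressed under wild-type conditions
#'
#' Evaluates each reaction's gene rule against a set of unexpressed genes and
#' closes (bounds 0, 0) the reactions whose rule is false. With
#' `scope = "neighborhood"` (the default) only reactions within `k`
#' metabolite-sharing steps of the supplied supplement metabolites are
#' considered, because shutting off every unexpressed reaction in a
#' genome-scale model typically abolishes growth; `scope = "global"`
#' considers all reactions.
#'
#' @param model A [metabolic_model()].
#' @param unexpressed_genes Character vector of gene ids with no wild-type
#'   expression.
#' @param scope `"neighborhood"` or `"global"`.
#' @param supplement_metabolites Metabolite ids anchoring the neighborhood
#'   (required for `scope = "neighborhood"`).
#' @param k Neighborhood radius in reaction steps (default 2).
#' @return The modified model.
#' @export
apply_expression_shutoff <- function(model, unexpressed_genes,
                                     scope = c("neighborhood", "global"),
                                     supplement_metabolites = NULL, k = 2) {
  scope <- match.arg(scope)
  off <- !vapply(
    seq_len(nrow(model$reactions)),
    function(i) {
      gpr_is_expressed(
        model$reactions$gene_rule[i], unexpressed_genes,
        model$reactions$id[i]
      )
    },
    logical(1)
  )
  if (scope == "neighborhood") {
    assert_that(
      length(supplement_metabolites) > 0,
      "supplement_metabolites required for neighborhood scope"
    )
    near <- reactions_near_metabolites(model, supplement_metabolites, k)
    off <- off & model$reactions$id %in% near
  }
  model$reactions$lower_bound[off] <- 0
  model$reactions$upper_bound[off] <- 0
  model
}

# Reactions within k steps of the given metabolites on the bipartite
# metabolite-reaction graph (a reaction is at step 1 if it touches the
# metabolite; its other metabolites seed step 2, and so on).
reactions_near_metabolites <- function(model, metabolites, k) {
  S <- stoich_matrix(model)
  mets <- intersect(metabolites, rownames(S))
  seen_rxn <- character(0)
  frontier <- mets
  for (step in seq_len(k)) {
    if (length(frontier) == 0) break
    touching <- colnames(S)[colSums(abs(S[frontier, , drop = FALSE])) > 0]
    new_rxn <- setdiff(touching, seen_rxn)
    seen_rxn <- union(seen_rxn, new_rxn)
    frontier <- setdiff(
      rownames(S)[rowSums(abs(S[, new_rxn, drop = FALSE])) > 0],
      frontier
    )
  }
  seen_rxn
}

#' Close spontaneous reactions
#'
#' Reactions flagged as spontaneous proceed uncatalyzed and typically too
#' slowly to sustain growth-scale flux; this closes all of them in one call.
#'
#' @param model A [metabolic_model()].
#' @return The modified model.
#' @export
close_spontaneous <- function(model) {
  sp <- model$reactions$spontaneous
  model$reactions$lower_bound[sp] <- 0
  model$reactions$upper_bound[sp] <- 0
  model
}

# -- perturbations -----------------------------------------------------------

#' Cap pathway reactions at a fraction of their reference flux
#'
#' Emulates partial enzymatic inhibition: each target reaction's flux
#' magnitude is capped at `fraction` times its parsimonious reference flux
#' (computed on the unperturbed model unless supplied). A reaction whose
#' reference flux is zero gets a cap of zero.
#'
#' @param model A [metabolic_model()].
#' @param reactions Reaction ids to constrain.
#' @param fraction Fraction of the reference flux to allow, in `[0, 1]`.
#' @param reference Optional [fba()] solution to take reference fluxes from.
#' @return The modified model.
#' @export
inhibit_pathway <- function(model, reactions, fraction, reference = NULL) {
  assert_that(
    is_number(fraction) && fraction >= 0 && fraction <= 1,
    "fraction must be in [0, 1]"
  )
  idx <- reaction_index(model, reactions)
  if (is.null(reference)) reference <- fba(model, parsimonious = TRUE)
  assert_that(reference$status == "optimal", "reference FBA must be feasible")
  ref_flux <- reference$fluxes$flux[match(reactions, reference$fluxes$reaction)]
  cap <- fraction * abs(ref_flux)
  model$reactions$upper_bound[idx] <- pmin(model$reactions$upper_bound[idx], cap)
  model$reactions$lower_bound[idx] <- pmax(model$reactions$lower_bound[idx], -cap)
  model
}

#' Add an enforced cofactor-draining reaction
#'
#' Adds a reaction converting the charged cofactor form to the discharged
#' form with an enforced minimum flux, emulating a compound that depletes the
#' charged pool (e.g. 5,10-methylene-THF -> THF).
#'
#' @param model A [metabolic_model()].
#' @param charged_id,discharged_id Metabolite ids of the charged and
#'   discharged cofactor forms.
#' @param drain_rate Enforced drain flux (mmol/gDW/hr).
#' @param reaction_id Id for the added reaction.
#' @return The modified model.
#' @export
add_cofactor_drain <- function(model, charged_id, discharged_id, drain_rate,
                               reaction_id = "COFACTOR_DRAIN") {
  missing <- setdiff(c(charged_id, discharged_id), model$metabolites$id)
  if (length(missing) > 0) {
    stop_metarescue(
      paste0("cofactor metabolite(s) not in model: ", paste(missing, collapse = ", ")),
      "metarescue_unknown_metabolite"
    )
  }
  assert_that(is_number(drain_rate) && drain_rate >= 0, "drain_rate must be >= 0")
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    toy_reaction(
      reaction_id,
      setNames(c(-1, 1), c(charged_id, discharged_id)),
      lb = drain_rate, ub = 1000
    )
  )
  validate_model(model)
}

#' Supplement a metabolite in silico
#'
#' Opens the uptake bound of the metabolite's exchange reaction so the model
#' may import it at up to `rate` (the exchange-flux sign convention is
#' negative = uptake). If the extracellular species exists but carries no
#' exchange reaction, one is created.
#'
#' @param model A [metabolic_model()].
#' @param metabolite Extracellular metabolite id (e.g. `"thymd_e"`).
#' @param rate Maximum uptake rate (mmol/gDW/hr), default 0.1.
#' @return The modified model.
#' @export
supplement <- function(model, metabolite, rate = 0.1) {
  assert_that(is_number(rate) && rate >= 0, "rate must be >= 0")
  if (!metabolite %in% model$metabolites$id) {
    stop_metarescue(
      paste0("metabolite not in model: ", metabolite),
      "metarescue_unknown_metabolite"
    )
  }
  ex_id <- find_exchange(model, metabolite)
  if (is.na(ex_id)) {
    ex_id <- paste0("EX_", metabolite)
    model$reactions <- dplyr::bind_rows(
      model$reactions,
      toy_reaction(ex_id, setNames(-1, metabolite), lb = 0, ub = 1000)
    )
  }
  i <- reaction_index(model, ex_id)
  model$reactions$lower_bound[i] <- min(model$reactions$lower_bound[i], -rate)
  model
}

find_exchange <- function(model, metabolite) {
  single <- vapply(model$reactions$stoichiometry, length, integer(1)) == 1
  hits <- which(single & vapply(
    model$reactions$stoichiometry,
    function(st) identical(names(st), metabolite), logical(1)
  ))
  if (length(hits) == 0) NA_character_ else model$reactions$id[hits[1]]
}

# -- scenarios ---------------------------------------------------------------

#' Define a pathway-inhibition scenario
#'
#' A scenario is a named perturbation of the model used to test whether a
#' hypothesized inhibition reproduces the experimental supplementation-rescue
#' pattern. Three kinds are supported: `pathway_fraction` (cap target
#' reactions at a fraction of their reference flux), `cofactor_drain`
#' (enforce a charged -> discharged drain) and `knockout` (target reactions
#' to zero flux).
#'
#' @param id Scenario identifier.
#' @param kind One of `"pathway_fraction"`, `"cofactor_drain"`, `"knockout"`.
#' @param reactions Target reaction ids (`pathway_fraction`, `knockout`).
#' @param fraction Flux fraction retained (`pathway_fraction`).
#' @param charged,discharged Cofactor metabolite ids (`cofactor_drain`).
#' @param drain_rate Enforced drain flux, or `NULL` to use half the reference
#'   charging flux at application time (`cofactor_drain`).
#' @param drain_reference Reaction id whose reference flux scales the default
#'   drain rate.
#' @return An `inhibition_scenario` object.
#' @export
inhibition_scenario <- function(id,
                                kind = c("pathway_fraction", "cofactor_drain", "knockout"),
                                reactions = NULL, fraction = 0.9,
                                charged = NULL, discharged = NULL,
                                drain_rate = NULL, drain_reference = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("pathway_fraction", "knockout")) {
    assert_that(length(reactions) >= 1, "scenario needs target reactions")
  }
  if (kind == "cofactor_drain") {
    assert_that(
      !is.null(charged) && !is.null(discharged),
      "cofactor_drain needs charged and discharged metabolite ids"
    )
  }
  structure(
    list(
      id = id, kind = kind, reactions = reactions, fraction = fraction,
      charged = charged, discharged = discharged, drain_rate = drain_rate,
      drain_reference = drain_reference
    ),
    class = "inhibition_scenario"
  )
}

#' Apply an inhibition scenario to a model
#'
#' @param model A [metabolic_model()].
#' @param scenario An [inhibition_scenario()].
#' @param reference Optional parsimonious [fba()] solution of the
#'   unperturbed model (computed if missing; used for fraction caps and the
#'   default drain rate).
#' @return The perturbed model.
#' @export
apply_scenario <- function(model, scenario, reference = NULL) {
  assert_that(inherits(scenario, "inhibition_scenario"), "scenario must be an inhibition_scenario")
  if (is.null(reference) && scenario$kind != "knockout") {
    reference <- fba(model, parsimonious = TRUE)
  }
  switch(scenario$kind,
    pathway_fraction = inhibit_pathway(
      model, scenario$reactions, scenario$fraction,
      reference = reference
    ),
    knockout = {
      idx <- reaction_index(model, scenario$reactions)
      model$reactions$lower_bound[idx] <- 0
      model$reactions$upper_bound[idx] <- 0
      model
    },
    cofactor_drain = {
      rate <- scenario$drain_rate
      if (is.null(rate)) {
        ref_rxn <- scenario$drain_reference %||% stop_metarescue(
          "cofactor_drain needs drain_rate or drain_reference",
          "metarescue_invalid_input"
        )
        ref_flux <- reference$fluxes$flux[match(ref_rxn, reference$fluxes$reaction)]
        rate <- 0.5 * abs(ref_flux)
      }
      add_cofactor_drain(model, scenario$charged, scenario$discharged, rate)
    }
  )
}

#' Growth benefit of a supplement under an inhibition scenario
#'
#' Computes `delta_mu = mu(inhibited + supplemented) - mu(inhibited)`. A pure
#' bound relaxation can never decrease an LP optimum, so the benefit is
#' nonnegative up to solver tolerance.
#'
#' @param model The (already expression-corrected) [metabolic_model()].
#' @param scenario An [inhibition_scenario()], or `NULL` for no inhibition.
#' @param metabolite Extracellular metabolite id to supplement.
#' @param rate Supplementation rate (mmol/gDW/hr).
#' @param reference Optional reference [fba()] solution (see
#'   [apply_scenario()]).
#' @return Tibble with one row: `metabolite`, `mu_inhibited`,
#'   `mu_supplemented`, `benefit`.
#' @export
growth_benefit <- function(model, scenario, metabolite, rate = 0.1, reference = NULL) {
  inhibited <- if (is.null(scenario)) model else apply_scenario(model, scenario, reference)
  base <- fba(inhibited, parsimonious = FALSE)
  if (base$status != "optimal") {
    return(tibble(
      metabolite = metabolite, mu_inhibited = NA_real_,
      mu_supplemented = NA_real_, benefit = NA_real_
    ))
  }
  supp <- fba(supplement(inhibited, metabolite, rate), parsimonious = FALSE)
  mu_s <- if (supp$status == "optimal") supp$objective else NA_real_
  tibble(
    metabolite = metabolite,
    mu_inhibited = base$objective,
    mu_supplemented = mu_s,
    benefit = mu_s - base$objective
  )
}

#' Benefit vectors for a set of supplements under one or more scenarios
#'
#' @param model A [metabolic_model()].
#' @param scenarios A list of [inhibition_scenario()] objects (named or with
#'   ids).
#' @param supplements Character vector of extracellular metabolite ids.
#' @param rate Supplementation rate.
#' @return Tibble `scenario`, `metabolite`, `mu_inhibited`, `mu_supplemented`,
#'   `benefit`.
#' @export
benefit_table <- function(model, scenarios, supplements, rate = 0.1) {
  if (inherits(scenarios, "inhibition_scenario")) scenarios <- list(scenarios)
  reference <- fba(model, parsimonious = TRUE)
  purrr::map_dfr(scenarios, function(sc) {
    inhibited <- apply_scenario(model, sc, reference)
    base <- fba(inhibited, parsimonious = FALSE)
    purrr::map_dfr(supplements, function(met) {
      if (base$status != "optimal") {
        return(tibble(
          metabolite = met, mu_inhibited = NA_real_,
          mu_supplemented = NA_real_, benefit = NA_real_
        ))
      }
      supp <- fba(supplement(inhibited, met, rate), parsimonious = FALSE)
      mu_s <- if (supp$status == "optimal") supp$objective else NA_real_
      tibble(
        metabolite = met, mu_inhibited = base$objective,
        mu_supplemented = mu_s, benefit = mu_s - base$objective
      )
    }) |>
      dplyr::mutate(scenario = sc$id, .before = 1)
  })
}

#' Random/exhaustive single-reaction knockout null distribution
#'
#' Samples reactions (or enumerates all candidates when `n_scenarios` is
#' `NULL` or exceeds the candidate count), knocks each to zero flux and
#' computes the benefit vector of every supplement, giving a null
#' distribution of rescue patterns against which a hypothesized pathway
#' inhibition can be compared.
#'
#' @param model A [metabolic_model()].
#' @param supplements Extracellular metabolite ids.
#' @param n_scenarios Number of knockouts to sample (`NULL` = enumerate all).
#' @param seed RNG seed for sampling.
#' @param rate Supplementation rate.
#' @param candidates Candidate reaction ids; defaults to all non-exchange,
#'   non-objective reactions.
#' @return Tibble as in [benefit_table()] with scenario ids `ko_<reaction>`.
#' @export
random_inhibition_null <- function(model, supplements, n_scenarios = NULL,
                                   seed = 1, rate = 0.1, candidates = NULL) {
  if (is.null(candidates)) {
    candidates <- setdiff(
      model$reactions$id,
      c(exchange_reactions(model), objective_reaction(model))
    )
  }
  if (!is.null(n_scenarios) && n_scenarios < length(candidates)) {
    candidates <- with_seed(seed, sample(candidates, n_scenarios))
  }
  scenarios <- purrr::map(
    candidates,
    function(r) inhibition_scenario(paste0("ko_", r), "knockout", reactions = r)
  )
  benefit_table(model, scenarios, supplements, rate = rate)
}

#' Rank inhibition scenarios by agreement with experimental rescue
#'
#' Correlates (Pearson) each scenario's model-calculated benefit vector with
#' the experimentally observed supplement growth rates and ranks scenarios by
#' descending correlation. Zero-variance benefit vectors have undefined
#' correlation and rank last; ties break by scenario id.
#'
#' @param benefits Tibble from [benefit_table()] (`scenario`, `metabolite`,
#'   `benefit`).
#' @param experimental Tibble with `metabolite` and `growth_rate` (1/hr).
#' @return A `rescue_comparison` tibble: `scenario`, `correlation`,
#'   `n_supplements`, `rank`.
#' @export
rank_scenarios <- function(benefits, experimental) {
  merged <- dplyr::inner_join(benefits, experimental, by = "metabolite")
  assert_that(nrow(merged) > 0, "no shared supplements between benefits and experimental data")
  out <- merged |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      correlation = {
        b <- .data$benefit
        g <- .data$growth_rate
        ok <- is.finite(b) & is.finite(g)
        if (sum(ok) < 3 || sd(b[ok]) == 0 || sd(g[ok]) == 0) NA_real_ else cor(b[ok], g[ok])
      },
      n_supplements = sum(is.finite(.data$benefit)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$correlation)), dplyr::desc(.data$correlation), .data$scenario) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("rescue_comparison", class(out))
  out
}

#' Folate-limitation scenario set for the toy model
#'
#' The three pathway-specific folate scenarios used throughout: a fractional
#' cap on the folate-dependent thymidylate synthase step (pyrimidine branch),
#' a fractional cap on the folate-dependent AICAR transformylase step (purine
#' branch), and a folate cofactor drain. Their mean benefit per supplement is
#' the combined folate-inhibition score.
#'
#' @param fraction Fraction of optimal flux retained by the caps (default
#'   0.9).
#' @param drain_rate Enforced drain flux, or `NULL` for half the reference
#'   folate-charging flux.
#' @return Named list of [inhibition_scenario()] objects.
#' @export
folate_scenarios <- function(fraction = 0.9, drain_rate = NULL) {
  list(
    tmds = inhibition_scenario("folate_tmds", "pathway_fraction",
      reactions = "TMDS", fraction = fraction
    ),
    aicart = inhibition_scenario("folate_aicart", "pathway_fraction",
      reactions = "AICART", fraction = fraction
    ),
    drain = inhibition_scenario("folate_drain", "cofactor_drain",
      charged = "mlthf_c", discharged = "thf_c",
      drain_rate = drain_rate, drain_reference = "SHMT"
    )
  )
}

#' Experimental-style supplementation rescue pattern for the toy system
#'
#' The growth-rate pattern the wet-lab supplementation experiments show under
#' drug treatment: thymidine, IMP and serine restore growth to roughly the
#' untreated rate while uridine, AMP, glycine, aspartate and citrate leave
#' cells at the inhibited rate.
#'
#' @param rescued_rate Growth rate of rescued cultures (default 0.6 1/hr).
#' @param inhibited_rate Growth rate of non-rescued cultures (default 0.25
#'   1/hr).
#' @return Tibble `metabolite`, `growth_rate`.
#' @export
toy_rescue_pattern <- function(rescued_rate = 0.6, inhibited_rate = 0.25) {
  tibble(
    metabolite = c(
      "thymd_e", "imp_e", "ser_e",
      "urd_e", "amp_e", "gly_e", "asp_e", "cit_e"
    ),
    growth_rate = c(rep(rescued_rate, 3), rep(inhibited_rate, 5))
  )
}
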