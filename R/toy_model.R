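#' Specification for the toy folate-centric network
#'
#' The toy model is the smallest stoichiometric network that expresses the
#' qualitative distinctions the supplementation-rescue analysis relies on:
#'
#' * thymidine salvage enters pyrimidine biosynthesis *downstream* of the
#'   folate-dependent thymidylate synthase (TMDS-like) step, while uridine
#'   enters upstream of it;
#' * IMP salvage reaches both purine end products, while AMP is blocked from
#'   the guanine branch by an irreversible step and can only be incorporated
#'   through a spontaneous phosphorylation or a gene-gated (cryptic)
#'   deaminase;
#' * serine charges the folate cofactor (serine -> glycine produces
#'   5,10-methylene-THF), glycine does not;
#' * a citrate transporter is present in the network but gene-gated off under
#'   wild-type expression.
#'
#' @param glucose_uptake Maximum glucose uptake flux (mmol/gDW/hr).
#' @param supplement_rate Default in-silico supplementation rate
#'   (mmol/gDW/hr) recorded on the model for downstream convenience.
#' @param ceiling_fraction Growth ceiling as a fraction of the carbon-limited
#'   optimum (default 0.99). The biomass reaction is capped just below the
#'   carbon limit, standing in for non-carbon growth ceilings (proteome,
#'   ribosome capacity), so that nutrient supplements confer no growth
#'   benefit on unstressed cells -- matching the control observation that
#'   supplements alone do not change the wild-type growth rate.
#' @return A list of class `toy_model_spec` with the pathway maps used by
#'   [make_toy_model()]: `folate_cycle` (charging/discharging reaction ids),
#'   `branch_map` (pathway name -> reaction ids), `transporter_map`
#'   (supplement metabolite -> exchange reaction id) and `unexpressed_genes`.
#' @export
toy_model_spec <- function(glucose_uptake = 10, supplement_rate = 0.1,
                           ceiling_fraction = 0.99) {
  assert_that(is_number(glucose_uptake) && glucose_uptake > 0, "glucose_uptake must be > 0")
  assert_that(
    is_number(ceiling_fraction) && ceiling_fraction > 0 && ceiling_fraction <= 1,
    "ceiling_fraction must be in (0, 1]"
  )
  structure(
    list(
      glucose_uptake = glucose_uptake,
      supplement_rate = supplement_rate,
      ceiling_fraction = ceiling_fraction,
      folate_cycle = list(
        charging = "SHMT",
        interconversion = "MTHFC",
        discharging = c("TMDS", "AICART"),
        regeneration = "DHFR",
        charged = "mlthf_c",
        discharged = "thf_c"
      ),
      branch_map = list(
        purine = c("PURSYN", "AICART", "ADSS", "IMPDH"),
        pyrimidine = c("PYRSYN", "RNR", "TMDS"),
        serine_glycine = c("SERSYN", "SHMT")
      ),
      transporter_map = c(
        thymidine = "EX_thymd_e",
        uridine = "EX_urd_e",
        imp = "EX_imp_e",
        amp = "EX_amp_e",
        serine = "EX_ser_e",
        glycine = "EX_gly_e",
        aspartate = "EX_asp_e",
        citrate = "EX_cit_e"
      ),
      unexpressed_genes = c("citT", "adeD")
    ),
    class = "toy_model_spec"
  )
}

toy_reaction <- function(id, stoich, lb = 0, ub = 1000, gene = "", spont = FALSE, obj = 0) {
  tibble(
    id = id, name = id, lower_bound = lb, upper_bound = ub,
    gene_rule = gene, spontaneous = spont, objective_coefficient = obj,
    stoichiometry = list(stoich)
  )
}

#' Build the toy folate-centric metabolic model
#'
#' Constructs a ~30-reaction network around a single carbon currency
#' (`cmet_c`) with a catalytic folate cycle (THF / 5,10-methylene-THF /
#' 10-formyl-THF / DHF), pyrimidine and purine biosynthesis, protein
#' synthesis, and salvage transporters for the eight supplements studied by
#' the rescue analysis. Biomass consumes dTMP, adenine and guanine
#' nucleotide pools, protein and glycine with unit coefficients, so only
#' relative growth-rate changes are meaningful.
#'
#' @param spec A [toy_model_spec()].
#' @return A [metabolic_model()] whose baseline FBA optimum is positive.
#' @examples
#' model <- make_toy_model()
#' fba(model)$objective
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  assert_that(inherits(spec, "toy_model_spec"), "spec must be a toy_model_spec")
  mets_c <- c(
    "glc_c", "cmet_c", "ser_c", "gly_c", "thf_c", "dhf_c", "mlthf_c", "fthf_c",
    "ump_c", "dump_c", "dtmp_c", "urd_c", "thymd_c", "aicar_c", "imp_c",
    "amp_c", "ade_c", "gua_c", "asp_c", "cit_c", "prot_c"
  )
  mets_e <- c(
    "glc_e", "ser_e", "gly_e", "urd_e", "thymd_e", "imp_e", "amp_e",
    "asp_e", "cit_e"
  )
  metabolites <- tibble(
    id = c(mets_c, mets_e),
    compartment = c(rep("c", length(mets_c)), rep("e", length(mets_e)))
  )

  ex <- function(met, lb = 0) {
    id <- paste0("EX_", met)
    toy_reaction(id, setNames(-1, met), lb = lb, ub = 1000)
  }
  transport <- function(id, met_e, met_c, gene = "") {
    toy_reaction(id, setNames(c(-1, 1), c(met_e, met_c)),
      lb = -1000, ub = 1000, gene = gene
    )
  }

  reactions <- dplyr::bind_rows(
    # exchanges: uptake closed except glucose; secretion open
    ex("glc_e", lb = -spec$glucose_uptake),
    ex("ser_e"), ex("gly_e"), ex("urd_e"), ex("thymd_e"),
    ex("imp_e"), ex("amp_e"), ex("asp_e"), ex("cit_e"),
    # transporters
    transport("GLCt", "glc_e", "glc_c", gene = "g_glct"),
    transport("SERt", "ser_e", "ser_c", gene = "g_sert"),
    transport("GLYt", "gly_e", "gly_c", gene = "g_glyt"),
    transport("URDt", "urd_e", "urd_c", gene = "g_urdt"),
    transport("THMDt", "thymd_e", "thymd_c", gene = "g_thmdt"),
    transport("IMPt", "imp_e", "imp_c", gene = "g_impt"),
    transport("AMPt", "amp_e", "amp_c", gene = "g_ampt"),
    transport("ASPt", "asp_e", "asp_c", gene = "g_aspt"),
    transport("CITt", "cit_e", "cit_c", gene = "citT"),
    # central carbon
    toy_reaction("GLYC", c(glc_c = -1, cmet_c = 2), gene = "g_glyc"),
    toy_reaction("CITL", c(cit_c = -1, cmet_c = 1), gene = "g_citl"),
    toy_reaction("SERSYN", c(cmet_c = -1, ser_c = 1), gene = "g_sersyn"),
    toy_reaction("ASPSYN", c(cmet_c = -1, asp_c = 1), gene = "g_aspsyn"),
    # folate cycle (catalytic: no net folate production or consumption)
    toy_reaction("SHMT", c(ser_c = -1, thf_c = -1, gly_c = 1, mlthf_c = 1), gene = "g_shmt"),
    toy_reaction("MTHFC", c(mlthf_c = -1, fthf_c = 1), gene = "g_mthfc"),
    toy_reaction("DHFR", c(dhf_c = -1, thf_c = 1), gene = "g_dhfr"),
    # pyrimidine branch
    toy_reaction("PYRSYN", c(cmet_c = -1, asp_c = -1, ump_c = 1), gene = "g_pyrsyn"),
    toy_reaction("RNR", c(ump_c = -1, dump_c = 1), gene = "g_rnr"),
    toy_reaction("TMDS", c(dump_c = -1, mlthf_c = -1, dtmp_c = 1, dhf_c = 1), gene = "g_tmds"),
    toy_reaction("URDK", c(urd_c = -1, ump_c = 1), gene = "g_urdk"),
    toy_reaction("TMDK", c(thymd_c = -1, dtmp_c = 1), gene = "g_tmdk"),
    # purine branch
    toy_reaction("PURSYN", c(cmet_c = -1, aicar_c = 1), gene = "g_pursyn"),
    toy_reaction("AICART", c(aicar_c = -1, fthf_c = -1, imp_c = 1, thf_c = 1), gene = "g_aicart"),
    toy_reaction("ADSS", c(imp_c = -1, ade_c = 1), gene = "g_adss"),
    toy_reaction("IMPDH", c(imp_c = -1, gua_c = 1), gene = "g_impdh"),
    toy_reaction("AMPD", c(amp_c = -1, imp_c = 1), gene = "adeD"),
    toy_reaction("AMPK", c(amp_c = -1, ade_c = 1), spont = TRUE),
    # protein and biomass
    toy_reaction("PROTSYN", c(cmet_c = -1, ser_c = -1, prot_c = 1), gene = "g_protsyn"),
    toy_reaction("BIOMASS",
      c(dtmp_c = -1, ade_c = -1, gua_c = -1, prot_c = -1, gly_c = -1),
      obj = 1
    )
  )

  model <- metabolic_model(metabolites, reactions, id = "toy_folate")
  # structural sanity demanded of the generator: every supplement exchange in
  # the transporter map must exist in the model
  missing <- setdiff(unname(spec$transporter_map), model$reactions$id)
  if (length(missing) > 0) {
    stop_metarescue(
      paste0("supplement without incorporation path: ", paste(missing, collapse = ", ")),
      "metarescue_model_invalid"
    )
  }
  # growth ceiling: cap biomass just below the carbon-limited optimum (see
  # toy_model_spec); supplements then benefit only inhibited models
  if (spec$ceiling_fraction < 1) {
    mu_carbon <- fba(model, parsimonious = FALSE)$objective
    model <- set_bounds(model, "BIOMASS", upper = spec$ceiling_fraction * mu_carbon)
  }
  attr(model, "spec") <- spec
  model
}

#' Tabulate producers and consumers of each internal metabolite
#'
#' Convenience check of stoichiometric consistency for generated models:
#' every internal (cytosolic) metabolite should have at least one producing
#' and one consuming reaction (reversible reactions count as both).
#'
#' @param model A [metabolic_model()].
#' @return Tibble with columns `metabolite`, `n_producers`, `n_consumers`.
#' @export
metabolite_connectivity <- function(model) {
  S <- stoich_matrix(model)
  rev <- model$reactions$lower_bound < 0 & model$reactions$upper_bound > 0
  internal <- model$metabolites$id[model$metabolites$compartment != "e"]
  purrr::map_dfr(internal, function(m) {
    row <- S[m, ]
    tibble(
      metabolite = m,
      n_producers = sum(row > 0 | (row != 0 & rev)),
      n_consumers = sum(row < 0 | (row != 0 & rev))
    )
  })
}
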