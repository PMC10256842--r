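# Constraint-based rescue analysis: model IO, FBA, perturbations, benefits.

test_that("model JSON round-trips and validation errors are specific", {
  m <- make_toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$gene_rule, m$reactions$gene_rule)
  expect_equal(
    fba(m2, parsimonious = FALSE)$objective,
    fba(m, parsimonious = FALSE)$objective,
    tolerance = 1e-10
  )

  bad <- m
  bad$reactions$lower_bound[3] <- bad$reactions$upper_bound[3] + 1
  expect_error(validate_bad <- metabolic_model(bad$metabolites, bad$reactions),
    class = "metarescue_model_bounds"
  )
  dangling <- m$reactions
  dangling$stoichiometry[[1]] <- c(ghost_c = -1)
  expect_error(metabolic_model(m$metabolites, dangling),
    class = "metarescue_model_dangling"
  )
})

test_that("FBA solves a closed-form linear chain and respects mass balance", {
  mets <- tibble::tibble(id = c("a_e", "a_c"), compartment = c("e", "c"))
  rx <- dplyr::bind_rows(
    tibble::tibble(
      id = "EX_a", lower_bound = -10, upper_bound = 1000,
      stoichiometry = list(c(a_e = -1))
    ),
    tibble::tibble(
      id = "At", lower_bound = -1000, upper_bound = 1000,
      stoichiometry = list(c(a_e = -1, a_c = 1))
    ),
    tibble::tibble(
      id = "BIO", lower_bound = 0, upper_bound = 1000,
      objective_coefficient = 1, stoichiometry = list(c(a_c = -10))
    )
  )
  chain <- metabolic_model(mets, rx, id = "chain")
  sol <- fba(chain)
  expect_equal(sol$objective, 1) # uptake 10, yield 0.1 per unit

  m <- make_toy_model()
  sol2 <- fba(m)
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% sol2$fluxes$flux)), 1e-9)
  expect_true(all(sol2$fluxes$flux >= m$reactions$lower_bound - 1e-9))
  expect_true(all(sol2$fluxes$flux <= m$reactions$upper_bound + 1e-9))
})

test_that("FBA equals the independently formulated HiGHS oracle", {
  m <- toy_wt_model()
  instances <- list(
    base = m,
    tmds_cap = inhibit_pathway(m, "TMDS", 0.9),
    drained = add_cofactor_drain(m, "mlthf_c", "thf_c", 3.3),
    supplemented = supplement(inhibit_pathway(m, "AICART", 0.9), "imp_e"),
    ko = set_bounds(m, "RNR", lower = 0, upper = 0)
  )
  for (inst in instances) {
    mine <- fba(inst, parsimonious = FALSE)$objective
    orc <- oracle_fba_mu(inst)
    expect_equal(mine, orc, tolerance = 1e-8)
  }
})

test_that("gene rules gate reactions with and/or semantics", {
  m <- make_toy_model()
  m$reactions$gene_rule[m$reactions$id == "GLYC"] <- "gA and gB"
  off <- apply_expression_shutoff(m, "gA",
    scope = "neighborhood",
    supplement_metabolites = "glc_c", k = 1
  )
  i <- which(off$reactions$id == "GLYC")
  expect_equal(off$reactions$upper_bound[i], 0)

  m$reactions$gene_rule[m$reactions$id == "GLYC"] <- "gA or gB"
  on <- apply_expression_shutoff(m, "gA",
    scope = "neighborhood",
    supplement_metabolites = "glc_c", k = 1
  )
  expect_gt(on$reactions$upper_bound[which(on$reactions$id == "GLYC")], 0)

  m$reactions$gene_rule[m$reactions$id == "GLYC"] <- "gA andnot ((gB"
  expect_error(
    apply_expression_shutoff(m, "gA", scope = "global"),
    class = "metarescue_gpr_parse"
  )
})

test_that("citrate rescue disappears when its transporter is unexpressed", {
  m <- make_toy_model() # citT still expressed here
  drain <- folate_scenarios()$drain
  pre <- growth_benefit(m, drain, "cit_e")
  expect_gt(pre$benefit, 0)
  off <- apply_expression_shutoff(m, "citT", scope = "global")
  post <- growth_benefit(off, drain, "cit_e")
  expect_equal(post$benefit, 0, tolerance = 1e-9)
})

test_that("fractional pathway caps scale growth as designed", {
  m <- toy_wt_model()
  mu_star <- fba(m, parsimonious = FALSE)$objective

  same <- inhibit_pathway(m, "TMDS", 1)
  expect_equal(fba(same, parsimonious = FALSE)$objective, mu_star, tolerance = 1e-9)

  capped <- inhibit_pathway(m, "TMDS", 0.9)
  expect_equal(fba(capped, parsimonious = FALSE)$objective, 0.9 * mu_star,
    tolerance = 1e-8
  )

  # SHMT is the only folate-charging reaction; closing it abolishes growth
  dead <- inhibit_pathway(m, "SHMT", 0)
  expect_equal(fba(dead, parsimonious = FALSE)$objective, 0, tolerance = 1e-9)
})

test_that("cofactor drain behaves across its operating range", {
  m <- toy_wt_model()
  mu_star <- fba(m, parsimonious = FALSE)$objective

  none <- add_cofactor_drain(m, "mlthf_c", "thf_c", 0)
  expect_equal(fba(none, parsimonious = FALSE)$objective, mu_star, tolerance = 1e-9)

  # drains above the total charging capacity are infeasible; locate the
  # breakpoint by bisection and compare against the capacity implied by the
  # carbon budget (uptake * 2 cmet per glucose)
  feasible_at <- function(d) {
    fba(add_cofactor_drain(m, "mlthf_c", "thf_c", d), parsimonious = FALSE)$status == "optimal"
  }
  lo <- 0
  hi <- 40
  expect_true(feasible_at(lo))
  expect_false(feasible_at(hi))
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (feasible_at(mid)) lo <- mid else hi <- mid
  }
  expect_equal(lo, 20, tolerance = 1e-3) # all 20 cmet into serine -> charges

  drained <- add_cofactor_drain(m, "mlthf_c", "thf_c", 3.3)
  mu_d <- fba(drained, parsimonious = FALSE)$objective
  expect_lt(mu_d, mu_star)
  ser <- fba(supplement(drained, "ser_e", 0.1), parsimonious = FALSE)$objective
  expect_gt(ser, mu_d)

  expect_error(add_cofactor_drain(m, "nope_c", "thf_c", 1),
    class = "metarescue_unknown_metabolite"
  )
})

test_that("supplementation opens uptake without side effects", {
  m <- toy_wt_model()
  mu_star <- fba(m, parsimonious = FALSE)$objective

  # rate 0 leaves growth unchanged; reverting the bound restores the model
  expect_equal(fba(supplement(m, "thymd_e", 0), parsimonious = FALSE)$objective,
    mu_star,
    tolerance = 1e-9
  )
  supped <- supplement(m, "thymd_e", 0.1)
  reverted <- set_bounds(supped, "EX_thymd_e", lower = 0)
  expect_equal(reverted$reactions, m$reactions)

  # thymidine salvage bypasses the folate-dependent step entirely: with a
  # generous supplement the capped model returns to the uninhibited optimum
  capped <- inhibit_pathway(m, "TMDS", 0.9)
  full <- fba(supplement(capped, "thymd_e", 0.5), parsimonious = FALSE)$objective
  expect_equal(full, mu_star, tolerance = 1e-8)
  # at the standard 0.1 rate the rescue is supplement-limited
  partial <- fba(supplement(capped, "thymd_e", 0.1), parsimonious = FALSE)$objective
  expect_equal(partial, 0.9 * mu_star + 0.1, tolerance = 1e-8)

  expect_error(supplement(m, "missing_e"), class = "metarescue_unknown_metabolite")
})

test_that("supplements are pure relaxations: growth never decreases", {
  m <- toy_wt_model()
  scenarios <- c(list(NULL), folate_scenarios())
  for (sc in scenarios) {
    inhibited <- if (is.null(sc)) m else apply_scenario(m, sc)
    mu0 <- fba(inhibited, parsimonious = FALSE)$objective
    for (met in toy_rescue_pattern()$metabolite) {
      mu1 <- fba(supplement(inhibited, met, 0.1), parsimonious = FALSE)$objective
      expect_gte(mu1, mu0 - 1e-9)
    }
  }
})

test_that("the designed rescue distinctions hold on the corrected model", {
  m <- toy_wt_model()
  scen <- folate_scenarios()
  supps <- toy_rescue_pattern()$metabolite
  bt <- benefit_table(m, scen, supps)

  b <- function(s, met) bt$benefit[bt$scenario == s & bt$metabolite == met]
  # thymidine enters below the folate step, uridine above it
  expect_gt(b("folate_tmds", "thymd_e"), 0)
  expect_equal(b("folate_tmds", "urd_e"), 0, tolerance = 1e-9)
  # IMP reaches both purine branches, AMP neither after shutoffs
  expect_gt(b("folate_aicart", "imp_e"), b("folate_aicart", "amp_e"))
  expect_equal(b("folate_aicart", "amp_e"), 0, tolerance = 1e-9)
  # serine charges the cofactor, glycine does not
  expect_gt(b("folate_drain", "ser_e"), b("folate_drain", "gly_e"))

  # without expression correction AMP rescues through the deaminase
  uncorrected <- make_toy_model()
  bt0 <- benefit_table(uncorrected, scen["aicart"], c("imp_e", "amp_e"))
  expect_gt(bt0$benefit[bt0$metabolite == "amp_e"], 0)

  # removing the thymidine transport path nulls its rescue
  no_thy <- remove_reaction(m, "THMDt")
  g <- growth_benefit(no_thy, scen$tmds, "thymd_e")
  expect_equal(g$benefit, 0, tolerance = 1e-9)
})

test_that("knockout null enumeration is deterministic and sane", {
  m <- toy_wt_model()
  supps <- c("thymd_e", "imp_e", "ser_e")
  a <- random_inhibition_null(m, supps, n_scenarios = 5, seed = 7)
  b <- random_inhibition_null(m, supps, n_scenarios = 5, seed = 7)
  expect_identical(a, b)
  expect_equal(length(unique(a$scenario)), 5)

  # a knockout of an always-zero-flux reaction reproduces baseline benefits
  blocked <- random_inhibition_null(m, supps, candidates = "AMPD")
  base <- benefit_table(
    m, inhibition_scenario("noop", "pathway_fraction", "TMDS", fraction = 1),
    supps
  )
  expect_equal(blocked$benefit, base$benefit, tolerance = 1e-9)
})

test_that("scenario ranking is correlation-ordered with stable degeneracies", {
  bench <- tibble::tibble(
    scenario = rep(c("s_prop", "s_anti", "s_flat"), each = 3),
    metabolite = rep(c("m1", "m2", "m3"), 3),
    benefit = c(1, 2, 3, 3, 2, 1, 1, 1, 1)
  )
  exp_rates <- tibble::tibble(metabolite = c("m1", "m2", "m3"), growth_rate = c(0.1, 0.2, 0.3))
  rk <- rank_scenarios(bench, exp_rates)
  expect_equal(rk$correlation[rk$scenario == "s_prop"], 1)
  expect_equal(rk$correlation[rk$scenario == "s_anti"], -1)
  expect_true(is.na(rk$correlation[rk$scenario == "s_flat"]))
  expect_equal(rk$scenario[rk$rank == max(rk$rank)], "s_flat")

  # positive rescaling of a benefit vector changes nothing
  scaled <- bench
  scaled$benefit[scaled$scenario == "s_prop"] <- scaled$benefit[scaled$scenario == "s_prop"] * 17
  expect_equal(rank_scenarios(scaled, exp_rates)$rank, rk$rank)
})
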