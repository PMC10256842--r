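# Synthetic-data generators: structural soundness and seeded determinism.

test_that("toy model is feasible, consistent, and starves without carbon", {
  m <- make_toy_model()
  expect_gt(fba(m, parsimonious = FALSE)$objective, 0)

  # every internal metabolite has at least one producer and one consumer
  conn <- metabolite_connectivity(m)
  expect_true(all(conn$n_producers >= 1))
  expect_true(all(conn$n_consumers >= 1))

  # every supplement in the transporter map has an incorporation path
  spec <- attr(m, "spec")
  expect_true(all(unname(spec$transporter_map) %in% m$reactions$id))

  # closing all uptakes abolishes growth
  closed <- m
  for (ex in exchange_reactions(m)) closed <- set_bounds(closed, ex, lower = 0)
  expect_equal(fba(closed, parsimonious = FALSE)$objective, 0, tolerance = 1e-9)
})

test_that("metabolomics generator reproduces exact fold changes without noise", {
  cfg <- synth_config(
    seed = 11, noise_sd = 0, effect_size = 2, class_labels = "antifolate",
    n_metabolites = 8, drugs_per_class = 1, n_replicates = 2
  )
  sig <- list(antifolate = c(C00003 = 2))
  tab <- simulate_metabolomics(cfg, signature_map = sig)
  ratios <- tab |>
    dplyr::filter(.data$metabolite == "C00003", .data$time_point > 0) |>
    dplyr::group_by(.data$time_point) |>
    dplyr::summarise(
      ratio = mean(.data$intensity[.data$condition == "antifolate"]) /
        mean(.data$intensity[.data$condition == "control"])
    )
  expect_equal(ratios$ratio, rep(4, nrow(ratios)), tolerance = 1e-12)

  # unperturbed metabolites are unchanged
  other <- tab |>
    dplyr::filter(.data$metabolite != "C00003", .data$time_point > 0) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      ratio = mean(.data$intensity[.data$condition == "antifolate"]) /
        mean(.data$intensity[.data$condition == "control"])
    )
  expect_equal(other$ratio, rep(1, nrow(other)), tolerance = 1e-12)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 5, n_metabolites = 12)
  expect_identical(simulate_metabolomics(cfg), simulate_metabolomics(cfg))
  expect_identical(
    simulate_growth_curve(noise_sd = 0.02, seed = 9),
    simulate_growth_curve(noise_sd = 0.02, seed = 9)
  )
  expect_identical(
    simulate_cell_lengths(seed = 4),
    simulate_cell_lengths(seed = 4)
  )
  s1 <- simulate_structures(seed = 3)
  s2 <- simulate_structures(seed = 3)
  expect_identical(s1$properties, s2$properties)
  expect_identical(s1$pockets, s2$pockets)
})

test_that("empty class set is rejected", {
  expect_error(synth_config(class_labels = character(0)), "class")
})

test_that("growth-curve generator spans 15 h on a 30-min grid and honors K", {
  gc <- simulate_growth_curve(r = 0.6, lag = 2, K = 1)
  expect_equal(nrow(gc), 31)
  expect_equal(range(gc$time), c(0, 15))
  flat <- simulate_growth_curve(r = 0.5, lag = 1, K = 0.02, od0 = 0.02)
  expect_equal(flat$od, rep(0.02, nrow(flat)))
  expect_error(simulate_growth_curve(r = 0.5, K = 0.01, od0 = 0.02), "initial OD")
})

test_that("dose-response signal rises from floor to top with concentration", {
  dr <- simulate_dose_response(ic50 = 40, hill = 1, top_signal = 1e6, floor_signal = 1e5)
  expect_equal(dr$signal[dr$concentration == 0], 1e5)
  expect_true(all(diff(dr$signal[order(dr$concentration)]) >= 0))
  # midpoint identity at c = ic50 for hill = 1
  mid <- simulate_dose_response(
    ic50 = 40, hill = 1, top_signal = 1e6, floor_signal = 1e5,
    concentrations = c(0, 40)
  )
  expect_equal(mid$signal[mid$concentration == 40], (1e6 + 1e5) / 2)
  # saturation towards the no-reaction signal
  sat <- simulate_dose_response(
    ic50 = 1, top_signal = 1e6, floor_signal = 1e5,
    concentrations = c(0, 1e6)
  )
  expect_equal(sat$signal[2], 1e6, tolerance = 1e-4)
  expect_error(
    simulate_dose_response(top_signal = 1, floor_signal = 2),
    "floor_signal"
  )
})

test_that("cell-length samples honor medians and the resolution floor", {
  cl <- simulate_cell_lengths(median_a = 1.06, median_b = 2.41, n = 500, seed = 8)
  expect_gte(min(cl$length), 0.5)
  meds <- tapply(cl$length, cl$condition, median)
  expect_equal(unname(meds["control"]), 1.06, tolerance = 0.12)
  expect_equal(unname(meds["treated"]), 2.41, tolerance = 0.25)
})

test_that("structure generator marks the related group as reference-like", {
  st <- simulate_structures(related_group = c("ref", "folK_like"), overlap = 0.8, seed = 2)
  expect_equal(dplyr::count(st$pockets, .data$protein)$n, rep(5, 12))
  rk <- rank_candidates(st$pockets, "ref")
  expect_equal(rk$protein[1], "folK_like")
  expect_error(simulate_structures(n_proteins = 1), "n_proteins")
})
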