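#' Simulate a bacterial growth curve
#'
#' OD600 readings on a 30-minute grid over 15 hours from a three-parameter
#' logistic whose inflection point is placed so that the tangent-intercept
#' lag equals `lag`, plus optional additive Gaussian noise.
#'
#' @param r Maximum specific growth rate (1/hr), > 0.
#' @param lag Lag time (hr), tangent-intercept definition.
#' @param K Carrying capacity (OD600). `K == od0` gives a flat curve.
#' @param noise_sd Additive Gaussian noise on OD (absolute units).
#' @param seed RNG seed.
#' @param od0 Initial OD level anchoring the lag definition.
#' @param interval Sampling interval (hr).
#' @param duration Total duration (hr).
#' @return Tibble `time`, `od`.
#' @examples
#' gc <- simulate_growth_curve(r = 0.6, lag = 2, K = 1)
#' fit_logistic_growth(gc)$r
#' @export
simulate_growth_curve <- function(r = 0.6, lag = 2, K = 1, noise_sd = 0,
                                  seed = 1, od0 = 0.02, interval = 0.5,
                                  duration = 15) {
  assert_that(is_number(r) && r > 0, "r must be > 0")
  assert_that(is_number(K) && K >= od0, "K must be >= initial OD")
  assert_that(interval > 0 && duration > 0, "time grid must be increasing")
  time <- seq(0, duration, by = interval)
  if (K <= od0) {
    od <- rep(K, length(time))
  } else {
    tm <- lag + 4 * (K / 2 - od0) / (r * K)
    od <- K / (1 + exp(-r * (time - tm)))
  }
  if (noise_sd > 0) {
    od <- with_seed(seed, pmax(od + rnorm(length(od), 0, noise_sd), 0))
  }
  tibble(time = time, od = od)
}

#' Simulate a chemiluminescence dose-response readout
#'
#' In an ATP-consumption assay, inhibiting the enzyme preserves ATP, so the
#' luminescence signal *rises* with inhibitor concentration: from
#' `floor_signal` (no inhibitor, full reaction) towards `top_signal`
#' (complete inhibition, matching the no-reaction control).
#'
#' @param ic50 Half-maximal inhibitor concentration (same units as
#'   `concentrations`), > 0.
#' @param hill Hill slope of the transition.
#' @param top_signal Signal with no enzymatic reaction (ATP intact).
#' @param floor_signal Signal at zero inhibitor (full reaction); must be
#'   below `top_signal`.
#' @param concentrations Inhibitor concentrations; must include 0.
#' @param noise_sd Additive Gaussian noise on the signal.
#' @param seed RNG seed.
#' @return Tibble `concentration`, `signal`, with the two reference signals
#'   attached as attributes `zero_inhibitor_signal` and `no_reaction_signal`.
#' @examples
#' dr <- simulate_dose_response(ic50 = 40)
#' fit_ic50(dr)$ic50
#' @export
simulate_dose_response <- function(ic50 = 40, hill = 1,
                                   top_signal = 1e6, floor_signal = 1e5,
                                   concentrations = c(0, 2.5, 5, 10, 20, 40, 80, 160, 320),
                                   noise_sd = 0, seed = 1) {
  assert_that(is_number(ic50) && ic50 > 0, "ic50 must be > 0")
  assert_that(0 %in% concentrations, "concentrations must include 0")
  if (floor_signal >= top_signal) {
    stop_metarescue("floor_signal must be below top_signal", "metarescue_invalid_input")
  }
  frac <- ifelse(
    concentrations == 0, 0,
    concentrations^hill / (ic50^hill + concentrations^hill)
  )
  signal <- floor_signal + (top_signal - floor_signal) * frac
  if (noise_sd > 0) {
    signal <- with_seed(seed, signal + rnorm(length(signal), 0, noise_sd))
  }
  out <- tibble(concentration = concentrations, signal = signal)
  attr(out, "zero_inhibitor_signal") <- floor_signal
  attr(out, "no_reaction_signal") <- top_signal
  out
}

#' Simulate single-cell length samples for two conditions
#'
#' Log-normal cell-length distributions with specified medians, floored at a
#' minimum measurable length (microscopy resolution limit). Defaults mirror
#' typical rod-shaped bacteria: untreated cells around 1 micron median and a
#' filamentous treated population with doubled median.
#'
#' @param median_a,median_b Medians (micrometers) of the two samples, > 0.
#' @param n Cells per sample (>= 300 recommended for the rank test).
#' @param sdlog Log-scale standard deviation of the underlying log-normal.
#' @param min_length Lower floor (micrometers).
#' @param seed RNG seed.
#' @param labels Condition labels for the two samples.
#' @return Tibble `condition`, `length`.
#' @export
simulate_cell_lengths <- function(median_a = 1.06, median_b = 2.41, n = 300,
                                  sdlog = 0.35, min_length = 0.5, seed = 1,
                                  labels = c("control", "treated")) {
  assert_that(median_a > 0 && median_b > 0, "medians must be > 0")
  assert_that(is_count(n), "n must be a positive integer")
  with_seed(seed, {
    a <- pmax(stats::rlnorm(n, log(median_a), sdlog), min_length)
    b <- pmax(stats::rlnorm(n, log(median_b), sdlog), min_length)
    tibble(
      condition = rep(labels, each = n),
      length = c(a, b)
    )
  })
}

#' Simulate protein structural-property and binding-pocket tables
#'
#' Emulates the two structural inputs of the candidate-ranking stage: a
#' global structural-property matrix (per-protein numeric features) and
#' binding-pocket bit-set fingerprints (five pockets per protein, sorted by
#' size). Proteins in `related_group` share an elevated fraction of the
#' reference protein's largest-pocket bits, so they rank above the unrelated
#' background.
#'
#' @param n_proteins Number of proteins (>= 2), including the reference.
#' @param n_properties Number of global structural properties.
#' @param pocket_universe_bits Size of the interaction-feature bit universe.
#' @param related_group Character vector of protein ids sharing pocket
#'   structure with the reference; must be a subset of the generated ids
#'   (`"ref"`, `"folK_like"`, `"prot03"`, ... by default).
#' @param overlap Fraction of reference pocket bits shared by related
#'   proteins.
#' @param seed RNG seed.
#' @param pockets_per_protein Pockets carried by each protein.
#' @param bits_per_pocket Bits set per pocket fingerprint.
#' @return List with `properties` (tibble `protein`, `prop_*`) and `pockets`
#'   (tibble `protein`, `pocket`, `size`, `bits` list-column of sorted bit
#'   indices).
#' @export
simulate_structures <- function(n_proteins = 12, n_properties = 8,
                                pocket_universe_bits = 256,
                                related_group = c("ref", "folK_like"),
                                overlap = 0.8, seed = 1,
                                pockets_per_protein = 5,
                                bits_per_pocket = 40) {
  assert_that(n_proteins >= 2, "n_proteins must be >= 2")
  proteins <- c("ref", "folK_like", sprintf("prot%02d", seq_len(max(n_proteins - 2, 0))))
  proteins <- proteins[seq_len(n_proteins)]
  assert_that(
    all(related_group %in% proteins),
    "related_group must be a subset of the generated protein ids"
  )
  with_seed(seed, {
    props <- matrix(rnorm(n_proteins * n_properties), nrow = n_proteins)
    ref_row <- props[1, ]
    for (p in setdiff(related_group, "ref")) {
      i <- match(p, proteins)
      props[i, ] <- 0.7 * ref_row + 0.3 * props[i, ]
    }
    properties <- dplyr::bind_cols(
      tibble(protein = proteins),
      as_tibble(setNames(
        as.data.frame(props),
        sprintf("prop_%02d", seq_len(n_properties))
      ))
    )
    ref_bits <- sort(sample(pocket_universe_bits, bits_per_pocket))
    pockets <- purrr::map_dfr(proteins, function(p) {
      sizes <- sort(round(runif(pockets_per_protein, 50, 400)), decreasing = TRUE)
      bits <- purrr::map(seq_len(pockets_per_protein), function(k) {
        if (p == "ref" && k == 1) {
          return(ref_bits)
        }
        if (p %in% related_group && k == 1) {
          n_shared <- round(overlap * bits_per_pocket)
          shared <- sample(ref_bits, n_shared)
          rest <- sample(setdiff(seq_len(pocket_universe_bits), ref_bits), bits_per_pocket - n_shared)
          return(sort(c(shared, rest)))
        }
        sort(sample(pocket_universe_bits, bits_per_pocket))
      })
      tibble(
        protein = p,
        pocket = sprintf("%s_pk%d", p, seq_len(pockets_per_protein)),
        size = sizes,
        bits = bits
      )
    })
    list(properties = properties, pockets = pockets)
  })
}
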