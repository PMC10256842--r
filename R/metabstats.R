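#' Log2 fold change between replicate groups
#'
#' Ratio of arithmetic replicate means on the raw intensity scale, reported
#' in log2 (configurable base). A pseudocount stabilizes ratios when either
#' mean can be zero; with the default pseudocount of 0 a zero denominator is
#' an error, and a sensible choice is half the smallest positive intensity
#' in the dataset.
#'
#' @param treated,control Numeric vectors of replicate intensities (>= 1
#'   value each).
#' @param pseudocount Nonnegative value added to both means.
#' @param base Logarithm base (default 2).
#' @return A single log fold-change value.
#' @examples
#' log_fold_change(c(4, 4), c(1, 1)) # = 2
#' @export
log_fold_change <- function(treated, control, pseudocount = 0, base = 2) {
  assert_that(length(treated) >= 1 && length(control) >= 1, "need >= 1 replicate per group")
  assert_that(is_number(pseudocount) && pseudocount >= 0, "pseudocount must be >= 0")
  num <- mean(treated) + pseudocount
  den <- mean(control) + pseudocount
  if (den == 0 || num == 0) {
    stop_metarescue(
      "zero group mean with pseudocount 0: fold change undefined",
      "metarescue_undefined_ratio"
    )
  }
  log(num / den, base = base)
}

#' One-sided Mann-Whitney rank test
#'
#' Exact p-value by full enumeration of rank arrangements (ties handled via
#' midranks) when the pooled sample size is at most `exact_limit`, and a
#' tie-corrected normal approximation otherwise. The statistic is the
#' Mann-Whitney U of `x` relative to `y`; `alternative = "greater"` asks
#' whether `x` tends to exceed `y`.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative `"greater"` or `"less"`.
#' @param exact_limit Pooled size up to which exact enumeration is used
#'   (default 12).
#' @return Tibble with `statistic` (U), `p_value`, `method`.
#' @examples
#' mann_whitney_one_sided(c(5, 6, 7), c(1, 2, 3), "greater") # U = 9, p = 0.05
#' @export
mann_whitney_one_sided <- function(x, y, alternative = c("greater", "less"),
                                   exact_limit = 12) {
  alternative <- match.arg(alternative)
  assert_that(length(x) >= 1 && length(y) >= 1, "empty sample")
  n <- length(x)
  m <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= exact_limit) {
    sel <- combn(n + m, n)
    u_all <- colSums(matrix(ranks[sel], nrow = n)) - n * (n + 1) / 2
    p <- if (alternative == "greater") {
      mean(u_all >= u_obs - 1e-9)
    } else {
      mean(u_all <= u_obs + 1e-9)
    }
    method <- "exact enumeration"
  } else {
    mu <- n * m / 2
    tie_tab <- table(ranks)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1))
    sigma <- sqrt(n * m / 12 * ((n + m + 1) - tie_term))
    # continuity-corrected z; U is supported on a half-integer lattice
    p <- if (alternative == "greater") {
      stats::pnorm((u_obs - mu - 0.5) / sigma, lower.tail = FALSE)
    } else {
      stats::pnorm((u_obs - mu + 0.5) / sigma, lower.tail = TRUE)
    }
    method <- "normal approximation, tie-corrected"
  }
  tibble(statistic = u_obs, p_value = max(p, .Machine$double.xmin), method = method)
}

#' Differential abundance table for a condition contrast
#'
#' For each metabolite and time point, computes the log2 fold change of
#' treated over control replicate means and a one-sided Mann-Whitney
#' p-value. By default the tested direction follows the observed median
#' difference (accumulation vs depletion) and is recorded per row;
#' significance stars use the `p <= 0.05 / 0.001 / 0.0001` convention.
#'
#' @param abundance Long abundance table (see [simulate_metabolomics()]).
#' @param contrast Length-2 character vector `c(treated, control)` of
#'   condition labels.
#' @param pseudocount Passed to [log_fold_change()].
#' @param alternative `"auto"` (direction of the observed median
#'   difference), `"greater"` or `"less"`.
#' @param time_points Time points to test (default: all shared).
#' @return Tibble `metabolite`, `time_point`, `log_fold_change`, `direction`,
#'   `statistic`, `p_value`, `stars`.
#' @export
differential_table <- function(abundance, contrast, pseudocount = 0,
                               alternative = "auto", time_points = NULL) {
  assert_that(length(contrast) == 2, "contrast must name two conditions")
  missing <- setdiff(contrast, unique(abundance$condition))
  if (length(missing) > 0) {
    stop_metarescue(
      paste0("condition(s) absent from table: ", paste(missing, collapse = ", ")),
      "metarescue_missing_condition"
    )
  }
  dat <- abundance |> dplyr::filter(.data$condition %in% contrast)
  if (is.null(time_points)) {
    by_cond <- split(dat$time_point, dat$condition)
    time_points <- sort(intersect(unique(by_cond[[contrast[1]]]), unique(by_cond[[contrast[2]]])))
  }
  assert_that(length(time_points) >= 1, "no shared time points between conditions")
  out <- tidyr::expand_grid(
    metabolite = unique(dat$metabolite),
    time_point = time_points
  ) |>
    purrr::pmap_dfr(function(metabolite, time_point) {
      tx <- dat$intensity[dat$metabolite == metabolite & dat$time_point == time_point &
        dat$condition == contrast[1]]
      cx <- dat$intensity[dat$metabolite == metabolite & dat$time_point == time_point &
        dat$condition == contrast[2]]
      assert_that(
        length(tx) >= 1 && length(cx) >= 1,
        paste0("condition missing at time point ", time_point)
      )
      alt <- if (alternative == "auto") {
        if (median(tx) >= median(cx)) "greater" else "less"
      } else {
        alternative
      }
      mw <- mann_whitney_one_sided(tx, cx, alt)
      tibble(
        metabolite = metabolite, time_point = time_point,
        log_fold_change = log_fold_change(tx, cx, pseudocount),
        direction = if (alt == "greater") "accumulation" else "depletion",
        statistic = mw$statistic, p_value = mw$p_value
      )
    }) |>
    dplyr::mutate(stars = significance_stars(.data$p_value))
  out
}

#' Heat-map-ready matrix of log fold changes
#'
#' Pivots a [differential_table()] result into a metabolite x time-point
#' matrix of log fold changes, the layout used for global metabolomic
#' heat maps.
#'
#' @param diff A [differential_table()] result.
#' @return Numeric matrix, metabolites x time points.
#' @export
lfc_matrix <- function(diff) {
  wide <- diff |>
    dplyr::select("metabolite", "time_point", "log_fold_change") |>
    tidyr::pivot_wider(names_from = "time_point", values_from = "log_fold_change")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$metabolite
  m
}
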