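# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on class.
stop_metarescue <- function(message, class) {
  abort(message, class = c(class, "metarescue_error"))
}

assert_that <- function(ok, message, class = "metarescue_invalid_input") {
  if (!isTRUE(ok)) stop_metarescue(message, class)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Evaluate code with a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Significance stars at the thresholds used throughout the reporting layer
# (p <= 0.05 "*", <= 0.001 "**", <= 0.0001 "***").
significance_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "***",
    p <= 1e-3 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

# Feature-matrix helpers for wide profile tibbles: every numeric column that
# is not metadata is a feature.
profile_meta_cols <- c(
  "drug", "mechanism", "condition", "concentration", "time_point", "replicate",
  "sample_id", "cluster", "dim1", "dim2"
)

profile_feature_names <- function(profiles) {
  setdiff(names(profiles)[vapply(profiles, is.numeric, logical(1))], profile_meta_cols)
}

profile_matrix <- function(profiles) {
  feats <- profile_feature_names(profiles)
  assert_that(length(feats) > 0, "no feature columns found in profiles")
  m <- as.matrix(profiles[, feats, drop = FALSE])
  rownames(m) <- profiles[["drug"]] %||% rownames(m)
  m
}
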