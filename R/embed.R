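#' Two-dimensional embedding of drug profiles
#'
#' Projects profiles to two dimensions for visual inspection of clustering
#' behaviour. The embedding algorithm is pluggable behind a determinism
#' contract: given the same inputs and `random_state`, the coordinates are
#' identical. The default is classical multidimensional scaling on Euclidean
#' distances (deterministic by construction and neighborhood-preserving at
#' this scale); `"pca"` projects onto the first two principal components.
#'
#' @param profiles Wide profile tibble (see [filter_profiles()]).
#' @param n_neighbors Neighborhood size the embedding should honor; used to
#'   check that enough profiles are present (`>= n_neighbors + 1`) and passed
#'   to neighborhood-based methods.
#' @param random_state Seed forwarded to stochastic embedding methods
#'   (deterministic methods ignore it but honor the contract trivially).
#' @param method `"mds"` (default) or `"pca"`.
#' @return Tibble `drug`, `dim1`, `dim2` (plus `mechanism` if present).
#' @export
embed_2d <- function(profiles, n_neighbors = 14, random_state = 42,
                     method = c("mds", "pca")) {
  method <- match.arg(method)
  X <- profile_matrix(profiles)
  assert_that(
    nrow(X) >= n_neighbors + 1,
    paste0("need at least n_neighbors + 1 = ", n_neighbors + 1, " profiles")
  )
  coords <- with_seed(random_state, {
    switch(method,
      mds = stats::cmdscale(stats::dist(X), k = 2),
      pca = stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
    )
  })
  # canonical sign: make the largest-magnitude loading of each axis positive
  for (j in 1:2) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  out <- tibble(
    drug = profiles$drug %||% paste0("profile_", seq_len(nrow(X))),
    dim1 = coords[, 1], dim2 = coords[, 2]
  )
  if (!is.null(profiles$mechanism)) out$mechanism <- profiles$mechanism
  out
}

#' Density-based clustering with noise (DBSCAN)
#'
#' Standard DBSCAN semantics: a core point has at least `min_samples` points
#' (including itself) within `eps`; clusters are the connected components of
#' density-reachability over core points; non-core points within `eps` of a
#' core point join its cluster (border points); everything else is noise
#' (label 0).
#'
#' @param points Numeric matrix or tibble of coordinates (e.g. an
#'   [embed_2d()] result; non-numeric columns are ignored).
#' @param eps Neighborhood radius (> 0).
#' @param min_samples Core-point threshold (>= 1).
#' @return Integer vector of cluster labels, 0 = noise.
#' @export
dbscan_cluster <- function(points, eps = 0.5, min_samples = 5) {
  assert_that(is_number(eps) && eps > 0, "eps must be > 0")
  assert_that(is_count(min_samples), "min_samples must be >= 1")
  X <- if (is.matrix(points)) {
    points
  } else {
    as.matrix(dplyr::select(as_tibble(points), dplyr::where(is.numeric)))
  }
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- D <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    frontier <- i
    while (length(frontier) > 0) {
      reach <- which(nb[frontier[1], ])
      frontier <- frontier[-1]
      for (j in reach) {
        if (labels[j] == 0L) {
          labels[j] <- cluster
          if (core[j]) frontier <- c(frontier, j)
        }
      }
    }
  }
  labels
}

#' Pearson correlation matrix across drug profiles
#'
#' Symmetric drug x drug correlation matrix of the (filtered) feature
#' vectors, with unit diagonal. A profile with zero variance has undefined
#' correlations; its entries are `NA` and a warning names it.
#'
#' @param profiles Wide profile tibble (>= 2 profiles, >= 2 features).
#' @return Numeric matrix with drug ids as dimnames.
#' @export
drug_correlation_matrix <- function(profiles) {
  X <- profile_matrix(profiles)
  assert_that(nrow(X) >= 2 && ncol(X) >= 2, "need >= 2 profiles and >= 2 features")
  flat <- apply(X, 1, sd) == 0
  if (any(flat)) {
    warn(paste0(
      "zero-variance profile(s), correlation undefined: ",
      paste(rownames(X)[flat], collapse = ", ")
    ))
  }
  R <- suppressWarnings(cor(t(X)))
  diag(R) <- 1
  R
}
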