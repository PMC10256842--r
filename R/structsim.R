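#' Global structural similarity matrix
#'
#' Standard-normalizes each structural property across proteins (z-score)
#' and computes the protein x protein Pearson correlation of the normalized
#' property vectors — the global, whole-chain notion of structural
#' similarity. Zero-variance properties carry no information and are dropped
#' with a warning.
#'
#' @param properties Tibble with a `protein` column and numeric property
#'   columns (>= 2 proteins, >= 2 informative properties).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
global_similarity_matrix <- function(properties) {
  X <- as.matrix(dplyr::select(properties, dplyr::where(is.numeric)))
  rownames(X) <- properties$protein
  assert_that(nrow(X) >= 2, "need >= 2 proteins")
  sds <- apply(X, 2, sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warn(paste0(
      "dropping zero-variance propert",
      if (sum(flat) == 1) "y: " else "ies: ",
      paste(colnames(X)[flat], collapse = ", ")
    ))
    X <- X[, !flat, drop = FALSE]
  }
  assert_that(ncol(X) >= 2, "need >= 2 informative properties")
  Z <- scale(X)
  R <- cor(t(Z))
  diag(R) <- 1
  R
}

#' Keep the largest binding pockets of each protein
#'
#' @param pockets Tibble `protein`, `pocket`, `size`, `bits` (list-column of
#'   bit indices).
#' @param k Pockets retained per protein (default 5, the usual cleft-analysis
#'   choice). Size ties break by lexicographically smaller pocket id.
#' @return Filtered pockets tibble.
#' @export
select_top_pockets <- function(pockets, k = 5) {
  assert_that(is_count(k), "k must be a positive integer")
  pockets |>
    dplyr::group_by(.data$protein) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$pocket, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}

#' Tanimoto coefficient between two pocket fingerprints
#'
#' `|A intersect B| / |A union B|` over bit-index sets. Two empty sets have
#' no defined similarity and raise an error.
#'
#' @param a,b Integer vectors of bit indices (sets).
#' @return Coefficient in `[0, 1]`.
#' @examples
#' pocket_tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
pocket_tanimoto <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  union_n <- length(union(a, b))
  if (union_n == 0) {
    stop_metarescue("Tanimoto undefined for two empty bit sets", "metarescue_empty_bitsets")
  }
  length(intersect(a, b)) / union_n
}

#' Rank candidate off-target proteins by pocket similarity to a reference
#'
#' Scores each candidate by aggregating pairwise Tanimoto coefficients
#' between its retained (top-k) pockets and the reference protein's retained
#' pockets — by default the maximum, i.e. the most reference-like cleft.
#' Pathway membership and externally computed whole-structure alignment
#' p-values can be merged for context.
#'
#' @param pockets Pockets tibble (`protein`, `pocket`, `size`, `bits`).
#' @param reference Reference protein id (must have >= 1 retained pocket).
#' @param k Pockets retained per protein before scoring.
#' @param aggregate `"max"` (default) or `"mean"` over pocket pairs.
#' @param pathway Optional character vector of proteins in the implicated
#'   pathway.
#' @param alignment_p Optional tibble `protein`, `p` of external alignment
#'   p-values.
#' @return Tibble `protein`, `score`, `best_pocket`, `n_pockets`,
#'   `in_pathway`, (`alignment_p`), sorted by descending score with ties by
#'   protein id; candidates without pockets score 0 and are flagged via
#'   `n_pockets = 0`.
#' @export
rank_candidates <- function(pockets, reference, k = 5,
                            aggregate = c("max", "mean"),
                            pathway = NULL, alignment_p = NULL) {
  aggregate <- match.arg(aggregate)
  kept <- select_top_pockets(pockets, k)
  ref <- kept |> dplyr::filter(.data$protein == reference)
  assert_that(nrow(ref) >= 1, "reference protein has no retained pockets")
  candidates <- setdiff(unique(pockets$protein), reference)
  out <- purrr::map_dfr(candidates, function(p) {
    mine <- kept |> dplyr::filter(.data$protein == p)
    if (nrow(mine) == 0) {
      return(tibble(
        protein = p, score = 0, best_pocket = NA_character_, n_pockets = 0L
      ))
    }
    pairs <- tidyr::expand_grid(i = seq_len(nrow(mine)), j = seq_len(nrow(ref)))
    sims <- purrr::map2_dbl(pairs$i, pairs$j, function(i, j) {
      pocket_tanimoto(mine$bits[[i]], ref$bits[[j]])
    })
    tibble(
      protein = p,
      score = if (aggregate == "max") max(sims) else mean(sims),
      best_pocket = mine$pocket[pairs$i[which.max(sims)]],
      n_pockets = nrow(mine)
    )
  })
  out$in_pathway <- if (is.null(pathway)) NA else out$protein %in% pathway
  if (!is.null(alignment_p)) {
    out <- dplyr::left_join(out, dplyr::rename(alignment_p, alignment_p = "p"), by = "protein")
  }
  out |> dplyr::arrange(dplyr::desc(.data$score), .data$protein)
}
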