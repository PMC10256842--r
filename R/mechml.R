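#' Filter and aggregate drug profiles for mechanism learning
#'
#' Applies the preprocessing used before signature learning: keep only
#' metabolites with annotation score above the threshold (high-confidence
#' identities) and, optionally, present in a query compound's namespace;
#' drop zero-time rows (no treatment effect yet); average replicate rows per
#' compound. Returns one wide feature row per drug.
#'
#' @param profiles Long profile table from [drug_profiles()]: columns
#'   `drug`, `mechanism`, `time_point`, `metabolite`, `lfc`,
#'   `annotation_score`.
#' @param score_threshold Annotation-score cutoff; features must score
#'   strictly above it (default 50).
#' @param shared_ids Optional metabolite ids defining the shared namespace
#'   (e.g. the query compound's features); features outside it are dropped.
#' @param exclude_zero_time Drop `time_point == 0` rows (default `TRUE`).
#' @param average Average remaining rows per drug (default `TRUE`).
#' @return Wide tibble: `drug`, `mechanism`, one numeric column per retained
#'   metabolite.
#' @export
filter_profiles <- function(profiles, score_threshold = 50, shared_ids = NULL,
                            exclude_zero_time = TRUE, average = TRUE) {
  dat <- profiles |> dplyr::filter(.data$annotation_score > score_threshold)
  if (!is.null(shared_ids)) {
    dat <- dat |> dplyr::filter(.data$metabolite %in% shared_ids)
  }
  if (exclude_zero_time) {
    dat <- dat |> dplyr::filter(.data$time_point != 0)
  }
  if (nrow(dat) == 0 || length(unique(dat$metabolite)) == 0) {
    stop_metarescue(
      "no features remain after filtering (empty feature intersection)",
      "metarescue_empty_features"
    )
  }
  if (average) {
    dat <- dat |>
      dplyr::group_by(.data$drug, .data$mechanism, .data$metabolite) |>
      dplyr::summarise(lfc = mean(.data$lfc), .groups = "drop")
  }
  dat |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "lfc") |>
    dplyr::arrange(.data$drug)
}

# -- multinomial logistic regression ----------------------------------------

softmax_probs <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Penalized multinomial fit: minimize total cross-entropy plus
# lambda/2 * ||W||^2 (intercepts unpenalized) by BFGS with analytic
# gradient. Zero initialization makes the fit deterministic.
fit_softmax <- function(X, y_idx, K, lambda, tol, max_iter) {
  n <- nrow(X)
  p <- ncol(X)
  Xi <- cbind(1, X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y_idx)] <- 1
  unpack <- function(theta) matrix(theta, nrow = p + 1, ncol = K)
  fn <- function(theta) {
    B <- unpack(theta)
    P <- softmax_probs(Xi %*% B)
    -sum(Y * log(pmax(P, 1e-300))) + lambda / 2 * sum(B[-1, ]^2)
  }
  gr <- function(theta) {
    B <- unpack(theta)
    P <- softmax_probs(Xi %*% B)
    G <- t(Xi) %*% (P - Y)
    G[-1, ] <- G[-1, ] + lambda * B[-1, ]
    as.vector(G)
  }
  opt <- optim(rep(0, (p + 1) * K), fn, gr,
    method = "BFGS",
    control = list(maxit = max_iter, reltol = tol)
  )
  if (opt$convergence != 0) {
    warn(paste0(
      "mechanism model did not converge within ", max_iter,
      " iterations (code ", opt$convergence, ")"
    ))
  }
  list(B = unpack(opt$par), value = opt$value, convergence = opt$convergence)
}

#' Train a multiclass mechanism-of-action model
#'
#' L2-regularized multinomial (softmax) logistic regression on standardized
#' log fold-change features. The optimizer starts from zero weights, so the
#' fit is deterministic given the data.
#'
#' @param profiles Wide profile tibble from [filter_profiles()]: `drug`,
#'   `mechanism`, feature columns.
#' @param lambda L2 penalty strength (default 1).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @param standardize Z-score features on the training data (default `TRUE`).
#' @return A `mechanism_model` object: weights (class x metabolite),
#'   intercepts, class order, feature names, standardization parameters and
#'   training metadata.
#' @export
train_mechanism_model <- function(profiles, lambda = 1, tol = 1e-6,
                                  max_iter = 1000, standardize = TRUE) {
  feats <- profile_feature_names(profiles)
  X <- profile_matrix(profiles)
  y <- as.character(profiles$mechanism)
  classes <- sort(unique(y))
  assert_that(length(classes) >= 2, "need at least two mechanism classes",
    class = "metarescue_single_class"
  )
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scale_ <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  fit <- fit_softmax(Xs, match(y, classes), length(classes), lambda, tol, max_iter)
  structure(
    list(
      weights = t(fit$B[-1, , drop = FALSE]), # class x metabolite
      intercepts = fit$B[1, ],
      classes = classes,
      features = feats,
      center = center,
      scale = scale_,
      lambda = lambda, tol = tol, max_iter = max_iter,
      deviance = fit$value, converged = fit$convergence == 0,
      n_profiles = nrow(X)
    ),
    class = "mechanism_model"
  )
}

#' @export
print.mechanism_model <- function(x, ...) {
  cat(sprintf(
    "<mechanism_model>  %d classes x %d features, %d profiles, lambda = %g\n",
    length(x$classes), length(x$features), x$n_profiles, x$lambda
  ))
  invisible(x)
}

#' @export
tidy.mechanism_model <- function(x, ...) {
  W <- x$weights
  tidyr::expand_grid(class = x$classes, metabolite = x$features) |>
    dplyr::mutate(weight = as.vector(t(W)))
}

#' @export
glance.mechanism_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes), n_features = length(x$features),
    n_profiles = x$n_profiles, lambda = x$lambda,
    deviance = x$deviance, converged = x$converged
  )
}

#' Predict mechanism-class probabilities
#'
#' @param model A [train_mechanism_model()] fit.
#' @param profiles Wide profile tibble with the model's feature columns.
#' @return Tibble: `drug` plus one probability column per class; each row
#'   sums to 1.
#' @export
predict_mechanism <- function(model, profiles) {
  missing <- setdiff(model$features, names(profiles))
  if (length(missing) > 0) {
    stop_metarescue(
      paste0("profile lacks model features: ", paste(head(missing, 5), collapse = ", ")),
      "metarescue_feature_mismatch"
    )
  }
  X <- as.matrix(profiles[, model$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  P <- softmax_probs(sweep(Xs %*% t(model$weights), 2, model$intercepts, "+"))
  colnames(P) <- model$classes
  dplyr::bind_cols(
    tibble(drug = profiles$drug %||% paste0("profile_", seq_len(nrow(P)))),
    as_tibble(P)
  )
}

#' Leave-one-out cross-validation of the mechanism model
#'
#' Refits the model with each profile held out and predicts its class. A
#' class with a single member cannot be trained in its own fold and is
#' flagged untrainable (prediction `NA`).
#'
#' @inheritParams train_mechanism_model
#' @return A `mechanism_loocv` object: per-profile predictions, row-normalized
#'   confusion matrix (rows = true class), per-class and overall accuracy.
#' @export
evaluate_loocv <- function(profiles, lambda = 1, tol = 1e-6, max_iter = 1000,
                           standardize = TRUE) {
  y <- as.character(profiles$mechanism)
  classes <- sort(unique(y))
  counts <- table(y)
  preds <- purrr::map_chr(seq_len(nrow(profiles)), function(i) {
    if (counts[[y[i]]] < 2) {
      return(NA_character_)
    }
    fit <- train_mechanism_model(profiles[-i, ],
      lambda = lambda, tol = tol,
      max_iter = max_iter, standardize = standardize
    )
    p <- predict_mechanism(fit, profiles[i, ])
    fit$classes[which.max(as.numeric(p[1, fit$classes]))]
  })
  predictions <- tibble(
    drug = profiles$drug, truth = y, predicted = preds,
    correct = !is.na(preds) & preds == y,
    untrainable = is.na(preds)
  )
  confusion <- matrix(0,
    nrow = length(classes), ncol = length(classes),
    dimnames = list(truth = classes, predicted = classes)
  )
  for (i in seq_along(preds)) {
    if (!is.na(preds[i])) confusion[y[i], preds[i]] <- confusion[y[i], preds[i]] + 1
  }
  rs <- rowSums(confusion)
  confusion_norm <- sweep(confusion, 1, pmax(rs, 1), "/")
  per_class <- tibble(
    class = classes,
    n = as.integer(table(factor(y, classes))),
    accuracy = purrr::map_dbl(classes, function(cl) {
      idx <- y == cl & !is.na(preds)
      if (!any(idx)) NA_real_ else mean(preds[idx] == cl)
    })
  )
  structure(
    list(
      predictions = predictions, confusion = confusion_norm,
      confusion_counts = confusion, per_class = per_class,
      overall_accuracy = mean(predictions$correct[!predictions$untrainable])
    ),
    class = "mechanism_loocv"
  )
}

#' @export
print.mechanism_loocv <- function(x, ...) {
  cat(sprintf(
    "<mechanism_loocv>  %d profiles, overall accuracy %.3f\n",
    nrow(x$predictions), x$overall_accuracy
  ))
  invisible(x)
}

#' @export
tidy.mechanism_loocv <- function(x, ...) x$per_class

#' @export
glance.mechanism_loocv <- function(x, ...) {
  tibble(
    n_profiles = nrow(x$predictions),
    n_untrainable = sum(x$predictions$untrainable),
    overall_accuracy = x$overall_accuracy
  )
}

#' Rank metabolites driving one class of the mechanism model
#'
#' Metabolites ranked by the absolute standardized-model weight for the
#' class, with the signed weight retained; ties break deterministically by
#' metabolite id.
#'
#' @param model A [train_mechanism_model()] fit.
#' @param class Class name.
#' @return Tibble `metabolite`, `score` (signed weight), `rank`.
#' @export
feature_importance <- function(model, class) {
  if (!class %in% model$classes) {
    stop_metarescue(paste0("unknown class: ", class), "metarescue_unknown_class")
  }
  w <- model$weights[match(class, model$classes), ]
  tibble(metabolite = model$features, score = as.numeric(w)) |>
    dplyr::arrange(dplyr::desc(abs(.data$score)), .data$metabolite) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Residual drug-specific signature after removing a class signature
#'
#' Removes the class-signature direction from a profile by orthogonal
#' projection in the model's standardized feature space:
#' `r = x - (<x, w> / <w, w>) w`, so the residual is exactly orthogonal to
#' the class weight vector. What remains is the drug-specific perturbation
#' unexplained by the class mechanism.
#'
#' @param model A [train_mechanism_model()] fit.
#' @param profile One-row wide profile tibble (or named numeric vector over
#'   the model features).
#' @param class Class whose signature to remove.
#' @return Tibble `metabolite`, `standardized`, `residual`.
#' @export
residual_signature <- function(model, profile, class) {
  if (!class %in% model$classes) {
    stop_metarescue(paste0("unknown class: ", class), "metarescue_unknown_class")
  }
  w <- as.numeric(model$weights[match(class, model$classes), ])
  if (sum(w^2) == 0) {
    stop_metarescue("class weight vector is zero", "metarescue_zero_weights")
  }
  x <- if (is.data.frame(profile)) {
    as.numeric(as.matrix(profile[1, model$features, drop = FALSE]))
  } else {
    as.numeric(profile[model$features])
  }
  xs <- unname((x - model$center) / model$scale)
  r <- xs - sum(xs * w) / sum(w * w) * w
  tibble(metabolite = model$features, standardized = xs, residual = r)
}
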