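# Mechanism-of-action learning: filtering, softmax model, LOOCV, residuals,
# embedding, clustering, correlation.

make_long_profiles <- function(n_met = 10, n_low = 4, drugs = c("d1", "d2"),
                               times = c(0, 4, 8)) {
  mets <- sprintf("M%02d", seq_len(n_met))
  scores <- c(runif(n_low, 0, 50), runif(n_met - n_low, 51, 100))
  tidyr::expand_grid(drug = drugs, time_point = times, metabolite = mets) |>
    dplyr::mutate(
      mechanism = "classA",
      lfc = rnorm(dplyr::n()),
      annotation_score = scores[match(.data$metabolite, mets)]
    )
}

test_that("profile filtering drops low-confidence features and zero time", {
  set.seed(1)
  long <- make_long_profiles(n_met = 10, n_low = 4)
  wide <- filter_profiles(long)
  expect_equal(length(profile_feature_names(wide)), 6)
  expect_equal(nrow(wide), 2) # averaged per drug

  # averaging is the feature-wise mean over retained rows
  d1 <- long |>
    dplyr::filter(
      .data$drug == "d1", .data$time_point != 0,
      .data$annotation_score > 50, .data$metabolite == "M05"
    )
  expect_equal(wide$M05[wide$drug == "d1"], mean(d1$lfc))

  expect_error(
    filter_profiles(dplyr::mutate(long, time_point = 0)),
    "empty feature"
  )
})

separable_panel <- function(seed = 21, effect = 3, noise = 0.2,
                            drugs_per_class = 3, classes = c("a", "b")) {
  cfg <- synth_config(
    seed = seed, effect_size = effect, noise_sd = noise,
    class_labels = classes, drugs_per_class = drugs_per_class,
    n_metabolites = 20, n_replicates = 2
  )
  filter_profiles(drug_profiles(simulate_metabolomics(cfg)))
}

test_that("softmax model separates verifiably separable classes", {
  pr <- separable_panel()
  # independent separability check before trusting the classifier
  expect_equal(oracle_nearest_centroid_loocv(pr), 1)
  model <- train_mechanism_model(pr)
  pred <- predict_mechanism(model, pr)
  expect_equal(rowSums(as.matrix(pred[, model$classes])), rep(1, nrow(pr)),
    tolerance = 1e-12
  )
  hard <- model$classes[max.col(as.matrix(pred[, model$classes]))]
  expect_equal(hard, as.character(pr$mechanism))
})

test_that("all-zero profiles give uniform class probabilities", {
  pr <- separable_panel()
  model <- train_mechanism_model(pr)
  zero <- pr[1, ]
  zero[, model$features] <- as.list(model$center) # standardizes to the origin
  p <- predict_mechanism(model, zero)
  # the L2 penalty keeps intercepts near the balanced-class optimum
  expect_equal(as.numeric(p[1, model$classes]), rep(0.5, 2), tolerance = 0.05)
})

test_that("single-class training is rejected and feature mismatch is caught", {
  pr <- separable_panel()
  expect_error(
    train_mechanism_model(dplyr::filter(pr, .data$mechanism == "a")),
    class = "metarescue_single_class"
  )
  model <- train_mechanism_model(pr)
  expect_error(
    predict_mechanism(model, pr[, 1:4]),
    class = "metarescue_feature_mismatch"
  )
})

test_that("LOOCV is perfect on strong signal and flags singleton classes", {
  pr <- separable_panel()
  cv <- evaluate_loocv(pr)
  expect_equal(cv$overall_accuracy, 1)
  expect_equal(rowSums(cv$confusion), rep(1, nrow(cv$confusion)),
    tolerance = 1e-12, ignore_attr = TRUE
  )

  singleton <- dplyr::bind_rows(
    pr,
    dplyr::mutate(pr[1, ], drug = "odd", mechanism = "lonely")
  )
  cv2 <- evaluate_loocv(singleton)
  expect_true(cv2$predictions$untrainable[cv2$predictions$truth == "lonely"])
})

test_that("feature importance ranks the informative feature first, ties by id", {
  pr <- separable_panel(seed = 5)
  # overwrite: one feature carries the whole signal
  feats <- profile_feature_names(pr)
  for (f in feats) pr[[f]] <- 0
  pr[[feats[3]]] <- ifelse(pr$mechanism == "a", 2, -2)
  model <- train_mechanism_model(pr)
  imp <- feature_importance(model, "a")
  expect_equal(imp$metabolite[1], feats[3])

  # all-equal weights break ties by metabolite id
  model0 <- model
  model0$weights[] <- 1
  imp0 <- feature_importance(model0, "a")
  expect_equal(imp0$metabolite, sort(feats))

  expect_error(feature_importance(model, "nope"), class = "metarescue_unknown_class")

  # importance is invariant to feature (column) order
  perm <- sample(seq_along(feats))
  pr_perm <- pr[, c("drug", "mechanism", feats[perm])]
  imp_perm <- feature_importance(train_mechanism_model(pr_perm), "a")
  expect_equal(
    dplyr::arrange(imp, .data$metabolite)$score,
    dplyr::arrange(imp_perm, .data$metabolite)$score,
    tolerance = 1e-5
  )
})

test_that("residual signature is the orthogonal complement projection", {
  pr <- separable_panel()
  model <- train_mechanism_model(pr)
  w <- as.numeric(model$weights[1, ])

  # x parallel to w -> residual 0 (build unstandardized x mapping onto w)
  x_par <- model$center + model$scale * w
  names(x_par) <- model$features
  r_par <- residual_signature(model, x_par, model$classes[1])
  expect_equal(r_par$residual, rep(0, length(w)), tolerance = 1e-10)

  # x orthogonal to w -> residual equals x (standardized)
  set.seed(2)
  z <- rnorm(length(w))
  z <- z - sum(z * w) / sum(w * w) * w
  x_orth <- model$center + model$scale * z
  names(x_orth) <- model$features
  r_orth <- residual_signature(model, x_orth, model$classes[1])
  expect_equal(r_orth$residual, z, tolerance = 1e-10)

  # random x -> residual orthogonal to w
  x_rand <- setNames(rnorm(length(w)), model$features)
  r_rand <- residual_signature(model, x_rand, model$classes[1])
  expect_lt(abs(sum(r_rand$residual * w)), 1e-10)

  model$weights[1, ] <- 0
  expect_error(
    residual_signature(model, x_rand, model$classes[1]),
    class = "metarescue_zero_weights"
  )
})

test_that("embedding is 2-D, deterministic, and separates distant classes", {
  pr <- separable_panel(seed = 9, effect = 4, noise = 0.1, drugs_per_class = 8)
  emb1 <- embed_2d(pr, n_neighbors = 14)
  emb2 <- embed_2d(pr, n_neighbors = 14)
  expect_identical(emb1, emb2)
  expect_setequal(c("dim1", "dim2") %in% names(emb1), TRUE)

  cents <- emb1 |>
    dplyr::group_by(.data$mechanism) |>
    dplyr::summarise(d1 = mean(.data$dim1), d2 = mean(.data$dim2))
  between <- sqrt(diff(cents$d1)^2 + diff(cents$d2)^2)
  within <- emb1 |>
    dplyr::left_join(cents, by = "mechanism") |>
    dplyr::mutate(d = sqrt((.data$dim1 - .data$d1)^2 + (.data$dim2 - .data$d2)^2)) |>
    dplyr::pull(.data$d)
  expect_gt(between, max(within))

  expect_error(embed_2d(pr[1:5, ], n_neighbors = 14), "n_neighbors")
})

test_that("DBSCAN finds blobs, merges dense sets, and matches the closure oracle", {
  set.seed(4)
  blob1 <- matrix(rnorm(20, 0, 0.1), ncol = 2)
  blob2 <- matrix(rnorm(20, 5, 0.1), ncol = 2)
  labs <- dbscan_cluster(rbind(blob1, blob2), eps = 0.5, min_samples = 3)
  expect_equal(length(unique(labs)), 2)
  expect_true(all(labs != 0))
  expect_equal(length(unique(labs[1:10])), 1)

  tight <- matrix(rnorm(16, 0, 0.05), ncol = 2)
  labs2 <- dbscan_cluster(tight, eps = 1, min_samples = 4)
  expect_equal(labs2, rep(1L, 8))

  for (rep in 1:5) {
    X <- matrix(runif(40), ncol = 2)
    eps <- runif(1, 0.1, 0.3)
    mine <- dbscan_cluster(X, eps = eps, min_samples = 3)
    orc <- oracle_dbscan(X, eps = eps, min_samples = 3)
    # core points partition identically (up to label names)
    core <- orc$core
    expect_true(all(mine[core] != 0))
    tab <- table(mine[core], orc$components[core])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    # non-core points: noise iff no admissible cluster, else a legal member
    for (i in which(!core)) {
      adm <- orc$admissible[[i]]
      if (length(adm) == 0) {
        expect_equal(mine[i], 0L)
      } else {
        legal_mine <- unique(mine[core][orc$components[core] %in% adm])
        expect_true(mine[i] %in% legal_mine)
      }
    }
  }
})

test_that("drug correlation matrix is a proper correlation matrix", {
  pr <- separable_panel()
  R <- drug_correlation_matrix(pr)
  expect_equal(diag(R), rep(1, nrow(pr)), ignore_attr = TRUE)
  expect_equal(R, t(R))
  expect_true(all(R >= -1 - 1e-12 & R <= 1 + 1e-12))

  # profile vs itself and vs its negation
  feats <- profile_feature_names(pr)
  dup <- pr[c(1, 1, 2), ]
  dup$drug <- c("p", "p_copy", "q")
  dup[3, feats] <- as.list(-as.numeric(dup[1, feats]))
  R2 <- drug_correlation_matrix(dup)
  expect_equal(R2["p", "p_copy"], 1)
  expect_equal(R2["p", "q"], -1)

  # hand-formula oracle on a small matrix
  set.seed(8)
  toy <- dplyr::bind_cols(
    tibble::tibble(drug = c("x", "y", "z"), mechanism = "m"),
    tibble::as_tibble(matrix(rnorm(12), nrow = 3, dimnames = list(NULL, paste0("f", 1:4))))
  )
  R3 <- drug_correlation_matrix(toy)
  X <- as.matrix(toy[, paste0("f", 1:4)])
  expect_equal(R3["x", "y"], oracle_pearson(X[1, ], X[2, ]), tolerance = 1e-12)
  expect_equal(R3["y", "z"], oracle_pearson(X[2, ], X[3, ]), tolerance = 1e-12)

  flat <- toy
  flat[2, paste0("f", 1:4)] <- as.list(rep(1, 4))
  expect_warning(R4 <- drug_correlation_matrix(flat), "zero-variance")
  expect_true(is.na(R4["x", "y"]))
})
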