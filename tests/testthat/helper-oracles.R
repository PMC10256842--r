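# Independent oracles used across the suite. Each is deliberately coded
# through a different route than the implementation it checks.

# ---- Mann-Whitney by direct pairwise enumeration ---------------------------
# U and its exact one-sided p computed from pairwise comparisons over every
# subset assignment of the pooled sample (the implementation instead
# enumerates rank sums).
oracle_mann_whitney <- function(x, y, alternative = "greater") {
  u_pairs <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- u_pairs(x, y)
  sel <- utils::combn(length(pooled), n)
  u_all <- apply(sel, 2, function(idx) u_pairs(pooled[idx], pooled[-idx]))
  p <- if (alternative == "greater") {
    mean(u_all >= u_obs - 1e-9)
  } else {
    mean(u_all <= u_obs + 1e-9)
  }
  list(statistic = u_obs, p_value = p)
}

# ---- DBSCAN by reachability closure ----------------------------------------
# Core points from the distance matrix; clusters as the transitive closure of
# core-core adjacency via boolean matrix powering; border points checked for
# adjacency to their cluster. Returns the core partition, noise set, and a
# per-point list of admissible clusters (border points may legally join any
# adjacent core cluster).
oracle_dbscan <- function(X, eps, min_samples) {
  D <- as.matrix(stats::dist(X))
  nb <- D <= eps
  core <- rowSums(nb) >= min_samples
  n <- nrow(X)
  adj <- nb & outer(core, core, "&")
  closure <- adj
  repeat {
    nxt <- closure | (closure %*% closure > 0)
    if (identical(nxt, closure)) break
    closure <- nxt
  }
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1L
    comp[which(closure[i, ] & core)] <- cl
    comp[i] <- cl
  }
  admissible <- lapply(seq_len(n), function(i) {
    if (core[i]) {
      return(comp[i])
    }
    unique(stats::na.omit(comp[which(nb[i, ] & core)]))
  })
  list(core = core, components = comp, admissible = admissible)
}

# ---- Pearson correlation by the raw covariance formula ---------------------
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# ---- FBA via an independently formulated LP solved by scipy/HiGHS ----------
# Builds the LP directly from the reaction list (native variable bounds, no
# shifting, no slack construction) and solves it with an interior-point/HiGHS
# code that shares nothing with the package's simplex.
oracle_fba_script <- function() {
  path <- file.path(tempdir(), "oracle_fba.py")
  if (!file.exists(path)) {
    writeLines(c(
      "import sys, json",
      "import numpy as np",
      "from scipy.optimize import linprog",
      "d = json.load(open(sys.argv[1]))",
      "mets = {m: i for i, m in enumerate(d['metabolites'])}",
      "n = len(d['reactions'])",
      "S = np.zeros((len(mets), n))",
      "for j, r in enumerate(d['reactions']):",
      "    for m, c in r['stoichiometry'].items():",
      "        S[mets[m], j] = c",
      "c = -np.array([r['objective'] for r in d['reactions']])",
      "bounds = [(r['lb'], r['ub']) for r in d['reactions']]",
      "res = linprog(c, A_eq=S, b_eq=np.zeros(len(mets)), bounds=bounds, method='highs')",
      "print(json.dumps({'status': int(res.status),",
      "                  'mu': None if res.status != 0 else -res.fun}))"
    ), path)
  }
  path
}

oracle_fba_mu <- function(model) {
  payload <- list(
    metabolites = model$metabolites$id,
    reactions = purrr::pmap(
      model$reactions[, c("id", "stoichiometry", "lower_bound", "upper_bound", "objective_coefficient")],
      function(id, stoichiometry, lower_bound, upper_bound, objective_coefficient) {
        list(
          id = id, stoichiometry = as.list(stoichiometry),
          lb = lower_bound, ub = upper_bound, objective = objective_coefficient
        )
      }
    )
  )
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, tf, auto_unbox = TRUE, digits = NA)
  out <- jsonlite::fromJSON(paste(
    system2("python", c(oracle_fba_script(), tf), stdout = TRUE),
    collapse = ""
  ))
  if (out$status != 0) NA_real_ else out$mu
}

# ---- nearest-centroid classifier -------------------------------------------
# Confirms class separability independently of the logistic-regression path:
# leave-one-out nearest class centroid on the raw feature matrix.
oracle_nearest_centroid_loocv <- function(profiles) {
  X <- as.matrix(profiles[, setdiff(
    names(profiles)[vapply(profiles, is.numeric, logical(1))],
    c("time_point", "replicate")
  ), drop = FALSE])
  y <- as.character(profiles$mechanism)
  preds <- vapply(seq_len(nrow(X)), function(i) {
    cents <- vapply(
      sort(unique(y[-i])),
      function(cl) colMeans(X[-i, , drop = FALSE][y[-i] == cl, , drop = FALSE]),
      numeric(ncol(X))
    )
    colnames(cents)[which.min(colSums((cents - X[i, ])^2))]
  }, character(1))
  mean(preds == y)
}

# Shared fixture: the expression-corrected toy model.
toy_wt_model <- function() {
  m <- make_toy_model()
  spec <- attr(m, "spec")
  close_spontaneous(
    apply_expression_shutoff(m, spec$unexpressed_genes, scope = "global")
  )
}
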