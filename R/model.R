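#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` is the substrate of every flux computation in the
#' package: a set of metabolites, a set of reactions with stoichiometry,
#' flux bounds and gene-protein-reaction (GPR) rules, and one objective
#' (biomass) reaction. Steady-state flux distributions satisfy `S v = 0`
#' with `lb <= v <= ub`.
#'
#' @param metabolites Tibble with columns `id`, `compartment` (and optionally
#'   `name`). Compartment `"e"` marks extracellular (boundary) species.
#' @param reactions Tibble with columns `id`, `lower_bound`, `upper_bound`,
#'   `gene_rule` (boolean expression over gene ids, `""` for none),
#'   `spontaneous` (logical), `objective_coefficient`, and `stoichiometry`
#'   (a list column of named numeric vectors, metabolite id -> coefficient,
#'   negative = consumed).
#' @param genes Character vector of gene ids (defaults to the ids appearing
#'   in the GPR rules).
#' @param id Model identifier.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [make_toy_model()], [read_model()], [fba()]
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL, id = "model") {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gene_rule" %in% names(reactions)) reactions$gene_rule <- ""
  if (!"spontaneous" %in% names(reactions)) reactions$spontaneous <- FALSE
  if (!"objective_coefficient" %in% names(reactions)) reactions$objective_coefficient <- 0
  # partial row sets (e.g. via bind_rows) leave NAs in optional columns
  reactions$name[is.na(reactions$name)] <- reactions$id[is.na(reactions$name)]
  reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
  reactions$spontaneous[is.na(reactions$spontaneous)] <- FALSE
  reactions$objective_coefficient[is.na(reactions$objective_coefficient)] <- 0
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gene_rule, gpr_gene_ids))))
  }
  model <- structure(
    list(
      id = id,
      metabolites = metabolites[, c("id", "name", "compartment")],
      reactions = reactions[, c(
        "id", "name", "lower_bound", "upper_bound", "gene_rule",
        "spontaneous", "objective_coefficient", "stoichiometry"
      )],
      genes = tibble(id = as.character(genes))
    ),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(
    sprintf(
      "<metabolic_model '%s'>  %d metabolites, %d reactions, %d genes\n",
      x$id, nrow(x$metabolites), nrow(x$reactions), nrow(x$genes)
    )
  )
  cat(sprintf(
    "objective: %s; exchanges: %d\n",
    paste(objective_reaction(x), collapse = ", "),
    length(exchange_reactions(x))
  ))
  invisible(x)
}

# -- structural accessors ----------------------------------------------------

#' Stoichiometric matrix of a model
#'
#' @param model A [metabolic_model()].
#' @return Numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- as.numeric(st)
  }
  S
}

#' @rdname stoich_matrix
#' @export
objective_reaction <- function(model) {
  model$reactions$id[model$reactions$objective_coefficient != 0]
}

#' @rdname stoich_matrix
#' @export
exchange_reactions <- function(model) {
  n_mets <- vapply(model$reactions$stoichiometry, length, integer(1))
  model$reactions$id[n_mets == 1]
}

reaction_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop_metarescue(
      paste0("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", ")),
      "metarescue_unknown_reaction"
    )
  }
  idx
}

#' Modify reaction bounds
#'
#' @param model A [metabolic_model()].
#' @param reaction Reaction id.
#' @param lower,upper New bounds (either may be `NULL` to keep the current one).
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  i <- reaction_index(model, reaction)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  validate_model(model)
}

#' Remove a reaction from a model
#'
#' @inheritParams set_bounds
#' @return The modified model.
#' @export
remove_reaction <- function(model, reaction) {
  i <- reaction_index(model, reaction)
  model$reactions <- model$reactions[-i, ]
  validate_model(model)
}

# -- validation --------------------------------------------------------------

validate_model <- function(model) {
  rx <- model$reactions
  assert_that(!anyDuplicated(model$metabolites$id), "duplicate metabolite ids",
    class = "metarescue_model_invalid"
  )
  assert_that(!anyDuplicated(rx$id), "duplicate reaction ids",
    class = "metarescue_model_invalid"
  )
  bad_bounds <- rx$id[rx$lower_bound > rx$upper_bound]
  if (length(bad_bounds) > 0) {
    stop_metarescue(
      paste0("bound inversion (lower > upper) in reaction(s): ", paste(bad_bounds, collapse = ", ")),
      "metarescue_model_bounds"
    )
  }
  referenced <- unique(unlist(lapply(rx$stoichiometry, names)))
  dangling <- setdiff(referenced, model$metabolites$id)
  if (length(dangling) > 0) {
    stop_metarescue(
      paste0("stoichiometry references unknown metabolite(s): ", paste(dangling, collapse = ", ")),
      "metarescue_model_dangling"
    )
  }
  malformed <- rx$id[vapply(
    rx$stoichiometry,
    function(st) length(st) == 0 || is.null(names(st)) || any(!is.finite(as.numeric(st))),
    logical(1)
  )]
  if (length(malformed) > 0) {
    stop_metarescue(
      paste0("malformed stoichiometry in reaction(s): ", paste(malformed, collapse = ", ")),
      "metarescue_model_stoichiometry"
    )
  }
  assert_that(length(objective_reaction(model)) >= 1, "model has no objective reaction",
    class = "metarescue_model_invalid"
  )
  model
}

# -- GPR rules ---------------------------------------------------------------

gpr_gene_ids <- function(rule) {
  if (is.na(rule) || !nzchar(rule)) {
    return(character(0))
  }
  tokens <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  setdiff(tokens[nzchar(tokens)], c("and", "or", "AND", "OR"))
}

# Evaluate a boolean GPR rule given a set of unexpressed genes. Empty rules
# (spontaneous or unannotated reactions) evaluate TRUE.
gpr_is_expressed <- function(rule, unexpressed, reaction_id = "?") {
  if (is.na(rule) || !nzchar(rule)) {
    return(TRUE)
  }
  expr_txt <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule, ignore.case = TRUE),
    ignore.case = TRUE
  )
  genes <- gpr_gene_ids(rule)
  env <- new.env(parent = baseenv())
  for (g in genes) assign(g, !(g %in% unexpressed), envir = env)
  parsed <- tryCatch(parse(text = expr_txt)[[1]], error = function(e) NULL)
  out <- if (is.null(parsed)) NULL else tryCatch(eval(parsed, env), error = function(e) NULL)
  if (!is.logical(out) || length(out) != 1 || is.na(out)) {
    stop_metarescue(
      paste0("unparseable gene rule in reaction ", reaction_id, ": '", rule, "'"),
      "metarescue_gpr_parse"
    )
  }
  out
}

# -- JSON serialization ------------------------------------------------------

#' Read or write a metabolic model in the constraint-based JSON dialect
#'
#' The on-disk format follows the community JSON schema for constraint-based
#' models (`metabolites`, `reactions`, `genes` arrays with per-reaction
#' `metabolites` coefficient maps), so published genome-scale models in that
#' dialect load directly. Writing then reading a model is the identity up to
#' numeric formatting.
#'
#' @param path File path.
#' @return `read_model()` returns a [metabolic_model()]; `write_model()`
#'   invisibly returns `path`.
#' @export
read_model <- function(path) {
  assert_that(file.exists(path), paste0("model file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- purrr::map_dfr(raw$metabolites, function(m) {
    tibble(
      id = m$id, name = m$name %||% m$id,
      compartment = m$compartment %||% "c"
    )
  })
  rxns <- purrr::map_dfr(raw$reactions, function(r) {
    st <- unlist(r$metabolites)
    tibble(
      id = r$id, name = r$name %||% r$id,
      lower_bound = as.numeric(r$lower_bound %||% -1000),
      upper_bound = as.numeric(r$upper_bound %||% 1000),
      gene_rule = r$gene_reaction_rule %||% "",
      spontaneous = isTRUE(r$annotation$spontaneous),
      objective_coefficient = as.numeric(r$objective_coefficient %||% 0),
      stoichiometry = list(st)
    )
  })
  genes <- vapply(raw$genes %||% list(), function(g) g$id, character(1))
  metabolic_model(mets, rxns, genes = genes, id = raw$id %||% "model")
}

#' @rdname read_model
#' @param model A [metabolic_model()].
#' @export
write_model <- function(model, path) {
  out <- list(
    id = model$id,
    metabolites = purrr::pmap(
      model$metabolites,
      function(id, name, compartment) list(id = id, name = name, compartment = compartment)
    ),
    reactions = purrr::pmap(
      model$reactions,
      function(id, name, lower_bound, upper_bound, gene_rule, spontaneous,
               objective_coefficient, stoichiometry) {
        list(
          id = id, name = name,
          metabolites = as.list(stoichiometry),
          lower_bound = lower_bound, upper_bound = upper_bound,
          gene_reaction_rule = gene_rule,
          objective_coefficient = objective_coefficient,
          annotation = list(spontaneous = spontaneous)
        )
      }
    ),
    genes = purrr::map(model$genes$id, function(g) list(id = g))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
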