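#' Construct a constraint-based metabolic model
#'
#' The container used throughout the package: metabolites and reactions as
#' tibbles, stoichiometry as a sparse metabolite-by-reaction matrix, plus the
#' gene list, the biomass objective and the declared compartments. Cobalamin
#' exchange reactions are tracked explicitly so that the deficiency scenario
#' ([close_cobalamin_uptake()]) knows which uptakes to shut.
#'
#' @param metabolites Tibble/data frame with columns `id`, `name`,
#'   `compartment`, and optionally `formula`, `charge`. Ids carry the
#'   compartment as a bracket suffix, e.g. `"succoa[m]"`.
#' @param reactions Tibble/data frame with columns `id`, `stoich` (a list
#'   column of named numeric vectors, negative = consumed), `lower_bound`,
#'   `upper_bound`, `subsystem`, `gpr` (GPR string, `""` for none),
#'   `is_exchange`, `is_sink`.
#' @param genes Character vector of gene identifiers.
#' @param objective_id Reaction id of the biomass objective.
#' @param compartments Character vector of compartment codes; defaults to the
#'   compartments seen in `metabolites`.
#' @param cobalamin_exchanges Character vector of exchange-reaction ids for
#'   cobalamin-family metabolites (may be empty for models without the
#'   pathway).
#' @return An object of class `metabolic_model`.
#' @seealso [validate_model()], [add_reactions()], [read_model()]
#' @export
metabolic_model <- function(metabolites, reactions, genes, objective_id,
                            compartments = NULL,
                            cobalamin_exchanges = character()) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  for (col in c("is_exchange", "is_sink")) {
    if (!col %in% names(reactions)) reactions[[col]] <- FALSE
  }
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(compartments)) {
    compartments <- sort(unique(metabolites$compartment))
  }
  S <- build_stoich_matrix(metabolites$id, reactions)
  rules <- lapply(reactions$gpr, parse_gpr)
  names(rules) <- reactions$id
  structure(
    list(
      metabolites = metabolites[, c("id", "name", "compartment", "formula", "charge")],
      reactions = reactions[, c("id", "stoich", "lower_bound", "upper_bound",
                                "subsystem", "gpr", "is_exchange", "is_sink")],
      S = S,
      genes = unique(genes),
      objective_id = objective_id,
      compartments = compartments,
      cobalamin_exchanges = cobalamin_exchanges,
      gpr_rules = rules
    ),
    class = "metabolic_model"
  )
}

build_stoich_matrix <- function(met_ids, reactions) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(reactions))) {
    st <- reactions$stoich[[j]]
    if (length(st) == 0) next
    rows <- match(names(st), met_ids)
    keep <- !is.na(rows)
    ii <- c(ii, rows[keep]); jj <- c(jj, rep(j, sum(keep))); xx <- c(xx, unname(st[keep]))
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(met_ids), nrow(reactions)),
    dimnames = list(met_ids, reactions$id)
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n",
      sep = "")
  cat("  objective: ", x$objective_id,
      " | compartments: ", paste(x$compartments, collapse = ", "), "\n", sep = "")
  nex <- sum(x$reactions$is_exchange)
  cat("  exchanges: ", nex, " (", length(x$cobalamin_exchanges),
      " cobalamin)\n", sep = "")
  invisible(x)
}

#' Reaction and metabolite identifiers
#' @param model A `metabolic_model`.
#' @return Character vector of ids in model order.
#' @export
reaction_ids <- function(model) model$reactions$id

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(model) model$metabolites$id

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Set flux bounds on reactions
#' @param model A `metabolic_model`.
#' @param ids Reaction ids.
#' @param lower,upper Replacement bounds, recycled along `ids`; `NULL` leaves
#'   the respective bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, ids, lower = NULL, upper = NULL) {
  idx <- rxn_index(model, ids)
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- rep(lower, length.out = length(idx))
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- rep(upper, length.out = length(idx))
  model
}

#' Add reactions (and supporting metabolites/genes) to a model
#'
#' Returns a new model; the input model is unchanged. Identifier collisions
#' with existing reactions, metabolites or genes are an error.
#'
#' @param model A `metabolic_model`.
#' @param new_reactions Tibble in the same shape as `model$reactions`
#'   (columns `id`, `stoich`, `lower_bound`, `upper_bound`, and optionally
#'   `subsystem`, `gpr`, `is_exchange`, `is_sink`). May be `NULL`.
#' @param new_metabolites Tibble in the shape of `model$metabolites`; may be
#'   `NULL`.
#' @param new_genes Character vector of genes to register; may be `NULL`.
#' @param cobalamin_exchanges Additional exchange ids to register as
#'   cobalamin-family.
#' @return The extended `metabolic_model`.
#' @export
add_reactions <- function(model, new_reactions = NULL, new_metabolites = NULL,
                          new_genes = NULL, cobalamin_exchanges = character()) {
  mets <- model$metabolites
  if (!is.null(new_metabolites) && nrow(new_metabolites) > 0) {
    new_metabolites <- tibble::as_tibble(new_metabolites)
    if (!"formula" %in% names(new_metabolites)) new_metabolites$formula <- NA_character_
    if (!"charge" %in% names(new_metabolites)) new_metabolites$charge <- NA_integer_
    if (!"name" %in% names(new_metabolites)) new_metabolites$name <- new_metabolites$id
    clash <- intersect(new_metabolites$id, mets$id)
    if (length(clash)) stop("metabolite id collision: ", paste(clash, collapse = ", "), call. = FALSE)
    mets <- dplyr::bind_rows(mets, new_metabolites[, names(mets)])
  }
  rxns <- model$reactions
  if (!is.null(new_reactions) && nrow(new_reactions) > 0) {
    new_reactions <- tibble::as_tibble(new_reactions)
    for (col in c("is_exchange", "is_sink")) {
      if (!col %in% names(new_reactions)) new_reactions[[col]] <- FALSE
    }
    if (!"subsystem" %in% names(new_reactions)) new_reactions$subsystem <- ""
    if (!"gpr" %in% names(new_reactions)) new_reactions$gpr <- ""
    clash <- intersect(new_reactions$id, rxns$id)
    if (length(clash)) stop("reaction id collision: ", paste(clash, collapse = ", "), call. = FALSE)
    rxns <- dplyr::bind_rows(rxns, new_reactions[, names(rxns)])
  }
  genes <- model$genes
  if (!is.null(new_genes)) {
    clash <- intersect(new_genes, genes)
    if (length(clash)) stop("gene id collision: ", paste(clash, collapse = ", "), call. = FALSE)
    genes <- c(genes, new_genes)
  }
  metabolic_model(
    metabolites = mets, reactions = rxns, genes = genes,
    objective_id = model$objective_id,
    compartments = sort(unique(c(model$compartments, mets$compartment))),
    cobalamin_exchanges = unique(c(model$cobalamin_exchanges, cobalamin_exchanges))
  )
}

#' Keep a subset of reactions (and the metabolites they touch)
#'
#' Used by context-specific extraction: drops all other reactions and any
#' metabolite no longer referenced.
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids to keep.
#' @return A reduced `metabolic_model` (the objective is kept only if it
#'   survives the subset).
#' @export
subset_reactions <- function(model, ids) {
  idx <- sort(rxn_index(model, ids))
  rxns <- model$reactions[idx, ]
  used <- unique(unlist(lapply(rxns$stoich, names)))
  mets <- model$metabolites[model$metabolites$id %in% used, ]
  genes <- model$genes[model$genes %in% unique(unlist(lapply(rxns$gpr, gpr_genes)))]
  metabolic_model(
    metabolites = mets, reactions = rxns, genes = genes,
    objective_id = if (model$objective_id %in% rxns$id) model$objective_id else NA_character_,
    compartments = model$compartments,
    cobalamin_exchanges = intersect(model$cobalamin_exchanges, rxns$id)
  )
}

# Parse a chemical formula (with pseudo-elements such as Co/R allowed) into a
# named element-count vector. Returns NULL for missing/empty formulas.
parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
  if (sum(nchar(parts)) != nchar(f)) return(NA)  # unparseable
  el <- sub("([A-Z][a-z]?).*", "\\1", parts)
  cnt <- sub("[A-Z][a-z]?", "", parts)
  cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
  tapply(cnt, el, sum)
}

# Element-count imbalance of a reaction; NULL when not checkable (some
# participant lacks a formula or a formula fails to parse).
reaction_imbalance <- function(stoich, formulas) {
  total <- list()
  for (mid in names(stoich)) {
    fc <- parse_formula(formulas[[mid]])
    if (is.null(fc) || identical(fc, NA)) return(NULL)
    for (el in names(fc)) {
      total[[el]] <- (total[[el]] %||% 0) + stoich[[mid]] * fc[[el]]
    }
  }
  out <- unlist(total)
  out[abs(out) > 1e-6]
}

#' Validate a metabolic model
#'
#' Checks every structural invariant of the container: unique ids, resolvable
#' stoichiometry and GPR leaves, ordered bounds, declared compartments,
#' single-metabolite exchange/sink reactions, and (where formulas are present
#' for every participant) elemental mass balance and charge balance of internal
#' reactions. The balance check skips exchange, sink and biomass reactions.
#'
#' @param model A `metabolic_model`.
#' @return A tibble with columns `type`, `id`, `message`; zero rows mean the
#'   model is valid.
#' @export
validate_model <- function(model) {
  bad <- list()
  flag <- function(type, id, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(type = type, id = id, message = message)
  }
  mets <- model$metabolites
  rxns <- model$reactions
  dup <- mets$id[duplicated(mets$id)]
  for (d in unique(dup)) flag("duplicate_metabolite", d, "metabolite id not unique")
  dup <- rxns$id[duplicated(rxns$id)]
  for (d in unique(dup)) flag("duplicate_reaction", d, "reaction id not unique")
  off <- setdiff(unique(mets$compartment), model$compartments)
  for (cp in off) flag("unknown_compartment", cp, "compartment not declared in model")
  for (j in seq_len(nrow(rxns))) {
    id <- rxns$id[j]
    st <- rxns$stoich[[j]]
    if (length(st) == 0) flag("empty_stoichiometry", id, "reaction has no metabolites")
    miss <- setdiff(names(st), mets$id)
    if (length(miss)) {
      flag("unknown_metabolite", id,
           paste0("stoichiometry cites unknown metabolite(s): ",
                  paste(miss, collapse = ", ")))
    }
    if (rxns$lower_bound[j] > rxns$upper_bound[j]) {
      flag("bound_inversion", id, "lower bound exceeds upper bound")
    }
    if ((rxns$is_exchange[j] || rxns$is_sink[j]) && length(st) != 1) {
      flag("boundary_arity", id, "exchange/sink reaction must touch exactly one metabolite")
    }
    glist <- tryCatch(gpr_genes(rxns$gpr[j]), error = function(e) NA)
    if (identical(glist, NA)) {
      flag("gpr_parse", id, "GPR does not parse")
    } else {
      missg <- setdiff(glist, model$genes)
      if (length(missg)) {
        flag("unknown_gene", id,
             paste0("GPR cites gene(s) absent from model: ",
                    paste(missg, collapse = ", ")))
      }
    }
    boundary <- rxns$is_exchange[j] || rxns$is_sink[j] ||
      identical(id, model$objective_id)
    if (!boundary && length(st) > 0 && !length(setdiff(names(st), mets$id))) {
      formulas <- stats::setNames(mets$formula, mets$id)[names(st)]
      imb <- reaction_imbalance(st, as.list(formulas))
      if (!is.null(imb) && length(imb)) {
        flag("mass_imbalance", id,
             paste0("unbalanced elements: ",
                    paste(sprintf("%s %+g", names(imb), imb), collapse = ", ")))
      }
      charges <- stats::setNames(mets$charge, mets$id)[names(st)]
      if (!anyNA(charges)) {
        dq <- sum(unlist(st) * charges)
        if (abs(dq) > 1e-6) flag("charge_imbalance", id, sprintf("net charge %+g", dq))
      }
    }
  }
  if (!is.na(model$objective_id) && !model$objective_id %in% rxns$id) {
    flag("unknown_objective", model$objective_id, "objective reaction not in model")
  }
  if (length(bad)) dplyr::bind_rows(bad) else {
    tibble::tibble(type = character(), id = character(), message = character())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
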