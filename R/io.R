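#' Write a metabolic model to disk
#'
#' Two native formats are supported: a single JSON file with full fidelity,
#' and a TSV triple (`reactions.tsv`, `metabolites.tsv`, `genes.tsv`) meant
#' for hand-editing, where stoichiometry is carried as a human-readable
#' formula string (`"a[c] + 2 b[c] -> c[m]"`, `<=>` for reversible).
#'
#' @param model A `metabolic_model`.
#' @param path For `native-json`, the file path; for `native-tsv`, a
#'   directory (created if absent).
#' @param format `"native-json"` or `"native-tsv"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("native-json", "native-tsv")) {
  format <- match.arg(format)
  if (format == "native-json") {
    payload <- list(
      metabolites = model$metabolites,
      reactions = dplyr::mutate(
        model$reactions,
        stoich = lapply(.data$stoich, as.list)
      ),
      genes = model$genes,
      objective_id = model$objective_id,
      compartments = model$compartments,
      cobalamin_exchanges = model$cobalamin_exchanges
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    rx <- model$reactions
    utils::write.table(
      data.frame(
        id = rx$id,
        formula = vapply(rx$stoich, format_reaction_string, character(1),
                         reversible = rx$lower_bound < 0),
        lower_bound = rx$lower_bound, upper_bound = rx$upper_bound,
        subsystem = rx$subsystem, gpr = rx$gpr,
        is_exchange = rx$is_exchange, is_sink = rx$is_sink,
        objective = rx$id == model$objective_id,
        cobalamin_exchange = rx$id %in% model$cobalamin_exchanges,
        stringsAsFactors = FALSE
      ),
      file.path(path, "reactions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(as.data.frame(model$metabolites),
                       file.path(path, "metabolites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(id = model$genes, stringsAsFactors = FALSE),
                       file.path(path, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

format_reaction_string <- function(stoich, reversible = FALSE) {
  if (length(stoich) == 1 && length(reversible) == 1) {
    # boundary reaction written one-sided
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  side <- function(s) {
    if (!length(s)) return("")
    paste(vapply(seq_along(s), function(i) {
      coef <- abs(s[[i]])
      if (abs(coef - 1) < 1e-12) names(s)[i] else paste(format(coef, digits = 12), names(s)[i])
    }, character(1)), collapse = " + ")
  }
  arrow <- if (isTRUE(reversible[1])) "<=>" else "->"
  paste(side(lhs), arrow, side(rhs))
}

parse_reaction_string <- function(text) {
  parts <- strsplit(text, "<=>|->")[[1]]
  if (length(parts) > 2) stop("malformed reaction string: ", text, call. = FALSE)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, "\\+")[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      toks <- strsplit(tm, "\\s+")[[1]]
      if (length(toks) == 2) {
        out[toks[2]] <- sign * as.numeric(toks[1])
      } else if (length(toks) == 1) {
        out[toks[1]] <- sign
      } else stop("malformed reaction term: '", tm, "'", call. = FALSE)
    }
    out
  }
  c(parse_side(parts[1], -1),
    if (length(parts) == 2) parse_side(parts[2], +1) else numeric(0))
}

#' Read a metabolic model
#'
#' @param path File (`native-json`, `sbml`) or directory (`native-tsv`).
#' @param format One of `"native-json"`, `"native-tsv"`, `"sbml"`. SBML
#'   import is a minimal Level-3 FBC reader (species, reactions, bounds,
#'   gene-product associations) and requires the `xml2` package.
#' @return A validated `metabolic_model`; malformed input (unknown metabolite
#'   references, duplicate ids, inverted bounds) raises an error listing all
#'   violations.
#' @export
read_model <- function(path, format = c("native-json", "native-tsv", "sbml")) {
  format <- match.arg(format)
  model <- switch(format,
    "native-json" = read_model_json(path),
    "native-tsv" = read_model_tsv(path),
    "sbml" = read_model_sbml(path)
  )
  report <- validate_model(model)
  if (nrow(report)) {
    stop("model failed validation:\n",
         paste(sprintf("  [%s] %s: %s", report$type, report$id, report$message),
               collapse = "\n"), call. = FALSE)
  }
  model
}

read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  rx <- tibble::as_tibble(payload$reactions)
  st <- rx$stoich
  if (is.data.frame(st)) {
    # jsonlite simplifies the per-reaction coefficient objects into one
    # wide frame; rebuild the named vectors row by row
    rx$stoich <- lapply(seq_len(nrow(st)), function(i) {
      v <- unlist(st[i, , drop = FALSE])
      v <- v[!is.na(v)]
      stats::setNames(as.numeric(v), names(v))
    })
  } else {
    rx$stoich <- lapply(st, function(s) {
      v <- unlist(s)
      stats::setNames(as.numeric(v), names(v))
    })
  }
  mets <- tibble::as_tibble(payload$metabolites)
  mets$formula <- as.character(mets$formula)
  mets$charge <- suppressWarnings(as.integer(mets$charge))
  metabolic_model(
    metabolites = mets, reactions = rx, genes = unlist(payload$genes),
    objective_id = payload$objective_id,
    compartments = unlist(payload$compartments),
    cobalamin_exchanges = as.character(unlist(payload$cobalamin_exchanges))
  )
}

read_model_tsv <- function(path) {
  rx <- utils::read.delim(file.path(path, "reactions.tsv"), stringsAsFactors = FALSE,
                          na.strings = "NA")
  mets <- utils::read.delim(file.path(path, "metabolites.tsv"), stringsAsFactors = FALSE,
                            na.strings = "NA")
  genes <- utils::read.delim(file.path(path, "genes.tsv"), stringsAsFactors = FALSE)$id
  rx$gpr[is.na(rx$gpr)] <- ""
  rx <- tibble::as_tibble(rx)
  rx$stoich <- lapply(rx$formula, parse_reaction_string)
  obj <- rx$id[rx$objective]
  metabolic_model(
    metabolites = mets, reactions = rx, genes = genes,
    objective_id = if (length(obj)) obj[1] else NA_character_,
    cobalamin_exchanges = rx$id[rx$cobalamin_exchange]
  )
}

read_model_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML import requires the 'xml2' package", call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # namespace stripping keeps "fbc:"-prefixed attribute names literal
  fattr <- function(node, name) {
    a <- xml2::xml_attr(node, name)
    ifelse(is.na(a), xml2::xml_attr(node, paste0("fbc:", name)), a)
  }
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "charge")))
  )
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  parse_assoc <- function(node) {
    if (length(node) == 0) return("")
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(fattr(node, "geneProduct"))
    kids <- xml2::xml_children(node)
    inner <- vapply(kids, parse_assoc, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(inner, collapse = op), ")")
  }
  rows <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    refs <- function(xp, sgn) {
      nd <- xml2::xml_find_all(rn, xp)
      st <- sgn * as.numeric(dplyr::coalesce(xml2::xml_attr(nd, "stoichiometry"), "1"))
      stats::setNames(st, xml2::xml_attr(nd, "species"))
    }
    st <- c(refs("./*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1),
            refs("./*[local-name()='listOfProducts']/*[local-name()='speciesReference']", +1))
    lbp <- fattr(rn, "lowerFluxBound")
    ubp <- fattr(rn, "upperFluxBound")
    assoc <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']/*")
    gpr <- if (inherits(assoc, "xml_missing")) "" else parse_assoc(assoc)
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    tibble::tibble(
      id = id, stoich = list(st),
      lower_bound = if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else if (rev) -1000 else 0,
      upper_bound = if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else 1000,
      subsystem = "", gpr = gpr,
      is_exchange = grepl("^(R_)?EX_", id), is_sink = grepl("^(R_)?(SK|DM)_", id)
    )
  })
  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  genes <- fattr(gp, "id")
  obj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  objective_id <- if (inherits(obj, "xml_missing")) NA_character_ else fattr(obj, "reaction")
  metabolic_model(
    metabolites = mets, reactions = dplyr::bind_rows(rows), genes = genes,
    objective_id = objective_id
  )
}

#' Read / write a medium composition table
#'
#' A medium is a two-column table `exchange_id`, `max_uptake` (flux units):
#' the maximum uptake rate allowed through each exchange reaction.
#'
#' @param path TSV file path.
#' @return [read_medium()] returns a named numeric vector of uptake limits.
#' @export
read_medium <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$max_uptake, df$exchange_id)
}

#' @rdname read_medium
#' @param medium Named numeric vector (names = exchange ids).
#' @export
write_medium <- function(medium, path) {
  utils::write.table(
    data.frame(exchange_id = names(medium), max_uptake = unname(medium)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
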