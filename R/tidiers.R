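#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy / glance methods
#'
#' Broom-style accessors: `tidy()` returns the long per-observation tibble
#' of a result object, `glance()` a one-row summary.
#'
#' @param x A package result object.
#' @param ... Unused.
#' @name cblflux-tidiers
NULL

#' @rdname cblflux-tidiers
#' @export
tidy.fba_solution <- function(x, ...) x$fluxes

#' @rdname cblflux-tidiers
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_id = x$objective_id,
                 sense = x$sense, objective_value = x$objective_value)
}

#' @rdname cblflux-tidiers
#' @export
tidy.fva_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname cblflux-tidiers
#' @export
glance.fva_result <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x),
    fraction = attr(x, "fraction"),
    optimum = attr(x, "optimum"),
    objective_id = attr(x, "objective_id")
  )
}

#' @rdname cblflux-tidiers
#' @export
tidy.scenario_battery <- function(x, ...) {
  purrr::imap_dfr(x$spans, function(span, nm) {
    kind <- x$scenarios$kind[match(nm, x$scenarios$name)]
    dplyr::mutate(tidy(span), scenario = nm, kind = kind, .before = 1)
  })
}

#' @rdname cblflux-tidiers
#' @export
glance.scenario_battery <- function(x, ...) {
  tibble::tibble(
    n_scenarios = length(x$spans),
    n_gene_ko = sum(x$scenarios$kind == "gene_ko"),
    n_reactions = nrow(x$spans[[1]]),
    fraction = x$fraction
  )
}

#' @rdname cblflux-tidiers
#' @export
tidy.scenario_clusters <- function(x, ...) x$assignments

#' @rdname cblflux-tidiers
#' @export
glance.scenario_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    n_scenarios = nrow(x$assignments),
    max_merge_height = max(x$merges$height),
    n_features = ncol(x$features)
  )
}

#' @rdname cblflux-tidiers
#' @export
tidy.diff_flux_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname cblflux-tidiers
#' @export
glance.diff_flux_result <- function(x, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison"),
    n_a = attr(x, "n_a"),
    n_b = attr(x, "n_b"),
    n_features = nrow(x),
    n_tested = sum(!x$excluded),
    n_excluded = sum(x$excluded),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' @rdname cblflux-tidiers
#' @export
tidy.symptom_assoc_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname cblflux-tidiers
#' @export
glance.symptom_assoc_result <- function(x, ...) {
  by_sym <- if (nrow(x)) {
    tibble::as_tibble(unclass(x)) |>
      dplyr::group_by(.data$symptom) |>
      dplyr::summarise(n_sig = sum(.data$significant, na.rm = TRUE),
                       .groups = "drop")
  } else {
    tibble::tibble(symptom = character(), n_sig = integer())
  }
  tibble::tibble(
    stratum = attr(x, "stratum"),
    n_symptoms_tested = length(unique(x$symptom)),
    n_symptoms_skipped = length(attr(x, "skipped")),
    n_significant = sum(by_sym$n_sig),
    min_carriers = attr(x, "min_carriers"),
    alpha = attr(x, "alpha")
  )
}

#' @rdname cblflux-tidiers
#' @export
glance.context_model <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    n_reactions = nrow(x$model$reactions),
    n_metabolites = nrow(x$model$metabolites),
    n_genes = length(x$model$genes),
    n_core = length(x$core_reactions),
    n_gapfilled = length(x$gapfilled_reactions),
    n_inconsistent_core = length(x$inconsistent_core)
  )
}

#' @rdname cblflux-tidiers
#' @export
tidy.personalized_cohort <- function(x, ...) {
  out <- purrr::map_dfr(x$contexts, glance)
  dplyr::left_join(out, x$metadata[, c("sample_id", "group")], by = "sample_id")
}

#' @rdname cblflux-tidiers
#' @export
glance.personalized_cohort <- function(x, ...) {
  sizes <- tidy(x)
  tibble::tibble(
    n_models = nrow(sizes),
    mean_reactions = mean(sizes$n_reactions),
    mean_metabolites = mean(sizes$n_metabolites),
    mean_genes = mean(sizes$n_genes),
    n_gapfilled_models = sum(sizes$n_gapfilled > 0)
  )
}

#' @rdname cblflux-tidiers
#' @export
tidy.gene_calls <- function(x, ...) {
  tibble::as_tibble(x$status, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "status")
}

#' @rdname cblflux-tidiers
#' @export
glance.synthetic_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  tibble::tibble(
    n_samples = nrow(x$metadata),
    n_genes = nrow(x$expression),
    n_control = sum(x$metadata$group == "control"),
    n_mut0 = sum(x$metadata$group == "mut0"),
    n_mutminus = sum(x$metadata$group == "mutminus"),
    n_other = sum(x$metadata$group == "other"),
    units = x$units
  )
}
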