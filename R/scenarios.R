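#' The inborn errors of cobalamin metabolism captured by the fixture
#'
#' The eleven disease genes of the knockout battery with their
#' complementation groups.
#'
#' @return A tibble with columns `group`, `gene`, `disease`.
#' @export
iecm_gene_table <- function() {
  tibble::tribble(
    ~group,  ~gene,     ~disease,
    "cblA",  "MMAA",    "Methylmalonic aciduria type cblA",
    "cblB",  "MMAB",    "Methylmalonic aciduria type cblB",
    "cblC",  "MMACHC",  "Methylmalonic aciduria and homocystinuria type cblC",
    "cblD",  "MMADHC",  "Methylmalonic aciduria and homocystinuria type cblD",
    "cblE",  "MTRR",    "Homocystinuria-megaloblastic anemia type cblE",
    "cblF",  "LMBRD1",  "Methylmalonic aciduria and homocystinuria type cblF",
    "cblG",  "MTR",     "Homocystinuria-megaloblastic anemia type cblG",
    "cblJ",  "ABCD4",   "Methylmalonic aciduria and homocystinuria type cblJ",
    "CD320", "CD320",   "Methylmalonic aciduria due to transcobalamin receptor defect",
    "mut",   "MMUT",    "Methylmalonic aciduria due to methylmalonyl-CoA mutase deficiency",
    "TCN2",  "TCN2",    "Transcobalamin II deficiency"
  )
}

#' Default scenario battery: wild type, eleven knockouts, deficiency
#'
#' @return A tibble with columns `name`, `kind` (`wild_type`, `gene_ko`,
#'   `deficiency`) and `genes` (list column).
#' @export
default_scenarios <- function() {
  genes <- iecm_gene_table()$gene
  dplyr::bind_rows(
    tibble::tibble(name = "WT", kind = "wild_type", genes = list(character())),
    tibble::tibble(name = genes, kind = "gene_ko",
                   genes = lapply(genes, identity)),
    tibble::tibble(name = "No_B12", kind = "deficiency", genes = list(character()))
  )
}

#' Run the knockout / deficiency scenario battery
#'
#' For each scenario the model is perturbed (gene deletion via
#' [delete_genes()], deficiency via [close_cobalamin_uptake()], nothing for
#' the wild type) and flux spans are computed with [run_fva()] at the given
#' fraction of the biomass optimum.
#'
#' @param model A `metabolic_model` (medium applied).
#' @param scenarios Scenario tibble as from [default_scenarios()]; must
#'   contain exactly one `wild_type` row.
#' @param fraction Fraction of optimum for FVA (default 0.99).
#' @return An object of class `scenario_battery`: list with `spans` (named
#'   list of `fva_result` tibbles, scenario order), `scenarios`, `fraction`.
#' @examples
#' \donttest{
#' bat <- run_scenario_battery(build_fixture_model())
#' names(bat$spans)
#' }
#' @export
run_scenario_battery <- function(model, scenarios = default_scenarios(),
                                 fraction = 0.99) {
  scenarios <- tibble::as_tibble(scenarios)
  if (sum(scenarios$kind == "wild_type") != 1) {
    stop("scenario battery must contain exactly one wild-type scenario",
         call. = FALSE)
  }
  bad <- setdiff(unlist(scenarios$genes[scenarios$kind == "gene_ko"]), model$genes)
  if (length(bad)) {
    stop("scenario battery cites gene(s) absent from model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  spans <- vector("list", nrow(scenarios))
  names(spans) <- scenarios$name
  for (i in seq_len(nrow(scenarios))) {
    pert <- switch(scenarios$kind[i],
      wild_type = model,
      gene_ko = delete_genes(model, scenarios$genes[[i]]),
      deficiency = close_cobalamin_uptake(model),
      stop("unknown scenario kind: ", scenarios$kind[i], call. = FALSE)
    )
    spans[[i]] <- tryCatch(
      run_fva(pert, fraction = fraction),
      error = function(e) {
        stop("scenario '", scenarios$name[i], "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  structure(list(spans = spans, scenarios = scenarios, fraction = fraction),
            class = "scenario_battery")
}

#' @export
print.scenario_battery <- function(x, ...) {
  cat("<scenario_battery> ", length(x$spans), " scenarios (",
      paste(x$scenarios$kind, collapse = ", "), ") at fraction ",
      x$fraction, "\n", sep = "")
  invisible(x)
}

# Bound-wise flux fraction relative to wild type. WT-zero bounds use an
# absolute floor so ratios stay defined; identical zero bounds give 1.
flux_fraction <- function(v, wt, floor = 1e-6) {
  out <- numeric(length(v))
  big <- abs(wt) > floor
  out[big] <- v[big] / wt[big]
  small <- !big & abs(v) <= floor
  out[small] <- 1
  rest <- !big & !small
  out[rest] <- v[rest] / floor
  out
}

#' Classify reactions affected by a scenario
#'
#' A reaction counts as affected when its minimal or maximal flux moved by
#' at least `threshold` times the wild-type span scale
#' (`max(|min_wt|, |max_wt|, floor)`). The reported `fraction_of_wt` is the
#' scenario/wild-type ratio on the bound of larger wild-type magnitude (the
#' quantity displayed in fraction-of-wild-type heatmaps).
#'
#' @param wt,scenario `fva_result` tibbles over the same reactions.
#' @param threshold Relative change needed to call a reaction affected
#'   (default 0.10; 0.05 reproduces the more sensitive reporting style).
#' @param floor Absolute floor for wild-type-zero reactions.
#' @return Tibble: `reaction_id`, `affected`, `fraction_of_wt`, `min_fraction`,
#'   `max_fraction`.
#' @export
classify_affected <- function(wt, scenario, threshold = 0.10, floor = 1e-6) {
  stopifnot(identical(wt$reaction_id, scenario$reaction_id))
  scale <- pmax(abs(wt$min_flux), abs(wt$max_flux), floor)
  d_min <- abs(scenario$min_flux - wt$min_flux)
  d_max <- abs(scenario$max_flux - wt$max_flux)
  affected <- d_min >= threshold * scale | d_max >= threshold * scale
  use_max <- abs(wt$max_flux) >= abs(wt$min_flux)
  frac <- ifelse(use_max,
                 flux_fraction(scenario$max_flux, wt$max_flux, floor),
                 flux_fraction(scenario$min_flux, wt$min_flux, floor))
  tibble::tibble(
    reaction_id = wt$reaction_id,
    affected = affected,
    fraction_of_wt = frac,
    min_fraction = flux_fraction(scenario$min_flux, wt$min_flux, floor),
    max_fraction = flux_fraction(scenario$max_flux, wt$max_flux, floor)
  )
}

#' Affected-flux table for a whole battery
#'
#' @param battery A `scenario_battery`.
#' @inheritParams classify_affected
#' @return Long tibble: `scenario`, `kind`, `reaction_id`, `affected`,
#'   `fraction_of_wt`, `min_fraction`, `max_fraction`.
#' @export
battery_affected <- function(battery, threshold = 0.10, floor = 1e-6) {
  wt_name <- battery$scenarios$name[battery$scenarios$kind == "wild_type"]
  wt <- battery$spans[[wt_name]]
  purrr::imap_dfr(battery$spans, function(span, nm) {
    cls <- classify_affected(wt, span, threshold = threshold, floor = floor)
    kind <- battery$scenarios$kind[match(nm, battery$scenarios$name)]
    dplyr::mutate(cls, scenario = nm, kind = kind, .before = 1)
  })
}

#' Hierarchically cluster the scenarios of a battery
#'
#' Scenarios are described by their bound-wise flux fractions relative to
#' wild type over every reaction affected in at least one non-wild-type
#' scenario (minimum and maximum columns concatenated), then clustered with
#' Euclidean distance and complete linkage. Flat clusters are obtained by
#' cutting at the largest gap between consecutive merge heights; clusters
#' are numbered by first scenario appearance (battery order), so the
#' wild-type cluster is cluster 1.
#'
#' @param battery A `scenario_battery` (at least two scenarios).
#' @inheritParams classify_affected
#' @return An object of class `scenario_clusters`: list with `assignments`
#'   (tibble `scenario`, `kind`, `cluster`), `n_clusters`, `merges` (tibble
#'   of merge heights), `hclust`, and `features` (the scenario-by-feature
#'   matrix used).
#' @export
cluster_scenarios <- function(battery, threshold = 0.10, floor = 1e-6) {
  if (length(battery$spans) < 2) {
    stop("need at least two scenarios to cluster", call. = FALSE)
  }
  aff <- battery_affected(battery, threshold = threshold, floor = floor)
  keep <- aff |>
    dplyr::filter(.data$kind != "wild_type", .data$affected) |>
    dplyr::pull(.data$reaction_id) |>
    unique()
  if (!length(keep)) {
    stop("no reaction is affected in any scenario; nothing to cluster",
         call. = FALSE)
  }
  # Feature matrix: per affected reaction, the change of the minimal and the
  # maximal flux against wild type, in flux units. Keeping flux units (rather
  # than per-reaction ratios) weights reactions by the amount of flux they
  # lose, so scenarios that silence the same central pathways cluster
  # together even when they differ on low-flux bookkeeping reactions;
  # ratios are still what the affected-flux reports display.
  wt_name <- battery$scenarios$name[battery$scenarios$kind == "wild_type"]
  wt <- battery$spans[[wt_name]]
  sel <- match(keep, wt$reaction_id)
  feat <- t(vapply(battery$spans, function(span) {
    c(span$min_flux[sel] - wt$min_flux[sel],
      span$max_flux[sel] - wt$max_flux[sel])
  }, numeric(2 * length(sel))))
  colnames(feat) <- c(paste0("min|", keep), paste0("max|", keep))
  rownames(feat) <- names(battery$spans)
  hc <- stats::hclust(stats::dist(feat, method = "euclidean"),
                      method = "complete")
  h <- hc$height
  n <- nrow(feat)
  tol <- 1e-9
  if (length(h) == 1L) {
    k <- if (h[1] > tol) 2L else 1L
  } else if (max(h) <= tol) {
    k <- 1L
  } else {
    g <- which.max(diff(h))
    k <- n - g
  }
  cl <- stats::cutree(hc, k = k)
  # renumber clusters by order of first appearance in battery order
  first <- vapply(unique(cl[rownames(feat)]), function(x) x, integer(1))
  relabel <- stats::setNames(seq_along(first), first)
  cl <- as.integer(relabel[as.character(cl)])
  assignments <- tibble::tibble(
    scenario = rownames(feat),
    kind = battery$scenarios$kind[match(rownames(feat), battery$scenarios$name)],
    cluster = cl
  )
  structure(
    list(assignments = assignments, n_clusters = k,
         merges = tibble::tibble(step = seq_along(h), height = h),
         hclust = hc, features = feat),
    class = "scenario_clusters"
  )
}

#' @export
print.scenario_clusters <- function(x, ...) {
  cat("<scenario_clusters> ", x$n_clusters, " clusters over ",
      nrow(x$assignments), " scenarios\n", sep = "")
  for (k in sort(unique(x$assignments$cluster))) {
    cat("  ", k, ": ",
        paste(x$assignments$scenario[x$assignments$cluster == k],
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
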