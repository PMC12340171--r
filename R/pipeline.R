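#' Run the full in-silico study end to end
#'
#' Orchestrates every stage on the fixture network: the wild-type /
#' knockout / deficiency scenario battery with affected-flux classification
#' and scenario clustering; synthetic-cohort generation; per-sample model
#' personalization; flux-span and production-potential interrogation; and
#' group / symptom differential-flux statistics. All outputs are written as
#' TSV (plus a JSON manifest with the configuration, its MD5 hash, the
#' package version and the seed), so re-running with an identical
#' configuration reproduces identical files.
#'
#' @param outdir Output directory (created; must be empty or absent).
#' @param model Parent model (default [build_fixture_model()]).
#' @param design Cohort design (default [cohort_design()] with `seed`).
#' @param seed Integer seed; overrides `design$seed`.
#' @param fva_fraction Fraction of optimum for all FVA calls (0.99).
#' @param affected_threshold Affected-flux threshold (0.10; the
#'   more sensitive 0.05 report is written alongside).
#' @param eflux_cap eFlux bound cap (1000).
#' @param epsilon Flux-support threshold (1e-4).
#' @param fdr_method `"bh"` or `"storey"`.
#' @param alpha Significance level on q (0.05).
#' @param min_carriers Minimum symptom carriers (8).
#' @param potential_metabolites Metabolites to probe for production
#'   potential (default: all model metabolites).
#' @return Invisibly, a list with the in-memory results (`battery`,
#'   `clusters`, `cohort`, `personalized`, `comparisons`, `symptoms`,
#'   `manifest`).
#' @export
run_full_study <- function(outdir,
                           model = build_fixture_model(),
                           design = cohort_design(seed = seed),
                           seed = 1L,
                           fva_fraction = 0.99,
                           affected_threshold = 0.10,
                           eflux_cap = 1000,
                           epsilon = 1e-4,
                           fdr_method = "bh",
                           alpha = 0.05,
                           min_carriers = 8,
                           potential_metabolites = NULL) {
  if (dir.exists(outdir) && length(list.files(outdir))) {
    stop("output directory exists and is not empty: ", outdir, call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  tsv <- function(df, file) {
    utils::write.table(as.data.frame(df), file.path(outdir, file),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  config <- list(
    seed = seed, fva_fraction = fva_fraction,
    affected_threshold = affected_threshold, eflux_cap = eflux_cap,
    epsilon = epsilon, fdr_method = fdr_method, alpha = alpha,
    min_carriers = min_carriers,
    design = list(n_control = design$n_control, n_mut0 = design$n_mut0,
                  n_mutminus = design$n_mutminus, n_other = design$n_other,
                  seed = design$seed)
  )

  battery <- stage("scenario_battery", {
    run_scenario_battery(model, fraction = fva_fraction)
  })
  clusters <- stage("cluster_scenarios", {
    cluster_scenarios(battery, threshold = affected_threshold)
  })
  stage("write_battery", {
    tsv(tidy(battery), "scenario_spans.tsv")
    tsv(battery_affected(battery, threshold = affected_threshold),
        "affected_fluxes.tsv")
    tsv(battery_affected(battery, threshold = 0.05),
        "affected_fluxes_sensitive.tsv")
    tsv(tidy(clusters), "scenario_clusters.tsv")
    tsv(clusters$merges, "cluster_merges.tsv")
  })

  cohort <- stage("simulate_cohort", generate_cohort(design))
  stage("write_cohort", {
    tsv(cohort$expression, "expression_rpkm.tsv")
    tsv(cohort$metadata, "metadata.tsv")
  })

  personalized <- stage("personalize", {
    personalize_cohort(model, cohort, epsilon = epsilon,
                       eflux_cap = eflux_cap)
  })
  stage("write_models", tsv(tidy(personalized), "personalized_models.tsv"))

  spans <- stage("fva", cohort_flux_spans(personalized,
                                          fraction = fva_fraction))
  fm <- stage("flux_matrix", collect_flux_matrix(spans))
  pots <- stage("production_potential", {
    cohort_production_potentials(personalized,
                                 metabolites = potential_metabolites)
  })
  pm <- stage("production_matrix",
              collect_flux_matrix(pots, mode = "production"))
  stage("write_matrices", {
    tsv(fm, "flux_matrix.tsv")
    tsv(pm, "production_matrix.tsv")
  })

  comparisons <- list()
  for (cmp in c("control-vs-mut0", "control-vs-mutminus",
                "mut0-vs-mutminus", "control-vs-other")) {
    groups <- parse_comparison(cmp)
    if (!all(groups %in% cohort$metadata$group)) next
    comparisons[[cmp]] <- stage(paste0("compare_", cmp), {
      dplyr::bind_rows(
        dplyr::mutate(tidy(compare_groups(fm, cohort$metadata, cmp,
                                          fdr_method = fdr_method,
                                          alpha = alpha)),
                      matrix = "flux"),
        dplyr::mutate(tidy(compare_groups(pm, cohort$metadata, cmp,
                                          fdr_method = fdr_method,
                                          alpha = alpha)),
                      matrix = "production")
      ) |> dplyr::mutate(comparison = cmp)
    })
  }
  stage("write_comparisons",
        tsv(dplyr::bind_rows(comparisons), "differential_flux.tsv"))

  symptoms <- list()
  for (st in c("mut", "other")) {
    if (st == "mut" &&
        !any(cohort$metadata$group %in% c("mut0", "mutminus"))) next
    if (st == "other" && !any(cohort$metadata$group == "other")) next
    symptoms[[st]] <- stage(paste0("symptoms_", st), {
      dplyr::bind_rows(
        dplyr::mutate(tidy(associate_symptoms(fm, cohort$metadata, st,
                                              min_carriers = min_carriers,
                                              fdr_method = fdr_method,
                                              alpha = alpha)),
                      matrix = "flux"),
        dplyr::mutate(tidy(associate_symptoms(pm, cohort$metadata, st,
                                              min_carriers = min_carriers,
                                              fdr_method = fdr_method,
                                              alpha = alpha)),
                      matrix = "production")
      ) |> dplyr::mutate(stratum = st)
    })
  }
  stage("write_symptoms",
        tsv(dplyr::bind_rows(symptoms), "symptom_associations.tsv"))

  manifest <- stage("manifest", {
    cfg_path <- file.path(outdir, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
    m <- list(
      package = "cblflux",
      version = as.character(utils::packageVersion("cblflux")),
      seed = seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      n_scenarios = length(battery$spans),
      n_clusters = clusters$n_clusters,
      n_models = length(personalized$contexts),
      summary = as.list(glance(personalized))
    )
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(list(battery = battery, clusters = clusters, cohort = cohort,
                 personalized = personalized, flux_matrix = fm,
                 production_matrix = pm, comparisons = comparisons,
                 symptoms = symptoms, manifest = manifest))
}
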