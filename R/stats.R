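# Differential-flux and production-potential statistics across sample
# groups and symptom strata.

#' Assemble a feature-by-sample flux matrix
#'
#' Rows are `min|<reaction>` and `max|<reaction>` flux bounds (or
#' `production|<metabolite>` potentials), columns are samples. Reactions
#' absent from a sample's personalized model count as zero flux; magnitudes
#' below `zero_tol` are snapped to zero; rows that are zero in every sample
#' are dropped (the retention rule: a feature is kept when it is nonzero in
#' at least one model).
#'
#' @param spans Named list (sample id -> `fva_result` tibble, or for
#'   `mode = "production"` a tibble with `metabolite_id` and `potential`).
#' @param mode `"both"` (min and max rows), `"min"`, `"max"`, or
#'   `"production"`.
#' @param universe Feature universe (reaction or metabolite ids); defaults
#'   to the union observed across samples.
#' @param zero_tol Magnitude below which a flux counts as zero.
#' @return A tibble of class `flux_matrix`: `feature_id`, `type`, one
#'   column per sample.
#' @export
collect_flux_matrix <- function(spans, mode = c("both", "min", "max", "production"),
                                universe = NULL, zero_tol = 1e-9) {
  mode <- match.arg(mode)
  ids <- names(spans)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("spans must be a named list (sample ids)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  key_col <- if (mode == "production") "metabolite_id" else "reaction_id"
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(spans, function(s) s[[key_col]])))
  }
  grab <- function(span, col) {
    v <- span[[col]][match(universe, span[[key_col]])]
    v[is.na(v)] <- 0
    v[abs(v) < zero_tol] <- 0
    v
  }
  blocks <- list()
  if (mode %in% c("both", "min")) {
    blocks$min <- vapply(spans, grab, numeric(length(universe)), col = "min_flux")
  }
  if (mode %in% c("both", "max")) {
    blocks$max <- vapply(spans, grab, numeric(length(universe)), col = "max_flux")
  }
  if (mode == "production") {
    blocks$production <- vapply(spans, grab, numeric(length(universe)),
                                col = "potential")
  }
  out <- purrr::imap_dfr(blocks, function(m, type) {
    m <- matrix(m, nrow = length(universe), dimnames = list(NULL, ids))
    dplyr::bind_cols(
      tibble::tibble(feature_id = paste0(type, "|", universe), type = type),
      tibble::as_tibble(m)
    )
  })
  keep <- rowSums(abs(as.matrix(out[, ids, drop = FALSE])) > 0) > 0
  out <- out[keep, ]
  class(out) <- c("flux_matrix", class(out))
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test: exact by enumeration when the smaller group has
#' at most eight values and the data are tie-free, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return Tibble with `statistic` (Mann-Whitney U of `a` vs `b`),
#'   `p_value`, `method` (`"exact"` or `"normal"`).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  if (max(c(a, b)) - min(c(a, b)) == 0) {
    # every observation identical: no evidence against the null
    return(tibble::tibble(statistic = length(a) * length(b) / 2,
                          p_value = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = min(1, wt$p.value),
    method = if (exact) "exact" else "normal"
  )
}

# Storey-style pi0 estimate by spline smoothing of pi0(lambda).
estimate_pi0 <- function(p) {
  lambda <- seq(0.05, 0.9, by = 0.05)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- tryCatch(stats::smooth.spline(lambda, pi0l, df = 3),
                  error = function(e) NULL)
  pi0 <- if (is.null(fit)) min(pi0l) else
    stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-3), 1)
}

#' Adjust p-values for multiple testing with feature exclusion
#'
#' Excluded features (zero or constant flux across all compared samples)
#' receive `NA` and do not count toward the number of tests. The default is
#' Benjamini-Hochberg; `method = "storey"` additionally scales by a
#' spline-smoothed estimate of the null proportion pi0.
#'
#' @param p P-values (may contain `NA` for excluded features).
#' @param exclude Logical mask of excluded features (same length).
#' @param method `"bh"` or `"storey"`.
#' @return Numeric vector of q-values (`NA` where excluded).
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))
#' @export
adjust_fdr <- function(p, exclude = NULL, method = c("bh", "storey")) {
  method <- match.arg(method)
  exclude <- exclude %||% rep(FALSE, length(p))
  use <- !exclude & !is.na(p)
  q <- rep(NA_real_, length(p))
  if (!any(use)) return(q)
  qb <- stats::p.adjust(p[use], method = "BH")
  if (method == "storey") {
    qb <- pmin(1, qb * estimate_pi0(p[use]))
  }
  q[use] <- qb
  q
}

parse_comparison <- function(comparison) {
  known <- c("control-vs-mut0", "control-vs-mutminus", "mut0-vs-mutminus",
             "control-vs-other")
  if (!comparison %in% known) {
    stop("unknown comparison '", comparison, "'; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  strsplit(comparison, "-vs-", fixed = TRUE)[[1]]
}

diff_flux_table <- function(matrix_tbl, sa, sb, label_a, label_b,
                            fdr_method, alpha, zero_tol = 1e-9) {
  ma <- as.matrix(matrix_tbl[, sa, drop = FALSE])
  mb <- as.matrix(matrix_tbl[, sb, drop = FALSE])
  both <- cbind(ma, mb)
  # constant-feature exclusion on the union of the compared samples,
  # strict equality after the zero snap
  excl <- apply(both, 1, function(v) length(unique(v)) == 1)
  tests <- purrr::map_dfr(seq_len(nrow(both)), function(i) {
    if (excl[i]) {
      return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                            method = NA_character_))
    }
    rank_sum_test(ma[i, ], mb[i, ])
  })
  med_a <- apply(ma, 1, stats::median)
  med_b <- apply(mb, 1, stats::median)
  out <- tibble::tibble(
    feature_id = matrix_tbl$feature_id,
    type = matrix_tbl$type,
    median_a = med_a,
    median_b = med_b,
    statistic = tests$statistic,
    p_value = tests$p_value,
    q_value = adjust_fdr(tests$p_value, exclude = excl, method = fdr_method),
    direction = dplyr::case_when(
      excl ~ NA_character_,
      med_a > med_b + zero_tol ~ paste0("higher_in_", label_a),
      med_b > med_a + zero_tol ~ paste0("higher_in_", label_b),
      TRUE ~ "tied_medians"
    ),
    excluded = excl
  )
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  dplyr::arrange(out, dplyr::desc(!out$excluded), .data$q_value,
                 .data$feature_id)
}

#' Differential flux between two sample groups
#'
#' Per retained feature of a flux matrix: a two-sided rank-sum test between
#' the two groups with constant-feature exclusion, FDR adjustment, group
#' medians and direction. Results are sorted by q-value, then feature id.
#'
#' @param matrix_tbl A `flux_matrix` from [collect_flux_matrix()].
#' @param metadata Tibble with `sample_id` and `group` (values among
#'   `control`, `mut0`, `mutminus`, `other`).
#' @param comparison One of `"control-vs-mut0"`, `"control-vs-mutminus"`,
#'   `"mut0-vs-mutminus"`, `"control-vs-other"`.
#' @param fdr_method `"bh"` or `"storey"`.
#' @param alpha Significance threshold on q (default 0.05).
#' @return A tibble of class `diff_flux_result` with columns `feature_id`,
#'   `type`, `median_a`, `median_b`, `statistic`, `p_value`, `q_value`,
#'   `direction`, `excluded`, `significant`.
#' @export
compare_groups <- function(matrix_tbl, metadata, comparison,
                           fdr_method = c("bh", "storey"), alpha = 0.05) {
  fdr_method <- match.arg(fdr_method)
  gg <- parse_comparison(comparison)
  samples <- colnames(matrix_tbl)[-(1:2)]
  sa <- intersect(samples, metadata$sample_id[metadata$group == gg[1]])
  sb <- intersect(samples, metadata$sample_id[metadata$group == gg[2]])
  if (!length(sa) || !length(sb)) {
    stop("comparison '", comparison, "' has an empty group in this matrix",
         call. = FALSE)
  }
  out <- diff_flux_table(matrix_tbl, sa, sb, gg[1], gg[2], fdr_method, alpha)
  structure(out, class = c("diff_flux_result", class(tibble::tibble())),
            comparison = comparison, alpha = alpha,
            n_a = length(sa), n_b = length(sb))
}

#' Flux-symptom association within a patient stratum
#'
#' Within the chosen stratum (`"mut"` = mut0 + mut-, `"other"` = other-MMA),
#' each symptom with at least `min_carriers` carriers is tested by a
#' present-vs-absent group comparison per feature. Symptom absence means
#' absent *or not reported*. Symptoms below the carrier threshold are
#' skipped and listed in the `skipped` attribute.
#'
#' @param matrix_tbl A `flux_matrix`.
#' @param metadata Metadata tibble with `sample_id`, `group`, and 0/1
#'   symptom columns.
#' @param stratum `"mut"` or `"other"`.
#' @param min_carriers Minimum carrier count for a symptom to be tested.
#' @param symptoms Symptom columns to consider (default: all 0/1 columns).
#' @inheritParams compare_groups
#' @return Tibble of class `symptom_assoc_result`: per-symptom differential
#'   tables bound together with a `symptom` column; attribute `skipped`
#'   lists symptoms below the carrier threshold.
#' @export
associate_symptoms <- function(matrix_tbl, metadata, stratum = c("mut", "other"),
                               min_carriers = 8, symptoms = NULL,
                               fdr_method = c("bh", "storey"), alpha = 0.05) {
  stratum <- match.arg(stratum)
  fdr_method <- match.arg(fdr_method)
  groups <- if (stratum == "mut") c("mut0", "mutminus") else "other"
  samples <- intersect(colnames(matrix_tbl)[-(1:2)],
                       metadata$sample_id[metadata$group %in% groups])
  meta <- metadata[match(samples, metadata$sample_id), ]
  if (is.null(symptoms)) {
    symptoms <- setdiff(names(meta), c("sample_id", "group"))
    symptoms <- symptoms[vapply(symptoms, function(s) {
      all(meta[[s]] %in% c(0, 1))
    }, logical(1))]
  }
  skipped <- character()
  res <- list()
  for (sym in symptoms) {
    carriers <- samples[meta[[sym]] == 1]
    noncarr <- samples[meta[[sym]] == 0]
    if (length(carriers) < min_carriers || !length(noncarr)) {
      skipped <- c(skipped, sym)
      message("skipping symptom '", sym, "': ", length(carriers),
              " carrier(s) in stratum '", stratum, "'")
      next
    }
    tab <- diff_flux_table(matrix_tbl, carriers, noncarr, "present", "absent",
                           fdr_method, alpha)
    tab$symptom <- sym
    res[[sym]] <- tab
  }
  out <- if (length(res)) dplyr::bind_rows(res) else {
    tibble::tibble(feature_id = character(), type = character(),
                   median_a = numeric(), median_b = numeric(),
                   statistic = numeric(), p_value = numeric(),
                   q_value = numeric(), direction = character(),
                   excluded = logical(), significant = logical(),
                   symptom = character())
  }
  structure(out, class = c("symptom_assoc_result", class(tibble::tibble())),
            stratum = stratum, min_carriers = min_carriers, alpha = alpha,
            skipped = skipped)
}

#' Flux spans for every model of a personalized cohort
#'
#' Runs [run_fva()] on each personalized model (biomass objective, given
#' fraction of each model's own optimum).
#'
#' @param pcohort A `personalized_cohort`.
#' @param fraction Fraction of optimum (default 0.99).
#' @return Named list of `fva_result` tibbles.
#' @export
cohort_flux_spans <- function(pcohort, fraction = 0.99) {
  lapply(pcohort$contexts, function(ctx) run_fva(ctx$model, fraction = fraction))
}

#' Production potentials for every model of a personalized cohort
#'
#' @param pcohort A `personalized_cohort`.
#' @param metabolites Metabolite ids to probe (default: all metabolites of
#'   each model).
#' @return Named list of tibbles (`metabolite_id`, `potential`).
#' @export
cohort_production_potentials <- function(pcohort, metabolites = NULL) {
  lapply(pcohort$contexts, function(ctx) {
    mets <- metabolites %||% ctx$model$metabolites$id
    mets <- intersect(mets, ctx$model$metabolites$id)
    tibble::tibble(
      metabolite_id = mets,
      potential = vapply(mets, function(m) {
        production_potential(ctx$model, m)
      }, numeric(1))
    )
  })
}
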