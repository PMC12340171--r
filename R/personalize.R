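# Transcriptome-driven model personalization: unit conversion, gene-id
# mapping, mixture-model active-gene calling, FASTCORE-style context
# extraction, biomass gap-filling, and eFlux bound scaling.

#' Convert an RPKM expression table to TPM
#'
#' TPM rescales each sample so its values sum to one million:
#' `TPM_i = RPKM_i / sum_j RPKM_j * 1e6`.
#'
#' @param expression Tibble with `gene_id` first and one numeric column per
#'   sample, or a `synthetic_cohort`.
#' @param units Units of the input (`"rpkm"` or `"tpm"`). Passing TPM input
#'   with `strict = TRUE` (default) is an error; with `strict = FALSE` it is
#'   returned unchanged.
#' @param strict Guard against double conversion.
#' @return The expression tibble in TPM (attribute `units = "tpm"`).
#' @export
rpkm_to_tpm <- function(expression, units = NULL, strict = TRUE) {
  if (inherits(expression, "synthetic_cohort")) {
    units <- units %||% expression$units
    expression <- expression$expression
  }
  units <- tolower(units %||% attr(expression, "units") %||% "rpkm")
  if (units == "tpm") {
    if (strict) stop("input is already in TPM", call. = FALSE)
    attr(expression, "units") <- "tpm"
    return(expression)
  }
  out <- expression
  for (col in names(out)[-1]) {
    v <- out[[col]]
    if (any(v < 0)) stop("negative expression in sample ", col, call. = FALSE)
    tot <- sum(v)
    if (tot <= 0) stop("all-zero expression profile: ", col, call. = FALSE)
    out[[col]] <- v / tot * 1e6
  }
  attr(out, "units") <- "tpm"
  out
}

#' Map expression gene identifiers onto model genes
#'
#' Applies a symbol-to-locus mapping table (identity when `mapping` is
#' `NULL`), sums rows that map to the same target (with a warning), and
#' drops genes absent from the model (count reported via message).
#'
#' @param expression Expression tibble (`gene_id` + sample columns).
#' @param model A `metabolic_model`.
#' @param mapping Optional tibble with columns `symbol`, `locus`.
#' @return Expression tibble restricted to model genes.
#' @export
map_gene_ids <- function(expression, model, mapping = NULL) {
  units <- attr(expression, "units")
  if (!is.null(mapping)) {
    idx <- match(expression$gene_id, mapping$symbol)
    expression$gene_id <- ifelse(is.na(idx), expression$gene_id,
                                 mapping$locus[idx])
  }
  if (anyDuplicated(expression$gene_id)) {
    warning("duplicate gene targets after mapping; values summed",
            call. = FALSE)
    expression <- expression |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                       .groups = "drop")
  }
  keep <- expression$gene_id %in% model$genes
  if (any(!keep)) {
    message(sum(!keep), " gene(s) absent from the model were dropped")
  }
  out <- expression[keep, ]
  attr(out, "units") <- units
  out
}

#' Call active genes from a cohort expression matrix
#'
#' Fits a two-component Gaussian mixture to the pooled `log2(TPM + 1)`
#' values of the whole cohort (all genes, all samples). Values whose
#' posterior probability of the expressed component is at least
#' `posterior_cutoff` are called active; values whose posterior of the
#' unexpressed component is at least the cutoff are inactive; everything in
#' between stays unknown (neither forced into the core nor forbidden). If
#' the fit is degenerate (single mode), a percentile threshold is used
#' instead and a message is emitted.
#'
#' @param expression TPM expression tibble (`gene_id` + sample columns).
#' @param posterior_cutoff Posterior needed for a definitive call (0.9).
#' @param fallback_quantile Percentile used when the mixture fit collapses.
#' @return An object of class `gene_calls`: list with `status` (character
#'   matrix genes x samples: `"active"`, `"unknown"`, `"inactive"`),
#'   `thresholds` (log2 boundaries), `method`, and the component means.
#' @export
call_active_genes <- function(expression, posterior_cutoff = 0.9,
                              fallback_quantile = 0.5) {
  genes <- expression$gene_id
  mat <- as.matrix(expression[, -1, drop = FALSE])
  rownames(mat) <- genes
  x <- log2(as.numeric(mat) + 1)
  fit <- tryCatch(
    Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL
  )
  degenerate <- is.null(fit) ||
    abs(diff(fit$parameters$mean)) < 2 * sqrt(max(fit$parameters$variance$sigmasq))
  lx <- log2(mat + 1)
  if (!degenerate) {
    hi <- which.max(fit$parameters$mean)
    post <- predict(fit, newdata = as.numeric(lx))$z[, hi]
    pm <- matrix(post, nrow = nrow(lx), dimnames = dimnames(lx))
    status <- matrix("unknown", nrow(lx), ncol(lx), dimnames = dimnames(lx))
    status[pm >= posterior_cutoff] <- "active"
    status[pm <= 1 - posterior_cutoff] <- "inactive"
    # report approximate value thresholds by grid inversion
    grid <- seq(min(x), max(x), length.out = 512)
    pg <- predict(fit, newdata = grid)$z[, hi]
    lower <- suppressWarnings(max(grid[pg <= 1 - posterior_cutoff]))
    upper <- suppressWarnings(min(grid[pg >= posterior_cutoff]))
    thresholds <- c(inactive_below = lower, active_above = upper)
    method <- "gmm"
    means <- sort(as.numeric(fit$parameters$mean))
  } else {
    message("mixture fit degenerate; falling back to percentile threshold")
    thr <- stats::quantile(x, fallback_quantile, names = FALSE)
    status <- ifelse(lx > thr, "active", "inactive")
    thresholds <- c(inactive_below = thr, active_above = thr)
    method <- "percentile"
    means <- NA_real_
  }
  structure(
    list(status = status, thresholds = thresholds, method = method,
         component_means_log2 = means,
         posterior_cutoff = posterior_cutoff),
    class = "gene_calls"
  )
}

#' @export
print.gene_calls <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("active", "unknown", "inactive")))
  cat("<gene_calls> ", nrow(x$status), " genes x ", ncol(x$status),
      " samples via ", x$method, "\n  ", sep = "")
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Score reactions from gene activity calls
#'
#' Maps gene-level statuses through each reaction's GPR: AND takes the
#' minimum of child statuses, OR the maximum (`active > unknown >
#' inactive`); reactions without gene association are `unknown`.
#'
#' @param model A `metabolic_model`.
#' @param status Named character vector (gene -> `"active"`, `"unknown"`,
#'   `"inactive"`) for one sample, e.g. a column of `gene_calls$status`.
#' @return Tibble `reaction_id`, `activity`.
#' @export
score_reactions <- function(model, status) {
  lev <- c(inactive = 0, unknown = 1, active = 2)
  sc <- lev[status]
  names(sc) <- names(status)
  vals <- vapply(model$gpr_rules, gpr_score, numeric(1), status = sc)
  tibble::tibble(
    reaction_id = model$reactions$id,
    activity = names(lev)[match(vals, lev)]
  )
}

# ---- FASTCORE-style extraction ---------------------------------------------

# LP7: find a flux vector supporting as many reactions of J (in the forward
# sense) as possible at level >= epsilon.
lp7 <- function(p, J, epsilon) {
  m <- nrow(p$A); n <- ncol(p$A); k <- length(J)
  A <- rbind(
    cbind(p$A, matrix(0, m, 2 * k)),
    cbind(matrix(0, k, n), diag(k) * 0, matrix(0, k, k))
  )
  # rows m+1..m+k: v_j - z_j - s_j = 0 with s_j >= 0
  for (t in seq_len(k)) {
    A[m + t, J[t]] <- 1
    A[m + t, n + t] <- -1
    A[m + t, n + k + t] <- -1
  }
  b <- c(p$b, rep(0, k))
  lb <- c(p$lb, rep(0, k), rep(0, k))
  ub <- c(p$ub, rep(epsilon, k), rep(1e9, k))
  obj <- c(rep(0, n), rep(1, k), rep(0, k))
  res <- .cpp_lp_solve(A, b, lb, ub, obj, TRUE)
  if (res$status != 0L) return(NULL)
  res$x[seq_len(n)]
}

# LP10: among fluxes supporting K at >= 0.99*epsilon (scaled up), minimise
# the L1 norm of the penalty set P.
lp10 <- function(p, K, P, epsilon, sf = 1e5) {
  m <- nrow(p$A); n <- ncol(p$A); k <- length(P)
  lb <- p$lb * sf; ub <- p$ub * sf
  lb[K] <- pmax(lb[K], 0.99 * epsilon * sf)
  A <- cbind(p$A, matrix(0, m, 3 * k))
  rows <- matrix(0, 2 * k, n + 3 * k)
  for (t in seq_len(k)) {
    # v_p - z_p + s1 = 0  (s1 >= 0  <=>  v_p <= z_p)
    rows[2 * t - 1, P[t]] <- 1
    rows[2 * t - 1, n + t] <- -1
    rows[2 * t - 1, n + k + t] <- 1
    # v_p + z_p - s2 = 0  (s2 >= 0  <=>  v_p >= -z_p)
    rows[2 * t, P[t]] <- 1
    rows[2 * t, n + t] <- 1
    rows[2 * t, n + 2 * k + t] <- -1
  }
  A <- rbind(A, rows)
  b <- c(p$b, rep(0, 2 * k))
  lb <- c(lb, rep(0, k), rep(0, 2 * k))
  ub <- c(ub, rep(1e9, 3 * k))
  obj <- c(rep(0, n), rep(1, k), rep(0, 2 * k))
  res <- .cpp_lp_solve(A, b, lb, ub, obj, FALSE)
  if (res$status != 0L) return(NULL)
  res$x[seq_len(n)]
}

find_sparse_mode <- function(p, J, P, singleton, epsilon) {
  if (!length(J)) return(integer(0))
  Juse <- if (singleton) J[1] else J
  v <- lp7(p, Juse, epsilon)
  if (is.null(v)) return(integer(0))
  K <- Juse[v[Juse] >= 0.99 * epsilon]
  if (!length(K)) return(integer(0))
  v <- lp10(p, K, P, epsilon)
  if (is.null(v)) return(integer(0))
  which(abs(v) >= 0.99 * epsilon)
}

# Core FASTCORE loop on a flux-consistent model. `core` are indices into the
# model's reactions. Returns indices of the extracted sub-network.
fastcore_indices <- function(model, core, epsilon = 1e-4) {
  p <- lp_parts(model)
  n <- ncol(p$A)
  irrev <- which(p$lb >= 0)
  J <- intersect(core, irrev)
  P <- setdiff(seq_len(n), core)
  flipped <- FALSE; singleton <- FALSE
  A <- find_sparse_mode(p, J, P, singleton, epsilon)
  if (length(setdiff(J, A))) {
    stop("inconsistent irreversible core reactions: ",
         paste(model$reactions$id[setdiff(J, A)], collapse = ", "),
         call. = FALSE)
  }
  J <- setdiff(core, A)
  guard <- 0
  while (length(J)) {
    if ((guard <- guard + 1) > 2 * length(core) + 50) {
      stop("context extraction failed to converge", call. = FALSE)
    }
    P <- setdiff(P, A)
    supp <- find_sparse_mode(p, J, P, singleton, epsilon)
    A <- union(A, supp)
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      JiRev <- setdiff(if (singleton) J[1] else J, irrev)
      if (flipped || !length(JiRev)) {
        if (singleton) {
          stop("inconsistent core reaction: ", model$reactions$id[J[1]],
               call. = FALSE)
        }
        flipped <- FALSE; singleton <- TRUE
      } else {
        # flip the orientation of the reversible candidates
        tmp <- p$lb[JiRev]
        p$lb[JiRev] <- -p$ub[JiRev]
        p$ub[JiRev] <- -tmp
        p$A[, JiRev] <- -p$A[, JiRev]
        flipped <- TRUE
      }
    }
  }
  sort(A)
}

#' Extract a context-specific sub-model around a reaction core
#'
#' FASTCORE-style extraction: the model is first reduced to its
#' flux-consistent part; core reactions outside it are reported (not
#' silently kept). The returned sub-model contains every consistent core
#' reaction, each able to carry `|v| >= epsilon`, plus a near-minimal set of
#' supporting non-core reactions found by alternating two linear programs
#' (maximise the number of core reactions above epsilon, then minimise the
#' L1 flux through non-core reactions).
#'
#' @param model A `metabolic_model` with medium applied and bounds set.
#' @param core Character vector of core reaction ids (non-empty).
#' @param epsilon Flux-support threshold (default 1e-4).
#' @return An object of class `context_model`: list with `model` (the
#'   sub-network), `core_reactions`, `gapfilled_reactions` (empty here),
#'   `inconsistent_core`, and `sample_id` (`NA` until set by the pipeline).
#' @export
extract_context_model <- function(model, core, epsilon = 1e-4) {
  if (!length(core)) stop("empty core", call. = FALSE)
  rxn_index(model, core)  # validates ids
  consistent <- find_flux_consistent(model, epsilon = epsilon)
  inconsistent_core <- setdiff(core, consistent)
  model_c <- subset_reactions(model, consistent)
  core_c <- intersect(core, consistent)
  if (!length(core_c)) {
    stop("no core reaction is flux-consistent under the given constraints",
         call. = FALSE)
  }
  idx <- fastcore_indices(model_c, match(core_c, model_c$reactions$id),
                          epsilon = epsilon)
  sub <- subset_reactions(model_c, model_c$reactions$id[idx])
  structure(
    list(model = sub, core_reactions = core_c,
         gapfilled_reactions = character(),
         inconsistent_core = inconsistent_core,
         sample_id = NA_character_),
    class = "context_model"
  )
}

#' @export
print.context_model <- function(x, ...) {
  cat("<context_model>", if (!is.na(x$sample_id)) x$sample_id else "",
      nrow(x$model$reactions), "reactions;",
      length(x$core_reactions), "core,",
      length(x$gapfilled_reactions), "gap-filled,",
      length(x$inconsistent_core), "inconsistent core\n")
  invisible(x)
}

#' Gap-fill a context model to enable biomass flux
#'
#' If the context already supports biomass at `epsilon`, it is returned
#' unchanged. Otherwise a near-minimal set of parent-model reactions is
#' added: an L1-weighted linear program over the candidate reactions picks
#' a sparse repair, then a deterministic greedy pass prunes additions that
#' are not needed.
#'
#' @param context A `context_model`.
#' @param parent The parent `metabolic_model` the context was extracted
#'   from (same medium).
#' @param epsilon Required biomass flux.
#' @return The `context_model` with `gapfilled_reactions` recorded.
#' @export
gapfill_biomass <- function(context, parent, epsilon = 1e-4) {
  obj <- parent$objective_id
  supports <- function(ids) {
    sub <- subset_reactions(parent, ids)
    if (!obj %in% sub$reactions$id) return(FALSE)
    sol <- solve_fba(sub, obj)
    sol$status == "optimal" && sol$objective_value >= epsilon - 1e-9
  }
  have <- context$model$reactions$id
  if (obj %in% have) {
    sol <- solve_fba(context$model, obj)
    if (sol$status == "optimal" && sol$objective_value >= epsilon - 1e-9) {
      return(context)
    }
  }
  if (!supports(parent$reactions$id)) {
    stop("parent model cannot support biomass; mis-configured medium?",
         call. = FALSE)
  }
  cand <- setdiff(parent$reactions$id, have)
  # L1-sparse repair on the parent network
  p <- lp_parts(parent)
  n <- ncol(p$A)
  ci <- match(cand, parent$reactions$id)
  k <- length(ci)
  oi <- match(obj, parent$reactions$id)
  lb <- p$lb; lb[oi] <- max(lb[oi], epsilon)
  A <- cbind(p$A, matrix(0, nrow(p$A), 3 * k))
  rows <- matrix(0, 2 * k, n + 3 * k)
  for (t in seq_len(k)) {
    rows[2 * t - 1, ci[t]] <- 1; rows[2 * t - 1, n + t] <- -1
    rows[2 * t - 1, n + k + t] <- 1
    rows[2 * t, ci[t]] <- 1; rows[2 * t, n + t] <- 1
    rows[2 * t, n + 2 * k + t] <- -1
  }
  A <- rbind(A, rows)
  b <- c(p$b, rep(0, 2 * k))
  lbf <- c(lb, rep(0, k), rep(0, 2 * k))
  ubf <- c(p$ub, rep(1e9, 3 * k))
  objv <- c(rep(0, n), rep(1, k), rep(0, 2 * k))
  res <- .cpp_lp_solve(A, b, lbf, ubf, objv, FALSE)
  if (res$status != 0L) {
    stop("gap-filling LP infeasible despite feasible parent", call. = FALSE)
  }
  adds <- cand[abs(res$x[ci]) > 1e-6]
  if (!obj %in% c(have, adds)) adds <- c(adds, obj)
  # deterministic greedy pruning
  for (r in sort(adds)) {
    trial <- setdiff(adds, r)
    if (supports(c(have, trial))) adds <- trial
  }
  context$model <- subset_reactions(parent, c(have, adds))
  context$gapfilled_reactions <- sort(adds)
  context
}

#' Scale reaction bounds by relative expression (eFlux)
#'
#' Per internal reaction, expression is mapped through the GPR (AND takes
#' the minimum, OR the sum — isozymes add capacity), normalised by the
#' sample's maximum reaction score, and used to scale the flux cap:
#' bounds become `(-cap * rho, +cap * rho)` intersected with the reaction's
#' original reversibility (irreversible reactions keep a lower bound of 0).
#' Internal reactions without gene association get the full `(-cap, cap)`
#' per reversibility. Exchange and sink bounds (the medium) are preserved.
#'
#' @param context A `context_model` (or a `metabolic_model`).
#' @param profile Named numeric vector of TPM values (gene -> TPM).
#' @param cap Maximal absolute bound (default 1000).
#' @return The model with expression-scaled bounds (same class as input).
#' @export
apply_eflux <- function(context, profile, cap = 1000) {
  is_ctx <- inherits(context, "context_model")
  model <- if (is_ctx) context$model else context
  if (all(profile <= 0)) stop("all-zero expression profile", call. = FALSE)
  internal <- !(model$reactions$is_exchange | model$reactions$is_sink)
  e <- vapply(model$gpr_rules, gpr_expression, numeric(1), expr = profile)
  scores <- e[internal]
  mx <- max(scores, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    stop("no positive reaction expression score; cannot scale bounds",
         call. = FALSE)
  }
  rho <- ifelse(is.na(e), 1, pmin(e / mx, 1))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  newlb <- ifelse(lb < 0, -cap * rho, 0)
  newub <- cap * rho
  model$reactions$lower_bound[internal] <- newlb[internal]
  model$reactions$upper_bound[internal] <- newub[internal]
  if (is_ctx) {
    context$model <- model
    context
  } else {
    model
  }
}

#' Build one personalized context-specific model
#'
#' Orchestrates the per-sample pipeline: reaction scoring from cohort-level
#' gene calls, removal of inactive reactions, FASTCORE-style extraction
#' around the active core (plus the biomass objective), biomass gap-filling
#' against the parent network (inactive reactions stay excluded), and
#' finally eFlux bound scaling from the sample's TPM profile.
#'
#' @param model Parent `metabolic_model` with medium applied.
#' @param sample_id Sample column to build.
#' @param tpm TPM expression tibble (already mapped to model genes).
#' @param calls Cohort-level `gene_calls` from [call_active_genes()].
#' @param epsilon Flux-support threshold (1e-4).
#' @param eflux_cap eFlux cap; `NULL` skips eFlux.
#' @param cache Optional environment used to reuse extractions across
#'   samples with identical activity patterns.
#' @return A `context_model` with provenance (`core_reactions`,
#'   `gapfilled_reactions`, `inconsistent_core`, `removed_inactive`,
#'   `sample_id`).
#' @export
build_personalized_model <- function(model, sample_id, tpm, calls,
                                     epsilon = 1e-4, eflux_cap = 1000,
                                     cache = NULL) {
  if (!sample_id %in% colnames(calls$status)) {
    stop("sample '", sample_id, "' not present in gene calls", call. = FALSE)
  }
  status <- calls$status[, sample_id]
  scores <- score_reactions(model, status)
  inactive <- scores$reaction_id[scores$activity == "inactive"]
  active <- scores$reaction_id[scores$activity == "active"]
  parent <- if (length(inactive)) {
    subset_reactions(model, setdiff(model$reactions$id, inactive))
  } else {
    model
  }
  core <- union(intersect(active, parent$reactions$id), model$objective_id)
  key <- paste(c("I", sort(inactive), "C", sort(core)), collapse = "|")
  ctx <- if (!is.null(cache) && !is.null(cache[[key]])) {
    cache[[key]]
  } else {
    out <- tryCatch(
      extract_context_model(parent, core, epsilon = epsilon),
      error = function(e) {
        stop("sample '", sample_id, "': ", conditionMessage(e), call. = FALSE)
      }
    )
    # gap-fill against the full parent: restoring biomass may override an
    # inactive call when the dropped reaction is essential for growth
    out <- gapfill_biomass(out, model, epsilon = epsilon)
    if (!is.null(cache)) cache[[key]] <- out
    out
  }
  ctx$sample_id <- sample_id
  ctx$removed_inactive <- inactive
  if (!is.null(eflux_cap)) {
    prof <- stats::setNames(tpm[[sample_id]], tpm$gene_id)
    ctx <- apply_eflux(ctx, prof, cap = eflux_cap)
  }
  ctx
}

#' Personalize a whole cohort
#'
#' Runs unit conversion, gene mapping, cohort-level gene calling and
#' per-sample model building for every sample of a cohort (or a subset).
#'
#' @param model Parent `metabolic_model` with medium applied.
#' @param cohort A `synthetic_cohort`, or a list with `expression` and
#'   `metadata` in the same shape.
#' @param samples Sample ids to build (default: all).
#' @param epsilon,eflux_cap See [build_personalized_model()].
#' @return An object of class `personalized_cohort`: list with `contexts`
#'   (named list of `context_model`s), `calls`, `tpm`, and `metadata`.
#' @export
personalize_cohort <- function(model, cohort, samples = NULL,
                               epsilon = 1e-4, eflux_cap = 1000) {
  units <- if (inherits(cohort, "synthetic_cohort")) cohort$units else
    attr(cohort$expression, "units") %||% "rpkm"
  tpm <- rpkm_to_tpm(cohort$expression, units = units, strict = FALSE)
  tpm <- map_gene_ids(tpm, model)
  calls <- call_active_genes(tpm)
  samples <- samples %||% cohort$metadata$sample_id
  cache <- new.env(parent = emptyenv())
  contexts <- lapply(samples, function(s) {
    build_personalized_model(model, s, tpm, calls, epsilon = epsilon,
                             eflux_cap = eflux_cap, cache = cache)
  })
  names(contexts) <- samples
  structure(
    list(contexts = contexts, calls = calls, tpm = tpm,
         metadata = cohort$metadata[cohort$metadata$sample_id %in% samples, ]),
    class = "personalized_cohort"
  )
}

#' @export
print.personalized_cohort <- function(x, ...) {
  sizes <- vapply(x$contexts, function(c) nrow(c$model$reactions), numeric(1))
  cat("<personalized_cohort> ", length(x$contexts), " models; ",
      "mean size ", round(mean(sizes), 1), " reactions\n", sep = "")
  invisible(x)
}
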