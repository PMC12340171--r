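#' @useDynLib cblflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

lp_status_label <- function(code) {
  c("optimal", "infeasible", "unbounded", "iteration_limit")[code + 1L]
}

lp_parts <- function(model) {
  list(
    A = as.matrix(model$S),
    b = rep(0, nrow(model$S)),
    lb = model$reactions$lower_bound,
    ub = model$reactions$upper_bound
  )
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject to
#' the steady-state constraint `S v = 0` and the flux bounds.
#'
#' @param model A `metabolic_model`.
#' @param objective_id Reaction id to optimize; defaults to the model's
#'   biomass objective.
#' @param sense `"max"` or `"min"`.
#' @return An object of class `fba_solution`: a list with `status`
#'   (`"optimal"`, `"infeasible"`, ...), `objective_value`, and `fluxes`
#'   (a tibble `reaction_id`, `flux`, in model order).
#' @examples
#' mod <- build_fixture_model()
#' sol <- solve_fba(mod)
#' sol$objective_value
#' @export
solve_fba <- function(model, objective_id = model$objective_id,
                      sense = c("max", "min")) {
  sense <- match.arg(sense)
  idx <- rxn_index(model, objective_id)
  p <- lp_parts(model)
  obj <- rep(0, ncol(p$A)); obj[idx] <- 1
  res <- .cpp_lp_solve(p$A, p$b, p$lb, p$ub, obj, sense == "max")
  status <- lp_status_label(res$status)
  fluxes <- tibble::tibble(reaction_id = model$reactions$id,
                           flux = as.numeric(res$x))
  if (status == "optimal") {
    resid <- max(abs(p$A %*% res$x))
    scale <- max(1, max(abs(res$x)))
    if (resid > 1e-6 * scale) {
      stop("LP solution violates steady state (residual ", signif(resid, 3), ")",
           call. = FALSE)
    }
  } else if (status %in% c("unbounded", "iteration_limit")) {
    stop("LP solver failed for objective '", objective_id, "': status ", status,
         call. = FALSE)
  }
  structure(
    list(status = status,
         objective_value = if (status == "optimal") res$objective else NA_real_,
         objective_id = objective_id, sense = sense, fluxes = fluxes),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> ", x$sense, " ", x$objective_id, ": ",
      if (x$status == "optimal") signif(x$objective_value, 6) else x$status,
      " (", x$status, ")\n", sep = "")
  invisible(x)
}

# Build the augmented LP system carrying the objective >= fraction * optimum
# constraint as an extra row with a bounded slack variable.
fva_system <- function(model, objective_id, fraction) {
  p <- lp_parts(model)
  idx <- rxn_index(model, objective_id)
  obj <- rep(0, ncol(p$A)); obj[idx] <- 1
  res <- .cpp_lp_solve(p$A, p$b, p$lb, p$ub, obj, TRUE)
  if (res$status != 0L) {
    stop("model infeasible: cannot optimize '", objective_id,
         "' (status ", lp_status_label(res$status), ")", call. = FALSE)
  }
  opt <- res$objective
  A <- rbind(cbind(p$A, 0), c(obj, -1))
  # the slack equals the objective value, so it is tightly bounded above by
  # the optimum itself (keeps the system well scaled)
  list(
    A = A, b = c(p$b, 0),
    lb = c(p$lb, fraction * opt),
    ub = c(p$ub, opt + 1e-6 * max(1, abs(opt))),
    optimum = opt
  )
}

#' Flux variability analysis
#'
#' For every reaction, the minimum and maximum steady-state flux subject to
#' the objective reaching at least `fraction` of its optimum. The
#' fraction-of-optimum requirement is imposed as an added constraint row, so
#' it is exact even when the objective reaction already has a nonzero lower
#' bound.
#'
#' @inheritParams solve_fba
#' @param fraction Required fraction of the objective optimum, in (0, 1].
#' @param reactions Reaction ids to analyze (default: all).
#' @return A tibble of class `fva_result` with columns `reaction_id`,
#'   `min_flux`, `max_flux`, and attributes `fraction`, `optimum`,
#'   `objective_id`.
#' @examples
#' spans <- run_fva(build_fixture_model(), fraction = 0.99)
#' head(spans)
#' @export
run_fva <- function(model, objective_id = model$objective_id, fraction = 0.99,
                    reactions = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(reactions)) reactions <- model$reactions$id
  cols <- rxn_index(model, reactions)
  sys <- fva_system(model, objective_id, fraction)
  sw <- .cpp_lp_sweep(sys$A, sys$b, sys$lb, sys$ub, as.integer(cols))
  if (sw$status != 0L) {
    stop("FVA sweep failed: status ", lp_status_label(sw$status), call. = FALSE)
  }
  vmin <- as.numeric(sw$min); vmax <- as.numeric(sw$max)
  # guard against solver round-off producing min > max by a hair
  swap <- !is.na(vmin) & !is.na(vmax) & vmin > vmax
  mid <- (vmin[swap] + vmax[swap]) / 2
  vmin[swap] <- mid; vmax[swap] <- mid
  out <- tibble::tibble(reaction_id = reactions, min_flux = vmin, max_flux = vmax)
  structure(out, class = c("fva_result", class(out)),
            fraction = fraction, optimum = sys$optimum,
            objective_id = objective_id)
}

#' Simulate gene knockouts
#'
#' Every reaction whose GPR evaluates to `FALSE` under the deletion gets
#' bounds `(0, 0)`; all other reactions are untouched. Genes absent from the
#' model are ignored with a warning.
#'
#' @param model A `metabolic_model`.
#' @param genes Character vector of genes to delete.
#' @return The constrained model.
#' @export
delete_genes <- function(model, genes) {
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    warning("ignoring gene(s) absent from model: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- intersect(genes, model$genes)
  if (!length(genes)) return(model)
  dead <- vapply(model$gpr_rules, function(r) !evaluate_gpr(r, genes), logical(1))
  if (any(dead)) {
    model$reactions$lower_bound[dead] <- 0
    model$reactions$upper_bound[dead] <- 0
  }
  model
}

#' Apply a growth medium
#'
#' Sets the lower bound of each listed exchange reaction to minus its
#' maximum uptake and closes the uptake (lower bound 0) of every other
#' exchange reaction. Secretion (upper) bounds are untouched.
#'
#' @param model A `metabolic_model`.
#' @param medium Named numeric vector: `exchange_id -> max uptake` (positive).
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium) {
  ex <- model$reactions$id[model$reactions$is_exchange]
  bad <- setdiff(names(medium), ex)
  if (length(bad)) {
    stop("medium cites non-exchange reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  model$reactions$lower_bound[model$reactions$is_exchange] <- 0
  if (length(medium)) {
    idx <- rxn_index(model, names(medium))
    model$reactions$lower_bound[idx] <- -abs(unname(medium))
  }
  model
}

#' Simulate cobalamin deficiency
#'
#' Closes the uptake (sets lower bound to 0) of every exchange reaction the
#' model declares as cobalamin-family. Nothing else changes; the operation is
#' idempotent.
#'
#' @param model A `metabolic_model` with a non-empty `cobalamin_exchanges`
#'   declaration (otherwise an error, flagging a mis-configured model).
#' @return The constrained model.
#' @export
close_cobalamin_uptake <- function(model) {
  if (!length(model$cobalamin_exchanges)) {
    stop("model declares no cobalamin exchange reactions; cannot simulate deficiency",
         call. = FALSE)
  }
  set_bounds(model, model$cobalamin_exchanges, lower = 0)
}

#' Find flux-consistent reactions
#'
#' A reaction is flux-consistent when it can carry `|v| >= epsilon` in at
#' least one direction under the current constraints (no objective
#' requirement). `method = "batch"` runs one warm-started sweep of paired
#' LPs; `method = "naive"` solves two independent LPs per reaction and is the
#' reference implementation the batch scheme must agree with.
#'
#' @param model A `metabolic_model`.
#' @param epsilon Minimum flux magnitude (default `1e-4`).
#' @param method `"batch"` or `"naive"`.
#' @return Character vector of flux-consistent reaction ids (model order).
#' @export
find_flux_consistent <- function(model, epsilon = 1e-4,
                                 method = c("batch", "naive")) {
  method <- match.arg(method)
  p <- lp_parts(model)
  n <- ncol(p$A)
  tol <- 1e-9
  if (method == "batch") {
    sw <- .cpp_lp_sweep(p$A, p$b, p$lb, p$ub, seq_len(n))
    if (sw$status != 0L) {
      stop("consistency sweep failed: status ", lp_status_label(sw$status),
           call. = FALSE)
    }
    ok <- (sw$max >= epsilon - tol) | (sw$min <= -(epsilon - tol))
  } else {
    ok <- logical(n)
    for (j in seq_len(n)) {
      obj <- rep(0, n); obj[j] <- 1
      mx <- .cpp_lp_solve(p$A, p$b, p$lb, p$ub, obj, TRUE)
      if (mx$status == 0L && mx$objective >= epsilon - tol) { ok[j] <- TRUE; next }
      mn <- .cpp_lp_solve(p$A, p$b, p$lb, p$ub, obj, FALSE)
      ok[j] <- mn$status == 0L && mn$objective <= -(epsilon - tol)
    }
  }
  model$reactions$id[ok]
}

#' Maximum production potential of a metabolite
#'
#' Temporarily adds a sink reaction draining the metabolite, maximizes its
#' flux, and reports the optimum. The input model is not modified.
#'
#' @param model A `metabolic_model` (medium already applied as desired).
#' @param metabolite_id Metabolite to test.
#' @return Maximum achievable synthesis flux (non-negative scalar).
#' @export
production_potential <- function(model, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite_id, call. = FALSE)
  }
  p <- lp_parts(model)
  sink <- rep(0, nrow(p$A))
  sink[match(metabolite_id, model$metabolites$id)] <- -1
  A <- cbind(p$A, sink)
  lb <- c(p$lb, 0); ub <- c(p$ub, 1e9)
  obj <- c(rep(0, ncol(p$A)), 1)
  res <- .cpp_lp_solve(A, p$b, lb, ub, obj, TRUE)
  if (res$status != 0L) {
    stop("base model infeasible while probing production of '", metabolite_id,
         "' (status ", lp_status_label(res$status), ")", call. = FALSE)
  }
  max(0, res$objective)
}
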