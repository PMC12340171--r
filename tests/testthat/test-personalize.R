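make_expr <- function(values, samples = "s1") {
  out <- tibble::tibble(gene_id = names(values[[1]]))
  for (s in seq_along(samples)) out[[samples[s]]] <- unname(values[[s]])
  attr(out, "units") <- "rpkm"
  out
}

test_that("RPKM to TPM follows the normalisation formula", {
  e <- make_expr(list(c(g1 = 5, g2 = 5)))
  tpm <- rpkm_to_tpm(e)
  expect_equal(tpm$s1, c(5e5, 5e5))
  e2 <- make_expr(list(c(g1 = 1, g2 = 3)))
  tpm2 <- rpkm_to_tpm(e2)
  expect_equal(tpm2$s1, c(2.5e5, 7.5e5))
  expect_equal(sum(tpm2$s1), 1e6)
  # unit guard
  expect_error(rpkm_to_tpm(tpm2, units = "tpm"), "already")
  expect_identical(rpkm_to_tpm(tpm2, units = "tpm", strict = FALSE), tpm2)
  zero <- make_expr(list(c(g1 = 0, g2 = 0)))
  expect_error(rpkm_to_tpm(zero), "all-zero")
})

test_that("gene mapping restricts to model genes and sums collisions", {
  mod <- fixture_model_cached()
  e <- make_expr(list(c(MMUT = 4, MTR = 2, NOT_IN_MODEL = 9)))
  expect_message(out <- map_gene_ids(e, mod), "dropped")
  expect_setequal(out$gene_id, c("MMUT", "MTR"))
  # two symbols collapsing onto one locus are summed
  e2 <- make_expr(list(c(symA = 4, symB = 6)))
  mapping <- tibble::tibble(symbol = c("symA", "symB"),
                            locus = c("MMUT", "MMUT"))
  expect_warning(out2 <- map_gene_ids(e2, mod, mapping), "summed")
  expect_equal(out2$s1[out2$gene_id == "MMUT"], 10)
})

test_that("the mixture caller separates a bimodal cohort and knows its truth", {
  co <- generate_cohort(cohort_design(n_control = 6, n_mut0 = 6,
                                      n_mutminus = 0, n_other = 0, seed = 21))
  mod <- fixture_model_cached()
  tpm <- map_gene_ids(rpkm_to_tpm(co$expression), mod)
  calls <- call_active_genes(tpm)
  expect_identical(calls$method, "gmm")
  # boundary lies between the two modes
  expect_gt(calls$thresholds[["active_above"]],
            calls$thresholds[["inactive_below"]])
  # truth: off-class genes inactive, on-class active, in (almost) all samples
  truth <- co$truth$gene_classes
  off <- truth$gene[truth$class == "off"]
  on <- setdiff(truth$gene[truth$class == "high"], c("MMUT", "SUCLA2"))
  st <- calls$status[intersect(off, rownames(calls$status)), , drop = FALSE]
  expect_gt(mean(st == "inactive"), 0.9)
  st_on <- calls$status[intersect(on, rownames(calls$status)), , drop = FALSE]
  expect_gt(mean(st_on == "active"), 0.95)
  # MMUT inactive in mut0 samples, active in controls
  mut0 <- co$metadata$sample_id[co$metadata$group == "mut0"]
  ctrl <- co$metadata$sample_id[co$metadata$group == "control"]
  expect_true(all(calls$status["MMUT", mut0] == "inactive"))
  expect_true(all(calls$status["MMUT", ctrl] == "active"))
})

test_that("doubling all TPM shifts the boundary by one log2 unit, same calls", {
  co <- generate_cohort(cohort_design(n_control = 6, n_mut0 = 6,
                                      n_mutminus = 0, n_other = 0, seed = 22))
  mod <- fixture_model_cached()
  tpm <- map_gene_ids(rpkm_to_tpm(co$expression), mod)
  doubled <- tpm
  for (col in names(doubled)[-1]) doubled[[col]] <- doubled[[col]] * 2
  a <- call_active_genes(tpm)
  b <- call_active_genes(doubled)
  # log2(2x + 1) ~ log2(x + 1) + 1 for the values at play (TPM >> 1)
  expect_equal(b$thresholds[["active_above"]],
               a$thresholds[["active_above"]] + 1, tolerance = 0.1)
  expect_identical(a$status, b$status)
})

test_that("an all-zero gene is inactive in every sample", {
  co <- generate_cohort(cohort_design(n_control = 4, n_mut0 = 4,
                                      n_mutminus = 0, n_other = 0, seed = 23))
  expr <- co$expression
  expr[expr$gene_id == "CBS", -1] <- 0
  mod <- fixture_model_cached()
  tpm <- map_gene_ids(rpkm_to_tpm(expr), mod)
  calls <- call_active_genes(tpm)
  expect_true(all(calls$status["CBS", ] == "inactive"))
})

test_that("reaction scoring follows AND=min / OR=max over activity levels", {
  mod <- fixture_model_cached()
  st <- stats::setNames(rep("active", length(mod$genes)), mod$genes)
  st["LDHA"] <- "active"; st["LDHB"] <- "inactive"
  sc <- score_reactions(mod, st)
  expect_identical(sc$activity[sc$reaction_id == "LDH_L"], "active")  # OR
  st["PCCA"] <- "active"; st["PCCB"] <- "inactive"
  sc <- score_reactions(mod, st)
  expect_identical(sc$activity[sc$reaction_id == "PCCm"], "inactive") # AND
  # empty GPR -> unknown
  expect_identical(sc$activity[sc$reaction_id == "GLCt"], "unknown")
  # random trees against a direct three-valued evaluator
  lev <- c(inactive = 0, unknown = 1, active = 2)
  set.seed(31)
  genes <- c("A", "B", "C")
  for (rep in 1:20) {
    text <- random_gpr(genes, depth = 2)
    status <- sample(names(lev), 3, replace = TRUE)
    names(status) <- genes
    direct <- function(nd) {
      if (nd$op == "gene") return(lev[[status[[nd$gene]]]])
      vals <- vapply(nd$children, direct, numeric(1))
      if (nd$op == "and") min(vals) else max(vals)
    }
    expected <- direct(parse_gpr(text))
    got <- cblflux:::gpr_score(parse_gpr(text),
                               stats::setNames(lev[status], names(status)))
    expect_identical(got, expected, info = text)
  }
})

test_that("extraction returns the whole model when the core is everything consistent", {
  mod <- fixture_model_cached()
  cons <- find_flux_consistent(mod)
  ctx <- extract_context_model(mod, cons)
  expect_setequal(ctx$model$reactions$id, cons)
  expect_length(ctx$inconsistent_core, 0)
})

test_that("extraction pulls in the unique support of a mid-chain core", {
  mod <- make_chain_model(cap = 10)
  ctx <- extract_context_model(mod, "AB")
  expect_setequal(ctx$model$reactions$id, c("EX_a", "AB", "EX_b"))
  expect_error(extract_context_model(mod, character()), "empty core")
})

test_that("every extracted core reaction passes an independent flux test", {
  for (seed in c(11, 29)) {
    mod <- random_network(seed, n_mets = 7, n_internal = 14)
    cons <- find_flux_consistent(mod)
    core <- cons[seq(1, length(cons), by = 2)]
    ctx <- extract_context_model(mod, core)
    kept_core <- intersect(core, ctx$model$reactions$id)
    expect_setequal(kept_core, intersect(core, cons))
    p <- cblflux:::lp_parts(ctx$model)
    for (r in kept_core) {
      j <- match(r, ctx$model$reactions$id)
      obj <- rep(0, ncol(p$A)); obj[j] <- 1
      hi <- cblflux:::.cpp_lp_solve(p$A, p$b, p$lb, p$ub, obj, TRUE)
      lo <- cblflux:::.cpp_lp_solve(p$A, p$b, p$lb, p$ub, obj, FALSE)
      expect_true(max(hi$objective, -lo$objective) >= 1e-4 * 0.98,
                  info = paste(seed, r))
    }
  }
})

test_that("enlarging the core never drops previously supported core reactions", {
  mod <- random_network(11, n_mets = 7, n_internal = 14)
  cons <- find_flux_consistent(mod)
  small <- cons[1:3]
  big <- cons[1:6]
  a <- extract_context_model(mod, small)
  b <- extract_context_model(mod, big)
  expect_true(all(intersect(small, a$model$reactions$id) %in%
                    b$model$reactions$id))
})

test_that("gap-filling is a no-op on a growing context and repairs a cut transporter", {
  mod <- fixture_model_cached()
  cons <- find_flux_consistent(mod)
  ctx <- extract_context_model(mod, cons)
  filled <- gapfill_biomass(ctx, mod)
  expect_length(filled$gapfilled_reactions, 0)

  # remove the folate transporter (essential, unique repair) from the context
  cut <- ctx
  cut$model <- subset_reactions(ctx$model,
                                setdiff(ctx$model$reactions$id, "FOLt"))
  repaired <- gapfill_biomass(cut, mod)
  expect_identical(repaired$gapfilled_reactions, "FOLt")
  sol <- solve_fba(repaired$model)
  expect_gt(sol$objective_value, 1e-4)

  # a parent that cannot grow is a configuration error
  starved <- apply_medium(mod, c())
  expect_error(gapfill_biomass(cut, starved), "parent model cannot support")
})

test_that("eFlux scales bounds by relative expression with the documented rules", {
  mod <- fixture_model_cached()
  profile <- stats::setNames(rep(100, length(mod$genes)), mod$genes)
  profile["PKM"] <- 1000   # top reaction score
  profile["LDHA"] <- 250; profile["LDHB"] <- 250  # OR sums to 500
  profile["MMUT"] <- 0
  scaled <- apply_eflux(mod, profile, cap = 1000)
  gi <- function(r, what) {
    i <- match(r, scaled$reactions$id)
    scaled$reactions[[what]][i]
  }
  # top-expressed reaction gets the full cap
  expect_equal(gi("GLYCl", "upper_bound"), 1000)
  expect_equal(gi("GLYCl", "lower_bound"), 0)      # irreversible keeps lb 0
  # rho = 0.5 reversible reaction gets (-500, 500)
  expect_equal(gi("LDH_L", "upper_bound"), 500)
  expect_equal(gi("LDH_L", "lower_bound"), -500)
  # zero-expression gene-associated reaction is closed
  expect_equal(gi("MMMm_cbl", "upper_bound"), 0)
  expect_equal(gi("MMMm_cbl", "lower_bound"), 0)
  # non-gene-associated internal reactions get the full cap per reversibility
  expect_equal(gi("GLCt", "upper_bound"), 1000)
  expect_equal(gi("GLCt", "lower_bound"), -1000)
  # exchange bounds (the medium) are preserved
  i <- match("EX_glc_D_e", mod$reactions$id)
  expect_identical(gi("EX_glc_D_e", "lower_bound"),
                   mod$reactions$lower_bound[i])
  expect_error(apply_eflux(mod, profile * 0), "all-zero")
})

test_that("raising one gene's expression never tightens its reactions' bounds", {
  mod <- fixture_model_cached()
  profile <- stats::setNames(rep(100, length(mod$genes)), mod$genes)
  profile["PKM"] <- 1000
  lo <- apply_eflux(mod, profile)
  profile2 <- profile; profile2["SHMT1"] <- profile2["SHMT1"] * 4
  hi <- apply_eflux(mod, profile2)
  i <- match("SHMTc", mod$reactions$id)
  expect_gte(hi$reactions$upper_bound[i], lo$reactions$upper_bound[i])
  expect_lte(hi$reactions$lower_bound[i], lo$reactions$lower_bound[i])
})

test_that("the per-sample pipeline is deterministic and tracks provenance", {
  mod <- fixture_model_cached()
  co <- generate_cohort(cohort_design(n_control = 3, n_mut0 = 3,
                                      n_mutminus = 0, n_other = 0, seed = 41))
  a <- personalize_cohort(mod, co)
  b <- personalize_cohort(mod, co)
  expect_identical(
    lapply(a$contexts, function(c) c$model$reactions),
    lapply(b$contexts, function(c) c$model$reactions)
  )
  g <- tidy(a)
  expect_identical(nrow(g), 6L)
  expect_true(all(g$n_core > 0))
})

test_that("MMUT survives into control contexts and not into mut0 contexts", {
  mod <- fixture_model_cached()
  co <- generate_cohort(cohort_design(n_control = 6, n_mut0 = 6,
                                      n_mutminus = 0, n_other = 0, seed = 43))
  pc <- personalize_cohort(mod, co)
  grp <- stats::setNames(co$metadata$group, co$metadata$sample_id)
  has_mmut <- vapply(pc$contexts, function(c) {
    "MMMm_cbl" %in% c$model$reactions$id
  }, logical(1))
  expect_true(all(has_mmut[names(which(grp == "control"))]))
  expect_false(any(has_mmut[names(which(grp == "mut0"))]))
  # every model grows
  for (ctx in pc$contexts) {
    expect_gt(solve_fba(ctx$model)$objective_value, 1e-4)
  }
})
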