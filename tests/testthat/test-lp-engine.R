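test_that("FBA solves a linear chain to its uptake capacity", {
  mod <- make_chain_model(cap = 10)
  sol <- solve_fba(mod)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  # steady state holds
  v <- sol$fluxes$flux
  expect_lt(max(abs(as.matrix(mod$S) %*% v)), 1e-8)
})

test_that("an unreachable objective yields zero, a forced one infeasibility", {
  mod <- make_chain_model(cap = 10)
  blocked <- set_bounds(mod, "AB", lower = 0, upper = 0)
  expect_equal(solve_fba(blocked)$objective_value, 0, tolerance = 1e-9)
  forced <- set_bounds(blocked, "EX_b", lower = 5)
  expect_identical(solve_fba(forced)$status, "infeasible")
})

test_that("FBA objectives match an independent LP oracle on random networks", {
  skip_if_not_installed("pracma")
  for (seed in 1:10) {
    mod <- random_network(seed)
    p <- cblflux:::lp_parts(mod)
    obj <- as.numeric(mod$reactions$id == mod$objective_id)
    mine <- solve_fba(mod)
    orc <- oracle_lp(p$A, p$b, p$lb, p$ub, obj, maximize = TRUE)
    skip_if(is.null(orc), "oracle did not converge")
    expect_equal(mine$objective_value, orc, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("FVA collapses a chain at fraction 1 and frees parallel branches", {
  mod <- make_chain_model(cap = 10)
  spans <- run_fva(mod, fraction = 1)
  expect_equal(spans$min_flux, rep(10, 3), tolerance = 1e-7)
  expect_equal(spans$max_flux, rep(10, 3), tolerance = 1e-7)

  br <- make_branch_model(cap = 10)
  spans <- run_fva(br, fraction = 0.99)
  b1 <- spans[spans$reaction_id == "branch1", ]
  # the other branch can carry the required 9.9, so each spans [0, 10]
  expect_equal(b1$min_flux, 0, tolerance = 1e-7)
  expect_equal(b1$max_flux, 10, tolerance = 1e-7)
})

test_that("the FVA sweep equals per-reaction brute-force LP pairs", {
  for (seed in c(3, 14, 27)) {
    mod <- random_network(seed, n_mets = 6, n_internal = 10)
    sw <- run_fva(mod, fraction = 0.9)
    bf <- brute_fva(mod, fraction = 0.9)
    expect_equal(sw$min_flux, bf$min_flux, tolerance = 1e-6)
    expect_equal(sw$max_flux, bf$max_flux, tolerance = 1e-6)
  }
})

test_that("FVA spans are nested across fractions and contain the FBA optimum", {
  mod <- fixture_model_cached()
  s100 <- run_fva(mod, fraction = 1)
  s99 <- run_fva(mod, fraction = 0.99)
  s50 <- run_fva(mod, fraction = 0.5)
  tol <- 1e-6
  expect_true(all(s100$min_flux >= s99$min_flux - tol))
  expect_true(all(s100$max_flux <= s99$max_flux + tol))
  expect_true(all(s99$min_flux >= s50$min_flux - tol))
  expect_true(all(s99$max_flux <= s50$max_flux + tol))
  # an optimal FBA flux vector lies within the fraction-1 spans
  v <- solve_fba(mod)$fluxes$flux
  expect_true(all(v >= s100$min_flux - 1e-5))
  expect_true(all(v <= s100$max_flux + 1e-5))
})

test_that("run_fva refuses an infeasible model", {
  mod <- make_chain_model()
  mod <- set_bounds(mod, "EX_b", lower = 20)  # demands more than uptake
  expect_error(run_fva(mod), "infeasible")
})

test_that("gene deletion zeroes exactly the reactions whose GPR fails", {
  mod <- fixture_model_cached()
  expect_warning(delete_genes(mod, "NOT_A_GENE"), "absent")
  # deleting one isozyme of an OR pair leaves the reaction open
  ko <- delete_genes(mod, "LDHB")
  i <- which(mod$reactions$id == "LDH_L")
  expect_identical(ko$reactions$upper_bound[i], mod$reactions$upper_bound[i])
  ko2 <- delete_genes(mod, c("LDHA", "LDHB"))
  expect_identical(unname(ko2$reactions$upper_bound[i]), 0)
  # MTR deletion blocks both methionine-synthase half-reactions
  mtr <- delete_genes(mod, "MTR")
  for (r in c("METS_CAT", "METS_FORM")) {
    j <- which(mod$reactions$id == r)
    expect_identical(unname(mtr$reactions$upper_bound[j]), 0)
  }
  spans <- run_fva(mtr, fraction = 0.99,
                   reactions = c("METS_CAT", "METS_FORM", "METS_R_REG"))
  expect_true(all(abs(spans$max_flux) < 1e-8))
})

test_that("gene deletion only shrinks the flux polytope", {
  mod <- set_bounds(fixture_model_cached(), "ATPM", lower = 0)
  ko <- delete_genes(mod, "MMUT")
  sol <- solve_fba(ko)
  v <- sol$fluxes$flux
  # the knockout solution is feasible in the wild type
  expect_true(all(v >= mod$reactions$lower_bound - 1e-7))
  expect_true(all(v <= mod$reactions$upper_bound + 1e-7))
  expect_lt(max(abs(as.matrix(mod$S) %*% v)), 1e-7)
})

test_that("apply_medium closes unlisted uptakes and validates its keys", {
  mod <- build_fixture_model()
  closed <- apply_medium(mod, c())
  ex <- closed$reactions$is_exchange
  expect_true(all(closed$reactions$lower_bound[ex] == 0))

  one <- apply_medium(mod, c(EX_glc_D_e = 10))
  i <- which(one$reactions$id == "EX_glc_D_e")
  expect_identical(unname(one$reactions$lower_bound[i]), -10)
  others <- one$reactions$is_exchange & one$reactions$id != "EX_glc_D_e"
  expect_true(all(one$reactions$lower_bound[others] == 0))
  # secretion bounds untouched
  expect_identical(one$reactions$upper_bound[ex],
                   mod$reactions$upper_bound[ex])
  expect_error(apply_medium(mod, c(MMEm = 5)), "non-exchange")
})

test_that("close_cobalamin_uptake is idempotent and guards configuration", {
  mod <- fixture_model_cached()
  once <- close_cobalamin_uptake(mod)
  twice <- close_cobalamin_uptake(once)
  expect_identical(once$reactions$lower_bound, twice$reactions$lower_bound)
  i <- match(mod$cobalamin_exchanges, mod$reactions$id)
  expect_true(all(once$reactions$lower_bound[i] == 0))
  # everything else untouched
  expect_identical(once$reactions$lower_bound[-i],
                   mod$reactions$lower_bound[-i])
  bare <- make_chain_model()
  expect_error(close_cobalamin_uptake(bare), "no cobalamin")
})

test_that("batch and naive flux-consistency testing agree", {
  for (seed in c(5, 21, 33, 48)) {
    mod <- random_network(seed, n_mets = 7, n_internal = 13)
    expect_identical(
      find_flux_consistent(mod, method = "batch"),
      find_flux_consistent(mod, method = "naive"),
      info = paste("seed", seed)
    )
  }
  # dead-end metabolite's reaction is excluded, a connected chain is kept
  mod <- make_chain_model()
  mod2 <- add_reactions(
    mod,
    new_metabolites = tibble::tibble(id = "dead[c]", name = "dead",
                                     compartment = "c",
                                     formula = NA_character_,
                                     charge = NA_integer_),
    new_reactions = tibble::tibble(
      id = "to_dead", stoich = list(c(`a[c]` = -1, `dead[c]` = 1)),
      lower_bound = 0, upper_bound = 10, subsystem = "", gpr = "",
      is_exchange = FALSE, is_sink = FALSE)
  )
  cons <- find_flux_consistent(mod2)
  expect_false("to_dead" %in% cons)
  expect_setequal(cons, c("EX_a", "AB", "EX_b"))
})

test_that("production potential reflects supply and dead ends", {
  mod <- make_chain_model(cap = 10)
  expect_equal(production_potential(mod, "a[c]"), 10, tolerance = 1e-7)
  mod2 <- add_reactions(
    mod,
    new_metabolites = tibble::tibble(id = "orphan[c]", name = "o",
                                     compartment = "c",
                                     formula = NA_character_,
                                     charge = NA_integer_)
  )
  # orphan metabolite participates in no reaction: potential 0
  expect_equal(production_potential(mod2, "orphan[c]"), 0)
  expect_error(production_potential(mod, "nope[c]"), "unknown metabolite")
})

test_that("production potential is monotone under bound tightening", {
  mod <- fixture_model_cached()
  base <- production_potential(mod, "pheme[m]")
  for (cap in c(5, 2, 0.5)) {
    tighter <- set_bounds(mod, "EX_hcbl_e", lower = -cap)
    tighter <- set_bounds(tighter, "EX_val_L_e", lower = -cap)
    p <- production_potential(tighter, "pheme[m]")
    expect_lte(p, base + 1e-7)
    base <- p
  }
})

test_that("LP results are reproducible across repeated runs", {
  mod <- fixture_model_cached()
  a <- run_fva(mod, fraction = 0.99)
  b <- run_fva(mod, fraction = 0.99)
  expect_equal(a$min_flux, b$min_flux, tolerance = 1e-12)
  expect_equal(a$max_flux, b$max_flux, tolerance = 1e-12)
})
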