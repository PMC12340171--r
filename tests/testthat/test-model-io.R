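test_that("json and tsv round-trips preserve the model", {
  mod <- build_fixture_model()
  for (fmt in c("native-json", "native-tsv")) {
    path <- if (fmt == "native-json") withr::local_tempfile(fileext = ".json")
            else withr::local_tempdir()
    write_model(mod, path, format = fmt)
    back <- read_model(path, format = fmt)
    expect_identical(back$reactions$id, mod$reactions$id)
    expect_identical(back$metabolites$id, mod$metabolites$id)
    expect_setequal(back$genes, mod$genes)
    expect_identical(back$objective_id, mod$objective_id)
    expect_setequal(back$cobalamin_exchanges, mod$cobalamin_exchanges)
    expect_equal(back$reactions$lower_bound, mod$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound, mod$reactions$upper_bound)
    expect_equal(as.matrix(back$S), as.matrix(mod$S))
    # GPR logic preserved (evaluate under each single-gene deletion)
    for (g in c("MMUT", "MTR", "LMBRD1", "PCCA")) {
      expect_identical(
        vapply(back$gpr_rules, evaluate_gpr, logical(1), deleted = g),
        vapply(mod$gpr_rules, evaluate_gpr, logical(1), deleted = g)
      )
    }
  }
})

test_that("reading a model citing an unknown metabolite fails with a validation error", {
  mod <- make_chain_model()
  mod$reactions$stoich[[2]] <- c(`a[c]` = -1, `ghost[c]` = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(metabolic_model(mod$metabolites, mod$reactions, mod$genes,
                              mod$objective_id), path)
  expect_error(read_model(path), "unknown metabolite")
})

test_that("validate_model flags exactly the seeded defects", {
  base <- build_fixture_model()
  expect_identical(nrow(validate_model(base)), 0L)

  seed_defect <- function(mutate) {
    m <- base
    mutate(m)
  }
  # one mutation per invariant, each expected to produce exactly its flag
  cases <- list(
    duplicate_metabolite = function(m) {
      m$metabolites$id[2] <- m$metabolites$id[1]; m
    },
    duplicate_reaction = function(m) {
      m$reactions$id[2] <- m$reactions$id[1]; m
    },
    bound_inversion = function(m) {
      m$reactions$lower_bound[5] <- m$reactions$upper_bound[5] + 1; m
    },
    unknown_metabolite = function(m) {
      st <- m$reactions$stoich[[40]]
      names(st)[1] <- "nonexistent[c]"
      m$reactions$stoich[[40]] <- st; m
    },
    unknown_gene = function(m) {
      m$reactions$gpr[m$reactions$id == "MMMm_cbl"] <- "NOSUCHGENE"; m
    },
    empty_stoichiometry = function(m) {
      m$reactions$stoich[[3]] <- numeric(0); m
    },
    boundary_arity = function(m) {
      i <- which(m$reactions$id == "EX_glc_D_e")
      m$reactions$stoich[[i]] <- c(`glc_D[e]` = -1, `h2o[e]` = 1); m
    },
    unknown_compartment = function(m) {
      m$metabolites$compartment[1] <- "x"; m
    }
  )
  for (nm in names(cases)) {
    rep <- validate_model(seed_defect(cases[[nm]]))
    expect_true(nm %in% rep$type, info = nm)
  }
})

test_that("mass balance check flags stoichiometric imbalance and skips boundaries", {
  mets <- tibble::tibble(id = c("x[c]", "y[c]"), name = c("x", "y"),
                         compartment = "c", formula = "C2H4O2",
                         charge = c(0L, 0L))
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "iso", stoich = list(c(`x[c]` = -1, `y[c]` = 1)),
                   lower_bound = 0, upper_bound = 10, subsystem = "",
                   gpr = "", is_exchange = FALSE, is_sink = FALSE),
    tibble::tibble(id = "dup", stoich = list(c(`x[c]` = -1, `y[c]` = 2)),
                   lower_bound = 0, upper_bound = 10, subsystem = "",
                   gpr = "", is_exchange = FALSE, is_sink = FALSE),
    tibble::tibble(id = "EX_x", stoich = list(c(`x[c]` = 1)),
                   lower_bound = 0, upper_bound = 10, subsystem = "",
                   gpr = "", is_exchange = TRUE, is_sink = FALSE)
  )
  m <- metabolic_model(mets, rxns, character(), objective_id = "EX_x")
  rep <- validate_model(m)
  expect_identical(rep$id[rep$type == "mass_imbalance"], "dup")
  # A -> B with identical formulas is balanced; the exchange is skipped
  expect_false("iso" %in% rep$id)
  expect_false("EX_x" %in% rep$id)
})

test_that("every internal reaction of the cobalamin extension is mass-balanced", {
  # element-count oracle: recompute balances independently of the validator
  mod <- build_fixture_model()
  ext <- build_cobalamin_extension()
  formulas <- stats::setNames(mod$metabolites$formula, mod$metabolites$id)
  count_elements <- function(f) {
    parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*\\.?[0-9]*", f))[[1]]
    el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
    n <- suppressWarnings(as.numeric(sub("^[A-Z][a-z]?", "", parts)))
    n[is.na(n)] <- 1
    tapply(n, el, sum)
  }
  for (i in seq_len(nrow(ext$reactions))) {
    r <- ext$reactions[i, ]
    if (r$is_exchange || r$is_sink) next
    st <- r$stoich[[1]]
    fs <- formulas[names(st)]
    if (any(is.na(fs))) next  # heterogeneous pools carry no formula
    tot <- list()
    for (k in seq_along(st)) {
      cnt <- count_elements(fs[[k]])
      for (el in names(cnt)) tot[[el]] <- (tot[[el]] %||% 0) + st[[k]] * cnt[[el]]
    }
    expect_true(all(abs(unlist(tot)) < 1e-9), info = r$id)
  }
})

test_that("a minimal SBML L3 FBC file can be imported", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">
 <model id="mini" fbc:strict="true">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
   <species id="B" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="lb0" value="0" constant="true"/>
   <parameter id="ub10" value="10" constant="true"/>
  </listOfParameters>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="g1" fbc:label="g1"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="EX_A" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="AB" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <fbc:geneProductAssociation><fbc:geneProductRef fbc:geneProduct="g1"/></fbc:geneProductAssociation>
    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="EX_B" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="EX_B" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  mod <- read_model(path, format = "sbml")
  expect_identical(nrow(mod$reactions), 3L)
  expect_identical(mod$objective_id, "EX_B")
  expect_identical(mod$reactions$gpr[mod$reactions$id == "AB"], "g1")
  expect_equal(solve_fba(mod)$objective_value, 10)
})

test_that("add_reactions is non-destructive and rejects collisions", {
  base <- build_base_model()
  same <- add_reactions(base)
  expect_identical(same$reactions$id, base$reactions$id)

  plus <- add_reactions(
    base,
    new_reactions = tibble::tibble(
      id = "SK_pheme_extra", stoich = list(c(`pheme[m]` = -1)),
      lower_bound = 0, upper_bound = 10, subsystem = "", gpr = "",
      is_exchange = FALSE, is_sink = TRUE
    )
  )
  expect_identical(nrow(plus$reactions), nrow(base$reactions) + 1L)
  expect_identical(nrow(plus$metabolites), nrow(base$metabolites))
  # original untouched
  expect_false("SK_pheme_extra" %in% base$reactions$id)

  expect_error(
    add_reactions(base, new_reactions = base$reactions[1, ]),
    "collision.*EX_glc_D_e"
  )
  expect_error(add_reactions(base, new_genes = "MMUT"), "collision")
})
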