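# Curated toy fibroblast network with an explicit cobalamin pathway.
#
# The network is a hand-curated miniature (not a reduction of a genome-scale
# reconstruction): a glycolysis stub, a TCA segment around succinyl-CoA,
# valine/isoleucine catabolism into propionyl-CoA and methylmalonyl-CoA,
# methionine and folate cycles, a heme branch fed by succinyl-CoA, ketone
# and carnitine handling that consume succinyl-CoA, and a biomass reaction
# that does not require heme (so cobalamin-pathway knockouts are viable).
# Currency metabolites (ATP, NAD(P)H, protons, water, gases, phosphate, CoA)
# live in a single cytosolic pool to keep the network small; pathway
# intermediates keep their physiological compartment.
#
# Chemistry bookkeeping: metabolites carry neutral-form formulas (with the
# corrin core written as the pseudo-elements "CoR") so the validator can
# check elemental balance of every internal reaction. Heterogeneous pools
# (protein-bound cobalamin, the degraded-cobalamin pool) carry no formula
# and are skipped by the balance checker.

fx_met <- function(id, name, formula = NA_character_) {
  comp <- sub("^.*\\[(\\w)\\]$", "\\1", id)
  tibble::tibble(id = id, name = name, compartment = comp,
                 formula = formula, charge = NA_integer_)
}

fx_rxn <- function(id, eq, subsystem, gpr = "", lb = NULL, ub = 1000,
                   exchange = FALSE, sink = FALSE) {
  if (is.null(lb)) lb <- if (grepl("<=>", eq, fixed = TRUE)) -1000 else 0
  tibble::tibble(
    id = id, stoich = list(parse_reaction_string(eq)),
    lower_bound = lb, upper_bound = ub, subsystem = subsystem, gpr = gpr,
    is_exchange = exchange, is_sink = sink
  )
}

#' The cobalamin absorption, transport and utilization extension
#'
#' A hard-coded curation of the cobalamin pathway: transcobalamin binding
#' (TCN2), receptor-mediated uptake (CD320), lysosomal export (LMBRD1/ABCD4),
#' cytosolic processing (MMACHC), branch routing (MMADHC), mitochondrial
#' adenosylation (MMAA/MMAB), methionine-synthase half-reactions
#' (METS_FORM/METS_CAT) with MTRR-dependent reactivation (METS_R_REG), and
#' the cofactor-explicit methylmalonyl-CoA mutase (MMMm_cbl). The two
#' catalytic reactions lose a small stoichiometric fraction (0.01) of their
#' cofactor to a dead-end degraded-cobalamin pool, which is what forces
#' continuous uptake through the absorption chain at steady state.
#'
#' @return An object of class `cobalamin_extension`: a list with tibbles
#'   `reactions`, `metabolites`, the character vector `genes` (the seven
#'   genes the extension adds), and `cobalamin_exchanges`.
#' @examples
#' ext <- build_cobalamin_extension()
#' nrow(ext$reactions)
#' @export
build_cobalamin_extension <- function() {
  mets <- dplyr::bind_rows(
    fx_met("hcbl[e]",   "hydroxocobalamin",               "CoRHO"),
    fx_met("cbl_tc[e]", "transcobalamin-bound cobalamin", NA),
    fx_met("hcbl[l]",   "hydroxocobalamin (lysosome)",    "CoRHO"),
    fx_met("hcbl[c]",   "hydroxocobalamin (cytosol)",     "CoRHO"),
    fx_met("cbl2[c]",   "cob(II)alamin",                  "CoR"),
    fx_met("cbl1[c]",   "cob(I)alamin",                   "CoRH"),
    fx_met("mecbl[c]",  "methylcobalamin",                "CoRCH3"),
    fx_met("cbl2[m]",   "cob(II)alamin (mitochondrion)",  "CoR"),
    fx_met("adocbl[m]", "adenosylcobalamin",              "CoRC10H11N5O3"),
    fx_met("cblox[c]",  "degraded cobalamin pool",        NA)
  )
  tr <- "Cobalamin transport"
  cm <- "Cobalamin metabolism"
  rxns <- dplyr::bind_rows(
    fx_rxn("EX_hcbl_e",   "hcbl[e] ->", "Exchange/demand reaction", exchange = TRUE),
    fx_rxn("EX_cbl_tc_e", "cbl_tc[e] ->", "Exchange/demand reaction", exchange = TRUE),
    fx_rxn("TCN2B",   "hcbl[e] -> cbl_tc[e]", tr, gpr = "TCN2", ub = 12),
    fx_rxn("CD320R",  "cbl_tc[e] + atp[c] + h2o[c] -> hcbl[l] + adp[c] + pi[c]",
           tr, gpr = "CD320", ub = 12),
    fx_rxn("LMBRDL",  "hcbl[l] -> hcbl[c]", tr, gpr = "LMBRD1 and ABCD4", ub = 12),
    fx_rxn("MMACHCP", "hcbl[c] + h[c] -> cbl2[c] + h2o[c]", cm, gpr = "MMACHC", ub = 12),
    fx_rxn("CBL2MITOm", "cbl2[c] -> cbl2[m]", tr, gpr = "MMADHC", ub = 12),
    fx_rxn("CBL2MITO2", "cbl2[c] + atp[c] + h2o[c] -> cbl2[m] + adp[c] + pi[c]",
           tr, gpr = "MMADHC", ub = 12),
    fx_rxn("METS_R_REG", "cbl2[c] + 0.5 nadph[c] -> cbl1[c] + 0.5 nadp[c]",
           "Methionine and cysteine metabolism", gpr = "MMADHC and MTRR", ub = 100),
    fx_rxn("METS_FORM", "cbl1[c] + 5mthf[c] -> mecbl[c] + thf[c]",
           "Methionine and cysteine metabolism", gpr = "MTR", ub = 100),
    fx_rxn("METS_CAT",
           "hcy_L[c] + mecbl[c] -> met_L[c] + 0.99 cbl1[c] + 0.01 cblox[c]",
           "Methionine and cysteine metabolism", gpr = "MTR", ub = 100),
    fx_rxn("MMAB_ADO2",
           "cbl2[m] + atp[c] + 0.5 nadh[c] -> adocbl[m] + pppi[c] + 0.5 nad[c] + h[c]",
           cm, gpr = "MMAA and MMAB", ub = 12),
    fx_rxn("MMACHCP2", "hcbl[c] + 0.5 nadph[c] -> cbl2[c] + 0.5 nadp[c] + h2o[c]",
           cm, gpr = "MMACHC", ub = 12),
    fx_rxn("DM_hcbl_c",   "hcbl[c] ->",   cm, sink = TRUE, ub = 2),
    fx_rxn("MMAB_ADO", "cbl2[m] + atp[c] -> adocbl[m] + pppi[c]", cm,
           gpr = "MMAA and MMAB", ub = 12),
    fx_rxn("ADOCBLHYDm", "adocbl[m] + h2o[c] -> cbl2[m] + adn[c]", cm, ub = 2),
    fx_rxn("MMMm_cbl", "lmmcoa[m] + 0.01 adocbl[m] -> succoa[m] + 0.01 cblox[c]",
           "Propionate metabolism", gpr = "MMUT"),
    fx_rxn("SK_cblox",    "cblox[c] ->",  cm, sink = TRUE, ub = 50),
    fx_rxn("DM_adocbl_m", "adocbl[m] ->", cm, sink = TRUE, ub = 2),
    fx_rxn("DM_mecbl_c",  "mecbl[c] ->",  cm, sink = TRUE, ub = 2),
    fx_rxn("DM_hcbl_l",   "hcbl[l] ->",   cm, sink = TRUE, ub = 2),
    fx_rxn("DM_cbl2_m",   "cbl2[m] ->",   cm, sink = TRUE, ub = 2),
    fx_rxn("DM_cbl2_c",   "cbl2[c] ->",   cm, sink = TRUE, ub = 2),
    fx_rxn("DM_cbl_tc_e", "cbl_tc[e] ->", cm, sink = TRUE, ub = 2)
  )
  structure(
    list(
      reactions = rxns,
      metabolites = mets,
      genes = c("TCN2", "CD320", "LMBRD1", "ABCD4", "MMACHC", "MMADHC", "MMAB"),
      cobalamin_exchanges = c("EX_hcbl_e", "EX_cbl_tc_e")
    ),
    class = "cobalamin_extension"
  )
}

#' @export
print.cobalamin_extension <- function(x, ...) {
  cat("<cobalamin_extension> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' The base toy fibroblast model (without the cobalamin extension)
#'
#' Deliberately lacks explicit cobalamin chemistry: methionine synthase and
#' methylmalonyl-CoA mutase only become functional once
#' [build_cobalamin_extension()] is applied, mirroring how cofactor-implicit
#' reconstructions are refined. Exchange reactions are created closed
#' (uptake 0); use [apply_medium()] with [fixture_medium()].
#'
#' @return A `metabolic_model`.
#' @export
build_base_model <- function() {
  mets <- dplyr::bind_rows(
    # extracellular
    fx_met("glc_D[e]", "D-glucose", "C6H12O6"),
    fx_met("val_L[e]", "L-valine", "C5H11NO2"),
    fx_met("ile_L[e]", "L-isoleucine", "C6H13NO2"),
    fx_met("met_L[e]", "L-methionine", "C5H11NO2S"),
    fx_met("ser_L[e]", "L-serine", "C3H7NO3"),
    fx_met("gly[e]",   "glycine", "C2H5NO2"),
    fx_met("glu_L[e]", "L-glutamate", "C5H9NO4"),
    fx_met("cys_L[e]", "L-cysteine", "C3H7NO2S"),
    fx_met("fol[e]",   "folate", "C19H19N7O6"),
    fx_met("fe2[e]",   "Fe2+", "Fe"),
    fx_met("o2[e]",    "oxygen", "O2"),
    fx_met("co2[e]",   "carbon dioxide", "CO2"),
    fx_met("h2o[e]",   "water", "H2O"),
    fx_met("h[e]",     "proton", "H"),
    fx_met("pi[e]",    "phosphate", "H3O4P"),
    fx_met("nh4[e]",   "ammonia", "H3N"),
    fx_met("lac_L[e]", "L-lactate", "C3H6O3"),
    fx_met("hcy_L[e]", "L-homocysteine", "C4H9NO2S"),
    fx_met("adn[e]",   "adenosine", "C10H13N5O4"),
    fx_met("bilirub[e]", "bilirubin", "C33H36N4O6"),
    fx_met("acac[e]",  "acetoacetate", "C4H6O3"),
    fx_met("crn[e]",   "L-carnitine", "C7H15NO3"),
    fx_met("succ[e]",  "succinate", "C4H6O4"),
    fx_met("mma[e]",   "methylmalonate", "C4H6O4"),
    fx_met("sarcs[e]", "sarcosine", "C3H7NO2"),
    fx_met("2obut[e]", "2-oxobutanoate", "C4H6O3"),
    fx_met("succrn[e]", "succinylcarnitine", "C11H19NO6"),
    # cytosolic (currency pool + cytosolic pathway intermediates)
    fx_met("glc_D[c]", "D-glucose", "C6H12O6"),
    fx_met("pyr[c]",   "pyruvate", "C3H4O3"),
    fx_met("lac_L[c]", "L-lactate", "C3H6O3"),
    fx_met("atp[c]",   "ATP", "C10H16N5O13P3"),
    fx_met("adp[c]",   "ADP", "C10H15N5O10P2"),
    fx_met("pi[c]",    "phosphate", "H3O4P"),
    fx_met("ppi[c]",   "diphosphate", "H4O7P2"),
    fx_met("pppi[c]",  "triphosphate", "H5O10P3"),
    fx_met("nad[c]",   "NAD+", "C21H27N7O14P2"),
    fx_met("nadh[c]",  "NADH", "C21H29N7O14P2"),
    fx_met("nadp[c]",  "NADP+", "C21H28N7O17P3"),
    fx_met("nadph[c]", "NADPH", "C21H30N7O17P3"),
    fx_met("h[c]",     "proton", "H"),
    fx_met("h2o[c]",   "water", "H2O"),
    fx_met("o2[c]",    "oxygen", "O2"),
    fx_met("co2[c]",   "carbon dioxide", "CO2"),
    fx_met("nh4[c]",   "ammonia", "H3N"),
    fx_met("coa[c]",   "coenzyme A", "C21H36N7O16P3S"),
    fx_met("ser_L[c]", "L-serine", "C3H7NO3"),
    fx_met("gly[c]",   "glycine", "C2H5NO2"),
    fx_met("glu_L[c]", "L-glutamate", "C5H9NO4"),
    fx_met("cys_L[c]", "L-cysteine", "C3H7NO2S"),
    fx_met("val_L[c]", "L-valine", "C5H11NO2"),
    fx_met("ile_L[c]", "L-isoleucine", "C6H13NO2"),
    fx_met("met_L[c]", "L-methionine", "C5H11NO2S"),
    fx_met("hcy_L[c]", "L-homocysteine", "C4H9NO2S"),
    fx_met("amet[c]",  "S-adenosyl-L-methionine", "C15H22N6O5S"),
    fx_met("ahcys[c]", "S-adenosyl-L-homocysteine", "C14H20N6O5S"),
    fx_met("adn[c]",   "adenosine", "C10H13N5O4"),
    fx_met("cyst_L[c]", "L-cystathionine", "C7H14N2O4S"),
    fx_met("2obut[c]", "2-oxobutanoate", "C4H6O3"),
    fx_met("sarcs[c]", "sarcosine", "C3H7NO2"),
    fx_met("fol[c]",   "folate", "C19H19N7O6"),
    fx_met("dhf[c]",   "dihydrofolate", "C19H21N7O6"),
    fx_met("thf[c]",   "tetrahydrofolate", "C19H23N7O6"),
    fx_met("mlthf[c]", "5,10-methylenetetrahydrofolate", "C20H23N7O6"),
    fx_met("methf[c]", "5,10-methenyltetrahydrofolate", "C20H21N7O6"),
    fx_met("10fthf[c]", "10-formyltetrahydrofolate", "C20H23N7O7"),
    fx_met("5mthf[c]", "5-methyltetrahydrofolate", "C20H25N7O6"),
    fx_met("thfglu[c]", "tetrahydrofolate polyglutamate", "C24H30N8O9"),
    fx_met("fe2[c]",   "Fe2+", "Fe"),
    fx_met("succ[c]",  "succinate", "C4H6O4"),
    fx_met("crn[c]",   "L-carnitine", "C7H15NO3"),
    fx_met("succrn[c]", "succinylcarnitine", "C11H19NO6"),
    fx_met("pheme[c]", "protoheme", "C34H32FeN4O4"),
    fx_met("bilirub[c]", "bilirubin", "C33H36N4O6"),
    fx_met("acac[c]",  "acetoacetate", "C4H6O3"),
    # mitochondrial
    fx_met("pyr[m]",   "pyruvate", "C3H4O3"),
    fx_met("accoa[m]", "acetyl-CoA", "C23H38N7O17P3S"),
    fx_met("oaa[m]",   "oxaloacetate", "C4H4O5"),
    fx_met("cit[m]",   "citrate", "C6H8O7"),
    fx_met("akg[m]",   "2-oxoglutarate", "C5H6O5"),
    fx_met("succoa[m]", "succinyl-CoA", "C25H40N7O19P3S"),
    fx_met("succ[m]",  "succinate", "C4H6O4"),
    fx_met("fum[m]",   "fumarate", "C4H4O4"),
    fx_met("mal_L[m]", "L-malate", "C4H6O5"),
    fx_met("ppcoa[m]", "propionyl-CoA", "C24H40N7O17P3S"),
    fx_met("dmmcoa[m]", "D-methylmalonyl-CoA", "C25H40N7O19P3S"),
    fx_met("lmmcoa[m]", "L-methylmalonyl-CoA", "C25H40N7O19P3S"),
    fx_met("mma[m]",   "methylmalonate", "C4H6O4"),
    fx_met("acac[m]",  "acetoacetate", "C4H6O3"),
    fx_met("aacoa[m]", "acetoacetyl-CoA", "C25H40N7O18P3S"),
    fx_met("succrn[m]", "succinylcarnitine", "C11H19NO6"),
    fx_met("5aop[m]",  "5-aminolevulinate", "C5H9NO3"),
    fx_met("pbg[m]",   "porphobilinogen", "C10H14N2O4"),
    fx_met("ppp9[m]",  "protoporphyrin IX", "C34H34N4O4"),
    fx_met("pheme[m]", "protoheme", "C34H32FeN4O4"),
    fx_met("fe2[m]",   "Fe2+", "Fe")
  )

  ex <- function(id, met, ub = 1000) {
    fx_rxn(id, paste(met, "->"), "Exchange/demand reaction",
           lb = 0, ub = ub, exchange = TRUE)
  }
  tp <- function(id, eq, gpr = "") fx_rxn(id, eq, "Transport", gpr = gpr)

  rxns <- dplyr::bind_rows(
    # exchanges (all created closed; fixture_medium() opens uptakes)
    ex("EX_glc_D_e", "glc_D[e]"), ex("EX_val_L_e", "val_L[e]"),
    ex("EX_ile_L_e", "ile_L[e]"), ex("EX_met_L_e", "met_L[e]"),
    ex("EX_ser_L_e", "ser_L[e]"), ex("EX_gly_e", "gly[e]"),
    ex("EX_glu_L_e", "glu_L[e]"), ex("EX_cys_L_e", "cys_L[e]"),
    ex("EX_fol_e", "fol[e]"), ex("EX_fe2_e", "fe2[e]"),
    ex("EX_o2_e", "o2[e]", ub = 1e5), ex("EX_co2_e", "co2[e]", ub = 1e5),
    ex("EX_h2o_e", "h2o[e]", ub = 1e5), ex("EX_h_e", "h[e]", ub = 1e5),
    ex("EX_pi_e", "pi[e]", ub = 1e5), ex("EX_nh4_e", "nh4[e]", ub = 1e5),
    ex("EX_lac_L_e", "lac_L[e]"), ex("EX_hcy_L_e", "hcy_L[e]"),
    ex("EX_adn_e", "adn[e]"),
    ex("EX_bilirub_e", "bilirub[e]"), ex("EX_acac_e", "acac[e]"),
    ex("EX_crn_e", "crn[e]"), ex("EX_succ_e", "succ[e]"),
    ex("EX_mma_e", "mma[e]"), ex("EX_sarcs_e", "sarcs[e]"),
    ex("EX_2obut_e", "2obut[e]"), ex("EX_succrn_e", "succrn[e]"),
    # transport
    tp("GLCt", "glc_D[e] <=> glc_D[c]"),
    tp("VALt", "val_L[e] <=> val_L[c]", gpr = "SLC7A5"),
    tp("ILEt", "ile_L[e] <=> ile_L[c]", gpr = "SLC7A5"),
    tp("METt", "met_L[e] <=> met_L[c]", gpr = "SLC7A5"),
    tp("SERt", "ser_L[e] <=> ser_L[c]"),
    tp("GLYt", "gly[e] <=> gly[c]"),
    tp("GLUt", "glu_L[e] <=> glu_L[c]"),
    tp("CYSt", "cys_L[e] <=> cys_L[c]"),
    tp("FOLt", "fol[e] <=> fol[c]", gpr = "SLC19A1"),
    tp("FE2t", "fe2[e] <=> fe2[c]"),
    tp("O2t", "o2[e] <=> o2[c]"),
    tp("CO2t", "co2[c] <=> co2[e]"),
    tp("H2Ot", "h2o[c] <=> h2o[e]"),
    tp("Ht", "h[c] <=> h[e]"),
    tp("PIt", "pi[e] <=> pi[c]"),
    tp("NH4t", "nh4[c] <=> nh4[e]"),
    tp("LACt", "lac_L[c] <=> lac_L[e]", gpr = "SLC16A1"),
    tp("HCYt", "hcy_L[c] -> hcy_L[e]"),
    tp("ADNt", "adn[c] <=> adn[e]"),
    tp("BILIRUBt", "bilirub[c] <=> bilirub[e]"),
    tp("ACACt", "acac[e] <=> acac[c]"),
    tp("ACACtm", "acac[c] -> acac[m]"),
    tp("CRNt", "crn[e] <=> crn[c]", gpr = "SLC22A5"),
    tp("SUCCtm", "succ[m] <=> succ[c]"),
    tp("SUCCt", "succ[c] <=> succ[e]"),
    tp("MMAtm", "mma[m] -> mma[e]"),
    tp("SARCSt", "sarcs[c] <=> sarcs[e]"),
    tp("2OBUTt", "2obut[c] <=> 2obut[e]"),
    tp("SUCCRNtm", "succrn[m] -> succrn[c]"),
    tp("SUCCRNt", "succrn[c] <=> succrn[e]"),
    tp("PYRtm", "pyr[c] <=> pyr[m]", gpr = "MPC1"),
    tp("PHEMEtm", "pheme[m] -> pheme[c]"),
    tp("FE2tm", "fe2[c] <=> fe2[m]"),
    # metabolite needed by transport row above but produced cytosolically
    fx_rxn("GLYCl",
           "glc_D[c] + 2 adp[c] + 2 pi[c] + 2 nad[c] -> 2 pyr[c] + 2 atp[c] + 2 nadh[c] + 2 h2o[c]",
           "Glycolysis/gluconeogenesis", gpr = "PKM"),
    fx_rxn("LDH_L", "pyr[c] + nadh[c] <=> lac_L[c] + nad[c]",
           "Glycolysis/gluconeogenesis", gpr = "LDHA or LDHB"),
    fx_rxn("MATc", "met_L[c] + atp[c] + h2o[c] -> amet[c] + pi[c] + ppi[c]",
           "Methionine and cysteine metabolism", gpr = "MAT2A or MAT1A"),
    fx_rxn("GNMTc", "amet[c] + gly[c] -> ahcys[c] + sarcs[c]",
           "Glycine, serine, alanine, and threonine metabolism", gpr = "GNMT"),
    fx_rxn("AHCc", "ahcys[c] + h2o[c] <=> hcy_L[c] + adn[c]",
           "Methionine and cysteine metabolism", gpr = "AHCY"),
    fx_rxn("CBSc", "hcy_L[c] + ser_L[c] -> cyst_L[c] + h2o[c]",
           "Methionine and cysteine metabolism", gpr = "CBS"),
    fx_rxn("CTHc", "cyst_L[c] + h2o[c] -> cys_L[c] + 2obut[c] + nh4[c]",
           "Methionine and cysteine metabolism", gpr = "CTH"),
    fx_rxn("SHMTc", "ser_L[c] + thf[c] <=> gly[c] + mlthf[c] + h2o[c]",
           "Folate metabolism", gpr = "SHMT1 or SHMT2"),
    fx_rxn("MTHFDc", "mlthf[c] + nadp[c] <=> methf[c] + nadph[c]",
           "Folate metabolism", gpr = "MTHFD1"),
    fx_rxn("MTHFCc", "methf[c] + h2o[c] <=> 10fthf[c]",
           "Folate metabolism", gpr = "MTHFD1"),
    fx_rxn("MTHFRc", "mlthf[c] + nadph[c] -> 5mthf[c] + nadp[c]",
           "Folate metabolism", gpr = "MTHFR"),
    fx_rxn("FOLR2c", "fol[c] + nadph[c] -> dhf[c] + nadp[c]",
           "Folate metabolism", gpr = "DHFR"),
    fx_rxn("DHFRc", "dhf[c] + nadph[c] -> thf[c] + nadp[c]",
           "Folate metabolism", gpr = "DHFR"),
    fx_rxn("FPGSc", "thf[c] + glu_L[c] + atp[c] -> thfglu[c] + adp[c] + pi[c]",
           "Folate metabolism", gpr = "FPGS"),
    fx_rxn("ADNSALVc", "adn[c] + 2 atp[c] -> 3 adp[c]",
           "Nucleotide interconversion", gpr = "ADK"),
    fx_rxn("NADPHSc", "nadh[c] + nadp[c] -> nad[c] + nadph[c]",
           "Miscellaneous"),
    fx_rxn("PPIHc", "ppi[c] + h2o[c] -> 2 pi[c]", "Miscellaneous"),
    fx_rxn("PPPIHc", "pppi[c] + h2o[c] -> ppi[c] + pi[c]", "Miscellaneous"),
    fx_rxn("ATPM", "atp[c] + h2o[c] -> adp[c] + pi[c]", "Miscellaneous",
           lb = 20),
    fx_rxn("FAOXC4C4DCc", "succrn[c] + h2o[c] -> succ[c] + crn[c]",
           "Fatty acid oxidation", gpr = "CPT2"),
    fx_rxn("HMOX1c",
           "pheme[c] + 3 o2[c] + 2 nadph[c] + 4 h[c] -> bilirub[c] + fe2[c] + co2[c] + 2 nadp[c] + 2 h2o[c]",
           "Heme degradation", gpr = "HMOX1"),
    # mitochondrion
    fx_rxn("PDHm", "pyr[m] + coa[c] + nad[c] -> accoa[m] + co2[c] + nadh[c]",
           "Glycolysis/gluconeogenesis", gpr = "PDHA1"),
    fx_rxn("PCm", "pyr[m] + co2[c] + atp[c] + h2o[c] -> oaa[m] + adp[c] + pi[c]",
           "Citric acid cycle", gpr = "PC"),
    fx_rxn("CSm", "accoa[m] + oaa[m] + h2o[c] -> cit[m] + coa[c]",
           "Citric acid cycle", gpr = "CS"),
    fx_rxn("ICDHxm", "cit[m] + nad[c] -> akg[m] + co2[c] + nadh[c]",
           "Citric acid cycle", gpr = "IDH3A"),
    fx_rxn("AKGDm", "akg[m] + coa[c] + nad[c] -> succoa[m] + co2[c] + nadh[c]",
           "Citric acid cycle", gpr = "OGDH", ub = 5),
    fx_rxn("SUCOASm", "succoa[m] + adp[c] + pi[c] <=> succ[m] + atp[c] + coa[c]",
           "Citric acid cycle", gpr = "SUCLG1 and SUCLA2"),
    fx_rxn("SUCD1m", "succ[m] + nad[c] -> fum[m] + nadh[c]",
           "Citric acid cycle", gpr = "SDHA"),
    fx_rxn("FUMm", "fum[m] + h2o[c] <=> mal_L[m]",
           "Citric acid cycle", gpr = "FH"),
    fx_rxn("MDHm", "mal_L[m] + nad[c] <=> oaa[m] + nadh[c]",
           "Citric acid cycle", gpr = "MDH2"),
    fx_rxn("OXPHOSm",
           "nadh[c] + 0.5 o2[c] + 2.5 adp[c] + 2.5 pi[c] -> nad[c] + 2.5 atp[c] + 3.5 h2o[c]",
           "Oxidative phosphorylation", gpr = "NDUFS1"),
    fx_rxn("VALDHm",
           "val_L[c] + coa[c] + 5 nad[c] + 3 h2o[c] -> ppcoa[m] + 2 co2[c] + 5 nadh[c] + nh4[c]",
           "Valine, leucine, and isoleucine metabolism", gpr = "ACAD8"),
    fx_rxn("ILEDHm",
           "ile_L[c] + 2 coa[c] + 4 nad[c] + 2 h2o[c] -> ppcoa[m] + accoa[m] + co2[c] + 4 nadh[c] + nh4[c]",
           "Valine, leucine, and isoleucine metabolism", gpr = "ACADSB"),
    fx_rxn("OBDHm", "2obut[c] + coa[c] + nad[c] -> ppcoa[m] + co2[c] + nadh[c]",
           "Propionate metabolism", gpr = "DBT", ub = 2),
    fx_rxn("PCCm", "ppcoa[m] + co2[c] + atp[c] + h2o[c] -> dmmcoa[m] + adp[c] + pi[c]",
           "Propionate metabolism", gpr = "PCCA and PCCB"),
    fx_rxn("MMEm", "dmmcoa[m] <=> lmmcoa[m]",
           "Propionate metabolism", gpr = "MCEE"),
    fx_rxn("MMCOAHm", "dmmcoa[m] + h2o[c] -> mma[m] + coa[c]",
           "Propionate metabolism"),
    fx_rxn("ACACT1m", "aacoa[m] + coa[c] <=> 2 accoa[m]",
           "Ketone body metabolism", gpr = "ACAT1"),
    fx_rxn("OCOAT1m", "acac[m] + succoa[m] -> aacoa[m] + succ[m]",
           "Ketone body metabolism", gpr = "OXCT1"),
    fx_rxn("SUCCOAPETm", "succoa[m] + h2o[c] -> succ[m] + coa[c]",
           "Fatty acid synthesis", gpr = "ACOT13"),
    fx_rxn("SUCCCROTm", "succoa[m] + crn[c] -> succrn[m] + coa[c]",
           "Fatty acid oxidation", gpr = "CROT"),
    fx_rxn("ALASm", "succoa[m] + gly[c] -> 5aop[m] + co2[c] + coa[c]",
           "Heme synthesis", gpr = "ALAS1 or ALAS2"),
    fx_rxn("PBGSm", "2 5aop[m] -> pbg[m] + 2 h2o[c]",
           "Heme synthesis", gpr = "ALAD"),
    fx_rxn("PPP9Sm", "4 pbg[m] + 2.5 o2[c] -> ppp9[m] + 6 co2[c] + 4 nh4[c] + 5 h2o[c]",
           "Heme synthesis", gpr = "HMBS"),
    fx_rxn("FCLTm", "ppp9[m] + fe2[m] -> pheme[m] + 2 h[c]",
           "Heme synthesis", gpr = "FECH"),
    # cellular methylation demand beyond the biomass requirement
    fx_rxn("DM_amet_c", "amet[c] ->", "Methionine and cysteine metabolism",
           sink = TRUE, ub = 20),
    # heme incorporation into cellular hemoproteins
    fx_rxn("DM_pheme_c", "pheme[c] ->", "Heme synthesis", sink = TRUE, ub = 20),
    # biomass (objective; amino acids, one-carbon units, methylation demand, ATP)
    fx_rxn("BIOMASS_fib",
           paste("20 atp[c] + 20 h2o[c] + 0.2 ser_L[c] + 0.3 gly[c] + 0.2 val_L[c]",
                 "+ 0.2 ile_L[c] + 0.1 met_L[c] + 0.05 cys_L[c] + 0.05 10fthf[c]",
                 "+ 0.02 thfglu[c] + 0.1 glu_L[c] + 0.05 amet[c]",
                 "-> 20 adp[c] + 20 pi[c] + 0.05 ahcys[c]"),
           "Biomass")
  )

  genes <- c(
    "MMUT", "MTR", "MTRR", "MMAA",
    "PKM", "LDHA", "LDHB", "PDHA1", "PC", "CS", "IDH3A", "OGDH", "SUCLG1", "SUCLA2",
    "SDHA", "FH", "MDH2", "NDUFS1", "MPC1",
    "MAT2A", "MAT1A", "GNMT", "AHCY", "CBS", "CTH", "ADK",
    "SHMT1", "SHMT2", "MTHFD1", "MTHFR", "DHFR", "FPGS",
    "ACAD8", "ACADSB", "DBT", "PCCA", "PCCB", "MCEE",
    "ACAT1", "OXCT1", "ACOT13", "CROT", "CPT2",
    "ALAS1", "ALAS2", "ALAD", "HMBS", "FECH", "HMOX1",
    "SLC7A5", "SLC19A1", "SLC16A1", "SLC22A5"
  )

  metabolic_model(
    metabolites = mets, reactions = rxns, genes = genes,
    objective_id = "BIOMASS_fib",
    compartments = c("c", "e", "l", "m")
  )
}

#' DMEM-like medium for the fixture model
#'
#' Maximum uptake rates (flux units) for the exchange reactions of a
#' DMEM-like culture medium, including hydroxocobalamin so the cobalamin
#' pathway is functional in the wild type.
#'
#' @return Named numeric vector suitable for [apply_medium()].
#' @export
fixture_medium <- function() {
  c(
    EX_glc_D_e = 300, EX_val_L_e = 30, EX_ile_L_e = 30, EX_met_L_e = 4,
    EX_ser_L_e = 60, EX_gly_e = 80, EX_glu_L_e = 20, EX_cys_L_e = 5,
    EX_fol_e = 2, EX_fe2_e = 10, EX_o2_e = 400, EX_h2o_e = 1000,
    EX_h_e = 100, EX_pi_e = 100, EX_acac_e = 40, EX_crn_e = 40,
    EX_adn_e = 5, EX_hcbl_e = 10
  )
}

#' The full fixture model: toy fibroblast plus cobalamin extension
#'
#' Applies [build_cobalamin_extension()] to [build_base_model()] via
#' [add_reactions()] and constrains the exchanges with [fixture_medium()].
#' On this medium the biomass objective is feasible, does not require heme,
#' and remains feasible under every single-gene knockout of the battery
#' (knockouts reshape flux spans rather than abolish growth).
#'
#' @param medium Named uptake vector; defaults to [fixture_medium()].
#' @return A `metabolic_model`.
#' @examples
#' mod <- build_fixture_model()
#' solve_fba(mod)$objective_value
#' @export
build_fixture_model <- function(medium = fixture_medium()) {
  base <- build_base_model()
  ext <- build_cobalamin_extension()
  mod <- add_reactions(base,
                       new_reactions = ext$reactions,
                       new_metabolites = ext$metabolites,
                       new_genes = ext$genes,
                       cobalamin_exchanges = ext$cobalamin_exchanges)
  apply_medium(mod, medium)
}
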