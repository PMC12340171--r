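# Synthetic expression cohorts with the group structure of a fibroblast
# methylmalonic-aciduria study: healthy controls, mut0 (complete
# methylmalonyl-CoA mutase deficiency), mut- (partial deficiency), and
# other causes of MMA, with per-sample symptom/treatment flags.

#' Describe a synthetic cohort design
#'
#' Defaults mirror the study structure the package emulates: 19 controls,
#' 143 mut-type patients (72 mut0 + 71 mut-), and 59 other-MMA patients
#' (221 samples in total). Expression is drawn from a bimodal log-normal
#' model (unexpressed mode at log2 ~1, expressed mode at log2 ~8, per-sample
#' dispersion sigma = 1 on the log2 scale), which makes the two expression
#' populations unambiguous for the mixture-model gene caller. Planted
#' effects: mut0 samples have MMUT at the unexpressed mode, mut- samples at
#' `mutminus_residual` times the control mean (partial activity), other-MMA
#' samples have normal MMUT but a reduced alternative causal gene; carriers
#' of failure to thrive have energy-pathway genes down-scaled.
#'
#' @param n_control,n_mut0,n_mutminus,n_other Group sizes.
#' @param mutminus_residual Multiplicative residual MMUT expression of mut-
#'   samples (default 0.25).
#' @param other_causal_gene Gene reduced in other-MMA samples (default
#'   `"SUCLA2"`, succinyl-CoA ligase deficiency).
#' @param other_causal_residual Residual expression factor for that gene.
#' @param gene_classes Tibble `gene`, `class` (`"high"` or `"off"`); defaults
#'   to every fixture-model gene expressed except a small set of
#'   fibroblast-silent isozymes (GNMT, MAT1A, ALAS2, LDHB, SHMT2).
#' @param off_log2,on_log2 Mode centres of the bimodal baseline (log2 RPKM).
#' @param gene_spread Between-gene standard deviation of baseline means.
#' @param sigma Per-sample log2 dispersion (noise).
#' @param plant_effects When `FALSE`, no disease or symptom expression
#'   effects are planted (a null cohort: every group is drawn from the same
#'   distribution), used for type-I-error calibration.
#' @param symptoms Tibble `symptom`, `prevalence` (per patient group;
#'   controls carry no symptoms), `effect_genes` (list column),
#'   `effect_factor`. Defaults: nine symptom/treatment flags, failure to
#'   thrive at prevalence 0.40 with a global 0.7x down-scaling of
#'   energy-pathway genes, muscle hypotonia at 0.21, reduced consciousness
#'   at 0.26, all others at 0.20 with no planted expression effect.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_control = 19, n_mut0 = 72, n_mutminus = 71,
                          n_other = 59, mutminus_residual = 0.25,
                          other_causal_gene = "SUCLA2",
                          other_causal_residual = 0.25,
                          gene_classes = default_gene_classes(),
                          off_log2 = 1, on_log2 = 8, gene_spread = 0.5,
                          sigma = 1, symptoms = default_symptoms(),
                          plant_effects = TRUE, seed = 1L) {
  counts <- c(n_control, n_mut0, n_mutminus, n_other)
  if (any(counts < 0)) stop("group sizes must be non-negative", call. = FALSE)
  if (any(symptoms$prevalence < 0 | symptoms$prevalence > 1)) {
    stop("symptom prevalences must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_control = n_control, n_mut0 = n_mut0, n_mutminus = n_mutminus,
         n_other = n_other, mutminus_residual = mutminus_residual,
         other_causal_gene = other_causal_gene,
         other_causal_residual = other_causal_residual,
         gene_classes = tibble::as_tibble(gene_classes),
         off_log2 = off_log2, on_log2 = on_log2, gene_spread = gene_spread,
         sigma = sigma, symptoms = tibble::as_tibble(symptoms),
         plant_effects = isTRUE(plant_effects), seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' @rdname cohort_design
#' @export
default_gene_classes <- function() {
  genes <- build_fixture_model()$genes
  off <- c("GNMT", "MAT1A", "ALAS2", "LDHB", "SHMT2")
  tibble::tibble(gene = genes,
                 class = ifelse(genes %in% off, "off", "high"))
}

#' @rdname cohort_design
#' @export
default_symptoms <- function() {
  energy <- c("PKM", "PDHA1", "PC", "CS", "IDH3A", "OGDH", "SDHA", "FH",
              "MDH2", "NDUFS1", "SUCLG1", "SUCLA2")
  tibble::tibble(
    symptom = c("failure_to_thrive", "hematological_abnormality",
                "neurological_abnormality", "hyperammonemia", "ketosis",
                "reduced_consciousness", "muscle_hypotonia", "antibiotics",
                "protein_restriction"),
    prevalence = c(0.40, 0.20, 0.20, 0.20, 0.20, 0.26, 0.21, 0.20, 0.20),
    effect_genes = c(list(energy), rep(list(character()), 8)),
    effect_factor = c(0.7, rep(1, 8))
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", x$n_control, " control + ", x$n_mut0, " mut0 + ",
      x$n_mutminus, " mut- + ", x$n_other, " other = ",
      x$n_control + x$n_mut0 + x$n_mutminus + x$n_other, " samples; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw symptom/treatment flags for a cohort
#'
#' Independent Bernoulli draws per symptom at the design's per-group
#' prevalence; control samples carry no symptoms.
#'
#' @param metadata Tibble with `sample_id` and `group`.
#' @param design A [cohort_design()].
#' @param seed Seed for the draws (defaults to `design$seed + 1`).
#' @return `metadata` with one 0/1 column per symptom.
#' @export
assign_symptoms <- function(metadata, design, seed = design$seed + 1L) {
  with_seed(seed, {
    for (i in seq_len(nrow(design$symptoms))) {
      sym <- design$symptoms$symptom[i]
      p <- design$symptoms$prevalence[i]
      draw <- stats::rbinom(nrow(metadata), 1, p)
      draw[metadata$group == "control"] <- 0L
      metadata[[sym]] <- as.integer(draw)
    }
    metadata
  })
}

#' Generate a synthetic expression cohort
#'
#' Draws an RPKM expression matrix over the fixture-model genes with the
#' design's group structure, planted disease effects and symptom effects,
#' plus sample metadata and the ground truth needed to score recovery.
#'
#' @param design A [cohort_design()].
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   (tibble, `gene_id` plus one column per sample, RPKM), `metadata`
#'   (tibble: `sample_id`, `group`, symptom columns), `truth` (list:
#'   per-gene baseline means, per-sample subtype, planted effects), and
#'   `units = "rpkm"`.
#' @examples
#' co <- generate_cohort(cohort_design(n_control = 3, n_mut0 = 3,
#'                                     n_mutminus = 2, n_other = 2))
#' dim(co$expression)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- c(rep("control", design$n_control), rep("mut0", design$n_mut0),
              rep("mutminus", design$n_mutminus), rep("other", design$n_other))
  n <- length(groups)
  if (n == 0) stop("cohort design has zero samples", call. = FALSE)
  sample_id <- sprintf("S%03d", seq_len(n))
  metadata <- tibble::tibble(sample_id = sample_id, group = groups)
  metadata <- assign_symptoms(metadata, design)
  genes <- design$gene_classes$gene
  cls <- design$gene_classes$class
  expr <- with_seed(design$seed, {
    base_mean <- ifelse(cls == "off", design$off_log2, design$on_log2) +
      stats::rnorm(length(genes), 0, design$gene_spread)
    names(base_mean) <- genes
    m <- matrix(stats::rnorm(length(genes) * n, 0, design$sigma),
                nrow = length(genes), ncol = n,
                dimnames = list(genes, sample_id))
    m <- m + base_mean
    # planted disease effects
    if (design$plant_effects && "MMUT" %in% genes) {
      mut0_shift <- design$off_log2 - base_mean[["MMUT"]]
      m["MMUT", groups == "mut0"] <- m["MMUT", groups == "mut0"] + mut0_shift
      m["MMUT", groups == "mutminus"] <-
        m["MMUT", groups == "mutminus"] + log2(design$mutminus_residual)
    }
    if (design$plant_effects && design$other_causal_gene %in% genes) {
      m[design$other_causal_gene, groups == "other"] <-
        m[design$other_causal_gene, groups == "other"] +
        log2(design$other_causal_residual)
    }
    # planted symptom effects on expression (upstream of the whole pipeline)
    for (i in seq_len(if (design$plant_effects) nrow(design$symptoms) else 0)) {
      eg <- intersect(design$symptoms$effect_genes[[i]], genes)
      fac <- design$symptoms$effect_factor[i]
      if (!length(eg) || fac == 1) next
      carriers <- metadata[[design$symptoms$symptom[i]]] == 1
      m[eg, carriers] <- m[eg, carriers] + log2(fac)
    }
    list(mat = 2^m, base_mean = base_mean)
  })
  expression <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(expr$mat)
  )
  structure(
    list(
      expression = expression,
      metadata = metadata,
      truth = list(
        base_mean_log2 = expr$base_mean,
        subtype = stats::setNames(groups, sample_id),
        gene_classes = design$gene_classes,
        planted = list(
          mut0_gene = "MMUT",
          mutminus_residual = design$mutminus_residual,
          other_causal_gene = design$other_causal_gene,
          symptoms = design$symptoms
        )
      ),
      units = "rpkm"
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$expression), " genes x ",
      ncol(x$expression) - 1, " samples (", x$units, ")\n", sep = "")
  print(table(x$metadata$group))
  invisible(x)
}
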