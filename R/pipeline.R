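# End-to-end helpers: simulate a trial, estimate EBVs, and feed the
# marker-density experiment. One master seed drives every stage through
# independent child streams.

#' Simulate a complete progeny trial
#'
#' Chains map construction, founder simulation, gene drop and phenotype
#' simulation for a mating design, deriving a deterministic child seed
#' for each stage from one master seed.
#'
#' @param design a [full_sib_design()] or [half_sib_design()].
#' @param seed master seed.
#' @param n_chromosomes,total_length_cM,n_markers map parameters
#'   (defaults: 12 chromosomes, 2,000 cM — the conifer-scale map).
#' @param n_qtl causal loci for the polygenic trait.
#' @param vc target [variance_components()]; defaults to the full-sib
#'   defaults, with the family terms zeroed and their variance folded
#'   into the residual for half-sib designs.
#' @param maf_min founder allele-frequency bound.
#' @return An object of class `sim_trial`: list with `pop`, `phenotypes`,
#'   `arch`, `map`, `design`, `seed`.
#' @export
simulate_trial <- function(design, seed, n_chromosomes = 12,
                           total_length_cM = 2000, n_markers = 46300,
                           n_qtl = 300, vc = NULL, maf_min = 0.05) {
  stopifnot(inherits(design, "mating_design"))
  if (is.null(vc)) {
    vc <- if (design$kind == "full-sib") {
      variance_components()
    } else {
      variance_components(sigma2_sf = 0, sigma2_f = 0, sigma2_e = 6.5)
    }
  }
  map <- make_genetic_map(n_chromosomes, total_length_cM, n_markers,
                          seed = child_seed(seed, 1))
  founders <- simulate_founders(n_founders_required(design), map,
                                maf_min = maf_min,
                                seed = child_seed(seed, 2))
  pop <- simulate_population(founders, design, map,
                             seed = child_seed(seed, 3))
  arch <- trait_architecture(map, n_qtl = n_qtl, vc = vc,
                             seed = child_seed(seed, 4))
  phen <- simulate_phenotypes(pop, arch, seed = child_seed(seed, 5))
  structure(list(pop = pop, phenotypes = phen, arch = arch, map = map,
                 design = design, seed = seed),
            class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf("sim_trial (%s, seed %d): ", x$design$kind, x$seed))
  print(x$pop)
  invisible(x)
}

#' Estimate breeding values for a simulated trial
#'
#' Builds the pedigree relationship matrix, estimates variance
#' components by [em_reml()] (or accepts supplied ones), solves the
#' mixed-model equations, and returns the offspring EBVs in trial order
#' — the response used by the genomic-prediction experiment.
#'
#' @param trial a [simulate_trial()] object.
#' @param vc optional known [variance_components()]; when `NULL`,
#'   EM-REML estimates are used.
#' @param tol,max_iter EM-REML controls (see [em_reml()]).
#' @return List with `ebv` (named vector over offspring), `A`, `spec`,
#'   `vc` (components used), `reml` (the `variance_estimates`, or NULL),
#'   `fit` (full `ebv_result`) and `h2`.
#' @export
trial_ebv <- function(trial, vc = NULL, tol = 1e-4, max_iter = 200) {
  stopifnot(inherits(trial, "sim_trial"))
  kind <- if (trial$design$kind == "full-sib") "fullsib" else "halfsib"
  spec <- model_spec(kind)
  A <- build_numerator_relationship(trial$pop$pedigree)
  pheno <- trial$phenotypes$pheno
  reml <- NULL
  if (is.null(vc)) {
    reml <- em_reml(pheno, spec, A, tol = tol, max_iter = max_iter)
    vc <- reml$vc
  }
  fit <- fit_ablup(pheno, spec, A, vc)
  ebv <- fit$ebv[as.character(trial$pop$info$id)]
  list(ebv = ebv, A = A, spec = spec, vc = vc, reml = reml, fit = fit,
       h2 = heritability(vc, kind))
}

#' Status number of a simulated trial's offspring crop
#'
#' Pedigree-based effective size of the planted trees, using founder
#' (and phantom unknown-parent) contributions.
#'
#' @param trial a [simulate_trial()] object.
#' @return Ns.
#' @export
trial_status_number <- function(trial) {
  stopifnot(inherits(trial, "sim_trial"))
  status_number_pedigree(trial$pop$pedigree, trial$pop$info$id)
}
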