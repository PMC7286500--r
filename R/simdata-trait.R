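# Trait architecture and phenotype simulation for the progeny trials.

#' Variance components of the trial mixed models
#'
#' Container for the variance terms of the two trial models: additive
#' genetic (`sigma2_a`), site x additive interaction (`sigma2_sa`), block
#' within site (`sigma2_srep`), site x family interaction (`sigma2_sf`),
#' family (`sigma2_f`) and residual (`sigma2_e`), all in squared trait
#' units. The full-sib model uses all six; the open-pollinated half-sib
#' model drops the family terms (`sigma2_sf = sigma2_f = 0`).
#'
#' Defaults give a narrow-sense heritability of about 0.21 under the
#' full-sib formula, a mid-range value for growth traits in conifer
#' progeny tests.
#'
#' @param sigma2_a,sigma2_sa,sigma2_srep,sigma2_sf,sigma2_f,sigma2_e
#'   non-negative variances.
#' @return An object of class `variance_components` (named numeric).
#' @export
variance_components <- function(sigma2_a = 2, sigma2_sa = 1,
                                sigma2_srep = 0.5, sigma2_sf = 0.5,
                                sigma2_f = 0.5, sigma2_e = 5.5) {
  vc <- c(sigma2_a = sigma2_a, sigma2_sa = sigma2_sa,
          sigma2_srep = sigma2_srep, sigma2_sf = sigma2_sf,
          sigma2_f = sigma2_f, sigma2_e = sigma2_e)
  if (any(!is.finite(vc)) || any(vc < 0)) {
    stop("variance components must be finite and non-negative", call. = FALSE)
  }
  class(vc) <- "variance_components"
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Define a polygenic additive trait architecture
#'
#' Samples `n_qtl` causal loci from the mapped markers and assigns each a
#' raw additive effect drawn from N(0, 1). At phenotype time the raw
#' effects are rescaled by a single constant so the realized additive
#' variance across the simulated offspring equals the target `sigma2_a`
#' exactly, giving precise control of heritability per replicate.
#'
#' By default the causal loci are excluded from the observable SNP panel
#' (see [snp_panel()]), so markers can predict only through relatedness
#' and within-family linkage — not through population-wide marker-QTL
#' LD, which the emulated trials do not exhibit.
#'
#' @param map a [make_genetic_map()] object.
#' @param n_qtl number of causal loci (must not exceed the map size).
#' @param vc target [variance_components()].
#' @param include_qtl_in_panel keep causal loci in the observable panel
#'   (for contrast experiments).
#' @param seed integer seed.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(map, n_qtl = 300,
                               vc = variance_components(),
                               include_qtl_in_panel = FALSE, seed) {
  stopifnot(inherits(map, "genetic_map"), inherits(vc, "variance_components"))
  check_positive_scalar(n_qtl, "n_qtl", int = TRUE)
  if (n_qtl > map$n_markers) {
    stop("'n_qtl' exceeds the number of mapped markers", call. = FALSE)
  }
  res <- with_seed(seed, {
    idx <- sort(sample.int(map$n_markers, n_qtl))
    list(idx = idx, eff = rnorm(n_qtl))
  })
  structure(list(qtl_idx = res$idx, qtl_marker = map$marker[res$idx],
                 raw_effects = res$eff, vc = vc,
                 include_qtl_in_panel = isTRUE(include_qtl_in_panel),
                 n_qtl = as.integer(n_qtl)),
            class = "trait_architecture")
}

#' Observable SNP panel of a simulated population
#'
#' Returns the offspring dosage matrix restricted to non-causal loci
#' (unless the architecture includes them), i.e. the genotypes a
#' genotyping assay would deliver.
#'
#' @param pop a [simulate_population()] object.
#' @param arch a [trait_architecture()]; omit for the full marker set.
#' @return Integer dosage matrix, offspring x panel markers.
#' @export
snp_panel <- function(pop, arch = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  if (is.null(arch) || arch$include_qtl_in_panel) {
    return(pop$dosage)
  }
  stopifnot(inherits(arch, "trait_architecture"))
  pop$dosage[, -arch$qtl_idx, drop = FALSE]
}

#' Simulate phenotypes over a trial population
#'
#' Builds each offspring record as
#' `overall mean + site effect + a + sa + s(rep) + sf + f + e`:
#' `a` is the scaled sum of causal allele effects; `sa` is a site
#' x additive deviation realized by drawing fresh causal-effect vectors
#' per site (so trees of the same site covary through their realized
#' relationships, a genetic G x E interaction); `s(rep)` is a shared
#' block-within-site effect; `sf` and `f` are site x family and family
#' effects (full-sib designs); `e` is white noise. Every realized
#' component is rescaled so its observation-level variance matches the
#' architecture's target exactly, giving exact realized heritability in
#' every replicate.
#'
#' @param pop a [simulate_population()] object.
#' @param arch a [trait_architecture()] on the same map.
#' @param seed integer seed.
#' @param overall_mean trait grand mean (default 10 trait units).
#' @param site_effects fixed site effects, recycled over sites; default
#'   `c(0, +0.5, -0.5) * sqrt(sigma2_e)`.
#' @return An object of class `sim_phenotypes`: list with `pheno`
#'   (data.frame `id`, `family`, `site`, `block`, `y`) and `truth`
#'   (data.frame of the realized effect components per offspring).
#' @export
simulate_phenotypes <- function(pop, arch, seed, overall_mean = 10,
                                site_effects = NULL) {
  stopifnot(inherits(pop, "sim_population"),
            inherits(arch, "trait_architecture"))
  if (max(arch$qtl_idx) > ncol(pop$dosage) ||
      !all(arch$qtl_marker == colnames(pop$dosage)[arch$qtl_idx])) {
    stop("trait architecture does not match the population's map", call. = FALSE)
  }
  vc <- arch$vc
  if (sum(vc) == 0) {
    stop("all variance components are zero: trait is degenerate", call. = FALSE)
  }
  info <- pop$info
  n <- nrow(info)
  sites <- sort(unique(info$site))
  if (is.null(site_effects)) {
    site_effects <- c(0, 0.5, -0.5) * sqrt(vc[["sigma2_e"]])
  }
  site_fx <- rep_len(site_effects, length(sites))
  names(site_fx) <- sites

  Zq <- pop$dosage[, arch$qtl_idx, drop = FALSE]
  storage.mode(Zq) <- "double"
  Zq <- scale(Zq, center = TRUE, scale = FALSE)

  with_seed(seed, {
    a <- scale_to_var(drop(Zq %*% arch$raw_effects), vc[["sigma2_a"]])

    sa <- numeric(n)
    if (vc[["sigma2_sa"]] > 0) {
      for (s in sites) {
        rows <- which(info$site == s)
        dev <- drop(Zq[rows, , drop = FALSE] %*% rnorm(arch$n_qtl))
        sa[rows] <- scale_to_var(dev, vc[["sigma2_sa"]])
      }
    }

    srep <- draw_group_effect(paste(info$site, info$block), vc[["sigma2_srep"]])
    sf <- draw_group_effect(paste(info$site, info$family), vc[["sigma2_sf"]])
    f <- draw_group_effect(info$family, vc[["sigma2_f"]])
    e <- scale_to_var(rnorm(n), vc[["sigma2_e"]])

    y <- overall_mean + site_fx[info$site] + a + sa + srep + sf + f + e
    pheno <- cbind(info, y = as.numeric(y))
    truth <- data.frame(id = info$id, a = a, sa = sa, srep = srep,
                        sf = sf, f = f, e = e,
                        site_effect = as.numeric(site_fx[info$site]),
                        stringsAsFactors = FALSE)
    structure(list(pheno = pheno, truth = truth, arch = arch,
                   overall_mean = overall_mean, site_effects = site_fx),
              class = "sim_phenotypes")
  })
}

#' @export
print.sim_phenotypes <- function(x, ...) {
  cat(sprintf("sim_phenotypes: %d records, mean %.3f, var %.3f\n",
              nrow(x$pheno), mean(x$pheno$y), stats::var(x$pheno$y)))
  invisible(x)
}

# center and rescale a vector to an exact empirical variance
scale_to_var <- function(x, target) {
  if (target == 0) return(numeric(length(x)))
  v <- stats::var(x)
  if (v == 0) {
    stop("cannot scale a constant effect vector to positive variance",
         call. = FALSE)
  }
  (x - mean(x)) * sqrt(target / v)
}

# one N(0, 1) draw per group level, expanded to observations and
# rescaled so the realized observation-level variance is exact
draw_group_effect <- function(group, sigma2) {
  if (sigma2 == 0) return(numeric(length(group)))
  g <- factor(group)
  scale_to_var(rnorm(nlevels(g))[as.integer(g)], sigma2)
}
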