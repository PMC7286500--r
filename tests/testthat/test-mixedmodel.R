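# Henderson MME / BLUP, EM-REML, heritability, ABLUP cross-validation.

# simple unrelated-individuals pedigree and phenotypes for closed forms
iid_toy <- function(n, s2a = 1, s2e = 2, seed = 1) {
  set.seed(seed)
  ped <- data.frame(id = paste0("i", 1:n), sire = "0", dam = "0")
  A <- build_numerator_relationship(ped)
  pheno <- data.frame(id = ped$id, site = "S1", y = rnorm(n, 5, 1.5))
  vc <- variance_components(sigma2_a = s2a, sigma2_sa = 0, sigma2_srep = 0,
                            sigma2_sf = 0, sigma2_f = 0, sigma2_e = s2e)
  list(ped = ped, A = A, pheno = pheno, vc = vc,
       spec = model_spec("fullsib", terms = "additive"))
}

test_that("BLUP equals scalar shrinkage for unrelated individuals", {
  toy <- iid_toy(30, s2a = 1, s2e = 2)
  fit <- fit_ablup(toy$pheno, toy$spec, toy$A, toy$vc)
  h2 <- 1 / (1 + 2)
  expect_equal(unname(fit$ebv[as.character(toy$pheno$id)]),
               h2 * (toy$pheno$y - mean(toy$pheno$y)), tolerance = 1e-8)
  expect_lt(abs(mean(fit$ebv)), 1e-8)
})

test_that("EBVs vanish in the infinite-shrinkage limit", {
  toy <- iid_toy(25)
  vc0 <- toy$vc
  vc0[["sigma2_a"]] <- 1e-10
  fit <- fit_ablup(toy$pheno, toy$spec, toy$A, vc0)
  expect_lt(max(abs(fit$ebv)), 1e-8)
})

test_that("MME solutions match the dense GLS oracle on a multi-site toy", {
  design <- full_sib_design(n_parents = 6, n_families = 4,
                            offspring_per_family = 9, n_sites = 3,
                            blocks_per_site = 2)
  tr <- simulate_trial(design, seed = 7, n_chromosomes = 2,
                       total_length_cM = 400, n_markers = 600, n_qtl = 60)
  pheno <- tr$phenotypes$pheno
  A <- build_numerator_relationship(tr$pop$pedigree)
  spec <- model_spec("fullsib")
  vc <- variance_components(2, 1, 0.5, 0.5, 0.5, 5.5)
  fit <- fit_ablup(pheno, spec, A, vc)

  # oracle: explicit inversion of the full observation covariance
  n <- nrow(pheno)
  ids <- as.character(pheno$id)
  X <- model.matrix(~ factor(site), data = pheno)
  Za <- matrix(0, n, nrow(A), dimnames = list(NULL, rownames(A)))
  Za[cbind(1:n, match(ids, rownames(A)))] <- 1
  B <- A[ids, ids] * outer(pheno$site, pheno$site, "==")
  Zr <- model.matrix(~ factor(paste(pheno$site, pheno$block)) - 1)
  Zsf <- model.matrix(~ factor(paste(pheno$site, pheno$family)) - 1)
  Zf <- model.matrix(~ factor(pheno$family) - 1)
  terms <- list(
    additive = list(Z = Za, G = A, s2 = 2),
    site_additive = list(Z = diag(n), G = B, s2 = 1),
    block = list(Z = Zr, G = diag(ncol(Zr)), s2 = 0.5),
    site_family = list(Z = Zsf, G = diag(ncol(Zsf)), s2 = 0.5),
    family = list(Z = Zf, G = diag(ncol(Zf)), s2 = 0.5),
    residual = list(Z = diag(n), G = diag(n), s2 = 5.5)
  )
  gls <- gls_oracle(pheno$y, X, terms)
  expect_equal(unname(fit$beta), unname(gls$beta), tolerance = 1e-8)
  expect_equal(unname(fit$ebv), unname(gls$u$additive), tolerance = 1e-8)
  expect_equal(unname(fit$random$family), unname(gls$u$family),
               tolerance = 1e-8)
})

test_that("confounded fixed effects and missing ids are rejected", {
  toy <- iid_toy(10)
  bad <- toy$pheno
  bad$id[1] <- "stranger"
  expect_error(build_mme(bad, toy$spec, toy$A, toy$vc), "missing")
  vc_bad <- toy$vc
  vc_bad[["sigma2_a"]] <- 0
  expect_error(build_mme(toy$pheno, toy$spec, toy$A, vc_bad), "> 0")
})

test_that("EM-REML sends the additive component to the boundary on noise", {
  set.seed(11)
  tr <- small_halfsib_trial()
  ped <- tr$pop$pedigree
  A <- build_numerator_relationship(ped)
  pheno <- tr$phenotypes$pheno
  pheno$y <- rnorm(nrow(pheno))        # pure noise, no structure
  est <- em_reml(pheno, model_spec("halfsib", terms = "additive"), A,
                 tol = 1e-10, max_iter = 3000)
  # with 12 families the REML sampling SD of sigma2_a on null data is
  # ~0.14, so a single realization can sit that far from the boundary
  expect_lt(est$vc[["sigma2_a"]], 0.15 * var(pheno$y))
  expect_gt(est$vc[["sigma2_e"]], 0.8 * var(pheno$y))
})

test_that("EM-REML equals the balanced half-sib ANOVA estimator", {
  set.seed(13)
  n_fam <- 24
  n_per <- 12
  ped <- data.frame(
    id = c(paste0("dam", 1:n_fam),
           paste0("o", seq_len(n_fam * n_per))),
    sire = "0",
    dam = c(rep("0", n_fam), rep(paste0("dam", 1:n_fam), each = n_per)))
  A <- build_numerator_relationship(ped)
  fam <- rep(1:n_fam, each = n_per)
  s2s <- 0.4                            # sire-model family variance
  y <- 3 + sqrt(s2s) * rnorm(n_fam)[fam] + rnorm(n_fam * n_per, 0, 1.5)
  pheno <- data.frame(id = ped$id[-(1:n_fam)], site = "S1", y = y)
  oracle <- anova_halfsib_oracle(y, fam)
  est <- em_reml(pheno, model_spec("halfsib", terms = "additive"), A,
                 init = variance_components(
                   sigma2_a = oracle[["sigma2_a"]], sigma2_sa = 1,
                   sigma2_srep = 1, sigma2_sf = 0, sigma2_f = 0,
                   sigma2_e = oracle[["sigma2_e"]]),
                 tol = 1e-12, max_iter = 2000)
  expect_true(est$converged)
  expect_equal(est$vc[["sigma2_a"]], oracle[["sigma2_a"]], tolerance = 1e-6)
  expect_equal(est$vc[["sigma2_e"]], oracle[["sigma2_e"]], tolerance = 1e-6)
})

test_that("EM-REML log-likelihood never decreases", {
  tr <- small_fullsib_trial()
  A <- build_numerator_relationship(tr$pop$pedigree)
  est <- em_reml(tr$phenotypes$pheno, model_spec("fullsib"), A,
                 tol = 1e-5, max_iter = 120)
  expect_gt(length(est$loglik), 3)
  expect_true(all(diff(est$loglik) > -1e-6 * abs(est$loglik[-1])))
})

test_that("heritability follows the two design-specific formulas", {
  vc_fs <- variance_components(2, 1, 99, 0.5, 0.5, 6)  # srep excluded
  expect_equal(heritability(vc_fs, "fullsib"), 2 / 10)
  vc_hs <- variance_components(1, 0, 0, 0, 0, 1)
  expect_equal(heritability(vc_hs, "halfsib"), 0.5)
  vc0 <- variance_components(0, 1, 0, 0, 0, 1)
  expect_equal(heritability(vc0, "fullsib"), 0)
  # scale invariance
  vc_scaled <- variance_components(2 * 7, 1 * 7, 0.5 * 7, 0.5 * 7,
                                   0.5 * 7, 6 * 7)
  vc_base <- variance_components(2, 1, 0.5, 0.5, 0.5, 6)
  expect_equal(heritability(vc_scaled, "fullsib"),
               heritability(vc_base, "fullsib"))
  expect_error(heritability(variance_components(0, 0, 0, 0, 0, 0),
                            "fullsib"), "> 0")
})

test_that("unrelated validation sets give degenerate folds, not fake zeros", {
  # with no relatives, masked individuals have no information channel:
  # predictions are constant and the fold is flagged missing, never 0
  toy <- iid_toy(40, s2a = 1, s2e = 1, seed = 17)
  cv <- ablup_cross_validate(toy$pheno, toy$spec, toy$A, toy$vc,
                             k = 4, reps = 2, seed = 19)
  expect_true(all(is.na(cv$folds$accuracy)))
  expect_true(all(abs(cv$predictions$predicted) < 1e-8))
})

test_that("cross-validated accuracy stays within [-1, 1] with relatives", {
  tr <- small_fullsib_trial()
  A <- build_numerator_relationship(tr$pop$pedigree)
  vc <- variance_components(2, 1, 0.5, 0.5, 0.5, 5.5)
  cv <- ablup_cross_validate(tr$phenotypes$pheno, model_spec("fullsib"),
                             A, vc, k = 5, reps = 1, seed = 19)
  expect_true(all(is.finite(cv$folds$accuracy)))
  expect_true(all(abs(cv$folds$accuracy) <= 1))
  expect_gt(cv$mean, 0)               # heritable trait: real signal
})

test_that("k = n cross-validation reproduces explicit leave-one-out", {
  toy_tr <- simulate_trial(full_sib_design(n_parents = 8, n_families = 5,
                                           offspring_per_family = 4,
                                           n_sites = 1, blocks_per_site = 2),
                           seed = 23, n_chromosomes = 2,
                           total_length_cM = 300, n_markers = 400,
                           n_qtl = 50)
  pheno <- toy_tr$phenotypes$pheno     # 20 individuals
  A <- build_numerator_relationship(toy_tr$pop$pedigree)
  spec <- model_spec("fullsib", terms = c("additive", "family"))
  vc <- variance_components(2, 0, 0, 0, 0.5, 5.5)
  n <- nrow(pheno)
  cv <- ablup_cross_validate(pheno, spec, A, vc, k = n, reps = 1, seed = 29)
  loo <- vapply(seq_len(n), function(i) {
    fit <- fit_ablup(pheno[-i, , drop = FALSE], spec, A, vc)
    fit$ebv[[as.character(pheno$id[i])]]
  }, numeric(1))
  got <- cv$predictions
  expect_equal(got$predicted[order(got$id)],
               loo[order(as.character(pheno$id))], tolerance = 1e-10)
})

test_that("masking nothing reproduces the full-data breeding values", {
  tr <- small_halfsib_trial()
  A <- build_numerator_relationship(tr$pop$pedigree)
  vc <- variance_components(2, 1, 0.5, 0, 0, 6.5)
  pheno <- tr$phenotypes$pheno
  full <- fit_ablup(pheno, model_spec("halfsib"), A, vc)
  again <- fit_ablup(pheno, model_spec("halfsib"), A, vc)
  expect_identical(full$ebv, again$ebv)
  expect_lt(abs(mean(full$ebv[as.character(pheno$id)])) /
              sd(full$ebv[as.character(pheno$id)]), 0.2)
})
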