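# Linear mixed models for the two trial designs: Henderson's mixed-model
# equations for BLUP/EBVs, EM-REML for variance components, heritability
# and pedigree-based (ABLUP) cross-validation.

TERM_VC <- c(additive = "sigma2_a", site_additive = "sigma2_sa",
             block = "sigma2_srep", site_family = "sigma2_sf",
             family = "sigma2_f", residual = "sigma2_e")

#' Specify a trial mixed model
#'
#' The full-sib model carries random additive, site x additive,
#' block-within-site, site x family and family effects plus residual;
#' the open-pollinated half-sib model drops the two family terms. Fixed
#' effects are the overall mean and site in both. The additive effect
#' has covariance `A * sigma2_a` (pedigree numerator relationships); the
#' site x additive interaction has additive covariance between trees of
#' the same site and none across sites (blockwise `A`), the standard
#' genetic G x E structure that keeps the term separable from the
#' residual; the remaining terms are i.i.d.
#'
#' @param kind `"fullsib"` or `"halfsib"`.
#' @param terms optional custom subset of
#'   `c("additive", "site_additive", "block", "site_family", "family")`
#'   for reduced models (e.g. single-site checks); the residual is always
#'   present.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("fullsib", "halfsib"), terms = NULL) {
  kind <- match.arg(kind)
  if (is.null(terms)) {
    terms <- if (kind == "fullsib") {
      c("additive", "site_additive", "block", "site_family", "family")
    } else {
      c("additive", "site_additive", "block")
    }
  } else {
    bad <- setdiff(terms, setdiff(names(TERM_VC), "residual"))
    if (length(bad)) {
      stop("unknown model terms: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(kind = kind, terms = terms), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec (%s): y = mean + site + %s + residual\n",
              x$kind, paste(x$terms, collapse = " + ")))
  invisible(x)
}

check_phenotypes <- function(pheno) {
  need <- c("id", "site", "y")
  if (!is.data.frame(pheno) || !all(need %in% names(pheno))) {
    stop("phenotypes must be a data.frame with at least columns id, site, y",
         call. = FALSE)
  }
  pheno
}

fixed_design <- function(pheno) {
  if (length(unique(pheno$site)) > 1L) {
    stats::model.matrix(~ site, data = transform(pheno, site = factor(site)))
  } else {
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  }
}

# same-site blockwise additive covariance among observations
site_additive_cov <- function(A_oo, site) {
  same <- outer(site, site, "==")
  A_oo * same
}

# per-term random-effect structure for the MME path
random_structures <- function(pheno, spec, A, vc) {
  n <- nrow(pheno)
  ids <- as.character(pheno$id)
  out <- list()
  for (term in spec$terms) {
    s2 <- vc[[TERM_VC[[term]]]]
    if (!is.finite(s2) || s2 <= 0) {
      stop(sprintf("variance component for term '%s' must be > 0", term),
           call. = FALSE)
    }
    lambda <- vc[["sigma2_e"]] / s2
    if (term == "additive") {
      lev <- rownames(A)
      Z <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
      Z[cbind(seq_len(n), match(ids, lev))] <- 1
      Ginv <- solve(A)
    } else if (term == "site_additive") {
      B <- site_additive_cov(A[ids, ids, drop = FALSE], pheno$site)
      Z <- diag(n)
      colnames(Z) <- ids
      Ginv <- matrix(0, n, n)
      for (s in unique(pheno$site)) {
        at <- which(pheno$site == s)
        Ginv[at, at] <- solve(B[at, at, drop = FALSE])
      }
    } else {
      g <- switch(term,
        block = factor(paste(pheno$site, pheno$block)),
        site_family = factor(paste(pheno$site, pheno$family)),
        family = factor(pheno$family))
      Z <- stats::model.matrix(~ g - 1)
      colnames(Z) <- levels(g)
      Ginv <- diag(ncol(Z))
    }
    out[[term]] <- list(Z = Z, Ginv = Ginv, lambda = lambda)
  }
  out
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the symmetric MME coefficient matrix and right-hand side for a
#' trial model: fixed block `X'X`, random blocks `Z_k'Z_k` plus the
#' inverse covariance of each term scaled by its variance ratio
#' (`A^{-1} * sigma2_e / sigma2_a` for the additive block, identity-based
#' penalties for i.i.d. terms). The additive effect spans every pedigree
#' member in `A`, so non-phenotyped parents and masked individuals
#' receive predicted breeding values through their relatives.
#'
#' @param phenotypes data.frame with `id`, `site`, `y` and, as the model
#'   requires, `family`, `block`.
#' @param spec a [model_spec()].
#' @param A numerator relationship matrix covering all phenotyped ids.
#' @param vc [variance_components()] with strictly positive entries for
#'   every included term and the residual.
#' @return An object of class `mme_system` for [solve_blup()].
#' @export
build_mme <- function(phenotypes, spec, A, vc) {
  pheno <- check_phenotypes(phenotypes)
  stopifnot(inherits(spec, "model_spec"))
  ids <- as.character(pheno$id)
  if (!all(ids %in% rownames(A))) {
    stop("phenotyped individuals missing from the relationship matrix",
         call. = FALSE)
  }
  X <- fixed_design(pheno)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is singular (confounded site levels)",
         call. = FALSE)
  }
  rs <- random_structures(pheno, spec, A, vc)
  W <- do.call(cbind, c(list(X), lapply(rs, `[[`, "Z")))
  C <- crossprod(W)
  rhs <- crossprod(W, pheno$y)
  # add penalties along the block diagonal
  offs <- ncol(X)
  blocks <- list(fixed = seq_len(ncol(X)))
  for (term in names(rs)) {
    q <- ncol(rs[[term]]$Z)
    at <- offs + seq_len(q)
    C[at, at] <- C[at, at] + rs[[term]]$Ginv * rs[[term]]$lambda
    blocks[[term]] <- at
    offs <- offs + q
  }
  structure(list(C = C, rhs = rhs, blocks = blocks, X = X,
                 labels = lapply(rs, function(r) colnames(r$Z)),
                 pheno = pheno, spec = spec),
            class = "mme_system")
}

#' Solve the mixed-model equations
#'
#' Direct symmetric factorization of the MME. Breeding values are
#' returned for every pedigree member in the additive block, including
#' individuals without phenotypes.
#'
#' @param system an [build_mme()] object.
#' @return An object of class `ebv_result`: list with `beta` (fixed
#'   solutions), `ebv` (named additive solutions over all pedigree ids),
#'   `random` (solutions of the other terms) and `fitted` values.
#' @export
solve_blup <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  R <- tryCatch(chol(system$C), error = function(e) NULL)
  if (is.null(R)) {
    stop(sprintf(
      "mixed-model equations numerically singular (reciprocal condition %.2e)",
      1 / kappa(system$C)), call. = FALSE)
  }
  sol <- backsolve(R, backsolve(R, system$rhs, transpose = TRUE))
  blocks <- system$blocks
  beta <- stats::setNames(sol[blocks$fixed], colnames(system$X))
  random <- list()
  for (term in setdiff(names(blocks), "fixed")) {
    random[[term]] <- stats::setNames(sol[blocks[[term]]],
                                      system$labels[[term]])
  }
  ebv <- random[["additive"]]
  structure(list(beta = beta, ebv = ebv, random = random,
                 spec = system$spec), class = "ebv_result")
}

#' @export
print.ebv_result <- function(x, ...) {
  cat(sprintf("ebv_result: %d breeding values (mean %.4g, sd %.4g)\n",
              length(x$ebv), mean(x$ebv), stats::sd(x$ebv)))
  invisible(x)
}

#' Fit ABLUP: pedigree-based breeding values in one call
#'
#' @inheritParams build_mme
#' @return An `ebv_result` (see [solve_blup()]).
#' @export
fit_ablup <- function(phenotypes, spec, A, vc) {
  solve_blup(build_mme(phenotypes, spec, A, vc))
}

# observation-level covariance contribution of each term (V-form REML)
vform_structures <- function(pheno, spec, A) {
  n <- nrow(pheno)
  ids <- as.character(pheno$id)
  A_oo <- A[ids, ids, drop = FALSE]
  M <- list()
  q <- c()
  for (term in spec$terms) {
    M[[term]] <- switch(term,
      additive = A_oo,
      site_additive = site_additive_cov(A_oo, pheno$site),
      block = same_group_matrix(paste(pheno$site, pheno$block)),
      site_family = same_group_matrix(paste(pheno$site, pheno$family)),
      family = same_group_matrix(pheno$family))
    q[term] <- switch(term,
      additive = n, site_additive = n,
      length(unique(switch(term,
        block = paste(pheno$site, pheno$block),
        site_family = paste(pheno$site, pheno$family),
        family = pheno$family))))
  }
  M[["residual"]] <- diag(n)
  q["residual"] <- n
  list(M = M, q = q)
}

same_group_matrix <- function(g) {
  Z <- stats::model.matrix(~ factor(g) - 1)
  tcrossprod(Z)
}

#' Estimate variance components by EM-REML
#'
#' Expectation-maximization REML on the observation-level covariance
#' `V = sum_k sigma2_k M_k + sigma2_e I`, where `M_k` is each random
#' term's relationship/incidence structure. Every iteration solves `V`,
#' forms the REML projection `P`, and applies the EM update
#' `sigma2_k <- sigma2_k + sigma2_k^2 / q_k * (y'P M_k P y - tr(P M_k))`,
#' which keeps all components non-negative and the REML log-likelihood
#' monotonically non-decreasing. Because plain EM crawls along flat
#' likelihood directions, each pair of EM steps is followed by a
#' SQUAREM-style log-space extrapolation that is accepted only when it
#' does not decrease the REML log-likelihood, so monotonicity is
#' preserved by construction. Iteration stops when the largest relative
#' component change over an EM step falls below `tol`.
#'
#' @inheritParams build_mme
#' @param init starting [variance_components()]; defaults to an equal
#'   split of the phenotypic variance over the model's terms.
#' @param tol relative-change convergence tolerance (default `1e-6`).
#' @param max_iter iteration cap (default 500); non-convergence is
#'   flagged, never an error.
#' @param accel_every set to 0 to disable the guarded extrapolation and
#'   run plain EM.
#' @return An object of class `variance_estimates`: list with `vc`
#'   (estimates; terms outside the model are zero), `loglik` (REML
#'   log-likelihood trace), `converged`, `iterations`.
#' @export
em_reml <- function(phenotypes, spec, A, init = NULL, tol = 1e-6,
                    max_iter = 500, accel_every = 5) {
  pheno <- check_phenotypes(phenotypes)
  stopifnot(inherits(spec, "model_spec"))
  y <- pheno$y
  n <- length(y)
  X <- fixed_design(pheno)
  st <- vform_structures(pheno, spec, A)
  comp <- names(st$M)
  if (is.null(init)) {
    v0 <- stats::var(y) / length(comp)
    s2 <- stats::setNames(rep(v0, length(comp)), comp)
  } else {
    s2 <- vapply(comp, function(term) init[[TERM_VC[[term]]]], numeric(1))
    names(s2) <- comp
    if (any(!is.finite(s2)) || any(s2 <= 0)) {
      stop("'init' must be strictly positive for every model term",
           call. = FALSE)
    }
  }
  floor_ <- 1e-8 * stats::var(y)

  # V-dependent quantities reused by the likelihood and the EM update
  eval_state <- function(s2) {
    V <- matrix(0, n, n)
    for (k in comp) V <- V + s2[[k]] * st$M[[k]]
    R <- chol(V)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(R))) +
                  determinant(XtViX, logarithm = TRUE)$modulus[1] +
                  sum(y * Py))
    list(P = P, Py = Py, ll = ll)
  }
  em_step <- function(s2, state) {
    new <- s2
    for (k in comp) {
      quad <- drop(crossprod(state$Py, st$M[[k]] %*% state$Py))
      trPM <- sum(state$P * st$M[[k]])
      new[[k]] <- max(s2[[k]] + s2[[k]]^2 / st$q[[k]] * (quad - trPM),
                      floor_)
    }
    new
  }

  state <- eval_state(s2)
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    # one EM step
    it <- it + 1L
    ll <- c(ll, state$ll)
    s2_1 <- em_step(s2, state)
    delta <- max(abs(s2_1 - s2) / pmax(s2, floor_))
    state_1 <- eval_state(s2_1)
    if (delta < tol) {
      s2 <- s2_1
      state <- state_1
      converged <- TRUE
      break
    }
    if (accel_every == 0 || it >= max_iter) {
      s2 <- s2_1
      state <- state_1
      next
    }
    # second EM step, then a SQUAREM-style log-space extrapolation,
    # accepted only when the REML log-likelihood does not decrease
    it <- it + 1L
    ll <- c(ll, state_1$ll)
    s2_2 <- em_step(s2_1, state_1)
    state_2 <- eval_state(s2_2)
    r <- log(s2_1) - log(s2)
    v <- (log(s2_2) - log(s2_1)) - r
    anorm <- sqrt(sum(r^2)) / max(sqrt(sum(v^2)), 1e-12)
    alpha <- -max(1, min(anorm, 64))
    cand <- pmax(exp(log(s2) - 2 * alpha * r + alpha^2 * v), floor_)
    accepted <- FALSE
    if (alpha < -1 && any(abs(cand - s2_2) > 0)) {
      state_c <- eval_state(cand)
      if (state_c$ll >= state_2$ll) {
        s2 <- cand
        state <- state_c
        accepted <- TRUE
      }
    }
    if (!accepted) {
      s2 <- s2_2
      state <- state_2
    }
    if (max(abs(s2_2 - s2_1) / pmax(s2_1, floor_)) < tol) {
      converged <- TRUE
      break
    }
  }
  vc_out <- variance_components(sigma2_a = 0, sigma2_sa = 0, sigma2_srep = 0,
                                sigma2_sf = 0, sigma2_f = 0, sigma2_e = 0)
  for (k in comp) vc_out[[TERM_VC[[k]]]] <- s2[[k]]
  structure(list(vc = vc_out, loglik = ll, converged = converged,
                 iterations = it, spec = spec),
            class = "variance_estimates")
}

#' @export
print.variance_estimates <- function(x, ...) {
  cat(sprintf("variance_estimates (%s after %d EM iterations):\n",
              if (x$converged) "converged" else "NOT converged — provisional",
              x$iterations))
  print(unclass(x$vc))
  invisible(x)
}

#' Narrow-sense heritability under a trial model
#'
#' Model-specific ratios: for the full-sib model
#' `h2 = sigma2_a / (sigma2_a + sigma2_sa + sigma2_sf + sigma2_f +
#' sigma2_e)`; for the half-sib model
#' `h2 = sigma2_a / (sigma2_a + sigma2_sa + sigma2_e)`. The
#' block-within-site variance is excluded from the denominator in both,
#' replication being an experimental rather than phenotypic source.
#'
#' @param vc [variance_components()] (or a [em_reml()] result's `$vc`).
#' @param model_kind `"fullsib"` or `"halfsib"`.
#' @return h2 in `[0, 1]`.
#' @export
heritability <- function(vc, model_kind = c("fullsib", "halfsib")) {
  model_kind <- match.arg(model_kind)
  if (inherits(vc, "variance_estimates")) vc <- vc$vc
  denom <- if (model_kind == "fullsib") {
    vc[["sigma2_a"]] + vc[["sigma2_sa"]] + vc[["sigma2_sf"]] +
      vc[["sigma2_f"]] + vc[["sigma2_e"]]
  } else {
    vc[["sigma2_a"]] + vc[["sigma2_sa"]] + vc[["sigma2_e"]]
  }
  if (denom <= 0) stop("heritability denominator must be > 0", call. = FALSE)
  vc[["sigma2_a"]] / denom
}

#' Pedigree-based (ABLUP) cross-validation
#'
#' Individuals are partitioned across all sites into `k` random folds.
#' For each fold the validation phenotypes are masked, the mixed-model
#' equations are re-solved with variance components held at their
#' full-data values, and the masked individuals' breeding values are
#' predicted purely through the relationship matrix. Fold accuracy is
#' the Pearson correlation between those predictions and the full-data
#' EBVs; folds with degenerate (constant) predictions are recorded as
#' missing.
#'
#' @inheritParams build_mme
#' @param k number of folds (between 2 and the number of records;
#'   `k = n` is leave-one-out, whose folds carry predictions but no
#'   correlation).
#' @param reps number of independent repartitions.
#' @param seed integer seed for the fold assignments.
#' @return List with `folds` (data.frame `rep`, `fold`, `accuracy`),
#'   `predictions` (per-individual predicted vs full-data EBVs),
#'   `per_rep` (mean accuracy per repetition) and `mean`.
#' @export
ablup_cross_validate <- function(phenotypes, spec, A, vc, k = 10, reps = 10,
                                 seed) {
  pheno <- check_phenotypes(phenotypes)
  check_positive_scalar(k, "k", int = TRUE)
  if (k < 2) stop("'k' must be at least 2", call. = FALSE)
  n <- nrow(pheno)
  if (k > n) stop("more folds than observations", call. = FALSE)
  full <- fit_ablup(pheno, spec, A, vc)
  res <- list()
  preds <- list()
  for (r in seq_len(reps)) {
    fold_of <- with_seed(child_seed(seed, r), {
      sample(rep_len(seq_len(k), n))
    })
    for (fd in seq_len(k)) {
      test_rows <- which(fold_of == fd)
      fit <- fit_ablup(pheno[-test_rows, , drop = FALSE], spec, A, vc)
      ids <- as.character(pheno$id[test_rows])
      pred <- fit$ebv[ids]
      ref <- full$ebv[ids]
      acc <- if (length(pred) < 2 || stats::sd(pred) == 0 ||
                 stats::sd(ref) == 0) {
        NA_real_
      } else {
        stats::cor(pred, ref)
      }
      res[[length(res) + 1L]] <- data.frame(rep = r, fold = fd, accuracy = acc)
      preds[[length(preds) + 1L]] <- data.frame(
        rep = r, fold = fd, id = ids, predicted = unname(pred),
        reference = unname(ref))
    }
  }
  folds <- do.call(rbind, res)
  per_rep <- tapply(folds$accuracy, folds$rep, mean, na.rm = TRUE)
  list(folds = folds, predictions = do.call(rbind, preds),
       per_rep = as.numeric(per_rep),
       mean = mean(folds$accuracy, na.rm = TRUE))
}
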