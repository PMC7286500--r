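# Ridge-regression BLUP of marker effects and GEBV prediction, with a
# dual-form solver for marker matrices far wider than the sample size.

#' Column-center a marker dosage matrix
#'
#' Subtracts each marker's mean dosage and stores the centering vector in
#' the `"centers"` attribute so prediction-time genotypes can be centered
#' identically. Centering an already-centered matrix is a no-op.
#'
#' @param Z numeric matrix, individuals x markers, dosages coded 0/1/2
#'   (or already centered values).
#' @return The centered matrix with attribute `centers`.
#' @export
center_markers <- function(Z) {
  stopifnot(is.matrix(Z))
  prior <- attr(Z, "centers") %||% 0
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2L, mu)
  attr(Zc, "centers") <- prior + mu
  Zc
}

#' Estimate the ridge parameter by spectral REML
#'
#' Treats the ridge model as the equivalent random-effect model
#' `y = 1 mu + u + e`, `u ~ N(0, sigma2_g Z Z')`, and maximizes the REML
#' log-likelihood over the variance ratio `lambda = sigma2_e / sigma2_g`
#' by a one-dimensional search on the eigenvalue decomposition of the
#' `n x n` kernel `Z Z'` — a single eigendecomposition regardless of
#' marker count. Alternatively, supply both variance components and the
#' ratio is returned directly.
#'
#' @param y response vector (typically EBVs).
#' @param Z centered marker matrix (ignored when `K` is given).
#' @param K optional precomputed kernel `Z Z'`.
#' @param sigma2_g,sigma2_e optional known components; when both are
#'   given no estimation is performed.
#' @param interval log10 search range for lambda.
#' @return List with `lambda`, `sigma2_g`, `sigma2_e`.
#' @export
estimate_lambda <- function(y, Z = NULL, K = NULL, sigma2_g = NULL,
                            sigma2_e = NULL, interval = c(-8, 8)) {
  if (!is.null(sigma2_g) && !is.null(sigma2_e)) {
    check_positive_scalar(sigma2_g, "sigma2_g")
    check_positive_scalar(sigma2_e, "sigma2_e", strict = FALSE)
    return(list(lambda = sigma2_e / sigma2_g, sigma2_g = sigma2_g,
                sigma2_e = sigma2_e))
  }
  n <- length(y)
  if (n < 3) stop("need at least 3 observations to estimate lambda",
                  call. = FALSE)
  if (is.null(K)) {
    stopifnot(is.matrix(Z), nrow(Z) == n)
    if (all(abs(Z) < 1e-12)) {
      stop("marker matrix has no variation", call. = FALSE)
    }
    K <- tcrossprod(Z)
  }
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (max(d) <= 0) stop("marker kernel has no variation", call. = FALSE)
  ys <- drop(crossprod(eg$vectors, y))
  xs <- drop(crossprod(eg$vectors, rep(1, n)))
  # REML profile log-likelihood of log10(lambda), sigma2_g profiled out
  negll <- function(l10) {
    del <- 10^l10
    w <- 1 / (d + del)
    xwx <- sum(w * xs^2)
    beta <- sum(w * xs * ys) / xwx
    r <- ys - xs * beta
    ypy <- sum(w * r^2)
    s2 <- ypy / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(d + del)) + log(xwx))
  }
  opt <- stats::optimize(negll, interval = interval)
  del <- 10^opt$minimum
  w <- 1 / (d + del)
  xwx <- sum(w * xs^2)
  beta <- sum(w * xs * ys) / xwx
  s2g <- sum(w * (ys - xs * beta)^2) / (n - 1)
  list(lambda = del, sigma2_g = s2g, sigma2_e = del * s2g)
}

#' Fit a ridge-regression BLUP marker-effect model
#'
#' Solves `g = (Z'Z + lambda I)^{-1} Z' (y - 1 mu)` with the intercept
#' estimated jointly (equal to the training mean for column-centered
#' `Z`). When markers outnumber individuals the equivalent dual identity
#' `g = Z' (Z Z' + lambda I)^{-1} (y - 1 mu)` is used, which gives the
#' same solution at `n x n` cost; both paths agree to solver precision.
#' All marker effects share one variance, so shrinkage is uniform.
#'
#' @param y response vector (EBVs in the trial analyses).
#' @param Z centered marker matrix ([center_markers()]), `n x m`.
#' @param lambda ridge parameter `sigma2_e / sigma2_g` (>= 0); zero is
#'   only accepted when `Z'Z` has full rank.
#' @param method `"auto"` (dual when `m > n`), `"primal"` or `"dual"`.
#' @return An object of class `marker_effect_model`: list with `mu`,
#'   `effects` (named by marker), `lambda`, `centers`, `fitted`.
#' @export
fit_rrblup <- function(y, Z, lambda, method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  stopifnot(is.matrix(Z), length(y) == nrow(Z))
  check_positive_scalar(lambda, "lambda", strict = FALSE)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  n <- nrow(Z)
  m <- ncol(Z)
  if (method == "auto") method <- if (m > n) "dual" else "primal"
  mu <- mean(y)
  r <- y - mu
  if (lambda == 0) {
    if (method == "dual") {
      stop("lambda = 0 is not supported in dual mode", call. = FALSE)
    }
    ZtZ <- crossprod(Z)
    if (qr(ZtZ)$rank < m) {
      stop("lambda = 0 with rank-deficient Z'Z: ridge penalty required",
           call. = FALSE)
    }
    g <- solve(ZtZ, crossprod(Z, r))
  } else if (method == "primal") {
    g <- solve(crossprod(Z) + diag(lambda, m), crossprod(Z, r))
  } else {
    K <- tcrossprod(Z)
    alpha <- solve_psd(K + diag(lambda, n), r)
    g <- crossprod(Z, alpha)
  }
  g <- drop(g)
  names(g) <- colnames(Z)
  structure(list(mu = mu, effects = g, lambda = lambda,
                 centers = attr(Z, "centers"),
                 marker_ids = colnames(Z),
                 fitted = drop(mu + Z %*% g)),
            class = "marker_effect_model")
}

# Cholesky solve with a logged jitter retry for near-singular kernels
solve_psd <- function(S, b) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    message("kernel factorization failed; retrying with 1e-10 diagonal jitter")
    R <- chol(S + diag(1e-10 * mean(diag(S)), nrow(S)))
  }
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' @export
print.marker_effect_model <- function(x, ...) {
  cat(sprintf("marker_effect_model: %d markers, lambda = %.4g, mu = %.4g\n",
              length(x$effects), x$lambda, x$mu))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' A GEBV is the intercept plus the sum of an individual's marker
#' effects: `GEBV_i = mu + sum_j z_ij g_j`, with new genotypes centered
#' by the training centering vector.
#'
#' @param model a [fit_rrblup()] object.
#' @param Z_new raw dosage matrix over the same markers (same ids, same
#'   order) as the training matrix.
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, Z_new) {
  stopifnot(inherits(model, "marker_effect_model"), is.matrix(Z_new))
  if (is.null(colnames(Z_new)) || is.null(model$marker_ids) ||
      !identical(colnames(Z_new), model$marker_ids)) {
    stop("marker ids/order of 'Z_new' do not match the trained model",
         call. = FALSE)
  }
  centers <- model$centers %||% 0
  Zc <- sweep(Z_new, 2L, centers)
  drop(model$mu + Zc %*% model$effects)
}
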