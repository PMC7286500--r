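# The marker-density experiment: SNP filtering, random marker-set
# sampling, replicated k-fold genomic cross-validation, accuracy
# summaries and marker-requirement calculators.

#' Filter SNPs on observed heterozygosity
#'
#' Retains markers whose observed heterozygote fraction (dosage == 1) is
#' strictly below `max_het`, the screen applied to exome-capture SNP
#' pools before genomic prediction (default threshold 0.40).
#'
#' @param G dosage matrix (individuals x markers, 0/1/2).
#' @param max_het retention threshold in `(0, 1]`.
#' @return Integer indices of retained markers.
#' @export
filter_snps_heterozygosity <- function(G, max_het = 0.40) {
  stopifnot(is.matrix(G))
  if (!is.numeric(max_het) || length(max_het) != 1L ||
      max_het <= 0 || max_het > 1) {
    stop("'max_het' must lie in (0, 1]", call. = FALSE)
  }
  het <- colMeans(G == 1L)
  unname(which(het < max_het))
}

#' Randomly sample marker sets from a filtered pool
#'
#' Draws `n_reps` independent subsets of `set_total` markers, uniformly
#' without replacement, deterministically for a given seed.
#'
#' @param pool integer vector of candidate marker indices.
#' @param set_total subset size (<= `length(pool)`).
#' @param n_reps number of replicate subsets.
#' @param seed integer seed.
#' @return List of `n_reps` sorted index vectors.
#' @export
sample_marker_sets <- function(pool, set_total, n_reps, seed) {
  check_positive_scalar(set_total, "set_total", int = TRUE)
  check_positive_scalar(n_reps, "n_reps", int = TRUE)
  if (set_total > length(pool)) {
    stop(sprintf("set_total (%d) exceeds pool size (%d)",
                 set_total, length(pool)), call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_reps), function(r) sort(sample(pool, set_total)))
  })
}

#' Replicated k-fold genomic cross-validation
#'
#' For each repeat, individuals (pooled across sites) are partitioned
#' into `folds` random folds; each fold in turn is held out, an RR-BLUP
#' model is trained on the remainder (markers re-centered on the
#' training folds, ridge parameter re-estimated per training set under
#' the `"reml"` strategy), and accuracy is the Pearson correlation
#' between the held-out individuals' EBVs and their predicted GEBVs.
#'
#' Internally the training and prediction equations are solved in the
#' `n x n` kernel (dual) form, which is algebraically identical to
#' explicit marker effects via [fit_rrblup()]/[predict_gebv()] but
#' independent of marker count.
#'
#' @param ebv response vector (one EBV per genotyped individual).
#' @param Z dosage matrix over the marker set to test.
#' @param folds,repeats cross-validation layout (default 10 x 10).
#' @param lambda `"reml"` for per-fold spectral REML, or a fixed
#'   numeric ridge parameter.
#' @param seed integer seed for the fold partitions.
#' @return Data.frame `repeat_` / `fold` / `accuracy` (class
#'   `gs_cv_result`); degenerate folds are `NA` with a logged count in
#'   attribute `n_degenerate`.
#' @export
gs_cross_validate <- function(ebv, Z, folds = 10, repeats = 10,
                              lambda = "reml", seed) {
  stopifnot(is.matrix(Z), length(ebv) == nrow(Z))
  check_positive_scalar(folds, "folds", int = TRUE)
  check_positive_scalar(repeats, "repeats", int = TRUE)
  n <- length(ebv)
  if (n < 2 * folds) stop("need at least 2 observations per fold",
                          call. = FALSE)
  storage.mode(Z) <- "double"
  Zc <- scale(Z, center = TRUE, scale = FALSE)   # global centering; per-fold
  K <- tcrossprod(Zc)                            # re-centering via rank-1 fix
  out <- vector("list", repeats * folds)
  n_degen <- 0L
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- with_seed(child_seed(seed, r), sample(rep_len(seq_len(folds), n)))
    for (fd in seq_len(folds)) {
      val <- which(fold_of == fd)
      tr <- which(fold_of != fd)
      acc <- kernel_ridge_fold(ebv, Zc, K, tr, val, lambda)
      if (is.na(acc)) n_degen <- n_degen + 1L
      row <- row + 1L
      out[[row]] <- data.frame(repeat_ = r, fold = fd, accuracy = acc)
    }
  }
  res <- do.call(rbind, out)
  if (n_degen > 0L) {
    message(sprintf("%d degenerate fold(s) recorded as missing", n_degen))
  }
  attr(res, "n_degenerate") <- n_degen
  class(res) <- c("gs_cv_result", class(res))
  res
}

# one CV fold in kernel form, with exact training-mean re-centering:
# if m = colMeans(Z[tr, ]), the training-centered kernel is
# K - 1 w' - w 1' + (m'm) 11' with w = Z m.
kernel_ridge_fold <- function(y, Zc, K, tr, val, lambda) {
  ind <- numeric(nrow(Zc))
  ind[tr] <- 1 / length(tr)
  m <- drop(crossprod(Zc, ind))          # training column means, no copy
  w <- drop(Zc %*% m)
  mm <- sum(m^2)
  Ktt <- K[tr, tr, drop = FALSE] - outer(w[tr], rep(1, length(tr))) -
    outer(rep(1, length(tr)), w[tr]) + mm
  Kvt <- K[val, tr, drop = FALSE] - outer(w[val], rep(1, length(tr))) -
    outer(rep(1, length(val)), w[tr]) + mm
  mu <- mean(y[tr])
  resid <- y[tr] - mu
  if (identical(lambda, "reml")) {
    eg <- eigen(Ktt, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    lam <- estimate_lambda_spectral(resid, d, eg$vectors)
    alpha <- eg$vectors %*% (crossprod(eg$vectors, resid) / (d + lam))
  } else {
    check_positive_scalar(lambda, "lambda")
    alpha <- solve_psd(Ktt + diag(lambda, length(tr)), resid)
  }
  pred <- mu + drop(Kvt %*% alpha)
  if (stats::sd(pred) == 0 || stats::sd(y[val]) == 0) return(NA_real_)
  stats::cor(y[val], pred)
}

# REML over the ridge ratio given an eigendecomposition of the kernel,
# response already centered (intercept handled by the caller)
estimate_lambda_spectral <- function(resid, d, U, interval = c(-8, 8)) {
  n <- length(resid)
  ys <- drop(crossprod(U, resid))
  xs <- drop(crossprod(U, rep(1, n)))
  negll <- function(l10) {
    del <- 10^l10
    w <- 1 / (d + del)
    xwx <- sum(w * xs^2)
    beta <- sum(w * xs * ys) / xwx
    s2 <- sum(w * (ys - xs * beta)^2) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(d + del)) + log(xwx))
  }
  10^stats::optimize(negll, interval = interval)$minimum
}

#' Run the full marker-density experiment
#'
#' Filters the SNP pool on heterozygosity, samples replicate random
#' marker sets at every grid size, and runs replicated k-fold genomic
#' cross-validation on each set. One master seed spawns independent
#' deterministic sub-streams per (grid point, marker replicate), so any
#' cell can be reproduced in isolation. Cross-validation partitions are
#' shared across SNP-set totals within a marker replicate (common random
#' numbers): the experiment's purpose is to compare set totals, and
#' pairing the folds removes fold-sampling noise from exactly that
#' comparison.
#'
#' @param ebv response vector (EBVs of the genotyped individuals).
#' @param Z full dosage matrix (individuals x all panel markers).
#' @param grid ascending unique SNP-set totals to test.
#' @param marker_reps random marker-set replicates per grid point
#'   (default 10).
#' @param folds,repeats cross-validation layout per marker set
#'   (default 10 x 10).
#' @param max_het heterozygosity filter threshold (default 0.40).
#' @param lambda ridge strategy, as in [gs_cross_validate()].
#' @param seed master seed.
#' @return Data.frame with one row per (set_total, marker_rep, repeat_,
#'   fold): class `marker_density_result`.
#' @export
run_marker_density_experiment <- function(ebv, Z,
                                          grid = c(200, 500, 1000, 2500,
                                                   5000, 10000, 15000,
                                                   25000, 50000),
                                          marker_reps = 10, folds = 10,
                                          repeats = 10, max_het = 0.40,
                                          lambda = "reml", seed) {
  stopifnot(is.matrix(Z), length(ebv) == nrow(Z))
  grid <- as.integer(grid)
  if (anyDuplicated(grid) || is.unsorted(grid)) {
    stop("'grid' must be unique and ascending", call. = FALSE)
  }
  pool <- filter_snps_heterozygosity(Z, max_het)
  if (max(grid) > length(pool)) {
    stop(sprintf("largest grid value (%d) exceeds filtered pool size (%d)",
                 max(grid), length(pool)), call. = FALSE)
  }
  out <- list()
  for (gi in seq_along(grid)) {
    sets <- sample_marker_sets(pool, grid[gi], marker_reps,
                               seed = child_seed(seed, gi, 0))
    for (mr in seq_len(marker_reps)) {
      cv <- gs_cross_validate(ebv, Z[, sets[[mr]], drop = FALSE],
                              folds = folds, repeats = repeats,
                              lambda = lambda,
                              seed = child_seed(seed, 0, mr))
      out[[length(out) + 1L]] <- cbind(set_total = grid[gi],
                                       marker_rep = mr, cv)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_pool") <- length(pool)
  class(res) <- c("marker_density_result", "data.frame")
  res
}

#' Summarize cross-validated accuracy per SNP-set total
#'
#' Each marker replicate is first reduced to the mean of its fold-level
#' accuracies; the reported per-grid-point mean, SD and SE
#' (`SD / sqrt(number of marker replicates)`) are then taken over those
#' replicate-level means. A single replicate reports SD = SE = 0.
#'
#' @param results a [run_marker_density_experiment()] data.frame (or any
#'   data.frame with `set_total`, `marker_rep`, `accuracy`).
#' @return Data.frame `set_total`, `mean_accuracy`, `sd_accuracy`,
#'   `se_accuracy`, `n_reps`, class `accuracy_summary`.
#' @export
summarize_accuracy <- function(results) {
  need <- c("set_total", "marker_rep", "accuracy")
  stopifnot(all(need %in% names(results)))
  if (all(is.na(results$accuracy))) {
    stop("no non-missing accuracies to summarize", call. = FALSE)
  }
  rep_means <- stats::aggregate(accuracy ~ set_total + marker_rep,
                                data = results, FUN = mean, na.rm = TRUE,
                                na.action = stats::na.pass)
  agg <- function(f) stats::aggregate(accuracy ~ set_total, data = rep_means,
                                      FUN = f, na.rm = TRUE,
                                      na.action = stats::na.pass)
  mu <- agg(mean)
  sdv <- stats::aggregate(accuracy ~ set_total, data = rep_means,
                          FUN = function(a) {
                            a <- a[!is.na(a)]
                            if (length(a) < 2) 0 else stats::sd(a)
                          })
  nr <- stats::aggregate(accuracy ~ set_total, data = rep_means,
                         FUN = function(a) sum(!is.na(a)))
  out <- data.frame(set_total = mu$set_total,
                    mean_accuracy = mu$accuracy,
                    sd_accuracy = sdv$accuracy,
                    se_accuracy = sdv$accuracy / sqrt(nr$accuracy),
                    n_reps = nr$accuracy)
  out <- out[order(out$set_total), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("accuracy_summary", "data.frame")
  out
}

#' Mean accuracy gain from doubling the marker count
#'
#' For every pair of grid points `(m, 2m)` present in a summary, the
#' ratio `mean_accuracy(2m) / mean_accuracy(m)` is computed; the mean of
#' these ratios is the doubling factor.
#'
#' @param summary an [summarize_accuracy()] data.frame.
#' @return List with `mean_factor` and `pairs` (per-pair detail).
#' @export
doubling_factor <- function(summary) {
  stopifnot(all(c("set_total", "mean_accuracy") %in% names(summary)))
  m <- summary$set_total
  lower <- m[(2 * m) %in% m]
  if (!length(lower)) {
    stop("grid contains no (m, 2m) pairs; choose a grid with doublings",
         call. = FALSE)
  }
  acc <- stats::setNames(summary$mean_accuracy, m)
  ratio <- acc[as.character(2 * lower)] / acc[as.character(lower)]
  pairs <- data.frame(from = lower, to = 2 * lower,
                      factor = as.numeric(ratio))
  list(mean_factor = mean(pairs$factor), pairs = pairs)
}

#' Smallest SNP-set total at which accuracy plateaus
#'
#' The plateau threshold is the smallest grid point whose mean accuracy
#' reaches `(1 - rel_tol)` of the best mean accuracy across the grid.
#'
#' @param summary an [summarize_accuracy()] data.frame.
#' @param rel_tol relative tolerance (default 0.02).
#' @return The plateau `set_total`.
#' @export
plateau_threshold <- function(summary, rel_tol = 0.02) {
  stopifnot(all(c("set_total", "mean_accuracy") %in% names(summary)))
  if (nrow(summary) < 2) stop("need at least 2 grid points", call. = FALSE)
  check_positive_scalar(rel_tol, "rel_tol", strict = FALSE)
  s <- summary[order(summary$set_total), ]
  cutoff <- (1 - rel_tol) * max(s$mean_accuracy)
  s$set_total[which(s$mean_accuracy >= cutoff)[1L]]
}

#' Accuracy ratio between the full-sib and half-sib designs
#'
#' @param summary_fullsib,summary_halfsib [summarize_accuracy()] results
#'   on identical grids.
#' @return List with `mean_ratio` and `per_set_total` detail.
#' @export
design_accuracy_ratio <- function(summary_fullsib, summary_halfsib) {
  fs <- summary_fullsib[order(summary_fullsib$set_total), ]
  hs <- summary_halfsib[order(summary_halfsib$set_total), ]
  if (!identical(as.integer(fs$set_total), as.integer(hs$set_total))) {
    stop("summaries use different SNP-set grids", call. = FALSE)
  }
  ratio <- fs$mean_accuracy / hs$mean_accuracy
  list(mean_ratio = mean(ratio),
       per_set_total = data.frame(set_total = fs$set_total, ratio = ratio))
}

#' Marker-requirement calculators
#'
#' `markers_meuwissen()` gives the classical minimum marker count
#' `10 * Ne * L` for accurate genomic prediction, with `L` the genome
#' length in Morgans. `marker_density_per_cM()` converts a marker count
#' on a map of `L_cM` centiMorgans to markers/cM, and
#' `markers_from_density()` inverts it — the deterministic
#' density-based targets (e.g. ~2 markers/cM when Ne <= 30).
#'
#' @param Ne effective population size.
#' @param L_morgans genome length in Morgans.
#' @param n_markers marker count.
#' @param L_cM genome length in centiMorgans.
#' @param density_per_cM marker density in markers/cM.
#' @return A single number.
#' @examples
#' markers_meuwissen(21, 20)        # 4200
#' marker_density_per_cM(5000, 2000) # 2.5
#' markers_from_density(2, 2000)    # 4000
#' @export
markers_meuwissen <- function(Ne, L_morgans) {
  check_positive_scalar(Ne, "Ne")
  check_positive_scalar(L_morgans, "L_morgans")
  10 * Ne * L_morgans
}

#' @rdname markers_meuwissen
#' @export
marker_density_per_cM <- function(n_markers, L_cM) {
  check_positive_scalar(n_markers, "n_markers")
  check_positive_scalar(L_cM, "L_cM")
  n_markers / L_cM
}

#' @rdname markers_meuwissen
#' @export
markers_from_density <- function(density_per_cM, L_cM) {
  check_positive_scalar(density_per_cM, "density_per_cM")
  check_positive_scalar(L_cM, "L_cM")
  density_per_cM * L_cM
}
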