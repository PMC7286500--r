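# Independent oracles used by the tests. These deliberately re-derive
# quantities by different algorithms than the package (direct GLS
# inversion, Wright's path counting, Monte-Carlo gene drop, balanced
# ANOVA), so agreement is evidence, not tautology.

# Generalized least squares with explicit inversion of the full
# observation covariance; returns fixed solutions and the BLUPs of each
# random term via u_k = s2_k G_k Z_k' V^{-1} (y - X beta).
gls_oracle <- function(y, X, terms) {
  V <- Reduce(`+`, lapply(terms, function(t) {
    t$s2 * (t$Z %*% t$G %*% t(t$Z))
  }))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  u <- lapply(terms, function(t) {
    if (is.null(t$keep) || t$keep) {
      drop(t$s2 * t$G %*% t(t$Z) %*% Vi %*% r)
    }
  })
  list(beta = drop(beta), u = u)
}

# Wright's path-counting inbreeding coefficient. Enumerates all
# ancestor paths from sire and dam; every pair of node-disjoint paths
# meeting at a common ancestor A contributes (1/2)^(n1+n2+1) (1 + F_A).
path_counting_inbreeding <- function(ped) {
  parents <- function(id) {
    row <- ped[ped$id == id, ]
    c(row$sire, row$dam)[c(row$sire, row$dam) != "0"]
  }
  ancestor_paths <- function(id) {
    out <- list(id)
    for (p in parents(id)) {
      out <- c(out, lapply(ancestor_paths(p), function(path) c(id, path)))
    }
    out
  }
  f_cache <- new.env()
  f_of <- function(id) {
    if (!is.null(f_cache[[id]])) return(f_cache[[id]])
    pp <- ped[ped$id == id, ]
    if (pp$sire == "0" || pp$dam == "0") {
      f_cache[[id]] <- 0
      return(0)
    }
    ps <- ancestor_paths(pp$sire)
    pd <- ancestor_paths(pp$dam)
    f <- 0
    for (a in ps) {
      for (b in pd) {
        if (a[length(a)] != b[length(b)]) next       # different ancestor
        shared <- intersect(a, b)
        if (length(shared) != 1L) next               # paths must be disjoint
        f <- f + 0.5^(length(a) - 1 + length(b) - 1 + 1) *
          (1 + f_of(a[length(a)]))
      }
    }
    f_cache[[id]] <- f
    f
  }
  vapply(ped$id, f_of, numeric(1))
}

# Monte-Carlo gene drop: founders carry unique allele labels; each
# offspring inherits one random allele per parent (unknown parents mint
# fresh labels). Returns the IBD-based estimate of the numerator
# relationship matrix over n_drops independent drops.
gene_drop_relationship <- function(ped, n_drops, seed) {
  set.seed(seed)
  n <- nrow(ped)
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  rownames(a1) <- rownames(a2) <- ped$id
  next_allele <- 0L
  mint <- function(k) {
    out <- matrix(seq.int(next_allele + 1L, next_allele + k * n_drops),
                  nrow = k)
    next_allele <<- next_allele + k * n_drops
    out
  }
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    a1[i, ] <- if (s == "0") mint(1L) else {
      pick <- runif(n_drops) < 0.5
      ifelse(pick, a1[s, ], a2[s, ])
    }
    a2[i, ] <- if (d == "0") mint(1L) else {
      pick <- runif(n_drops) < 0.5
      ifelse(pick, a1[d, ], a2[d, ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        A[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
      } else {
        k <- (as.numeric(a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
              (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
        A[i, j] <- A[j, i] <- 2 * mean(k)
      }
    }
  }
  A
}

# VanRaden-style realized genomic relationship from offspring dosages,
# standardized by the founder allele frequencies.
genomic_relationship_oracle <- function(pop, founders) {
  p <- founders$freq
  Z <- pop$dosage
  storage.mode(Z) <- "double"
  Zc <- sweep(Z, 2, 2 * p)
  G <- tcrossprod(Zc) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(pop$dosage), rownames(pop$dosage))
  G
}

# Balanced one-way ANOVA (method of moments) for half-sib families,
# mapped to the animal-model scale: sigma2_a = 4 sigma2_s.
anova_halfsib_oracle <- function(y, family) {
  fam <- factor(family)
  n0 <- length(y) / nlevels(fam)
  stopifnot(n0 == round(n0))            # balanced only
  fit <- stats::aov(y ~ fam)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  s2_s <- (ms[1] - ms[2]) / n0
  s2_w <- ms[2]
  c(sigma2_a = 4 * s2_s, sigma2_e = s2_w - 3 * s2_s)
}
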