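# Genetic map, founder haplotypes and meiosis for the trial simulator.

#' Build a random genetic map
#'
#' Lays out `n_markers` loci on `n_chromosomes` chromosomes of equal
#' genetic length summing to `total_length_cM`. Each marker is assigned
#' to a chromosome with probability proportional to chromosome length and
#' placed uniformly along it; positions are sorted within chromosomes.
#'
#' Conifer genomes are commonly approximated as ~2,000 cM total, which is
#' the default scale used by the simulated trial designs.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param total_length_cM total map length in centiMorgans.
#' @param n_markers total number of mapped loci (>= `n_chromosomes`).
#' @param seed integer seed; the map is deterministic given the seed.
#' @return An object of class `genetic_map`: a list with `chr_lengths`
#'   (named numeric), `marker`, `chromosome`, `position_cM` (parallel
#'   vectors in map order), `total_length_cM` and `n_markers`.
#' @examples
#' gm <- make_genetic_map(12, 2000, 240, seed = 1)
#' sum(gm$chr_lengths)
#' @export
make_genetic_map <- function(n_chromosomes, total_length_cM, n_markers, seed) {
  check_positive_scalar(n_chromosomes, "n_chromosomes", int = TRUE)
  check_positive_scalar(total_length_cM, "total_length_cM")
  check_positive_scalar(n_markers, "n_markers", int = TRUE)
  if (n_markers < n_chromosomes) {
    stop("'n_markers' must be at least 'n_chromosomes'", call. = FALSE)
  }
  chr_lengths <- rep(total_length_cM / n_chromosomes, n_chromosomes)
  names(chr_lengths) <- paste0("chr", seq_len(n_chromosomes))
  res <- with_seed(seed, {
    chr <- sample.int(n_chromosomes, n_markers, replace = TRUE,
                      prob = chr_lengths)
    pos <- runif(n_markers, 0, chr_lengths[chr])
    list(chr = chr, pos = pos)
  })
  ord <- order(res$chr, res$pos)
  chr <- res$chr[ord]
  pos <- res$pos[ord]
  map <- list(
    chr_lengths = chr_lengths,
    marker = sprintf("M%06d", seq_len(n_markers)),
    chromosome = names(chr_lengths)[chr],
    position_cM = pos,
    total_length_cM = total_length_cM,
    n_markers = as.integer(n_markers)
  )
  class(map) <- "genetic_map"
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d markers on %d chromosomes, %.1f cM total\n",
              x$n_markers, length(x$chr_lengths), x$total_length_cM))
  invisible(x)
}

# marker indices per chromosome, in map order
map_chr_index <- function(map) {
  split(seq_len(map$n_markers), factor(map$chromosome,
                                       levels = names(map$chr_lengths)))
}

#' Simulate founder haplotypes in linkage equilibrium
#'
#' Draws a per-marker allele frequency uniformly on
#' `[maf_min, 1 - maf_min]` and samples each founder haplotype allele
#' independently at that frequency. Founders therefore carry no linkage
#' disequilibrium: all LD in their descendants is generated by family
#' structure and recombination, which is the mechanism the downstream
#' genomic-prediction experiments rely on. Markers that come out
#' monomorphic are resampled so every marker segregates.
#'
#' @param n_founders number of founders.
#' @param map a [make_genetic_map()] object.
#' @param maf_min lower bound for the allele frequency, in `(0, 0.5]`.
#' @param seed integer seed.
#' @return An object of class `founder_pool`: list with `haplotypes`
#'   (integer matrix, `2 * n_founders` rows, one column per marker,
#'   alleles 0/1; rows `2i - 1` and `2i` belong to founder `i`), `freq`
#'   (the sampled per-marker frequency of allele 1) and `n_founders`.
#' @export
simulate_founders <- function(n_founders, map, maf_min = 0.05, seed) {
  check_positive_scalar(n_founders, "n_founders", int = TRUE)
  stopifnot(inherits(map, "genetic_map"))
  if (!is.numeric(maf_min) || length(maf_min) != 1L ||
      maf_min <= 0 || maf_min > 0.5) {
    stop("'maf_min' must lie in (0, 0.5]", call. = FALSE)
  }
  m <- map$n_markers
  out <- with_seed(seed, {
    freq <- runif(m, maf_min, 1 - maf_min)
    h <- matrix(0L, nrow = 2L * n_founders, ncol = m)
    h[] <- as.integer(runif(length(h)) < rep(freq, each = 2L * n_founders))
    # resample any monomorphic column (possible at small founder counts)
    repeat {
      cs <- colSums(h)
      bad <- which(cs == 0L | cs == nrow(h))
      if (!length(bad)) break
      for (j in bad) {
        h[, j] <- as.integer(runif(nrow(h)) < freq[j])
      }
    }
    list(h = h, freq = freq)
  })
  colnames(out$h) <- map$marker
  pool <- list(haplotypes = out$h, freq = out$freq,
               n_founders = as.integer(n_founders))
  class(pool) <- "founder_pool"
  pool
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf("founder_pool: %d founders x %d markers\n",
              x$n_founders, ncol(x$haplotypes)))
  invisible(x)
}

#' Generate one gamete from a parent by simulated meiosis
#'
#' Recombination follows the Haldane model: per chromosome the crossover
#' count is Poisson with mean `length_cM / 100`, crossover positions are
#' uniform, there is no interference, and the starting haplotype is
#' chosen with probability 1/2. The gamete is the resulting mosaic of the
#' two parental haplotypes.
#'
#' Uses the current RNG state; seed externally (e.g. [with_seed()] via
#' [simulate_population()]) for reproducibility.
#'
#' @param parent_haplotypes integer matrix with 2 rows (the parent's
#'   phased haplotypes) and one column per mapped marker.
#' @param map the [make_genetic_map()] object the haplotypes follow.
#' @return Integer vector of alleles, one per marker.
#' @export
make_gamete <- function(parent_haplotypes, map) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.matrix(parent_haplotypes) || nrow(parent_haplotypes) != 2L ||
      ncol(parent_haplotypes) != map$n_markers) {
    stop("'parent_haplotypes' must be a 2 x n_markers matrix", call. = FALSE)
  }
  idx <- map_chr_index(map)
  gam <- integer(map$n_markers)
  for (k in seq_along(idx)) {
    j <- idx[[k]]
    gam[j] <- gamete_chromosome(parent_haplotypes[, j, drop = FALSE],
                                map$position_cM[j],
                                map$chr_lengths[[k]])
  }
  gam
}

# meiosis for one chromosome: haplo is 2 x m, pos the marker positions (cM)
gamete_chromosome <- function(haplo, pos, len_cM) {
  n_co <- rpois(1L, len_cM / 100)
  start <- sample.int(2L, 1L)
  if (n_co == 0L || ncol(haplo) == 0L) {
    return(haplo[start, ])
  }
  co <- sort(runif(n_co, 0, len_cM))
  # haplotype in use at a marker flips once per crossover to its left
  use <- (start - 1L + findInterval(pos, co)) %% 2L + 1L
  haplo[cbind(use, seq_along(pos))]
}
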