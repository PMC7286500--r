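# Simulator: map construction, founders, meiosis, gene drop, phenotypes.

test_that("genetic map conserves marker counts and lengths", {
  gm <- make_genetic_map(12, 2000, 24, seed = 1)
  expect_s3_class(gm, "genetic_map")
  expect_equal(sum(gm$chr_lengths), 2000)
  expect_equal(unname(gm$chr_lengths), rep(2000 / 12, 12))
  expect_equal(gm$n_markers, 24L)
  expect_equal(length(gm$position_cM), 24L)
  counts <- table(gm$chromosome)
  expect_equal(sum(counts), 24L)
  # positions within bounds, sorted within chromosome
  for (ch in unique(gm$chromosome)) {
    p <- gm$position_cM[gm$chromosome == ch]
    expect_true(all(p >= 0 & p <= gm$chr_lengths[[ch]]))
    expect_false(is.unsorted(p))
  }
})

test_that("single-chromosome single-marker boundary case works", {
  gm <- make_genetic_map(1, 100, 1, seed = 3)
  expect_equal(length(gm$chr_lengths), 1L)
  expect_true(gm$position_cM >= 0 && gm$position_cM <= 100)
})

test_that("map construction is deterministic and validates inputs", {
  expect_identical(make_genetic_map(4, 500, 40, seed = 9),
                   make_genetic_map(4, 500, 40, seed = 9))
  expect_error(make_genetic_map(0, 100, 5, seed = 1), "positive")
  expect_error(make_genetic_map(2, -1, 5, seed = 1), "positive")
  expect_error(make_genetic_map(4, 100, 3, seed = 1), "at least")
})

test_that("founder pools respect frequency bounds and never fix alleles", {
  gm <- make_genetic_map(2, 200, 150, seed = 5)
  fp <- simulate_founders(8, gm, maf_min = 0.1, seed = 6)
  expect_true(all(fp$haplotypes %in% c(0L, 1L)))
  obs <- colMeans(fp$haplotypes)
  expect_true(all(obs > 0 & obs < 1))
  expect_true(all(fp$freq >= 0.1 & fp$freq <= 0.9))
  expect_error(simulate_founders(8, gm, maf_min = 0.6, seed = 1), "0.5")
  expect_error(simulate_founders(8, gm, maf_min = 0, seed = 1), "0.5")
})

test_that("maf_min = 0.5 forces all frequencies to one half", {
  gm <- make_genetic_map(1, 100, 60, seed = 2)
  fp <- simulate_founders(200, gm, maf_min = 0.5, seed = 3)
  expect_true(all(fp$freq == 0.5))
  # realized frequency within binomial sampling error of 0.5
  expect_true(all(abs(colMeans(fp$haplotypes) - 0.5) < 5 * sqrt(0.25 / 400)))
})

test_that("founders are in linkage equilibrium", {
  gm <- make_genetic_map(4, 400, 200, seed = 10)
  fp <- simulate_founders(1000, gm, seed = 11)
  cc <- cor(fp$haplotypes)
  offdiag <- cc[upper.tri(cc)]
  # brute-force mean pairwise allelic correlation across all marker pairs
  expect_lt(abs(mean(offdiag)), 0.004)
  expect_lt(mean(offdiag^2), 0.002)
})

test_that("meiosis degenerates correctly and matches the Haldane map", {
  # zero-length chromosome: gamete equals an intact parental haplotype
  gm0 <- structure(list(chr_lengths = c(chr1 = 0), marker = c("M1", "M2"),
                        chromosome = c("chr1", "chr1"),
                        position_cM = c(0, 0), total_length_cM = 0,
                        n_markers = 2L), class = "genetic_map")
  hap <- rbind(c(1L, 0L), c(0L, 1L))
  set.seed(1)
  g <- replicate(20, make_gamete(hap, gm0))
  expect_true(all(apply(g, 2, function(x) {
    identical(x, hap[1, ]) || identical(x, hap[2, ])
  })))

  # homozygous parent: gamete identical regardless of crossovers
  gm1 <- make_genetic_map(1, 300, 50, seed = 4)
  haph <- matrix(rep(rbinom(50, 1, 0.5), each = 2), nrow = 2)
  storage.mode(haph) <- "integer"
  set.seed(2)
  expect_identical(make_gamete(haph, gm1), haph[1, ])

  # recombination fraction at 100 cM ~ Haldane 0.5 (1 - exp(-2))
  gm2 <- structure(list(chr_lengths = c(chr1 = 100), marker = c("M1", "M2"),
                        chromosome = c("chr1", "chr1"),
                        position_cM = c(0, 100), total_length_cM = 100,
                        n_markers = 2L), class = "genetic_map")
  hap2 <- rbind(c(1L, 1L), c(0L, 0L))
  set.seed(3)
  gam <- replicate(10000, make_gamete(hap2, gm2))
  rec <- mean(gam[1, ] != gam[2, ])
  expect_lt(abs(rec - 0.5 * (1 - exp(-2))), 0.02)
})

test_that("gene drop is Mendelian-consistent and dosage matches haplotypes", {
  tr <- small_fullsib_trial()
  pop <- tr$pop
  n_off <- nrow(pop$info)
  h1 <- pop$haplotypes[paste0(pop$info$id, ".1"), ]
  h2 <- pop$haplotypes[paste0(pop$info$id, ".2"), ]
  expect_identical(unname(pop$dosage), unname(h1 + h2))
  # no opposing homozygotes between offspring and either recorded parent
  ped <- pop$pedigree
  off <- ped[ped$sire != "0", ]
  pdos <- pop$haplotypes[paste0(off$sire, ".1"), ] +
    pop$haplotypes[paste0(off$sire, ".2"), ]
  odos <- pop$dosage[off$id, ]
  expect_equal(sum((pdos == 0 & odos == 2) | (pdos == 2 & odos == 0)), 0)
  mdos <- pop$haplotypes[paste0(off$dam, ".1"), ] +
    pop$haplotypes[paste0(off$dam, ".2"), ]
  expect_equal(sum((mdos == 0 & odos == 2) | (mdos == 2 & odos == 0)), 0)
})

test_that("parents with dosages 0 and 2 always give heterozygous offspring", {
  tr <- small_fullsib_trial()
  pop <- tr$pop
  ped <- pop$pedigree
  off <- ped[ped$sire != "0", ][1:40, ]
  sd_ <- pop$haplotypes[paste0(off$sire, ".1"), ] +
    pop$haplotypes[paste0(off$sire, ".2"), ]
  dd <- pop$haplotypes[paste0(off$dam, ".1"), ] +
    pop$haplotypes[paste0(off$dam, ".2"), ]
  odos <- pop$dosage[off$id, ]
  fixed_het <- (sd_ == 0 & dd == 2) | (sd_ == 2 & dd == 0)
  expect_true(all(odos[fixed_het] == 1))
  expect_gt(sum(fixed_het), 0)
})

test_that("population structure follows the design and is seed-stable", {
  tr <- small_fullsib_trial()
  d <- tr$design
  expect_equal(nrow(tr$pop$info), d$n_families * d$offspring_per_family)
  expect_equal(length(unique(tr$pop$info$family)), d$n_families)
  # balanced round-robin: site counts differ by at most one per family
  tab <- table(tr$pop$info$family, tr$pop$info$site)
  expect_true(all(abs(tab - mean(tab)) <= 1))
  f <- simulate_founders(n_founders_required(d), tr$map, seed = 77)
  p1 <- simulate_population(f, d, tr$map, seed = 123)
  p2 <- simulate_population(f, d, tr$map, seed = 123)
  expect_identical(p1, p2)
  expect_error(simulate_population(simulate_founders(3, tr$map, seed = 1),
                                   d, tr$map, seed = 1), "founders")
})

test_that("half-sib families with a single pollen donor become full sibs", {
  gm <- make_genetic_map(5, 1000, 6000, seed = 21)
  d <- half_sib_design(n_families = 4, offspring_per_family = 10,
                       pollen_pool_size = 1, n_sites = 1, blocks_per_site = 1)
  f <- simulate_founders(n_founders_required(d), gm, seed = 22)
  pop <- simulate_population(f, d, gm, seed = 23)
  # realized genomic relatedness among nominal half sibs ~ full-sib 0.5
  G <- genomic_relationship_oracle(pop, f)
  fam <- pop$info$family
  same <- outer(fam, fam, "==") & upper.tri(G[pop$info$id, pop$info$id])
  mean_rel <- mean(G[pop$info$id, pop$info$id][same])
  expect_lt(abs(mean_rel - 0.5), 0.05)
})

test_that("realized genomic relatedness matches pedigree expectation", {
  gm <- make_genetic_map(5, 1000, 6000, seed = 31)
  dfs <- full_sib_design(n_parents = 16, n_families = 8,
                         offspring_per_family = 12, n_sites = 1,
                         blocks_per_site = 1, parent_skew = 0)
  ffs <- simulate_founders(16, gm, seed = 32)
  pfs <- simulate_population(ffs, dfs, gm, seed = 33)
  Gfs <- genomic_relationship_oracle(pfs, ffs)[pfs$info$id, pfs$info$id]
  same_fam <- outer(pfs$info$family, pfs$info$family, "==") & upper.tri(Gfs)
  expect_lt(abs(mean(Gfs[same_fam]) - 0.5), 0.03)

  dhs <- half_sib_design(n_families = 8, offspring_per_family = 12,
                         pollen_pool_size = 200, n_sites = 1,
                         blocks_per_site = 1)
  fhs <- simulate_founders(n_founders_required(dhs), gm, seed = 34)
  phs <- simulate_population(fhs, dhs, gm, seed = 35)
  Ghs <- genomic_relationship_oracle(phs, fhs)[phs$info$id, phs$info$id]
  same_fam <- outer(phs$info$family, phs$info$family, "==") & upper.tri(Ghs)
  expect_lt(abs(mean(Ghs[same_fam]) - 0.25), 0.03)
})

test_that("phenotype simulation respects the variance architecture", {
  # null architecture: white noise only
  gm <- make_genetic_map(2, 400, 220, seed = 41)
  d <- full_sib_design(n_parents = 10, n_families = 6,
                       offspring_per_family = 20, n_sites = 3,
                       blocks_per_site = 2)
  f <- simulate_founders(10, gm, seed = 42)
  pop <- simulate_population(f, d, gm, seed = 43)
  vc0 <- variance_components(sigma2_a = 0, sigma2_sa = 0, sigma2_srep = 0,
                             sigma2_sf = 0, sigma2_f = 0, sigma2_e = 2)
  arch0 <- trait_architecture(gm, n_qtl = 50, vc = vc0, seed = 44)
  ph0 <- simulate_phenotypes(pop, arch0, seed = 45)
  expect_equal(ph0$truth$a, rep(0, nrow(ph0$pheno)))
  expect_equal(var(ph0$truth$e), 2, tolerance = 1e-10)
  expect_equal(ph0$pheno$y - 10 - ph0$truth$site_effect, ph0$truth$e,
               tolerance = 1e-12)

  # noiseless single-site limit: phenotype - mean - site = additive value
  vc1 <- variance_components(sigma2_a = 1.5, sigma2_sa = 0, sigma2_srep = 0,
                             sigma2_sf = 0, sigma2_f = 0, sigma2_e = 0)
  arch1 <- trait_architecture(gm, n_qtl = 50, vc = vc1, seed = 46)
  ph1 <- simulate_phenotypes(pop, arch1, seed = 47, site_effects = 0)
  expect_equal(ph1$pheno$y - 10, ph1$truth$a, tolerance = 1e-12)
  expect_equal(var(ph1$truth$a), 1.5, tolerance = 1e-10)

  # degenerate trait rejected
  vcz <- variance_components(0, 0, 0, 0, 0, 0)
  archz <- trait_architecture(gm, n_qtl = 10, vc = vcz, seed = 48)
  expect_error(simulate_phenotypes(pop, archz, seed = 1), "degenerate")
})

test_that("realized variance decomposition recovers each component", {
  d <- full_sib_design(n_parents = 54, n_families = 37,
                       offspring_per_family = 54)
  gm <- make_genetic_map(12, 2000, 400, seed = 51)
  f <- simulate_founders(54, gm, seed = 52)
  pop <- simulate_population(f, d, gm, seed = 53)   # 1,998 offspring
  arch <- trait_architecture(gm, n_qtl = 300, seed = 54)
  ph <- simulate_phenotypes(pop, arch, seed = 55)
  tv <- ph$truth
  target <- arch$vc
  expect_equal(var(tv$a), target[["sigma2_a"]], tolerance = 1e-10)
  got <- c(var(tv$sa), var(tv$srep), var(tv$sf), var(tv$f), var(tv$e))
  want <- c(target[["sigma2_sa"]], target[["sigma2_srep"]],
            target[["sigma2_sf"]], target[["sigma2_f"]],
            target[["sigma2_e"]])
  expect_true(all(abs(got - want) / want < 0.15))
  # components assemble the record exactly
  recon <- 10 + tv$site_effect + tv$a + tv$sa + tv$srep + tv$sf + tv$f + tv$e
  expect_equal(ph$pheno$y, recon, tolerance = 1e-12)
})

test_that("phenotype simulation is deterministic given the seed", {
  tr1 <- simulate_trial(full_sib_design(n_parents = 10, n_families = 5,
                                        offspring_per_family = 6),
                        seed = 99, n_chromosomes = 2, total_length_cM = 200,
                        n_markers = 500, n_qtl = 40)
  tr2 <- simulate_trial(full_sib_design(n_parents = 10, n_families = 5,
                                        offspring_per_family = 6),
                        seed = 99, n_chromosomes = 2, total_length_cM = 200,
                        n_markers = 500, n_qtl = 40)
  expect_identical(tr1$pop, tr2$pop)
  expect_identical(tr1$phenotypes$pheno, tr2$phenotypes$pheno)
})
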