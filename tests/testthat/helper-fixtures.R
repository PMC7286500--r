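# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a small but structurally complete full-sib trial
small_fullsib_trial <- function() {
  cached("small_fs", function() {
    design <- full_sib_design(n_parents = 20, n_families = 12,
                              offspring_per_family = 12, n_sites = 3,
                              blocks_per_site = 4)
    simulate_trial(design, seed = 42, n_chromosomes = 5,
                   total_length_cM = 1000, n_markers = 3100, n_qtl = 100)
  })
}

small_halfsib_trial <- function() {
  cached("small_hs", function() {
    design <- half_sib_design(n_families = 12, offspring_per_family = 12,
                              pollen_pool_size = 60, n_sites = 3,
                              blocks_per_site = 4)
    simulate_trial(design, seed = 43, n_chromosomes = 5,
                   total_length_cM = 1000, n_markers = 3100, n_qtl = 100)
  })
}

# three-generation, 25-individual pedigree with mixed structure
pedigree_3gen <- function() {
  data.frame(
    id   = c(paste0("g", 1:8),
             "x1", "x2", "x3", "x4", "x5", "x6",
             "y1", "y2", "y3", "y4", "y5", "y6", "y7", "y8", "y9", "y10",
             "z1"),
    sire = c(rep("0", 8),
             "g1", "g1", "g3", "g5", "g7", "g7",
             "x1", "x1", "x3", "x3", "x5", "x5", "x1", "x3", "x5", "x1",
             "y1"),
    dam  = c(rep("0", 8),
             "g2", "g4", "g4", "g6", "g8", "g6",
             "x2", "x2", "x4", "x4", "x6", "x6", "x4", "x6", "x2", "x6",
             "y3"),
    stringsAsFactors = FALSE
  )
}

# the scaled two-design marker-density study: ~600 trees per design,
# 7-point grid, 5 marker replicates, 5x5-fold CV (sizes documented in
# the methods vignette)
scaled_density_study <- function(master_seed) {
  grid <- c(200, 500, 1000, 2500, 5000, 10000, 20000)
  one <- function(kind) {
    design <- if (kind == "fullsib") {
      full_sib_design(offspring_per_family = 16)     # 37 x 16 = 592
    } else {
      half_sib_design(offspring_per_family = 24)     # 25 x 24 = 600
    }
    seed <- child_seed(master_seed, if (kind == "fullsib") 1 else 2)
    tr <- simulate_trial(design, seed = child_seed(seed, 101))
    e <- trial_ebv(tr)
    Z <- snp_panel(tr$pop, tr$arch)
    res <- run_marker_density_experiment(unname(e$ebv), Z, grid = grid,
                                         marker_reps = 5, folds = 5,
                                         repeats = 5,
                                         seed = child_seed(seed, 202))
    list(results = res, summary = summarize_accuracy(res),
         ns = trial_status_number(tr), h2 = e$h2)
  }
  list(fullsib = one("fullsib"), halfsib = one("halfsib"), grid = grid)
}

cached_density_study <- function(master_seed = 1) {
  cached(paste0("density_study_", master_seed),
         function() scaled_density_study(master_seed))
}

# deterministic random pedigree generator for property sweeps
random_pedigree <- function(n_founders, n_descendants, seed) {
  set.seed(seed)
  id <- c(paste0("f", seq_len(n_founders)),
          paste0("o", seq_len(n_descendants)))
  sire <- dam <- rep("0", length(id))
  for (k in seq_len(n_descendants)) {
    i <- n_founders + k
    pool <- id[seq_len(i - 1L)]
    pair <- sample(pool, 2L)
    sire[i] <- pair[1L]
    dam[i] <- pair[2L]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}
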