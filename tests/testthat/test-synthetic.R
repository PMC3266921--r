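# Ground-truthed synthetic data generator.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_taxa = 16, core_taxa = 2, taxa_per_plant = 2,
         taxa_per_location = 1, n_plants = 2, n_locations = 2,
         larvae_per_cell = 2),
    list(...))
  do.call(generator_config, args)
}

test_that("configuration validates its ranges", {
  expect_error(generator_config(substitution_rate = 0.25), class = "trflp_config")
  expect_error(generator_config(plant_effect = 1.2), class = "trflp_config")
  expect_error(generator_config(core_taxa = 50, n_taxa = 10), class = "trflp_config")
  expect_s3_class(generator_config(), "generator_config")
})

test_that("the pool is deterministic and zero-rate collapses to the root", {
  cfg <- small_cfg(seed = 5)
  p1 <- generate_taxon_pool(cfg)
  p2 <- generate_taxon_pool(cfg)
  expect_identical(p1$sequences, p2$sequences)

  cfg0 <- small_cfg(substitution_rate = 0, seed = 5)
  p0 <- generate_taxon_pool(cfg0)
  expect_true(all(p0$sequences == p0$root))
})

test_that("every taxon's fragment hits its assigned target length", {
  cfg <- small_cfg(seed = 6)
  pool <- generate_taxon_pool(cfg)
  for (id in names(pool$sequences)) {
    amp <- extract_amplicon(pool$sequences[[id]], id = id)
    trf <- terminal_fragment(amp, bfai())
    expect_true(trf$cut_found)
    expect_equal(trf$length_bp, unname(pool$trf_bp[id]))
  }
  expect_equal(anyDuplicated(pool$trf_bp), 0L)
})

test_that("pairwise divergence matches the binomial expectation", {
  cfg <- generator_config(n_taxa = 40, seed = 7)
  pool <- generate_taxon_pool(cfg)
  m <- do.call(rbind, strsplit(unname(pool$sequences), ""))
  set.seed(8)
  pairs <- t(replicate(200, sample(nrow(m), 2)))
  frac <- apply(pairs, 1, function(ij) mean(m[ij[1], ] != m[ij[2], ]))
  r <- cfg$substitution_rate
  L <- cfg$root_length_bp
  expected <- 2 * r * (1 - r) * (L - 39) / L  # 39 primer-protected sites
  se <- sqrt(expected * (1 - expected) / L)
  expect_lt(abs(mean(frac) - expected), 3 * se)
})

test_that("membership follows the occupancy model", {
  # deterministic limit: plant taxa occur exactly in their plant's samples
  cfg <- small_cfg(plant_effect = 1, location_effect = 0,
                   baseline_occupancy = 0, artificial_diet = FALSE, seed = 9)
  truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
  for (j in which(truth$roles$role == "plant")) {
    match_rows <- truth$design$host_plant == truth$roles$plant[j]
    expect_equal(unname(truth$membership[, j]), match_rows)
  }
  # core taxa occupy every sample
  expect_true(all(truth$membership[, truth$roles$role == "core"]))

  # stochastic occupancy within 3 binomial SEs over 200 matching samples
  cfg2 <- generator_config(n_plants = 2, n_locations = 1, larvae_per_cell = 100,
                           artificial_diet = FALSE, seed = 10)
  truth2 <- assemble_communities(cfg2, generate_taxon_pool(cfg2))
  j <- which(truth2$roles$role == "plant")[1]
  rows <- truth2$design$host_plant == truth2$roles$plant[j]
  occ <- mean(truth2$membership[rows, j])
  se <- sqrt(0.9 * 0.1 / sum(rows))
  expect_lt(abs(occ - cfg2$plant_effect), 3 * se)
})

test_that("noise-free simulation reproduces the true fragment list", {
  cfg <- small_cfg(size_jitter_sd_bp = 0, dropout_prob = 0,
                   spurious_peak_rate = 0, artificial_diet = FALSE, seed = 11)
  truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
  prof <- simulate_electropherograms(truth, cfg)
  ids <- vapply(prof, function(p) p$sample_id, "")
  for (s in unique(ids)) {
    true_sizes <- sort(truth$trf_bp[truth$membership[s, ]])
    pair <- prof[ids == s]
    expect_equal(pair[[1]]$peaks$size_bp, unname(true_sizes))
    expect_equal(pair[[2]]$peaks$size_bp, unname(true_sizes))
  }
})

test_that("total dropout empties the profiles", {
  cfg <- small_cfg(dropout_prob = 1, core_dropout_prob = 1,
                   spurious_peak_rate = 0, artificial_diet = FALSE, seed = 12)
  truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
  prof <- simulate_electropherograms(truth, cfg)
  expect_true(all(vapply(prof, function(p) nrow(p$peaks) == 0L, TRUE)))
})

test_that("consensus recovery of true peaks matches (1-dropout)^2", {
  cfg <- generator_config(n_plants = 2, n_locations = 1, larvae_per_cell = 120,
                          core_taxa = 0, dropout_prob = 0.2,
                          size_jitter_sd_bp = 0, spurious_peak_rate = 0,
                          artificial_diet = FALSE, seed = 13)
  truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
  prof <- simulate_electropherograms(truth, cfg)
  cons <- consensus_profiles(prof)
  hits <- 0L; trials <- 0L
  for (p in cons) {
    true_sizes <- truth$trf_bp[truth$membership[p$sample_id, ]]
    trials <- trials + length(true_sizes)
    hits <- hits + sum(true_sizes %in% p$peaks$size_bp)
  }
  expected <- (1 - cfg$dropout_prob)^2
  se <- sqrt(expected * (1 - expected) / trials)
  expect_lt(abs(hits / trials - expected), 3 * se)
})

test_that("every emitted peak traces to a member taxon or spurious record", {
  cfg <- small_cfg(seed = 14)
  truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
  prof <- simulate_electropherograms(truth, cfg)
  prov <- attr(prof, "provenance")
  expect_equal(nrow(prov), sum(vapply(prof, function(p) nrow(p$peaks), 0L)))
  real <- prov[prov$origin != "spurious", ]
  expect_true(all(truth$membership[cbind(real$sample, real$origin)]))
})

test_that("plant effect dominates location effect, and swapping reverses it", {
  run_contrast <- function(pe, le, seed) {
    cfg <- generator_config(plant_effect = pe, location_effect = le,
                            artificial_diet = FALSE, seed = seed)
    truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
    prof <- lapply(simulate_electropherograms(truth, cfg), filter_peaks)
    pm <- bin_profiles(consensus_profiles(prof))
    plant_location_contrast(similarity_matrix(pm), truth$design)$difference
  }
  expect_gt(run_contrast(0.9, 0.3, 21), 0)
  expect_lt(run_contrast(0.3, 0.9, 21), 0)
})

test_that("clone libraries resample member taxa with recorded weights", {
  cfg <- small_cfg(seed = 15)
  truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
  sid <- truth$design$sample_id[1]
  lib <- generate_clone_library(truth, sid, n_clones = 90, seed = 99)
  expect_length(lib$sequences, 90L)
  expect_equal(sum(lib$taxon_counts), 90L)
  members <- truth$roles$taxon_id[truth$membership[sid, ]]
  expect_true(all(names(lib$taxon_counts) %in% members))
  # all clones are copies of pool sequences
  src <- sub("^clone[0-9]+_", "", names(lib$sequences))
  expect_identical(unname(lib$sequences), unname(truth$pool$sequences[src]))
  expect_error(generate_clone_library(truth, "nope"), "no such sample")

  # multinomial frequencies track the weights at large n
  big <- generate_clone_library(truth, sid, n_clones = 10000, seed = 100)
  p <- big$weights / sum(big$weights)
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(big$taxon_counts / 10000 - p) <= 3 * se + 1e-6))
})

test_that("one-member samples give monomorphic clone libraries", {
  cfg <- small_cfg(core_taxa = 1, baseline_occupancy = 0, plant_effect = 0,
                   location_effect = 0, artificial_diet = FALSE, seed = 16)
  truth <- assemble_communities(cfg, generate_taxon_pool(cfg))
  lib <- generate_clone_library(truth, truth$design$sample_id[1], n_clones = 10)
  expect_equal(length(unique(unname(lib$sequences))), 1L)
})
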