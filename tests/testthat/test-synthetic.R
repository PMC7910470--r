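test_that("zero divergence collapses the whole library to one sequence", {
  cfg <- sim_config(seed = 5, n_families = 2, genera_per_family = 2,
                    species_per_genus = 2, ind_law = "fixed", ind_mean = 3,
                    div_family = 0, div_genus = 0, div_species = 0,
                    theta_intra = 0, deep_split = NULL, merge_pairs = NULL,
                    partial_fraction = 0, numt_fraction = 0, n_unnamed = 0)
  sim <- simulate_library(cfg)
  expect_equal(length(unique(sim$library$sequences$residues)), 1L)
  dm <- k2p_distances(sim$library)
  expect_true(all(dm$pairs$d == 0))
  tab <- haplotype_table(sim$library)
  expect_true(all(tab$n_haplotypes == 1L))
})

test_that("a fixed seed reproduces the library byte for byte", {
  cfg <- sim_config(seed = 99)
  s1 <- simulate_library(cfg)
  s2 <- simulate_library(cfg)
  expect_identical(s1$library$sequences, s2$library$sequences)
  expect_identical(s1$library$specimens, s2$library$specimens)
  expect_identical(s1$truth$records, s2$truth$records)
  s3 <- simulate_library(sim_config(seed = 100))
  expect_false(identical(s1$library$sequences$residues,
                         s3$library$sequences$residues))
})

test_that("simulated sequences stay stop-free in frame 0", {
  sim <- simulate_library(sim_config(seed = 12, partial_fraction = 0,
                                     numt_fraction = 0))
  reports <- screen_numts(sim$library)
  expect_equal(sum(reports$numt_suspect), 0L)
  expect_equal(sum(reports$flagged), 0L)
})

test_that("K2P distance estimates are unbiased for the branch length", {
  set.seed(401)
  L <- 2000
  root <- evolve_sequence(strrep("ACGT", L / 4), 0, 3)
  for (t in c(0.02, 0.1, 0.2)) {
    d_hat <- replicate(120, {
      a <- evolve_sequence(root, t / 2, 3)
      b <- evolve_sequence(root, t / 2, 3)
      k2p_pair(a, b)$d
    })
    mc_se <- sd(d_hat) / sqrt(length(d_hat))
    expect_lt(abs(mean(d_hat) - t), 3 * mc_se + 1e-9)
  }
})

test_that("realized transition:transversion ratio reflects kappa", {
  set.seed(402)
  L <- 40000
  a <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  for (kappa in c(1, 3, 6)) {
    b <- evolve_sequence(a, 0.05, kappa, avoid_stops = FALSE)
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    diff <- A != B
    ts <- sum(diff & ((A %in% c("A", "G")) == (B %in% c("A", "G"))))
    tv <- sum(diff) - ts
    # per-event transition share kappa/(kappa+2) => count ratio ~ kappa/2
    expect_equal(ts / tv, kappa / 2, tolerance = 0.25)
  }
})

test_that("partial and numt fractions are realized within binomial error", {
  cfg <- sim_config(seed = 44, n_families = 2, genera_per_family = 3,
                    species_per_genus = 4, ind_law = "fixed", ind_mean = 10,
                    deep_split = NULL, merge_pairs = NULL,
                    partial_fraction = 0.1, numt_fraction = 0.1,
                    n_unnamed = 0)
  sim <- simulate_library(cfg)
  n <- nrow(sim$truth$records)
  for (col in c("is_partial", "is_numt")) {
    k <- sum(sim$truth$records[[col]])
    expect_lt(abs(k - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9) + 2)
  }
  # partial records fall in the 300-500 bp tier, from the 3' end
  tab <- library_table(sim$library)
  partial_ids <- sim$truth$records$sequence_id[sim$truth$records$is_partial]
  expect_true(all(tab$tier[tab$sequence_id %in% partial_ids] == "partial"))
  one <- tab$residues[tab$sequence_id == partial_ids[1]]
  expect_match(one, "-+$")  # trailing gap block
})

test_that("planted numts carry a single-base frameshift deletion", {
  cfg <- sim_config(seed = 45, n_families = 1, genera_per_family = 1,
                    species_per_genus = 4, ind_law = "fixed", ind_mean = 5,
                    deep_split = NULL, merge_pairs = NULL,
                    partial_fraction = 0, numt_fraction = 0.3, n_unnamed = 0)
  sim <- simulate_library(cfg)
  rec <- sim$truth$records
  expect_gt(sum(rec$is_numt), 0)
  tab <- library_table(sim$library)
  numt_res <- tab$residues[tab$sequence_id %in%
                             rec$sequence_id[rec$is_numt]]
  expect_true(all(vapply(numt_res, function(r)
    sum(strsplit(r, "")[[1]] == "-") == 1L, logical(1))))
})

test_that("merge pairs must be congeneric and indices in range", {
  expect_error(simulate_library(sim_config(
    seed = 1, n_families = 2, genera_per_family = 1, species_per_genus = 2,
    deep_split = NULL,
    merge_pairs = data.frame(species_a = 1, species_b = 3, eps = 0.002))),
    "congeneric")
  expect_error(simulate_library(sim_config(
    seed = 1, n_families = 1, genera_per_family = 1, species_per_genus = 2,
    merge_pairs = NULL,
    deep_split = data.frame(species = 99, delta = 0.08))),
    "out of range")
})

test_that("truth evaluation flags mismatched inputs", {
  sim <- simulate_library(sim_config(seed = 46, n_families = 1,
                                     genera_per_family = 1,
                                     species_per_genus = 4,
                                     ind_law = "fixed", ind_mean = 3,
                                     deep_split = NULL, merge_pairs = NULL))
  aud <- run_audit(sim)
  truth_bad <- sim$truth
  truth_bad$species$species[1] <- "Genus99 species999"
  expect_error(truth_eval(aud, truth_bad), "mismatched ids")
})
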