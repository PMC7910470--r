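test_that("K2P closed form matches hand-computed cases", {
  a <- strrep("A", 100)
  # identical sequences
  same <- k2p_pair(a, a)
  expect_equal(same$P, 0)
  expect_equal(same$Q, 0)
  expect_equal(same$d, 0)
  # 10 transitions / 100 sites: d = -1/2 ln(0.8)
  b10 <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_pair(a, b10)$P, 0.1)
  expect_equal(k2p_pair(a, b10)$d, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(round(k2p_pair(a, b10)$d, 6), 0.111572)
  # 5 transitions + 5 transversions
  b55 <- paste0(strrep("G", 5), strrep("C", 5), strrep("A", 90))
  d55 <- k2p_pair(a, b55)
  expect_equal(c(d55$P, d55$Q), c(0.05, 0.05))
  expect_equal(d55$d, -0.5 * log(0.85) - 0.25 * log(0.90),
               tolerance = 1e-12)
  expect_equal(round(d55$d, 6), 0.1076)
})

test_that("saturation and low overlap are flagged, not computed", {
  a <- strrep("A", 100)
  # 40 transitions + 25 transversions: 1 - 2P - Q = -0.05
  b <- paste0(strrep("G", 40), strrep("C", 25), strrep("A", 35))
  sat <- k2p_pair(a, b)
  expect_equal(sat$status, "saturated")
  expect_true(is.na(sat$d))
  short <- k2p_pair(paste0(strrep("-", 60), strrep("A", 40)), a)
  expect_equal(short$status, "low_overlap")
  expect_equal(short$overlap, 40L)
  expect_error(k2p_pair("ACGT", "ACGTA"), "align")
})

test_that("gaps and ambiguity codes are excluded pairwise", {
  a <- paste0("RN-", strrep("A", 100))
  b <- paste0("AAG", strrep("A", 99), "G")
  cmp <- k2p_pair(a, b)
  expect_equal(cmp$overlap, 100L)  # first three sites dropped
  expect_equal(cmp$P, 0.01)        # the single A/G transition remains
})

test_that("K2P agrees with the site-loop oracle on random messy pairs", {
  set.seed(101)
  for (i in 1:300) {
    pr <- random_pair(L = 150, p_sub = runif(1, 0, 0.35),
                      p_messy = runif(1, 0, 0.15))
    got <- k2p_pair(pr[1], pr[2], min_overlap = 50)
    want <- k2p_oracle(pr[1], pr[2], min_overlap = 50)
    expect_equal(got$overlap, want$overlap)
    expect_equal(got$status, want$status)
    if (want$status == "ok") {
      expect_equal(got$d, want$d, tolerance = 1e-12)
    }
  }
})

test_that("K2P correction inflates distances relative to p-distance", {
  set.seed(33)
  for (i in 1:100) {
    pr <- random_pair(L = 300, p_sub = runif(1, 0.01, 0.25), p_messy = 0)
    got <- k2p_pair(pr[1], pr[2])
    if (got$status != "ok") next
    p_dist <- got$P + got$Q
    if (p_dist == 0) expect_equal(got$d, 0) else
      expect_gt(got$d, p_dist)
  }
})

test_that("distance matrices are symmetric with a zero diagonal", {
  sim <- simulate_library(sim_config(seed = 3, n_families = 2,
                                     genera_per_family = 2,
                                     species_per_genus = 2,
                                     ind_law = "fixed", ind_mean = 3,
                                     deep_split = NULL, merge_pairs = NULL))
  dm <- k2p_distances(sim$library)
  expect_identical(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  expect_true(all(dm$d[!is.na(dm$d)] >= 0))
  # matches an independent run of the pairwise function
  i <- dm$ids[2]; j <- dm$ids[5]
  res <- lib <- sim$library$sequences
  d_ij <- k2p_pair(res$residues[res$sequence_id == i],
                   res$residues[res$sequence_id == j])$d
  expect_equal(dm$d[i, j], d_ij)
})

test_that("cross-check against ape::dist.dna on clean alignments", {
  set.seed(77)
  mats <- replicate(12, {
    pr <- random_pair(L = 400, p_sub = runif(1, 0.01, 0.2), p_messy = 0)
    c(k2p_pair(pr[1], pr[2])$d,
      as.numeric(ape::dist.dna(ape::as.DNAbin(
        do.call(rbind, strsplit(tolower(pr), ""))), model = "K80")))
  })
  expect_equal(mats[1, ], mats[2, ], tolerance = 1e-10)
})

test_that("rank summary uses exclusive levels and percent units", {
  # toy: 2 conspecifics at d ~ 1%, one congeneric ~ 10% away
  L <- 1000
  base <- strrep("ACGT", 250)
  mk <- function(n_ts) paste0(strrep("G", n_ts),
                              substr(base, n_ts + 1, L))
  lib <- toy_library(
    c("Genus01 species001", "Genus01 species001", "Genus01 species002"),
    c(base, mk(10), mk(105))
  )
  dm <- k2p_distances(lib)
  rs <- summarize_divergence(dm, lib)
  ws <- rs[rs$level == "within_species", ]
  wg <- rs[rs$level == "within_genus", ]
  expect_equal(ws$n_comparisons, 1L)
  expect_equal(wg$n_comparisons, 2L)
  expect_equal(ws$mean_pct, 100 * k2p_oracle(base, mk(10))$d)
  expect_equal(wg$mean_pct,
               100 * mean(c(k2p_oracle(base, mk(105))$d,
                            k2p_oracle(mk(10), mk(105))$d)))
  # within_species excludes heterospecific pairs entirely
  expect_lt(ws$max_pct, wg$min_pct)
})

test_that("rank levels partition the valid labelled pairs", {
  sim <- simulate_library(sim_config(seed = 11, ind_law = "fixed",
                                     ind_mean = 2, n_unnamed = 0))
  dm <- k2p_distances(sim$library)
  rs <- summarize_divergence(dm, sim$library)
  n_valid <- sum(dm$pairs$status == "ok")
  labelled <- sum(rs$n_comparisons)
  # remaining valid pairs are cross-family
  tab <- library_table(sim$library)
  fam <- tab$family[match(dm$pairs$id_a, tab$sequence_id)]
  fam_b <- tab$family[match(dm$pairs$id_b, tab$sequence_id)]
  cross <- sum(dm$pairs$status == "ok" & fam != fam_b)
  expect_equal(labelled + cross, n_valid)
})

test_that("summaries are invariant to input order", {
  sim <- simulate_library(sim_config(seed = 19, n_families = 1,
                                     genera_per_family = 2,
                                     species_per_genus = 2,
                                     ind_law = "fixed", ind_mean = 3))
  lib <- sim$library
  set.seed(91)
  perm <- sample(nrow(lib$sequences))
  lib2 <- lib
  lib2$sequences <- lib$sequences[perm, ]
  lib2$specimens <- lib$specimens[sample(nrow(lib$specimens)), ]
  rs1 <- summarize_divergence(k2p_distances(lib), lib)
  rs2 <- summarize_divergence(k2p_distances(lib2), lib2)
  expect_equal(rs1, rs2)
})

test_that("pearson_corr matches hand computation and rejects degeneracy", {
  expect_equal(pearson_corr(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_corr(c(1, 2, 3), c(2, 1, 3))$r, 0.5)
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(4, 3, 2, 1))$r, -1)
  # p from the t transform with n - 2 df
  set.seed(4)
  x <- rnorm(20); y <- x + rnorm(20)
  got <- pearson_corr(x, y)
  r <- got$r
  t_stat <- r * sqrt((20 - 2) / (1 - r^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_stat), 18),
               tolerance = 1e-12)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})
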