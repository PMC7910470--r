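random_dist_fixture <- function(n, p_edge_scale = 0.05) {
  ids <- sprintf("s%03d", seq_len(n))
  d_pairs <- tibble::tibble(
    id_a = character(), id_b = character(), d = numeric())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d_pairs <- rbind(d_pairs, tibble::tibble(
      id_a = ids[i], id_b = ids[j],
      d = stats::rexp(1, rate = 1 / p_edge_scale)))
  }
  # a few invalid pairs must contribute no edge
  inv <- sample(nrow(d_pairs), max(1, n %/% 10))
  d_pairs$d[inv] <- NA_real_
  list(ids = ids, dm = manual_k2p(ids, d_pairs), pairs = d_pairs)
}

test_that("singletons and chaining behave as single linkage demands", {
  dm1 <- manual_k2p("a", tibble::tibble(id_a = character(),
                                        id_b = character(), d = numeric()))
  p1 <- cluster_barcodes(dm1, "a")
  expect_equal(p1$assignment$cluster_id, "LC:000001")
  # chaining: a-b and b-c below tau join a and c despite d(a,c) > tau
  dm3 <- manual_k2p(c("a", "b", "c"), tibble::tibble(
    id_a = c("a", "b", "a"), id_b = c("b", "c", "c"),
    d = c(0.01, 0.01, 0.03)))
  p3 <- cluster_barcodes(dm3, c("a", "b", "c"), tau = 0.022)
  expect_equal(length(unique(p3$assignment$cluster_id)), 1L)
  # two trios separated by 0.10 stay apart
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  grid <- t(combn(ids, 2))
  d6 <- tibble::tibble(
    id_a = grid[, 1], id_b = grid[, 2],
    d = ifelse(substr(grid[, 1], 1, 1) == substr(grid[, 2], 1, 1),
               0.005, 0.10))
  p6 <- cluster_barcodes(manual_k2p(ids, d6), ids)
  expect_equal(partition_sets(p6$assignment),
               list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
})

test_that("partition equals union-find components on random matrices", {
  set.seed(55)
  for (n in c(5, 12, 30, 50)) {
    fx <- random_dist_fixture(n)
    tau <- stats::runif(1, 0.01, 0.15)
    got <- partition_sets(cluster_barcodes(fx$dm, fx$ids, tau)$assignment)
    want <- union_find_partition(fx$ids, fx$pairs, tau)
    expect_equal(got, want)
  }
})

test_that("partitions refine monotonically in tau", {
  set.seed(56)
  fx <- random_dist_fixture(30)
  taus <- sort(stats::runif(4, 0.01, 0.2))
  parts <- lapply(taus, function(tau)
    cluster_barcodes(fx$dm, fx$ids, tau)$assignment)
  for (k in seq_len(length(taus) - 1)) {
    fine <- split(parts[[k]]$sequence_id, parts[[k]]$cluster_id)
    coarse_of <- setNames(parts[[k + 1]]$cluster_id,
                          parts[[k + 1]]$sequence_id)
    for (members in fine) {
      expect_equal(length(unique(coarse_of[members])), 1L)
    }
  }
})

test_that("cluster ids are stable under input reordering", {
  set.seed(57)
  fx <- random_dist_fixture(20)
  p1 <- cluster_barcodes(fx$dm, fx$ids, 0.05)
  perm <- sample(length(fx$ids))
  dm2 <- fx$dm
  dm2$ids <- fx$ids[perm]
  dm2$pairs <- fx$dm$pairs[sample(nrow(fx$dm$pairs)), ]
  p2 <- cluster_barcodes(dm2, fx$ids[perm], 0.05)
  expect_equal(p1$assignment, p2$assignment)
})

test_that("eligibility and tau bounds are enforced", {
  dm3 <- manual_k2p(c("a", "b", "c"), tibble::tibble(
    id_a = c("a", "b", "a"), id_b = c("b", "c", "c"),
    d = c(0.01, 0.01, 0.03)))
  expect_error(cluster_barcodes(dm3, c("a", "b"), tau = 0.5), "tau")
  expect_warning(p0 <- cluster_barcodes(dm3, character(0)), "empty")
  expect_equal(nrow(p0$assignment), 0L)
  # partial-tier sequences outside the eligible set are simply absent
  p2 <- cluster_barcodes(dm3, c("a", "b"))
  expect_equal(sort(p2$assignment$sequence_id), c("a", "b"))
})

test_that("concordance categories follow their definitions on toys", {
  mk_lib <- function(species) toy_library(
    species, rep(strrep("ACGT", 200), length(species)),
    ids = sprintf("q%d", seq_along(species)))
  # MATCH: one species, one pure cluster
  libm <- mk_lib(c("Genus01 spA", "Genus01 spA"))
  dmm <- manual_k2p(c("q1", "q2"), tibble::tibble(
    id_a = "q1", id_b = "q2", d = 0.001))
  cm <- classify_concordance(cluster_barcodes(dmm, c("q1", "q2")), libm)
  expect_equal(cm$category, "MATCH")
  # SPLIT: one species in two pure clusters
  dms <- manual_k2p(c("q1", "q2"), tibble::tibble(
    id_a = "q1", id_b = "q2", d = 0.08))
  cs <- classify_concordance(cluster_barcodes(dms, c("q1", "q2")), libm)
  expect_equal(cs$category, "SPLIT")
  expect_equal(cs$n_clusters, 2L)
  # MERGE: two species sharing one cluster
  libg <- mk_lib(c("Genus01 spA", "Genus01 spB"))
  cg <- classify_concordance(cluster_barcodes(dmm, c("q1", "q2")), libg)
  expect_equal(cg$category, c("MERGE", "MERGE"))
  # MIXTURE: two clusters, one shared
  libx <- mk_lib(c("Genus01 spA", "Genus01 spA", "Genus01 spB"))
  dmx <- manual_k2p(c("q1", "q2", "q3"), tibble::tibble(
    id_a = c("q1", "q1", "q2"), id_b = c("q2", "q3", "q3"),
    d = c(0.09, 0.001, 0.09)))
  cx <- classify_concordance(cluster_barcodes(dmx, c("q1", "q2", "q3")),
                             libx)
  expect_equal(cx$category[cx$species == "Genus01 spA"], "MIXTURE")
  expect_equal(cx$category[cx$species == "Genus01 spB"], "MERGE")
  # UNASSESSED: no eligible sequence
  cu <- classify_concordance(cluster_barcodes(dmm, "q1"),
                             mk_lib(c("Genus01 spA", "Genus01 spB")))
  expect_equal(cu$category[cu$species == "Genus01 spB"], "UNASSESSED")
})

test_that("unnamed records never render a cluster impure", {
  lib <- toy_library(c("Genus01 spA", NA), rep(strrep("ACGT", 200), 2),
                     ids = c("q1", "q2"))
  dm <- manual_k2p(c("q1", "q2"), tibble::tibble(
    id_a = "q1", id_b = "q2", d = 0.001))
  cc <- classify_concordance(cluster_barcodes(dm, c("q1", "q2")), lib)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$category, "MATCH")
})

test_that("planted splits and merges are classified as such", {
  sim <- simulate_library(sim_config(
    seed = 101, n_families = 1, genera_per_family = 1,
    species_per_genus = 6, ind_law = "fixed", ind_mean = 4,
    deep_split = data.frame(species = 2, delta = 0.08),
    merge_pairs = data.frame(species_a = 5, species_b = 6, eps = 0.002),
    partial_fraction = 0, numt_fraction = 0, n_unnamed = 0))
  aud <- run_audit(sim)
  ev <- truth_eval(aud, sim$truth)
  expect_equal(ev$split_recovery, 1)
  expect_equal(ev$merge_recovery, 1)
  expect_equal(ev$category_recovery, 1)
})
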