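# Independent oracles used across the suite. Deliberately naive: explicit
# site loops and union-find, no shared code with the package internals.

# K2P by an explicit per-site walk with a transition/transversion lookup.
k2p_oracle <- function(a, b, min_overlap = 100) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(A) == length(B))
  purine <- c("A", "G")
  pyrimidine <- c("C", "T")
  ov <- ts <- tv <- 0L
  for (i in seq_along(A)) {
    x <- A[i]; y <- B[i]
    if (!(x %in% c(purine, pyrimidine)) || !(y %in% c(purine, pyrimidine))) {
      next
    }
    ov <- ov + 1L
    if (x == y) next
    same_class <- (x %in% purine && y %in% purine) ||
      (x %in% pyrimidine && y %in% pyrimidine)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  if (ov < min_overlap) {
    return(list(overlap = ov, d = NA_real_, status = "low_overlap"))
  }
  P <- ts / ov
  Q <- tv / ov
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    return(list(overlap = ov, P = P, Q = Q, d = NA_real_,
                status = "saturated"))
  }
  list(overlap = ov, P = P, Q = Q,
       d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q), status = "ok")
}

# Stop counting by a manual codon walk (invertebrate mitochondrial code:
# only TAA and TAG are stops); terminal codon excluded, ambiguous skipped.
stop_walk_oracle <- function(seq, frame) {
  s <- gsub("-", "", toupper(seq), fixed = TRUE)
  chars <- strsplit(s, "")[[1]]
  count <- 0L
  codons <- character(0)
  i <- frame + 1L
  while (i + 2L <= length(chars)) {
    codons <- c(codons, paste0(chars[i], chars[i + 1L], chars[i + 2L]))
    i <- i + 3L
  }
  if (length(codons) > 1) {
    for (cd in codons[-length(codons)]) {
      if (grepl("[^ACGT]", cd)) next
      if (cd %in% c("TAA", "TAG")) count <- count + 1L
    }
  }
  count
}

# Connected components under d <= tau via plain union-find.
union_find_partition <- function(ids, pairs, tau) {
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (r in seq_len(nrow(pairs))) {
    if (is.na(pairs$d[r]) || pairs$d[r] > tau) next
    i <- match(pairs$id_a[r], ids)
    j <- match(pairs$id_b[r], ids)
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  # canonical form: sorted list of sorted member sets
  unname(lapply(split(ids, roots), sort))[order(
    vapply(split(ids, roots), min, character(1)))]
}

partition_sets <- function(assignment) {
  unname(lapply(split(assignment$sequence_id, assignment$cluster_id), sort))
}

# Random unrooted tree with strictly positive branch lengths and its
# additive distance matrix.
random_additive_matrix <- function(n) {
  tr <- ape::unroot(ape::rtree(n, rooted = TRUE))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Random aligned residue pair with gaps and ambiguities sprinkled in.
random_pair <- function(L = 200, p_sub = 0.1, p_messy = 0.05) {
  a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  b <- a
  flip <- runif(L) < p_sub
  b[flip] <- vapply(b[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  mess <- c("N", "-", "R", "Y", "W")
  ia <- runif(L) < p_messy
  ib <- runif(L) < p_messy
  a[ia] <- sample(mess, sum(ia), replace = TRUE)
  b[ib] <- sample(mess, sum(ib), replace = TRUE)
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# Minimal library builder for toy examples.
toy_library <- function(species, residues, genus = NULL, family = NULL,
                        ids = NULL) {
  n <- length(residues)
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  genus <- genus %||% ifelse(is.na(species), "Genus01",
                             sub(" .*", "", species))
  family <- family %||% rep("Famidae01", n)
  specimens <- tibble::tibble(
    specimen_id = sprintf("v%02d", seq_len(n)),
    species_label = species, genus = genus, family = family,
    site_id = "site01", method = "net", sequence_id = ids
  )
  sequences <- tibble::tibble(
    sequence_id = ids, residues = residues,
    ungapped_length = nchar(gsub("-", "", residues, fixed = TRUE))
  )
  assemble_library(specimens, sequences)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hand-crafted k2p_dist with prescribed distances (for toy gap/cluster
# examples where the d values themselves are the fixture).
manual_k2p <- function(ids, d_pairs) {
  # d_pairs: tibble id_a, id_b, d
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  pairs <- tibble::tibble(id_a = character(), id_b = character(),
                          overlap = integer(), P = numeric(),
                          Q = numeric(), d = numeric(), status = character())
  for (r in seq_len(nrow(d_pairs))) {
    i <- d_pairs$id_a[r]; j <- d_pairs$id_b[r]
    m[i, j] <- m[j, i] <- d_pairs$d[r]
    pairs <- rbind(pairs, tibble::tibble(
      id_a = min(i, j), id_b = max(i, j), overlap = 658L,
      P = NA_real_, Q = NA_real_, d = d_pairs$d[r],
      status = if (is.na(d_pairs$d[r])) "saturated" else "ok"))
  }
  structure(list(ids = ids, d = m,
                 overlap = matrix(658L, n, n, dimnames = list(ids, ids)),
                 pairs = pairs, min_overlap = 100),
            class = "k2p_dist")
}
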