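base_lut <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L  # odd  = purine
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("C")] <- 2L  # even = pyrimidine
  lut[utf8ToInt("T")] <- 4L
  lut
})

encode_bases <- function(residues) {
  # gaps and ambiguity codes -> NA; excluded site-wise (pairwise deletion)
  base_lut[as.integer(charToRaw(residues))]
}

k2p_core <- function(ea, eb, min_overlap) {
  valid <- !is.na(ea) & !is.na(eb)
  overlap <- sum(valid)
  if (overlap < min_overlap) {
    return(list(overlap = overlap, P = NA_real_, Q = NA_real_,
                d = NA_real_, status = "low_overlap"))
  }
  a <- ea[valid]
  b <- eb[valid]
  ndiff <- sum(a != b)
  nts <- sum(a != b & (a %% 2L) == (b %% 2L))  # purine<->purine, pyr<->pyr
  P <- nts / overlap
  Q <- (ndiff - nts) / overlap
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(overlap = overlap, P = P, Q = Q, d = NA_real_,
                status = "saturated"))
  }
  list(overlap = overlap, P = P, Q = Q,
       d = -0.5 * log(w1) - 0.25 * log(w2), status = "ok")
}

#' Kimura 2-parameter distance between two sequences
#'
#' Computes the K2P distance `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`,
#' where `P` and `Q` are the proportions of transition and transversion
#' differences over the compared sites. Sites where either sequence carries
#' a gap or an IUPAC ambiguity code are excluded (pairwise deletion).
#' Pairs whose argument of either logarithm is non-positive are reported
#' as `saturated`; pairs with fewer than `min_overlap` comparable sites as
#' `low_overlap`. Both carry `d = NA` and are excluded from summaries.
#'
#' @param a,b Residue strings of equal length (aligned coordinates).
#' @param min_overlap Minimum number of comparable sites (default 100).
#' @param id_a,id_b Optional ids carried into the result.
#' @return A one-row tibble: `id_a`, `id_b`, `overlap`, `P`, `Q`, `d`,
#'   `status` (one of `ok`, `saturated`, `low_overlap`).
#' @examples
#' k2p_pair(strrep("ACGT", 25), strrep("ACGT", 25))
#' @export
k2p_pair <- function(a, b, min_overlap = 100,
                     id_a = NA_character_, id_b = NA_character_) {
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths; align the library first",
         call. = FALSE)
  }
  res <- k2p_core(encode_bases(a), encode_bases(b), min_overlap)
  tibble::tibble(id_a = id_a, id_b = id_b, overlap = res$overlap,
                 P = res$P, Q = res$Q, d = res$d, status = res$status)
}

#' All pairwise K2P distances for a library
#'
#' Computes every unordered pair over the library's sequences under
#' pairwise deletion. The library must be aligned (equal residue-string
#' lengths); alignment itself is out of scope and an unaligned input is an
#' error, not an implicit alignment.
#'
#' @param lib A `barcode_library`.
#' @param min_overlap Minimum comparable sites per pair (default 100).
#' @return An object of class `k2p_dist`: a list with `ids`, symmetric
#'   matrices `d` (distance; `NA` marks saturated/low-overlap pairs,
#'   diagonal exactly 0) and `overlap`, and a long tibble `pairs`
#'   (columns as in [k2p_pair()]).
#' @export
k2p_distances <- function(lib, min_overlap = 100) {
  stopifnot(inherits(lib, "barcode_library"))
  if (!lib$alignment_flag) {
    stop("library is not aligned (unequal sequence lengths); align first",
         call. = FALSE)
  }
  ids <- lib$sequences$sequence_id
  n <- length(ids)
  enc <- lapply(lib$sequences$residues, encode_bases)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ov <- matrix(0L, n, n, dimnames = list(ids, ids))
  npair <- as.integer(n * (n - 1L) / 2)
  pa <- pb <- character(npair)
  pov <- integer(npair)
  pP <- pQ <- pd <- numeric(npair)
  pstat <- character(npair)
  k <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      res <- k2p_core(enc[[i]], enc[[j]], min_overlap)
      k <- k + 1L
      pa[k] <- ids[i]; pb[k] <- ids[j]
      pov[k] <- res$overlap
      pP[k] <- res$P; pQ[k] <- res$Q; pd[k] <- res$d
      pstat[k] <- res$status
      d[i, j] <- d[j, i] <- res$d
      ov[i, j] <- ov[j, i] <- res$overlap
    }
  }
  diag(d) <- 0
  structure(
    list(ids = ids, d = d, overlap = ov,
         pairs = tibble::tibble(id_a = pa, id_b = pb, overlap = pov,
                                P = pP, Q = pQ, d = pd, status = pstat),
         min_overlap = min_overlap),
    class = "k2p_dist"
  )
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("<k2p_dist> ", length(x$ids), " sequences, ",
      nrow(x$pairs), " pairs (",
      sum(x$pairs$status != "ok"), " invalid)\n", sep = "")
  invisible(x)
}

#' @export
tidy.k2p_dist <- function(x, ...) x$pairs

#' @export
glance.k2p_dist <- function(x, ...) {
  tibble::tibble(
    n_sequences = length(x$ids),
    n_pairs = nrow(x$pairs),
    n_saturated = sum(x$pairs$status == "saturated"),
    n_low_overlap = sum(x$pairs$status == "low_overlap"),
    mean_d = mean(x$pairs$d[x$pairs$status == "ok"]),
    max_d = max(c(x$pairs$d[x$pairs$status == "ok"], -Inf))
  )
}

pairs_with_taxa <- function(dm, lib) {
  lab <- lib$specimens[!duplicated(lib$specimens$sequence_id),
                       c("sequence_id", "species_label", "genus", "family")]
  dm$pairs |>
    dplyr::inner_join(lab, by = c(id_a = "sequence_id")) |>
    dplyr::inner_join(lab, by = c(id_b = "sequence_id"),
                      suffix = c("_a", "_b"))
}

#' Rank-stratified divergence summary
#'
#' Summarises valid pairwise K2P distances at three mutually exclusive
#' levels: `within_species` (conspecific pairs), `within_genus`
#' (congeneric pairs of different species) and `within_family`
#' (confamilial pairs of different genera). Records without a species
#' label are excluded. Distances are reported in percent; `se` is the
#' standard error of the mean over comparisons.
#'
#' @param dm A `k2p_dist`.
#' @param lib The `barcode_library` the distances were computed from.
#' @return A tibble with columns `level`, `n_seqs`, `n_taxa`,
#'   `n_comparisons`, `min_pct`, `mean_pct`, `max_pct`, `se_pct`.
#' @export
summarize_divergence <- function(dm, lib) {
  stopifnot(inherits(dm, "k2p_dist"), inherits(lib, "barcode_library"))
  px <- pairs_with_taxa(dm, lib) |>
    dplyr::filter(.data$status == "ok",
                  !is.na(.data$species_label_a), !is.na(.data$species_label_b))
  level_of <- with(px, dplyr::case_when(
    species_label_a == species_label_b ~ "within_species",
    genus_a == genus_b ~ "within_genus",
    family_a == family_b ~ "within_family",
    TRUE ~ NA_character_
  ))
  taxon_of <- list(within_species = c("species_label_a", "species_label_b"),
                   within_genus = c("genus_a", "genus_b"),
                   within_family = c("family_a", "family_b"))
  purrr::map_dfr(names(taxon_of), function(lv) {
    sub <- px[!is.na(level_of) & level_of == lv, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(level = lv, n_seqs = 0L, n_taxa = 0L,
                            n_comparisons = 0L, min_pct = NA_real_,
                            mean_pct = NA_real_, max_pct = NA_real_,
                            se_pct = NA_real_))
    }
    dpct <- 100 * sub$d
    tibble::tibble(
      level = lv,
      n_seqs = dplyr::n_distinct(c(sub$id_a, sub$id_b)),
      n_taxa = dplyr::n_distinct(c(sub[[taxon_of[[lv]][1]]],
                                   sub[[taxon_of[[lv]][2]]])),
      n_comparisons = nrow(sub),
      min_pct = min(dpct),
      mean_pct = mean(dpct),
      max_pct = max(dpct),
      se_pct = if (nrow(sub) > 1) sd(dpct) / sqrt(nrow(sub)) else NA_real_
    )
  })
}

#' Pearson product-moment correlation with a t-test
#'
#' Thin wrapper over [stats::cor.test()] returning a tidy one-row tibble,
#' used for the audit's sampling-effort checks (e.g. number of specimens
#' per species against maximum intraspecific divergence).
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-degenerate.
#' @return A tibble with `r`, `p_value`, `n` and `df`.
#' @examples
#' pearson_corr(c(1, 2, 3), c(2, 1, 3))
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), df = unname(ct$parameter))
}

#' Write a K2P distance matrix to disk
#'
#' Writes both the square tab-separated matrix and a long-format pair
#' table (`id_a`, `id_b`, `overlap`, `P`, `Q`, `d`, `status`).
#'
#' @param dm A `k2p_dist`.
#' @param matrix_path,pairs_path Output paths (TSV); `NULL` skips one.
#' @return Invisibly, the paths written.
#' @export
write_k2p <- function(dm, matrix_path = NULL, pairs_path = NULL) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (!is.null(matrix_path)) {
    out <- data.frame(sequence_id = dm$ids, dm$d, check.names = FALSE)
    write.table(out, matrix_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(pairs_path)) {
    write.table(as.data.frame(dm$pairs), pairs_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(c(matrix_path, pairs_path))
}
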