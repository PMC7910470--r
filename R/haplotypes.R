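#' Collapse a set of aligned sequences into haplotypes
#'
#' Within one species, alignment columns containing a gap or an IUPAC
#' ambiguity code in any member are removed, and sequences identical over
#' the remaining columns are counted as one haplotype (the usual
#' complete-site convention of population-genetic software). Haplotypes
#' are species-scoped: identical sequences in different species are
#' distinct haplotypes.
#'
#' @param residues Character vector of aligned residue strings (>= 1).
#' @return A list: `h` (number of haplotypes), `freqs` (relative
#'   frequencies, decreasing, summing to 1), `membership` (haplotype index
#'   per input sequence), `n_used`, `n_sites` (columns retained).
#' @examples
#' collapse_haplotypes(c("ACGT", "ACGT", "ACGA"))
#' @export
collapse_haplotypes <- function(residues) {
  stopifnot(length(residues) >= 1)
  if (length(unique(nchar(residues))) != 1) {
    stop("sequences have unequal lengths; align the library first",
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(residues), "", fixed = TRUE))
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep)) {
    stop("no comparable sites: every column has a gap or ambiguity",
         call. = FALSE)
  }
  key <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  counts <- sort(table(key), decreasing = TRUE)
  list(
    h = length(counts),
    freqs = as.numeric(counts) / length(residues),
    membership = match(key, names(counts)),
    n_used = length(residues),
    n_sites = sum(keep)
  )
}

#' Nei's haplotype diversity
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))`: the probability that two sequences
#' drawn at random differ, with the small-sample correction `n/(n-1)`.
#' Equals 0 when all sequences are identical and exactly 1 when all are
#' distinct.
#'
#' @param freqs Haplotype relative frequencies (sum to 1).
#' @param n Number of sequences the frequencies were estimated from.
#' @return `Hd` in `[0, 1]`, or `NA` when `n < 2`.
#' @examples
#' haplotype_diversity(c(0.75, 0.25), 4)  # 0.5
#' @export
haplotype_diversity <- function(freqs, n) {
  if (n < 2) return(NA_real_)
  if (abs(sum(freqs) - 1) > 1e-8) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  counts <- freqs * n
  if (all(abs(counts - round(counts)) < 1e-9)) {
    # integer-count form: exact 0 and 1 at the boundary cases
    counts <- round(counts)
    (n^2 - sum(counts^2)) / (n * (n - 1))
  } else {
    (n / (n - 1)) * (1 - sum(freqs^2))
  }
}

#' Per-species haplotype summary
#'
#' Collapses haplotypes within every named species and computes Nei's
#' haplotype diversity. `hd_reported` marks the subset of species with
#' more than `min_n_for_hd` sequences, for which diversity estimates are
#' conventionally displayed. Attributes `total_haplotypes` (sum of the
#' per-species counts) and `total_haplotypes_global` (distinct residue
#' strings over all named-species sequences, i.e. a cross-species string
#' collapse) carry the library-level totals; these differ only if
#' identical sequences occur in more than one species.
#'
#' @param lib A `barcode_library`.
#' @param min_n_for_hd Display threshold for `Hd` (default 10, strict).
#' @return A tibble: `species`, `n_used`, `n_haplotypes`, `hd`,
#'   `hd_reported`.
#' @export
haplotype_table <- function(lib, min_n_for_hd = 10) {
  stopifnot(inherits(lib, "barcode_library"))
  tab <- library_table(lib) |> dplyr::filter(!is.na(.data$species_label))
  out <- tab |>
    dplyr::group_by(species = .data$species_label) |>
    dplyr::group_modify(function(df, key) {
      hp <- collapse_haplotypes(df$residues)
      tibble::tibble(
        n_used = hp$n_used,
        n_haplotypes = hp$h,
        hd = haplotype_diversity(hp$freqs, hp$n_used)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(hd_reported = .data$n_used > min_n_for_hd)
  attr(out, "total_haplotypes") <- sum(out$n_haplotypes)
  attr(out, "total_haplotypes_global") <-
    dplyr::n_distinct(tab$residues)
  out
}
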