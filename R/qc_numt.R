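#' @keywords internal
mito_stop_codons <- function() {
  code <- Biostrings::getGeneticCode("5")  # invertebrate mitochondrial
  names(code)[code == "*"]                 # TAA, TAG (TGA encodes Trp)
}

count_internal_stops <- function(bases, frame, stops) {
  # bases: character vector of single upper-case residues, gap-free
  n <- length(bases)
  start <- frame + 1L
  n_codons <- (n - frame) %/% 3L
  if (n_codons < 1L) return(0L)
  idx <- start + 3L * (seq_len(n_codons) - 1L)
  codons <- paste0(bases[idx], bases[idx + 1L], bases[idx + 2L])
  # terminal codon of the frame is excluded: a trailing stop is legitimate
  codons <- codons[-length(codons)]
  resolved <- !grepl("[^ACGT]", codons)  # codons with ambiguity are skipped
  sum(codons[resolved] %in% stops)
}

#' Reading-frame detection and stop-codon screen for one sequence
#'
#' Translates the gap-stripped sequence in the three forward frames under
#' the invertebrate mitochondrial genetic code (translation table 5, where
#' TGA encodes tryptophan and only TAA/TAG are stops) and reports the frame
#' with the fewest internal stop codons. Sequences are assumed to be
#' delivered in barcode (5'->3' coding) orientation; no reverse complement
#' is attempted unless `try_revcomp = TRUE`. Codons containing ambiguity
#' codes are skipped and the terminal codon of each frame is not counted.
#' An internal gap run whose length is not a multiple of three (in aligned
#' input) is flagged as a putative frameshift indel; terminal gap runs are
#' treated as missing data, not indels.
#'
#' @param residues A single residue string (may contain `-` gaps).
#' @param sequence_id Optional id carried into the report.
#' @param try_revcomp If `TRUE`, also screen the reverse complement and
#'   keep the orientation with fewer stops (rescue mode).
#' @return A one-row tibble: `sequence_id`, `best_frame` (0, 1 or 2),
#'   `stop_count_best`, `numt_suspect` (`stop_count_best > 0`),
#'   `indel_suspect`, and `flagged` (`numt_suspect | indel_suspect`).
#' @examples
#' detect_frame(strrep("ATT", 30))
#' @export
detect_frame <- function(residues, sequence_id = NA_character_,
                         try_revcomp = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  stripped <- gsub("-", "", residues, fixed = TRUE)
  if (nchar(stripped) < 30) {
    stop("too short for frame detection (< 30 nt)", call. = FALSE)
  }
  stops <- mito_stop_codons()
  bases <- strsplit(stripped, "", fixed = TRUE)[[1]]
  counts <- vapply(0:2, function(f) count_internal_stops(bases, f, stops),
                   integer(1))
  if (isTRUE(try_revcomp)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(stripped)))
    rc_bases <- strsplit(rc, "", fixed = TRUE)[[1]]
    rc_counts <- vapply(0:2, function(f)
      count_internal_stops(rc_bases, f, stops), integer(1))
    if (min(rc_counts) < min(counts)) counts <- rc_counts
  }
  best <- which.min(counts) - 1L  # ties -> lowest frame index
  tibble::tibble(
    sequence_id = sequence_id,
    best_frame = best,
    stop_count_best = counts[best + 1L],
    numt_suspect = counts[best + 1L] > 0L,
    indel_suspect = has_frameshift_gap(residues),
    flagged = numt_suspect | indel_suspect
  )
}

has_frameshift_gap <- function(residues) {
  runs <- rle(strsplit(residues, "", fixed = TRUE)[[1]] == "-")
  if (!any(runs$values)) return(FALSE)
  gap_idx <- which(runs$values)
  # leading/trailing runs are incomplete-read padding, not indels
  internal <- gap_idx[gap_idx > 1L & gap_idx < length(runs$values)]
  any(runs$lengths[internal] %% 3L != 0L)
}

#' Screen a whole library for putative numts
#'
#' Runs [detect_frame()] on every sequence of the library. Suspects are
#' flagged, never removed: downstream stages decide what to do with them.
#'
#' @param lib A `barcode_library`.
#' @inheritParams detect_frame
#' @return A tibble with one row per sequence (columns as in
#'   [detect_frame()]).
#' @export
screen_numts <- function(lib, try_revcomp = FALSE) {
  stopifnot(inherits(lib, "barcode_library"))
  if (nrow(lib$sequences) == 0) {
    return(detect_frame(strrep("A", 30))[0, ])
  }
  purrr::map2_dfr(lib$sequences$residues, lib$sequences$sequence_id,
                  detect_frame, try_revcomp = try_revcomp)
}
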