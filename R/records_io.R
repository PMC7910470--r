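IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Read barcode sequences from a FASTA file
#'
#' Parses a (possibly aligned) FASTA file of nucleotide barcodes. The token
#' before the first whitespace in each header is the sequence id. Residues
#' are upper-cased; IUPAC ambiguity codes and the gap character `-` are
#' retained (ambiguous sites are excluded pair- or column-wise downstream,
#' never stripped at read time).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `sequence_id`, `residues` and
#'   `ungapped_length` (number of non-gap characters, in bp).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "AC-GT"), fa)
#' read_barcode_fasta(fa)
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence_id in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  residues <- toupper(as.character(set))
  validate_residues(residues, ids)
  tibble::tibble(
    sequence_id = ids,
    residues = unname(residues),
    ungapped_length = ungapped_length(residues)
  )
}

validate_residues <- function(residues, ids) {
  ok <- paste(IUPAC_CHARS, collapse = "")
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    if (nchar(r) == 0) {
      stop("empty sequence for id '", ids[[i]], "'", call. = FALSE)
    }
    bad <- regexpr(sprintf("[^%s]", ok), r)
    if (bad > 0) {
      stop(sprintf("non-IUPAC character '%s' in sequence '%s' at position %d",
                   substr(r, bad, bad), ids[[i]], bad), call. = FALSE)
    }
  }
  invisible(TRUE)
}

ungapped_length <- function(residues) {
  nchar(residues) - stringr::str_count(residues, stringr::fixed("-"))
}

#' Write barcode sequences to a FASTA file
#'
#' @param sequences A tibble as returned by [read_barcode_fasta()] (only
#'   `sequence_id` and `residues` are used).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(setNames(sequences$residues,
                                         sequences$sequence_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Reads a tab-separated, UTF-8 specimen table. Lines starting with `#` are
#' ignored. Mandatory columns: `specimen_id`, `species`, `genus`, `family`,
#' `sequence_id`; optional: `site_id`, `method`. An empty `species` field
#' denotes an unnamed taxon (stored as `NA`); such records take part in
#' clustering and tree building but are excluded from per-species
#' statistics. Collection methods other than `pan_trap` or `net` are mapped
#' to `other`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of specimen records with columns `specimen_id`,
#'   `species_label`, `genus`, `family`, `site_id`, `method`, `sequence_id`.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path)) {
    stop("specimen table not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  required <- c("specimen_id", "species", "genus", "family", "sequence_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("specimen table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup) > 0) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    specimen_id = df$specimen_id,
    species_label = dplyr::na_if(trimws(df$species), ""),
    genus = df$genus,
    family = df$family,
    site_id = if ("site_id" %in% names(df)) df$site_id else NA_character_,
    method = normalize_method(if ("method" %in% names(df)) df$method
                              else rep("other", nrow(df))),
    sequence_id = df$sequence_id
  )
}

normalize_method <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("pan_trap", "net"), x, "other")
}

#' Write a specimen metadata table
#'
#' @param records A specimen tibble as returned by [read_specimen_table()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(records, path) {
  out <- data.frame(
    specimen_id = records$specimen_id,
    species = ifelse(is.na(records$species_label), "", records$species_label),
    genus = records$genus,
    family = records$family,
    site_id = records$site_id,
    method = records$method,
    sequence_id = records$sequence_id,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Join specimen records and sequences into a validated barcode library
#'
#' Records whose `sequence_id` does not resolve to a sequence are dropped
#' with a warning (the count is kept in the returned object). The
#' `alignment_flag` is set when all residue strings have identical length,
#' i.e. the library can be treated as a multiple alignment.
#'
#' @param records Specimen tibble ([read_specimen_table()]).
#' @param sequences Sequence tibble ([read_barcode_fasta()]).
#' @return An object of class `barcode_library`: a list with elements
#'   `specimens`, `sequences` (tibbles), `alignment_flag` and `n_dropped`.
#' @examples
#' seqs <- tibble::tibble(sequence_id = c("s1", "s2"),
#'                        residues = c("ACGT", "ACGA"),
#'                        ungapped_length = c(4L, 4L))
#' recs <- tibble::tibble(specimen_id = c("v1", "v2"),
#'                        species_label = "Apis mellifera",
#'                        genus = "Apis", family = "Apidae",
#'                        site_id = "site1", method = "net",
#'                        sequence_id = c("s1", "s2"))
#' assemble_library(recs, seqs)
#' @export
assemble_library <- function(records, sequences) {
  dup <- records$specimen_id[duplicated(records$specimen_id)]
  if (length(dup) > 0) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  named <- !is.na(records$species_label)
  bad <- named & (is.na(records$genus) | records$genus == "" |
                  is.na(records$family) | records$family == "")
  if (any(bad)) {
    stop("named species with empty genus/family: ",
         paste(records$specimen_id[bad], collapse = ", "), call. = FALSE)
  }
  keep <- records$sequence_id %in% sequences$sequence_id
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    stop("no sequenced specimens: no specimen sequence_id matches the FASTA",
         call. = FALSE)
  }
  if (n_dropped > 0) {
    warning(n_dropped, " specimen record(s) dropped: sequence_id not in FASTA",
            call. = FALSE)
  }
  records <- records[keep, , drop = FALSE]
  sequences <- sequences[sequences$sequence_id %in% records$sequence_id, ,
                         drop = FALSE]
  structure(
    list(
      specimens = records,
      sequences = sequences,
      alignment_flag = length(unique(nchar(sequences$residues))) == 1L,
      n_dropped = n_dropped
    ),
    class = "barcode_library"
  )
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("<barcode_library>\n")
  cat("  specimens: ", nrow(x$specimens),
      " (", sum(is.na(x$specimens$species_label)), " unnamed)\n", sep = "")
  cat("  sequences: ", nrow(x$sequences), "\n", sep = "")
  cat("  aligned:   ", x$alignment_flag, "\n", sep = "")
  if (x$n_dropped > 0) cat("  dropped:   ", x$n_dropped, "\n", sep = "")
  invisible(x)
}

#' Assign record-level length tiers
#'
#' Barcode records are tiered by ungapped length: `full` (eligible for
#' cluster assignment, by default >= 500 bp, the conventional minimum for
#' cluster/BIN eligibility), `partial` (>= 300 bp but shorter than
#' `full_min`; used in distance and haplotype computations but not
#' clustered), and `reject`. Thresholds are inclusive at the lower bound of
#' each tier.
#'
#' @param ungapped Integer vector of ungapped lengths (bp).
#' @param full_min Minimum bp for the `full` tier (default 500).
#' @param partial_min Minimum bp for the `partial` tier (default 300).
#' @return A character vector over `c("full", "partial", "reject")`.
#' @examples
#' length_tier(c(658, 400, 120))
#' @export
length_tier <- function(ungapped, full_min = 500, partial_min = 300) {
  dplyr::case_when(
    ungapped >= full_min ~ "full",
    ungapped >= partial_min ~ "partial",
    TRUE ~ "reject"
  )
}

#' Joined per-record view of a barcode library
#'
#' @param lib A `barcode_library`.
#' @param full_min,partial_min Length-tier thresholds, see [length_tier()].
#' @return A tibble with one row per sequenced specimen, joining metadata,
#'   residues and the length tier.
#' @export
library_table <- function(lib, full_min = 500, partial_min = 300) {
  stopifnot(inherits(lib, "barcode_library"))
  dplyr::inner_join(lib$specimens, lib$sequences, by = "sequence_id") |>
    dplyr::mutate(tier = length_tier(.data$ungapped_length,
                                     full_min, partial_min))
}

#' @export
glance.barcode_library <- function(x, ...) {
  tab <- library_table(x)
  tibble::tibble(
    n_specimens = nrow(tab),
    n_species = dplyr::n_distinct(tab$species_label[!is.na(tab$species_label)]),
    n_genera = dplyr::n_distinct(tab$genus),
    n_families = dplyr::n_distinct(tab$family),
    n_full = sum(tab$tier == "full"),
    n_partial = sum(tab$tier == "partial"),
    n_reject = sum(tab$tier == "reject"),
    aligned = x$alignment_flag
  )
}
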