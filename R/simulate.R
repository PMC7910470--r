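TS_PARTNER <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T (1=A, 2=C, 3=G, 4=T)

is_stop_codon <- function(c1, c2, c3) {
  # TAA / TAG under the invertebrate mitochondrial code
  c1 == 4L && c2 == 1L && (c3 == 1L || c3 == 3L)
}

random_root <- function(L) {
  s <- sample.int(4L, L, replace = TRUE)
  n_codons <- L %/% 3L
  for (cd in seq_len(n_codons)) {
    p <- 3L * (cd - 1L) + 1L
    if (is_stop_codon(s[p], s[p + 1L], s[p + 2L])) {
      s[p + 2L] <- sample(c(2L, 4L), 1L)  # TAC / TAT, never a stop
    }
  }
  s
}

evolve_int <- function(s, t, kappa, avoid_stops = TRUE) {
  L <- length(s)
  n_events <- stats::rpois(L, t)
  p_ts <- kappa / (kappa + 2)
  for (site in which(n_events > 0L)) {
    cd <- (site - 1L) %/% 3L       # frame-0 codon of this site
    p0 <- 3L * cd + 1L
    in_codon <- p0 + 2L <= L
    for (ev in seq_len(n_events[site])) {
      cur <- s[site]
      tvs <- setdiff(1:4, c(cur, TS_PARTNER[cur]))
      targets <- c(TS_PARTNER[cur], tvs)
      probs <- c(p_ts, (1 - p_ts) / 2, (1 - p_ts) / 2)
      if (avoid_stops && in_codon) {
        codon <- s[p0:(p0 + 2L)]
        pos <- site - p0 + 1L
        makes_stop <- vapply(targets, function(b) {
          codon[pos] <- b
          is_stop_codon(codon[1], codon[2], codon[3])
        }, logical(1))
        # redirect, never revert: >= 1 non-stop target always exists,
        # so the substitution count (hence realized divergence) is kept
        targets <- targets[!makes_stop]
        probs <- probs[!makes_stop] / sum(probs[!makes_stop])
      }
      s[site] <- if (length(targets) == 1L) targets else
        sample(targets, 1L, prob = probs)
    }
  }
  s
}

int_to_residues <- function(s) {
  paste(c("A", "C", "G", "T", "-")[s], collapse = "")
}

residues_to_int <- function(residues) {
  m <- match(strsplit(toupper(residues), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T", "-"))
  if (anyNA(m)) stop("only A/C/G/T/- supported here", call. = FALSE)
  m
}

#' Evolve a sequence under a K2P substitution process
#'
#' Applies a Poisson number of substitution events per site (expectation
#' `t` events/site, so `t` is the branch length in expected substitutions
#' per site, with multiple hits possible). Each event is a transition with
#' probability `kappa/(kappa + 2)` and each of the two transversions with
#' probability `1/(kappa + 2)`. With `avoid_stops = TRUE` (the default
#' used by the library generator) an event whose target codon would be a
#' frame-0 TAA/TAG stop is redirected to a non-stop target base —
#' emulating purifying selection on the COI reading frame while leaving
#' the number of realized substitutions, and hence the expected distance,
#' unchanged.
#'
#' @param residues A residue string over A/C/G/T.
#' @param t Branch length in expected substitutions per site.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param avoid_stops Keep the frame-0 reading frame stop-free.
#' @return The evolved residue string.
#' @export
evolve_sequence <- function(residues, t, kappa = 3, avoid_stops = TRUE) {
  stopifnot(t >= 0, kappa > 0)
  int_to_residues(evolve_int(residues_to_int(residues), t, kappa,
                             avoid_stops))
}

#' Configuration for the synthetic barcode-library generator
#'
#' Defaults emulate a desk-scale multi-family wild-bee COI library:
#' mean conspecific K2P divergence near 0.2%, congeneric divergence in the
#' 9-16% range, a few planted deep conspecific splits, one planted
#' near-zero interspecific ("merge") pair, a small partial-length tier
#' and a small fraction of single-base frameshift numts.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param L Alignment length in bp (default 658, the standard COI
#'   barcode).
#' @param n_families,genera_per_family,species_per_genus Taxonomy shape.
#' @param ind_mean Mean of the geometric law (minimum 1) for individuals
#'   per species; a fixed count when `ind_law = "fixed"`.
#' @param ind_law `"geometric"` or `"fixed"`.
#' @param kappa Transition/transversion rate ratio (default 3).
#' @param div_family,div_genus,div_species Expected substitutions/site on
#'   the family, genus and species ancestral branches.
#' @param theta_intra Expected pairwise conspecific divergence; each
#'   individual sits `theta_intra/2` from its species ancestor (star
#'   genealogy).
#' @param deep_split Data frame `species` (global species index),
#'   `delta` (divergence between the two planted conspecific lineages);
#'   `"auto"` plants 3 splits at 0.08; use `NULL` for none.
#' @param merge_pairs Data frame `species_a`, `species_b` (global
#'   indices, must be congeneric), `eps` (planted interspecific
#'   divergence); `"auto"` plants one pair at 0.002; `NULL` for none.
#' @param partial_fraction Fraction of records truncated (from the 3'
#'   end) into the 300-500 bp tier.
#' @param numt_fraction Fraction of records given a single-base
#'   frameshift deletion (a planted numt-like artefact).
#' @param n_unnamed Number of extra unnamed (empty species label)
#'   specimens drawn from a random genus ancestor.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, L = 658L, n_families = 3L,
                       genera_per_family = 3L, species_per_genus = 4L,
                       ind_mean = 8, ind_law = c("geometric", "fixed"),
                       kappa = 3, div_family = 0.05, div_genus = 0.04,
                       div_species = 0.06, theta_intra = 0.002,
                       deep_split = "auto", merge_pairs = "auto",
                       partial_fraction = 0.011, numt_fraction = 0.02,
                       n_unnamed = 1L) {
  ind_law <- match.arg(ind_law)
  S <- n_families * genera_per_family * species_per_genus
  if (identical(deep_split, "auto")) {
    deep_split <- if (S >= 8) {
      data.frame(species = unique(pmin(S, round(S * c(0.15, 0.5, 0.85)))),
                 delta = 0.08)
    } else NULL
  }
  if (identical(merge_pairs, "auto")) {
    merge_pairs <- if (species_per_genus >= 2) {
      data.frame(species_a = S - 1L, species_b = S, eps = 0.002)
    } else NULL
  }
  stopifnot(L >= 300, kappa > 0, theta_intra >= 0,
            div_family >= 0, div_genus >= 0, div_species >= 0,
            partial_fraction >= 0, partial_fraction <= 1,
            numt_fraction >= 0, numt_fraction <= 1)
  cfg <- list(seed = as.integer(seed), L = as.integer(L),
              n_families = n_families, genera_per_family = genera_per_family,
              species_per_genus = species_per_genus, ind_mean = ind_mean,
              ind_law = ind_law, kappa = kappa, div_family = div_family,
              div_genus = div_genus, div_species = div_species,
              theta_intra = theta_intra, deep_split = deep_split,
              merge_pairs = merge_pairs, partial_fraction = partial_fraction,
              numt_fraction = numt_fraction, n_unnamed = as.integer(n_unnamed))
  class(cfg) <- "sim_config"
  cfg
}

species_index_table <- function(cfg) {
  S <- cfg$n_families * cfg$genera_per_family * cfg$species_per_genus
  idx <- seq_len(S)
  fam <- (idx - 1L) %/% (cfg$genera_per_family * cfg$species_per_genus) + 1L
  gen <- (idx - 1L) %/% cfg$species_per_genus + 1L
  tibble::tibble(
    species_idx = idx,
    family = sprintf("Famidae%02d", fam),
    genus = sprintf("Genus%02d", gen),
    species = sprintf("Genus%02d species%03d", gen, idx)
  )
}

#' Simulate a barcode library with known truth
#'
#' Generates an aligned COI-like library down a family -> genus ->
#' species hierarchy under the K2P substitution process of
#' [evolve_sequence()], with a star genealogy within species, planted
#' deep conspecific splits, planted near-zero interspecific pairs,
#' 3'-truncated partial-tier records and single-base frameshift numts.
#' The first individual of every species (and of every planted lineage)
#' is never truncated, so each species keeps at least one cluster-eligible
#' record.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_library`: `library` (a
#'   `barcode_library`), and `truth` with `records` (per-specimen truth:
#'   true species, lineage, planted numt/partial flags) and `species`
#'   (expected concordance category per named species) plus the `config`.
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sp_tab <- species_index_table(cfg)
  S <- nrow(sp_tab)
  if (!is.null(cfg$deep_split) && nrow(cfg$deep_split) > 0 &&
      any(cfg$deep_split$species > S)) {
    stop("deep_split species index out of range", call. = FALSE)
  }
  if (!is.null(cfg$merge_pairs) && nrow(cfg$merge_pairs) > 0) {
    ga <- sp_tab$genus[cfg$merge_pairs$species_a]
    gb <- sp_tab$genus[cfg$merge_pairs$species_b]
    if (any(ga != gb)) {
      stop("merge pair across genera: planted merges must be congeneric",
           call. = FALSE)
    }
  }
  root <- random_root(cfg$L)
  # ancestors down the hierarchy
  fam_anc <- lapply(seq_len(cfg$n_families), function(f)
    evolve_int(root, cfg$div_family, cfg$kappa))
  n_gen <- cfg$n_families * cfg$genera_per_family
  gen_anc <- lapply(seq_len(n_gen), function(g)
    evolve_int(fam_anc[[(g - 1L) %/% cfg$genera_per_family + 1L]],
               cfg$div_genus, cfg$kappa))
  sp_anc <- vector("list", S)
  for (i in seq_len(S)) {
    g <- (i - 1L) %/% cfg$species_per_genus + 1L
    sp_anc[[i]] <- evolve_int(gen_anc[[g]], cfg$div_species, cfg$kappa)
  }
  # planted merges: second species collapses onto the first
  merge_ids <- integer(0)
  if (!is.null(cfg$merge_pairs) && nrow(cfg$merge_pairs) > 0) {
    for (r in seq_len(nrow(cfg$merge_pairs))) {
      a <- cfg$merge_pairs$species_a[r]
      b <- cfg$merge_pairs$species_b[r]
      sp_anc[[b]] <- evolve_int(sp_anc[[a]], cfg$merge_pairs$eps[r],
                                cfg$kappa)
      merge_ids <- c(merge_ids, a, b)
    }
  }
  # planted deep splits: two lineage ancestors delta apart
  split_ids <- integer(0)
  lineage_anc <- vector("list", S)
  if (!is.null(cfg$deep_split) && nrow(cfg$deep_split) > 0) {
    for (r in seq_len(nrow(cfg$deep_split))) {
      i <- cfg$deep_split$species[r]
      dl <- cfg$deep_split$delta[r] / 2
      lineage_anc[[i]] <- list(evolve_int(sp_anc[[i]], dl, cfg$kappa),
                               evolve_int(sp_anc[[i]], dl, cfg$kappa))
      split_ids <- c(split_ids, i)
    }
  }
  # individuals
  n_ind <- switch(cfg$ind_law,
    geometric = stats::rgeom(S, prob = 1 / cfg$ind_mean) + 1L,
    fixed = rep(as.integer(cfg$ind_mean), S)
  )
  n_ind[split_ids] <- pmax(n_ind[split_ids], 4L)  # both lineages sampled
  rows <- list()
  seqs <- list()
  k <- 0L
  anchor <- logical(0)
  for (i in seq_len(S)) {
    for (j in seq_len(n_ind[i])) {
      k <- k + 1L
      lineage <- 0L
      anc <- sp_anc[[i]]
      if (!is.null(lineage_anc[[i]])) {
        lineage <- (j - 1L) %% 2L + 1L
        anc <- lineage_anc[[i]][[lineage]]
      }
      seqs[[k]] <- evolve_int(anc, cfg$theta_intra / 2, cfg$kappa)
      rows[[k]] <- tibble::tibble(
        species_idx = i, lineage = lineage,
        species = sp_tab$species[i], genus = sp_tab$genus[i],
        family = sp_tab$family[i]
      )
      # first two individuals of a species (= first of each planted
      # lineage) are anchors, kept full-length
      anchor <- c(anchor, j <= 2L)
    }
  }
  if (cfg$n_unnamed > 0) {
    for (u in seq_len(cfg$n_unnamed)) {
      k <- k + 1L
      g <- sample.int(n_gen, 1L)
      seqs[[k]] <- evolve_int(evolve_int(gen_anc[[g]], cfg$div_species,
                                         cfg$kappa),
                              cfg$theta_intra / 2, cfg$kappa)
      rows[[k]] <- tibble::tibble(
        species_idx = NA_integer_, lineage = 0L, species = NA_character_,
        genus = sprintf("Genus%02d", g),
        family = sp_tab$family[match(sprintf("Genus%02d", g),
                                     sp_tab$genus)]
      )
      anchor <- c(anchor, TRUE)
    }
  }
  n <- k
  meta <- dplyr::bind_rows(rows)
  meta$specimen_id <- sprintf("SIM%04d", seq_len(n))
  meta$sequence_id <- sprintf("SEQ%04d", seq_len(n))
  meta$site_id <- sample(sprintf("site%02d", 1:5), n, replace = TRUE)
  meta$method <- sample(c("pan_trap", "net"), n, replace = TRUE,
                        prob = c(0.87, 0.13))
  # partial-tier truncation (3' end), anchors exempt
  is_partial <- !anchor & stats::runif(n) < cfg$partial_fraction
  for (idx in which(is_partial)) {
    len <- sample(300:499, 1L)
    seqs[[idx]][(len + 1L):cfg$L] <- 5L  # '-'
  }
  # planted numts: delete exactly one base (gap in the aligned output)
  is_numt <- !is_partial & stats::runif(n) < cfg$numt_fraction
  for (idx in which(is_numt)) {
    seqs[[idx]][sample.int(cfg$L, 1L)] <- 5L
  }
  sequences <- tibble::tibble(
    sequence_id = meta$sequence_id,
    residues = vapply(seqs, int_to_residues, character(1))
  )
  sequences$ungapped_length <- ungapped_length(sequences$residues)
  specimens <- tibble::tibble(
    specimen_id = meta$specimen_id,
    species_label = meta$species,
    genus = meta$genus,
    family = meta$family,
    site_id = meta$site_id,
    method = meta$method,
    sequence_id = meta$sequence_id
  )
  lib <- assemble_library(specimens, sequences)
  expected <- sp_tab |>
    dplyr::mutate(expected_category = dplyr::case_when(
      .data$species_idx %in% split_ids ~ "SPLIT",
      .data$species_idx %in% merge_ids ~ "MERGE",
      TRUE ~ "MATCH"
    ))
  structure(
    list(
      library = lib,
      truth = list(
        records = dplyr::bind_cols(
          meta[, c("specimen_id", "sequence_id", "species", "genus",
                   "family", "lineage")],
          tibble::tibble(is_numt = is_numt, is_partial = is_partial)
        ),
        species = expected[, c("species", "genus", "family",
                               "expected_category")],
        config = cfg
      )
    ),
    class = "sim_library"
  )
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library> seed ", x$truth$config$seed, "\n", sep = "")
  print(x$library)
  cat("  planted: ",
      sum(x$truth$species$expected_category == "SPLIT"), " split, ",
      sum(x$truth$species$expected_category == "MERGE"), " merge, ",
      sum(x$truth$records$is_numt), " numt, ",
      sum(x$truth$records$is_partial), " partial\n", sep = "")
  invisible(x)
}

#' Write a library to FASTA + specimen TSV
#'
#' @param lib A `barcode_library`.
#' @param fasta_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_library <- function(lib, fasta_path, meta_path) {
  stopifnot(inherits(lib, "barcode_library"))
  write_barcode_fasta(lib$sequences, fasta_path)
  write_specimen_table(lib$specimens, meta_path)
  invisible(c(fasta_path, meta_path))
}

#' Evaluate an audit run against simulation truth
#'
#' @param audit A `barcode_audit` object ([run_audit()]) computed on a
#'   simulated library.
#' @param truth The `truth` element of a [simulate_library()] result.
#' @return A one-row tibble: fraction of species in their expected
#'   concordance category, split/merge recovery, numt screen sensitivity
#'   and specificity (against planted frameshifts).
#' @export
truth_eval <- function(audit, truth) {
  stopifnot(inherits(audit, "barcode_audit"))
  conc <- audit$concordance
  exp_sp <- truth$species
  if (!all(exp_sp$species %in% conc$species)) {
    stop("mismatched ids: truth species absent from audit output",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(exp_sp, conc, by = "species")
  qc <- dplyr::inner_join(audit$qc, truth$records, by = "sequence_id")
  planted <- qc$is_numt
  tibble::tibble(
    n_species = nrow(joined),
    category_recovery = mean(joined$expected_category == joined$category),
    split_recovery = mean(joined$category[
      joined$expected_category == "SPLIT"] == "SPLIT"),
    merge_recovery = mean(joined$category[
      joined$expected_category == "MERGE"] == "MERGE"),
    numt_sensitivity = if (any(planted)) mean(qc$flagged[planted]) else NA_real_,
    numt_sensitivity_stop_only = if (any(planted))
      mean(qc$numt_suspect[planted]) else NA_real_,
    numt_specificity = mean(!qc$flagged[!planted])
  )
}
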