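#' Run the full barcode-library audit
#'
#' Executes the whole audit on a validated library: numt/stop-codon
#' screening, pairwise K2P distances, rank-stratified divergence
#' summaries, per-species barcode-gap analysis, threshold single-linkage
#' clustering with concordance classification, haplotype diversity,
#' sampling-effort correlations and a neighbour-joining tree. When
#' `out_dir` is given, all report tables (TSV), the Newick tree, a JSON
#' summary and a log of dropped/flagged records are written; on failure
#' partial outputs are removed.
#'
#' @param lib A `barcode_library`, or a `sim_library` (its library is
#'   used).
#' @param out_dir Optional output directory.
#' @param tau Single-linkage clustering threshold (K2P fraction).
#' @param min_overlap Minimum comparable sites per pair.
#' @param full_min,partial_min Length-tier thresholds in bp.
#' @param min_n_for_plots Minimum records/species for the gap plot set.
#' @param min_n_for_hd Display threshold for haplotype diversity.
#' @param gap_threshold Deep-divergence exceedance threshold (%).
#' @param leaves Tree leaf policy, see [tree_leaves()].
#' @return An object of class `barcode_audit` (a list of the stage
#'   results; see the elements `qc`, `distances`, `rank_divergence`,
#'   `gap_table`, `gap_report`, `partition`, `concordance`,
#'   `concordance_summary`, `haplotypes`, `family_table`,
#'   `correlations`, `tree`, `params`).
#' @export
run_audit <- function(lib, out_dir = NULL, tau = 0.022, min_overlap = 100,
                      full_min = 500, partial_min = 300,
                      min_n_for_plots = 3, min_n_for_hd = 10,
                      gap_threshold = 2.0,
                      leaves = c("haplotypes", "all", "species-medoid")) {
  if (inherits(lib, "sim_library")) lib <- lib$library
  stopifnot(inherits(lib, "barcode_library"))
  leaves <- match.arg(leaves)
  params <- list(tau = tau, min_overlap = min_overlap, full_min = full_min,
                 partial_min = partial_min, min_n_for_plots = min_n_for_plots,
                 min_n_for_hd = min_n_for_hd, gap_threshold = gap_threshold,
                 leaves = leaves)
  tab <- library_table(lib, full_min, partial_min)
  qc <- screen_numts(lib)
  dm <- k2p_distances(lib, min_overlap = min_overlap)
  rank_div <- summarize_divergence(dm, lib)
  gap_tab <- species_gap_table(dm, lib, min_n_for_plots = min_n_for_plots)
  gap_rep <- gap_overlap_report(gap_tab, threshold = gap_threshold)
  eligible <- tab$sequence_id[tab$tier == "full"]
  partition <- cluster_barcodes(dm, eligible, tau = tau)
  concordance <- classify_concordance(partition, lib)
  conc_sum <- concordance_summary(concordance)
  haplos <- haplotype_table(lib, min_n_for_hd = min_n_for_hd)
  fam_tab <- family_table(lib)
  correlations <- audit_correlations(gap_tab, haplos)
  leaf_ids <- tree_leaves(lib, dm, leaves)
  tree <- if (length(leaf_ids) >= 3 &&
              !anyNA(dm$d[leaf_ids, leaf_ids])) {
    nj_tree(dm, taxa = leaf_ids)
  } else NULL
  audit <- structure(
    list(qc = qc, distances = dm, rank_divergence = rank_div,
         gap_table = gap_tab, gap_report = gap_rep, partition = partition,
         concordance = concordance, concordance_summary = conc_sum,
         haplotypes = haplos, family_table = fam_tab,
         correlations = correlations, tree = tree, params = params,
         library = lib),
    class = "barcode_audit"
  )
  if (!is.null(out_dir)) write_audit(audit, out_dir)
  audit
}

family_table <- function(lib) {
  tab <- library_table(lib)
  per_fam <- tab |>
    dplyr::group_by(family = .data$family) |>
    dplyr::summarise(
      records = dplyr::n(),
      genera = dplyr::n_distinct(.data$genus),
      species = dplyr::n_distinct(
        .data$species_label[!is.na(.data$species_label)]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family)
  dplyr::bind_rows(
    per_fam,
    tibble::tibble(
      family = "Total",
      records = sum(per_fam$records),
      genera = dplyr::n_distinct(tab$genus),
      species = dplyr::n_distinct(
        tab$species_label[!is.na(tab$species_label)])
    )
  )
}

audit_correlations <- function(gap_tab, haplos) {
  safe_corr <- function(x, y) {
    tryCatch(pearson_corr(x, y),
             error = function(e) tibble::tibble(r = NA_real_,
                                                p_value = NA_real_,
                                                n = length(x),
                                                df = NA_real_))
  }
  gm <- gap_tab |> dplyr::filter(!is.na(.data$max_intra_pct))
  hd <- haplos |> dplyr::filter(.data$hd_reported)
  dplyr::bind_rows(
    dplyr::mutate(safe_corr(gm$n, gm$max_intra_pct),
                  comparison = "n_vs_max_intra", .before = 1),
    dplyr::mutate(safe_corr(hd$n_used, hd$n_haplotypes),
                  comparison = "n_vs_n_haplotypes", .before = 1),
    dplyr::mutate(safe_corr(hd$n_used, hd$hd),
                  comparison = "n_vs_hd", .before = 1)
  )
}

#' Per-species audit table
#'
#' Joins the barcode-gap, haplotype and concordance results into the
#' audit's one-row-per-named-species report table.
#'
#' @param audit A `barcode_audit`.
#' @return A tibble.
#' @export
species_table <- function(audit) {
  stopifnot(inherits(audit, "barcode_audit"))
  conc <- audit$concordance |>
    dplyr::mutate(cluster_ids = vapply(.data$clusters, paste,
                                       character(1), collapse = ";")) |>
    dplyr::select("species", "n_eligible", "n_clusters", "cluster_ids",
                  "category")
  audit$gap_table |>
    dplyr::left_join(dplyr::select(audit$haplotypes, "species",
                                   "n_haplotypes", "hd"),
                     by = "species") |>
    dplyr::left_join(conc, by = "species")
}

#' @export
tidy.barcode_audit <- function(x, ...) species_table(x)

#' @export
glance.barcode_audit <- function(x, ...) {
  g <- glance(x$library)
  ws <- x$rank_divergence[x$rank_divergence$level == "within_species", ]
  wg <- x$rank_divergence[x$rank_divergence$level == "within_genus", ]
  cs <- x$concordance_summary
  pick <- function(cat) {
    v <- cs$n[cs$category == cat]
    if (length(v)) v else 0L
  }
  tibble::tibble(
    n_specimens = g$n_specimens, n_species = g$n_species,
    n_clusters = nrow(x$partition$sizes),
    n_match = pick("MATCH"), n_split = pick("SPLIT"),
    n_merge = pick("MERGE"), n_mixture = pick("MIXTURE"),
    n_unassessed = pick("UNASSESSED"),
    mean_within_species_pct = ws$mean_pct,
    mean_within_genus_pct = wg$mean_pct,
    total_haplotypes = attr(x$haplotypes, "total_haplotypes"),
    n_numt_suspect = sum(x$qc$flagged)
  )
}

#' @export
print.barcode_audit <- function(x, ...) {
  cat("<barcode_audit>\n")
  print(glance(x))
  invisible(x)
}

#' Headline percentages of an audit
#'
#' Concordance category shares, the share of single-record species, and
#' the mean number of specimens per cluster, each with its numerator and
#' denominator stated.
#'
#' @param audit A `barcode_audit`.
#' @return A tibble: `metric`, `numerator`, `denominator`, `value`
#'   (percent for the shares; a plain mean for specimens per cluster).
#' @export
percentage_summaries <- function(audit) {
  stopifnot(inherits(audit, "barcode_audit"))
  conc <- audit$concordance
  n_species <- nrow(conc)
  if (n_species == 0) stop("zero named species", call. = FALSE)
  n_cat <- function(cat) sum(conc$category == cat)
  singles <- sum(audit$gap_table$n == 1)
  sizes <- audit$partition$sizes
  tibble::tibble(
    metric = c("match_pct", "split_pct", "merge_pct", "mixture_pct",
               "single_record_species_pct", "specimens_per_cluster_mean"),
    numerator = c(n_cat("MATCH"), n_cat("SPLIT"), n_cat("MERGE"),
                  n_cat("MIXTURE"), singles, sum(sizes$n)),
    denominator = c(rep(n_species, 5), nrow(sizes)),
    value = c(100 * n_cat("MATCH") / n_species,
              100 * n_cat("SPLIT") / n_species,
              100 * n_cat("MERGE") / n_species,
              100 * n_cat("MIXTURE") / n_species,
              100 * singles / n_species,
              sum(sizes$n) / max(nrow(sizes), 1))
  )
}

round_pct_cols <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) &
    grepl("(_pct$|^pct$|^hd$|^value$)", names(df))
  df[num] <- lapply(df[num], round, 2)
  df
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(round_pct_cols(df))
  df[] <- lapply(df, function(x) if (is.list(x))
    vapply(x, paste, character(1), collapse = ";") else x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_audit <- function(audit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    emit <- function(df, name) {
      p <- file.path(out_dir, name)
      write_tsv_plain(df, p)
      written <<- c(written, p)
    }
    emit(audit$family_table, "family_table.tsv")
    emit(audit$rank_divergence, "rank_divergence.tsv")
    emit(species_table(audit), "species_table.tsv")
    emit(audit$concordance |> dplyr::select(-"clusters") |>
           dplyr::bind_cols(cluster_ids = vapply(audit$concordance$clusters,
                                                 paste, character(1),
                                                 collapse = ";")),
         "concordance.tsv")
    emit(audit$partition$assignment, "clusters.tsv")
    emit(audit$haplotypes, "haplotypes.tsv")
    emit(audit$qc, "qc.tsv")
    emit(audit$correlations, "correlations.tsv")
    if (!is.null(audit$tree)) {
      p <- file.path(out_dir, "tree.nwk")
      to_newick(audit$tree, p)
      written <- c(written, p)
    }
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(params = audit$params,
           glance = as.list(glance(audit)),
           percentages = percentage_summaries(audit),
           rank_divergence = audit$rank_divergence),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    written <- c(written, p)
    p <- file.path(out_dir, "audit.log")
    writeLines(c(
      sprintf("dropped_records\t%d", audit$library$n_dropped),
      sprintf("flagged_numt\t%s",
              paste(audit$qc$sequence_id[audit$qc$flagged], collapse = ",")),
      sprintf("clusters\t%d", nrow(audit$partition$sizes)),
      sprintf("clamped_branches\t%s",
              if (is.null(audit$tree)) "NA"
              else attr(audit$tree, "clamped"))
    ), p)
    written <- c(written, p)
  }, error = on_fail)
  invisible(out_dir)
}
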