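#' Per-species barcode-gap table
#'
#' For every named species, summarises intraspecific K2P distances
#' (`mean_intra_pct`, `max_intra_pct`; `NA` when fewer than two specimens)
#' and the distance to the nearest heterospecific neighbour (`nn_dist_pct`
#' = the minimum valid distance between any member of the species and any
#' member of another named species; ties between neighbour species are
#' broken alphabetically). `gap_ok` is `TRUE` when the maximum
#' intraspecific distance lies below the nearest-neighbour distance — the
#' local barcode gap that makes identification reliable — and `NA` when
#' `max_intra_pct` is undefined. Saturated and low-overlap pairs are
#' skipped in both scans. `in_plot_set` marks species with at least
#' `min_n_for_plots` records, the subset conventionally used for
#' distribution plots and exceedance reports.
#'
#' @param dm A `k2p_dist`.
#' @param lib The `barcode_library` the distances were computed from.
#' @param min_n_for_plots Minimum records per species for the plotting /
#'   reporting subset (default 3).
#' @return A tibble with one row per named species: `species`, `n`,
#'   `mean_intra_pct`, `max_intra_pct`, `nn_species`, `nn_dist_pct`,
#'   `gap_ok`, `in_plot_set`.
#' @export
species_gap_table <- function(dm, lib, min_n_for_plots = 3) {
  stopifnot(inherits(dm, "k2p_dist"), inherits(lib, "barcode_library"))
  tab <- library_table(lib) |> dplyr::filter(!is.na(.data$species_label))
  species <- sort(unique(tab$species_label))
  counts <- tab |> dplyr::count(.data$species_label)
  px <- pairs_with_taxa(dm, lib) |>
    dplyr::filter(.data$status == "ok",
                  !is.na(.data$species_label_a),
                  !is.na(.data$species_label_b))
  con <- px |> dplyr::filter(.data$species_label_a == .data$species_label_b)
  intra <- if (nrow(con) == 0) {
    tibble::tibble(species = character(), mean_intra_pct = numeric(),
                   max_intra_pct = numeric())
  } else {
    con |>
      dplyr::group_by(species = .data$species_label_a) |>
      dplyr::summarise(mean_intra_pct = 100 * mean(.data$d),
                       max_intra_pct = 100 * max(.data$d), .groups = "drop")
  }
  inter <- px |> dplyr::filter(.data$species_label_a != .data$species_label_b)
  # nn scan over both orientations of each heterospecific pair
  both <- dplyr::bind_rows(
    dplyr::transmute(inter, species = .data$species_label_a,
                     other = .data$species_label_b, d = .data$d),
    dplyr::transmute(inter, species = .data$species_label_b,
                     other = .data$species_label_a, d = .data$d)
  )
  nn <- if (nrow(both) == 0) {
    tibble::tibble(species = character(), nn_species = character(),
                   nn_dist_pct = numeric())
  } else {
    both |>
      dplyr::group_by(.data$species) |>
      dplyr::filter(.data$d == min(.data$d)) |>
      dplyr::summarise(nn_species = min(.data$other),
                       nn_dist_pct = 100 * min(.data$d), .groups = "drop")
  }
  if (nrow(nn) == 0 && length(species) > 0) {
    warning("no heterospecific comparisons: nearest-neighbour fields are NA",
            call. = FALSE)
  }
  tibble::tibble(species = species) |>
    dplyr::left_join(counts, by = c(species = "species_label")) |>
    dplyr::left_join(intra, by = "species") |>
    dplyr::left_join(nn, by = "species") |>
    dplyr::mutate(
      gap_ok = dplyr::if_else(is.na(.data$max_intra_pct) |
                                is.na(.data$nn_dist_pct),
                              NA, .data$max_intra_pct < .data$nn_dist_pct),
      in_plot_set = .data$n >= min_n_for_plots
    )
}

#' Barcode-gap overlap report
#'
#' Reports, over the plotting subset (species with `in_plot_set = TRUE`),
#' the species whose maximum intraspecific divergence exceeds `threshold`
#' percent (putative deep conspecific lineages), the observed ranges of
#' mean intraspecific and nearest-neighbour distances, and the number of
#' species without a local barcode gap.
#'
#' @param gap_table Output of [species_gap_table()].
#' @param threshold Exceedance threshold in percent K2P (default 2).
#' @return A list of class `gap_report` with elements `threshold_pct`,
#'   `exceedances` (tibble), `mean_intra_range_pct`, `nn_dist_range_pct`
#'   and `n_gap_fail`.
#' @export
gap_overlap_report <- function(gap_table, threshold = 2.0) {
  sub <- gap_table |> dplyr::filter(.data$in_plot_set)
  exceed <- sub |>
    dplyr::filter(!is.na(.data$max_intra_pct),
                  .data$max_intra_pct > threshold) |>
    dplyr::arrange(dplyr::desc(.data$max_intra_pct))
  rng <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) c(NA_real_, NA_real_) else range(x)
  }
  structure(
    list(
      threshold_pct = threshold,
      exceedances = exceed,
      mean_intra_range_pct = rng(sub$mean_intra_pct),
      nn_dist_range_pct = rng(sub$nn_dist_pct),
      n_gap_fail = sum(!sub$gap_ok, na.rm = TRUE)
    ),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> threshold ", x$threshold_pct, "% K2P\n", sep = "")
  cat("  species exceeding threshold: ", nrow(x$exceedances), "\n", sep = "")
  if (nrow(x$exceedances) > 0) {
    cat("   ", paste(sprintf("%s (%.2f%%)", x$exceedances$species,
                             x$exceedances$max_intra_pct), collapse = ", "),
        "\n")
  }
  cat(sprintf("  mean intra range: [%.2f, %.2f]%%\n",
              x$mean_intra_range_pct[1], x$mean_intra_range_pct[2]))
  cat(sprintf("  NN distance range: [%.2f, %.2f]%%\n",
              x$nn_dist_range_pct[1], x$nn_dist_range_pct[2]))
  cat("  species without barcode gap: ", x$n_gap_fail, "\n", sep = "")
  invisible(x)
}
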