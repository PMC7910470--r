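#' Threshold single-linkage cluster partition
#'
#' Partitions the cluster-eligible sequences into the connected components
#' of the graph whose edges join pairs with a valid K2P distance `d <= tau`
#' (plain single linkage at a fixed threshold; the default 0.022 is the
#' conventional seed threshold for barcode cluster delineation). Saturated
#' and low-overlap pairs contribute no edge. The result is a set of local
#' clusters — not registry BINs: a global registry would include records
#' beyond the library at hand. Cluster ids `LC:%06d` are assigned in order
#' of each cluster's lexicographically smallest member, so the partition is
#' stable under input reordering.
#'
#' @param dm A `k2p_dist`.
#' @param eligible_ids Character vector of sequence ids eligible for
#'   clustering (typically the full-length tier, >= 500 bp).
#' @param tau Distance threshold as a K2P fraction, in (0, 0.2].
#' @return An object of class `cluster_partition`: list with `assignment`
#'   (tibble `sequence_id`, `cluster_id`), `tau`, and `sizes` (tibble
#'   `cluster_id`, `n`).
#' @export
cluster_barcodes <- function(dm, eligible_ids, tau = 0.022) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (!(tau > 0 && tau <= 0.2)) {
    stop("tau must lie in (0, 0.2]", call. = FALSE)
  }
  eligible_ids <- intersect(dm$ids, eligible_ids)
  if (length(eligible_ids) == 0) {
    warning("no cluster-eligible sequences: empty partition", call. = FALSE)
    assignment <- tibble::tibble(sequence_id = character(),
                                 cluster_id = character())
    return(structure(list(assignment = assignment, tau = tau,
                          sizes = dplyr::count(assignment,
                                               .data$cluster_id)),
                     class = "cluster_partition"))
  }
  edges <- dm$pairs |>
    dplyr::filter(.data$status == "ok", .data$d <= tau,
                  .data$id_a %in% eligible_ids,
                  .data$id_b %in% eligible_ids)
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = eligible_ids)
  )
  comp <- igraph::components(g)$membership
  # deterministic ids: clusters ordered by smallest member sequence_id
  smallest <- tapply(names(comp), comp, min)
  rank <- match(comp, as.integer(names(sort(smallest))))
  assignment <- tibble::tibble(
    sequence_id = names(comp),
    cluster_id = sprintf("LC:%06d", rank)
  ) |> dplyr::arrange(.data$sequence_id)
  structure(
    list(assignment = assignment, tau = tau,
         sizes = dplyr::count(assignment, .data$cluster_id, name = "n")),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> tau = ", x$tau, ": ",
      nrow(x$sizes), " cluster(s) over ", nrow(x$assignment),
      " sequence(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.cluster_partition <- function(x, ...) x$assignment

#' @export
glance.cluster_partition <- function(x, ...) {
  tibble::tibble(
    tau = x$tau,
    n_sequences = nrow(x$assignment),
    n_clusters = nrow(x$sizes),
    n_singletons = sum(x$sizes$n == 1L),
    max_cluster_size = if (nrow(x$sizes)) max(x$sizes$n) else NA_integer_,
    mean_cluster_size = if (nrow(x$sizes)) mean(x$sizes$n) else NA_real_
  )
}

#' Species-to-cluster concordance classification
#'
#' Classifies every named species against the cluster partition:
#' * `MATCH` — exactly one cluster, containing no other named species
#'   (a one-to-one correspondence);
#' * `SPLIT` — two or more clusters, each containing only this species
#'   (deep conspecific lineages);
#' * `MERGE` — a single cluster shared with at least one other named
#'   species (barcode-sharing species pair);
#' * `MIXTURE` — two or more clusters, at least one shared;
#' * `UNASSESSED` — no cluster-eligible sequences.
#' Records without a species label never render a cluster impure; they are
#' unnamed taxa pending identification, not conflicting species.
#'
#' @param partition A `cluster_partition`.
#' @param lib The `barcode_library`.
#' @return A tibble with one row per named species: `species`,
#'   `n_eligible`, `n_clusters`, `clusters` (list column), `category`.
#' @export
classify_concordance <- function(partition, lib) {
  stopifnot(inherits(partition, "cluster_partition"),
            inherits(lib, "barcode_library"))
  tab <- library_table(lib)
  asg <- dplyr::inner_join(partition$assignment,
                           tab[, c("sequence_id", "species_label")],
                           by = "sequence_id")
  species <- sort(unique(tab$species_label[!is.na(tab$species_label)]))
  cl_species <- asg |>
    dplyr::filter(!is.na(.data$species_label)) |>
    dplyr::distinct(.data$cluster_id, .data$species_label)
  n_species_in_cluster <- cl_species |>
    dplyr::count(.data$cluster_id, name = "n_species")
  purrr::map_dfr(species, function(sp) {
    cls <- sort(unique(asg$cluster_id[!is.na(asg$species_label) &
                                        asg$species_label == sp]))
    if (length(cls) == 0) {
      return(tibble::tibble(species = sp, n_eligible = 0L, n_clusters = 0L,
                            clusters = list(character()),
                            category = "UNASSESSED"))
    }
    shared <- any(n_species_in_cluster$n_species[
      n_species_in_cluster$cluster_id %in% cls] > 1L)
    category <- if (length(cls) == 1L) {
      if (shared) "MERGE" else "MATCH"
    } else {
      if (shared) "MIXTURE" else "SPLIT"
    }
    tibble::tibble(
      species = sp,
      n_eligible = sum(asg$species_label == sp, na.rm = TRUE),
      n_clusters = length(cls),
      clusters = list(cls),
      category = category
    )
  })
}

#' Summary counts of concordance categories
#'
#' @param concordance Output of [classify_concordance()].
#' @return A tibble `category`, `n`, `pct` (percent of named species,
#'   including unassessed ones in the denominator).
#' @export
concordance_summary <- function(concordance) {
  total <- nrow(concordance)
  concordance |>
    dplyr::count(.data$category) |>
    dplyr::mutate(pct = 100 * .data$n / total)
}
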