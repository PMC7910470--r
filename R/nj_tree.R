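#' Neighbour-joining tree from a K2P distance matrix
#'
#' Builds an unrooted neighbour-joining tree over the requested taxa.
#' The distance matrix must be complete over those taxa (saturated or
#' low-overlap pairs are an error, reported pair by pair). Negative
#' branch lengths — an occasional by-product of the NJ agglomeration —
#' are clamped to zero; the number of clamped branches is recorded in the
#' `clamped` attribute.
#'
#' @param dm A `k2p_dist`, or a complete symmetric numeric matrix with
#'   dimnames.
#' @param taxa Optional subset of sequence ids (default: all).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm, taxa = NULL) {
  m <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  if (!is.null(taxa)) {
    missing_taxa <- setdiff(taxa, rownames(m))
    if (length(missing_taxa) > 0) {
      stop("taxa not in distance matrix: ",
           paste(missing_taxa, collapse = ", "), call. = FALSE)
    }
    m <- m[taxa, taxa, drop = FALSE]
  }
  if (nrow(m) < 3) {
    stop("need at least 3 taxa for a neighbour-joining tree", call. = FALSE)
  }
  bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pairs <- apply(head(bad, 10), 1, function(ij)
      paste0(rownames(m)[ij[1]], "/", colnames(m)[ij[2]]))
    stop("distance matrix incomplete (saturated or low-overlap pairs): ",
         paste(pairs, collapse = ", "),
         if (nrow(bad) > 10) " ..." else "", call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(m))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- n_clamped
  tree
}

#' Serialise a tree to Newick text
#'
#' Deterministic output: children are ordered alphabetically by the
#' smallest leaf label below them before writing, and branch lengths are
#' printed with 6 significant digits.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Choose tree leaves for the audit tree
#'
#' Returns, for a library, the representative sequence ids used as tree
#' leaves: one per species-scoped haplotype (`"haplotypes"`, the default,
#' keeps desk-scale trees readable), every sequence (`"all"`), or one
#' medoid sequence per named species (`"species-medoid"`, the sequence
#' with the smallest summed distance to its conspecifics).
#'
#' @param lib A `barcode_library`.
#' @param dm A `k2p_dist` (needed for `"species-medoid"`).
#' @param leaves One of `"haplotypes"`, `"all"`, `"species-medoid"`.
#' @return Character vector of sequence ids.
#' @export
tree_leaves <- function(lib, dm = NULL,
                        leaves = c("haplotypes", "all", "species-medoid")) {
  leaves <- match.arg(leaves)
  tab <- library_table(lib)
  if (leaves == "all") return(tab$sequence_id)
  named <- tab |> dplyr::filter(!is.na(.data$species_label))
  if (leaves == "species-medoid") {
    stopifnot(inherits(dm, "k2p_dist"))
    reps <- named |>
      dplyr::group_by(.data$species_label) |>
      dplyr::group_map(function(df, key) {
        ids <- df$sequence_id
        if (length(ids) == 1) return(ids)
        sub <- dm$d[ids, ids]
        ids[which.min(rowSums(sub, na.rm = TRUE))]
      })
    return(sort(unlist(reps)))
  }
  reps <- named |>
    dplyr::group_by(.data$species_label) |>
    dplyr::group_map(function(df, key) {
      hp <- collapse_haplotypes(df$residues)
      vapply(seq_len(hp$h), function(i)
        min(df$sequence_id[hp$membership == i]), character(1))
    })
  sort(unlist(reps))
}
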