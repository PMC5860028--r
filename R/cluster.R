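# Greedy radius clustering, the engine shared by fragment clustering
# (0.5 A, superposed backbone RMSD) and pose clustering (3.5 A, receptor-
# frame RMSD).

#' Greedy radius clustering on a distance matrix
#'
#' Repeatedly selects the element with the most neighbors within `radius`
#' (ties: lowest index), forms a cluster of that center plus its neighbors,
#' removes them, and continues until no elements remain. Guarantees that any
#' two cluster centers are more than `radius` apart.
#'
#' @param d symmetric `n x n` distance matrix.
#' @param radius neighborhood radius (same units as `d`).
#' @return list of clusters in formation order, each a list with `center`
#'   (index into the input) and `members` (indices, center included).
#' @export
greedy_cluster <- function(d, radius) {
  n <- nrow(d)
  stopifnot(n >= 1L, ncol(d) == n)
  within <- d <= radius
  active <- rep(TRUE, n)
  clusters <- list()
  while (any(active)) {
    idx <- which(active)
    counts <- colSums(within[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]          # which.max: lowest index wins
    members <- idx[within[center, idx]]
    clusters[[length(clusters) + 1L]] <- list(center = center,
                                              members = members)
    active[members] <- FALSE
  }
  clusters
}

#' Cluster fragment conformations
#'
#' Greedy clustering of a fragment library on the pairwise superposed
#' backbone RMSD ([kabsch_rmsd()]) at a stringent radius (default 0.5 A),
#' retaining the centers of the largest `max_clusters` clusters for docking.
#' Clusters are ordered by size, descending; size ties keep formation order.
#'
#' @param records nonempty list of `fragment_record`.
#' @param radius clustering radius in Angstrom (default 0.5).
#' @param max_clusters number of clusters retained (default 25).
#' @return a `fragment_cluster_set`: list with `clusters` (each a list of
#'   `center` fragment_record, `member_count`, `center_index`,
#'   `member_indices`) and `n_input`.
#' @export
cluster_fragments <- function(records, radius = 0.5, max_clusters = 25L) {
  n <- length(records)
  if (n == 0L)
    stop_fragdock("no fragments to cluster", "validation_error")
  bbs <- lapply(records, function(r) flatten_backbone(r$backbone))
  d <- matrix(0, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kabsch_fit(bbs[[i]], bbs[[j]])$rmsd
    }
  }
  cl <- greedy_cluster(d, radius)
  sizes <- vapply(cl, function(c) length(c$members), 0L)
  ord <- order(-sizes, seq_along(cl))          # size desc, formation order
  ord <- ord[seq_len(min(max_clusters, length(ord)))]
  clusters <- lapply(ord, function(k) list(
    center = records[[cl[[k]]$center]],
    member_count = length(cl[[k]]$members),
    center_index = cl[[k]]$center,
    member_indices = cl[[k]]$members))
  structure(list(clusters = clusters, n_input = n, radius = radius),
            class = "fragment_cluster_set")
}

#' @export
print.fragment_cluster_set <- function(x, ...) {
  cat(sprintf("<fragment_cluster_set: %d cluster(s) from %d fragments>\n",
              length(x$clusters), x$n_input))
  invisible(x)
}
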