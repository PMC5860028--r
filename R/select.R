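# Model selection: pose clustering in the receptor frame, cluster-size
# ranking, interface-overlap removal, the (pass-through) refinement hook,
# and evaluation against a native complex with the CAPRI acceptable
# peptide criterion.

#' Receptor-frame RMSD between two docked poses
#'
#' RMSD between the two transformed ligand backbones in the common, fixed
#' receptor frame, without re-superposition: superposing would erase the
#' binding-site location, which is exactly what pose clustering must
#' distinguish.
#'
#' @param a,b `dock_pose`s referring to fragments of equal backbone length.
#' @param fragments list of `fragment_record` indexed by `fragment_id`
#'   (e.g. [cluster_centers()]).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, fragments) {
  pa <- pose_backbone(a, fragments[[a$fragment_id]])
  pb <- pose_backbone(b, fragments[[b$fragment_id]])
  if (nrow(pa) != nrow(pb))
    stop_fragdock("poses refer to fragments of different length",
                  "validation_error")
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Cluster docked poses and rank clusters by size
#'
#' Greedy radius clustering ([greedy_cluster()]) of the pooled pose
#' ensemble on the receptor-frame RMSD (default radius 3.5 A, the
#' resolution of basins of attraction). The representative of each cluster
#' is its lowest-energy member. Clusters are ranked by member count,
#' descending (ties: lower representative energy), and at most `max_report`
#' are returned with consecutive ranks from 1.
#'
#' @param poses nonempty list of `dock_pose`.
#' @param fragments list of `fragment_record` indexed by `fragment_id`.
#' @param radius clustering radius, Angstrom (default 3.5).
#' @param max_report maximum clusters returned (default 20).
#' @return list of `pose_cluster` (fields `representative`, `member_count`,
#'   `rank`, `center_index`, `rep_index`, `member_indices`), with
#'   attributes `n_input` and `total_members` (= `n_input`; counted before
#'   truncation).
#' @export
cluster_poses <- function(poses, fragments, radius = 3.5,
                          max_report = 20L) {
  n <- length(poses)
  if (n == 0L) stop_fragdock("no poses to cluster", "validation_error")
  bbs <- lapply(poses, function(p)
    pose_backbone(p, fragments[[p$fragment_id]]))
  natoms <- unique(vapply(bbs, nrow, 0L))
  if (length(natoms) != 1L)
    stop_fragdock("poses refer to fragments of different length",
                  "validation_error")
  flat <- t(vapply(bbs, as.vector, numeric(natoms * 3L)))
  d <- as.matrix(stats::dist(flat)) / sqrt(natoms)
  cl <- greedy_cluster(d, radius)
  etot <- vapply(poses, function(p) p$e_total, 0)
  reps <- vapply(cl, function(c) c$members[which.min(etot[c$members])], 0L)
  sizes <- vapply(cl, function(c) length(c$members), 0L)
  ord <- order(-sizes, etot[reps], seq_along(cl))
  total <- sum(sizes)
  ord <- ord[seq_len(min(max_report, length(ord)))]
  out <- lapply(seq_along(ord), function(r) {
    k <- ord[r]
    structure(list(representative = poses[[reps[k]]],
                   member_count = sizes[k], rank = r,
                   center_index = cl[[k]]$center,
                   rep_index = reps[k],
                   member_indices = cl[[k]]$members),
              class = "pose_cluster")
  })
  attr(out, "n_input") <- n
  attr(out, "total_members") <- total
  out
}

#' Remove clusters overlapping declared domain-domain interfaces
#'
#' A cluster is removed when any backbone atom of its representative's
#' transformed fragment lies within `contact_cutoff` of any atom of an
#' excluded receptor residue. Survivors keep their relative order and are
#' re-ranked consecutively from 1.
#'
#' @param clusters list of `pose_cluster`.
#' @param receptor the docked `chain_structure`.
#' @param excluded_residues integer vector of 0-based receptor residue
#'   indices marking other-domain interfaces (may be empty).
#' @param fragments list of `fragment_record` indexed by `fragment_id`.
#' @param contact_cutoff contact distance in Angstrom (default 5.0).
#' @return the surviving clusters, re-ranked.
#' @export
filter_interface_overlap <- function(clusters, receptor, excluded_residues,
                                     fragments, contact_cutoff = 5.0) {
  if (length(excluded_residues) == 0L) return(clusters)
  excluded_residues <- as.integer(excluded_residues)
  n <- chain_length(receptor)
  if (any(excluded_residues < 0L | excluded_residues >= n))
    stop_fragdock("excluded residue index out of range", "validation_error")
  sel <- receptor$atoms$res_index %in% excluded_residues
  exc <- as.matrix(receptor$atoms[sel, c("x", "y", "z")])
  keep <- vapply(clusters, function(cl) {
    bb <- pose_backbone(cl$representative,
                        fragments[[cl$representative$fragment_id]])
    d2 <- outer(rowSums(bb^2), rowSums(exc^2), "+") - 2 * bb %*% t(exc)
    min(d2) > contact_cutoff^2
  }, TRUE)
  out <- clusters[keep]
  for (r in seq_along(out)) out[[r]]$rank <- r
  attributes(out)[c("n_input", "total_members")] <-
    attributes(clusters)[c("n_input", "total_members")]
  out
}

#' Local-refinement hook (pass-through)
#'
#' Placeholder stage where a force-field minimizer may be plugged in to
#' relax cluster representatives. The default refiner is the identity: the
#' input is returned unchanged and a message notes that refinement is
#' disabled. A custom `refiner(pose)` may be supplied.
#'
#' @param clusters list of `pose_cluster`.
#' @param refiner optional function mapping a `dock_pose` to a refined
#'   `dock_pose`.
#' @return the clusters, with representatives refined when a refiner is
#'   given; counts and ranks unchanged.
#' @export
refine_representatives <- function(clusters, refiner = NULL) {
  if (is.null(refiner)) {
    message("refinement disabled: returning representatives unchanged")
    return(clusters)
  }
  out <- lapply(clusters, function(cl) {
    cl$representative <- refiner(cl$representative)
    cl
  })
  attributes(out)[c("n_input", "total_members")] <-
    attributes(clusters)[c("n_input", "total_members")]
  out
}

#' Evaluate predictions with the CAPRI acceptable peptide criterion
#'
#' The model receptor is superposed onto the native receptor by an optimal
#' rigid fit on CA atoms matched by author residue number; that transform is
#' applied to every predicted peptide, and each prediction's backbone RMSD
#' to the native peptide (no further superposition) is reported. A
#' prediction is acceptable when its RMSD is at most `threshold`
#' (default 4.0 A).
#'
#' @param predictions list of `pose_cluster` (rank order).
#' @param native_receptor,native_peptide the native complex chains.
#' @param model_receptor the receptor used for docking.
#' @param fragments list of `fragment_record` indexed by `fragment_id`.
#' @param threshold acceptance threshold in Angstrom (default 4.0).
#' @return an `evaluation_report`: list with `table` (rank, rmsd,
#'   acceptable), `best_rank_acceptable` (NA when none) and `threshold`.
#' @export
evaluate_capri <- function(predictions, native_receptor, native_peptide,
                           model_receptor, fragments, threshold = 4.0) {
  nat_ca <- ca_table(native_receptor)
  mod_ca <- ca_table(model_receptor)
  common <- intersect(nat_ca$key, mod_ca$key)
  if (length(common) < 3L)
    stop_fragdock("fewer than 3 common CA atoms between receptors",
                  "validation_error")
  a <- as.matrix(mod_ca[match(common, mod_ca$key), c("x", "y", "z")])
  b <- as.matrix(nat_ca[match(common, nat_ca$key), c("x", "y", "z")])
  fit <- kabsch_fit(a, b)
  sup <- rigid_transform(fit$rotation, fit$translation)
  nat_bb <- flatten_backbone(
    extract_backbone(native_peptide, 0L, chain_length(native_peptide)))
  rmsds <- vapply(predictions, function(cl) {
    bb <- pose_backbone(cl$representative,
                        fragments[[cl$representative$fragment_id]])
    bb <- apply_transform(sup, bb)
    if (nrow(bb) != nrow(nat_bb))
      stop_fragdock("prediction and native peptide lengths differ",
                    "validation_error")
    sqrt(mean(rowSums((bb - nat_bb)^2)))
  }, 0)
  acc <- rmsds <= threshold
  ranks <- vapply(predictions, function(cl) cl$rank, 0L)
  best <- if (any(acc)) min(ranks[acc]) else NA_integer_
  structure(list(table = data.frame(rank = ranks, rmsd = rmsds,
                                    acceptable = acc),
                 best_rank_acceptable = best, threshold = threshold),
            class = "evaluation_report")
}

ca_table <- function(chain) {
  a <- chain$atoms[chain$atoms$name == "CA", , drop = FALSE]
  a$key <- paste(a$seq_index, a$ins, sep = "|")
  a
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d prediction(s), threshold %.1f A>\n",
              nrow(x$table), x$threshold))
  if (is.na(x$best_rank_acceptable)) {
    cat("no acceptable prediction\n")
  } else {
    cat(sprintf("best acceptable rank: %d (%.2f A)\n",
                x$best_rank_acceptable,
                min(x$table$rmsd[x$table$rank == x$best_rank_acceptable])))
  }
  invisible(x)
}
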