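# Rigid-body docking of library fragments: per rotation, the FFT score
# field over all translations is evaluated and the best non-wrapping
# translation kept; one pose per rotation is pooled and the lowest-energy
# `keep` poses retained.

#' Construct a docked pose
#'
#' @param fragment_id 1-based index of the fragment in the docked library.
#' @param rotation_index 1-based index into the rotation set.
#' @param trans_voxel integer length-3 voxel translation (0-based).
#' @param transform `rigid_transform` mapping original fragment coordinates
#'   into the receptor frame.
#' @param e_rep,e_att,e_elec per-term scores.
#' @param e_total weighted total score.
#' @return a `dock_pose`.
#' @export
dock_pose <- function(fragment_id, rotation_index, trans_voxel, transform,
                      e_rep, e_att, e_elec, e_total) {
  structure(list(fragment_id = as.integer(fragment_id),
                 rotation_index = as.integer(rotation_index),
                 trans_voxel = as.integer(trans_voxel),
                 transform = transform,
                 e_rep = e_rep, e_att = e_att, e_elec = e_elec,
                 e_total = e_total),
            class = "dock_pose")
}

#' Transformed backbone coordinates of a pose
#' @param pose a `dock_pose`.
#' @param fragment the `fragment_record` the pose refers to.
#' @return `(4L) x 3` coordinate matrix in the receptor frame.
#' @export
pose_backbone <- function(pose, fragment) {
  apply_transform(pose$transform, flatten_backbone(fragment$backbone))
}

#' Dock one fragment by FFT translational scan over a rotation set
#'
#' For each rotation the fragment is discretized ([make_ligand_grids()]),
#' the score field over all translations computed ([correlate()]), and the
#' single best translation that does not wrap the ligand across the periodic
#' boundary is kept (ties: lowest linear voxel index). The per-rotation best
#' poses are pooled and the `keep` lowest-energy poses returned, sorted
#' ascending by total score (ties: lower rotation index). Per-term scores
#' are recomputed at the chosen translation by direct summation.
#'
#' @param receptor an `energy_grids`.
#' @param fragment a `fragment_record`.
#' @param rotations a `rotation_set`.
#' @param weights a `weight_set` or preset name.
#' @param keep maximum poses returned (default 250).
#' @param fragment_id id stored in the poses (default 1).
#' @return list of `dock_pose`, possibly empty (with a warning) when no
#'   rotation admits a valid translation.
#' @export
dock_fragment <- function(receptor, fragment, rotations,
                          weights = weight_set(), keep = 250L,
                          fragment_id = 1L) {
  stopifnot(is_count(keep), keep >= 1)
  weights <- weight_set(weights)
  spec <- receptor$spec
  poses <- list()
  for (ri in seq_len(rotations$n)) {
    lig <- make_ligand_grids(fragment, rotations$matrices[[ri]], spec)
    off_lo <- apply(lig$offsets, 2, min)
    off_hi <- apply(lig$offsets, 2, max)
    t_lo <- pmax(0, -off_lo)
    t_hi <- spec$dims - 1L - off_hi
    if (any(t_lo > t_hi)) next
    s <- correlate(receptor, lig, weights)
    sub <- s[(t_lo[1]:t_hi[1]) + 1L, (t_lo[2]:t_hi[2]) + 1L,
             (t_lo[3]:t_hi[3]) + 1L, drop = FALSE]
    best <- arrayInd(which.min(sub), dim(sub))
    tvox <- as.integer(t_lo + best[1, ] - 1L)
    e <- pose_energies(receptor, lig, tvox, weights)
    transl <- spec$origin + tvox * spec$spacing -
      as.numeric(rotations$matrices[[ri]] %*% lig$centroid)
    poses[[length(poses) + 1L]] <- dock_pose(
      fragment_id, ri, tvox,
      rigid_transform(rotations$matrices[[ri]], transl),
      e$e_rep, e$e_att, e$e_elec, e$e_total)
  }
  if (length(poses) == 0L) {
    warning("no valid translation for any rotation; empty result")
    return(poses)
  }
  etot <- vapply(poses, function(p) p$e_total, 0)
  rot <- vapply(poses, function(p) p$rotation_index, 0L)
  ord <- order(etot, rot)
  poses[ord[seq_len(min(keep, length(poses)))]]
}

# Direct per-term rescoring of a ligand placement at voxel translation tvox.
pose_energies <- function(receptor, lig, tvox, weights) {
  vox <- sweep(lig$offsets, 2, tvox + 1L, "+")   # 1-based array indices
  e_rep <- sum(receptor$rep[vox])
  e_att <- sum(receptor$att[vox])
  e_elec <- sum(lig$charges * receptor$elec[vox])
  list(e_rep = e_rep, e_att = e_att, e_elec = e_elec,
       e_total = weights$w_rep * e_rep + weights$w_att * e_att +
         weights$w_elec * e_elec)
}

#' Dock every retained fragment cluster center
#'
#' @param receptor an `energy_grids`.
#' @param cluster_set a `fragment_cluster_set` from [cluster_fragments()].
#' @param rotations a `rotation_set`.
#' @param weights a `weight_set` or preset name.
#' @param keep poses kept per fragment (default 250).
#' @return pooled list of `dock_pose`, tagged with `fragment_id` equal to
#'   the cluster index.
#' @export
dock_library <- function(receptor, cluster_set, rotations,
                         weights = weight_set(), keep = 250L) {
  if (length(cluster_set$clusters) == 0L)
    stop_fragdock("empty fragment library", "validation_error")
  out <- list()
  for (i in seq_along(cluster_set$clusters)) {
    p <- dock_fragment(receptor, cluster_set$clusters[[i]]$center,
                       rotations, weights, keep, fragment_id = i)
    out <- c(out, p)
  }
  out
}

#' Fragment records addressed by pose `fragment_id`
#' @param cluster_set a `fragment_cluster_set`.
#' @return list of `fragment_record` (cluster centers, in rank order).
#' @export
cluster_centers <- function(cluster_set) {
  lapply(cluster_set$clusters, function(cl) cl$center)
}
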