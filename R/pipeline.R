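# End-to-end protocol driver: the four stages chained in-process.

#' Run the full motif-docking protocol
#'
#' Chains the four stages: (1) build the motif fragment library from the
#' database chains (identity exclusion, motif padding and size control),
#' (2) cluster the fragments at the stringent radius and keep the top
#' cluster centers, (3) FFT-dock every center over the rotation set and
#' pool the top poses, (4) cluster the pose ensemble, rank by cluster size,
#' drop clusters overlapping excluded interface residues, and (optionally)
#' evaluate against a native complex.
#'
#' @param receptor the receptor `chain_structure` (tails are trimmed per
#'   the configuration before docking).
#' @param chains database chains for the fragment search.
#' @param motif motif string.
#' @param config a `run_config` (default [default_run_config()]).
#' @param target_sequences sequences for the identity exclusion (defaults
#'   to the receptor sequence).
#' @param peptide_context,motif_offset peptide sequence context for
#'   restriction moves (see [build_library()]).
#' @param excluded_residues 0-based receptor residues whose neighborhood is
#'   disallowed (domain-domain interfaces).
#' @param native_receptor,native_peptide optional native complex for CAPRI
#'   evaluation.
#' @return list with `library`, `fragment_clusters`, `poses`, `clusters`,
#'   `report` (NULL without a native), `receptor` (trimmed), `grid`.
#' @export
run_pipeline <- function(receptor, chains, motif,
                         config = default_run_config(),
                         target_sequences = NULL,
                         peptide_context = NULL, motif_offset = 0L,
                         excluded_residues = integer(0),
                         native_receptor = NULL, native_peptide = NULL) {
  config <- validate_run_config(config)
  receptor <- trim_unstructured_tails(receptor, config$max_tail)
  target_sequences <- target_sequences %||% chain_sequence(receptor)
  lib <- build_library(motif, chains, target_sequences,
                       low = config$library_low,
                       high = config$library_high,
                       min_len = config$min_motif_length,
                       max_iter = config$max_library_iter,
                       identity_threshold = config$identity_threshold,
                       peptide_context = peptide_context,
                       motif_offset = motif_offset)
  message(sprintf("library: %d fragments (pattern %s)",
                  length(lib$records), render_motif(lib$pattern_final)))
  fcl <- cluster_fragments(lib$records, config$frag_cluster_radius,
                           config$max_fragment_clusters)
  message(sprintf("fragment clusters kept: %d", length(fcl$clusters)))
  frags <- cluster_centers(fcl)
  extent <- max(vapply(frags, function(f) {
    bb <- flatten_backbone(f$backbone)
    max(dist(bb))
  }, 0))
  spec <- auto_grid_spec(receptor, extent + 2 * config$grid_spacing,
                         config$grid_spacing)
  grids <- make_receptor_grids(receptor, spec, config$core_radius,
                               config$shell_width, config$elec_cutoff)
  rots <- generate_rotations(config$n_rotations, config$rotation_seed)
  poses <- dock_library(grids, fcl, rots, weight_set(config$weight_set),
                        config$keep_per_fragment)
  message(sprintf("poses pooled: %d", length(poses)))
  # cluster everything, drop interface-overlapping clusters, then report
  # the top max_report by size
  pcl <- cluster_poses(poses, frags, config$pose_cluster_radius,
                       max_report = length(poses))
  pcl <- filter_interface_overlap(pcl, receptor, excluded_residues, frags,
                                  config$contact_cutoff)
  if (length(pcl) > config$max_report) {
    keep_attrs <- attributes(pcl)[c("n_input", "total_members")]
    pcl <- pcl[seq_len(config$max_report)]
    attributes(pcl)[c("n_input", "total_members")] <- keep_attrs
  }
  pcl <- suppressMessages(refine_representatives(pcl))
  message(sprintf("clusters reported: %d", length(pcl)))
  report <- NULL
  if (!is.null(native_receptor) && !is.null(native_peptide)) {
    report <- evaluate_capri(pcl, native_receptor, native_peptide,
                             receptor, frags, config$capri_threshold)
  }
  list(library = lib, fragment_clusters = fcl, poses = poses,
       clusters = pcl, report = report, receptor = receptor,
       grid = spec)
}
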