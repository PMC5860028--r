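# Run configuration: every stage parameter in one validated list, with
# defaults equal to the protocol's published constants where stated.

RUN_CONFIG_DEFAULTS <- list(
  frag_cluster_radius   = 0.5,     # A, stringent fragment clustering
  max_fragment_clusters = 25L,     # cluster centers retained for docking
  keep_per_fragment     = 250L,    # top poses pooled per fragment run
  pose_cluster_radius   = 3.5,     # A, basin-of-attraction resolution
  capri_threshold       = 4.0,     # A, acceptable peptide backbone RMSD
  identity_threshold    = 0.30,    # sequence-identity exclusion
  library_low           = 100L,    # target library size window
  library_high          = 1000L,
  min_motif_length      = 5L,      # shorter motifs padded with wildcards
  max_library_iter      = 20L,
  weight_set            = "standard",
  grid_spacing          = 1.0,     # A per voxel
  n_rotations           = 120L,    # desk-scale rotational sampling
  rotation_seed         = 1L,
  core_radius           = 1.8,     # A, repulsive core
  shell_width           = 3.0,     # A, attractive shell
  elec_cutoff           = 12.0,    # A, Coulomb truncation
  contact_cutoff        = 5.0,     # A, interface-overlap removal
  max_report            = 20L,     # clusters reported
  max_tail              = 3L       # unstructured-tail trimming cap
)

RUN_CONFIG_INT <- c("max_fragment_clusters", "keep_per_fragment",
                    "library_low", "library_high", "min_motif_length",
                    "max_library_iter", "n_rotations", "rotation_seed",
                    "max_report", "max_tail")

#' Default run configuration
#'
#' All stage parameters with their defaults: clustering radii 0.5 / 3.5 A,
#' 25 fragment clusters, 250 poses kept per fragment, 30% identity
#' exclusion, library window 100-1000, minimum motif length 5 and the
#' 4.0 A CAPRI acceptance threshold, plus grid, rotation and filtering
#' settings.
#'
#' @return a validated `run_config` list.
#' @export
default_run_config <- function() {
  validate_run_config(RUN_CONFIG_DEFAULTS)
}

#' Validate a run configuration
#'
#' Checks every field's type and range and rejects unknown keys.
#'
#' @param cfg named list of configuration values.
#' @return the configuration as a `run_config`, with integer fields
#'   coerced.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown) > 0L)
    stop_fragdock(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "validation_error")
  full <- RUN_CONFIG_DEFAULTS
  full[names(cfg)] <- cfg
  for (k in RUN_CONFIG_INT) {
    if (!is_count(full[[k]]))
      stop_fragdock(sprintf("config '%s' must be an integer", k),
                    "validation_error")
    full[[k]] <- as.integer(full[[k]])
  }
  num_pos <- c("frag_cluster_radius", "pose_cluster_radius",
               "capri_threshold", "grid_spacing", "core_radius",
               "shell_width", "elec_cutoff", "contact_cutoff")
  for (k in num_pos)
    if (!(is.numeric(full[[k]]) && length(full[[k]]) == 1L &&
          full[[k]] > 0))
      stop_fragdock(sprintf("config '%s' must be a positive number", k),
                    "validation_error")
  if (!(full$identity_threshold > 0 && full$identity_threshold <= 1))
    stop_fragdock("identity_threshold must be in (0, 1]",
                  "validation_error")
  if (full$library_low >= full$library_high)
    stop_fragdock("library_low must be < library_high", "validation_error")
  weight_set(full$weight_set)      # errors on unknown names
  if (full$max_tail < 0L)
    stop_fragdock("max_tail must be >= 0", "validation_error")
  structure(full, class = "run_config")
}

#' Read a run configuration from a key = value file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Unknown keys are rejected.
#'
#' @param path file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_fragdock(sprintf("config file '%s' not found", path), "io_error")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop_fragdock(sprintf("malformed config line: '%s'", l),
                    "validation_error")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (is.na(num)) val else num
  }
  validate_run_config(cfg)
}
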