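# Tab-separated tables and multi-model PDB export for the pipeline's
# intermediate and final results. All numeric formatting is fixed-width so
# identical runs produce byte-identical files.

fmt <- function(x, digits = 6) sprintf(paste0("%.", digits, "f"), x)

#' Write a fragment-library index and representative structures
#'
#' One PDB per retained cluster representative plus a tab-separated index
#' (source_id, chain, start, sequence, cluster_size, file).
#'
#' @param cluster_set a `fragment_cluster_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the index path.
#' @export
write_library <- function(cluster_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cluster_set$clusters), function(i) {
    cl <- cluster_set$clusters[[i]]
    file <- sprintf("fragment_%02d.pdb", i)
    write_pdb(fragment_to_chain(cl$center), file.path(dir, file))
    data.frame(source_id = cl$center$source_id,
               chain = cl$center$chain_id, start = cl$center$start,
               sequence = cl$center$sequence,
               cluster_size = cl$member_count, file = file,
               stringsAsFactors = FALSE)
  })
  idx <- file.path(dir, "index.tsv")
  write.table(do.call(rbind, rows), idx, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(idx)
}

#' Read a fragment library written by [write_library()]
#' @param dir library directory containing `index.tsv`.
#' @return a list of `fragment_record` in index order.
#' @export
read_library <- function(dir) {
  idx <- file.path(dir, "index.tsv")
  if (!file.exists(idx))
    stop_fragdock(sprintf("no index.tsv under '%s'", dir), "io_error")
  tab <- read.table(idx, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    ch <- read_pdb(file.path(dir, tab$file[i]))[[1]]
    fragment_record(tab$source_id[i], tab$chain[i], tab$start[i],
                    chain_sequence(ch),
                    extract_backbone(ch, 0L, chain_length(ch)))
  })
}

# A fragment rendered as a standalone peptide chain (backbone only).
fragment_to_chain <- function(fragment, chain_id = "P",
                              coords = NULL) {
  bb <- coords %||% flatten_backbone(fragment$backbone)
  codes <- strsplit(fragment$sequence, "")[[1]]
  L <- length(codes)
  rows <- lapply(seq_len(L), function(i)
    data.frame(res_index = i - 1L, code = codes[i], seq_index = i,
               ins = "", name = BACKBONE_ATOMS,
               element = substr(BACKBONE_ATOMS, 1, 1),
               x = bb[(i - 1L) * 4L + 1:4, 1],
               y = bb[(i - 1L) * 4L + 1:4, 2],
               z = bb[(i - 1L) * 4L + 1:4, 3],
               occupancy = 1, bfactor = 0,
               stringsAsFactors = FALSE))
  chain_structure(chain_id, do.call(rbind, rows),
                  source_id = fragment$source_id)
}

#' Write docked poses as a tab-separated table
#'
#' Columns: fragment_id, rotation, translation voxel, the full rigid
#' transform (row-major rotation, translation), per-term scores and total.
#'
#' @param poses list of `dock_pose`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pose_table <- function(poses, path) {
  header <- c("fragment_id", "rotation", "tx", "ty", "tz",
              paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
              "ox", "oy", "oz", "e_rep", "e_att", "e_elec", "e_total")
  lines <- vapply(poses, function(p) paste(c(
    p$fragment_id, p$rotation_index, p$trans_voxel,
    fmt(as.vector(t(p$transform$rotation)), 9),
    fmt(p$transform$translation, 6),
    fmt(c(p$e_rep, p$e_att, p$e_elec, p$e_total), 6)),
    collapse = "\t"), "")
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read a pose table written by [write_pose_table()]
#' @param path pose table path.
#' @return list of `dock_pose`.
#' @export
read_pose_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    rot <- matrix(as.numeric(r[paste0("r", rep(1:3, each = 3),
                                      rep(1:3, 3))]), 3, 3, byrow = TRUE)
    dock_pose(r$fragment_id, r$rotation, c(r$tx, r$ty, r$tz),
              rigid_transform(rot, as.numeric(r[c("ox", "oy", "oz")])),
              r$e_rep, r$e_att, r$e_elec, r$e_total)
  })
}

#' Write a ranked cluster summary
#'
#' @param clusters list of `pose_cluster`.
#' @param path output path.
#' @param rmsd optional per-cluster RMSD-to-native column (same order).
#' @return invisibly, `path`.
#' @export
write_cluster_summary <- function(clusters, path, rmsd = NULL) {
  header <- c("rank", "member_count", "fragment_id", "rotation",
              "e_rep", "e_att", "e_elec", "e_total")
  if (!is.null(rmsd)) header <- c(header, "rmsd_native")
  lines <- vapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]; p <- cl$representative
    v <- c(cl$rank, cl$member_count, p$fragment_id, p$rotation_index,
           fmt(c(p$e_rep, p$e_att, p$e_elec, p$e_total), 6))
    if (!is.null(rmsd)) v <- c(v, fmt(rmsd[i], 3))
    paste(v, collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' Write ranked peptide models as a multi-model PDB
#'
#' One MODEL/ENDMDL block per cluster representative, rank order.
#'
#' @param clusters list of `pose_cluster`.
#' @param fragments list of `fragment_record` indexed by `fragment_id`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_models_pdb <- function(clusters, fragments, path) {
  out <- character(0)
  for (cl in clusters) {
    frag <- fragments[[cl$representative$fragment_id]]
    ch <- fragment_to_chain(frag,
                            coords = pose_backbone(cl$representative,
                                                   frag))
    tmp <- tempfile(fileext = ".pdb")
    write_pdb(ch, tmp)
    lines <- readLines(tmp)
    unlink(tmp)
    lines <- lines[!grepl("^END", lines)]
    out <- c(out, sprintf("MODEL     %4d", cl$rank), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read peptide models from a multi-model PDB
#' @param path multi-model PDB path.
#' @return list of `chain_structure`, one per MODEL.
#' @export
read_models_pdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L)
    return(read_pdb(path))
  lapply(seq_along(starts), function(i) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(c(lines[(starts[i] + 1L):(ends[i] - 1L)], "END"), tmp)
    on.exit(unlink(tmp))
    read_pdb(tmp)[[1]]
  })
}
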