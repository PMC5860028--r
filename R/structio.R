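# PDB structure input/output and backbone extraction.
#
# Structures are held as `chain_structure` objects: one protein chain as an
# atom table (one row per atom) plus residue bookkeeping. Internally residues
# are indexed 0-based and contiguous; the author numbering from the PDB file
# is kept only for reporting and for receptor matching during evaluation.

#' Construct a chain structure
#'
#' @param chain_id single chain identifier character.
#' @param atoms data.frame with columns `res_index` (0-based contiguous
#'   residue index), `code` (one-letter residue code, "X" for nonstandard),
#'   `seq_index` (author residue numbering), `ins` (insertion code, "" if
#'   none), `name` (atom name), `element`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`.
#' @param source_id provenance tag (file path or entry id).
#' @return an object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, atoms, source_id = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("res_index", "code", "seq_index", "ins", "name", "element",
            "x", "y", "z", "occupancy", "bfactor")
  if (!all(need %in% names(atoms)))
    stop_fragdock("atom table missing required columns", "validation_error")
  if (nrow(atoms) > 0 && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_fragdock("non-finite coordinates", "validation_error")
  rownames(atoms) <- NULL
  structure(list(chain_id = chain_id, atoms = atoms, source_id = source_id),
            class = "chain_structure")
}

#' Number of residues in a chain
#' @param chain a `chain_structure`.
#' @return integer residue count.
#' @export
chain_length <- function(chain) {
  if (nrow(chain$atoms) == 0L) return(0L)
  max(chain$atoms$res_index) + 1L
}

#' One-letter sequence of a chain
#' @param chain a `chain_structure`.
#' @return a single string, one character per residue ("X" for nonstandard).
#' @export
chain_sequence <- function(chain) {
  if (nrow(chain$atoms) == 0L) return("")
  codes <- chain$atoms$code[!duplicated(chain$atoms$res_index)]
  paste(codes, collapse = "")
}

#' Per-residue backbone completeness
#'
#' A residue is backbone-complete iff atoms named N, CA, C and O are each
#' present exactly once.
#'
#' @param chain a `chain_structure`.
#' @return logical vector of length `chain_length(chain)`.
#' @export
backbone_complete <- function(chain) {
  n <- chain_length(chain)
  if (n == 0L) return(logical(0))
  ok <- rep(TRUE, n)
  for (at in BACKBONE_ATOMS) {
    cnt <- tabulate(chain$atoms$res_index[chain$atoms$name == at] + 1L, n)
    ok <- ok & cnt == 1L
  }
  ok
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure %s/%s: %d residues, %d atoms>\n",
              x$source_id, x$chain_id, chain_length(x), nrow(x$atoms)))
  invisible(x)
}

#' Read a PDB file into chain structures
#'
#' Parses ATOM records via [bio3d::read.pdb()]. HETATM records and waters are
#' excluded. For alternate locations the conformer with the highest occupancy
#' is kept (ties broken by file order). Residues of nonstandard type are kept
#' with one-letter code "X". Residues are ordered by (author number,
#' insertion code).
#'
#' @param path PDB file path.
#' @return a list of `chain_structure`, one per chain identifier.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path))
    stop_fragdock(sprintf("cannot read '%s': no such file", path), "io_error")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop_fragdock(sprintf("cannot parse '%s': %s", path,
                                          conditionMessage(e)), "io_error"))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0L)
    stop_fragdock(sprintf("'%s' contains no ATOM records", path),
                  "empty_structure_error")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$elesy[is.na(at$elesy)] <- ""
  out <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    key <- paste(ca$resno, ca$insert, sep = "|")
    # resolve alternate locations per residue: winning label is the one whose
    # first atom has the highest occupancy; ties go to the label seen first
    keep <- rep(TRUE, nrow(ca))
    for (k in unique(key[ca$alt != ""])) {
      idx <- which(key == k)
      labs <- unique(ca$alt[idx][ca$alt[idx] != ""])
      occ <- vapply(labs, function(l) ca$o[idx][ca$alt[idx] == l][1], 0)
      win <- labs[which.max(occ)]
      keep[idx] <- ca$alt[idx] == "" | ca$alt[idx] == win
    }
    ca <- ca[keep, , drop = FALSE]
    ord <- order(ca$resno, ca$insert)
    ca <- ca[ord, , drop = FALSE]
    rid <- paste(ca$resno, ca$insert, sep = "|")
    res_index <- cumsum(!duplicated(rid)) - 1L
    code <- unname(AA3TO1[ca$resid])
    code[is.na(code)] <- "X"
    atoms <- data.frame(
      res_index = res_index, code = code, seq_index = ca$resno,
      ins = ca$insert, name = ca$elety, element = ca$elesy,
      x = ca$x, y = ca$y, z = ca$z, occupancy = ca$o, bfactor = ca$b,
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- chain_structure(ch, atoms, source_id = path)
  }
  out
}

#' Write chain structures to a PDB file
#'
#' Standard ATOM records with 1-based serials, a TER record per chain and a
#' final END. Round-tripping through [read_pdb()] preserves sequences and
#' coordinates to 1e-3 Angstrom (the format's coordinate precision).
#'
#' @param structures list of `chain_structure` (may be empty).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "chain_structure")) structures <- list(structures)
  if (length(structures) == 0L) {
    ok <- tryCatch({ writeLines("END", path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop_fragdock(sprintf("cannot write '%s'", path), "io_error")
    return(invisible(path))
  }
  at <- do.call(rbind, lapply(structures, function(s) {
    if (nrow(s$atoms) == 0L)
      stop_fragdock("chain with zero atoms cannot be written",
                    "validation_error")
    cbind(s$atoms, chain = s$chain_id, stringsAsFactors = FALSE)
  }))
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  resid3 <- unname(AA3[at$code])
  resid3[is.na(resid3)] <- "UNK"
  tryCatch(
    bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                     resno = at$seq_index, resid = resid3,
                     eleno = seq_len(nrow(at)), elety = at$name,
                     chain = at$chain, insert = at$ins,
                     o = at$occupancy, b = at$bfactor, elesy = at$element,
                     chainter = TRUE, end = TRUE),
    error = function(e)
      stop_fragdock(sprintf("cannot write '%s': %s", path,
                            conditionMessage(e)), "io_error"))
  invisible(path)
}

#' Extract a backbone coordinate window
#'
#' Returns the N, CA, C, O coordinates of `length` consecutive residues
#' starting at 0-based residue `start`, as an `length x 4 x 3` array (atom
#' order N, CA, C, O). The chain is never modified.
#'
#' @param chain a `chain_structure`.
#' @param start 0-based residue index of the window start.
#' @param length number of residues in the window.
#' @return numeric array of dimension `c(length, 4, 3)`.
#' @export
extract_backbone <- function(chain, start, length) {
  stopifnot(is_count(start), is_count(length), length >= 1)
  n <- chain_length(chain)
  if (start + length > n)
    stop_fragdock("window exceeds chain length", "validation_error")
  win <- start:(start + length - 1L)
  if (!all(backbone_complete(chain)[win + 1L]))
    stop_fragdock("incomplete backbone in window", "missing_backbone_error")
  bb <- array(NA_real_, c(length, 4L, 3L),
              dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
  a <- chain$atoms
  for (j in seq_along(BACKBONE_ATOMS)) {
    rows <- a[a$name == BACKBONE_ATOMS[j] & a$res_index %in% win, ,
              drop = FALSE]
    rows <- rows[order(rows$res_index), , drop = FALSE]
    bb[, j, ] <- as.matrix(rows[, c("x", "y", "z")])
  }
  bb
}

#' Trim unstructured terminal tails
#'
#' Removes runs of "unstructured" residues from both chain termini. A
#' terminal residue counts as unstructured when its backbone is incomplete or
#' its mean B-factor exceeds the chain's 90th percentile of per-residue mean
#' B-factors (a configurable policy; set `max_tail = 0` to disable). At most
#' `max_tail` residues are removed from each terminus; interior residues are
#' never removed.
#'
#' @param chain a `chain_structure`.
#' @param max_tail maximum residues to remove per terminus (>= 0).
#' @return the trimmed `chain_structure` (possibly empty).
#' @export
trim_unstructured_tails <- function(chain, max_tail = 3L) {
  stopifnot(is_count(max_tail), max_tail >= 0)
  n <- chain_length(chain)
  if (n == 0L || max_tail == 0L) return(chain)
  bmean <- vapply(split(chain$atoms$bfactor, chain$atoms$res_index), mean, 0)
  thr <- quantile(bmean, 0.9, names = FALSE)
  bad <- !backbone_complete(chain) | bmean > thr
  head_run <- 0L
  while (head_run < n && head_run < max_tail && bad[head_run + 1L])
    head_run <- head_run + 1L
  tail_run <- 0L
  while (tail_run < n - head_run && tail_run < max_tail && bad[n - tail_run])
    tail_run <- tail_run + 1L
  keep <- chain$atoms$res_index >= head_run &
    chain$atoms$res_index <= n - 1L - tail_run
  atoms <- chain$atoms[keep, , drop = FALSE]
  if (nrow(atoms) > 0)
    atoms$res_index <- atoms$res_index - head_run
  chain_structure(chain$chain_id, atoms, chain$source_id)
}
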