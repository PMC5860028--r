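# Deterministic synthetic fixtures: a toy receptor slab bearing a groove
# pocket, a planted native complex whose pose is the designed optimum of
# the scoring function, and fragment databases with exactly controlled
# motif-match counts. Everything is a pure function of a fixture_spec, so
# every pipeline stage is testable without downloading structures.
#
# Geometry is idealized: residues are placed on a lattice (3.5 A along the
# chain, 4.8 A between strands, 4 A between layers) with fixed intra-residue
# backbone offsets of roughly ideal bond lengths. Background database
# sequences are drawn from an alphabet that excludes the motif's first fixed
# residue, so motif matches occur exactly where they are planted.

#' Fixture specification
#'
#' @param seed integer; fixes every output bit-exactly.
#' @param n_db_chains number of database chains.
#' @param planted_matches motif matches planted into the database.
#' @param motif motif string planted and searched (default "RXL").
#' @param noise_sigma Gaussian coordinate jitter of planted fragment
#'   backbones, Angstrom (default 0.25: conformational variability small
#'   enough that jittered copies of one conformer co-cluster at 0.5 A).
#' @param pocket_depth pocket depth in Angstrom; 0 gives a convex slab,
#'   values >= 4 carve the binding groove (default 6).
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_db_chains = 30L,
                         planted_matches = 150L, motif = "RXL",
                         noise_sigma = 0.25, pocket_depth = 6) {
  stopifnot(is_count(seed), is_count(n_db_chains),
            is_count(planted_matches), planted_matches >= 1,
            noise_sigma >= 0, pocket_depth >= 0)
  structure(list(seed = as.integer(seed),
                 n_db_chains = as.integer(n_db_chains),
                 planted_matches = as.integer(planted_matches),
                 motif = motif, noise_sigma = noise_sigma,
                 pocket_depth = pocket_depth),
            class = "fixture_spec")
}

# backbone offsets relative to CA; "xy" lies flat in the slab plane, "xz"
# points up (used for the peptide so its atoms rise out of the groove) and
# "xz_down" points down (used for receptor strands so layer tops are flat).
res_template <- function(plane = c("xy", "xz", "xz_down")) {
  plane <- match.arg(plane)
  off <- rbind(N = c(-0.93, 1.08, 0), CA = c(0, 0, 0),
               C = c(1.26, 0.85, 0), O = c(1.88, 1.94, 0))
  if (plane != "xy") off <- off[, c(1, 3, 2)]
  if (plane == "xz_down") off[, 3] <- -off[, 3]
  off
}

# Atom rows for one residue: backbone (template offsets around ca) plus an
# optional buried charge-bearing side-chain atom.
residue_atoms <- function(code, res_index, ca, template, side_atom = NULL) {
  names <- rownames(template)
  xyz <- sweep(template, 2, ca, "+")
  if (!is.null(side_atom)) {
    names <- c(names, side_atom$name)
    xyz <- rbind(xyz, ca + side_atom$offset)
  }
  data.frame(res_index = res_index, code = code, seq_index = res_index + 1L,
             ins = "", name = names,
             element = substr(names, 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bfactor = 20,
             stringsAsFactors = FALSE, row.names = NULL)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

# residues sampled for background positions: neutral, never the motif guard
NEUTRAL_AA <- c("A", "S", "T", "V", "L", "I", "F", "G", "M", "N", "Q", "W")

#' Build the toy receptor
#'
#' A solid three-layer slab (6 x 3 lattice per 3 A layer, strands 2.4 A
#' apart; 54 residues). When `pocket_depth >= 4` two wall rows are raised
#' flush with the slab's long edges, forming a groove ~3 A deep and ~4.8 A
#' wide along the top face (66 residues total) that geometrically
#' complements an extended 5-residue peptide and is the slab's only concave
#' feature; an aspartate with a buried carboxylate under the groove floor
#' makes the pocket's electrostatic signature asymmetric along the groove.
#' All other residues are neutral. Deterministic in `spec$seed`.
#'
#' @param spec a `fixture_spec`.
#' @return a `chain_structure` (chain "R").
#' @export
make_toy_receptor <- function(spec) {
  with_seed(spec$seed + 101L, {
    xs <- seq(0, by = 3.5, length.out = 6)
    ys <- c(2.4, 4.8, 7.2)
    zs <- c(0, 3, 6)
    groove_y <- ys[2]                       # 4.8
    sites <- expand.grid(x = xs, y = ys, z = zs)
    # the binding groove is formed by two wall rows raised flush with the
    # slab's long edges, flanking the y = 4.8 channel; the pocket thereby
    # sits far (> 8 A) above the bottom attachment face and is the slab's
    # only concave feature
    if (spec$pocket_depth >= 4)
      sites <- rbind(sites, expand.grid(x = xs,
                                        y = groove_y + c(-2.4, 2.4),
                                        z = 6 + 3 * (1:(1 +
                                          (spec$pocket_depth >= 8)))))
    codes <- sample(NEUTRAL_AA, nrow(sites), replace = TRUE)
    # groove-floor aspartate (buried carboxylate) under the peptide's
    # N-terminal arginine, one lattice step in from the slab face so the
    # groove is the closest accessible approach to the charge
    d_site <- which(sites$x == 3.5 & sites$y == groove_y & sites$z == 6)
    if (length(d_site) == 1L) codes[d_site] <- "D"
    tmpl <- res_template("xz_down")
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      side <- if (codes[i] == "D")
        list(name = "CG", offset = c(-1.75, 0, -1)) else NULL
      residue_atoms(codes[i], i - 1L,
                    c(sites$x[i], sites$y[i], sites$z[i]), tmpl, side)
    })
    chain_structure("R", do.call(rbind, rows), source_id = "toy_receptor")
  })
}

# peptide sequence implied by the (padded) motif: wildcards become alanine
motif_peptide_sequence <- function(motif, min_len = 5L) {
  pat <- pad_motif(compile_motif(motif), min_len)
  s <- unclass(pat)
  s[s == "X"] <- "A"
  paste(s, collapse = "")
}

#' Build the planted native complex
#'
#' Places an extended 5-residue peptide (sequence from the padded motif,
#' wildcards as alanine) in the receptor groove with its charged arginine
#' over the groove-floor aspartate. The placement is designed to be the
#' global optimum of the standard weight set; the identity transform is
#' recorded as ground truth (the fragment's native coordinates equal the
#' bound pose). Tests verify the construction by exhaustive scoring rather
#' than assuming it.
#'
#' @param spec a `fixture_spec`.
#' @return list with `receptor` and `native_peptide` (`chain_structure`s),
#'   `fragment` (the bound backbone as a `fragment_record`), `truth` (a
#'   `rigid_transform`, the identity), and `excluded_residues` (0-based
#'   receptor residues marking the other-domain attachment face).
#' @export
make_planted_complex <- function(spec) {
  receptor <- make_toy_receptor(spec)
  seq <- motif_peptide_sequence(spec$motif)
  L <- nchar(seq)
  tmpl <- res_template("xz")
  codes <- strsplit(seq, "")[[1]]
  rows <- lapply(seq_len(L), function(i)
    residue_atoms(codes[i], i - 1L, c(1.75 + 3.5 * (i - 1), 4.8, 8.6),
                  tmpl))
  peptide <- chain_structure("P", do.call(rbind, rows),
                             source_id = "planted_peptide")
  frag <- fragment_record("planted_peptide", "P", 0L, seq,
                          extract_backbone(peptide, 0L, L))
  # the slab's bottom layer is the face where the other domain attaches;
  # poses overlapping it are removed by the interface filter (the groove
  # on the top face is > 8 A away)
  a <- receptor$atoms
  bottom <- sort(unique(a$res_index[a$name == "CA" & a$z <= 0]))
  list(receptor = receptor, native_peptide = peptide, fragment = frag,
       truth = rigid_transform(diag(3), c(0, 0, 0)),
       excluded_residues = bottom)
}

# A second, clearly distinct conformer: the last two residues swung 90
# degrees about z around the third CA. Superposed backbone RMSD to the
# extended conformer is well above the 0.5 A clustering radius.
kinked_conformer <- function(L = 5L) {
  ext <- extended_conformer(L)
  pivot <- ext[3, 2, ]
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  out <- ext
  for (i in 4:L) for (j in 1:4)
    out[i, j, ] <- as.numeric(rot %*% (ext[i, j, ] - pivot)) + pivot
  out
}

extended_conformer <- function(L = 5L) {
  tmpl <- res_template("xz")
  bb <- array(0, c(L, 4, 3))
  for (i in seq_len(L)) bb[i, , ] <- sweep(tmpl, 2, c(3.5 * (i - 1), 0, 0),
                                           "+")
  dimnames(bb) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  bb
}

#' Build a synthetic fragment database with planted motif matches
#'
#' Generates `spec$n_db_chains` chains of random background sequence over
#' an alphabet excluding the motif's first fixed residue (so matches cannot
#' arise by chance) and plants exactly `spec$planted_matches` windows whose
#' sequence realizes the padded motif (wildcards as alanine) and whose
#' backbone is a conformer jittered by `noise_sigma`. Optional extras
#' support library-size-control scenarios: `extra_windows` are additional
#' planted window sequences (matching a looser pattern but not the motif)
#' and `next_chars` fixes the residue immediately following each planted
#' window (recycled). The achieved match count is verified with
#' [find_matches()] before returning.
#'
#' @param spec a `fixture_spec`.
#' @param conformers list of `L x 4 x 3` conformer arrays cycled over
#'   planted windows (default: the extended conformer).
#' @param extra_windows character vector of extra window sequences.
#' @param next_chars characters following planted windows (recycled;
#'   must avoid the motif's first fixed residue).
#' @return list of `chain_structure` with attribute `planted` (data.frame
#'   of chain, start, kind).
#' @export
make_fragment_database <- function(spec, conformers = NULL,
                                   extra_windows = character(0),
                                   next_chars = NULL) {
  pat <- pad_motif(compile_motif(spec$motif), 5L)
  L <- length(pat)
  fixed <- unclass(pat)[unclass(pat) != "X"]
  if (length(fixed) == 0L)
    stop_fragdock("fixture motif needs at least one fixed position",
                  "validation_error")
  guard <- fixed[1]
  if (is.null(conformers)) conformers <- list(extended_conformer(L))
  # full amino-acid alphabet minus the guard (and minus any residue whose
  # absence the extra-window scenario relies on), so background sequences
  # look like real protein sequences to the identity filter yet can never
  # contain a motif match by accident
  background <- setdiff(AA1, c(guard, "G"[length(extra_windows) > 0]))
  fill_alphabet <- setdiff(NEUTRAL_AA, c(guard, "G"))
  n_extra <- length(extra_windows)
  total <- spec$planted_matches + n_extra
  stride <- L + 5L                         # window + flank + jitter slack
  per_chain <- ceiling(total / spec$n_db_chains)
  chain_len <- max(40L, per_chain * stride + 6L)
  if (chain_len > 250L)
    stop_fragdock("too many planted matches for the database size",
                  "validation_error")
  pat_chars <- unclass(pat)
  with_seed(spec$seed + 202L, {
    kinds <- c(rep("motif", spec$planted_matches), rep("extra", n_extra))
    windows <- c(rep(NA_character_, spec$planted_matches), extra_windows)
    if (!is.null(next_chars)) {
      nc <- rep_len(next_chars, spec$planted_matches)
      nc <- c(nc, rep(NA_character_, n_extra))
    } else nc <- rep(NA_character_, total)
    perm <- sample.int(total)              # scatter kinds across slots
    windows <- windows[perm]; kinds <- kinds[perm]; nc <- nc[perm]
    chains <- vector("list", spec$n_db_chains)
    planted <- list()
    w <- 0L
    tmpl <- res_template("xy")
    for (ci in seq_len(spec$n_db_chains)) {
      codes <- sample(background, chain_len, replace = TRUE)
      bb_override <- list()
      for (s in seq_len(per_chain)) {
        if (w >= total) break
        w <- w + 1L
        # jittered slot positions keep chains from sharing aligned windows
        start <- (s - 1L) * stride + sample(0:3, 1L) + 1L
        win <- if (is.na(windows[w])) {
          # realize the motif: fixed positions literal, wildcards random
          # neutral residues (charges live only where the motif puts them)
          vapply(pat_chars, function(ch)
            if (ch == "X") sample(fill_alphabet, 1L) else ch, "")
        } else strsplit(windows[w], "")[[1]]
        codes[(start + 1L):(start + L)] <- win
        if (!is.na(nc[w])) codes[start + L + 1L] <- nc[w]
        conf <- conformers[[(w - 1L) %% length(conformers) + 1L]]
        jit <- array(rnorm(length(conf), 0, spec$noise_sigma), dim(conf))
        bb_override[[length(bb_override) + 1L]] <-
          list(start = start, bb = conf + jit)
        planted[[length(planted) + 1L]] <-
          data.frame(chain = ci, start = start, kind = kinds[w],
                     stringsAsFactors = FALSE)
      }
      rows <- lapply(seq_len(chain_len), function(i)
        residue_atoms(codes[i], i - 1L, c(3.5 * (i - 1), 0, 0), tmpl))
      atoms <- do.call(rbind, rows)
      for (ov in bb_override) {
        for (ri in seq_len(dim(ov$bb)[1])) {
          res <- ov$start + ri - 1L
          for (j in 1:4) {
            row <- which(atoms$res_index == res &
                           atoms$name == BACKBONE_ATOMS[j])
            atoms[row, c("x", "y", "z")] <- ov$bb[ri, j, ]
          }
        }
      }
      chains[[ci]] <- chain_structure("A", atoms,
                                      source_id = sprintf("db%03d", ci))
    }
    got <- sum(vapply(chains, function(ch)
      length(find_matches(pat, chain_sequence(ch))), 0L))
    if (got != spec$planted_matches)
      stop_fragdock(sprintf(
        "planted %d matches but found %d; fixture spec is inconsistent",
        spec$planted_matches, got), "validation_error")
    attr(chains, "planted") <- do.call(rbind, planted)
    chains
  })
}

#' Library-size-control scenario fixtures
#'
#' Three ready-made databases exercising the [build_library()] size loop:
#' `"in_range"` (initial match count already inside the target window),
#' `"generalize"` (too few matches of a fully fixed motif; one generalize
#' move reaches the window) and `"restrict"` (thousands of matches; one
#' restrict move using the peptide flank reaches the window).
#'
#' @param case one of "in_range", "generalize", "restrict".
#' @param seed integer seed.
#' @return list with `chains`, `motif`, `peptide_context`, `motif_offset`,
#'   and `expected` (named list: initial and final match counts).
#' @export
make_library_fixture <- function(case = c("in_range", "generalize",
                                          "restrict"), seed = 1L) {
  case <- match.arg(case)
  if (case == "in_range") {
    sp <- fixture_spec(seed = seed, n_db_chains = 30L,
                       planted_matches = 150L, motif = "RXL")
    chains <- make_fragment_database(sp)
    list(chains = chains, motif = "RXL",
         peptide_context = "RALAA", motif_offset = 0L,
         expected = list(initial = 150L, final = 150L, iterations = 1L))
  } else if (case == "generalize") {
    sp <- fixture_spec(seed = seed, n_db_chains = 30L,
                       planted_matches = 50L, motif = "KGRRL")
    chains <- make_fragment_database(
      sp, extra_windows = rep("KARRL", 100L))
    list(chains = chains, motif = "KGRRL",
         peptide_context = "KGRRL", motif_offset = 0L,
         expected = list(initial = 50L, final = 150L, iterations = 2L))
  } else {
    sp <- fixture_spec(seed = seed, n_db_chains = 60L,
                       planted_matches = 1200L, motif = "RXL")
    chains <- make_fragment_database(
      sp, next_chars = c(rep("W", 300L), rep("F", 900L)))
    list(chains = chains, motif = "RXL",
         peptide_context = "RALAAW", motif_offset = 0L,
         expected = list(initial = 1200L, final = 300L, iterations = 2L))
  }
}
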