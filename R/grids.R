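# Receptor- and ligand-side energy grids for FFT docking.
#
# The receptor is discretized into three scalar fields: a repulsive core
# (occupancy within core_radius of any heavy atom), an attractive surface
# shell (a band of width shell_width outside the core, valued -1), and a
# Coulombic potential with distance-dependent dielectric eps(r) = 4r,
# truncated at 12 A. The ligand contributes a heavy-atom occupancy field and
# a point-charge field; the docking score is the weighted sum of the three
# cross-correlations.

#' Construct a grid specification
#'
#' @param spacing voxel edge length in Angstrom (> 0).
#' @param dims integer vector of 3 voxel counts (each >= 8).
#' @param origin coordinates of the center of voxel (0,0,0), Angstrom.
#' @return a `grid_spec`.
#' @export
grid_spec <- function(spacing, dims, origin) {
  dims <- as.integer(dims)
  if (!(length(dims) == 3L && all(dims >= 8L)))
    stop_fragdock("dims must be 3 integers >= 8", "validation_error")
  if (!(is.numeric(spacing) && spacing > 0))
    stop_fragdock("spacing must be positive", "validation_error")
  structure(list(spacing = spacing, dims = dims,
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Choose a grid that fits receptor plus ligand without wrap-around
#'
#' Picks the smallest FFT-friendly dimensions (prime factors 2, 3, 5) that
#' hold the receptor extent plus the ligand extent plus a safety pad, and
#' centers the receptor in the box, so every non-wrapping translation of the
#' ligand around the receptor is a valid FFT translation.
#'
#' @param receptor a `chain_structure`.
#' @param ligand_extent maximal ligand diameter in Angstrom (scalar).
#' @param spacing voxel size, Angstrom (default 1.0).
#' @param pad extra voxels per side (default 2).
#' @return a `grid_spec`.
#' @export
auto_grid_spec <- function(receptor, ligand_extent, spacing = 1.0,
                           pad = 2L) {
  xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  ext <- hi - lo
  need <- ceiling((ext + ligand_extent) / spacing) + 1L + 2L * pad
  dims <- vapply(need, function(n) smooth235(max(8L, n)), 0L)
  phys <- (dims - 1L) * spacing
  origin <- lo - (phys - ext) / 2
  grid_spec(spacing, dims, origin)
}

# Residue-level unit-charge model: Asp/Glu -1 on the carboxylate carbon,
# Lys/Arg +1 on the terminal nitrogen, His +0.1; backbone neutral. When the
# preferred side-chain atom is absent (e.g. backbone-only models) the charge
# falls back to CB, then CA.
CHARGE_MODEL <- list(
  D = list(q = -1,   atoms = c("CG", "CB", "CA")),
  E = list(q = -1,   atoms = c("CD", "CB", "CA")),
  K = list(q = +1,   atoms = c("NZ", "CB", "CA")),
  R = list(q = +1,   atoms = c("NH1", "CZ", "CB", "CA")),
  H = list(q = +0.1, atoms = c("ND1", "CB", "CA"))
)

# Charged-atom table (x, y, z, q) for a chain under the residue-level model.
residue_charges <- function(chain) {
  a <- chain$atoms
  out <- list()
  for (ri in unique(a$res_index)) {
    rows <- a[a$res_index == ri, , drop = FALSE]
    mod <- CHARGE_MODEL[[rows$code[1]]]
    if (is.null(mod)) next
    hit <- mod$atoms[mod$atoms %in% rows$name][1]
    if (is.na(hit)) next
    r <- rows[rows$name == hit, , drop = FALSE][1, ]
    out[[length(out) + 1L]] <- c(r$x, r$y, r$z, mod$q)
  }
  if (length(out) == 0L)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("x", "y", "z", "q"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("x", "y", "z", "q")
  m
}

# Per-atom charges for a backbone-only fragment: charged residue codes put
# their unit charge on the CA row (side chains are absent from fragments).
fragment_charges <- function(fragment) {
  L <- dim(fragment$backbone)[1]
  q <- numeric(L * 4L)
  codes <- strsplit(fragment$sequence, "")[[1]]
  for (i in seq_len(L)) {
    mod <- CHARGE_MODEL[[codes[i]]]
    if (!is.null(mod)) q[(i - 1L) * 4L + 2L] <- mod$q   # CA row
  }
  q
}

voxel_axes <- function(spec) {
  lapply(1:3, function(a)
    spec$origin[a] + (seq_len(spec$dims[a]) - 1L) * spec$spacing)
}

#' Discretize a receptor into energy grids
#'
#' @param receptor a `chain_structure`.
#' @param spec a `grid_spec` that contains all receptor atoms.
#' @param core_radius repulsive core radius around heavy atoms, Angstrom
#'   (default 1.8).
#' @param shell_width width of the attractive shell outside the core,
#'   Angstrom (default 3.0).
#' @param elec_cutoff Coulomb truncation distance, Angstrom (default 12).
#' @return an `energy_grids` list with fields `spec`, `rep` (1 inside the
#'   repulsive core, else 0), `att` (<= 0; minus the number of receptor
#'   atoms whose shell covers the voxel, so concave sites score deeper than
#'   flat surface) and `elec` (Coulomb potential with eps(r) = 4r, distances
#'   capped below at one voxel, screened to zero inside the core).
#' @export
make_receptor_grids <- function(receptor, spec, core_radius = 1.8,
                                shell_width = 3.0, elec_cutoff = 12.0) {
  xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  xyz <- xyz[receptor$atoms$element != "H" &
               !startsWith(receptor$atoms$name, "H"), , drop = FALSE]
  if (nrow(xyz) == 0L)
    stop_fragdock("receptor has no heavy atoms", "validation_error")
  ax <- voxel_axes(spec)
  lo_ok <- vapply(1:3, function(a) all(xyz[, a] >= ax[[a]][1]), TRUE)
  hi_ok <- vapply(1:3, function(a)
    all(xyz[, a] <= ax[[a]][spec$dims[a]]), TRUE)
  if (!all(lo_ok & hi_ok))
    stop_fragdock("receptor atoms fall outside the grid", "grid_fit_error")
  rep_g <- array(0, spec$dims)
  att_g <- array(0, spec$dims)
  shell_radius <- core_radius + shell_width
  for (i in seq_len(nrow(xyz))) {
    center <- xyz[i, ]
    rng <- lapply(1:3, function(a)
      which(abs(ax[[a]] - center[a]) <= shell_radius))
    if (any(vapply(rng, length, 0L) == 0L)) next
    dx2 <- (ax[[1]][rng[[1]]] - center[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - center[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - center[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    rep_sub <- rep_g[rng[[1]], rng[[2]], rng[[3]]]
    rep_sub[d2 <= core_radius^2] <- 1
    rep_g[rng[[1]], rng[[2]], rng[[3]]] <- rep_sub
    # attractive shell counts contacting atoms (a discretized attractive
    # vdW term): concave sites with more nearby receptor atoms score
    # deeper than flat surface, which is what lets cluster-size ranking
    # find binding pockets
    att_sub <- att_g[rng[[1]], rng[[2]], rng[[3]]]
    ann <- d2 > core_radius^2 & d2 <= shell_radius^2
    att_sub[ann] <- att_sub[ann] - 1
    att_g[rng[[1]], rng[[2]], rng[[3]]] <- att_sub
  }
  att_g[rep_g > 0] <- 0                       # core and shell are disjoint
  elec_g <- array(0, spec$dims)
  ch <- residue_charges(receptor)
  for (i in seq_len(nrow(ch))) {
    center <- ch[i, 1:3]; q <- ch[i, 4]
    rng <- lapply(1:3, function(a)
      which(abs(ax[[a]] - center[a]) <= elec_cutoff))
    if (any(vapply(rng, length, 0L) == 0L)) next
    dx2 <- (ax[[1]][rng[[1]]] - center[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - center[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - center[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    r <- pmax(sqrt(d2), spec$spacing)          # cap below at one voxel
    pot <- q / (4 * r * r)                     # eps(r) = 4r  =>  q/(4 r^2)
    pot[d2 > elec_cutoff^2] <- 0
    elec_g[rng[[1]], rng[[2]], rng[[3]]] <-
      elec_g[rng[[1]], rng[[2]], rng[[3]]] + pot
  }
  # inside the repulsive core the Coulomb field is screened to zero: no
  # ligand atom can physically reach it, and leaving the 1/r^2 singularity
  # there would reward core-penetrating poses
  elec_g[rep_g > 0] <- 0
  structure(list(spec = spec, rep = rep_g, att = att_g, elec = elec_g),
            class = "energy_grids")
}

#' Discretize a rotated fragment into ligand grids
#'
#' The fragment backbone is centered on its centroid, rotated, and each
#' heavy atom deposited into its nearest voxel relative to the grid origin
#' voxel (negative offsets wrap, in the usual FFT circular convention).
#' Total occupancy equals the heavy-atom count.
#'
#' @param fragment a `fragment_record`.
#' @param rotation 3x3 proper rotation matrix.
#' @param spec the shared `grid_spec`.
#' @return a `ligand_grids` list with fields `spec`, `occ`, `q`, `offsets`
#'   (n x 3 integer voxel offsets from the centroid voxel), `charges`
#'   (per-atom), and `centroid` (the original fragment centroid).
#' @export
make_ligand_grids <- function(fragment, rotation, spec) {
  rot <- rigid_transform(rotation)$rotation
  coords <- flatten_backbone(fragment$backbone)
  centroid <- colMeans(coords)
  rc <- sweep(coords, 2, centroid) %*% t(rot)
  offsets <- round(rc / spec$spacing)
  ext <- apply(offsets, 2, max) - apply(offsets, 2, min)
  if (any(ext >= spec$dims))
    stop_fragdock("rotated ligand exceeds the grid", "grid_fit_error")
  occ <- array(0, spec$dims)
  qg <- array(0, spec$dims)
  charges <- fragment_charges(fragment)
  idx <- sweep(offsets %% matrix(spec$dims, nrow(offsets), 3, byrow = TRUE),
               2, c(1L, 1L, 1L), "+")
  for (i in seq_len(nrow(idx))) {
    occ[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      occ[idx[i, 1], idx[i, 2], idx[i, 3]] + 1
    if (charges[i] != 0)
      qg[idx[i, 1], idx[i, 2], idx[i, 3]] <-
        qg[idx[i, 1], idx[i, 2], idx[i, 3]] + charges[i]
  }
  structure(list(spec = spec, occ = occ, q = qg,
                 offsets = offsets, charges = charges,
                 centroid = centroid),
            class = "ligand_grids")
}

#' Docking score weight sets
#'
#' The total score is `w_rep * E_rep + w_att * E_att + w_elec * E_elec`
#' (lower is better). "standard" balances shape and electrostatics;
#' "elec-favored" up-weights the Coulomb term five-fold, for interfaces
#' dominated by electrostatic attraction.
#'
#' @param name "standard" or "elec-favored", or a `weight_set` passed
#'   through unchanged.
#' @return a `weight_set` list with `name`, `w_rep`, `w_att`, `w_elec`.
#' @export
weight_set <- function(name = "standard") {
  if (inherits(name, "weight_set")) return(name)
  presets <- list(
    standard       = list(w_rep = 50, w_att = 1.0, w_elec = 300),
    `elec-favored` = list(w_rep = 50, w_att = 1.0, w_elec = 1500))
  if (!name %in% names(presets))
    stop_fragdock(sprintf("unknown weight set '%s'", name),
                  "validation_error")
  w <- presets[[name]]
  if (w$w_rep <= 0)
    stop_fragdock("w_rep must be positive", "validation_error")
  structure(c(list(name = name), w), class = "weight_set")
}

#' FFT cross-correlation docking score field
#'
#' Computes, for every integer translation `t` of the ligand grids over the
#' receptor grids (circular convention),
#' `S(t) = w_rep * sum_x rep(x) occ(x - t) + w_att * sum_x att(x) occ(x - t)
#'  + w_elec * sum_x elec(x) q(x - t)`,
#' evaluated with forward/inverse FFTs.
#'
#' @param receptor an `energy_grids`.
#' @param ligand a `ligand_grids` on the same grid.
#' @param weights a `weight_set` (or preset name).
#' @return numeric array of scores, one per translation (0-based translation
#'   `t` lives at array index `t + 1`).
#' @export
correlate <- function(receptor, ligand, weights = weight_set()) {
  weights <- weight_set(weights)
  if (!identical(receptor$spec$dims, ligand$spec$dims) ||
      receptor$spec$spacing != ligand$spec$spacing)
    stop_fragdock("receptor and ligand grids do not match",
                  "validation_error")
  nvox <- prod(receptor$spec$dims)
  xcorr <- function(f, l)
    Re(fft(fft(f) * Conj(fft(l)), inverse = TRUE)) / nvox
  shape <- weights$w_rep * receptor$rep + weights$w_att * receptor$att
  s <- xcorr(shape, ligand$occ)
  if (any(ligand$q != 0))
    s <- s + weights$w_elec * xcorr(receptor$elec, ligand$q)
  s
}
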