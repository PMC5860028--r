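test_that("grid specs validate and auto-sizing fits receptor plus ligand", {
  expect_error(grid_spec(0, c(8, 8, 8), c(0, 0, 0)),
               class = "validation_error")
  expect_error(grid_spec(1, c(4, 8, 8), c(0, 0, 0)),
               class = "validation_error")
  rec <- make_toy_receptor(fixture_spec(seed = 1))
  spec <- auto_grid_spec(rec, 20, 1.0)
  expect_true(all(spec$dims >= 8))
  # FFT-friendly sizes only
  for (d in spec$dims) {
    m <- d
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    expect_equal(m, 1)
  }
  ax <- fragdock:::voxel_axes(spec)
  xyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  for (a in 1:3) {
    expect_true(all(xyz[, a] >= ax[[a]][1]))
    expect_true(all(xyz[, a] <= ax[[a]][spec$dims[a]]))
  }
})

test_that("repulsive core voxels match brute-force enumeration", {
  ch <- toy_chain("A")
  # single atom exactly at a voxel center in a symmetric grid
  ch$atoms <- ch$atoms[ch$atoms$name == "CA", ]
  ch$atoms[, c("x", "y", "z")] <- 0
  spec <- grid_spec(1.0, c(16, 16, 16), origin = c(-8, -8, -8))
  g <- make_receptor_grids(ch, spec, core_radius = 1.8, shell_width = 3.0)
  ax <- fragdock:::voxel_axes(spec)
  brute_core <- 0L; brute_shell <- 0L
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    d <- sqrt(ax[[1]][i]^2 + ax[[2]][j]^2 + ax[[3]][k]^2)
    if (d <= 1.8) brute_core <- brute_core + 1L
    else if (d <= 4.8) brute_shell <- brute_shell + 1L
  }
  expect_equal(sum(g$rep), brute_core)
  expect_equal(sum(g$att), -brute_shell)
})

test_that("receptor grids satisfy their sign and disjointness invariants", {
  rec <- make_toy_receptor(fixture_spec(seed = 2))
  spec <- auto_grid_spec(rec, 18, 1.0)
  g <- make_receptor_grids(rec, spec)
  expect_true(all(g$rep >= 0))
  expect_true(all(g$att <= 0))
  expect_true(all(g$rep * g$att == 0))
  expect_true(all(is.finite(g$elec)))
  expect_true(all(g$elec[g$rep > 0] == 0))
  # chargeless receptor -> elec identically zero
  neutral <- rec
  neutral$atoms$code <- "A"
  g2 <- make_receptor_grids(neutral, spec)
  expect_true(all(g2$elec == 0))
  # receptor outside the grid -> fit error
  small <- grid_spec(1.0, c(8, 8, 8), c(0, 0, 0))
  expect_error(make_receptor_grids(rec, small), class = "grid_fit_error")
})

test_that("ligand grids conserve occupancy and respect the grid", {
  frag <- fragment_record("t", "A", 0L, "RALAA",
                          fragdock:::extended_conformer(5L))
  spec <- grid_spec(1.0, c(32, 32, 32), c(-16, -16, -16))
  set.seed(41)
  for (i in 1:5) {
    lg <- make_ligand_grids(frag, random_rotation(), spec)
    expect_equal(sum(lg$occ), 20)
    expect_equal(sum(lg$q), 1)   # single arginine charge at its CA
  }
  lg <- make_ligand_grids(frag, diag(3), spec)
  # centroid maps to the origin voxel: offsets average ~0
  expect_lt(max(abs(colMeans(lg$offsets))), 1)
  tiny <- grid_spec(1.0, c(8, 8, 8), c(-4, -4, -4))
  expect_error(make_ligand_grids(frag, diag(3), tiny),
               class = "grid_fit_error")
})

test_that("a unit-voxel ligand reproduces the receptor field", {
  rec <- make_toy_receptor(fixture_spec(seed = 1))
  spec <- auto_grid_spec(rec, 6, 1.0)
  g <- make_receptor_grids(rec, spec)
  lig <- structure(list(spec = spec, occ = array(0, spec$dims),
                        q = array(0, spec$dims),
                        offsets = matrix(0L, 1, 3), charges = 0,
                        centroid = c(0, 0, 0)),
                   class = "ligand_grids")
  lig$occ[1, 1, 1] <- 1
  s <- correlate(g, lig, weight_set("standard"))
  w <- weight_set("standard")
  expect_equal(s, w$w_rep * g$rep + w$w_att * g$att, tolerance = 1e-9)
})

test_that("FFT correlation equals the direct sum, per term and weighted", {
  set.seed(43)
  for (i in 1:10) {
    dims <- c(8, 8, 8)
    spec <- grid_spec(1.0, dims, c(0, 0, 0))
    g <- structure(list(spec = spec,
                        rep = array(rpois(512, 0.5), dims),
                        att = array(-rpois(512, 1), dims),
                        elec = array(rnorm(512), dims)),
                   class = "energy_grids")
    lig <- structure(list(spec = spec,
                          occ = array(rpois(512, 0.2), dims),
                          q = array(rnorm(512, sd = 0.3), dims),
                          offsets = matrix(0L, 1, 3), charges = 0,
                          centroid = c(0, 0, 0)),
                     class = "ligand_grids")
    w <- structure(list(name = "w", w_rep = runif(1, 0.5, 2),
                        w_att = runif(1, 0.5, 2),
                        w_elec = runif(1, 10, 400)),
                   class = "weight_set")
    direct <- w$w_rep * oracle_direct_correlate(g$rep, lig$occ) +
      w$w_att * oracle_direct_correlate(g$att, lig$occ) +
      w$w_elec * oracle_direct_correlate(g$elec, lig$q)
    got <- correlate(g, lig, w)
    expect_lt(max(abs(got - direct)), 1e-6 * max(abs(direct)))
  }
})

test_that("rotation sets are deterministic, proper and quasi-uniform", {
  r1 <- generate_rotations(1)
  expect_equal(r1$matrices[[1]], diag(3))
  a <- generate_rotations(100, 7)
  b <- generate_rotations(100, 7)
  expect_identical(a$matrices, b$matrices)
  c2 <- generate_rotations(100, 8)
  expect_false(identical(a$matrices, c2$matrices))
  for (m in a$matrices[1:20]) {
    expect_lt(max(abs(crossprod(m) - diag(3))), 1e-8)
    expect_equal(det(m), 1, tolerance = 1e-8)
  }
  big <- generate_rotations(500, 1)
  d <- rotation_distances(big)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.5)
})

test_that("rotation sets round trip through the plain-text format", {
  rs <- generate_rotations(10, 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_rotations(rs, path)
  back <- read_rotations(path)
  expect_equal(back$n, 10L)
  for (i in 1:10)
    expect_equal(back$matrices[[i]], rs$matrices[[i]], tolerance = 1e-10)
})

test_that("dock_fragment honors keep, ordering and score decomposition", {
  cx <- make_planted_complex(fixture_spec(seed = 1))
  spec <- auto_grid_spec(cx$receptor,
                         max(dist(flatten_backbone(cx$fragment$backbone)))
                         + 2, 1.0)
  g <- make_receptor_grids(cx$receptor, spec)
  rots <- generate_rotations(40, 1)
  w <- weight_set("standard")
  poses <- dock_fragment(g, cx$fragment, rots, w, keep = 250L)
  expect_lte(length(poses), 40L)              # at most one per rotation
  e <- vapply(poses, function(p) p$e_total, 0)
  expect_true(all(diff(e) >= 0))              # sorted ascending
  expect_lte(length(dock_fragment(g, cx$fragment, rots, w, keep = 5L)), 5L)
  for (p in poses[1:5]) {
    expect_equal(p$e_total,
                 w$w_rep * p$e_rep + w$w_att * p$e_att +
                   w$w_elec * p$e_elec, tolerance = 1e-9)
    # pose energies match the correlation field value at (rotation, t)
    lig <- make_ligand_grids(cx$fragment, rots$matrices[[p$rotation_index]],
                             spec)
    s <- correlate(g, lig, w)
    expect_equal(p$e_total, s[p$trans_voxel[1] + 1, p$trans_voxel[2] + 1,
                              p$trans_voxel[3] + 1], tolerance = 1e-6)
  }
})

test_that("translating the receptor translates the best pose equally", {
  cx <- make_planted_complex(fixture_spec(seed = 1))
  ext <- max(dist(flatten_backbone(cx$fragment$backbone)))
  # generous padding: the Coulomb neighborhood (12 A) must not clip at the
  # grid boundary, or the shifted grids are no longer exact copies
  spec <- auto_grid_spec(cx$receptor, ext + 30, 1.0)
  g <- make_receptor_grids(cx$receptor, spec)
  rots <- generate_rotations(1)
  p0 <- dock_fragment(g, cx$fragment, rots, keep = 1L)[[1]]
  v <- c(2, 1, 1)
  shifted <- cx$receptor
  shifted$atoms$x <- shifted$atoms$x + v[1] * spec$spacing
  shifted$atoms$y <- shifted$atoms$y + v[2] * spec$spacing
  shifted$atoms$z <- shifted$atoms$z + v[3] * spec$spacing
  g2 <- make_receptor_grids(shifted, spec)
  p1 <- dock_fragment(g2, cx$fragment, rots, keep = 1L)[[1]]
  expect_equal(p1$trans_voxel, p0$trans_voxel + as.integer(v))
  expect_equal(p1$e_total, p0$e_total, tolerance = 1e-9)
})

test_that("the planted pose is recovered at rank one", {
  cx <- make_planted_complex(fixture_spec(seed = 1))
  ext <- max(dist(flatten_backbone(cx$fragment$backbone)))
  spec <- auto_grid_spec(cx$receptor, ext + 2, 1.0)
  g <- make_receptor_grids(cx$receptor, spec)
  rots <- generate_rotations(64, 1)      # identity (true rotation) first
  poses <- dock_fragment(g, cx$fragment, rots, keep = 250L)
  p1 <- poses[[1]]
  expect_equal(p1$rotation_index, 1L)
  truth_bb <- flatten_backbone(cx$fragment$backbone)
  disp <- sqrt(mean(rowSums((pose_backbone(p1, cx$fragment) - truth_bb)^2)))
  expect_lte(disp, spec$spacing * sqrt(3))
})

test_that("dock_library pools per-fragment runs with fragment ids", {
  cx <- make_planted_complex(fixture_spec(seed = 1))
  ext <- max(dist(flatten_backbone(cx$fragment$backbone)))
  spec <- auto_grid_spec(cx$receptor, ext + 2, 1.0)
  g <- make_receptor_grids(cx$receptor, spec)
  rots <- generate_rotations(12, 1)
  recs <- list(cx$fragment,
               fragment_record("t", "A", 0L, "RALAA",
                               fragdock:::kinked_conformer(5L)))
  cs <- cluster_fragments(recs, 0.5, 25L)
  expect_length(cs$clusters, 2L)
  pool <- dock_library(g, cs, rots, keep = 5L)
  expect_lte(length(pool), 10L)
  expect_setequal(unique(vapply(pool, function(p) p$fragment_id, 0L)),
                  c(1L, 2L))
  single <- structure(list(clusters = cs$clusters[1], n_input = 1,
                           radius = 0.5), class = "fragment_cluster_set")
  alone <- dock_library(g, single, rots, keep = 5L)
  one <- dock_fragment(g, cs$clusters[[1]]$center, rots, keep = 5L)
  expect_equal(vapply(alone, function(p) p$e_total, 0),
               vapply(one, function(p) p$e_total, 0))
})
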