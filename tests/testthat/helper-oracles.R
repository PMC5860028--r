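# Independent oracles used across the suite. Each is a deliberately plain
# reimplementation, kept free of the package's code paths it checks.

# direct (non-FFT) circular cross-correlation: S(t) = sum_x F(x) L(x - t)
oracle_direct_correlate <- function(f, l) {
  d <- dim(f)
  out <- array(0, d)
  for (t1 in 0:(d[1] - 1)) for (t2 in 0:(d[2] - 1)) for (t3 in 0:(d[3] - 1)) {
    sh <- l[((0:(d[1] - 1) - t1) %% d[1]) + 1,
            ((0:(d[2] - 1) - t2) %% d[2]) + 1,
            ((0:(d[3] - 1) - t3) %% d[3]) + 1]
    out[t1 + 1, t2 + 1, t3 + 1] <- sum(f * sh)
  }
  out
}

# plain greedy radius clustering, written independently of greedy_cluster()
oracle_greedy <- function(d, radius) {
  n <- nrow(d)
  alive <- seq_len(n)
  res <- list()
  while (length(alive) > 0) {
    best_i <- NA; best_count <- -1
    for (i in alive) {
      cnt <- sum(d[i, alive] <= radius)
      if (cnt > best_count) { best_count <- cnt; best_i <- i }
    }
    members <- alive[d[best_i, alive] <= radius]
    res[[length(res) + 1]] <- list(center = best_i, members = members)
    alive <- setdiff(alive, members)
  }
  res
}

# brute-force minimal RMSD: coarse Euler-angle scan then Nelder-Mead polish
oracle_min_rmsd <- function(a, b) {
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(ang) sqrt(mean(rowSums((ac %*% t(rot_euler(ang)) - bc)^2)))
  grid <- seq(0, 2 * pi - 0.35, by = 0.35)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (u in grid) for (v in seq(0, pi, by = 0.35)) for (w in grid) {
    val <- obj(c(u, v, w))
    if (val < best) { best <- val; best_ang <- c(u, v, w) }
  }
  opt <- optim(best_ang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  opt$value
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# small straight-chain structure with full backbones, for I/O tests
toy_chain <- function(codes, chain_id = "A", bfactors = NULL,
                      drop_atom = NULL) {
  n <- length(codes)
  if (is.null(bfactors)) bfactors <- rep(20, n)
  rows <- lapply(seq_len(n), function(i) {
    names <- c("N", "CA", "C", "O")
    off <- rbind(c(-0.93, 1.08, 0), c(0, 0, 0), c(1.26, 0.85, 0),
                 c(1.88, 1.94, 0))
    keep <- if (!is.null(drop_atom) && i %in% drop_atom$res)
      names != drop_atom$name else rep(TRUE, 4)
    data.frame(res_index = i - 1L, code = codes[i], seq_index = i,
               ins = "", name = names[keep],
               element = substr(names[keep], 1, 1),
               x = 3.5 * (i - 1) + off[keep, 1], y = off[keep, 2],
               z = off[keep, 3],
               occupancy = 1, bfactor = bfactors[i],
               stringsAsFactors = FALSE)
  })
  chain_structure(chain_id, do.call(rbind, rows), source_id = "toy")
}

# a quick dock pose at an explicit placement, for select-stage tests
pose_at <- function(rotation, translation, e_total = 0, fragment_id = 1L,
                    rotation_index = 1L) {
  dock_pose(fragment_id, rotation_index, c(0L, 0L, 0L),
            rigid_transform(rotation, translation),
            e_rep = 0, e_att = e_total, e_elec = 0, e_total = e_total)
}
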