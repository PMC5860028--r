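# Quasi-uniform rotational sampling.
#
# Rotations are generated from a low-discrepancy (radical-inverse / Halton)
# point set on the unit cube mapped to unit quaternions by Shoemake's
# subgroup algorithm, which yields a quasi-uniform cover of SO(3). The seed
# applies a Cranley-Patterson shift to the sequence, so different seeds give
# different but equally uniform sets and identical (n, seed) pairs reproduce
# bit-identical rotations. The identity is always the first element.

radical_inverse <- function(i, base) {
  f <- 1 / base; r <- 0
  while (i > 0) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Generate a deterministic quasi-uniform rotation set
#'
#' @param n number of rotations (>= 1); the first is always the identity.
#' @param seed integer seed; same `(n, seed)` gives identical rotations.
#' @return a `rotation_set`: list with `matrices` (list of 3x3 proper
#'   rotations), `quaternions` (`n x 4`, x/y/z/w), `n`, `seed`.
#' @export
generate_rotations <- function(n, seed = 1L) {
  stopifnot(is_count(n), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(as.integer(seed))
  shift <- runif(3)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  quats <- matrix(0, n, 4)
  quats[1, ] <- c(0, 0, 0, 1)
  mats <- vector("list", n)
  mats[[1]] <- diag(3)
  bases <- c(2L, 3L, 5L)
  for (i in seq_len(n - 1L)) {
    u <- vapply(1:3, function(j)
      (radical_inverse(i, bases[j]) + shift[j]) %% 1, 0)
    r1 <- sqrt(1 - u[1]); r2 <- sqrt(u[1])
    t1 <- 2 * pi * u[2]; t2 <- 2 * pi * u[3]
    q <- c(sin(t1) * r1, cos(t1) * r1, sin(t2) * r2, cos(t2) * r2)
    quats[i + 1L, ] <- q
    mats[[i + 1L]] <- quat_to_matrix(q)
  }
  structure(list(matrices = mats, quaternions = quats, n = n,
                 seed = as.integer(seed)),
            class = "rotation_set")
}

#' Angular distance between rotations of a rotation set
#'
#' @param rotset a `rotation_set`.
#' @return `n x n` matrix of rotation angles in radians.
#' @export
rotation_distances <- function(rotset) {
  q <- rotset$quaternions
  dots <- abs(q %*% t(q))
  dots[dots > 1] <- 1
  2 * acos(dots)
}

#' Write / read a rotation set as plain text
#'
#' One rotation per line, nine row-major matrix entries.
#' @param rotset a `rotation_set`.
#' @param path file path.
#' @return invisibly, `path` (write) or a `rotation_set` (read; the
#'   quaternions are reconstructed from the matrices).
#' @export
write_rotations <- function(rotset, path) {
  lines <- vapply(rotset$matrices, function(m)
    paste(sprintf("%.12f", as.vector(t(m))), collapse = " "), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rotations
#' @export
read_rotations <- function(path) {
  lines <- readLines(path)
  mats <- lapply(lines, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != 9L)
      stop_fragdock("rotation line must have 9 numbers", "validation_error")
    matrix(v, 3, 3, byrow = TRUE)
  })
  quats <- t(vapply(mats, matrix_to_quat, numeric(4)))
  structure(list(matrices = mats, quaternions = quats, n = length(mats),
                 seed = NA_integer_),
            class = "rotation_set")
}

matrix_to_quat <- function(m) {
  w <- sqrt(max(0, 1 + m[1, 1] + m[2, 2] + m[3, 3])) / 2
  if (w > 1e-8) {
    x <- (m[3, 2] - m[2, 3]) / (4 * w)
    y <- (m[1, 3] - m[3, 1]) / (4 * w)
    z <- (m[2, 1] - m[1, 2]) / (4 * w)
  } else {
    x <- sqrt(max(0, 1 + m[1, 1] - m[2, 2] - m[3, 3])) / 2
    y <- sign(m[1, 2]) * sqrt(max(0, 1 - m[1, 1] + m[2, 2] - m[3, 3])) / 2
    z <- sign(m[1, 3]) * sqrt(max(0, 1 - m[1, 1] - m[2, 2] + m[3, 3])) / 2
  }
  q <- c(x, y, z, w)
  q / sqrt(sum(q^2))
}
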