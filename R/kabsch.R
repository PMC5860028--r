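# Optimal rigid superposition (Kabsch, SVD form with reflection correction)
# and the backbone RMSD metrics used throughout the protocol.

#' Optimal rigid superposition of two point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% a + t` onto `b` (SVD solution with determinant correction so that
#' reflections are never returned).
#'
#' @param a,b `n x 3` coordinate matrices in correspondence, `n >= 3`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
kabsch_fit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.matrix(a) || ncol(a) != 3L || !identical(dim(a), dim(b)))
    stop_fragdock("coordinate sets must be n x 3 of equal size",
                  "validation_error")
  if (nrow(a) < 3L)
    stop_fragdock("need at least 3 points", "validation_error")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  h <- crossprod(ac, bc)                 # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- ac %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - bc)^2)))
  list(rotation = rot, translation = as.numeric(cb - rot %*% ca),
       rmsd = rmsd)
}

#' Minimal RMSD under optimal superposition
#'
#' @param a,b `n x 3` coordinate matrices (or `L x 4 x 3` backbone arrays,
#'   which are flattened residue-major in atom order N, CA, C, O).
#' @return minimal RMSD in Angstrom over all proper rigid motions.
#' @export
kabsch_rmsd <- function(a, b) {
  kabsch_fit(flatten_backbone(a), flatten_backbone(b))$rmsd
}

#' Flatten a backbone array to an atom coordinate matrix
#' @param x an `L x 4 x 3` array or an `n x 3` matrix (returned unchanged).
#' @return `(4L) x 3` matrix, residue-major, atoms in order N, CA, C, O.
#' @export
flatten_backbone <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) != 3L || d[2] != 4L || d[3] != 3L)
    stop_fragdock("expected an L x 4 x 3 backbone array", "validation_error")
  out <- matrix(NA_real_, d[1] * 4L, 3L)
  for (i in seq_len(d[1])) out[(i - 1L) * 4L + 1:4, ] <- x[i, , ]
  out
}

#' Construct and validate a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix (det +1 within 1e-8).
#' @param translation length-3 numeric vector, Angstrom.
#' @return a `rigid_transform` list.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)))
    stop_fragdock("rotation must be 3x3", "validation_error")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop_fragdock("rotation is not proper orthonormal", "validation_error")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param coords `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}
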