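#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft quantile rnorm runif setNames sd optim dist
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
         X = "UNK")

AA3TO1 <- setNames(names(AA3)[1:20], AA3[1:20])

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

stop_fragdock <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "fragdock_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x)

#' Smallest FFT-friendly integer
#'
#' Returns the smallest integer `>= n` whose prime factors are all in
#' {2, 3, 5}, the sizes for which the FFT is fastest.
#'
#' @param n lower bound (positive integer).
#' @return an integer `>= n` with only 2/3/5 prime factors.
#' @keywords internal
smooth235 <- function(n) {
  n <- as.integer(ceiling(n))
  if (n < 1L) return(1L)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}
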