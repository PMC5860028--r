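# Linear-motif handling: pattern compilation, wildcard matching, the
# sequence-identity exclusion filter, fragment harvesting and the iterative
# library-size control (generalize / restrict) loop.

#' Compile a motif string
#'
#' A motif is written over the 20 one-letter amino-acid codes plus "X", the
#' wildcard that matches any residue (e.g. "RXL", the cyclin-binding motif).
#'
#' @param text nonempty motif string.
#' @param origin provenance tag ("user", "expanded", "generalized",
#'   "restricted").
#' @return a `motif_pattern`: character vector of positions ("X" = wildcard)
#'   with attributes `origin` and `original` (logical, TRUE where the
#'   position came from the user's motif).
#' @export
compile_motif <- function(text, origin = "user") {
  if (!is.character(text) || length(text) != 1L || nchar(text) == 0L)
    stop_fragdock("motif must be a nonempty string", "validation_error")
  pos <- strsplit(text, "")[[1]]
  bad <- !(pos %in% c(AA1, "X"))
  if (any(bad))
    stop_fragdock(sprintf("illegal motif character(s): %s",
                          paste(unique(pos[bad]), collapse = ", ")),
                  "validation_error")
  structure(pos, origin = origin, original = rep(TRUE, length(pos)),
            class = "motif_pattern")
}

#' Render a motif pattern back to its string form
#' @param pattern a `motif_pattern`.
#' @return single string, "X" at wildcard positions.
#' @export
render_motif <- function(pattern) paste(unclass(pattern), collapse = "")

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern %s (%s)>\n", render_motif(x),
              attr(x, "origin")))
  invisible(x)
}

#' Find motif matches in a sequence
#'
#' Reports every 0-based start position at which all fixed positions of the
#' pattern agree with the sequence; wildcards match anything and overlapping
#' matches are all reported.
#'
#' @param pattern a `motif_pattern`.
#' @param sequence one-letter amino-acid string.
#' @return integer vector of 0-based start positions (possibly empty).
#' @export
find_matches <- function(pattern, sequence) {
  L <- length(pattern)
  s <- strsplit(sequence, "")[[1]]
  nw <- length(s) - L + 1L
  if (nw < 1L) return(integer(0))
  ok <- rep(TRUE, nw)
  for (k in seq_len(L)) {
    if (pattern[k] == "X") next
    ok <- ok & s[k:(k + nw - 1L)] == pattern[k]
  }
  which(ok) - 1L
}

# Global (Needleman-Wunsch) alignment with match +1, mismatch 0, linear gap
# -1; traceback prefers diagonal, then up (gap in b), then left. Returns the
# optimal score and the number of identical aligned positions.
nw_align <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  for (i in seq_len(n)) {
    diag_add <- (av[i] == bv) + 0
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + diag_add[j],
                               S[i, j + 1L] - 1,
                               S[i + 1L, j] - 1)
    }
  }
  i <- n; j <- m; matches <- 0L
  while (i > 0L && j > 0L) {
    here <- S[i + 1L, j + 1L]
    if (here == S[i, j] + (av[i] == bv[j])) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (here == S[i, j + 1L] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = S[n + 1L, m + 1L], matches = matches)
}

#' Pairwise sequence identity
#'
#' Identity is the number of identical aligned positions in a global
#' alignment (match +1, mismatch 0, linear gap penalty -1) divided by the
#' length of the shorter sequence. Symmetric by construction.
#'
#' @param a,b nonempty one-letter sequences.
#' @return identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b))
    stop_fragdock("sequences must be nonempty", "validation_error")
  nw_align(a, b)$matches / min(nchar(a), nchar(b))
}

#' Exclude database chains similar to the target
#'
#' Removes any chain with more than `threshold` sequence identity to any of
#' the supplied target sequences, preventing the fragment search from simply
#' rediscovering the target's own structure. Order is preserved.
#'
#' @param chains list of `chain_structure`.
#' @param target_sequences character vector of target sequences (receptor
#'   and/or peptide parent; all supplied sequences are compared).
#' @param threshold exclusion threshold in (0, 1]; default 0.30.
#' @return the surviving chains, in input order.
#' @export
filter_by_identity <- function(chains, target_sequences, threshold = 0.30) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  if (length(target_sequences) == 0L) return(chains)
  keep <- vapply(chains, function(ch) {
    s <- chain_sequence(ch)
    if (!nzchar(s)) return(TRUE)
    all(vapply(target_sequences,
               function(t) sequence_identity(s, t) <= threshold, TRUE))
  }, TRUE)
  chains[keep]
}

#' Harvest backbone fragments at motif matches
#'
#' Scans every chain for pattern matches and extracts the backbone window at
#' each match. Matches whose window contains a backbone-incomplete residue
#' are skipped silently; the skip count is attached as attribute
#' `n_skipped`.
#'
#' @param pattern a `motif_pattern`.
#' @param chains list of `chain_structure`.
#' @return list of `fragment_record` with attribute `n_skipped`.
#' @export
harvest_fragments <- function(pattern, chains) {
  records <- list()
  skipped <- 0L
  L <- length(pattern)
  for (ch in chains) {
    seq <- chain_sequence(ch)
    for (p in find_matches(pattern, seq)) {
      bb <- tryCatch(extract_backbone(ch, p, L),
                     fragdock_error = function(e) NULL)
      if (is.null(bb)) { skipped <- skipped + 1L; next }
      records[[length(records) + 1L]] <- fragment_record(
        source_id = ch$source_id, chain_id = ch$chain_id, start = p,
        sequence = substr(seq, p + 1L, p + L), backbone = bb)
    }
  }
  attr(records, "n_skipped") <- skipped
  records
}

#' Construct a fragment record
#'
#' @param source_id,chain_id provenance of the source chain.
#' @param start 0-based residue index of the match.
#' @param sequence matched residue codes (length = backbone rows).
#' @param backbone `L x 4 x 3` backbone coordinate array (N, CA, C, O).
#' @return a `fragment_record`.
#' @export
fragment_record <- function(source_id, chain_id, start, sequence, backbone) {
  if (nchar(sequence) != dim(backbone)[1])
    stop_fragdock("sequence length != backbone length", "validation_error")
  if (!all(is.finite(backbone)))
    stop_fragdock("non-finite backbone coordinates", "validation_error")
  structure(list(source_id = source_id, chain_id = chain_id,
                 start = as.integer(start), sequence = sequence,
                 backbone = backbone),
            class = "fragment_record")
}

# Pad a short motif with wildcards up to min_len. Wildcards are added in
# pairs, C-terminal side first, then alternating sides pairwise (so "RXL"
# with min_len 5 becomes "RXLXX").
pad_motif <- function(pattern, min_len) {
  k <- min_len - length(pattern)
  if (k <= 0L) return(pattern)
  ends <- vapply(seq_len(k), function(i)
    if (((i - 1L) %/% 2L) %% 2L == 0L) "C" else "N", "")
  n_c <- sum(ends == "C"); n_n <- k - n_c
  pos <- c(rep("X", n_n), unclass(pattern), rep("X", n_c))
  orig <- c(rep(FALSE, n_n), attr(pattern, "original"), rep(FALSE, n_c))
  structure(pos, origin = "expanded", original = orig,
            class = "motif_pattern")
}

# One GENERALIZE move: turn the outermost non-original fixed position into a
# wildcard; failing that, turn the original fixed position whose residue is
# least frequent in the database into a wildcard, but never drop below two
# fixed positions. Returns NULL when no move is available.
generalize_motif <- function(pattern, aa_freq) {
  pos <- unclass(pattern)
  orig <- attr(pattern, "original")
  fixed <- which(pos != "X")
  added <- fixed[!orig[fixed]]
  if (length(added) > 0L) {
    # outermost: greatest distance to the nearest sequence end, inverted --
    # i.e. the added fixed position closest to either terminus; C side wins
    # ties (restriction appended C first, so it is undone first)
    dist_end <- pmin(added - 1L, length(pos) - added)
    cand <- added[dist_end == min(dist_end)]
    k <- cand[length(cand)]
  } else {
    if (length(fixed) <= 2L) return(NULL)
    f <- aa_freq[pos[fixed]]
    f[is.na(f)] <- 0
    k <- fixed[which.min(f)]
  }
  pos[k] <- "X"
  structure(pos, origin = "generalized", original = orig,
            class = "motif_pattern")
}

# One RESTRICT move: extend the pattern by one fixed position copied from
# the peptide's real flanking sequence, alternating C-terminal then
# N-terminal. `context` is the full peptide sequence, `offset` the 0-based
# position of the current pattern within it. Returns NULL when both flanks
# are exhausted or no context was supplied.
restrict_motif <- function(pattern, context, offset, prefer = "C") {
  if (is.null(context)) return(NULL)
  pos <- unclass(pattern)
  orig <- attr(pattern, "original")
  L <- length(pos)
  c_next <- offset + L        # 0-based index of the next C-flank residue
  n_next <- offset - 1L
  can_c <- c_next <= nchar(context) - 1L
  can_n <- n_next >= 0L
  side <- if (prefer == "C" && can_c) "C"
          else if (prefer == "N" && can_n) "N"
          else if (can_c) "C" else if (can_n) "N" else NA
  if (is.na(side)) return(NULL)
  if (side == "C") {
    res <- substr(context, c_next + 1L, c_next + 1L)
    pos <- c(pos, res); orig <- c(orig, FALSE)
    off <- offset
  } else {
    res <- substr(context, n_next + 1L, n_next + 1L)
    pos <- c(res, pos); orig <- c(FALSE, orig)
    off <- offset - 1L
  }
  structure(pos, origin = "restricted", original = orig,
            class = "motif_pattern", offset = off, side = side)
}

#' Build a motif fragment library of controlled size
#'
#' Implements the iterative library-size control: after excluding database
#' chains with more than `identity_threshold` identity to the target, the
#' motif is padded with wildcards to `min_len` residues, then repeatedly
#' adjusted until its match count over the database falls inside
#' `[low, high]`: too many matches trigger a RESTRICT move (extend the
#' pattern by one fixed residue taken from the peptide's real flanking
#' sequence, alternating C- then N-terminal), too few a GENERALIZE move
#' (convert a fixed position to a wildcard; added positions first, then the
#' least frequent original residue, never below two fixed positions). The
#' loop stops when the count is in range, no move is available, or
#' `max_iter` iterations have run; fragments are then harvested with the
#' final pattern.
#'
#' @param motif motif string (e.g. "RXL").
#' @param chains database chains (list of `chain_structure`).
#' @param target_sequences sequences driving the identity exclusion.
#' @param low,high target library size window (default 100-1000).
#' @param min_len minimum pattern length; shorter motifs are padded with
#'   wildcards (default 5).
#' @param max_iter iteration cap (default 20).
#' @param identity_threshold exclusion threshold (default 0.30).
#' @param peptide_context full peptide sequence containing the motif;
#'   required for RESTRICT moves.
#' @param motif_offset 0-based position of `motif` inside `peptide_context`.
#' @return a `fragment_library`: list with `pattern_final`, `records` and
#'   `history` (data.frame of pattern rendering and match count per
#'   iteration).
#' @export
build_library <- function(motif, chains, target_sequences = character(0),
                          low = 100L, high = 1000L, min_len = 5L,
                          max_iter = 20L, identity_threshold = 0.30,
                          peptide_context = NULL, motif_offset = 0L) {
  stopifnot(low < high, is_count(min_len), is_count(max_iter))
  pattern <- compile_motif(motif)
  chains <- filter_by_identity(chains, target_sequences,
                               identity_threshold)
  pattern <- pad_motif(pattern, min_len)
  seqs <- vapply(chains, chain_sequence, "")
  aa_freq <- table(factor(unlist(strsplit(seqs, "")), levels = AA1))
  aa_freq <- as.numeric(aa_freq) / max(1, sum(aa_freq))
  names(aa_freq) <- AA1
  count_matches <- function(p)
    sum(vapply(seqs, function(s) length(find_matches(p, s)), 0L))
  offset <- motif_offset
  prefer <- "C"
  history <- data.frame(pattern = character(0), matches = integer(0),
                        stringsAsFactors = FALSE)
  for (iter in seq_len(max_iter)) {
    n <- count_matches(pattern)
    history <- rbind(history,
                     data.frame(pattern = render_motif(pattern), matches = n,
                                stringsAsFactors = FALSE))
    if (n >= low && n <= high) break
    if (n > high) {
      nxt <- restrict_motif(pattern, peptide_context, offset, prefer)
      if (is.null(nxt)) break
      offset <- attr(nxt, "offset")
      prefer <- if (attr(nxt, "side") == "C") "N" else "C"
      pattern <- nxt
    } else {
      nxt <- generalize_motif(pattern, aa_freq)
      if (is.null(nxt)) break
      pattern <- nxt
    }
  }
  if (render_motif(pattern) != history$pattern[nrow(history)]) {
    history <- rbind(history,
                     data.frame(pattern = render_motif(pattern),
                                matches = count_matches(pattern),
                                stringsAsFactors = FALSE))
  }
  final_n <- history$matches[nrow(history)]
  if (final_n == 0L) {
    cond <- structure(
      class = c("empty_library_error", "fragdock_error", "error",
                "condition"),
      list(message = "no motif matches after all generalization moves",
           call = sys.call(), history = history))
    stop(cond)
  }
  records <- harvest_fragments(pattern, chains)
  structure(list(pattern_final = pattern, records = records,
                 history = history),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library %s: %d fragments, %d iteration(s)>\n",
              render_motif(x$pattern_final), length(x$records),
              nrow(x$history)))
  invisible(x)
}
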