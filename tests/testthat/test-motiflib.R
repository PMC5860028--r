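test_that("motif compilation handles wildcards and rejects bad characters", {
  p <- compile_motif("RXL")
  expect_s3_class(p, "motif_pattern")
  expect_equal(as.character(p), c("R", "X", "L"))
  expect_equal(render_motif(p), "RXL")
  expect_equal(sum(unclass(compile_motif("KGRRL")) != "X"), 5L)
  expect_error(compile_motif("B1Z"), class = "validation_error")
  expect_error(compile_motif(""), class = "validation_error")
})

test_that("find_matches reports all overlapping wildcard matches", {
  expect_equal(find_matches(compile_motif("RXL"), "ARALKRKLQ"), c(1L, 5L))
  expect_equal(find_matches(compile_motif("KGRRL"), "AAARRLAAA"), integer(0))
  expect_equal(find_matches(compile_motif("XX"), "AAA"), c(0L, 1L))
  expect_equal(find_matches(compile_motif("AAAA"), "AA"), integer(0))
})

test_that("find_matches equals a per-window brute-force scan", {
  set.seed(11)
  ab <- c("A", "R", "L", "G", "S")
  for (rep in 1:300) {
    L <- sample(2:5, 1)
    pat_chars <- sample(c(ab, "X", "X"), L, replace = TRUE)
    seqv <- sample(ab, sample(5:25, 1), replace = TRUE)
    pat <- compile_motif(paste(pat_chars, collapse = ""))
    brute <- integer(0)
    for (p in 0:(length(seqv) - L)) {
      ok <- TRUE
      for (k in seq_len(L)) {
        if (pat_chars[k] != "X" && seqv[p + k] != pat_chars[k]) ok <- FALSE
      }
      if (ok) brute <- c(brute, p)
    }
    expect_equal(find_matches(pat, paste(seqv, collapse = "")), brute)
  }
})

test_that("sequence identity follows the global-alignment definition", {
  expect_equal(sequence_identity("KGRRL", "KGRRL"), 1.0)
  expect_equal(sequence_identity("AAAA", "AAAT"), 0.75)
  expect_error(sequence_identity("", "A"), class = "validation_error")
  set.seed(13)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(AA, 30, TRUE), collapse = "")
    b <- paste(sample(AA, sample(20:35, 1), TRUE), collapse = "")
    expect_equal(sequence_identity(a, b), sequence_identity(b, a))
    expect_gte(sequence_identity(a, b), 0)
    expect_lte(sequence_identity(a, b), 1)
  }
})

test_that("identity matches the independent Biostrings alignment", {
  library(Biostrings)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(0, 20, 20, dimnames = list(AA, AA)); diag(mat) <- 1
  set.seed(7)
  for (i in 1:15) {
    a <- paste(sample(AA, 30, TRUE), collapse = "")
    b <- paste(sample(AA, 30, TRUE), collapse = "")
    aln <- pairwiseAlignment(a, b, substitutionMatrix = mat,
                             gapOpening = 0, gapExtension = 1,
                             type = "global")
    mine <- fragdock:::nw_align(a, b)
    expect_equal(mine$score, score(aln))
    expect_equal(mine$matches / 30, nmatch(aln) / 30)
  }
})

test_that("identity filter removes homologs and keeps unrelated chains", {
  set.seed(17)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  target <- paste(sample(AA, 40, TRUE), collapse = "")
  dup <- toy_chain(strsplit(target, "")[[1]])
  unrelated <- toy_chain(sample(AA, 40, TRUE))
  expect_gt(sequence_identity(chain_sequence(dup), target), 0.30)
  expect_lte(sequence_identity(chain_sequence(unrelated), target), 0.30)
  kept <- filter_by_identity(list(dup, unrelated), target)
  expect_length(kept, 1L)
  expect_equal(chain_sequence(kept[[1]]), chain_sequence(unrelated))
  # strict inequality: threshold 1.0 removes nothing, even duplicates
  expect_length(filter_by_identity(list(dup, unrelated), target, 1.0), 2L)
})

test_that("harvest_fragments extracts planted windows and tallies skips", {
  sp <- fixture_spec(seed = 2, n_db_chains = 5L, planted_matches = 7L)
  db <- make_fragment_database(sp)
  pat <- fragdock:::pad_motif(compile_motif(sp$motif), 5L)
  recs <- harvest_fragments(pat, db)
  expect_length(recs, 7L)
  expect_equal(attr(recs, "n_skipped"), 0L)
  for (r in recs) {
    expect_equal(nchar(r$sequence), 5L)
    expect_equal(length(find_matches(pat, r$sequence)), 1L)
  }
  # a match window overlapping a backbone-incomplete residue is skipped
  broken <- toy_chain(strsplit("AARALAA", "")[[1]],
                      drop_atom = list(res = 4, name = "O"))
  recs2 <- harvest_fragments(pat, list(broken))
  expect_length(recs2, 0L)
  expect_equal(attr(recs2, "n_skipped"), 1L)
  expect_length(harvest_fragments(pat, list()), 0L)
})

test_that("short motifs are padded to the minimum length, C pair first", {
  expect_equal(render_motif(fragdock:::pad_motif(compile_motif("RXL"), 5L)),
               "RXLXX")
  expect_equal(render_motif(fragdock:::pad_motif(compile_motif("KGRR"), 5L)),
               "KGRRX")
  expect_equal(render_motif(fragdock:::pad_motif(compile_motif("RL"), 5L)),
               "XRLXX")
  expect_equal(render_motif(fragdock:::pad_motif(compile_motif("KGRRL"), 5L)),
               "KGRRL")
})

test_that("build_library stops immediately when the count is in range", {
  fx <- make_library_fixture("in_range", seed = 1)
  lib <- build_library(fx$motif, fx$chains,
                       peptide_context = fx$peptide_context,
                       motif_offset = fx$motif_offset)
  expect_equal(nrow(lib$history), 1L)
  expect_equal(lib$history$matches, 150L)
  expect_length(lib$records, 150L)
  expect_equal(render_motif(lib$pattern_final), "RXLXX")
})

test_that("build_library generalizes an undersized motif into range", {
  fx <- make_library_fixture("generalize", seed = 1)
  lib <- build_library(fx$motif, fx$chains,
                       peptide_context = fx$peptide_context,
                       motif_offset = fx$motif_offset)
  expect_equal(lib$history$matches, c(50L, 150L))
  expect_equal(lib$history$pattern, c("KGRRL", "KXRRL"))
  expect_length(lib$records, 150L)
})

test_that("build_library restricts an oversized motif using the flank", {
  fx <- make_library_fixture("restrict", seed = 1)
  lib <- build_library(fx$motif, fx$chains,
                       peptide_context = fx$peptide_context,
                       motif_offset = fx$motif_offset)
  expect_equal(lib$history$matches, c(1200L, 300L))
  expect_equal(lib$history$pattern, c("RXLXX", "RXLXXW"))
  expect_length(lib$records, 300L)
})

test_that("an unmatchable motif raises an empty-library error with history", {
  db <- list(toy_chain(rep("A", 30)))
  err <- tryCatch(build_library("WW", db), empty_library_error = identity)
  expect_s3_class(err, "empty_library_error")
  expect_true(is.data.frame(err$history))
  expect_equal(err$history$matches[nrow(err$history)], 0L)
})

test_that("kabsch_rmsd is zero under rigid motion and matches brute force", {
  set.seed(23)
  a <- matrix(rnorm(15, sd = 3), 5, 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  th <- pi / 2
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  b <- sweep(a %*% t(rz), 2, c(10, -2, 3), "+")
  expect_lt(kabsch_rmsd(a, b), 1e-8)
  for (i in 1:3) {
    p <- matrix(rnorm(15, sd = 2), 5, 3)
    q <- matrix(rnorm(15, sd = 2), 5, 3)
    expect_equal(kabsch_rmsd(p, q), oracle_min_rmsd(p, q),
                 tolerance = 1e-3)
    expect_equal(kabsch_rmsd(p, q), kabsch_rmsd(q, p), tolerance = 1e-9)
    # invariant under a rigid motion of either argument
    rr <- random_rotation()
    q2 <- sweep(q %*% t(rr), 2, rnorm(3, sd = 5), "+")
    expect_equal(kabsch_rmsd(p, q2), kabsch_rmsd(p, q), tolerance = 1e-9)
  }
  expect_error(kabsch_rmsd(a[1:2, ], a[1:2, ]), class = "validation_error")
})

test_that("kabsch_rmsd agrees with the bio3d fitted RMSD", {
  set.seed(29)
  for (i in 1:5) {
    p <- matrix(rnorm(24, sd = 2), 8, 3)
    q <- p + matrix(rnorm(24, sd = 0.4), 8, 3)
    ref <- bio3d::rmsd(as.vector(t(p)), as.vector(t(q)), fit = TRUE)
    # bio3d rounds its RMSD to three decimals
    expect_lt(abs(kabsch_rmsd(p, q) - ref), 6e-4)
  }
})

test_that("fragment clustering follows the greedy rule and the cap", {
  ext <- fragdock:::extended_conformer(5L)
  kink <- fragdock:::kinked_conformer(5L)
  expect_gt(kabsch_rmsd(ext, kink), 0.5)
  mk <- function(bb, n) lapply(seq_len(n), function(i)
    fragment_record("t", "A", 0L, "RALAA", bb))
  recs <- c(mk(ext, 30), mk(kink, 5))
  cs <- cluster_fragments(recs, 0.5, 25L)
  expect_equal(vapply(cs$clusters, function(c) c$member_count, 0L),
               c(30L, 5L))
  expect_equal(cs$clusters[[1]]$center_index, 1L)   # tie-break lowest index

  # 26 mutually distant conformations -> cap at 25 singletons
  set.seed(31)
  far <- lapply(1:26, function(i) {
    bb <- ext + array(rnorm(60, sd = 3), dim(ext))
    fragment_record("t", "A", 0L, "RALAA", bb)
  })
  d <- outer(seq_along(far), seq_along(far), Vectorize(function(i, j)
    kabsch_rmsd(far[[i]]$backbone, far[[j]]$backbone)))
  expect_true(all(d[upper.tri(d)] > 0.5))
  cs2 <- cluster_fragments(far, 0.5, 25L)
  expect_length(cs2$clusters, 25L)
  expect_true(all(vapply(cs2$clusters, function(c) c$member_count, 0L) == 1L))
})

test_that("greedy fragment clustering matches the independent oracle", {
  set.seed(37)
  ext <- fragdock:::extended_conformer(5L)
  for (case in 1:3) {
    recs <- lapply(1:40, function(i) fragment_record(
      "t", "A", 0L, "RALAA", ext + array(rnorm(60, sd = 0.3), dim(ext))))
    n <- length(recs)
    d <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- kabsch_rmsd(recs[[i]]$backbone,
                                        recs[[j]]$backbone)
    got <- greedy_cluster(d, 0.5)
    want <- oracle_greedy(d, 0.5)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$center, want[[k]]$center)
      expect_equal(sort(got[[k]]$members), sort(want[[k]]$members))
    }
    # retained centers pairwise exceed the radius
    centers <- vapply(got, function(c) c$center, 0L)
    if (length(centers) > 1)
      expect_true(all(d[centers, centers][upper.tri(diag(length(centers)))]
                      > 0.5))
  }
})
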