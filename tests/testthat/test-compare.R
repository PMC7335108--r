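test_that("osa_distance handles the canonical edit cases", {
  expect_equal(osa_distance(c("A", "B"), c("A", "B")), 0L)
  # adjacent transposition costs one
  expect_equal(osa_distance(c("GH136_I", "GH136_II"),
                            c("GH136_II", "GH136_I")), 1L)
  # the restricted variant may not edit a transposed substring again:
  # CA -> AC -> ABC is illegal, so the distance is 3, not 2
  expect_equal(osa_distance(c("C", "A"), c("A", "B", "C")), 3L)
  expect_equal(r_dl_unrestricted(c("C", "A"), c("A", "B", "C")), 2L)
  expect_equal(osa_distance(character(0), c("A", "B", "C")), 3L)
  # multi-token symbols must not alias through concatenation
  expect_equal(osa_distance(c("GH1", "12"), c("GH112")), 2L)
})

test_that("osa_distance equals the recursive oracle on random strings", {
  set.seed(13)
  for (rep in 1:150) {
    s <- random_token_string(6)
    t <- random_token_string(6)
    d <- osa_distance(s, t)
    expect_identical(d, as.integer(r_osa(s, t)))
    # elementary bounds and symmetry
    expect_gte(d, abs(length(s) - length(t)))
    expect_lte(d, max(length(s), length(t)))
    expect_identical(osa_distance(t, s), d)
    expect_identical(osa_distance(s, s), 0L)
  }
})

test_that("landscape distance matrices are symmetric with zero diagonal", {
  mk <- function(tokens, id) tibble::tibble(
    genome_id = id, anchor_gene_id = "a", window = 11L,
    anchor_index = 1L, tokens = list(tokens),
    trunc_upstream = FALSE, trunc_downstream = FALSE)
  tpl <- locus_templates()$compact
  landscapes <- dplyr::bind_rows(
    mk(tpl, "g1"), mk(tpl, "g2"), mk(tpl, "g3"),
    mk(tpl[-2], "g4"))  # one deleted gene
  D <- landscape_distance_matrix(landscapes)
  expect_true(all(D == t(D)))
  expect_true(all(diag(D) == 0))
  expect_equal(D["g1:a", "g2:a"], 0L)
  expect_equal(D["g1:a", "g4:a"], 1L)  # single deletion

  # OTHER tokens can be excluded from the comparison
  with_other <- dplyr::bind_rows(mk(c(tpl, "OTHER"), "g5"), mk(tpl, "g6"))
  expect_equal(landscape_distance_matrix(with_other)["g5:a", "g6:a"], 1L)
  expect_equal(
    landscape_distance_matrix(with_other, include_other = FALSE)["g5:a", "g6:a"],
    0L)
})

test_that("pcoa reproduces Euclidean geometry", {
  # two items at distance d separate by exactly d on axis 1
  D <- matrix(c(0, 7.5, 7.5, 0), 2)
  ord <- pcoa(D, k = 1)
  expect_equal(as.numeric(abs(ord$points[1, 1] - ord$points[2, 1])), 7.5)

  # unit-square corners reconstruct their distances
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(stats::dist(pts))
  ord <- pcoa(D, k = 2)
  expect_lt(max(abs(as.matrix(stats::dist(ord$points)) - D)), 1e-8)

  # all-zero distances give all-zero coordinates and eigenvalues
  ord0 <- pcoa(matrix(0, 3, 3), k = 2)
  expect_true(all(abs(ord0$points) < 1e-12))
  expect_true(all(abs(ord0$eigenvalues) < 1e-12))
})

test_that("pcoa agrees with classical scaling from cmdscale", {
  set.seed(31)
  pts <- matrix(rnorm(24 * 3), ncol = 3)
  D <- as.matrix(stats::dist(pts))
  ord <- pcoa(D, k = 3)
  ref <- stats::cmdscale(D, k = 3, eig = TRUE)
  # coordinates agree up to per-axis sign
  for (j in 1:3) {
    expect_true(max(abs(ord$points[, j] - ref$points[, j])) < 1e-6 ||
                  max(abs(ord$points[, j] + ref$points[, j])) < 1e-6)
  }
  expect_equal(ord$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-8)
})

test_that("pcoa validates its inputs", {
  D <- as.matrix(stats::dist(matrix(rnorm(10), ncol = 2)))
  expect_error(pcoa(D, k = 5), "k must satisfy")
  expect_error(pcoa(D, k = 0), "k must satisfy")
  bad <- D; bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoa(bad, 2), "symmetric")
})

test_that("non-Euclidean OSA matrices report clamped negative eigenvalues", {
  co <- small_cohort()
  hits <- truth_hits(co)
  loci <- detect_loci(hits, co$genes)
  landscapes <- extract_landscapes(co$genes, loci, hits, window = 11)
  D <- landscape_distance_matrix(landscapes)
  ord <- pcoa(D, k = 2)
  expect_true(length(ord$negative_eigenvalues) > 0)
  expect_true(all(ord$eigenvalues >= 0))
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))  # descending
})

test_that("representative_landscape picks the modal string", {
  mk <- function(tokens, id) tibble::tibble(
    genome_id = id, anchor_gene_id = "a", window = 11L, anchor_index = 1L,
    tokens = list(tokens), trunc_upstream = FALSE, trunc_downstream = FALSE)
  tpl <- locus_templates()$compact
  grp <- dplyr::bind_rows(mk(tpl, "g1"), mk(tpl, "g2"), mk(tpl, "g3"),
                          mk(rev(tpl), "g4"))
  rep_l <- representative_landscape(grp)
  expect_identical(rep_l$tokens[[1]], tpl)

  # all distinct: minimal mean OSA distance wins
  centre <- c("A", "B", "C", "D")
  grp2 <- dplyr::bind_rows(
    mk(centre, "c"),
    mk(c("A", "B", "C", "E"), "v1"),     # 1 from centre
    mk(c("A", "B", "C"), "v2"),          # 1 from centre
    mk(c("X", "Y", "C", "D"), "v3"))     # 2 from centre
  rep2 <- representative_landscape(grp2)
  expect_identical(rep2$genome_id, "c")

  # 2-2 tie with equal mean distances: lexicographically smaller string
  grp3 <- dplyr::bind_rows(mk(c("B", "A"), "g1"), mk(c("B", "A"), "g2"),
                           mk(c("A", "B"), "g3"), mk(c("A", "B"), "g4"))
  rep3 <- representative_landscape(grp3)
  expect_identical(rep3$tokens[[1]], c("A", "B"))

  expect_error(representative_landscape(grp[0, ]), "non-empty")
})

test_that("the representative is always a member of its group", {
  co <- small_cohort()
  hits <- truth_hits(co)
  loci <- detect_loci(hits, co$genes)
  landscapes <- extract_landscapes(co$genes, loci, hits, window = 11)
  reps <- representative_landscapes(landscapes, co$sgb)
  expect_equal(nrow(reps), length(unique(
    co$sgb$sgb_id[co$sgb$genome_id %in% landscapes$genome_id])))
  strings <- vapply(landscapes$tokens, paste, character(1), collapse = " ")
  for (i in seq_len(nrow(reps))) {
    expect_true(paste(reps$tokens[[i]], collapse = " ") %in% strings)
  }
})
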