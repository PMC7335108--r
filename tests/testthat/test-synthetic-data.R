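test_that("mutate_to_identity hits its identity target", {
  ref <- random_protein_fixture(200)
  # identity case: target 100 returns the reference unchanged
  expect_identical(mutate_to_identity(ref, 100, seed = 1), ref)
  mut <- mutate_to_identity(ref, 70, seed = 7)
  pid <- percent_identity(ref, mut)
  expect_gte(pid, 67)
  expect_lte(pid, 73)
  expect_equal(r_nw_identity(substr(ref, 1, 30), substr(mut, 1, 30)),
               percent_identity(substr(ref, 1, 30), substr(mut, 1, 30)))
  # determinism: same seed, same output
  expect_identical(mutate_to_identity(ref, 70, seed = 7), mut)
  expect_false(identical(mutate_to_identity(ref, 70, seed = 8), mut))
})

test_that("mutate_to_identity validates its inputs", {
  ref <- random_protein_fixture(50)
  expect_error(mutate_to_identity(ref, 0, seed = 1), "target_identity")
  expect_error(mutate_to_identity(ref, 101, seed = 1), "target_identity")
  expect_error(mutate_to_identity("SHORTSEQ", 70, seed = 1), "length >= 20")
})

test_that("cohort_design enforces its invariants", {
  expect_error(cohort_design(frac_gh112_only = 0.7, frac_no_locus = 0.4),
               "frac")
  expect_error(cohort_design(identity_range = c(90, 80)), "identity_range")
  expect_error(cohort_design(identity_range = c(80, 120)), "identity_range")
  expect_error(
    cohort_design(n_sgbs = 1,
                  locus_template_per_sgb = list(c("GH136_I", "SBP"))),
    "GH112")
  expect_error(
    cohort_design(n_sgbs = 1,
                  locus_template_per_sgb = list(c("GH112", "GH112"))),
    "GH112")
})

test_that("category counts follow the floor rounding rule exactly", {
  design <- cohort_design(n_sgbs = 2L, genomes_per_sgb = 10L,
                          frac_gh112_only = 0.2, frac_no_locus = 0.1,
                          seed = 5L)
  co <- simulate_cohort(design)
  counts <- table(co$truth$genomes$category)
  expect_equal(as.integer(counts[c("primary", "secondary", "none")]),
               c(14L, 4L, 2L))
  # per SGB too: floor(0.2 * 10) = 2 secondary, floor(0.1 * 10) = 1 none
  per_sgb <- table(co$truth$genomes$sgb_id, co$truth$genomes$category)
  expect_true(all(per_sgb[, "secondary"] == 2L))
  expect_true(all(per_sgb[, "none"] == 1L))
})

test_that("a zero-genome design yields empty tables and truth", {
  co <- simulate_cohort(cohort_design(n_sgbs = 2L, genomes_per_sgb = 0L))
  expect_equal(nrow(co$genes), 0L)
  expect_equal(nrow(co$sgb), 0L)
  expect_equal(nrow(co$truth$genomes), 0L)
})

test_that("simulation is deterministic under the root seed", {
  design <- cohort_design(n_sgbs = 2L, genomes_per_sgb = 4L, seed = 99L)
  a <- simulate_cohort(design)
  b <- simulate_cohort(design)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(cohort_design(n_sgbs = 2L, genomes_per_sgb = 4L,
                                      seed = 100L))
  expect_false(identical(a$genes, c2$genes))
})

test_that("planted genes match their recorded identities and categories", {
  co <- small_cohort()
  tg <- co$truth$genes
  set.seed(3)
  some <- tg[sample.int(nrow(tg), 20L), ]
  for (i in seq_len(nrow(some))) {
    prot <- co$genes$protein[co$genes$gene_id == some$gene_id[i]]
    ref <- co$refs$protein[co$refs$family == some$family[i]][1]
    expect_lt(abs(percent_identity(prot, ref) - some$target_identity[i]), 3.5)
  }
  # category consistency: primary iff GH112 and >= 1 GH136 subunit planted
  fam_by_genome <- split(tg$family, tg$genome_id)
  for (i in seq_len(nrow(co$truth$genomes))) {
    g <- co$truth$genomes$genome_id[i]
    fams <- fam_by_genome[[g]]
    expected <- if (is.null(fams)) "none"
      else if ("GH112" %in% fams && any(fams %in% gh136_tokens())) "primary"
      else if ("GH112" %in% fams) "secondary" else "none"
    expect_identical(co$truth$genomes$category[i], expected)
  }
})

test_that("background genes stay far below the identity threshold", {
  refs <- reference_families()
  set.seed(21)
  n_bg <- 1000L
  bg <- vapply(sample(150:400, n_bg, replace = TRUE),
               random_protein_fixture, character(1))
  pid <- hmoloci:::.nw_identity_batch_cpp(bg, refs$protein, 0)
  expect_lt(max(pid), 40)
})

test_that("planted loci are recovered at a threshold 5 points below the range", {
  co <- small_cohort()  # identities 80-95
  hits <- small_hits(75)
  loci <- detect_loci(hits, co$genes)
  truth <- co$truth$genomes
  primaries <- truth$genome_id[truth$category == "primary"]
  expect_setequal(unique(loci$genome_id), primaries)
})

test_that("locus strand is randomized but gene order is preserved in truth", {
  co <- small_cohort()
  truth <- co$truth$genomes
  with_locus <- truth[truth$category != "none", ]
  strands <- vapply(seq_len(nrow(with_locus)), function(i) {
    g <- co$genes[co$genes$genome_id == with_locus$genome_id[i] &
                    grepl("_loc", co$genes$gene_id), ]
    unique(g$strand)
  }, character(1))
  expect_setequal(unique(strands), c("+", "-"))
})
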