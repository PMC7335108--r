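test_that("prevalence counts genomes once regardless of paralogs", {
  sgb <- tibble::tibble(genome_id = c("g1", "g2", "g3"),
                        sgb_id = c("S1", "S1", "S2"))
  hits <- tibble::tibble(
    genome_id = c("g1", "g1", "g1", "g2"),
    gene_id = c("a", "b", "c", "d"),
    family = c("GH112", "GH112", "GH112", "GH136_I"),
    ref_id = "r", pct_identity = 90)
  tab <- prevalence(hits, sgb, families = c("GH112", "GH136_I", "GH136_II"))
  g112 <- tab[tab$family == "GH112", ]
  expect_equal(g112$n_genomes[g112$scope == "global"], 1L)
  expect_equal(g112$n_genes[g112$scope == "global"], 3L)  # paralogs reported
  expect_equal(g112$fraction[g112$scope == "global"], 1 / 3)
  # aggregate GH136 row counts genomes with >= 1 subunit
  g136 <- tab[tab$family == "GH136", ]
  expect_equal(g136$n_genomes[g136$scope == "global"], 1L)

  empty <- prevalence(hits[0, ], sgb, families = c("GH112", "GH10"))
  expect_true(all(empty$n_genomes == 0L))
  expect_true(all(empty$fraction == 0))
})

test_that("per-SGB counts sum to global counts for every family", {
  co <- small_cohort()
  hits <- small_hits(70)
  tab <- prevalence(hits, co$sgb)
  for (fam in unique(tab$family)) {
    sub <- tab[tab$family == fam, ]
    expect_equal(sub$n_genomes[sub$scope == "global"],
                 sum(sub$n_genomes[sub$scope != "global"]))
    expect_equal(sub$n_genes[sub$scope == "global"],
                 sum(sub$n_genes[sub$scope != "global"]))
  }
})

test_that("prevalence matches the planted design on a synthetic cohort", {
  co <- small_cohort()  # 2 SGBs x 10 genomes, floor rule: 1 sec, 1 none
  hits <- small_hits(70)
  tab <- prevalence(hits, co$sgb)
  truth <- co$truth$genomes
  for (s in unique(truth$sgb_id)) {
    n_primary <- sum(truth$sgb_id == s & truth$category == "primary")
    n_secondary <- sum(truth$sgb_id == s & truth$category == "secondary")
    cell <- function(fam) {
      tab$n_genomes[tab$family == fam & tab$scope == s]
    }
    expect_equal(cell("GH112"), n_primary + n_secondary)
    expect_equal(cell("GH136"), n_primary)
  }
})

test_that("prevalence demands a complete SGB assignment", {
  hits <- tibble::tibble(genome_id = "ghost", gene_id = "a",
                         family = "GH112", ref_id = "r", pct_identity = 90)
  sgb <- tibble::tibble(genome_id = "g1", sgb_id = "S1")
  expect_error(prevalence(hits, sgb), "ghost")
})

test_that("prevalence is invariant to gene order and strand", {
  co <- small_cohort()
  hits <- small_hits(70)
  tab <- prevalence(hits, co$sgb)
  shuffled <- with_seed_fixture(5, co$genes[sample.int(nrow(co$genes)), ])
  shuffled$strand <- ifelse(shuffled$strand == "+", "-", "+")
  hits2 <- search_homologs(shuffled, co$refs, 70)
  expect_equal(prevalence(hits2, co$sgb), tab)
})

test_that("no prevalence cell grows when the threshold rises", {
  co <- small_cohort()
  t70 <- prevalence(small_hits(70), co$sgb)
  t80 <- prevalence(small_hits(80), co$sgb)
  expect_true(all(t80$n_genomes <= t70$n_genomes))
  expect_true(all(t80$n_genes <= t70$n_genes))
})

test_that("prevalence ratios divide genome counts within a scope", {
  tab <- tibble::tibble(
    family = c("GH112", "GH136", "GH10"),
    scope = "SGB01",
    n_genomes = c(26L, 10L, 0L),
    n_cohort = 40L, fraction = c(26, 10, 0) / 40, n_genes = c(30L, 10L, 0L))
  expect_equal(prevalence_ratio(tab, "GH112", "GH136", "SGB01"), 2.6)
  expect_equal(prevalence_ratio(tab, "GH136", "GH136", "SGB01"), 1.0)
  expect_error(prevalence_ratio(tab, "GH112", "GH10", "SGB01"),
               "undefined ratio")
  expect_error(prevalence_ratio(tab, "GH112", "GH136", "nope"), "no prevalence")
})

test_that("GH112:GH136 ratio reflects the planted secondary fraction", {
  # 30% of GH112 carriers lack GH136 -> ratio 1 / 0.7
  design <- cohort_design(n_sgbs = 1L, genomes_per_sgb = 20L,
                          frac_gh112_only = 0.3, frac_no_locus = 0,
                          seed = 8L)
  co <- simulate_cohort(design)
  hits <- search_homologs(co$genes, co$refs, 70)
  tab <- prevalence(hits, co$sgb)
  expect_equal(prevalence_ratio(tab, "GH112", "GH136"), 20 / 14,
               tolerance = 1e-12)
})

test_that("degrader summaries are complete contingency tables", {
  co <- small_cohort()
  hits <- small_hits(70)
  cats <- classify_degraders(hits, co$sgb$genome_id)
  degr <- degrader_summary(cats, co$sgb)
  expect_equal(degr$primary + degr$secondary + degr$none, degr$n_cohort)
  expect_equal(sum(degr$n_cohort), nrow(co$sgb))
  # matches the planted truth
  truth <- co$truth$genomes
  for (i in seq_len(nrow(degr))) {
    s <- degr$sgb_id[i]
    expect_equal(degr$primary[i],
                 sum(truth$sgb_id == s & truth$category == "primary"))
    expect_equal(degr$secondary[i],
                 sum(truth$sgb_id == s & truth$category == "secondary"))
  }
  # an SGB with no genomes classified still yields a zero-consistent row
  all_primary <- tibble::tibble(
    genome_id = c("a", "b"), category = "primary")
  sgb2 <- tibble::tibble(genome_id = c("a", "b"), sgb_id = "S1")
  degr2 <- degrader_summary(all_primary, sgb2)
  expect_equal(degr2$secondary, 0L)
  expect_equal(degr2$none, 0L)
})
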