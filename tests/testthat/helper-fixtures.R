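# Shared small fixtures, built once per test run.

with_seed_fixture <- function(seed, expr) withr::with_seed(seed, expr)

the_fixtures <- new.env()

small_cohort <- function() {
  if (is.null(the_fixtures$small)) {
    the_fixtures$small <- simulate_cohort(
      cohort_design(n_sgbs = 2L, genomes_per_sgb = 10L, seed = 42L))
  }
  the_fixtures$small
}

small_hits <- function(threshold = 70) {
  key <- paste0("hits", threshold)
  if (is.null(the_fixtures[[key]])) {
    co <- small_cohort()
    the_fixtures[[key]] <- search_homologs(co$genes, co$refs, threshold)
  }
  the_fixtures[[key]]
}

# Hits reconstructed from ground truth (no alignment): every planted gene
# hits its planted family at its target identity.
truth_hits <- function(cohort) {
  tg <- cohort$truth$genes
  tibble::tibble(genome_id = tg$genome_id, gene_id = tg$gene_id,
                 family = tg$family,
                 ref_id = paste0(tg$family, "_ref01"),
                 pct_identity = tg$target_identity)
}

# Hand-built single-contig gene table from a token layout; proteins are
# omitted (landscape geometry tests only need coordinates and products).
toy_contig <- function(tokens, genome_id = "g1", strand = "+",
                       products = NULL) {
  n <- length(tokens)
  if (is.null(products)) {
    products <- ifelse(tokens == "OTHER", "YjdC-like protein",
                       "hypothetical protein")
  }
  starts <- seq(1L, by = 1000L, length.out = n)
  tibble::tibble(
    genome_id = genome_id, contig_id = paste0(genome_id, "_c1"),
    gene_id = sprintf("%s_%03d", genome_id, seq_len(n)),
    start = starts, end = starts + 899L,
    strand = strand, product = products, protein = NA_character_)
}

# Hits assigning given families to gene indices of a toy contig.
toy_hits <- function(genes, idx, families, pct = 90) {
  tibble::tibble(genome_id = genes$genome_id[idx],
                 gene_id = genes$gene_id[idx],
                 family = families,
                 ref_id = paste0(families, "_ref01"),
                 pct_identity = pct)
}

# Mirror a single-contig gene table: reverse coordinates and flip strands.
mirror_contig <- function(genes) {
  L <- max(genes$end) + 1L
  out <- genes
  out$start <- L - genes$end
  out$end <- L - genes$start
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out[order(out$start), , drop = FALSE]
}
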