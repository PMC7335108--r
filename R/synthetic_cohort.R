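PRODUCT_BY_TOKEN <- c(
  GH112    = "galacto-N-biose/lacto-N-biose phosphorylase, glycoside hydrolase family 112",
  GH136_I  = "lacto-N-biosidase subunit I, glycoside hydrolase family 136",
  GH136_II = "lacto-N-biosidase subunit II, glycoside hydrolase family 136",
  GH10     = "endo-1,4-beta-xylanase, glycoside hydrolase family 10",
  GH29     = "alpha-L-fucosidase, glycoside hydrolase family 29",
  GH95     = "alpha-L-fucosidase, glycoside hydrolase family 95",
  GH42     = "beta-galactosidase, glycoside hydrolase family 42",
  GH36     = "alpha-galactosidase, glycoside hydrolase family 36",
  GH98     = "endo-beta-1,4-galactosidase, glycoside hydrolase family 98",
  SBP      = "ABC transporter solute binding protein",
  PP       = "ABC transporter permease protein",
  TransR   = "transcriptional regulator",
  HisK     = "histidine kinase sensory protein",
  HP       = "hypothetical protein"
)

#' Design of a synthetic SGB-structured cohort
#'
#' Bundles and validates the parameters of the synthetic pangenome
#' generator: how many species-level genome bins (SGBs), how many genomes
#' per SGB, which locus architecture each SGB carries, the identity range
#' of planted locus genes to the family references, the fractions of
#' GH112-only (secondary degrader) and locus-free genomes, the per-locus
#' rearrangement probability, and the root seed.
#'
#' @param n_sgbs Number of SGBs.
#' @param genomes_per_sgb Genomes per SGB; scalar or length-`n_sgbs` vector.
#' @param locus_template_per_sgb List of family-token vectors, one per SGB;
#'   defaults to alternating [locus_templates()] `compact` / `extended`.
#' @param identity_range Length-2 numeric in `[0, 100]`: planted-gene
#'   identities to the references are drawn uniformly from this interval.
#' @param frac_gh112_only Fraction of genomes per SGB planted with a GH112
#'   gene but no GH136 subunit (secondary degraders).
#' @param frac_no_locus Fraction of genomes per SGB without any locus.
#' @param n_background_genes Background (hypothetical protein) genes per
#'   genome.
#' @param rearrangement_rate Probability that a planted locus undergoes one
#'   rearrangement (gene deletion, HP insertion, or adjacent swap).
#' @param seed Integer root seed; every random draw derives from it.
#' @return A validated `cohort_design` list.
#' @export
#' @examples
#' cohort_design(n_sgbs = 2, genomes_per_sgb = 5, seed = 1)
cohort_design <- function(n_sgbs = 5L,
                          genomes_per_sgb = 24L,
                          locus_template_per_sgb = NULL,
                          identity_range = c(80, 95),
                          frac_gh112_only = 0.15,
                          frac_no_locus = 0.10,
                          n_background_genes = 30L,
                          rearrangement_rate = 0.3,
                          seed = 1L) {
  n_sgbs <- as.integer(n_sgbs)
  stopifnot(n_sgbs >= 1L)
  if (length(genomes_per_sgb) == 1L) {
    genomes_per_sgb <- rep(as.integer(genomes_per_sgb), n_sgbs)
  }
  genomes_per_sgb <- as.integer(genomes_per_sgb)
  if (length(genomes_per_sgb) != n_sgbs || any(genomes_per_sgb < 0L)) {
    stop("genomes_per_sgb must be non-negative, one value per SGB")
  }
  if (is.null(locus_template_per_sgb)) {
    tpl <- locus_templates()
    locus_template_per_sgb <- lapply(seq_len(n_sgbs), function(i) {
      if (i %% 2L == 1L) tpl$compact else tpl$extended
    })
  }
  if (length(locus_template_per_sgb) != n_sgbs) {
    stop("locus_template_per_sgb must have one template per SGB")
  }
  for (tpl in locus_template_per_sgb) {
    if (!all(tpl %in% family_tokens())) {
      stop("locus template contains tokens outside the controlled vocabulary")
    }
    if (sum(tpl == "GH112") != 1L) {
      stop("every locus template must contain exactly one GH112 token")
    }
  }
  if (length(identity_range) != 2L || any(identity_range < 0) ||
      any(identity_range > 100) || identity_range[1] > identity_range[2]) {
    stop("identity_range must be an interval within [0, 100]")
  }
  if (frac_gh112_only < 0 || frac_no_locus < 0 ||
      frac_gh112_only + frac_no_locus > 1) {
    stop("frac_gh112_only + frac_no_locus must lie in [0, 1]")
  }
  if (rearrangement_rate < 0 || rearrangement_rate > 1) {
    stop("rearrangement_rate must lie in [0, 1]")
  }
  structure(list(
    n_sgbs = n_sgbs,
    genomes_per_sgb = genomes_per_sgb,
    locus_template_per_sgb = locus_template_per_sgb,
    identity_range = as.numeric(identity_range),
    frac_gh112_only = frac_gh112_only,
    frac_no_locus = frac_no_locus,
    n_background_genes = as.integer(n_background_genes),
    rearrangement_rate = rearrangement_rate,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Mutate a protein towards a target percent identity
#'
#' Substitutes a deterministic number of randomly chosen positions,
#' `round(L * (1 - target/100))`, each with a different residue, so the
#' identity of the result to the reference (under [percent_identity()])
#' lands within about 3 percentage points of the target.
#'
#' @param reference Protein sequence (length >= 20).
#' @param target_identity Target percent identity in `(0, 100]`.
#' @param seed Integer seed; same inputs and seed reproduce the output.
#' @return Mutated protein string.
#' @export
#' @examples
#' ref <- paste(rep("ACDEFGHIKL", 5), collapse = "")
#' mut <- mutate_to_identity(ref, 80, seed = 1)
#' percent_identity(ref, mut)
mutate_to_identity <- function(reference, target_identity, seed) {
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 100) {
    stop("target_identity must lie in (0, 100]")
  }
  if (!is.character(reference) || length(reference) != 1L ||
      nchar(reference) < 20L) {
    stop("reference must be a single protein of length >= 20")
  }
  L <- nchar(reference)
  k <- round(L * (1 - target_identity / 100))
  if (k == 0L) return(reference)
  with_local_seed(as.integer(seed), {
    res <- strsplit(reference, "")[[1]]
    pos <- sample.int(L, k)
    for (p in pos) {
      res[p] <- sample(setdiff(AA_ALPHABET20, res[p]), 1L)
    }
    paste(res, collapse = "")
  })
}

# One rearrangement of a locus token string: delete a non-anchor gene,
# insert an HP gene, or swap two adjacent non-anchor genes. The GH112
# anchor is never moved or removed. Uses the current RNG stream.
rearrange_tokens <- function(tokens) {
  anchor <- which(tokens == "GH112")
  op <- sample(c("delete", "insert", "swap"), 1L)
  if (op == "delete") {
    cand <- setdiff(seq_along(tokens), anchor)
    if (length(cand) == 0L) return(tokens)
    tokens <- tokens[-sample_one(cand)]
  } else if (op == "insert") {
    at <- sample.int(length(tokens) + 1L, 1L)  # position before which to insert
    tokens <- append(tokens, "HP", after = at - 1L)
  } else {
    idx <- seq_len(length(tokens) - 1L)
    pairs <- idx[idx != anchor & idx + 1L != anchor]
    if (length(pairs) == 0L) return(tokens)
    i <- sample_one(pairs)
    tokens[c(i, i + 1L)] <- tokens[c(i + 1L, i)]
  }
  tokens
}

# sample() with the surprise single-integer behaviour removed
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Simulate an SGB-structured cohort with planted HMO loci
#'
#' Generates one single-contig annotated genome per cohort member:
#' background hypothetical-protein genes plus, per planted category, an
#' HMO-utilization locus whose genes carry protein sequences mutated to
#' identities drawn uniformly from the design's identity range. Category
#' counts per SGB follow a fixed rounding rule — `floor(frac * n)` genomes
#' secondary (GH112 without GH136) and `floor(frac * n)` without a locus,
#' the remainder primary — assigned in index order and then shuffled under
#' the cohort seed. The locus strand is random per genome; on the minus
#' strand the gene order on the contig is reversed so the locus still reads
#' 5'-to-3' in transcription order. Everything planted is recorded in the
#' returned ground truth.
#'
#' @param design A [cohort_design()].
#' @param refs Reference families; defaults to [reference_families()].
#' @return List with elements `genes` (one gene table for the whole
#'   cohort), `sgb` (tibble `genome_id`, `sgb_id`), `truth` (list of
#'   `genomes` and `genes` tibbles), `refs`, and `design`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_design(n_sgbs = 1, genomes_per_sgb = 3,
#'                                         seed = 7))
#' cohort$truth$genomes
simulate_cohort <- function(design, refs = reference_families()) {
  stopifnot(inherits(design, "cohort_design"))
  ref_by_family <- split(refs, refs$family)

  truth_genomes <- list()
  truth_genes <- list()
  gene_tables <- list()
  sgb_rows <- list()
  genome_index <- 0L

  for (s in seq_len(design$n_sgbs)) {
    sgb_id <- sprintf("SGB%02d", s)
    n <- design$genomes_per_sgb[s]
    if (n == 0L) next
    template <- design$locus_template_per_sgb[[s]]

    n_sec <- floor(design$frac_gh112_only * n)
    n_none <- floor(design$frac_no_locus * n)
    n_pri <- n - n_sec - n_none
    categories <- c(rep("secondary", n_sec), rep("none", n_none),
                    rep("primary", n_pri))
    categories <- with_local_seed(substream_seed(design$seed, s * 100000L),
                                  sample(categories))

    for (g in seq_len(n)) {
      genome_index <- genome_index + 1L
      genome_id <- sprintf("%s_g%03d", sgb_id, g)
      category <- categories[g]
      gseed <- substream_seed(design$seed, genome_index)

      sim <- with_local_seed(gseed, simulate_genome(
        genome_id = genome_id, category = category, template = template,
        design = design, ref_by_family = ref_by_family, gseed = gseed))

      gene_tables[[genome_index]] <- sim$genes
      sgb_rows[[genome_index]] <- tibble::tibble(genome_id = genome_id,
                                                 sgb_id = sgb_id)
      truth_genomes[[genome_index]] <- tibble::tibble(
        genome_id = genome_id, sgb_id = sgb_id, category = category,
        anchor_gene_id = sim$anchor_gene_id,
        locus_tokens = list(sim$locus_tokens))
      truth_genes[[genome_index]] <- sim$truth_genes
    }
  }

  empty_genes <- tibble::tibble(
    genome_id = character(), contig_id = character(), gene_id = character(),
    start = integer(), end = integer(), strand = character(),
    product = character(), protein = character())
  list(
    genes = dplyr::bind_rows(c(list(empty_genes), gene_tables)),
    sgb = dplyr::bind_rows(c(
      list(tibble::tibble(genome_id = character(), sgb_id = character())),
      sgb_rows)),
    truth = list(
      genomes = dplyr::bind_rows(c(list(tibble::tibble(
        genome_id = character(), sgb_id = character(), category = character(),
        anchor_gene_id = character(), locus_tokens = list())), truth_genomes)),
      genes = dplyr::bind_rows(c(list(tibble::tibble(
        genome_id = character(), gene_id = character(), family = character(),
        target_identity = numeric())), truth_genes))),
    refs = refs,
    design = design
  )
}

# Build one genome under the current RNG stream (seeded by the caller).
simulate_genome <- function(genome_id, category, template, design,
                            ref_by_family, gseed) {
  n_bg <- design$n_background_genes

  locus_tokens <- switch(category,
    primary = template,
    secondary = template[!template %in% gh136_tokens()],
    none = character(0))
  rearranged <- length(locus_tokens) > 0 &&
    runif(1) < design$rearrangement_rate
  if (rearranged) locus_tokens <- rearrange_tokens(locus_tokens)

  # proteins for locus genes: references mutated to a drawn identity;
  # HP genes inserted by rearrangement have no reference lineage and get a
  # random protein like the background
  n_locus <- length(locus_tokens)
  locus_prot <- character(n_locus)
  locus_target <- rep(NA_real_, n_locus)
  planted_from_ref <- rep(TRUE, n_locus)
  if (n_locus > 0) {
    template_hp <- sum(template == "HP")
    hp_seen <- 0L
    for (i in seq_len(n_locus)) {
      tok <- locus_tokens[i]
      if (tok == "HP") {
        hp_seen <- hp_seen + 1L
        if (hp_seen > template_hp) {  # HP gained by insertion
          planted_from_ref[i] <- FALSE
          locus_prot[i] <- random_protein(sample(150:400, 1L))
          next
        }
      }
      fam_refs <- ref_by_family[[tok]]
      if (is.null(fam_refs)) stop("no reference sequence for family ", tok)
      ref_row <- fam_refs[sample.int(nrow(fam_refs), 1L), ]
      tgt <- runif(1, design$identity_range[1], design$identity_range[2])
      locus_prot[i] <- mutate_to_identity(
        ref_row$protein, tgt, seed = substream_seed(gseed, 1000L + i))
      locus_target[i] <- tgt
    }
  }

  bg_prot <- vapply(seq_len(n_bg),
                    function(i) random_protein(sample(150:400, 1L)),
                    character(1))
  bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)

  locus_strand <- sample(c("+", "-"), 1L)
  # physical order on the contig: template order, reversed on minus strand
  phys_idx <- if (locus_strand == "-") rev(seq_len(n_locus)) else
    seq_len(n_locus)

  # contig layout: locus sits mid-contig, genes non-overlapping with 50 bp
  # intergenic gaps, coordinates 1-based inclusive
  h <- ceiling(n_bg / 2)
  bg_ids <- sprintf("%s_bg%03d", genome_id, seq_len(n_bg))
  loc_ids <- sprintf("%s_loc%02d", genome_id, phys_idx)
  prot <- c(bg_prot[seq_len(h)], locus_prot[phys_idx],
            bg_prot[seq_len(n_bg)[-seq_len(h)]])
  strand <- c(bg_strand[seq_len(h)], rep(locus_strand, n_locus),
              bg_strand[seq_len(n_bg)[-seq_len(h)]])
  product <- c(rep("hypothetical protein", h),
               unname(PRODUCT_BY_TOKEN[locus_tokens[phys_idx]]),
               rep("hypothetical protein", n_bg - h))
  gene_id <- c(bg_ids[seq_len(h)], loc_ids, bg_ids[-seq_len(h)])
  fam <- c(rep(NA_character_, h),
           ifelse(planted_from_ref[phys_idx], locus_tokens[phys_idx],
                  NA_character_),
           rep(NA_character_, n_bg - h))
  tgt <- c(rep(NA_real_, h), locus_target[phys_idx], rep(NA_real_, n_bg - h))
  len <- 3L * nchar(prot) + 3L
  start <- c(1L, head(cumsum(len + 50L), -1L) + 1L)
  genes <- tibble::tibble(
    genome_id = genome_id, contig_id = paste0(genome_id, "_c1"),
    gene_id = gene_id, start = start, end = start + len - 1L,
    strand = strand, product = product, protein = prot,
    family = fam, target_identity = tgt)

  anchor_gene_id <- if (n_locus > 0) {
    sprintf("%s_loc%02d", genome_id, which(locus_tokens == "GH112"))
  } else NA_character_

  truth_genes <- genes[!is.na(genes$family),
                       c("genome_id", "gene_id", "family", "target_identity")]
  genes$family <- NULL
  genes$target_identity <- NULL
  list(genes = genes, anchor_gene_id = anchor_gene_id,
       locus_tokens = locus_tokens, truth_genes = truth_genes)
}

#' Expected landscape tokens of a planted locus
#'
#' Pads a planted locus token string with the `HP` tokens contributed by
#' flanking background genes to the full window the landscape extractor
#' reports, anchored at the GH112 gene.
#'
#' @param locus_tokens Planted locus token string in transcription order.
#' @param window Flanking-gene window `n` (genes each side of the anchor).
#' @return Character vector of length `2 * window + 1`.
#' @export
expected_landscape_tokens <- function(locus_tokens, window = 11L) {
  anchor <- which(locus_tokens == "GH112")
  stopifnot(length(anchor) == 1L)
  pad_up <- window - (anchor - 1L)
  pad_down <- window - (length(locus_tokens) - anchor)
  stopifnot(pad_up >= 0L, pad_down >= 0L)
  c(rep("HP", pad_up), locus_tokens, rep("HP", pad_down))
}
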