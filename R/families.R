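#' Family token vocabulary
#'
#' Controlled vocabulary of gene-family tokens used throughout the package:
#' glycoside hydrolase (CAZyme) families involved in HMO and host-glycan
#' utilization (GH112 lacto-N-biose/galacto-N-biose phosphorylase, the two
#' GH136 lacto-N-biosidase subunits, GH10 xylanase, GH29/GH95 fucosidases,
#' GH42 beta-galactosidase, GH36, GH98) plus locus-accessory families: ABC
#' transporter solute binding protein (SBP), permease protein (PP),
#' transcriptional regulator (TransR), histidine kinase sensor (HisK) and
#' hypothetical protein (HP).
#'
#' @return Character vector of valid family tokens.
#' @export
#' @examples
#' family_tokens()
family_tokens <- function() {
  c("GH112", "GH136_I", "GH136_II", "GH10", "GH29", "GH95",
    "GH42", "GH36", "GH98", "SBP", "PP", "TransR", "HisK", "HP")
}

#' GH136 subunit tokens
#' @return Character vector of the two lacto-N-biosidase subunit tokens.
#' @export
gh136_tokens <- function() c("GH136_I", "GH136_II")

#' Default locus templates
#'
#' Ordered gene-family token strings of the two canonical HMO-utilization
#' locus architectures: the compact locus (transcriptional regulator, ABC
#' transporter, GH136 subunits, GH112 phosphorylase, histidine kinase) and
#' the extended locus additionally carrying GH29 and GH95 fucosidase genes.
#'
#' @return Named list of two character vectors of family tokens.
#' @export
#' @examples
#' locus_templates()$compact
locus_templates <- function() {
  list(
    compact  = c("TransR", "SBP", "PP", "PP", "HP",
                 "GH136_I", "GH136_II", "GH112", "HisK"),
    extended = c("TransR", "SBP", "PP", "PP", "HP", "GH29", "GH95",
                 "GH136_I", "GH136_II", "GH112", "HisK")
  )
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

#' Synthetic reference family sequences
#'
#' Builds a deterministic set of synthetic reference protein sequences, one
#' or more per family token, standing in for the reference-genome proteins
#' a real screen would use. Sequences are random proteins drawn once from a
#' fixed internal seed, so the set is identical across sessions; they carry
#' no biological signal beyond being mutually unrelated, which is the
#' property the identity screen needs.
#'
#' @param families Character vector of family tokens (default all).
#' @param n_per_family Number of reference sequences per family.
#' @param length_range Length range (residues) references are drawn from.
#' @return A tibble with columns `ref_id`, `family`, `genome_label`,
#'   `protein`.
#' @export
#' @examples
#' refs <- reference_families()
#' head(refs)
reference_families <- function(families = family_tokens(),
                               n_per_family = 1L,
                               length_range = c(180L, 260L)) {
  stopifnot(all(families %in% family_tokens()), n_per_family >= 1L)
  genome_labels <- c("refA", "refB", "refC", "refD", "refE")
  with_local_seed(903271L, {
    rows <- lapply(seq_along(families), function(i) {
      fam <- families[i]
      lens <- sample(seq(length_range[1], length_range[2]), n_per_family,
                     replace = TRUE)
      tibble::tibble(
        ref_id = sprintf("%s_ref%02d", fam, seq_len(n_per_family)),
        family = fam,
        genome_label = genome_labels[(i + seq_len(n_per_family) - 2L) %%
                                       length(genome_labels) + 1L],
        protein = vapply(lens, random_protein, character(1))
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Write reference families as FASTA
#'
#' Headers follow `>ref_id|FAMILY|genome_label`.
#'
#' @param refs Tibble as returned by [reference_families()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  seqs <- Biostrings::AAStringSet(refs$protein)
  names(seqs) <- paste(refs$ref_id, refs$family, refs$genome_label, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read reference families from FASTA
#'
#' @param path FASTA path with `>ref_id|FAMILY|genome_label` headers.
#' @return Tibble with columns `ref_id`, `family`, `genome_label`, `protein`.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed reference headers (expect ref_id|FAMILY|genome_label): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  refs <- tibble::tibble(
    ref_id = vapply(parts, `[`, character(1), 1L),
    family = vapply(parts, `[`, character(1), 2L),
    genome_label = vapply(parts, `[`, character(1), 3L),
    protein = unname(as.character(seqs))
  )
  unknown <- setdiff(refs$family, family_tokens())
  if (length(unknown) > 0) {
    stop("unknown family tokens in reference FASTA: ",
         paste(unknown, collapse = ", "))
  }
  refs
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seed for indexed units under a root seed.
# Distinct for every index below 65536; always a valid 32-bit integer.
substream_seed <- function(root_seed, index) {
  (as.integer(root_seed) %% 32749L) * 65536L + (as.integer(index) %% 65536L)
}
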