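#' Percent identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment under a fixed scoring scheme —
#' match +1, mismatch 0, linear gap -1 — with identity defined as
#' 100 x identical columns / total alignment columns, end gaps included.
#' Among co-optimal alignments the one maximizing the number of matches is
#' scored, which makes the value symmetric and deterministic.
#'
#' @param a,b Non-empty residue strings.
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("ACDEFGHIKL", "ACDEFGHIKV")  # 90
#' percent_identity("AAAA", "AAAATTTT")          # 50
percent_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || is.na(a) || is.na(b) || nchar(a) == 0L ||
      nchar(b) == 0L) {
    stop("percent_identity() requires two non-empty sequences")
  }
  .nw_identity_cpp(a, b)
}

#' Screen genes against reference families by percent identity
#'
#' For every gene carrying a protein sequence, computes the best percent
#' identity against each family's reference sequences and reports a hit for
#' a family when that best identity reaches the threshold. Mirrors a
#' BLAST-then-filter homolog screen, with the package's exact global-identity
#' definition in place of a heuristic local search. A gene may hit several
#' distinct families but at most once per family; ties between references
#' of a family are broken towards the lexicographically smallest `ref_id`.
#'
#' @param genes Gene table (see [gene_table_columns()]); rows without a
#'   protein sequence are skipped.
#' @param refs Reference tibble as from [reference_families()] or
#'   [read_reference_fasta()].
#' @param threshold Identity threshold in `(0, 100]`; genes at or above it
#'   are reported (default 70, the conventional stringent cut-off).
#' @return Tibble of family hits: `genome_id`, `gene_id`, `family`,
#'   `ref_id`, `pct_identity`, sorted by genome, gene, family.
#' @export
search_homologs <- function(genes, refs, threshold = 70) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 100) {
    stop("threshold must be a single value in (0, 100]")
  }
  if (is.null(refs) || nrow(refs) == 0L) {
    stop("empty reference set")
  }
  validate_gene_table(genes)
  empty <- tibble::tibble(genome_id = character(), gene_id = character(),
                          family = character(), ref_id = character(),
                          pct_identity = numeric())
  genes <- genes[!is.na(genes$protein) & nchar(genes$protein) > 0L, ,
                 drop = FALSE]
  if (nrow(genes) == 0L) return(empty)

  refs <- refs[order(refs$ref_id), , drop = FALSE]
  pid <- .nw_identity_batch_cpp(genes$protein, refs$protein,
                                min_identity = threshold)
  hits <- lapply(unique(refs$family), function(fam) {
    cols <- which(refs$family == fam)
    sub <- pid[, cols, drop = FALSE]
    best_j <- max.col(sub, ties.method = "first")  # refs sorted by ref_id
    best <- sub[cbind(seq_len(nrow(sub)), best_j)]
    keep <- best >= threshold
    if (!any(keep)) return(NULL)
    tibble::tibble(
      genome_id = genes$genome_id[keep],
      gene_id = genes$gene_id[keep],
      family = fam,
      ref_id = refs$ref_id[cols][best_j[keep]],
      pct_identity = best[keep]
    )
  })
  out <- dplyr::bind_rows(c(list(empty), hits))
  dplyr::arrange(out, .data$genome_id, .data$gene_id, .data$family)
}

#' Write / read family-hit tables
#'
#' Tab-separated with columns `genome_id`, `gene_id`, `family`, `ref_id`,
#' `pct_identity`. Precomputed tables from external search tools can be
#' supplied to the rest of the pipeline through [read_hits_tsv()].
#'
#' @param hits Hit tibble as from [search_homologs()].
#' @param path File path.
#' @return `path` ([write_hits_tsv()]) or the hit tibble ([read_hits_tsv()]).
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  out <- tibble::as_tibble(read.delim(path, colClasses = c(
    genome_id = "character", gene_id = "character", family = "character",
    ref_id = "character", pct_identity = "numeric")))
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("pct_identity outside [0, 100] in ", path)
  }
  out
}
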