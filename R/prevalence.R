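#' Family prevalence, globally and per SGB
#'
#' Counts genomes (not genes) carrying at least one hit per family, both
#' across the whole cohort and within each species-level genome bin, with
#' fractions relative to cohort sizes. A genome with several paralogs of a
#' family still counts once; paralog-inclusive gene counts are emitted in
#' the `n_genes` column for transparency. An aggregate `GH136` row counts
#' genomes with at least one of the two subunits.
#'
#' @param hits Family-hit tibble.
#' @param sgb SGB assignment tibble (`genome_id`, `sgb_id`) covering every
#'   hit genome; its genome list defines the cohort sizes.
#' @param families Family tokens to tabulate (default the full
#'   vocabulary).
#' @return Tibble: `family`, `scope` (`"global"` or an SGB id),
#'   `n_genomes`, `n_cohort`, `fraction`, `n_genes`.
#' @export
prevalence <- function(hits, sgb, families = family_tokens()) {
  offenders <- setdiff(unique(hits$genome_id), sgb$genome_id)
  if (length(offenders) > 0L) {
    stop("genomes without SGB assignment: ",
         paste(offenders, collapse = ", "))
  }
  sgb_ids <- sort(unique(sgb$sgb_id))
  cohort_global <- nrow(sgb)
  cohort_by_sgb <- table(sgb$sgb_id)

  fam_list <- c(as.list(families), list(gh136_tokens()))
  fam_names <- c(families, "GH136")

  rows <- lapply(seq_along(fam_list), function(i) {
    fh <- hits[hits$family %in% fam_list[[i]], , drop = FALSE]
    genomes <- unique(fh$genome_id)
    per_sgb <- sgb[sgb$genome_id %in% genomes, , drop = FALSE]
    counts <- table(factor(per_sgb$sgb_id, levels = sgb_ids))
    gene_global <- nrow(dplyr::distinct(fh, .data$genome_id, .data$gene_id))
    gsgb <- dplyr::distinct(fh, .data$genome_id, .data$gene_id)
    gsgb$sgb_id <- sgb$sgb_id[match(gsgb$genome_id, sgb$genome_id)]
    gcounts <- table(factor(gsgb$sgb_id, levels = sgb_ids))
    tibble::tibble(
      family = fam_names[i],
      scope = c("global", sgb_ids),
      n_genomes = c(length(genomes), as.integer(counts)),
      n_cohort = c(cohort_global, as.integer(cohort_by_sgb[sgb_ids])),
      fraction = ifelse(n_cohort > 0, n_genomes / n_cohort, 0),
      n_genes = c(gene_global, as.integer(gcounts)))
  })
  dplyr::bind_rows(rows)
}

#' Prevalence ratio between two families
#'
#' Ratio of genome counts of `family_a` to `family_b` within a scope
#' (`"global"` or one SGB id). `"GH136"` refers to the aggregate family:
#' genomes with at least one subunit.
#'
#' @param table Prevalence tibble from [prevalence()].
#' @param family_a,family_b Family tokens (including `"GH136"`).
#' @param scope `"global"` or an SGB id present in the table.
#' @return Numeric ratio.
#' @export
#' @examples
#' ## a family carried by 26 genomes vs one carried by 10 gives 2.6
prevalence_ratio <- function(table, family_a, family_b, scope = "global") {
  cell <- function(fam) {
    row <- table[table$family == fam & table$scope == scope, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("no prevalence cell for family ", fam, " in scope ", scope)
    }
    row$n_genomes
  }
  a <- cell(family_a)
  b <- cell(family_b)
  if (b == 0L) {
    stop("undefined ratio: family ", family_b, " has zero genomes in scope ",
         scope)
  }
  a / b
}

#' Per-SGB degrader-category summary
#'
#' Contingency counts of primary / secondary / none degrader categories
#' per SGB; every SGB row sums to its cohort size.
#'
#' @param categories Tibble `genome_id`, `category` from
#'   [classify_degraders()].
#' @param sgb SGB assignment tibble.
#' @return Tibble: `sgb_id`, `primary`, `secondary`, `none`, `n_cohort`.
#' @export
degrader_summary <- function(categories, sgb) {
  sgb_ids <- sort(unique(sgb$sgb_id))
  joined <- dplyr::left_join(sgb, categories, by = "genome_id")
  joined$category[is.na(joined$category)] <- "none"
  tab <- table(factor(joined$sgb_id, levels = sgb_ids),
               factor(joined$category,
                      levels = c("primary", "secondary", "none")))
  out <- tibble::tibble(
    sgb_id = sgb_ids,
    primary = as.integer(tab[, "primary"]),
    secondary = as.integer(tab[, "secondary"]),
    none = as.integer(tab[, "none"]))
  out$n_cohort <- out$primary + out$secondary + out$none
  out
}

#' Write prevalence / degrader tables as TSV
#'
#' @param x Tibble from [prevalence()] or [degrader_summary()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
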