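#' Call HMO-utilization loci by GH112 + GH136 co-occurrence
#'
#' A genome carries a locus when it has a GH112 phosphorylase hit and at
#' least one GH136 lacto-N-biosidase subunit hit anywhere in the genome
#' (the co-occurrence rule is genome-wide, not windowed). Every GH112 hit
#' in a qualifying genome anchors one locus; the remaining family hits of
#' the genome are attached as locus members.
#'
#' @param hits Family-hit tibble from [search_homologs()], produced at a
#'   single threshold.
#' @param genes Gene table containing every hit gene.
#' @return Tibble with one row per locus: `genome_id`, `anchor_gene_id`,
#'   `contig_id`, `start`, `end`, `strand`, `anchor_pct_identity`, and a
#'   `members` list-column of the genome's other family hits.
#' @export
detect_loci <- function(hits, genes) {
  validate_gene_table(genes)
  key <- paste(genes$genome_id, genes$gene_id)
  missing <- !paste(hits$genome_id, hits$gene_id) %in% key
  if (any(missing)) {
    stop("hits reference genes absent from the gene table: ",
         paste(unique(hits$gene_id[missing]), collapse = ", "))
  }
  empty <- tibble::tibble(
    genome_id = character(), anchor_gene_id = character(),
    contig_id = character(), start = integer(), end = integer(),
    strand = character(), anchor_pct_identity = numeric(), members = list())
  if (nrow(hits) == 0L) return(empty)

  has_gh136 <- unique(hits$genome_id[hits$family %in% gh136_tokens()])
  anchors <- hits[hits$family == "GH112" & hits$genome_id %in% has_gh136, ,
                  drop = FALSE]
  if (nrow(anchors) == 0L) return(empty)

  gi <- match(paste(anchors$genome_id, anchors$gene_id), key)
  loci <- tibble::tibble(
    genome_id = anchors$genome_id,
    anchor_gene_id = anchors$gene_id,
    contig_id = genes$contig_id[gi],
    start = genes$start[gi],
    end = genes$end[gi],
    strand = genes$strand[gi],
    anchor_pct_identity = anchors$pct_identity,
    members = lapply(seq_len(nrow(anchors)), function(i) {
      hits[hits$genome_id == anchors$genome_id[i] &
             !(hits$gene_id == anchors$gene_id[i] & hits$family == "GH112"), ,
           drop = FALSE]
    })
  )
  dplyr::arrange(loci, .data$genome_id, .data$anchor_gene_id)
}

#' Classify a genome as primary degrader, secondary degrader, or neither
#'
#' `primary`: at least one GH112 hit and at least one GH136 subunit hit —
#' the genome can attack complex HMO and host glycans. `secondary`: GH112
#' hits only — the genome consumes released lacto-/galacto-N-biose.
#' `none`: otherwise.
#'
#' @param hits Family hits of a single genome (may have zero rows).
#' @return One of `"primary"`, `"secondary"`, `"none"`.
#' @export
#' @examples
#' classify_degrader(tibble::tibble(genome_id = "g", gene_id = "a",
#'   family = c("GH112", "GH136_I"), ref_id = "r", pct_identity = 90))
classify_degrader <- function(hits) {
  if (length(unique(hits$genome_id)) > 1L) {
    stop("classify_degrader() expects hits from a single genome; got: ",
         paste(unique(hits$genome_id), collapse = ", "))
  }
  has112 <- any(hits$family == "GH112")
  has136 <- any(hits$family %in% gh136_tokens())
  if (has112 && has136) "primary"
  else if (has112) "secondary"
  else "none"
}

#' Classify every genome of a cohort
#'
#' Applies [classify_degrader()] genome-wise; genomes with no hits at all
#' are `"none"`.
#'
#' @param hits Family-hit tibble for the cohort.
#' @param genome_ids All genome ids in the cohort (so hit-free genomes are
#'   still classified).
#' @return Tibble `genome_id`, `category`.
#' @export
classify_degraders <- function(hits, genome_ids) {
  has112 <- genome_ids %in% hits$genome_id[hits$family == "GH112"]
  has136 <- genome_ids %in% hits$genome_id[hits$family %in% gh136_tokens()]
  tibble::tibble(
    genome_id = genome_ids,
    category = dplyr::case_when(has112 & has136 ~ "primary",
                                has112 ~ "secondary",
                                TRUE ~ "none"))
}

#' Check a landscape for the full locus signature
#'
#' The robust signature of an HMO-utilization locus: the landscape token
#' string contains at least one GH112, at least one GH136 subunit, at
#' least one ABC-transporter component (SBP or PP) and a transcriptional
#' regulator.
#'
#' @param landscape A one-row landscape tibble (from
#'   [extract_landscape()]) or a bare token character vector.
#' @return Logical.
#' @export
#' @examples
#' signature_check(locus_templates()$compact)
signature_check <- function(landscape) {
  tokens <- landscape_tokens(landscape)
  any(tokens == "GH112") &&
    any(tokens %in% gh136_tokens()) &&
    any(tokens %in% c("SBP", "PP")) &&
    any(tokens == "TransR")
}

# Accept either a token vector or a landscape row and return the tokens.
landscape_tokens <- function(landscape) {
  if (is.character(landscape)) return(landscape)
  if (is.data.frame(landscape) && "tokens" %in% names(landscape)) {
    if (nrow(landscape) != 1L) {
      stop("expected a single landscape (one row)")
    }
    return(landscape$tokens[[1]])
  }
  stop("landscape must be a token vector or a one-row landscape tibble")
}

#' Write / read called loci as JSON
#'
#' @param loci Locus tibble from [detect_loci()].
#' @param path File path.
#' @return `path` ([write_loci_json()]) or a locus tibble
#'   ([read_loci_json()]).
#' @export
write_loci_json <- function(loci, path) {
  payload <- lapply(seq_len(nrow(loci)), function(i) {
    list(genome_id = loci$genome_id[i],
         anchor_gene_id = loci$anchor_gene_id[i],
         contig_id = loci$contig_id[i],
         start = loci$start[i], end = loci$end[i],
         strand = loci$strand[i],
         anchor_pct_identity = loci$anchor_pct_identity[i],
         members = loci$members[[i]][, c("gene_id", "family", "ref_id",
                                         "pct_identity")])
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_loci_json
#' @export
read_loci_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(raw, function(x) {
    members <- dplyr::bind_rows(lapply(x$members, function(m) {
      tibble::tibble(genome_id = x$genome_id, gene_id = m$gene_id,
                     family = m$family, ref_id = m$ref_id,
                     pct_identity = as.numeric(m$pct_identity))
    }))
    if (nrow(members) == 0L) {
      members <- tibble::tibble(genome_id = character(), gene_id = character(),
                                family = character(), ref_id = character(),
                                pct_identity = numeric())
    }
    tibble::tibble(genome_id = x$genome_id,
                   anchor_gene_id = x$anchor_gene_id,
                   contig_id = x$contig_id,
                   start = as.integer(x$start), end = as.integer(x$end),
                   strand = x$strand,
                   anchor_pct_identity = as.numeric(x$anchor_pct_identity),
                   members = list(members))
  })
  dplyr::bind_rows(rows)
}
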