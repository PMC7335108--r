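#' Default product-keyword table for tokenization
#'
#' Ordered case-insensitive keyword map applied to a gene's product string
#' when the gene has no family hit; the first matching keyword wins.
#'
#' @return Named character vector mapping keyword to family token.
#' @export
default_token_keywords <- function() {
  c("solute binding"    = "SBP",
    "solute-binding"    = "SBP",
    "permease"          = "PP",
    "histidine kinase"  = "HisK",
    "regulator"         = "TransR",
    "hypothetical"      = "HP")
}

#' Tokenize genes into family tokens
#'
#' A gene with at least one family hit takes its hit token (GH112 first if
#' present, then the best identity, ties towards the alphabetically first
#' family). Otherwise the product string is matched against the keyword
#' table; genes matching nothing become `OTHER`.
#'
#' @param genes Gene table.
#' @param hits Family-hit tibble for the same genomes.
#' @param keywords Keyword map, see [default_token_keywords()].
#' @return Character vector of tokens, one per gene-table row.
#' @export
tokenize_genes <- function(genes, hits, keywords = default_token_keywords()) {
  validate_gene_table(genes)
  tokens <- rep("OTHER", nrow(genes))

  # keyword fallback on products
  prod <- tolower(genes$product)
  prod[is.na(prod)] <- ""
  for (i in seq_along(keywords)) {
    hit <- tokens == "OTHER" & grepl(names(keywords)[i], prod, fixed = TRUE)
    tokens[hit] <- keywords[[i]]
  }

  # family hits take precedence
  if (nrow(hits) > 0L) {
    picked <- hits |>
      dplyr::mutate(is_gh112 = .data$family == "GH112") |>
      dplyr::arrange(.data$genome_id, .data$gene_id,
                     dplyr::desc(.data$is_gh112),
                     dplyr::desc(.data$pct_identity), .data$family) |>
      dplyr::distinct(.data$genome_id, .data$gene_id, .keep_all = TRUE)
    m <- match(paste(genes$genome_id, genes$gene_id),
               paste(picked$genome_id, picked$gene_id))
    tokens[!is.na(m)] <- picked$family[m[!is.na(m)]]
  }
  tokens
}

#' Extract the gene landscape around a GH112 anchor
#'
#' Takes the `n` genes preceding and following the anchor in coordinate
#' order on the anchor's contig (fewer at contig edges, recorded in
#' truncation flags) and tokenizes them. When the anchor lies on the minus
#' strand the gene order is reversed and the truncation flags swapped, so
#' the locus always reads 5'-to-3' left-to-right and plus- and minus-strand
#' loci are directly comparable.
#'
#' @param genes Gene table.
#' @param anchor_gene_id Gene id of the GH112 anchor.
#' @param hits Family-hit tibble (must contain a GH112 hit for the anchor).
#' @param window Flanking genes per side, `n` (default 11).
#' @param keywords Keyword map for tokenization.
#' @return One-row tibble: `genome_id`, `anchor_gene_id`, `window`,
#'   `anchor_index`, `tokens` (list-column), `trunc_upstream`,
#'   `trunc_downstream`.
#' @export
extract_landscape <- function(genes, anchor_gene_id, hits, window = 11L,
                              keywords = default_token_keywords()) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  a <- which(genes$gene_id == anchor_gene_id)
  if (length(a) != 1L) {
    stop("anchor gene not found (or ambiguous): ", anchor_gene_id)
  }
  is_anchor_hit <- hits$gene_id == anchor_gene_id &
    hits$genome_id == genes$genome_id[a] & hits$family == "GH112"
  if (!any(is_anchor_hit)) {
    stop("anchor gene has no GH112 hit: ", anchor_gene_id)
  }

  contig <- genes[genes$genome_id == genes$genome_id[a] &
                    genes$contig_id == genes$contig_id[a], , drop = FALSE]
  contig <- contig[order(contig$start, contig$gene_id), , drop = FALSE]
  p <- which(contig$gene_id == anchor_gene_id)

  lo <- max(1L, p - window)
  hi <- min(nrow(contig), p + window)
  sel <- contig[lo:hi, , drop = FALSE]
  anchor_index <- p - lo + 1L
  trunc_left <- (p - lo) < window
  trunc_right <- (hi - p) < window

  tokens <- tokenize_genes(sel, hits, keywords)
  minus <- contig$strand[p] == "-"
  if (minus) {
    tokens <- rev(tokens)
    anchor_index <- length(tokens) - anchor_index + 1L
    tmp <- trunc_left; trunc_left <- trunc_right; trunc_right <- tmp
  }
  tibble::tibble(
    genome_id = genes$genome_id[a],
    anchor_gene_id = anchor_gene_id,
    window = window,
    anchor_index = anchor_index,
    tokens = list(tokens),
    trunc_upstream = trunc_left,
    trunc_downstream = trunc_right)
}

#' Extract landscapes for all called loci
#'
#' @param genes Gene table.
#' @param loci Locus tibble from [detect_loci()].
#' @param hits Family-hit tibble.
#' @param window Flanking genes per side.
#' @param keywords Keyword map for tokenization.
#' @return Landscape tibble, one row per locus.
#' @export
extract_landscapes <- function(genes, loci, hits, window = 11L,
                               keywords = default_token_keywords()) {
  empty <- tibble::tibble(
    genome_id = character(), anchor_gene_id = character(),
    window = integer(), anchor_index = integer(), tokens = list(),
    trunc_upstream = logical(), trunc_downstream = logical())
  if (nrow(loci) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    extract_landscape(genes[genes$genome_id == loci$genome_id[i], ,
                            drop = FALSE],
                      loci$anchor_gene_id[i], hits, window, keywords)
  })
  dplyr::bind_rows(rows)
}

#' Write / read landscapes as TSV
#'
#' Columns: `genome_id`, `anchor_gene_id`, `window`, `anchor_index`,
#' `tokens` (space-separated), `trunc_upstream`, `trunc_downstream`.
#'
#' @param landscapes Landscape tibble.
#' @param path File path.
#' @return `path` ([write_landscapes_tsv()]) or a landscape tibble
#'   ([read_landscapes_tsv()]).
#' @export
write_landscapes_tsv <- function(landscapes, path) {
  flat <- landscapes
  flat$tokens <- vapply(landscapes$tokens, paste, character(1), collapse = " ")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscapes_tsv
#' @export
read_landscapes_tsv <- function(path) {
  flat <- tibble::as_tibble(read.delim(path, colClasses = c(
    genome_id = "character", anchor_gene_id = "character",
    window = "integer", anchor_index = "integer", tokens = "character",
    trunc_upstream = "logical", trunc_downstream = "logical")))
  flat$tokens <- strsplit(flat$tokens, " ", fixed = TRUE)
  flat
}
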