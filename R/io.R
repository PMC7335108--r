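#' Columns of a gene table
#'
#' The in-memory gene table is one tibble for any number of genomes, one
#' row per annotated gene: `genome_id`, `contig_id`, `gene_id`, `start`,
#' `end` (1-based, inclusive), `strand` (`+`/`-`), `product`, `protein`
#' (may be `NA`).
#'
#' @return Character vector of required column names.
#' @export
gene_table_columns <- function() {
  c("genome_id", "contig_id", "gene_id", "start", "end", "strand",
    "product", "protein")
}

validate_gene_table <- function(genes) {
  missing <- setdiff(gene_table_columns(), names(genes))
  if (length(missing) > 0L) {
    stop("gene table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(genes) == 0L) return(invisible(genes))
  bad <- which(genes$start > genes$end | genes$start < 1L)
  if (length(bad) > 0L) {
    stop("invalid coordinates (start > end or start < 1) for gene(s): ",
         paste(genes$gene_id[head(bad, 5L)], collapse = ", "))
  }
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("unknown strand for gene(s): ",
         paste(genes$gene_id[head(bad, 5L)], collapse = ", "))
  }
  dup <- duplicated(paste(genes$genome_id, genes$gene_id))
  if (any(dup)) {
    stop("duplicate gene ids within a genome: ",
         paste(unique(genes$gene_id[dup]), collapse = ", "))
  }
  invisible(genes)
}

sort_gene_table <- function(genes) {
  genes[order(genes$genome_id, genes$contig_id, genes$start, genes$gene_id), ,
        drop = FALSE]
}

#' Write one genome as GFF3 + protein FASTA
#'
#' GFF3 version 3, one `gene` feature per record with `ID` and `product`
#' attributes; proteins keyed by gene id in the companion FASTA. The
#' writer is deliberately minimal and deterministic (no timestamps), so
#' repeated runs are byte-identical.
#'
#' @param genes Gene table rows of a single genome.
#' @param gff_path Output GFF3 path.
#' @param faa_path Output protein FASTA path (default: `gff_path` with
#'   `.faa` in place of `.gff3`).
#' @return `gff_path`, invisibly.
#' @export
write_genome_gff3 <- function(genes, gff_path,
                              faa_path = sub("\\.gff3$", ".faa", gff_path)) {
  validate_gene_table(genes)
  stopifnot(length(unique(genes$genome_id)) == 1L)
  genes <- sort_gene_table(genes)
  # percent-encode characters reserved in GFF3 attribute values
  esc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub("&", "%26", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    gsub("\t", "%09", x, fixed = TRUE)
  }
  lines <- c(
    "##gff-version 3",
    sprintf("%s\thmoloci\tgene\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
            genes$contig_id, genes$start, genes$end, genes$strand,
            genes$gene_id, esc(genes$product)))
  writeLines(lines, gff_path)
  with_prot <- genes[!is.na(genes$protein) & nchar(genes$protein) > 0L, ,
                     drop = FALSE]
  seqs <- Biostrings::AAStringSet(with_prot$protein)
  names(seqs) <- with_prot$gene_id
  Biostrings::writeXStringSet(seqs, faa_path)
  invisible(gff_path)
}

read_genome_gff3 <- function(gff_path, faa_path, genome_id) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  genes <- tibble::tibble(
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(gr$ID),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(gr$product),
    protein = NA_character_)
  if (any(genes$strand == "*")) {
    stop("record(s) without strand in ", gff_path, ": ",
         paste(genes$gene_id[genes$strand == "*"], collapse = ", "))
  }
  if (!is.null(faa_path) && file.exists(faa_path)) {
    seqs <- Biostrings::readAAStringSet(faa_path)
    m <- match(genes$gene_id, names(seqs))
    genes$protein[!is.na(m)] <- as.character(seqs)[m[!is.na(m)]]
  }
  genes
}

#' Read annotated genomes
#'
#' Accepts either a directory of `<genome_id>.gff3` (+ optional matching
#' `<genome_id>.faa`) pairs, or a single consolidated tab-separated file
#' with the gene-table columns. Records are validated (coordinates,
#' strand, duplicate ids) and sorted by genome, contig and start.
#'
#' @param path Directory of GFF3/FASTA pairs, or a TSV file.
#' @return Gene table tibble (see [gene_table_columns()]).
#' @export
read_genomes <- function(path) {
  if (dir.exists(path)) {
    gffs <- sort(list.files(path, pattern = "\\.gff3$", full.names = TRUE))
    if (length(gffs) == 0L) {
      stop("no .gff3 files found under ", path)
    }
    tables <- lapply(gffs, function(f) {
      gid <- sub("\\.gff3$", "", basename(f))
      read_genome_gff3(f, sub("\\.gff3$", ".faa", f), gid)
    })
    genes <- dplyr::bind_rows(tables)
  } else if (file.exists(path)) {
    genes <- read_gene_table_tsv(path)
  } else {
    stop("no such file or directory: ", path)
  }
  validate_gene_table(genes)
  sort_gene_table(genes)
}

#' Write / read a consolidated gene table TSV
#'
#' @param genes Gene table tibble.
#' @param path File path.
#' @return `path` ([write_gene_table_tsv()]) or a gene table
#'   ([read_gene_table_tsv()]).
#' @export
write_gene_table_tsv <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_gene_table_tsv
#' @export
read_gene_table_tsv <- function(path) {
  genes <- tibble::as_tibble(read.delim(path, colClasses = c(
    genome_id = "character", contig_id = "character", gene_id = "character",
    start = "integer", end = "integer", strand = "character",
    product = "character", protein = "character"), na.strings = ""))
  genes$protein[!is.na(genes$protein) & genes$protein == ""] <- NA_character_
  genes
}

#' Write / read SGB assignments
#'
#' Two-column TSV: `genome_id`, `sgb_id`.
#'
#' @param sgb Assignment tibble.
#' @param path File path.
#' @return `path` or the assignment tibble.
#' @export
write_sgb_tsv <- function(sgb, path) {
  write.table(sgb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sgb_tsv
#' @export
read_sgb_tsv <- function(path) {
  tibble::as_tibble(read.delim(path, colClasses = c(
    genome_id = "character", sgb_id = "character")))
}

#' Write a simulated cohort to disk
#'
#' Per-genome GFF3 + protein FASTA under `dir/genomes/`, SGB assignments
#' (`sgb.tsv`), the reference FASTA (`references.faa`, synthetic
#' sequences) and the ground truth (`ground_truth.json`).
#'
#' @param cohort Cohort list from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  for (gid in unique(cohort$genes$genome_id)) {
    write_genome_gff3(cohort$genes[cohort$genes$genome_id == gid, ,
                                   drop = FALSE],
                      file.path(gdir, paste0(gid, ".gff3")))
  }
  write_sgb_tsv(cohort$sgb, file.path(dir, "sgb.tsv"))
  write_reference_fasta(cohort$refs, file.path(dir, "references.faa"))
  write_truth_json(cohort$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Write / read ground truth JSON
#'
#' @param truth Ground-truth list (`genomes`, `genes` tibbles) from
#'   [simulate_cohort()].
#' @param path File path.
#' @return `path` or the ground-truth list.
#' @export
write_truth_json <- function(truth, path) {
  genomes <- truth$genomes
  genomes$locus_tokens <- lapply(genomes$locus_tokens, as.list)
  jsonlite::write_json(list(genomes = genomes, genes = truth$genes), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  genomes <- dplyr::bind_rows(lapply(raw$genomes, function(x) {
    tibble::tibble(
      genome_id = x$genome_id, sgb_id = x$sgb_id, category = x$category,
      anchor_gene_id = if (is.null(x$anchor_gene_id)) NA_character_ else
        x$anchor_gene_id,
      locus_tokens = list(as.character(unlist(x$locus_tokens))))
  }))
  genes <- dplyr::bind_rows(lapply(raw$genes, function(x) {
    tibble::tibble(genome_id = x$genome_id, gene_id = x$gene_id,
                   family = x$family,
                   target_identity = as.numeric(x$target_identity))
  }))
  list(genomes = genomes, genes = genes)
}
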