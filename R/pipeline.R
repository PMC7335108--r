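#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end analysis: the
#' homolog-screen identity threshold (70 by default, the stringent
#' locus-definition cut-off), the landscape window (11 flanking genes per
#' side by default), the number of ordination axes, the tokenization
#' keyword table, whether `OTHER` tokens take part in landscape
#' comparison, and the input/output paths.
#'
#' @param genomes_path Directory of GFF3/FASTA pairs or consolidated TSV.
#' @param refs_path Reference family FASTA
#'   (`>ref_id|FAMILY|genome_label` headers).
#' @param sgb_path SGB assignment TSV.
#' @param out_dir Output directory.
#' @param identity_threshold Percent-identity threshold in `(0, 100]`.
#' @param window Flanking genes per side of the GH112 anchor (`n >= 1`).
#' @param axes Ordination axes (`k >= 1`).
#' @param include_other Keep `OTHER` tokens in landscape comparison.
#' @param keywords Product-keyword table for tokenization.
#' @param families Family tokens tabulated in the prevalence report.
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed matters when the config drives simulation).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes_path, refs_path, sgb_path, out_dir,
                            identity_threshold = 70, window = 11L,
                            axes = 2L, include_other = TRUE,
                            keywords = default_token_keywords(),
                            families = family_tokens(), seed = 1L) {
  if (identity_threshold <= 0 || identity_threshold > 100) {
    stop("identity_threshold must lie in (0, 100]")
  }
  if (window < 1L) stop("window must be >= 1")
  if (axes < 1L) stop("axes must be >= 1")
  structure(list(
    genomes_path = genomes_path, refs_path = refs_path, sgb_path = sgb_path,
    out_dir = out_dir, identity_threshold = identity_threshold,
    window = as.integer(window), axes = as.integer(axes),
    include_other = isTRUE(include_other), keywords = keywords,
    families = families, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys take the
#' defaults. Values passed through `overrides` (e.g. from CLI flags) win
#' over the file.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  conf <- yaml::read_yaml(path)
  conf[names(overrides)] <- overrides
  keywords <- if (is.null(conf$keywords)) default_token_keywords() else
    unlist(conf$keywords)
  pipeline_config(
    genomes_path = conf$genomes_path, refs_path = conf$refs_path,
    sgb_path = conf$sgb_path, out_dir = conf$out_dir,
    identity_threshold = conf$identity_threshold %||% 70,
    window = conf$window %||% 11L, axes = conf$axes %||% 2L,
    include_other = conf$include_other %||% TRUE,
    keywords = keywords,
    families = conf$families %||% family_tokens(),
    seed = conf$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full locus-mining pipeline
#'
#' Stages: homolog screen -> locus calling -> landscape extraction ->
#' OSA distance matrix + PCoA + per-SGB representatives -> prevalence and
#' degrader reporting. All artifacts are written under the configured
#' output directory together with a run manifest (parameters, seed, input
#' digests, package version); identical inputs and config reproduce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage-progress messages on standard error.
#' @return Invisibly, a list with every intermediate result (`hits`,
#'   `loci`, `landscapes`, `distance`, `ordination`, `representatives`,
#'   `prevalence`, `degrader_summary`, `categories`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "read_genomes"
  result <- tryCatch({
    genes <- read_genomes(config$genomes_path)
    refs <- read_reference_fasta(config$refs_path)
    sgb <- read_sgb_tsv(config$sgb_path)
    say("read ", length(unique(genes$genome_id)), " genomes, ",
        nrow(refs), " references, ", nrow(sgb), " SGB assignments")

    stage <- "search"
    hits <- search_homologs(genes, refs, config$identity_threshold)
    write_hits_tsv(hits, file.path(config$out_dir, "hits.tsv"))
    say("search: ", nrow(hits), " family hits at threshold ",
        config$identity_threshold)

    stage <- "loci"
    loci <- detect_loci(hits, genes)
    write_loci_json(loci, file.path(config$out_dir, "loci.json"))
    categories <- classify_degraders(hits, sort(unique(sgb$genome_id)))
    say("loci: ", nrow(loci), " loci in ",
        length(unique(loci$genome_id)), " genomes")

    stage <- "landscape"
    landscapes <- extract_landscapes(genes, loci, hits, config$window,
                                     config$keywords)
    write_landscapes_tsv(landscapes,
                         file.path(config$out_dir, "landscapes.tsv"))
    say("landscape: ", nrow(landscapes), " landscapes (window ",
        config$window, ")")

    stage <- "compare"
    if (nrow(landscapes) > 0L) {
      D <- landscape_distance_matrix(landscapes, config$include_other)
      write_distance_tsv(D, file.path(config$out_dir, "distance_matrix.tsv"))
      ord <- if (nrow(landscapes) > config$axes) {
        pcoa(D, config$axes)
      } else NULL
      if (!is.null(ord)) {
        write_ordination_tsv(ord, file.path(config$out_dir, "ordination.tsv"))
      }
      reps <- representative_landscapes(landscapes, sgb,
                                        config$include_other)
      reps$signature <- vapply(seq_len(nrow(reps)), function(i)
        signature_check(reps[i, ]), logical(1))
      write_landscapes_tsv(
        reps[, c(names(landscapes), "sgb_id", "n_landscapes", "signature")],
        file.path(config$out_dir, "representatives.tsv"))
    } else {
      D <- matrix(integer(0), 0, 0)
      ord <- NULL
      reps <- NULL
      # empty cohorts still produce the full artifact set
      writeLines("id", file.path(config$out_dir, "distance_matrix.tsv"))
      write_landscapes_tsv(
        tibble::tibble(genome_id = character(), anchor_gene_id = character(),
                       window = integer(), anchor_index = integer(),
                       tokens = list(), trunc_upstream = logical(),
                       trunc_downstream = logical(), sgb_id = character(),
                       n_landscapes = integer(), signature = logical()),
        file.path(config$out_dir, "representatives.tsv"))
    }
    say("compare: distance matrix ", nrow(D), " x ", ncol(D))

    stage <- "report"
    prev <- prevalence(hits, sgb, config$families)
    write_report_tsv(prev, file.path(config$out_dir, "prevalence.tsv"))
    degr <- degrader_summary(categories, sgb)
    write_report_tsv(degr, file.path(config$out_dir, "degrader_summary.tsv"))
    say("report: ", sum(degr$primary), " primary / ", sum(degr$secondary),
        " secondary / ", sum(degr$none), " none")

    stage <- "manifest"
    manifest <- list(
      package = "hmoloci",
      version = as.character(utils::packageVersion("hmoloci")),
      parameters = list(
        identity_threshold = config$identity_threshold,
        window = config$window, axes = config$axes,
        include_other = config$include_other,
        families = config$families,
        keywords = as.list(config$keywords),
        seed = config$seed),
      inputs = list(
        genomes_path = config$genomes_path,
        refs_path = config$refs_path,
        sgb_path = config$sgb_path,
        digests = input_digests(config)),
      counts = list(
        genomes = length(unique(genes$genome_id)),
        hits = nrow(hits), loci = nrow(loci),
        landscapes = nrow(landscapes)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(hits = hits, loci = loci, landscapes = landscapes, distance = D,
         ordination = ord, representatives = reps, prevalence = prev,
         degrader_summary = degr, categories = categories,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

input_digests <- function(config) {
  paths <- c(config$refs_path, config$sgb_path)
  if (dir.exists(config$genomes_path)) {
    paths <- c(paths, sort(list.files(config$genomes_path,
                                      full.names = TRUE)))
  } else {
    paths <- c(paths, config$genomes_path)
  }
  digests <- tools::md5sum(paths)
  stats::setNames(as.list(unname(digests)), basename(paths))
}
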