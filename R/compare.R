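#' Optimal string alignment distance between token strings
#'
#' Restricted Damerau-Levenshtein distance: unit-cost insertion, deletion,
#' substitution and adjacent transposition, with no substring edited more
#' than once. Computed over whole tokens, not characters, so
#' multi-character tokens cannot alias. Note OSA violates the triangle
#' inequality (e.g. `CA -> AC -> ABC` costs 2 but `osa_distance(CA, ABC)`
#' is 3).
#'
#' @param s,t Character vectors of tokens.
#' @return Non-negative integer distance.
#' @export
#' @examples
#' osa_distance(c("GH136_I", "GH136_II"), c("GH136_II", "GH136_I"))  # 1
#' osa_distance(c("C", "A"), c("A", "B", "C"))                       # 3
osa_distance <- function(s, t) {
  stopifnot(is.character(s), is.character(t))
  alphabet <- unique(c(s, t))
  .osa_dist_cpp(match(s, alphabet), match(t, alphabet))
}

#' Pairwise OSA distance matrix of landscapes
#'
#' Both gene membership and gene position influence the distance: a gene
#' present in one landscape but not the other costs an indel, a gene in a
#' different position costs substitutions or a transposition.
#'
#' @param landscapes Landscape tibble (>= 1 row).
#' @param include_other Keep `OTHER` tokens in the comparison (default);
#'   with `FALSE` they are dropped from every token string first.
#' @return Symmetric integer matrix with landscape ids
#'   (`genome_id:anchor_gene_id`) as dimnames.
#' @export
landscape_distance_matrix <- function(landscapes, include_other = TRUE) {
  if (nrow(landscapes) == 0L) {
    stop("need at least one landscape")
  }
  toks <- landscapes$tokens
  if (!include_other) {
    toks <- lapply(toks, function(x) x[x != "OTHER"])
  }
  alphabet <- unique(unlist(toks, use.names = FALSE))
  coded <- lapply(toks, function(x) match(x, alphabet))
  D <- .osa_dist_matrix_cpp(coded)
  ids <- landscape_ids(landscapes)
  dimnames(D) <- list(ids, ids)
  D
}

landscape_ids <- function(landscapes) {
  paste(landscapes$genome_id, landscapes$anchor_gene_id, sep = ":")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: the squared distances are double-centered
#' (`B = -1/2 J D^2 J`), eigendecomposed, and coordinates are the
#' eigenvectors scaled by the square roots of their eigenvalues.
#' Negative eigenvalues — expected here, since OSA distances are not
#' Euclidean — are clamped to zero and reported.
#'
#' @param D Square symmetric distance matrix (zero diagonal).
#' @param k Number of ordination axes, `1 <= k < nrow(D)`.
#' @return Object of class `hmo_pcoa`: list with `ids`, `points`
#'   (n x k matrix), `eigenvalues` (all n, descending, clamped) and
#'   `negative_eigenvalues` (the original values of the clamped ones).
#' @export
#' @examples
#' D <- matrix(c(0, 4, 4, 0), 2)
#' pcoa(D, k = 1)$points  # axis-1 separation is exactly 4
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0)) {
    stop("D must be a square symmetric matrix with zero diagonal")
  }
  k <- as.integer(k)
  if (k < 1L || k >= n) {
    stop("k must satisfy 1 <= k < number of items")
  }
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- eig$values            # already descending
  neg <- lambda[lambda < 0]
  clamped <- pmax(lambda, 0)
  pts <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(clamped[seq_len(k)]), nrow = k)
  colnames(pts) <- paste0("axis", seq_len(k))
  rownames(pts) <- rownames(D)
  structure(list(ids = rownames(D), points = pts, eigenvalues = clamped,
                 negative_eigenvalues = neg),
            class = "hmo_pcoa")
}

#' @export
print.hmo_pcoa <- function(x, ...) {
  cat("PCoA ordination:", length(x$ids), "items,",
      ncol(x$points), "axes\n")
  pos <- sum(x$eigenvalues > 0)
  cat("  positive eigenvalues:", pos,
      "| clamped negative:", length(x$negative_eigenvalues), "\n")
  if (sum(x$eigenvalues) > 0) {
    cat("  variance explained by reported axes:",
        sprintf("%.1f%%", 100 * sum(x$eigenvalues[seq_len(ncol(x$points))]) /
                  sum(x$eigenvalues)), "\n")
  }
  invisible(x)
}

#' Most conserved landscape of a group
#'
#' Operationalizes "most conserved gene neighborhood" as the modal token
#' string of the group; ties are broken by (i) minimal mean OSA distance
#' to all group members, then (ii) the lexicographically smallest token
#' string. The result is always a member of the input group.
#'
#' @param landscapes Landscape tibble of one group (e.g. one SGB).
#' @param include_other Passed to [landscape_distance_matrix()].
#' @return One-row landscape tibble.
#' @export
representative_landscape <- function(landscapes, include_other = TRUE) {
  if (is.null(landscapes) || nrow(landscapes) == 0L) {
    stop("representative_landscape() needs a non-empty group")
  }
  strings <- vapply(landscapes$tokens, paste, character(1), collapse = " ")
  counts <- table(strings)
  best <- names(counts)[counts == max(counts)]
  if (length(best) > 1L) {
    D <- landscape_distance_matrix(landscapes, include_other = include_other)
    mean_d <- rowMeans(D)
    cand_mean <- vapply(best, function(s) min(mean_d[strings == s]),
                        numeric(1))
    best <- best[cand_mean == min(cand_mean)]
    best <- sort(best)[1L]
  }
  landscapes[which(strings == best)[1L], , drop = FALSE]
}

#' Representative landscape per SGB
#'
#' @param landscapes Landscape tibble for the cohort.
#' @param sgb SGB assignment tibble (`genome_id`, `sgb_id`).
#' @param include_other Passed to [representative_landscape()].
#' @return Landscape tibble with an `sgb_id` column, one row per SGB that
#'   has at least one landscape.
#' @export
representative_landscapes <- function(landscapes, sgb, include_other = TRUE) {
  joined <- dplyr::inner_join(landscapes, sgb, by = "genome_id")
  rows <- lapply(split(joined, joined$sgb_id), function(grp) {
    rep_row <- representative_landscape(grp, include_other = include_other)
    rep_row$n_landscapes <- nrow(grp)
    rep_row
  })
  dplyr::bind_rows(rows)
}

#' Write a distance matrix / ordination to TSV
#'
#' @param D Distance matrix with dimnames.
#' @param ord `hmo_pcoa` object.
#' @param path File path (for the ordination, eigenvalues go to
#'   `<path>.eigenvalues.tsv`).
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(id = rownames(D), D, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
write_ordination_tsv <- function(ord, path) {
  df <- data.frame(id = ord$ids, ord$points, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- data.frame(axis = seq_along(ord$eigenvalues),
                   eigenvalue = ord$eigenvalues)
  write.table(ev, paste0(path, ".eigenvalues.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
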