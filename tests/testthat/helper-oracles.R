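# Independent reference implementations used as oracles. Kept deliberately
# simple and separate from the package's compiled kernels.

# Global alignment identity by explicit (score, matches) matrices in R.
r_nw_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  la <- length(x); lb <- length(y)
  S <- matrix(0, la + 1, lb + 1)
  M <- matrix(0, la + 1, lb + 1)
  S[, 1] <- -(0:la)
  S[1, ] <- -(0:lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      m <- as.integer(x[i] == y[j])
      cand_s <- c(S[i, j] + m, S[i, j + 1] - 1, S[i + 1, j] - 1)
      cand_m <- c(M[i, j] + m, M[i, j + 1], M[i + 1, j])
      best <- max(cand_s)
      pick <- cand_s == best
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- max(cand_m[pick])
    }
  }
  s <- S[la + 1, lb + 1]; m <- M[la + 1, lb + 1]
  200 * m / (la + lb + m - s)
}

# Plain recursive OSA distance over token vectors (no memoization);
# only usable for short strings.
r_osa <- function(s, t) {
  i <- length(s); j <- length(t)
  if (i == 0) return(j)
  if (j == 0) return(i)
  d <- r_osa(s[-i], t[-j]) + as.integer(s[i] != t[j])
  d <- min(d, r_osa(s[-i], t) + 1L, r_osa(s, t[-j]) + 1L)
  if (i > 1 && j > 1 && s[i] == t[j - 1] && s[i - 1] == t[j]) {
    d <- min(d, r_osa(s[seq_len(i - 2)], t[seq_len(j - 2)]) + 1L)
  }
  d
}

# Unrestricted Damerau-Levenshtein (transposed symbols may take part in
# further edits), by the Lowrance-Wagner algorithm.
r_dl_unrestricted <- function(s, t) {
  alphabet <- unique(c(s, t))
  la <- length(s); lb <- length(t)
  d <- matrix(0L, la + 2, lb + 2)
  maxdist <- la + lb
  d[1, ] <- maxdist
  d[, 1] <- maxdist
  d[2, 2:(lb + 2)] <- 0:lb
  d[2:(la + 2), 2] <- 0:la
  last_row <- stats::setNames(rep(0L, length(alphabet)), alphabet)
  for (i in seq_len(la)) {
    last_col <- 0L
    for (j in seq_len(lb)) {
      i1 <- last_row[[t[j]]]
      j1 <- last_col
      cost <- as.integer(s[i] != t[j])
      if (cost == 0L) last_col <- j
      d[i + 2, j + 2] <- min(
        d[i + 1, j + 1] + cost,
        d[i + 1, j + 2] + 1L,
        d[i + 2, j + 1] + 1L,
        d[i1 + 1, j1 + 1] + (i - i1 - 1L) + 1L + (j - j1 - 1L))
    }
    last_row[[s[i]]] <- i
  }
  d[la + 2, lb + 2]
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_protein_fixture <- random_aa_string

random_token_string <- function(max_len, alphabet = c("A", "B", "C", "D")) {
  n <- sample(0:max_len, 1)
  if (n == 0) character(0) else sample(alphabet, n, replace = TRUE)
}
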