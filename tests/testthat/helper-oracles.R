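# Independent oracles used to validate package computations.

# Plain-R affine-gap Smith-Waterman, score only. Written against the
# recurrences directly (row loop with an explicit column loop); kept
# independent of the compiled implementation it checks.
sw_oracle <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  A <- utf8ToInt(a); B <- utf8ToInt(b)
  n <- length(A); m <- length(B)
  Hprev <- numeric(m + 1)
  Fprev <- rep(-Inf, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    s <- ifelse(A[i] == B, match, mismatch)
    Fcur <- pmax(Hprev - open - ext, Fprev - ext)
    H <- numeric(m + 1)
    E <- -Inf
    for (j in seq_len(m)) {
      E <- max(H[j] - open - ext, E - ext)
      H[j + 1] <- max(0, Hprev[j] + s[j], E, Fcur[j + 1])
    }
    best <- max(best, H)
    Hprev <- H; Fprev <- Fcur
  }
  best
}

# Adjusted Rand index from a contingency table of two labelings.
ari <- function(tab) {
  n <- sum(tab)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  e <- b * cc / choose(n, 2)
  (a - e) / ((b + cc) / 2 - e)
}

# Reciprocal overlap of two 0-based half-open intervals: the overlap as a
# fraction of whichever interval is covered worse.
reciprocal_overlap <- function(a1, a2, b1, b2) {
  ov <- max(0, min(a2, b2) - max(a1, b1))
  min(ov / (a2 - a1), ov / (b2 - b1))
}

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

mutate_string <- function(s, positions, to) {
  x <- strsplit(s, "")[[1]]
  x[positions] <- to
  paste(x, collapse = "")
}
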