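#' GC content of sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both numerator
#' and denominator. A sequence with no unambiguous base has undefined GC
#' and is reported as `NA` with a warning.
#'
#' @param seqs Character vector of sequences over `{A,C,G,T,N}`.
#' @return Numeric vector of GC fractions in `[0, 1]` (or `NA`).
#' @export
compute_gc <- function(seqs) {
  stopifnot(is.character(seqs), all(nzchar(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(cnt)
  gc <- (cnt[, "G"] + cnt[, "C"]) / denom
  if (any(denom == 0)) {
    warning("GC undefined for ", sum(denom == 0),
            " sequence(s) containing only ambiguous bases")
    gc[denom == 0] <- NA_real_
  }
  unname(gc)
}

#' Oligonucleotide (k-mer) frequencies of a sequence
#'
#' Counts overlapping length-`k` words on the given strand only (no
#' reverse-complement collapsing, mirroring classic word-frequency tools);
#' words containing `N` are skipped. Frequencies are normalized to sum to 1
#' and returned in lexicographic word order.
#'
#' @param seq Character scalar.
#' @param k Word size (default 4, tetranucleotides — the field standard for
#'   composition-based binning).
#' @param collapse Collapse each word with its reverse complement
#'   (canonical k-mers) before normalizing.
#' @return Named numeric vector of length `4^k` summing to 1.
#' @export
kmer_freqs <- function(seq, k = 4L, collapse = FALSE) {
  assert_seq(seq)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nchar(seq) < k) stop("sequence shorter than k")
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), k)
  if (collapse) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(names(cnt))))
    cnt <- cnt + cnt[rc]
  }
  tot <- sum(cnt)
  if (tot == 0) stop("no valid ", k, "-mer window (all contain N)")
  cnt / tot
}

#' Composition profiles for a contig set
#'
#' One row per contig: id, length, GC fraction, and the `4^k` k-mer
#' frequency columns.
#'
#' @param contigs Named character vector of contig sequences.
#' @param k Word size.
#' @return Data frame of class `composition_profiles` with attribute `k`.
#' @export
composition_profiles <- function(contigs, k = 4L) {
  stopifnot(is.character(contigs), length(contigs) >= 1L,
            !is.null(names(contigs)))
  freqs <- t(vapply(contigs, kmer_freqs, numeric(4L^k), k = k))
  df <- data.frame(contig_id = names(contigs),
                   length = unname(nchar(contigs)),
                   gc = compute_gc(contigs),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(freqs, row.names = NULL))
  attr(df, "k") <- as.integer(k)
  class(df) <- c("composition_profiles", "data.frame")
  df
}

freq_matrix <- function(profiles) {
  stopifnot(inherits(profiles, "composition_profiles"))
  m <- as.matrix(profiles[, -(1:3), drop = FALSE])
  rownames(m) <- profiles$contig_id
  m
}

#' Principal-component projection of composition profiles
#'
#' Column-centers the k-mer frequency matrix (no variance scaling —
#' frequencies share a scale) and decomposes it by SVD. Component signs are
#' fixed so that each component's largest-magnitude loading is positive,
#' making projections reproducible across platforms. Reference profiles can
#' be projected into the fitted space afterwards with
#' [project_profiles()] without influencing the fit.
#'
#' @param profiles A [composition_profiles()] data frame with at least two
#'   rows.
#' @param n_components Number of components to report (`P`); at most
#'   `min(nrow - 1, 4^k)`.
#' @return List of class `pca_projection`: `projection` (data frame of
#'   contig ids and `PC1..PCP`), `explained_variance` over all computed
#'   components, plus the rotation, centers and singular-value sdev needed
#'   to project new profiles.
#' @export
pca_project <- function(profiles, n_components = 2L) {
  m <- freq_matrix(profiles)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 profiles for PCA")
  n_components <- as.integer(n_components)
  max_p <- min(n - 1L, ncol(m))
  if (n_components < 1L || n_components > max_p)
    stop("n_components must be in [1, ", max_p, "]")
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(pr$sdev^2)
  ev <- if (tot > 0) pr$sdev^2 / tot else rep(0, length(pr$sdev))
  proj <- data.frame(contig_id = profiles$contig_id,
                     scores[, seq_len(n_components), drop = FALSE],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(projection = proj,
                 explained_variance = ev,
                 rotation = rot, centers = pr$center, sdev = pr$sdev,
                 n_components = n_components),
            class = "pca_projection")
}

#' Project additional profiles into a fitted PCA space
#'
#' @param fit A [pca_project()] result.
#' @param profiles Profiles to project (e.g. reference genomes); they do
#'   not influence the fitted components.
#' @return Data frame of contig ids and coordinates on the fitted
#'   components.
#' @export
project_profiles <- function(fit, profiles) {
  stopifnot(inherits(fit, "pca_projection"))
  m <- freq_matrix(profiles)
  if (!identical(colnames(m), rownames(fit$rotation)))
    stop("profiles were computed with a different word size than the fit")
  sc <- sweep(m, 2L, fit$centers) %*%
    fit$rotation[, seq_len(fit$n_components), drop = FALSE]
  data.frame(contig_id = profiles$contig_id, sc,
             stringsAsFactors = FALSE, row.names = NULL)
}
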