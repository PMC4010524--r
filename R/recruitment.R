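#' Recruit a read pool onto a genome
#'
#' Each read is placed at its best local-alignment locus (seeded banded
#' Smith-Waterman against a k-mer index of the genome) and recruited when
#' it reaches `min_identity` percent identity over at least `min_cov` of
#' its length. Recruited reads increment the count of every window
#' overlapping their subject span; windows tile the genome at the given
#' step and density is the count divided by the window's actual length
#' (reads per base).
#'
#' @param reads Named character vector of reads.
#' @param genome Genome sequence.
#' @param min_identity Percent identity cutoff.
#' @param min_cov Minimum aligned fraction of the read length.
#' @param window,step Window size and tiling step in bases.
#' @param band,seed_k Banded-alignment parameters (see [align_local()]).
#' @param scoring An [alignment_scoring()] list.
#' @param genome_id Label carried into the profile.
#' @return Object of class `recruitment_profile`: a data frame of windows
#'   (`start`, `end`, `count`, `density`) with the genome-wide median
#'   density, recruitment counts and per-read placements in attributes.
#' @export
recruit <- function(reads, genome, min_identity = 50, min_cov = 0.7,
                    window = 1000L, step = 500L, band = 48L, seed_k = 13L,
                    scoring = alignment_scoring(), genome_id = "genome") {
  stopifnot(length(reads) >= 1L)
  assert_seq(genome, "genome")
  L <- nchar(genome)
  window <- as.integer(window); step <- as.integer(step)
  idx <- cpp_kmer_index(genome, as.integer(seed_k))
  hits <- cpp_map_reads(idx, unname(reads), as.integer(band),
                        scoring$match, scoring$mismatch,
                        -scoring$gap_open, -scoring$gap_ext)
  ident <- ifelse(hits[, "columns"] > 0,
                  100 * hits[, "matches"] / hits[, "columns"], NA_real_)
  recruited <- hits[, "found"] == 1 & !is.na(ident) &
    ident >= min_identity & hits[, "columns"] >= min_cov * nchar(reads)
  spans <- matrix(NA_integer_, nrow = length(reads), ncol = 2L,
                  dimnames = list(names(reads), c("start", "end")))
  spans[recruited, 1L] <- as.integer(hits[recruited, "s_start"])
  spans[recruited, 2L] <- as.integer(hits[recruited, "s_end"])

  win_starts <- seq.int(0L, max(0L, L - 1L), by = step)
  win_starts <- win_starts[win_starts < L]
  win_ends <- pmin(win_starts + window, L)
  counts <- integer(length(win_starts))
  for (i in which(recruited)) {
    s <- spans[i, 1L]; e <- spans[i, 2L]
    # windows with win_start < e and win_end > s
    lo <- max(1L, ceiling((s - window) / step) + 1L)
    hi <- min(length(win_starts), floor((e - 1L) / step) + 1L)
    if (lo > hi) next
    j <- lo:hi
    j <- j[win_ends[j] > s]
    counts[j] <- counts[j] + 1L
  }
  density <- counts / (win_ends - win_starts)
  prof <- data.frame(start = win_starts, end = win_ends, count = counts,
                     density = density)
  structure(prof,
            class = c("recruitment_profile", "data.frame"),
            genome_id = genome_id, window = window, step = step,
            genome_length = L,
            median_density = median(density),
            n_reads = length(reads), n_recruited = sum(recruited),
            read_spans = spans)
}

#' Detect genomic islands as under-recruited regions
#'
#' Scans a recruitment profile for maximal runs of windows whose density
#' falls below `density_ratio_threshold` times the genome-wide median,
#' merges runs separated by less than `merge_gap` bases, and reports runs
#' strictly longer than `min_len` (the classic ">15 kb" island rule).
#' Boundaries snap to window edges, so reported coordinates carry an
#' uncertainty of about one tiling step.
#'
#' @param profile A [recruit()] result.
#' @param min_len Minimum island length in bases (strict inequality).
#' @param density_ratio_threshold Fraction of the median density below
#'   which a window counts as under-recruited.
#' @param merge_gap Runs closer than this many bases are merged.
#' @return Data frame of class `genomic_islands`: `island_id`, `start`,
#'   `end`, `length`, `mean_density`, `density_ratio`.
#' @export
detect_islands <- function(profile, min_len = 15000L,
                           density_ratio_threshold = 0.2,
                           merge_gap = 2000L) {
  stopifnot(inherits(profile, "recruitment_profile"), nrow(profile) >= 1L)
  med <- attr(profile, "median_density")
  empty <- data.frame(island_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mean_density = numeric(0), density_ratio = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("genomic_islands", "data.frame")
  if (med == 0) {
    warning("median recruitment density is 0; cannot call islands")
    return(empty)
  }
  low <- profile$density < density_ratio_threshold * med
  if (!any(low)) return(empty)
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- data.frame(start = profile$start[starts_i[r$values]],
                     end = profile$end[ends_i[r$values]])
  runs <- runs[order(runs$start), , drop = FALSE]
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] < merge_gap)
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], runs$end[i])
    else merged <- rbind(merged, runs[i, ])
  }
  merged$length <- merged$end - merged$start
  merged <- merged[merged$length > min_len, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  mean_density <- vapply(seq_len(nrow(merged)), function(i) {
    inside <- profile$start >= merged$start[i] & profile$end <= merged$end[i]
    if (any(inside)) mean(profile$density[inside]) else 0
  }, numeric(1))
  out <- data.frame(island_id = sprintf("GI_%02d", seq_len(nrow(merged))),
                    start = merged$start, end = merged$end,
                    length = merged$length,
                    mean_density = mean_density,
                    density_ratio = mean_density / med,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("genomic_islands", "data.frame")
  out
}

#' GC skew along a genome
#'
#' `(G - C) / (G + C)` in sliding windows (25 kb windows stepped every
#' 1 kb by default, the classic replication-strand diagnostic track).
#' Windows without any G or C report a skew of 0 with `undefined = TRUE`.
#' A genome shorter than one window yields a single whole-genome value
#' with a warning.
#'
#' @param genome Genome sequence.
#' @param window,step Window size and step in bases.
#' @return Data frame with `start`, `end`, `skew`, `undefined`.
#' @export
gc_skew <- function(genome, window = 25000L, step = 1000L) {
  assert_seq(genome)
  L <- nchar(genome)
  x <- seq_to_chars(genome)
  cg <- cumsum(x == "G")
  cc <- cumsum(x == "C")
  if (L < window) {
    warning("genome shorter than one window; returning whole-genome skew")
    starts <- 0L; ends <- L
  } else {
    starts <- seq.int(0L, L - window, by = as.integer(step))
    ends <- starts + as.integer(window)
  }
  g <- cg[ends] - c(0, cg)[starts + 1L]
  c_ <- cc[ends] - c(0, cc)[starts + 1L]
  tot <- g + c_
  skew <- ifelse(tot == 0, 0, (g - c_) / tot)
  data.frame(start = starts, end = ends, skew = skew,
             undefined = tot == 0)
}

#' Codon usage table of a gene set
#'
#' Counts in-frame codons (frame 0 of each CDS) pooled over all genes and
#' normalizes to fractions over the 64 codons in lexicographic order.
#' Sequences whose length is not divisible by 3 have their trailing
#' partial codon dropped, with a warning.
#'
#' @param gene_sequences Character vector of CDS sequences.
#' @return Object of class `codon_usage_table`: named numeric vector of 64
#'   codon fractions with the total codon count in attribute `n_codons`.
#' @export
codon_usage <- function(gene_sequences) {
  if (length(gene_sequences) == 0L) stop("no gene sequences")
  stopifnot(is.character(gene_sequences), all(nzchar(gene_sequences)))
  if (any(nchar(gene_sequences) %% 3 != 0))
    warning("dropping trailing partial codons in ",
            sum(nchar(gene_sequences) %% 3 != 0), " gene(s)")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(gene_sequences), width = 3L, step = 3L)
  tot_counts <- colSums(counts)
  n <- sum(tot_counts)
  if (n == 0) stop("no complete codon in input")
  structure(tot_counts / n, n_codons = n, class = "codon_usage_table")
}

#' Squared-difference codon usage deviation
#'
#' `sum over 64 codons of (f_a - f_b)^2`: symmetric, zero iff the tables
#' are identical. Elevated values between a gene set and the genome's core
#' genes flag putatively horizontally transferred regions.
#'
#' @param table_a,table_b [codon_usage()] tables.
#' @return Nonnegative numeric scalar.
#' @export
codon_deviation <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "codon_usage_table"),
            inherits(table_b, "codon_usage_table"))
  sum((unclass(table_a) - unclass(table_b))^2)
}

#' Codon-usage deviation of islands against the core genome
#'
#' Pools the genes inside each island, pools the genes outside all islands
#' ("core"), and scores the deviation of each island's codon table (and of
#' all island genes together) against the core table. A permutation null
#' drawing random core-gene subsets of matching size gives the percentile
#' of the pooled island score.
#'
#' @param genome Genome sequence.
#' @param islands A [detect_islands()] result (or any data frame with
#'   `start`/`end`).
#' @param genes Gene-call data frame with 0-based half-open `start`/`end`
#'   on the genome.
#' @param n_resamples Size of the core-subset permutation null (0 to skip).
#' @param seed Seed for the resampling.
#' @return List with `islands` (the input plus a `codon_deviation`
#'   column), `pooled_deviation`, `null_scores` and `pooled_percentile`.
#' @export
island_codon_deviation <- function(genome, islands, genes,
                                   n_resamples = 200L, seed = 1) {
  assert_seq(genome)
  gene_seq <- function(rows)
    substring(genome, rows$start + 1L, rows$end)
  in_island <- rep(FALSE, nrow(genes))
  which_island <- rep(NA_integer_, nrow(genes))
  for (i in seq_len(nrow(islands))) {
    hit <- genes$start < islands$end[i] & genes$end > islands$start[i]
    in_island <- in_island | hit
    which_island[hit] <- i
  }
  if (!any(in_island)) stop("no gene overlaps an island")
  if (all(in_island)) stop("no core gene outside the islands")
  core_tab <- codon_usage(gene_seq(genes[!in_island, , drop = FALSE]))
  island_dev <- vapply(seq_len(nrow(islands)), function(i) {
    rows <- genes[which(which_island == i), , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    codon_deviation(codon_usage(gene_seq(rows)), core_tab)
  }, numeric(1))
  pooled_tab <- codon_usage(gene_seq(genes[in_island, , drop = FALSE]))
  pooled <- codon_deviation(pooled_tab, core_tab)
  null_scores <- numeric(0)
  pct <- NA_real_
  if (n_resamples > 0L) {
    core_rows <- which(!in_island)
    m <- sum(in_island)
    null_scores <- with_seed(seed, vapply(seq_len(n_resamples), function(r) {
      pick <- sample(core_rows, min(m, length(core_rows)))
      codon_deviation(codon_usage(gene_seq(genes[pick, , drop = FALSE])),
                      core_tab)
    }, numeric(1)))
    pct <- mean(pooled > null_scores)
  }
  islands$codon_deviation <- island_dev
  list(islands = islands, pooled_deviation = pooled,
       null_scores = null_scores, pooled_percentile = pct)
}
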