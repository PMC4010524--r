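#' Default local-alignment scoring
#'
#' Match +1, mismatch -1, gap open -2, gap extend -1; a gap of length L
#' scores `gap_open + L * gap_ext`.
#'
#' @return Named list of the four signed scores.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                              gap_ext = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_ext <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

aln_from_cpp <- function(r, query_id = NA_character_,
                         subject_id = NA_character_) {
  if (!r$found || r$score <= 0) {
    return(structure(list(query_id = query_id, subject_id = subject_id,
                          no_hit = TRUE, score = 0,
                          identity_percent = NA_real_, aligned_length = 0L,
                          matches = 0L, query_span = c(NA_integer_,
                                                       NA_integer_),
                          subject_span = c(NA_integer_, NA_integer_)),
                     class = "local_alignment"))
  }
  structure(list(
    query_id = query_id, subject_id = subject_id, no_hit = FALSE,
    score = r$score,
    identity_percent = 100 * r$matches / r$columns,
    aligned_length = as.integer(r$columns),
    matches = as.integer(r$matches),
    query_span = c(as.integer(r$q_start), as.integer(r$q_end)),
    subject_span = c(as.integer(r$s_start), as.integer(r$s_end))),
    class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  if (x$no_hit) cat("<local_alignment> no hit\n")
  else cat(sprintf(
    "<local_alignment> score %.0f, identity %.1f%% over %d columns, q[%d,%d) s[%d,%d)\n",
    x$score, x$identity_percent, x$aligned_length,
    x$query_span[1], x$query_span[2], x$subject_span[1], x$subject_span[2]))
  invisible(x)
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman local alignment. `method = "exact"` runs the full
#' dynamic program, which defines correctness; `"banded"` seeds candidate
#' diagonals with shared k-mers and restricts the dynamic program to a band
#' around them (much faster on long subjects, exact whenever the optimal
#' path stays within the band, as it does for substitution-divergent
#' sequences). `"auto"` uses the exact program for small problems and the
#' banded path otherwise. Score ties are broken toward the smallest
#' `(query_start, subject_start)`. Spans are 0-based half-open; identity is
#' matches over alignment columns.
#'
#' @param a,b Query and subject sequences.
#' @param scoring An [alignment_scoring()] list.
#' @param method `"auto"`, `"exact"` or `"banded"`.
#' @param band Half-width of the banded path's diagonal band.
#' @param seed_k k-mer size used to seed the banded path.
#' @return A `local_alignment` object; `no_hit` is `TRUE` when no positive-
#'   scoring alignment exists (e.g. all-mismatch inputs).
#' @export
align_local <- function(a, b, scoring = alignment_scoring(),
                        method = c("auto", "exact", "banded"), band = 48L,
                        seed_k = 13L) {
  assert_seq(a, "query"); assert_seq(b, "subject")
  method <- match.arg(method)
  if (method == "auto")
    method <- if (as.numeric(nchar(a)) * nchar(b) <= 4e6) "exact"
              else "banded"
  if (method == "exact") {
    r <- cpp_sw_full(a, b, scoring$match, scoring$mismatch,
                     -scoring$gap_open, -scoring$gap_ext)
  } else {
    idx <- cpp_kmer_index(b, as.integer(seed_k))
    r <- cpp_best_hit(idx, a, as.integer(band), scoring$match,
                      scoring$mismatch, -scoring$gap_open, -scoring$gap_ext)
  }
  aln_from_cpp(r)
}

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of `frag_len` bases (the classic ANI
#' fragmentation; 1020 bp by default). A terminal remainder shorter than
#' half a fragment is dropped, otherwise kept as a short fragment. A genome
#' shorter than `frag_len` yields itself as a single fragment, with a
#' warning.
#'
#' @param genome Sequence to fragment.
#' @param frag_len Fragment length in bases.
#' @param step Distance between fragment starts (defaults to `frag_len`,
#'   i.e. non-overlapping).
#' @return Named character vector of fragments with 0-based start
#'   coordinates in attribute `starts`.
#' @export
fragment_genome <- function(genome, frag_len = 1020L, step = frag_len) {
  assert_seq(genome)
  L <- nchar(genome)
  frag_len <- as.integer(frag_len); step <- as.integer(step)
  if (L < frag_len) {
    warning("genome shorter than one fragment; returning it whole")
    out <- stats::setNames(genome, "frag_00001")
    attr(out, "starts") <- 0L
    return(out)
  }
  starts <- seq.int(0L, L - frag_len, by = step)
  frags <- substring(genome, starts + 1L, starts + frag_len)
  last_end <- starts[length(starts)] + frag_len
  rem <- L - last_end
  if (rem >= frag_len / 2) {
    starts <- c(starts, last_end)
    frags <- c(frags, substring(genome, last_end + 1L, L))
  }
  names(frags) <- sprintf("frag_%05d", seq_along(frags))
  attr(frags, "starts") <- starts
  frags
}

#' Fragment-based average nucleotide identity (ANI)
#'
#' The query genome is cut into consecutive fragments, each fragment is
#' aligned to the subject at its best locus, and fragments passing the
#' identity and coverage cutoffs contribute their percent identity; ANI is
#' the unweighted mean identity of the kept fragments. With no passing
#' fragment ANI is undefined and reported as `NA` (never 0). Symmetric mode
#' runs both directions and averages the two ANI values.
#'
#' @param query_genome,subject_genome Genome sequences.
#' @param min_identity Fragment identity cutoff in percent.
#' @param min_cov Minimum aligned fraction of the fragment length.
#' @param frag_len Fragment length (see [fragment_genome()]).
#' @param band,seed_k Banded-alignment parameters (see [align_local()]).
#' @param symmetric Average both directions.
#' @param scoring An [alignment_scoring()] list.
#' @param query_name,subject_name Labels carried into the result.
#' @return Object of class `ani_result` with `ani_percent`,
#'   `n_fragments_total`, `n_fragments_used`, `aligned_fraction` and the
#'   per-fragment table.
#' @export
compute_ani <- function(query_genome, subject_genome, min_identity = 50,
                        min_cov = 0.7, frag_len = 1020L, band = 48L,
                        seed_k = 13L, symmetric = FALSE,
                        scoring = alignment_scoring(),
                        query_name = "query", subject_name = "subject") {
  assert_seq(query_genome, "query genome")
  assert_seq(subject_genome, "subject genome")
  one_way <- function(q, s) {
    frags <- fragment_genome(q, frag_len = frag_len)
    idx <- cpp_kmer_index(s, as.integer(seed_k))
    res <- lapply(frags, function(f)
      cpp_best_hit(idx, f, as.integer(band), scoring$match,
                   scoring$mismatch, -scoring$gap_open, -scoring$gap_ext))
    ident <- vapply(res, function(r)
      if (r$found && r$columns > 0) 100 * r$matches / r$columns
      else NA_real_, numeric(1))
    cols <- vapply(res, function(r) r$columns, numeric(1))
    keep <- !is.na(ident) & ident >= min_identity &
      cols >= min_cov * nchar(frags)
    list(n_total = length(frags), n_used = sum(keep),
         ani = if (any(keep)) mean(ident[keep]) else NA_real_,
         table = data.frame(fragment = names(frags),
                            start = attr(frags, "starts"),
                            identity = ident, aligned_length = cols,
                            kept = keep, stringsAsFactors = FALSE,
                            row.names = NULL))
  }
  fwd <- one_way(query_genome, subject_genome)
  rev <- if (symmetric) one_way(subject_genome, query_genome) else NULL
  ani <- if (symmetric) {
    if (is.na(fwd$ani) || is.na(rev$ani)) NA_real_
    else (fwd$ani + rev$ani) / 2
  } else fwd$ani
  structure(list(
    query_genome = query_name, subject_genome = subject_name,
    ani_percent = ani,
    n_fragments_total = fwd$n_total, n_fragments_used = fwd$n_used,
    aligned_fraction = fwd$n_used / fwd$n_total,
    forward_ani = fwd$ani,
    reverse_ani = if (symmetric) rev$ani else NA_real_,
    fragments = fwd$table, symmetric = symmetric),
    class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: ", x$query_genome, x$subject_genome))
  if (is.na(x$ani_percent)) cat("ANI undefined (no fragment passed)\n")
  else cat(sprintf("ANI %.2f%% (%d/%d fragments, aligned fraction %.2f)%s\n",
                   x$ani_percent, x$n_fragments_used, x$n_fragments_total,
                   x$aligned_fraction,
                   if (x$symmetric) " [symmetric]" else ""))
  invisible(x)
}

#' Species-boundary call from an ANI value
#'
#' Two genomes are called the same species when their ANI reaches the
#' cutoff (inclusive at the boundary); 94% is the conventional
#' species-delineation threshold.
#'
#' @param ani An `ani_result` or a numeric ANI percentage.
#' @param cutoff Species cutoff in percent.
#' @return `TRUE` (same species) or `FALSE`.
#' @export
species_call <- function(ani, cutoff = 94.0) {
  val <- if (inherits(ani, "ani_result")) ani$ani_percent else ani
  stopifnot(is.numeric(val), length(val) == 1L)
  if (is.na(val)) stop("ANI is undefined; species call not possible")
  val >= cutoff
}

#' Reciprocal best-hit ortholog pairs
#'
#' Aligns every sequence of one CDS collection against the other in both
#' directions. A hit counts only when it reaches `min_identity` percent
#' identity and covers at least `min_len_frac` of the query's length; a
#' pair is emitted only when each member is the other's best hit. Pairing
#' operates on nucleotide CDS identity. Best-hit ties are broken by higher
#' identity, then lexicographic subject id.
#'
#' @param cds_a,cds_b Named character vectors of CDS sequences.
#' @param min_identity Percent identity cutoff (applied to the query side).
#' @param min_len_frac Minimum aligned fraction of the query length.
#' @param scoring An [alignment_scoring()] list.
#' @return Data frame with one row per reciprocal pair: `id_a`, `id_b`,
#'   `identity_ab`, `identity_ba`.
#' @export
ortholog_pairs <- function(cds_a, cds_b, min_identity = 50,
                           min_len_frac = 0.7,
                           scoring = alignment_scoring()) {
  if (length(cds_a) == 0L || length(cds_b) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      identity_ab = numeric(0), identity_ba = numeric(0),
                      stringsAsFactors = FALSE))
  stopifnot(!is.null(names(cds_a)), !is.null(names(cds_b)))
  best_hits <- function(qs, ss) {
    vapply(names(qs), function(qi) {
      q <- qs[[qi]]
      best_id <- NA_character_; best_score <- -Inf; best_ident <- -Inf
      for (si in sort(names(ss))) {
        r <- align_local(q, ss[[si]], scoring = scoring)
        if (r$no_hit) next
        if (r$identity_percent < min_identity ||
            r$aligned_length < min_len_frac * nchar(q)) next
        if (r$score > best_score ||
            (r$score == best_score && r$identity_percent > best_ident)) {
          best_id <- si; best_score <- r$score
          best_ident <- r$identity_percent
        }
      }
      c(best_id, as.character(best_ident))
    }, character(2))
  }
  ab <- best_hits(cds_a, cds_b)
  ba <- best_hits(cds_b, cds_a)
  pairs <- NULL
  for (qi in colnames(ab)) {
    si <- ab[1, qi]
    if (is.na(si)) next
    if (!is.na(ba[1, si]) && ba[1, si] == qi)
      pairs <- rbind(pairs, data.frame(
        id_a = qi, id_b = si,
        identity_ab = as.numeric(ab[2, qi]),
        identity_ba = as.numeric(ba[2, si]),
        stringsAsFactors = FALSE))
  }
  pairs %||% data.frame(id_a = character(0), id_b = character(0),
                        identity_ab = numeric(0), identity_ba = numeric(0),
                        stringsAsFactors = FALSE)
}
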