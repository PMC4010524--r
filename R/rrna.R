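#' Classify 16S reads against a labelled reference set
#'
#' Each read is aligned against every reference; the best hit (highest
#' score, ties broken by longer alignment then lexicographic reference id)
#' is used. A read is assigned at all only when the alignment is longer
#' than `min_aln_len` bases and reaches `floor_identity` percent identity;
#' it is assigned to the reference's genus when identity reaches
#' `genus_identity`, otherwise to the reference's high-level taxon. The
#' genus thresholds are asserted on every output row.
#'
#' The identity floor replaces the e-value criterion of database searches:
#' an e-value needs a database-size model, whereas a minimum identity plus
#' the alignment-length rule gives an equivalent specificity control for a
#' fixed reference set.
#'
#' @param reads Named character vector of reads.
#' @param reference_set List with `sequences` (named character vector) and
#'   `taxonomy` (data frame with `ref_id`, `high_level`, `genus`), as
#'   produced by [make_rrna_references()].
#' @param min_aln_len Minimum alignment length in bases (strict `>`).
#' @param genus_identity Percent identity required for a genus assignment.
#' @param floor_identity Minimum percent identity for any assignment.
#' @param scoring An [alignment_scoring()] list.
#' @return Data frame of class `rrna_assignments`: `read_id`,
#'   `best_ref_id`, `identity_percent`, `aligned_length`, `assigned_rank`
#'   (`genus`, `high_level` or `unclassified`), `taxon`, `high_level`.
#' @export
classify_reads <- function(reads, reference_set, min_aln_len = 100L,
                           genus_identity = 95, floor_identity = 80,
                           scoring = alignment_scoring()) {
  refs <- reference_set$sequences
  taxo <- reference_set$taxonomy
  if (length(refs) == 0L) stop("empty reference set")
  stopifnot(all(c("ref_id", "high_level", "genus") %in% names(taxo)),
            all(names(refs) %in% taxo$ref_id))
  rows <- lapply(names(reads), function(ri) {
    best <- NULL
    for (si in sort(names(refs))) {
      a <- align_local(reads[[ri]], refs[[si]], scoring = scoring)
      if (a$no_hit) next
      better <- is.null(best) || a$score > best$aln$score ||
        (a$score == best$aln$score &&
           (a$aligned_length > best$aln$aligned_length))
      if (better) best <- list(ref = si, aln = a)
    }
    if (is.null(best))
      return(data.frame(read_id = ri, best_ref_id = NA_character_,
                        identity_percent = NA_real_, aligned_length = 0L,
                        assigned_rank = "unclassified",
                        taxon = NA_character_, high_level = NA_character_,
                        stringsAsFactors = FALSE))
    a <- best$aln
    tr <- taxo[taxo$ref_id == best$ref, , drop = FALSE]
    assigned <- a$aligned_length > min_aln_len &&
      a$identity_percent >= floor_identity
    rank <- if (!assigned) "unclassified"
            else if (a$identity_percent >= genus_identity) "genus"
            else "high_level"
    data.frame(
      read_id = ri, best_ref_id = best$ref,
      identity_percent = a$identity_percent,
      aligned_length = a$aligned_length,
      assigned_rank = rank,
      taxon = switch(rank, genus = tr$genus[1],
                     high_level = tr$high_level[1], NA_character_),
      high_level = if (rank == "unclassified") NA_character_
                   else tr$high_level[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  g <- out$assigned_rank == "genus"
  stopifnot(all(out$identity_percent[g] >= genus_identity),
            all(out$aligned_length[g] > min_aln_len))
  class(out) <- c("rrna_assignments", "data.frame")
  out
}

#' Community profile from 16S assignments
#'
#' Per-taxon fractions over the assigned reads at the high taxonomic
#' level, plus the unclassified fraction over all reads.
#'
#' @param assignments A [classify_reads()] result.
#' @return Data frame with `taxon`, `n_reads`, `fraction` (fractions sum
#'   to 1 over assigned reads); the unclassified fraction over all reads is
#'   in attribute `unclassified_fraction`.
#' @export
community_profile <- function(assignments) {
  stopifnot(is.data.frame(assignments))
  if (nrow(assignments) == 0L) stop("no assignments")
  assigned <- assignments[assignments$assigned_rank != "unclassified", ,
                          drop = FALSE]
  if (nrow(assigned) == 0L) {
    out <- data.frame(taxon = character(0), n_reads = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
    attr(out, "unclassified_fraction") <- 1
    return(out)
  }
  tab <- table(assigned$high_level)
  out <- data.frame(taxon = names(tab), n_reads = as.integer(tab),
                    fraction = as.numeric(tab) / nrow(assigned),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unclassified_fraction") <-
    1 - nrow(assigned) / nrow(assignments)
  out
}
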