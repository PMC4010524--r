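#' Filter contigs by length and gene count
#'
#' Retains contigs with length >= `min_len` (the 5 kb boundary itself is
#' kept) and at least `min_genes` gene calls. The two rules commute; counts
#' discarded per rule are reported for the run log.
#'
#' @param contigs Named character vector of contig sequences.
#' @param gene_calls Gene-call data frame (see [read_gene_calls()]).
#' @param min_len Minimum contig length in bases.
#' @param min_genes Minimum number of predicted genes.
#' @return List with `contigs` (the retained subset, order preserved) and
#'   `discarded`, a named count vector (`short`, `few_genes`).
#' @export
filter_contigs <- function(contigs, gene_calls, min_len = 5000L,
                           min_genes = 3L) {
  if (length(contigs) == 0L)
    return(list(contigs = contigs,
                discarded = c(short = 0L, few_genes = 0L)))
  lens <- nchar(contigs)
  ngenes <- table(factor(gene_calls$contig_id, levels = names(contigs)))
  ngenes <- as.integer(ngenes[names(contigs)])
  keep_len <- lens >= min_len
  keep_genes <- ngenes >= min_genes
  list(contigs = contigs[keep_len & keep_genes],
       discarded = c(short = sum(!keep_len),
                     few_genes = sum(keep_len & !keep_genes)))
}

#' Taxonomic uniformity of a contig's gene labels
#'
#' A contig receives a taxon only when its gene best-hit labels agree: in
#' strict mode (the default, `min_agreement = 1`) every non-`"unknown"`
#' label must name the same high-level taxon; a tolerant mode accepts the
#' majority taxon when its share of informative labels reaches
#' `min_agreement`. Contigs with no informative labels (or no gene calls at
#' all, which also raises a warning) are `"unassigned"`.
#'
#' @param labels Character vector of per-gene taxon labels for one contig
#'   (`"unknown"` allowed).
#' @param min_agreement Required agreement fraction in `(0, 1]`.
#' @return A single taxon label, or `"unassigned"`.
#' @export
taxonomic_uniformity <- function(labels, min_agreement = 1) {
  stopifnot(min_agreement > 0, min_agreement <= 1)
  if (length(labels) == 0L) {
    warning("contig has no gene calls; unassigned")
    return("unassigned")
  }
  inf <- labels[labels != "unknown"]
  if (length(inf) == 0L) return("unassigned")
  tab <- sort(table(inf), decreasing = TRUE)
  top <- tab[1]
  if (top / length(inf) >= min_agreement) names(top) else "unassigned"
}

#' Per-contig uniformity labels
#'
#' Applies [taxonomic_uniformity()] to every contig in a gene-call table.
#'
#' @param contig_ids Contig ids to label (contigs absent from `gene_calls`
#'   get `"unassigned"` with a warning).
#' @param gene_calls Gene-call data frame.
#' @param min_agreement Passed to [taxonomic_uniformity()].
#' @return Named character vector of labels.
#' @export
uniformity_labels <- function(contig_ids, gene_calls, min_agreement = 1) {
  out <- vapply(contig_ids, function(id) {
    taxonomic_uniformity(
      gene_calls$taxon_label[gene_calls$contig_id == id], min_agreement)
  }, character(1))
  names(out) <- contig_ids
  out
}

#' Cluster contigs into genome bins
#'
#' K-means clustering in a composition space built from the first two
#' principal components of the oligonucleotide frequencies augmented with
#' standardized GC content. Each cluster is labelled with the majority
#' uniformity taxon of its members; members whose own label conflicts with
#' the cluster label are flagged (never silently reassigned).
#'
#' @param projection A [pca_project()] result (needs >= 2 components).
#' @param profiles The matching [composition_profiles()].
#' @param taxon_labels Named per-contig uniformity labels
#'   (see [uniformity_labels()]).
#' @param K Number of bins.
#' @param seed Seed for the k-means initialization.
#' @return Object of class `genome_bins`: a list of bins, each with
#'   `bin_id`, `taxon_label`, `contig_ids` and `flagged`.
#' @export
assign_bins <- function(projection, profiles, taxon_labels, K, seed = 1) {
  stopifnot(inherits(projection, "pca_projection"))
  proj <- projection$projection
  stopifnot(identical(proj$contig_id, profiles$contig_id))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(proj)) stop("K exceeds the number of contigs")
  if (projection$n_components < 2L && nrow(proj) > 2L)
    stop("binning needs at least 2 principal components")
  gc <- profiles$gc
  gz <- if (length(unique(gc)) > 1L) as.numeric(scale(gc)) else gc * 0
  feats <- cbind(as.matrix(proj[, -1, drop = FALSE])[, 1:min(2, projection$n_components), drop = FALSE], gc_z = gz)
  km <- with_seed(seed, kmeans(feats, centers = K, nstart = 25L,
                               iter.max = 100L))
  labels <- taxon_labels[proj$contig_id]
  bins <- lapply(seq_len(K), function(k) {
    ids <- proj$contig_id[km$cluster == k]
    labs <- labels[ids]
    inf <- labs[labs != "unassigned" & !is.na(labs)]
    taxon <- if (length(inf)) {
      tab <- sort(table(inf), decreasing = TRUE)
      # tie-break: lexicographic
      names(tab)[tab == tab[1]][order(names(tab)[tab == tab[1]])][1]
    } else "unassigned"
    flagged <- ids[!is.na(labs) & labs != "unassigned" & labs != taxon]
    list(bin_id = sprintf("bin_%02d", k), taxon_label = taxon,
         contig_ids = ids, flagged = flagged)
  })
  structure(bins, class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  for (b in x)
    cat(sprintf("%s  %-22s %4d contigs%s\n", b$bin_id, b$taxon_label,
                length(b$contig_ids),
                if (length(b$flagged))
                  sprintf("  (%d flagged)", length(b$flagged)) else ""))
  invisible(x)
}

#' Summary statistics for a genome bin
#'
#' The classic per-bin report: total size, gene and contig counts, average
#' contig size, length-weighted average GC, average gene length, coding
#' percentage and length-weighted fold coverage.
#'
#' @param bin One element of a [assign_bins()] result (or any list with
#'   `contig_ids`).
#' @param contigs Named character vector of contig sequences.
#' @param gene_calls Gene-call data frame.
#' @param depths Named per-contig depth vector (fold coverage).
#' @return One-row data frame with columns `bin_id`, `taxon_label`,
#'   `size_mbp`, `n_genes`, `n_contigs`, `avg_contig_kb`, `avg_gc_percent`,
#'   `avg_gene_length_bp`, `coding_percent`, `coverage_x`.
#' @export
bin_stats <- function(bin, contigs, gene_calls, depths = NULL) {
  ids <- bin$contig_ids
  if (length(ids) == 0L) stop("empty bin")
  missing <- setdiff(ids, names(contigs))
  if (length(missing)) stop("unknown contig in bin: ", missing[1])
  seqs <- contigs[ids]
  lens <- nchar(seqs)
  total <- sum(lens)
  genes <- gene_calls[gene_calls$contig_id %in% ids, , drop = FALSE]
  glen <- genes$end - genes$start
  gc <- compute_gc(seqs)
  cov <- if (!is.null(depths)) {
    sum(depths[ids] * lens) / total
  } else NA_real_
  data.frame(
    bin_id = bin$bin_id %||% NA_character_,
    taxon_label = bin$taxon_label %||% NA_character_,
    size_mbp = total / 1e6,
    n_genes = nrow(genes),
    n_contigs = length(ids),
    avg_contig_kb = mean(lens) / 1e3,
    avg_gc_percent = 100 * sum(gc * lens) / total,
    avg_gene_length_bp = if (nrow(genes)) mean(glen) else NA_real_,
    coding_percent = 100 * sum(glen) / total,
    coverage_x = cov,
    stringsAsFactors = FALSE)
}
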