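#' Read a FASTA file with strict validation
#'
#' Sequences are uppercased and restricted to the `{A,C,G,T,N}` alphabet;
#' record ids (first whitespace-delimited token of the header) must be
#' non-empty and unique within the file. Order is preserved.
#'
#' @param path Path to a FASTA file (gzip accepted).
#' @return Named character vector of sequences, with full headers in the
#'   `descriptions` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(x))
  if (any(!nzchar(ids)))
    stop("FASTA format error: empty id at record ",
         which(!nzchar(ids))[1])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("FASTA format error: duplicate id '", dup[1], "'")
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("FASTA format error: empty sequence for record '",
         ids[empty[1]], "'")
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad))
    stop("FASTA format error: non-IUPAC-DNA character in record '",
         ids[bad[1]], "'")
  names(seqs) <- ids
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector over `{A,C,G,T,N}`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read gene calls from a GFF3 file
#'
#' GFF3 coordinates (1-based, inclusive) are converted to the package's
#' internal 0-based half-open convention at this boundary; nothing else in
#' the package sees 1-based coordinates. The `taxon` attribute supplies the
#' per-gene best-hit taxon label (`"unknown"` when absent) and the optional
#' `besthit_identity` attribute a percent identity.
#'
#' @param path Path to a GFF3 file.
#' @param contig_lengths Optional named vector of contig lengths; when
#'   supplied, gene calls referencing unknown contigs or extending beyond a
#'   contig end are format errors.
#' @return Data frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `taxon_label`, `besthit_identity`.
#' @export
read_gene_calls <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("gene call format error: ", conditionMessage(e),
                        call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  taxon <- if ("taxon" %in% names(mc)) as.character(mc$taxon)
           else rep(NA_character_, length(gr))
  taxon[is.na(taxon) | !nzchar(taxon)] <- "unknown"
  ident <- if ("besthit_identity" %in% names(mc))
    suppressWarnings(as.numeric(as.character(mc$besthit_identity)))
  else rep(NA_real_, length(gr))
  df <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    taxon_label = taxon,
    besthit_identity = ident,
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  if (any(df$end <= df$start))
    stop("gene call format error: empty or inverted interval on contig ",
         df$contig_id[which(df$end <= df$start)[1]])
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(df$contig_id, names(contig_lengths))
    if (length(unknown))
      stop("gene call format error: unknown contig '", unknown[1], "'")
    over <- df$end > contig_lengths[df$contig_id]
    if (any(over))
      stop("gene call format error: gene extends beyond contig '",
           df$contig_id[which(over)[1]], "'")
  }
  df
}

#' Write gene calls to GFF3
#'
#' Converts the internal 0-based half-open intervals back to GFF3 1-based
#' inclusive coordinates, carrying `taxon` (and `besthit_identity` when
#' present) as attributes.
#'
#' @param genes Data frame as returned by [read_gene_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_calls <- function(genes, path) {
  stopifnot(all(c("contig_id", "start", "end", "taxon_label")
                %in% names(genes)))
  strand <- genes$strand %||% rep(".", nrow(genes))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "metadraft"
  S4Vectors::mcols(gr)$ID <- sprintf("gene_%05d", seq_len(nrow(genes)))
  S4Vectors::mcols(gr)$taxon <- genes$taxon_label
  if (!is.null(genes$besthit_identity))
    S4Vectors::mcols(gr)$besthit_identity <- genes$besthit_identity
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
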