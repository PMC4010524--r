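#' Taxon composition model
#'
#' A taxon is modelled as an order-`m` Markov chain over `{A,C,G,T}` whose
#' transition rows are pinned to a target GC content: for every context the
#' conditional probability of emitting `G` or `C` equals `gc_target`, while
#' multiplicative, context-specific biases within the AT and GC base groups
#' create the taxon-specific oligonucleotide signature that composition-based
#' binning exploits. Pinning guarantees the realized GC content of a generated
#' genome is a binomial proportion around `gc_target` (within a fraction of a
#' percentage point at 100 kb scale), independent of signature strength.
#'
#' @param name Taxon label (e.g. `"Thaumarchaeota"`).
#' @param gc_target Target GC content, fraction in `[0, 1]`.
#' @param genome_length Genome length in bases (at least 10 kb for
#'   [generate_genome()]).
#' @param markov_order Markov order; `2` (trinucleotide bias) is the default
#'   and the minimal order that gives distinct tetranucleotide signatures.
#' @param transition_weights Optional `4^markov_order x 4` matrix of
#'   conditional next-base weights (columns A, C, G, T; contexts in
#'   lexicographic order). Rows must be nonnegative and sum to 1. When
#'   supplied, it is used as-is (no GC pinning).
#' @param signature_sd Standard deviation of the log-normal multiplicative
#'   bias applied per context when building default weights; larger values
#'   give stronger, more separable composition signatures.
#' @param signature_seed Seed for the signature draw; defaults to a hash of
#'   `name` so that models for the same taxon are reproducible.
#' @return An object of class `taxon_model`.
#' @export
taxon_model <- function(name, gc_target, genome_length, markov_order = 2L,
                        transition_weights = NULL, signature_sd = 0.35,
                        signature_seed = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(gc_target), gc_target >= 0, gc_target <= 1)
  stopifnot(is.numeric(genome_length), genome_length >= 1)
  markov_order <- as.integer(markov_order)
  if (markov_order < 0L) stop("markov_order must be >= 0")
  if (is.null(transition_weights)) {
    seed <- signature_seed %||% (sum(utf8ToInt(name)) + 1000L)
    transition_weights <- make_transition_weights(
      gc_target, markov_order, signature_sd, seed)
  } else {
    transition_weights <- as.matrix(transition_weights)
  }
  validate_transition_weights(transition_weights, markov_order)
  structure(
    list(name = name, gc_target = gc_target,
         genome_length = as.integer(genome_length),
         markov_order = markov_order,
         transition_weights = transition_weights),
    class = "taxon_model")
}

#' @export
print.taxon_model <- function(x, ...) {
  cat(sprintf("<taxon_model> %s: GC %.1f%%, order %d, genome %s bp\n",
              x$name, 100 * x$gc_target, x$markov_order,
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

# GC-pinned transition weights: per context, biased within base groups but
# with P(G|ctx) + P(C|ctx) = gc exactly.
make_transition_weights <- function(gc, order, signature_sd, seed) {
  nctx <- 4L^order
  base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  with_seed(seed, {
    w <- matrix(rnorm(nctx * 4L, sd = signature_sd), nctx, 4L)
    w <- sweep(exp(w), 2L, base, `*`)
    at <- w[, c(1L, 4L), drop = FALSE]
    gcp <- w[, c(2L, 3L), drop = FALSE]
    at <- at / rowSums(at) * (1 - gc)
    gcp <- gcp / rowSums(gcp) * gc
    out <- cbind(at[, 1L], gcp[, 1L], gcp[, 2L], at[, 2L])
    colnames(out) <- BASES
    out
  })
}

validate_transition_weights <- function(w, order) {
  nctx <- 4L^order
  if (!is.matrix(w) || nrow(w) != nctx || ncol(w) != 4L)
    stop("transition_weights must be a ", nctx, " x 4 matrix", call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0))
    stop("transition weights must be finite and nonnegative", call. = FALSE)
  rs <- rowSums(w)
  if (any(abs(rs - 1) > 1e-8))
    stop("transition weight rows must sum to 1", call. = FALSE)
  invisible(w)
}

#' Generate a genome sequence from a taxon model
#'
#' Simulates the model's Markov chain for `genome_length` bases. The first
#' `markov_order` bases are drawn from the marginal base composition of the
#' transition matrix; all subsequent bases follow the conditional weights.
#' Deterministic given `seed`.
#'
#' @param model A [taxon_model()].
#' @param seed Integer seed.
#' @return A character scalar over `{A,C,G,T}` of length `genome_length`.
#' @export
generate_genome <- function(model, seed) {
  stopifnot(inherits(model, "taxon_model"))
  validate_transition_weights(model$transition_weights, model$markov_order)
  n <- model$genome_length
  if (n < 1L) stop("genome_length must be positive")
  marg <- colMeans(model$transition_weights)
  with_seed(seed, {
    init <- if (model$markov_order > 0L) {
      sample.int(4L, model$markov_order, replace = TRUE, prob = marg) - 1L
    } else integer(0)
    u <- runif(n)
    cpp_markov_sim(model$transition_weights, model$markov_order,
                   as.integer(n), u, as.integer(init))
  })
}

#' Mutate a genome by independent site substitutions
#'
#' Each site is substituted with probability `d`, independently, to one of
#' the three alternative bases chosen uniformly; sequence length is
#' preserved (no indels). This is the planted-divergence model for strain
#' pairs: the expected ANI of a pair is `100 * (1 - d)` percent.
#'
#' @param genome Character scalar over `{A,C,G,T}`.
#' @param d Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The mutated sequence, with the realized substitution count in
#'   attribute `n_substituted`.
#' @export
mutate_genome <- function(genome, d, seed) {
  assert_seq(genome, allow_n = FALSE)
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0, d <= 1)
  x <- seq_to_chars(genome)
  n <- length(x)
  out <- with_seed(seed, {
    hit <- which(runif(n) < d)
    if (length(hit)) {
      cur <- match(x[hit], BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      x[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    list(seq = chars_to_seq(x), nsub = length(hit))
  })
  structure(out$seq, n_substituted = out$nsub)
}

#' Plant compositionally foreign islands into a host genome
#'
#' Replaces randomly placed, non-overlapping host segments with sequence
#' generated from donor taxon models, emulating horizontally acquired
#' genomic islands: inside each island the composition follows the donor
#' model; outside the islands the sequence is identical to the host genome.
#'
#' @param genome Host genome sequence.
#' @param plan List of island requests, each a list with elements `length`
#'   (bases) and `donor` (a [taxon_model()]).
#' @param seed Integer seed.
#' @param max_tries Placement attempts per island before giving up.
#' @return A list with `sequence` (the genome with islands spliced in) and
#'   `islands`, a data frame of 0-based half-open `start`/`end` coordinates
#'   plus the donor name, sorted by `start`.
#' @export
plant_islands <- function(genome, plan, seed, max_tries = 200L) {
  assert_seq(genome, allow_n = FALSE)
  L <- nchar(genome)
  if (length(plan) == 0L) {
    return(list(sequence = genome,
                islands = data.frame(start = integer(0), end = integer(0),
                                     donor = character(0),
                                     stringsAsFactors = FALSE)))
  }
  lens <- vapply(plan, function(p) as.numeric(p$length), numeric(1))
  if (any(lens <= 0)) stop("island lengths must be positive")
  if (sum(lens) >= 0.5 * L)
    stop("total island length must be < 50% of the genome")
  placed <- matrix(numeric(0), ncol = 2)
  with_seed(seed, {
    for (i in seq_along(plan)) {
      len <- lens[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- floor(runif(1, 0, L - len + 1))
        e <- s + len
        if (!any(s < placed[, 2] & e > placed[, 1])) {
          placed <- rbind(placed, c(s, e)); ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place island ", i,
                    " without overlap after ", max_tries, " tries")
    }
  })
  ord <- order(placed[, 1])
  placed <- placed[ord, , drop = FALSE]
  donors <- vapply(plan, function(p) p$donor$name, character(1))[ord]
  seq <- genome
  for (i in seq_len(nrow(placed))) {
    donor <- plan[[ord[i]]]$donor
    seg_model <- taxon_model(donor$name, donor$gc_target,
                             genome_length = placed[i, 2] - placed[i, 1],
                             markov_order = donor$markov_order,
                             transition_weights = donor$transition_weights)
    seg <- generate_genome(seg_model, derive_seed(seed, paste0("island", i)))
    substr(seq, placed[i, 1] + 1, placed[i, 2]) <- seg
  }
  list(sequence = seq,
       islands = data.frame(start = as.integer(placed[, 1]),
                            end = as.integer(placed[, 2]),
                            donor = donors, stringsAsFactors = FALSE))
}

#' Specify a synthetic community
#'
#' Bundles the taxon models and all sampling parameters used by
#' [shred_and_sample()]. Defaults emulate a three-taxon enrichment: contig
#' lengths log-normal with a 20 kb median truncated to `[1 kb, 200 kb]`,
#' read lengths around 270 bp, and synthetic gene calls of ~800 bp.
#'
#' @param taxa List of [taxon_model()] objects.
#' @param abundances Relative abundances, summing to 1.
#' @param read_length_mean,read_length_sd Read length distribution (bases).
#' @param contig_length_meanlog,contig_length_sdlog Log-normal contig length
#'   parameters.
#' @param n_contigs Total number of contigs, allocated to taxa by abundance.
#' @param island_plan List of lists with `host` (taxon name), `length`
#'   (bases) and `donor` (a [taxon_model()]).
#' @param divergence_plan List of lists with `taxon` and per-site
#'   substitution probability `d` in `[0, 0.3)`; each entry yields a strain
#'   pair at known divergence.
#' @param label_noise Probability that a synthetic gene call carries a wrong
#'   taxon label.
#' @param gene_length_mean,gene_length_sd Synthetic gene length distribution.
#' @param read_depth Fold coverage of the read pool at abundance 1.
#' @param contig_depth_total Total depth apportioned to contigs by abundance.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(taxa, abundances,
                           read_length_mean = 270, read_length_sd = 10,
                           contig_length_meanlog = log(20000),
                           contig_length_sdlog = 0.6,
                           n_contigs = 300L,
                           island_plan = list(),
                           divergence_plan = list(),
                           label_noise = 0,
                           gene_length_mean = 800, gene_length_sd = 150,
                           read_depth = 20, contig_depth_total = 60) {
  stopifnot(length(taxa) >= 1L,
            all(vapply(taxa, inherits, logical(1), "taxon_model")))
  if (length(abundances) != length(taxa))
    stop("need one abundance per taxon")
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-6)
    stop("abundances must be nonnegative and sum to 1")
  names(taxa) <- vapply(taxa, `[[`, character(1), "name")
  for (p in island_plan) {
    if (!p$host %in% names(taxa)) stop("island host not in taxa: ", p$host)
    if (p$length <= 0) stop("island lengths must be > 0")
    stopifnot(inherits(p$donor, "taxon_model"))
  }
  for (p in divergence_plan) {
    if (!p$taxon %in% names(taxa)) stop("divergence taxon not in taxa")
    if (p$d < 0 || p$d >= 0.3) stop("divergence d must be in [0, 0.3)")
  }
  stopifnot(label_noise >= 0, label_noise <= 1)
  structure(
    list(taxa = taxa, abundances = abundances / sum(abundances),
         read_length_mean = read_length_mean,
         read_length_sd = read_length_sd,
         contig_length_meanlog = contig_length_meanlog,
         contig_length_sdlog = contig_length_sdlog,
         n_contigs = as.integer(n_contigs),
         island_plan = island_plan, divergence_plan = divergence_plan,
         label_noise = label_noise,
         gene_length_mean = gene_length_mean,
         gene_length_sd = gene_length_sd,
         read_depth = read_depth,
         contig_depth_total = contig_depth_total),
    class = "community_spec")
}

#' Generate a synthetic community with full ground truth
#'
#' Builds per-taxon genomes (with islands planted into their hosts), strain
#' pairs at the planted divergences, a contig set with taxon-labelled
#' synthetic gene calls, and a read pool. Reads in the default
#' `"water_column"` pool never overlap a planted island interval, emulating
#' an environmental read set from which island content is absent; the
#' `"enrichment"` pool samples the whole genomes.
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @param read_pool `"water_column"` (islands excluded) or `"enrichment"`.
#' @return An object of class `synthetic_community`: a list with `genomes`,
#'   `islands`, `strains`, `contigs`, `gene_calls`, `reads` and a `truth`
#'   list mapping every artifact back to its source.
#' @export
shred_and_sample <- function(spec, seed,
                             read_pool = c("water_column", "enrichment")) {
  stopifnot(inherits(spec, "community_spec"))
  read_pool <- match.arg(read_pool)
  taxa <- spec$taxa
  nt <- length(taxa)

  genomes <- list()
  islands <- data.frame(taxon = character(0), start = integer(0),
                        end = integer(0), donor = character(0),
                        stringsAsFactors = FALSE)
  for (nm in names(taxa)) {
    g <- generate_genome(taxa[[nm]], derive_seed(seed, paste0("genome:", nm)))
    plan <- Filter(function(p) p$host == nm, spec$island_plan)
    if (length(plan)) {
      pl <- plant_islands(g, plan, derive_seed(seed, paste0("islands:", nm)))
      g <- pl$sequence
      if (nrow(pl$islands))
        islands <- rbind(islands,
                         cbind(taxon = nm, pl$islands,
                               stringsAsFactors = FALSE))
    }
    genomes[[nm]] <- g
  }

  strains <- list()
  for (p in spec$divergence_plan) {
    m <- mutate_genome(genomes[[p$taxon]], p$d,
                       derive_seed(seed, paste0("strain:", p$taxon)))
    strains[[p$taxon]] <- list(sequence = as.character(m), d = p$d,
                               n_substituted = attr(m, "n_substituted"))
  }

  # contigs: allocation by largest remainder so counts sum to n_contigs
  alloc <- floor(spec$n_contigs * spec$abundances)
  rem <- spec$n_contigs - sum(alloc)
  if (rem > 0) {
    frac <- spec$n_contigs * spec$abundances - alloc
    alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  contigs <- character(0)
  ctruth <- NULL
  gene_calls <- NULL
  idx <- 0L
  with_seed(derive_seed(seed, "contigs"), {
    for (ti in seq_len(nt)) {
      nm <- names(taxa)[ti]
      L <- nchar(genomes[[nm]])
      for (j in seq_len(alloc[ti])) {
        idx <- idx + 1L
        len <- round(rlnorm(1, spec$contig_length_meanlog,
                            spec$contig_length_sdlog))
        len <- max(1000L, min(len, 200000L, L))
        s <- floor(runif(1, 0, L - len + 1))
        id <- sprintf("contig_%04d", idx)
        contigs[id] <- substr(genomes[[nm]], s + 1, s + len)
        ctruth <- rbind(ctruth, data.frame(
          contig_id = id, taxon = nm, genome_start = s, genome_end = s + len,
          depth = spec$contig_depth_total * spec$abundances[ti],
          stringsAsFactors = FALSE))
        gene_calls <- rbind(gene_calls, synth_gene_calls(
          id, len, nm, names(taxa), spec))
      }
    }
  })
  rownames(ctruth) <- NULL

  reads <- character(0)
  rtruth <- NULL
  with_seed(derive_seed(seed, paste0("reads:", read_pool)), {
    parts <- list()
    for (ti in seq_len(nt)) {
      nm <- names(taxa)[ti]
      L <- nchar(genomes[[nm]])
      n_reads <- round(spec$read_depth * spec$abundances[ti] * L /
                         spec$read_length_mean)
      if (n_reads < 1L) next
      excl <- if (read_pool == "water_column")
        islands[islands$taxon == nm, c("start", "end"), drop = FALSE]
      else islands[0, c("start", "end")]
      ivls <- complement_intervals(L, excl)
      rlen <- pmax(50L, round(rnorm(n_reads, spec$read_length_mean,
                                    spec$read_length_sd)))
      # interval chosen per read, weighted by placeable starts
      w <- pmax(ivls$end - ivls$start - rlen[1] + 1, 0)
      if (all(w == 0)) next
      k <- sample.int(nrow(ivls), n_reads, replace = TRUE, prob = w)
      ok <- ivls$end[k] - ivls$start[k] >= rlen
      k <- k[ok]; rlen <- rlen[ok]
      s <- floor(runif(length(k), ivls$start[k],
                       ivls$end[k] - rlen + 1))
      parts[[nm]] <- data.frame(
        taxon = nm, start = s, end = s + rlen,
        sequence = substring(genomes[[nm]], s + 1, s + rlen),
        stringsAsFactors = FALSE)
    }
    if (length(parts)) {
      all <- do.call(rbind, parts)
      rownames(all) <- NULL
      ids <- sprintf("read_%06d", seq_len(nrow(all)))
      reads <- stats::setNames(all$sequence, ids)
      rtruth <- data.frame(read_id = ids, taxon = all$taxon,
                           start = all$start, end = all$end,
                           stringsAsFactors = FALSE)
    }
  })

  structure(
    list(genomes = genomes, islands = islands, strains = strains,
         contigs = contigs, gene_calls = gene_calls, reads = reads,
         truth = list(contigs = ctruth, reads = rtruth, islands = islands,
                      strains = data.frame(
                        taxon = names(strains),
                        d = vapply(strains, `[[`, numeric(1), "d"),
                        n_substituted = vapply(strains, `[[`, numeric(1),
                                               "n_substituted"),
                        stringsAsFactors = FALSE, row.names = NULL)),
         spec = spec, seed = seed, read_pool = read_pool),
    class = "synthetic_community")
}

# non-overlapping synthetic gene intervals on one contig; labels are the
# true taxon with optional noise flips (assumes the ambient RNG stream)
synth_gene_calls <- function(contig_id, len, taxon, all_taxa, spec) {
  n_max <- ceiling(len / (spec$gene_length_mean * 0.5)) + 2L
  glen <- pmax(300, pmin(round(rnorm(n_max, spec$gene_length_mean,
                                     spec$gene_length_sd)), 1500))
  gap <- round(runif(n_max, 50, 150))
  starts <- round(runif(1, 20, 150)) + c(0, cumsum(glen + gap))[seq_len(n_max)]
  ends <- starts + glen
  keep <- ends <= len
  if (!any(keep)) return(NULL)
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(starts)
  lab <- rep(taxon, n)
  if (spec$label_noise > 0 && length(all_taxa) > 1L) {
    flip <- runif(n) < spec$label_noise
    if (any(flip))
      lab[flip] <- vapply(which(flip), function(i)
        sample(setdiff(all_taxa, taxon), 1L), character(1))
  }
  data.frame(contig_id = contig_id, start = starts, end = ends,
             strand = sample(c("+", "-"), n, replace = TRUE),
             taxon_label = lab, besthit_identity = NA_real_,
             stringsAsFactors = FALSE)
}

# complement of 0-based half-open intervals within [0, L)
complement_intervals <- function(L, excl) {
  if (is.null(excl) || nrow(excl) == 0L)
    return(data.frame(start = 0, end = L))
  excl <- excl[order(excl$start), , drop = FALSE]
  starts <- c(0, excl$end)
  ends <- c(excl$start, L)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Synthetic labelled 16S reference set
#'
#' Generates one reference sequence per taxonomy row, each an independent
#' random sequence at the given GC content. Real 16S genes share conserved
#' regions that these synthetic references do not emulate; they provide
#' unambiguous, fully labelled targets for exercising the classification
#' thresholds.
#'
#' @param taxonomy Data frame with columns `high_level` and `genus` (one
#'   reference per row); an optional `ref_id` column overrides the default
#'   ids.
#' @param length Reference length in bases.
#' @param gc GC content of the references.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and `taxonomy`
#'   (the input with a `ref_id` column).
#' @export
make_rrna_references <- function(taxonomy, length = 1500, gc = 0.5, seed = 1) {
  stopifnot(is.data.frame(taxonomy),
            all(c("high_level", "genus") %in% names(taxonomy)))
  if (is.null(taxonomy$ref_id))
    taxonomy$ref_id <- sprintf("ref_%02d", seq_len(nrow(taxonomy)))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_seed(seed, vapply(seq_len(nrow(taxonomy)), function(i) {
    chars_to_seq(sample(BASES, length, replace = TRUE, prob = p))
  }, character(1)))
  names(seqs) <- taxonomy$ref_id
  list(sequences = seqs, taxonomy = taxonomy)
}

#' Sample 16S-like reads from a labelled reference set
#'
#' Draws each read's source reference from a multinomial at the given
#' proportions, slices a random window, and applies independent site
#' substitutions at rate `divergence`.
#'
#' @param refs A reference set from [make_rrna_references()].
#' @param proportions Per-reference sampling proportions (summing to 1).
#' @param n Number of reads.
#' @param read_length_mean,read_length_sd Read length distribution.
#' @param divergence Per-site substitution probability applied to each read.
#' @param seed Integer seed.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame with the source `ref_id` and `high_level` per read).
#' @export
sample_rrna_reads <- function(refs, proportions, n, read_length_mean = 250,
                              read_length_sd = 20, divergence = 0,
                              seed = 1) {
  stopifnot(length(proportions) == length(refs$sequences),
            abs(sum(proportions) - 1) < 1e-6)
  with_seed(seed, {
    src <- sample.int(length(refs$sequences), n, replace = TRUE,
                      prob = proportions)
    reads <- character(n)
    for (i in seq_len(n)) {
      ref <- refs$sequences[[src[i]]]
      L <- nchar(ref)
      rlen <- min(L, max(120L, round(rnorm(1, read_length_mean,
                                           read_length_sd))))
      s <- floor(runif(1, 0, L - rlen + 1))
      r <- substr(ref, s + 1, s + rlen)
      if (divergence > 0) {
        x <- seq_to_chars(r)
        hit <- which(runif(rlen) < divergence)
        if (length(hit)) {
          cur <- match(x[hit], BASES)
          shift <- sample.int(3L, length(hit), replace = TRUE)
          x[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
        }
        r <- chars_to_seq(x)
      }
      reads[i] <- r
    }
    names(reads) <- sprintf("rread_%05d", seq_len(n))
    list(reads = reads,
         truth = data.frame(read_id = names(reads),
                            ref_id = refs$taxonomy$ref_id[src],
                            high_level = refs$taxonomy$high_level[src],
                            stringsAsFactors = FALSE))
  })
}
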