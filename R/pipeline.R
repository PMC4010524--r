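#' Pipeline configuration
#'
#' Builds a validated configuration holding every threshold of the
#' pipeline with its default. Unknown keys are rejected and each value is
#' checked against its documented domain before any stage runs.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    outdir = "metadraft_out",
    # binning
    min_contig_len = 5000, min_genes = 3, k = 4, n_components = 2, K = 3,
    min_agreement = 1.0,
    # ANI / orthologs
    ani_min_identity = 50, ani_min_cov = 0.7, ani_fragment_len = 1020,
    species_cutoff = 94.0,
    # recruitment / islands
    recruit_min_identity = 50, recruit_min_cov = 0.7,
    recruit_window = 1000, recruit_step = 500,
    island_min_len = 15000, island_density_ratio = 0.2,
    island_merge_gap = 2000,
    gcskew_window = 25000, gcskew_step = 1000,
    # rRNA
    rrna_min_aln_len = 100, rrna_genus_identity = 95,
    rrna_floor_identity = 80,
    # synthetic community (defaults emulate the three-taxon enrichment)
    community = list(
      gc_targets = c(Thaumarchaeota = 0.34, Epsilonproteobacteria = 0.43,
                     Gammaproteobacteria = 0.53),
      abundances = c(0.5, 0.3, 0.2),
      genome_length = 200000, n_contigs = 300,
      island_length = 20000, island_host = "Thaumarchaeota",
      divergence = 0.15, read_depth = 20))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg,
                                             call. = FALSE)
  chk(cfg$min_contig_len >= 0, "min_contig_len must be >= 0")
  chk(cfg$min_genes >= 0, "min_genes must be >= 0")
  chk(cfg$k >= 1 && cfg$k <= 8, "k must be in [1, 8]")
  chk(cfg$K >= 1, "K must be >= 1")
  chk(cfg$n_components >= 1, "n_components must be >= 1")
  chk(cfg$min_agreement > 0 && cfg$min_agreement <= 1,
      "min_agreement must be in (0, 1]")
  chk(cfg$ani_min_identity >= 0 && cfg$ani_min_identity <= 100,
      "ani_min_identity must be a percentage")
  chk(cfg$ani_min_cov >= 0 && cfg$ani_min_cov <= 1,
      "ani_min_cov must be in [0, 1]")
  chk(cfg$ani_fragment_len >= 100, "ani_fragment_len must be >= 100")
  chk(cfg$species_cutoff >= 0 && cfg$species_cutoff <= 100,
      "species_cutoff must be a percentage")
  chk(cfg$recruit_min_identity >= 0 && cfg$recruit_min_identity <= 100,
      "recruit_min_identity must be a percentage")
  chk(cfg$recruit_min_cov >= 0 && cfg$recruit_min_cov <= 1,
      "recruit_min_cov must be in [0, 1]")
  chk(cfg$recruit_window >= 1 && cfg$recruit_step >= 1,
      "recruitment window/step must be >= 1")
  chk(cfg$island_min_len > 0, "island_min_len must be > 0")
  chk(cfg$island_density_ratio > 0 && cfg$island_density_ratio < 1,
      "island_density_ratio must be in (0, 1)")
  chk(cfg$island_merge_gap >= 0, "island_merge_gap must be >= 0")
  chk(cfg$gcskew_window >= 1 && cfg$gcskew_step >= 1,
      "GC-skew window/step must be >= 1")
  chk(cfg$rrna_min_aln_len > 0, "rrna_min_aln_len must be > 0")
  chk(cfg$rrna_genus_identity >= 0 && cfg$rrna_genus_identity <= 100,
      "rrna_genus_identity must be a percentage")
  chk(cfg$rrna_floor_identity >= 0 && cfg$rrna_floor_identity <= 100,
      "rrna_floor_identity must be a percentage")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys must be known configuration names; values are validated
#' as in [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config must be a YAML mapping")
  do.call(pipeline_config, vals)
}

default_community <- function(cfg) {
  cc <- cfg$community
  taxa <- lapply(names(cc$gc_targets), function(nm)
    taxon_model(nm, cc$gc_targets[[nm]], genome_length = cc$genome_length))
  donor <- taxon_model("island_donor", 0.60,
                       genome_length = cc$island_length)
  community_spec(
    taxa, cc$abundances, n_contigs = cc$n_contigs,
    island_plan = list(list(host = cc$island_host,
                            length = cc$island_length, donor = donor)),
    divergence_plan = list(list(taxon = cc$island_host,
                                d = cc$divergence)),
    read_depth = cc$read_depth)
}

#' Run pipeline stages
#'
#' Orchestrates the analysis stages on a synthetic community, writing each
#' stage's tabular/FASTA artifacts into `outdir` together with a manifest
#' (config echo, seed, package version, artifact checksums) sufficient to
#' re-run the pipeline bit-identically. Stage `"all"` chains
#' simulate, profile, bin, ani, recruit, islands and classify-rrna.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stage names, or `"all"`.
#' @return Invisibly, a list with the in-memory results of each stage and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  all_stages <- c("simulate", "profile", "bin", "ani", "recruit",
                  "islands", "classify-rrna")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list()
  artifacts <- character(0)
  put <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(outdir, name)
  }

  comm <- shred_and_sample(default_community(config),
                           derive_seed(seed, "simulate"))
  res$community <- comm
  if ("simulate" %in% stages) {
    write_fasta(comm$contigs, put("contigs.fasta"))
    write_fasta(comm$reads, put("reads.fasta"))
    write_gene_calls(comm$gene_calls, put("genes.gff3"))
    write_tsv(comm$truth$contigs, put("truth.tsv"))
  }

  if (any(c("profile", "bin") %in% stages)) {
    profiles <- composition_profiles(comm$contigs, k = config$k)
    fit <- pca_project(profiles, n_components = config$n_components)
    res$profiles <- profiles; res$pca <- fit
    if ("profile" %in% stages) {
      write_tsv(profiles, put("profiles.tsv"))
      write_tsv(fit$projection, put("projection.tsv"))
    }
  }

  if ("bin" %in% stages) {
    filt <- filter_contigs(comm$contigs, comm$gene_calls,
                           config$min_contig_len, config$min_genes)
    labs <- uniformity_labels(names(filt$contigs), comm$gene_calls,
                              config$min_agreement)
    keep <- profiles$contig_id %in% names(filt$contigs)
    prof_f <- profiles[keep, , drop = FALSE]
    class(prof_f) <- class(profiles)
    attr(prof_f, "k") <- attr(profiles, "k")
    fit_f <- pca_project(prof_f, n_components = config$n_components)
    bins <- assign_bins(fit_f, prof_f, labs, K = config$K,
                        seed = derive_seed(seed, "bin"))
    depths <- stats::setNames(comm$truth$contigs$depth,
                              comm$truth$contigs$contig_id)
    stats_df <- do.call(rbind, lapply(bins, bin_stats,
                                      contigs = comm$contigs,
                                      gene_calls = comm$gene_calls,
                                      depths = depths))
    res$bins <- bins; res$bin_stats <- stats_df
    memb <- do.call(rbind, lapply(bins, function(b)
      data.frame(contig_id = b$contig_ids, bin_id = b$bin_id,
                 taxon_label = b$taxon_label, stringsAsFactors = FALSE)))
    write_tsv(memb, put("bins.tsv"))
    write_tsv(stats_df, put("bin_stats.tsv"))
  }

  if ("ani" %in% stages) {
    rows <- NULL
    for (nm in names(comm$strains)) {
      r <- compute_ani(comm$genomes[[nm]], comm$strains[[nm]]$sequence,
                       min_identity = config$ani_min_identity,
                       min_cov = config$ani_min_cov,
                       frag_len = config$ani_fragment_len,
                       query_name = nm, subject_name = paste0(nm, "_strain"))
      rows <- rbind(rows, data.frame(
        query = r$query_genome, subject = r$subject_genome,
        ani_percent = r$ani_percent,
        n_fragments_used = r$n_fragments_used,
        n_fragments_total = r$n_fragments_total,
        aligned_fraction = r$aligned_fraction,
        same_species = species_call(r, config$species_cutoff),
        stringsAsFactors = FALSE))
    }
    res$ani <- rows
    if (!is.null(rows)) write_tsv(rows, put("ani.tsv"))
  }

  if (any(c("recruit", "islands") %in% stages)) {
    host <- unique(comm$islands$taxon)
    host <- if (length(host)) host[1] else names(comm$genomes)[1]
    genome <- comm$genomes[[host]]
    host_reads <- comm$reads[comm$truth$reads$taxon == host]
    prof <- recruit(host_reads, genome,
                    min_identity = config$recruit_min_identity,
                    min_cov = config$recruit_min_cov,
                    window = config$recruit_window,
                    step = config$recruit_step, genome_id = host)
    res$recruitment <- prof
    if ("recruit" %in% stages) {
      write_tsv(as.data.frame(prof), put("recruitment.tsv"))
      write_tsv(gc_skew(genome, config$gcskew_window, config$gcskew_step),
                put("gcskew.tsv"))
    }
    if ("islands" %in% stages) {
      isl <- detect_islands(prof, min_len = config$island_min_len,
                            density_ratio_threshold =
                              config$island_density_ratio,
                            merge_gap = config$island_merge_gap)
      host_genes <- genome_gene_calls(genome, host,
                                      derive_seed(seed, "host-genes"))
      if (nrow(isl)) {
        cdn <- island_codon_deviation(genome, isl, host_genes,
                                      seed = derive_seed(seed, "codon"))
        isl <- cdn$islands
        res$codon <- cdn
      }
      res$islands <- isl
      write_tsv(as.data.frame(isl), put("islands.tsv"))
    }
  }

  if ("classify-rrna" %in% stages) {
    taxo <- data.frame(
      high_level = names(config$community$gc_targets),
      genus = paste0(names(config$community$gc_targets), "_genus"),
      stringsAsFactors = FALSE)
    refs <- make_rrna_references(taxo, seed = derive_seed(seed, "rrna-ref"))
    pool <- sample_rrna_reads(refs, config$community$abundances, n = 500,
                              divergence = 0.02,
                              seed = derive_seed(seed, "rrna-reads"))
    asn <- classify_reads(pool$reads, refs,
                          min_aln_len = config$rrna_min_aln_len,
                          genus_identity = config$rrna_genus_identity,
                          floor_identity = config$rrna_floor_identity)
    profcomm <- community_profile(asn)
    res$rrna <- list(assignments = asn, profile = profcomm)
    write_tsv(asn, put("rrna_assignments.tsv"))
    write_tsv(profcomm, put("community_profile.tsv"))
  }

  manifest <- list(
    package = "metadraft",
    version = as.character(packageVersion("metadraft")),
    r_version = as.character(getRversion()),
    seed = seed,
    stages = stages,
    config = unclass(config),
    artifacts = as.list(stats::setNames(
      as.character(tools::md5sum(file.path(outdir, artifacts))),
      artifacts)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}

# synthetic gene intervals directly on a genome (used for island
# codon-usage scoring in the orchestrated run)
genome_gene_calls <- function(genome, taxon, seed, mean_len = 800,
                              sd_len = 150) {
  L <- nchar(genome)
  with_seed(seed, {
    out <- NULL
    pos <- round(runif(1, 20, 150))
    while (TRUE) {
      glen <- 3L * round(max(300, min(rnorm(1, mean_len, sd_len), 1500)) / 3)
      if (pos + glen > L) break
      out <- rbind(out, data.frame(
        contig_id = taxon, start = pos, end = pos + glen,
        strand = sample(c("+", "-"), 1L), taxon_label = taxon,
        besthit_identity = NA_real_, stringsAsFactors = FALSE))
      pos <- pos + glen + round(runif(1, 50, 150))
    }
    out
  })
}
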