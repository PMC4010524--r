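make_genes <- function(contig_id, n, len = 500, taxon = "T") {
  if (n == 0)
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      taxon_label = character(0),
                      besthit_identity = numeric(0)))
  starts <- seq(0, by = len + 10, length.out = n)
  data.frame(contig_id = contig_id, start = starts, end = starts + len,
             strand = "+", taxon_label = taxon,
             besthit_identity = NA_real_, stringsAsFactors = FALSE)
}

test_that("contig filters enforce both boundaries exactly", {
  contigs <- c(short = strrep("A", 4999), keep = strrep("A", 5000),
               few = strrep("A", 6000))
  genes <- rbind(make_genes("short", 3), make_genes("keep", 3),
                 make_genes("few", 2))
  out <- filter_contigs(contigs, genes)
  expect_identical(names(out$contigs), "keep")
  expect_equal(unname(out$discarded), c(1L, 1L))

  empty <- filter_contigs(character(0), genes)
  expect_length(empty$contigs, 0)
})

test_that("filter order does not matter", {
  set.seed(2)
  lens <- sample(c(3000, 5000, 8000), 20, replace = TRUE)
  contigs <- vapply(lens, function(l) strrep("A", l), character(1))
  names(contigs) <- sprintf("c%02d", 1:20)
  genes <- do.call(rbind, lapply(names(contigs), function(id)
    make_genes(id, sample(0:5, 1))))
  both <- filter_contigs(contigs, genes)
  # length filter first, then gene filter on the survivors
  len_first <- contigs[nchar(contigs) >= 5000]
  staged <- filter_contigs(len_first, genes, min_len = 0)
  expect_identical(names(both$contigs), names(staged$contigs))
})

test_that("taxonomic uniformity requires all informative labels to agree", {
  expect_equal(taxonomic_uniformity(rep("Thaum", 3)), "Thaum")
  expect_equal(taxonomic_uniformity(c("Thaum", "Epsilon", "Thaum")),
               "unassigned")
  expect_equal(taxonomic_uniformity(c("unknown", "unknown")), "unassigned")
  expect_equal(taxonomic_uniformity(c("Thaum", "unknown", "Thaum")),
               "Thaum")
  expect_warning(lab <- taxonomic_uniformity(character(0)), "no gene")
  expect_equal(lab, "unassigned")
  # tolerant mode admits a 2/3 majority
  expect_equal(
    taxonomic_uniformity(c("Thaum", "Epsilon", "Thaum"),
                         min_agreement = 0.6), "Thaum")
})

test_that("bins recover the planted taxa and stay taxonomically pure", {
  comm <- fx("three_taxon")
  filt <- filter_contigs(comm$contigs, comm$gene_calls)
  prof <- composition_profiles(filt$contigs)
  fit <- pca_project(prof, 2)
  labs <- uniformity_labels(names(filt$contigs), comm$gene_calls)
  bins <- assign_bins(fit, prof, labs, K = 3, seed = 5)

  expect_setequal(vapply(bins, `[[`, character(1), "taxon_label"),
                  c("Thaumarchaeota", "Epsilonproteobacteria",
                    "Gammaproteobacteria"))
  # noise-free labels: every cluster pure, nothing flagged
  expect_true(all(lengths(lapply(bins, `[[`, "flagged")) == 0))
  # disjoint cover of the retained contigs
  all_ids <- unlist(lapply(bins, `[[`, "contig_ids"))
  expect_false(any(duplicated(all_ids)))
  expect_setequal(all_ids, names(filt$contigs))
  # deterministic under the same seed
  bins2 <- assign_bins(fit, prof, labs, K = 3, seed = 5)
  expect_identical(lapply(bins, `[[`, "contig_ids"),
                   lapply(bins2, `[[`, "contig_ids"))
})

test_that("K = 1 yields a single bin and excessive K errors", {
  comm <- fx("three_taxon")
  prof <- composition_profiles(comm$contigs[1:10])
  fit <- pca_project(prof, 2)
  labs <- uniformity_labels(prof$contig_id, comm$gene_calls)
  one <- assign_bins(fit, prof, labs, K = 1)
  expect_length(one, 1)
  expect_setequal(one[[1]]$contig_ids, prof$contig_id)
  expect_error(assign_bins(fit, prof, labs, K = 11), "exceeds")
})

test_that("bin statistics reproduce hand-computed values", {
  contigs <- c(
    c1 = paste0(strrep("G", 3000), strrep("A", 7000)),    # 10 kb, GC .30
    c2 = paste0(strrep("G", 12000), strrep("A", 18000)))  # 30 kb, GC .40
  genes <- data.frame(contig_id = "c1", start = 0L, end = 9000L,
                      strand = "+", taxon_label = "T",
                      besthit_identity = NA_real_)
  one <- bin_stats(list(bin_id = "b", taxon_label = "T",
                        contig_ids = "c1"),
                   contigs, genes, depths = c(c1 = 12, c2 = 40))
  expect_equal(one$coding_percent, 90)
  expect_equal(one$size_mbp, 0.01)
  expect_equal(one$n_genes, 1)
  expect_equal(one$coverage_x, 12)

  both <- bin_stats(list(bin_id = "b", taxon_label = "T",
                         contig_ids = c("c1", "c2")),
                    contigs, genes, depths = c(c1 = 12, c2 = 40))
  expect_equal(both$avg_gc_percent, 37.5)   # length-weighted
  expect_equal(both$size_mbp, 0.04)
  expect_equal(both$n_contigs, 2)
  expect_equal(both$avg_contig_kb, 20)
  expect_equal(both$coverage_x, (12 * 10000 + 40 * 30000) / 40000)
  expect_error(bin_stats(list(contig_ids = character(0)), contigs, genes),
               "empty bin")
})

test_that("bin sizes sum to the clustered contig length", {
  comm <- fx("three_taxon")
  filt <- filter_contigs(comm$contigs, comm$gene_calls)
  prof <- composition_profiles(filt$contigs)
  fit <- pca_project(prof, 2)
  labs <- uniformity_labels(names(filt$contigs), comm$gene_calls)
  bins <- assign_bins(fit, prof, labs, K = 3, seed = 5)
  sizes <- vapply(bins, function(b)
    bin_stats(b, comm$contigs, comm$gene_calls)$size_mbp, numeric(1))
  expect_equal(sum(sizes) * 1e6, sum(nchar(filt$contigs)))
})
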