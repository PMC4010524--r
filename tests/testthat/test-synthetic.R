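test_that("generated genomes hit their GC target and are deterministic", {
  flat <- taxon_model("flat", 0.5, 100000, markov_order = 0,
                      transition_weights = matrix(0.25, 1, 4))
  g <- generate_genome(flat, 7)
  expect_equal(nchar(g), 100000)
  expect_true(compute_gc(g) >= 0.48 && compute_gc(g) <= 0.52)
  expect_identical(g, generate_genome(flat, 7))
  expect_false(identical(g, generate_genome(flat, 8)))

  # GC pinning holds for biased signature models at several targets
  for (gc in c(0.34, 0.43, 0.53)) {
    m <- taxon_model(paste0("t", gc), gc, 100000)
    expect_lt(abs(compute_gc(generate_genome(m, 11)) - gc), 0.02)
  }
})

test_that("degenerate transition weights are honoured or rejected", {
  only_g <- taxon_model("G", 1, 50, markov_order = 0,
                        transition_weights = matrix(c(0, 0, 1, 0), 1, 4))
  expect_identical(generate_genome(only_g, 1), strrep("G", 50))
  expect_error(
    taxon_model("bad", 0.5, 1000, markov_order = 0,
                transition_weights = matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4)),
    "sum to 1")
  expect_error(
    taxon_model("neg", 0.5, 1000, markov_order = 0,
                transition_weights = matrix(c(-0.5, 0.5, 0.5, 0.5), 1, 4)),
    "nonnegative")
})

test_that("mutation rate is honoured at the boundaries and in expectation", {
  g <- substr(fx("ani_genome"), 1, 200000)
  m0 <- mutate_genome(g, 0, 5)
  expect_identical(as.character(m0), g)
  expect_equal(attr(m0, "n_substituted"), 0)

  m1 <- mutate_genome(substr(g, 1, 5000), 1, 5)
  expect_false(any(strsplit(as.character(m1), "")[[1]] ==
                     strsplit(substr(g, 1, 5000), "")[[1]]))

  m <- mutate_genome(g, 0.05, 5)
  frac <- attr(m, "n_substituted") / nchar(g)
  expect_true(frac >= 0.047 && frac <= 0.053)  # binomial 99.9% interval
  expect_equal(nchar(as.character(m)), nchar(g))
})

test_that("island planting preserves the host outside islands", {
  host <- taxon_model("host", 0.34, 100000)
  donor <- taxon_model("donor", 0.60, 20000)
  g <- generate_genome(host, 9)

  none <- plant_islands(g, list(), 1)
  expect_identical(none$sequence, g)
  expect_equal(nrow(none$islands), 0)

  pl <- plant_islands(g, list(list(length = 20000, donor = donor)), 3)
  expect_equal(nrow(pl$islands), 1)
  expect_equal(pl$islands$end - pl$islands$start, 20000)
  expect_equal(nchar(pl$sequence), nchar(g))
  s <- pl$islands$start; e <- pl$islands$end
  if (s > 0)
    expect_identical(substr(pl$sequence, 1, s), substr(g, 1, s))
  if (e < nchar(g))
    expect_identical(substr(pl$sequence, e + 1, nchar(g)),
                     substr(g, e + 1, nchar(g)))
  # donor GC 0.60 into host 0.34: island windows are GC-richer than flanks
  island_gc <- compute_gc(substr(pl$sequence, s + 1, e))
  flank <- paste0(substr(pl$sequence, max(1, s - 10000), s),
                  substr(pl$sequence, e + 1, min(nchar(g), e + 10000)))
  expect_gt(island_gc, compute_gc(flank))
})

test_that("island placement failures and invalid plans are rejected", {
  host <- taxon_model("host", 0.34, 50000)
  donor <- taxon_model("donor", 0.60, 10000)
  g <- generate_genome(host, 2)
  expect_error(
    plant_islands(g, list(list(length = 30000, donor = donor)), 1),
    "50%")
  expect_error(
    plant_islands(g, rep(list(list(length = 8000, donor = donor)), 3),
                  1, max_tries = 1),
    "overlap|50%")
})

test_that("community sampling carries faithful ground truth", {
  comm <- fx("island_20k")  # single taxon, one island, water-column reads
  expect_true(all(comm$truth$contigs$taxon == "Thaumarchaeota"))
  expect_true(all(comm$gene_calls$taxon_label == "Thaumarchaeota"))
  # gene intervals valid and non-overlapping within each contig
  for (id in unique(comm$gene_calls$contig_id)) {
    gg <- comm$gene_calls[comm$gene_calls$contig_id == id, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start >= 0 & gg$end <= nchar(comm$contigs[[id]])))
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # water-column pool: no read overlaps the planted island
  isl <- comm$islands
  rt <- comm$truth$reads
  expect_false(any(rt$start < isl$end & rt$end > isl$start))
  # contigs match their recorded genome coordinates
  i <- 1
  ct <- comm$truth$contigs[i, ]
  expect_identical(comm$contigs[[ct$contig_id]],
                   substr(comm$genomes[[ct$taxon]], ct$genome_start + 1,
                          ct$genome_end))
})

test_that("identical spec and seed reproduce the community byte for byte", {
  host <- taxon_model("h", 0.40, 30000)
  spec <- community_spec(list(host), 1, n_contigs = 10, read_depth = 2)
  a <- shred_and_sample(spec, 77)
  b <- shred_and_sample(spec, 77)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$reads, b$reads)
  expect_identical(a$gene_calls, b$gene_calls)
})

test_that("taxa five GC points apart separate in contig GC", {
  lo <- taxon_model("lo", 0.38, 80000)
  hi <- taxon_model("hi", 0.43, 80000)
  spec <- community_spec(list(lo, hi), c(0.5, 0.5), n_contigs = 40,
                         read_depth = 0)
  comm <- shred_and_sample(spec, 13)
  gc <- compute_gc(comm$contigs)
  taxon <- comm$truth$contigs$taxon
  expect_lt(mean(gc[taxon == "lo"]), mean(gc[taxon == "hi"]))
})

test_that("abundance and label-noise validation reject bad specs", {
  tm <- taxon_model("a", 0.5, 20000)
  expect_error(community_spec(list(tm), 0.9), "sum to 1")
  expect_error(community_spec(list(tm), 1, divergence_plan =
                                list(list(taxon = "a", d = 0.5))),
               "0.3")
  expect_error(community_spec(list(tm), 1, island_plan =
                                list(list(host = "b", length = 10,
                                          donor = tm))),
               "host")
})
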