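# Shared synthetic fixtures, built once per test run and cached.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, switch(
      name,
      # three-taxon enrichment community, no islands: the binning fixture
      three_taxon = {
        taxa <- list(
          taxon_model("Thaumarchaeota", 0.34, 200000),
          taxon_model("Epsilonproteobacteria", 0.43, 200000),
          taxon_model("Gammaproteobacteria", 0.53, 200000))
        spec <- community_spec(taxa, c(0.5, 0.3, 0.2), n_contigs = 300,
                               read_depth = 0)
        shred_and_sample(spec, 101)
      },
      # single host with one planted 20 kb island, 20x water-column reads
      island_20k = {
        host <- taxon_model("Thaumarchaeota", 0.34, 200000)
        donor <- taxon_model("donor", 0.60, 20000)
        spec <- community_spec(
          list(host), 1, n_contigs = 5,
          island_plan = list(list(host = "Thaumarchaeota", length = 20000,
                                  donor = donor)),
          read_depth = 20)
        shred_and_sample(spec, 202)
      },
      island_20k_recruit = {
        comm <- fx("island_20k")
        recruit(comm$reads, comm$genomes$Thaumarchaeota)
      },
      ani_genome = generate_genome(taxon_model("T", 0.34, 200000), 301),
      stop("unknown fixture: ", name)),
      envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}
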