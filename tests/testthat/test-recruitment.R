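# build a recruitment_profile by hand to exercise island-calling logic
fake_profile <- function(density, window = 1000L, step = 1000L) {
  n <- length(density)
  prof <- data.frame(start = (seq_len(n) - 1L) * step,
                     end = (seq_len(n) - 1L) * step + window,
                     count = round(density * window), density = density)
  structure(prof, class = c("recruitment_profile", "data.frame"),
            genome_id = "fake", window = window, step = step,
            genome_length = (n - 1L) * step + window,
            median_density = stats::median(density),
            n_reads = sum(round(density * window)),
            n_recruited = sum(round(density * window)))
}

test_that("reads drawn from the genome itself are all recruited", {
  set.seed(51)
  g <- random_seq(30000)
  starts <- sample(0:(30000 - 300), 150)
  reads <- vapply(starts, function(s) substr(g, s + 1, s + 300),
                  character(1))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  prof <- recruit(reads, g)
  expect_equal(attr(prof, "n_recruited"), 150)
  spans <- attr(prof, "read_spans")
  expect_equal(unname(spans[, "start"]), starts)
})

test_that("reads from an unrelated genome recruit at background zero", {
  set.seed(52)
  g <- random_seq(30000)
  reads <- vapply(1:100, function(i) random_seq(300), character(1))
  names(reads) <- sprintf("r%03d", 1:100)
  prof <- recruit(reads, g)
  expect_lte(attr(prof, "n_recruited"), 1)
})

test_that("window counts conserve recruited reads", {
  set.seed(53)
  g <- random_seq(20000)
  # reads placed strictly inside single windows (no boundary crossing)
  starts <- rep(seq(100, 19100, by = 1000), each = 3) + c(0, 200, 400)
  reads <- vapply(starts, function(s) substr(g, s + 1, s + 250),
                  character(1))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  # non-overlapping tiling: counts partition the reads exactly
  prof <- recruit(reads, g, window = 1000, step = 1000)
  expect_equal(sum(prof$count), length(reads))
  # overlapping windows count boundary-spanning reads once per window
  prof2 <- recruit(reads, g, window = 1000, step = 500)
  expect_gte(sum(prof2$count), length(reads))
})

test_that("island calls come from runs of under-recruited windows", {
  base <- rep(0.1, 100)
  # 20 fully-depleted 1 kb windows: a 20 kb island
  d <- base; d[40:59] <- 0
  isl <- detect_islands(fake_profile(d))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 39000)
  expect_equal(isl$end, 59000)
  expect_equal(isl$length, 20000)
  expect_lt(isl$density_ratio, 0.2)

  # 10 kb dip: below the >15 kb rule, never called
  d <- base; d[40:49] <- 0
  expect_equal(nrow(detect_islands(fake_profile(d))), 0)

  # exactly 15 kb is not >15 kb
  d <- base; d[40:54] <- 0
  expect_equal(nrow(detect_islands(fake_profile(d))), 0)

  # two 9 kb dips separated by 1 kb merge into one 19 kb island
  d <- base; d[c(40:48, 50:58)] <- 0
  isl <- detect_islands(fake_profile(d))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$length, 19000)

  # uniform recruitment: nothing to call
  expect_equal(nrow(detect_islands(fake_profile(base))), 0)

  # all-zero median cannot normalize
  expect_warning(out <- detect_islands(fake_profile(rep(0, 30))),
                 "median")
  expect_equal(nrow(out), 0)
})

test_that("island calls ignore read input order", {
  comm <- fx("island_20k")
  prof <- fx("island_20k_recruit")
  isl <- detect_islands(prof)
  set.seed(54)
  shuffled <- comm$reads[sample(length(comm$reads))]
  isl2 <- detect_islands(recruit(shuffled, comm$genomes$Thaumarchaeota))
  expect_equal(isl$start, isl2$start)
  expect_equal(isl$end, isl2$end)
})

test_that("GC skew matches its definition and negates under complement", {
  sk <- gc_skew(strrep("G", 30000), window = 25000, step = 1000)
  expect_true(all(sk$skew == 1))
  sk <- gc_skew(strrep("GC", 15000), window = 25000, step = 1000)
  expect_true(all(sk$skew == 0))
  sk <- gc_skew(strrep("AT", 15000), window = 25000, step = 1000)
  expect_true(all(sk$undefined))
  expect_true(all(sk$skew == 0))

  set.seed(55)
  g <- random_seq(60000, gc = 0.45)
  comp <- chartr("ACGT", "TGCA", g)
  expect_equal(gc_skew(comp)$skew, -gc_skew(g)$skew)

  expect_warning(one <- gc_skew(random_seq(10000)), "shorter")
  expect_equal(nrow(one), 1)
})

test_that("codon usage counts in-frame codons and normalizes", {
  t1 <- codon_usage("ATGATG")
  expect_equal(unname(t1["ATG"]), 1)
  expect_equal(sum(t1), 1)
  expect_equal(attr(t1, "n_codons"), 2)

  t2 <- codon_usage(c("ATGATG", "ATGATG"))
  expect_equal(as.numeric(t2), as.numeric(t1))  # fractions scale-invariant

  expect_warning(t3 <- codon_usage("ATGAT"), "partial")
  expect_equal(unname(t3["ATG"]), 1)
  expect_error(codon_usage(character(0)), "no gene")

  set.seed(56)
  t4 <- codon_usage(vapply(1:5, function(i) random_seq(300), character(1)))
  expect_equal(sum(t4), 1)
  expect_length(unclass(t4), 64)
})

test_that("codon deviation is a symmetric squared distance", {
  set.seed(57)
  a <- codon_usage(random_seq(3000))
  b <- codon_usage(random_seq(3000, gc = 0.7))
  expect_equal(codon_deviation(a, a), 0)
  expect_equal(codon_deviation(a, b), codon_deviation(b, a))
  expect_equal(codon_deviation(a, b), sum((unclass(a) - unclass(b))^2))
  expect_gt(codon_deviation(a, b), 0)
})
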