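test_that("local alignment handles identity and all-mismatch inputs", {
  s <- "ACGTACGTGGCCAT"
  r <- align_local(s, s)
  expect_false(r$no_hit)
  expect_equal(r$identity_percent, 100)
  expect_equal(r$query_span, c(0L, nchar(s)))
  expect_equal(r$subject_span, c(0L, nchar(s)))
  expect_equal(r$score, nchar(s))

  r <- align_local("AAAA", "TTTT")
  expect_true(r$no_hit)
})

test_that("exact aligner scores agree with a plain-R dynamic program", {
  set.seed(21)
  for (i in 1:25) {
    a <- random_seq(sample(40:150, 1))
    b <- random_seq(sample(40:150, 1))
    if (i %% 3 == 0) {
      # make a related pair so positive scores are exercised too
      core <- random_seq(120)
      a <- core
      b <- mutate_string(core, sample(120, 12),
                         sample(c("A", "C", "G", "T"), 12, TRUE))
    }
    r <- align_local(a, b, method = "exact")
    expect_equal(r$score, sw_oracle(a, b), info = paste("pair", i))
  }
})

test_that("seeded banded alignment equals the exact program on divergent copies", {
  set.seed(31)
  for (i in 1:10) {
    g <- random_seq(4000)
    q <- substr(g, 1001, 1500)
    q <- mutate_string(q, sample(500, 25),
                       sample(c("A", "C", "G", "T"), 25, TRUE))
    exact <- align_local(q, g, method = "exact")
    banded <- align_local(q, g, method = "banded")
    expect_equal(banded$score, exact$score)
    expect_equal(banded$identity_percent, exact$identity_percent)
  }
})

test_that("genome fragmentation follows the half-fragment remainder rule", {
  g10200 <- random_seq(10200)
  f <- fragment_genome(g10200)
  expect_length(f, 10)
  expect_true(all(nchar(f) == 1020))

  f <- fragment_genome(random_seq(10710))
  expect_length(f, 11)
  expect_equal(unname(nchar(f[11])), 510)   # 510 >= 1020/2: kept

  f <- fragment_genome(random_seq(10400))
  expect_length(f, 10)                      # 200 < 510: dropped

  expect_warning(f <- fragment_genome(random_seq(800)), "whole")
  expect_length(f, 1)
  expect_equal(unname(nchar(f[1])), 800)
})

test_that("self-ANI is exactly 100 with full aligned fraction", {
  g <- substr(fx("ani_genome"), 1, 60000)
  r <- compute_ani(g, g)
  expect_identical(r$ani_percent, 100)
  expect_identical(r$aligned_fraction, 1)
  expect_equal(r$n_fragments_used, r$n_fragments_total)
})

test_that("ANI decreases with planted divergence and recovers its value", {
  g <- substr(fx("ani_genome"), 1, 60000)
  anis <- vapply(c(0.02, 0.05, 0.10), function(d) {
    mean(vapply(1:2, function(rep) {
      m <- mutate_genome(g, d, 1000 * d + rep)
      compute_ani(g, as.character(m))$ani_percent
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(anis) < 0))
  expect_true(all(abs(anis - 100 * (1 - c(0.02, 0.05, 0.10))) <= 1.0))
})

test_that("unrelated genomes give undefined ANI, not zero", {
  set.seed(91)
  r <- compute_ani(random_seq(40000), random_seq(40000))
  expect_true(is.na(r$ani_percent))
  expect_equal(r$n_fragments_used, 0)
  expect_error(species_call(r), "undefined")
})

test_that("symmetric ANI agrees between directions on strain pairs", {
  g <- substr(fx("ani_genome"), 1, 50000)
  m <- as.character(mutate_genome(g, 0.05, 17))
  fwd <- compute_ani(g, m)$ani_percent
  rev <- compute_ani(m, g)$ani_percent
  expect_lte(abs(fwd - rev), 1.0)
  sym <- compute_ani(g, m, symmetric = TRUE)
  expect_equal(sym$ani_percent, (sym$forward_ani + sym$reverse_ani) / 2)
})

test_that("species boundary is inclusive at the cutoff", {
  expect_true(species_call(99.0))
  expect_false(species_call(85.2))
  expect_false(species_call(79.5))
  expect_true(species_call(94.0))
  expect_false(species_call(93.999))
  expect_error(species_call(NA_real_), "undefined")
})

test_that("ortholog pairing is reciprocal and enforces query coverage", {
  set.seed(41)
  cds <- vapply(1:6, function(i) random_seq(450), character(1))
  names(cds) <- sprintf("g%d", 1:6)
  self <- ortholog_pairs(cds, cds)
  expect_equal(nrow(self), 6)
  expect_identical(self$id_a, self$id_b)

  # a CDS matching over only 60% of its length is rejected even at high
  # identity
  short_match <- paste0(substr(cds[["g1"]], 1, 270), random_seq(180))
  b <- c(h1 = short_match)
  expect_equal(nrow(ortholog_pairs(cds["g1"], b)), 0)

  # reciprocity: best hit must agree in both directions
  a2 <- c(x = cds[["g2"]])
  b2 <- c(y = cds[["g2"]], z = mutate_string(
    cds[["g2"]], sample(450, 9), sample(c("A", "C", "G", "T"), 9, TRUE)))
  pr <- ortholog_pairs(a2, b2)
  expect_equal(pr$id_b, "y")
  expect_equal(nrow(ortholog_pairs(character(0), b2)), 0)
})
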