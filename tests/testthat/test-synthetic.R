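test_that("generated genomes hit the requested length and GC", {
  g <- generate_genome(1000, 0.5, seed = 1)
  expect_equal(nchar(g$seq), 1000L)
  g2 <- generate_genome(10000, 1.0, seed = 2)
  expect_true(all(strsplit(g2$seq, "")[[1]] %in% c("G", "C")))
  # binomial 99% interval at n = 1e5, p = 0.3 is well within +/- 0.01
  g3 <- generate_genome(100000, 0.3, seed = 3)
  gc <- gc_content(g3) / 100
  expect_lt(abs(gc - 0.3), 0.01)
  expect_identical(generate_genome(500, 0.4, seed = 9)$seq,
                   generate_genome(500, 0.4, seed = 9)$seq)
  expect_error(generate_genome(100, 1.2), "gc")
})

test_that("mutated variants realize the requested divergence", {
  g <- generate_genome(100000, 0.5, seed = 4)
  m0 <- mutate_genome(g, 0, seed = 5)
  expect_identical(m0$record$seq, g$seq)
  expect_equal(m0$divergence, 0)
  m <- mutate_genome(g, 0.01, seed = 6)
  expect_gte(m$divergence, 0.008)
  expect_lte(m$divergence, 0.012)
  # realized divergence is the exact Hamming fraction
  d <- mean(strsplit(g$seq, "")[[1]] != strsplit(m$record$seq, "")[[1]])
  expect_equal(m$divergence, d)
  expect_identical(mutate_genome(g, 0.01, seed = 6)$record$seq, m$record$seq)
})

test_that("fragmentation reaches the target completeness within one contig", {
  g <- generate_genome(1e6, 0.5, seed = 7)
  full <- fragment_genome(g, 1.0, c(5000, 10000), seed = 8)
  expect_equal(full$completeness, 1.0)
  expect_equal(sum(nchar(full$contigs$seq)), 1e6)
  half <- fragment_genome(g, 0.5, c(5000, 10000), seed = 9)
  expect_lt(abs(half$completeness - 0.5), 0.01)  # one contig is <= 1% here
  again <- fragment_genome(g, 0.5, c(5000, 10000), seed = 9)
  expect_identical(again$contigs$seq, half$contigs$seq)
  expect_error(fragment_genome(g, 0.5, c(5000, 2e6), seed = 1), "range")
})

test_that("abundance profiles are normalized and pair-correlated", {
  ab <- simulate_abundances(10, 50, redundant_pairs = list(c(1, 6)), seed = 10)
  expect_equal(unname(colSums(ab)), rep(1, 50))
  expect_true(all(ab >= 0))
  # paired genomes correlate above 0.9, independent ones do not,
  # in >= 95% of replicates at the stated parameters
  paired_ok <- indep_ok <- logical(40)
  for (i in seq_len(40)) {
    a <- simulate_abundances(10, 50, redundant_pairs = list(c(1, 6)),
                             correlated_noise_sd = 0.05, seed = 100 + i)
    paired_ok[i] <- pearson_r(a[1, ], a[6, ]) > 0.9
    indep_ok[i] <- abs(pearson_r(a[2, ], a[3, ])) < 0.9
  }
  expect_gte(mean(paired_ok), 0.95)
  expect_gte(mean(indep_ok), 0.95)
})

test_that("read simulation conserves counts and recovers origin fractions", {
  g1 <- generate_genome(20000, 0.5, seed = 11, id = "g1")
  g2 <- generate_genome(20000, 0.5, seed = 12, id = "g2")
  ab <- matrix(c(0.8, 0.2), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  comm <- community_spec(rbind(g1, g2), ab, total_reads = 100000,
                         read_length = 100, error_rate = 0, seed = 13)
  sim <- simulate_reads(comm)
  expect_equal(nrow(sim$reads$s1), 100000L)
  frac <- table(sim$truth$s1$ref_id) / 100000
  expect_lt(abs(frac[["g1"]] - 0.8), 0.01)
  expect_lt(abs(frac[["g2"]] - 0.2), 0.01)
  # error-free reads are exact substrings (or reverse complements)
  idx <- sample.int(100000, 50)
  for (i in idx) {
    tr <- sim$truth$s1[i, ]
    want <- substr(rbind(g1, g2)$seq[match(tr$ref_id, c("g1", "g2"))],
                   tr$ref_start + 1, tr$ref_start + 100)
    got <- sim$reads$s1$seq[i]
    if (tr$strand == "-") got <- revcomp(got)
    expect_identical(got, want)
  }
  sim2 <- simulate_reads(comm)
  expect_identical(sim2$reads$s1$seq, sim$reads$s1$seq)
})

test_that("planted genes and reverse translation are exact", {
  refdb <- synthetic_nifh_refdb(n = 3, seed = 14)
  nt <- reverse_translate(refdb$seq[1], seed = 15)
  expect_equal(nchar(nt), 3 * nchar(refdb$seq[1]))
  expect_identical(unname(six_frame_translate(nt)[["+1"]]), refdb$seq[1])
  g <- generate_genome(5000, 0.5, seed = 16)
  g2 <- plant_gene(g, nt, 1000)
  expect_identical(substr(g2$seq, 1001, 1000 + nchar(nt)), nt)
  expect_equal(nchar(g2$seq), 5000L)
  expect_error(plant_gene(g, nt, 4500), "fit")
})
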