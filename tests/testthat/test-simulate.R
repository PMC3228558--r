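test_that("mutation honors rates, determinism, and the binomial expectation", {
  set.seed(1)
  s <- rand_dna(500)
  clean <- mutate_sequence(s, 0, 0)
  expect_equal(clean$sequence, s)
  expect_equal(clean$identity, 100)

  m1 <- mutate_sequence(s, 0.1, 0.01, seed = 99L)
  m2 <- mutate_sequence(s, 0.1, 0.01, seed = 99L)
  expect_identical(m1$sequence, m2$sequence)
  expect_identical(m1$identity, m2$identity)

  big <- mutate_sequence(rand_dna(10000), 0.1, 0, seed = 7L)
  # realized substitutions within 3 sigma of Binomial(10000, 0.1)
  expect_lt(abs(big$n_sub - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_equal(big$identity, 100 * (10000 - big$n_sub) / 10000)

  expect_error(mutate_sequence(s, 1, 0), "rates must lie")
  expect_error(mutate_sequence(s, 0.999, 0), "destroy")
  expect_error(mutate_sequence(strrep("A", 20), 0.8, 0), "destroy")
})

test_that("simulation is deterministic and honors n_implants = 0", {
  mito <- fixture_mito()
  p0 <- simulation_params(nuclear_length = 20000L, n_implants = 0L,
                          rng_seed = 4L)
  sim <- simulate_genome(mito, p0)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nchar(sim$genome$sequence), 20000L)

  p <- simulation_params(nuclear_length = 200000L, n_implants = 5L,
                         fragment_length_range = c(100L, 2000L),
                         rng_seed = 11L)
  s1 <- simulate_genome(mito, p)
  s2 <- simulate_genome(mito, p)
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(s1$truth, s2$truth)
  # truth identities inside the requested band (with 2-point slack)
  expect_true(all(s1$truth$realized_identity >= 61))
})

test_that("implants never overlap and truth describes them fully", {
  mito <- fixture_mito()
  p <- simulation_params(nuclear_length = 400000L, n_implants = 12L,
                         fragment_length_range = c(100L, 3000L),
                         p_split = 0.5, rng_seed = 21L)
  sim <- simulate_genome(mito, p)
  tr <- sim$truth
  expect_equal(nrow(tr), 12L)
  o <- order(tr$nuclear_start)
  expect_true(all(tr$nuclear_start[o][-1L] - tr$nuclear_end[o][-12L] >= 2500L))
  expect_true(all(tr$n_blocks >= 1L & tr$n_blocks <= 4L))
  expect_true(all(tr$strand %in% c("+", "-")))
  # a 100%-identity unsplit implant is literally the mito fragment
  p2 <- simulation_params(nuclear_length = 100000L, n_implants = 2L,
                          fragment_length_range = c(500L, 500L),
                          target_identity_range = c(100, 100),
                          indel_rate = 0, p_split = 0, p_minus_strand = 0,
                          p_junction_spanning = 0, rng_seed = 31L)
  s2 <- simulate_genome(mito, p2)
  t2 <- s2$truth[1L, ]
  got <- substr(s2$genome$sequence, t2$nuclear_start + 1L, t2$nuclear_end)
  expect_equal(got, substr(mito$sequence, t2$mito_start + 1L, t2$mito_end))
})

test_that("zero-divergence implants are recovered end to end", {
  mito <- fixture_mito()
  p <- simulation_params(nuclear_length = 600000L, n_implants = 20L,
                         fragment_length_range = c(200L, 4000L),
                         target_identity_range = c(100, 100),
                         indel_rate = 0, p_split = 0,
                         p_junction_spanning = 0, rng_seed = 41L)
  sim <- simulate_genome(mito, p)
  hsps <- find_hsps(mito, sim$genome)
  asm <- assemble_numts(hsps)
  ev <- evaluate_recovery(asm, sim$truth)
  expect_equal(ev$n_truth, 20L)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
  # coordinates match truth closely; ends can drift a few bases because
  # the optimal local alignment may extend into chance background matches
  for (r in seq_len(nrow(ev$matches))) {
    d <- ev$matches$detected[r]; t <- ev$matches$truth[r]
    expect_lte(abs(asm$numts$nuc_start[d] - sim$truth$nuclear_start[t]), 10L)
    expect_lte(abs(asm$numts$nuc_end[d] - sim$truth$nuclear_end[t]), 10L)
    expect_equal(asm$numts$strand[d], sim$truth$strand[t])
  }
})

test_that("junction-spanning implants assemble into single wrapped NumtS", {
  mito <- fixture_mito()
  p <- simulation_params(nuclear_length = 300000L, n_implants = 5L,
                         fragment_length_range = c(800L, 3000L),
                         target_identity_range = c(92, 100),
                         p_junction_spanning = 1, p_split = 0,
                         rng_seed = 51L)
  sim <- simulate_genome(mito, p)
  expect_true(all(sim$truth$wraps_junction))
  hsps <- find_hsps(mito, sim$genome)
  asm <- assemble_numts(hsps)
  ev <- evaluate_recovery(asm, sim$truth)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$junction_single_rate, 1.0)
  # the assembled spans wrap the origin
  expect_true(any(asm$numts$wraps_junction))
})

test_that("recovery metrics equal a brute-force overlap evaluation", {
  set.seed(61)
  truth <- data.frame(implant_id = sprintf("T%02d", 1:8), chrom = "chr1",
                      nuclear_start = seq(0L, by = 10000L, length.out = 8L),
                      nuclear_end = seq(0L, by = 10000L, length.out = 8L) +
                        2000L,
                      strand = "+", mito_start = 0L, mito_end = 2000L,
                      wraps_junction = FALSE, realized_identity = 95,
                      n_blocks = 1L)
  # detections: 6 good (jittered), 1 too-short overlap, 1 spurious
  det <- data.frame(
    numts_idx = 1:8, chrom = "chr1",
    nuc_start = c(truth$nuclear_start[1:6] + sample(-50:50, 6L), 60200L,
                  90000L),
    nuc_end = c(truth$nuclear_end[1:6] + sample(-50:50, 6L), 60500L, 91000L))
  ev <- evaluate_recovery(det, truth, min_overlap_frac = 0.5)
  expect_equal(ev$recall, 6 / 8)
  expect_equal(ev$precision, 6 / 8)
  # trivial conventions
  ev0 <- evaluate_recovery(det[0, ], truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1.0)
  expect_true(ev0$zero_detection)
  evt <- evaluate_recovery(
    data.frame(numts_idx = 1L, chrom = truth$chrom,
               nuc_start = truth$nuclear_start,
               nuc_end = truth$nuclear_end), truth)
  expect_equal(evt$precision, 1.0)
  expect_equal(evt$recall, 1.0)
})

test_that("calibration grid: recall and precision hold at 80%+ identity", {
  mito <- fixture_mito()
  for (ident in c(100, 90, 80)) {
    p <- simulation_params(nuclear_length = 500000L, n_implants = 20L,
                           fragment_length_range = c(200L, 3000L),
                           target_identity_range = c(ident, ident),
                           p_split = 0, p_junction_spanning = 0,
                           rng_seed = 70L + ident)
    sim <- simulate_genome(mito, p)
    asm <- assemble_numts(find_hsps(mito, sim$genome))
    ev <- evaluate_recovery(asm, sim$truth)
    expect_gte(ev$recall, 0.95)
    expect_gte(ev$precision, 0.95)
  }
})
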