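test_that("merge rule honors the strict nuclear and inclusive mito bounds", {
  p <- assembly_params()
  base <- function(nuc_gap, mito_gap, strand = "+") {
    h1 <- mk_hsp(nuc_start = 1000L, nuc_end = 2000L, strand = strand,
                 mito_start = 3000L, mito_end = 4000L)
    if (strand == "+") {
      h2 <- mk_hsp(nuc_start = 2000L + nuc_gap, nuc_end = 3000L + nuc_gap,
                   strand = strand, mito_start = 4000L + mito_gap,
                   mito_end = 4500L + mito_gap)
    } else {
      h2 <- mk_hsp(nuc_start = 2000L + nuc_gap, nuc_end = 3000L + nuc_gap,
                   strand = strand, mito_start = 2000L - mito_gap,
                   mito_end = 3000L - mito_gap)
    }
    mergeable(h1, h2, p)
  }
  # nuclear bound is exclusive ("less than 2000 bp apart")
  expect_true(base(1999L, 0L))
  expect_false(base(2000L, 0L))
  # mito bound is inclusive ("not more than 2000 bp apart")
  expect_true(base(0L, 2000L))
  expect_false(base(0L, 2001L))
  # same thresholds on the minus strand, in reversed mito order
  expect_true(base(1999L, 2000L, strand = "-"))
  expect_false(base(0L, 2001L, strand = "-"))
  # overlapping HSPs (negative gaps) always pass their bound
  expect_true(base(-8L, 5L))
  expect_true(base(100L, -50L))
})

test_that("merge rule is circular across the control-region junction", {
  p <- assembly_params()
  h1 <- mk_hsp(nuc_start = 1000L, nuc_end = 1546L, strand = "+",
               mito_start = 16023L, mito_end = 16569L)
  h2 <- mk_hsp(nuc_start = 1646L, nuc_end = 2222L, strand = "+",
               mito_start = 0L, mito_end = 576L)
  expect_true(mergeable(h1, h2, p)) # circular gap 0, nuclear gap 100
  # but not when the oriented (forward) gap exceeds the bound
  h3a <- mk_hsp(nuc_start = 1000L, nuc_end = 1546L, strand = "+",
                mito_start = 10000L, mito_end = 12000L)
  h3b <- mk_hsp(nuc_start = 1646L, nuc_end = 2222L, strand = "+",
                mito_start = 14500L, mito_end = 15000L)
  expect_false(mergeable(h3a, h3b, p)) # oriented gap 2500
  # on the minus strand the oriented gap runs the other way
  h4a <- mk_hsp(nuc_start = 1000L, nuc_end = 1546L, strand = "-",
                mito_start = 16023L, mito_end = 16569L)
  h4b <- mk_hsp(nuc_start = 1646L, nuc_end = 2222L, strand = "-",
                mito_start = 2100L, mito_end = 2676L)
  expect_false(mergeable(h4a, h4b, p)) # oriented circular gap 13347
  # an HSP merges with itself (zero gaps)
  expect_true(mergeable(h1, h1, p))
  # orientation is required
  h2m <- h2; h2m$strand <- "-"
  expect_false(mergeable(h1, h2m, p))
  # different chromosomes are a contract violation
  h2c <- h2; h2c$chrom <- "chr2"
  expect_error(mergeable(h1, h2c, p), "same chromosome")
})

test_that("assembly keeps singletons and builds multi-block chains", {
  one <- mk_hsp(nuc_start = 100L, nuc_end = 600L, mito_start = 40L,
                mito_end = 540L)
  asm <- assemble_numts(one)
  expect_equal(nrow(asm$numts), 1L)
  expect_equal(asm$numts$nuc_start, 100L)
  expect_equal(asm$numts$nuc_end, 600L)
  expect_equal(asm$numts$n_members, 1L)

  # a ten-block chain: consecutive mito fragments < 2 kb apart on both axes
  starts <- cumsum(c(0L, rep(1500L, 9L)))
  hs <- hsp_table(chrom = "chr3", nuc_start = 10000L + starts,
                  nuc_end = 10000L + starts + 800L, strand = "+",
                  mito_start = 2000L + starts %/% 2L,
                  mito_end = 2000L + starts %/% 2L + 700L,
                  percent_identity = 90)
  asm10 <- assign_ids(assemble_numts(hs))
  expect_equal(nrow(asm10$numts), 1L)
  expect_equal(asm10$numts$n_members, 10L)
  expect_equal(asm10$members$member_id,
               sprintf("HSA_NumtS_001_b%d", 1:10))
  expect_equal(nrow(assemble_numts(empty_numts <- hs[0, ])$numts), 0L)
})

test_that("junction-spanning chains get a wrapped mitochondrial span", {
  h1 <- mk_hsp(nuc_start = 1000L, nuc_end = 1546L, strand = "+",
               mito_start = 16023L, mito_end = 16569L)
  h2 <- mk_hsp(nuc_start = 1646L, nuc_end = 2222L, strand = "+",
               mito_start = 0L, mito_end = 576L)
  h1$hsp_id <- "a"; h2$hsp_id <- "b"
  asm <- assemble_numts(rbind(h1, h2))
  expect_equal(nrow(asm$numts), 1L)
  expect_true(asm$numts$wraps_junction)
  expect_equal(asm$numts$mito_start, 16023L)
  expect_equal(asm$numts$mito_end, 576L)
  # non-wrapping chain reports a plain interval
  h3 <- mk_hsp(nuc_start = 3000L, nuc_end = 3500L, strand = "+",
               mito_start = 5000L, mito_end = 5500L, id = "c")
  asm2 <- assemble_numts(h3)
  expect_false(asm2$numts$wraps_junction)
})

test_that("assembly equals the pairwise-graph oracle and conserves members", {
  skip_if_not_installed("igraph")
  set.seed(101)
  p <- assembly_params()
  for (rep in 1:30) {
    h <- random_hsps(sample(5:50, 1L))
    asm <- assemble_numts(h, p)
    # conservation: every HSP in exactly one NumtS
    expect_equal(sum(asm$numts$n_members), nrow(h))
    expect_equal(sort(asm$members$hsp_id), sort(h$hsp_id))
    # no chain mixes strands or chromosomes
    expect_true(all(tapply(asm$members$strand, asm$members$numts_idx,
                           function(s) length(unique(s))) == 1L))
    expect_true(all(tapply(asm$members$chrom, asm$members$numts_idx,
                           function(s) length(unique(s))) == 1L))
    # oracle: connected components of the full mergeable graph
    oracle <- oracle_partition(h, p)
    expect_true(same_partition(asm$members$numts_idx, asm$members$hsp_id,
                               oracle, h$hsp_id))
  }
})

test_that("assembly is invariant to input order and stable per chain", {
  set.seed(202)
  h <- random_hsps(40)
  asm1 <- assemble_numts(h)
  for (rep in 1:5) {
    hp <- h[sample(nrow(h)), ]
    asm2 <- assemble_numts(hp)
    expect_equal(asm2$numts, asm1$numts)
    expect_true(same_partition(asm1$members$numts_idx, asm1$members$hsp_id,
                               asm2$members$numts_idx, asm2$members$hsp_id))
  }
  # re-assembling each chain's members alone returns exactly that chain
  for (ci in unique(asm1$members$numts_idx)) {
    sub <- asm1$members[asm1$members$numts_idx == ci,
                        setdiff(names(asm1$members),
                                c("numts_idx", "member_rank"))]
    class(sub) <- c("hsp_table", "data.frame")
    expect_equal(nrow(assemble_numts(sub)$numts), 1L)
  }
})

test_that("ids are zero-padded, block-suffixed, and width-expanding", {
  set.seed(77)
  # 14+ singleton NumtS, far apart on one chromosome
  n <- 20L
  starts <- seq(0L, by = 5000L, length.out = n)
  h <- hsp_table(chrom = "chr1", nuc_start = starts, nuc_end = starts + 500L,
                 strand = "+", mito_start = seq(0L, by = 700L, length.out = n),
                 mito_end = seq(0L, by = 700L, length.out = n) + 500L,
                 percent_identity = 88)
  asm <- assign_ids(assemble_numts(h))
  expect_equal(asm$numts$numts_id[14L], "HSA_NumtS_014")
  expect_equal(asm$numts$numts_id[1L], "HSA_NumtS_001")
  # round-trip: ordinal parses back from the id
  expect_equal(as.integer(sub("^HSA_NumtS_", "", asm$numts$numts_id)),
               seq_len(n))

  # width expands past 999
  big <- 1000L
  starts <- seq(0L, by = 3000L, length.out = big)
  hbig <- hsp_table(chrom = "chr1", nuc_start = starts,
                    nuc_end = starts + 400L, strand = "+",
                    mito_start = (starts %% 16000L),
                    mito_end = (starts %% 16000L) + 400L,
                    percent_identity = 80)
  asmb <- assign_ids(assemble_numts(hbig))
  expect_equal(nrow(asmb$numts), big)
  expect_equal(asmb$numts$numts_id[big], "HSA_NumtS_1000")
  expect_equal(asmb$numts$numts_id[1L], "HSA_NumtS_0001")
})

test_that("output follows karyotype order", {
  set.seed(9)
  h <- random_hsps(30, chroms = c("chr10", "chr2", "chrX", "chr1"))
  asm <- assemble_numts(h)
  r <- karyotype_rank(asm$numts$chrom)
  expect_true(!is.unsorted(r))
  expect_equal(karyotype_rank(c("chr1", "chr2", "chr10", "chrX", "chrY")),
               c(1, 2, 10, 23, 24))
})
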