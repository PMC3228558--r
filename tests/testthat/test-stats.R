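test_that("coverage profile counts per-position occupancy", {
  h <- mk_hsp(nuc_start = 100L, nuc_end = 110L, mito_start = 0L,
              mito_end = 10L)
  cov <- coverage_profile(h, 100L)
  expect_equal(cov$counts[1:10], rep(1L, 10))
  expect_equal(sum(cov$counts), 10L)
  expect_equal(sum(coverage_profile(h[0, ], 100L)$counts), 0L)
  expect_error(coverage_profile(mk_hsp(nuc_start = 0L, nuc_end = 10L,
                                       mito_start = 95L, mito_end = 105L),
                                100L), "outside")
})

test_that("coverage profile equals the per-position brute-force oracle", {
  set.seed(303)
  L <- 2000L
  n <- 100L
  s <- sample(0:(L - 50L), n, replace = TRUE)
  e <- pmin(L, s + sample(1:300, n, replace = TRUE))
  h <- hsp_table(chrom = "chr1", nuc_start = s + 10000L,
                 nuc_end = e + 10000L, strand = "+",
                 mito_start = s, mito_end = e, percent_identity = 90)
  cov <- coverage_profile(h, L)
  oracle <- integer(L)
  for (i in seq_len(n)) for (p in s[i]:(e[i] - 1L))
    oracle[p + 1L] <- oracle[p + 1L] + 1L
  expect_equal(cov$counts, oracle)
  # conservation: total counts = total interval length
  expect_equal(sum(cov$counts), sum(e - s))
})

test_that("chromosome table reproduces published per-chromosome arithmetic", {
  # 92 NumtS spanning 108317 bp of a 242951149 bp chromosome -> 0.045%
  starts <- seq(0L, by = 10000L, length.out = 92L)
  spans <- c(rep(1177L, 91L), 108317L - 91L * 1177L)
  numts <- data.frame(numts_idx = 1:92, chrom = "2", strand = "+",
                      nuc_start = starts, nuc_end = starts + spans,
                      n_members = 1L, member_length_sum = spans)
  cl <- data.frame(chrom = c("2", "18"), length = c(242951149, 76117153))
  st <- chromosome_stats(numts, cl)
  expect_equal(st$numts_count, c(92L, 0L))
  expect_equal(st$total_span, c(108317L, 0L))
  expect_equal(st$span_percent, c(0.045, 0.000))
  expect_equal(attr(st, "grand_total_span"), 108317L)
  expect_error(chromosome_stats(numts, data.frame(chrom = "18",
                                                  length = 1)), "2")
})

test_that("chromosome table totals match brute-force re-summation in both modes", {
  set.seed(404)
  h <- random_hsps(60)
  asm <- assemble_numts(h)
  cl <- data.frame(chrom = c("chr1", "chr2"), length = c(1e6, 2e6))
  for (mode in c("envelope", "member_sum")) {
    st <- chromosome_stats(asm, cl, span_mode = mode)
    for (cc in cl$chrom) {
      rows <- asm$numts[asm$numts$chrom == cc, ]
      want <- if (mode == "envelope") sum(rows$nuc_end - rows$nuc_start)
              else sum(rows$member_length_sum)
      expect_equal(st$total_span[st$chrom == cc], want)
    }
    expect_equal(attr(st, "grand_total_span"), sum(st$total_span))
  }
})

test_that("pearson_r matches its defining identities and stats::cor", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearson_r(a, b), cor(a, b))
  # affine invariance (up to the sign of the scale)
  expect_equal(pearson_r(3 * a + 7, b), pearson_r(a, b))
  expect_equal(pearson_r(-2 * a + 1, b), -pearson_r(a, b))
  expect_error(pearson_r(rep(1, 5), a[1:5]), "zero variance")
  expect_error(pearson_r(1:2, 1:3), "equal length")
})

test_that("five-number summary uses order-statistic interpolation", {
  expect_equal(five_number_summary(5),
               list(min = 5, q1 = 5, median = 5, q3 = 5, max = 5))
  fns <- five_number_summary(c(1, 2, 3, 4))
  expect_equal(fns$q1, 1.75)
  expect_equal(fns$median, 2.5)
  expect_equal(fns$q3, 3.25)
  set.seed(6)
  v <- rnorm(37)
  f <- five_number_summary(v)
  expect_true(f$min <= f$q1 && f$q1 <= f$median &&
                f$median <= f$q3 && f$q3 <= f$max)
  expect_error(five_number_summary(numeric(0)), "empty")
})

test_that("span differences and concatenation distances recompute by brute force", {
  h <- mk_hsp(nuc_start = 0L, nuc_end = 100L, mito_start = 0L,
              mito_end = 100L)
  expect_equal(span_differences(h), 0)

  # overlapping adjacent members give a negative distance
  h1 <- mk_hsp(nuc_start = 1000L, nuc_end = 1500L, mito_start = 100L,
               mito_end = 600L, id = "a")
  h2 <- mk_hsp(nuc_start = 1492L, nuc_end = 2000L, mito_start = 600L,
               mito_end = 1100L, id = "b")
  asm <- assemble_numts(rbind(h1, h2))
  expect_equal(concatenation_distances(asm), -8)

  set.seed(21)
  h <- random_hsps(50)
  asm <- assemble_numts(h)
  got <- sort(concatenation_distances(asm))
  want <- c()
  m <- asm$members
  for (ci in unique(m$numts_idx)) {
    g <- m[m$numts_idx == ci, ]
    g <- g[order(g$nuc_start), ]
    if (nrow(g) > 1L)
      want <- c(want, g$nuc_start[-1L] - g$nuc_end[-nrow(g)])
  }
  expect_equal(got, sort(want))
  expect_equal(span_differences(h),
               abs((h$nuc_end - h$nuc_start) - (h$mito_end - h$mito_start)))
})

test_that("flank repeat content matches a per-base marking oracle", {
  set.seed(31)
  cl <- data.frame(chrom = "chr1", length = 50000L)
  numts <- data.frame(numts_idx = 1:5, chrom = "chr1",
                      nuc_start = c(500L, 5000L, 12000L, 30000L, 48500L),
                      nuc_end = c(1500L, 7000L, 12400L, 33000L, 49900L))
  # no repeats -> all zero
  no_rep <- data.frame(chrom = character(), start = integer(),
                       end = integer())
  expect_equal(flank_repeat_content(numts, no_rep, cl)$per_numts$fraction,
               rep(0, 5))
  # full-coverage repeats -> fraction 1
  all_rep <- data.frame(chrom = "chr1", start = 0L, end = 50000L)
  expect_equal(flank_repeat_content(numts, all_rep, cl)$per_numts$fraction,
               rep(1, 5))
  # random repeats vs brute force
  rs <- sample(0:49000, 200L, replace = TRUE)
  reps <- data.frame(chrom = "chr1", start = rs,
                     end = pmin(50000L, rs + sample(10:800, 200L, TRUE)))
  got <- flank_repeat_content(numts, reps, cl, flank = 1000L)
  mask <- logical(50000L)
  for (i in seq_len(nrow(reps)))
    if (reps$end[i] > reps$start[i])
      mask[(reps$start[i] + 1L):reps$end[i]] <- TRUE
  for (i in 1:5) {
    fl <- c(max(0L, numts$nuc_start[i] - 1000L):(numts$nuc_start[i] - 1L),
            numts$nuc_end[i]:(min(50000L, numts$nuc_end[i] + 1000L) - 1L))
    expect_equal(got$per_numts$repeat_bases[i], sum(mask[fl + 1L]))
    expect_equal(got$per_numts$flank_bases[i], length(fl))
  }
  # cumulative table is a CDF over 1% bins
  cum <- got$cumulative
  expect_equal(nrow(cum), 101L)
  expect_true(!is.unsorted(cum$fraction_of_numts))
  expect_equal(cum$fraction_of_numts[101L], 1)
})

test_that("count percentages round half away from zero", {
  df <- data.frame(category = c("a", "b"), count = c(339L, 427L))
  got <- count_percentages(df, total = 766L)
  expect_equal(got$percent, c(44.26, 55.74))
  expect_equal(round_half_away(0.0005, 3), 0.001) # ties go up
  expect_equal(round_half_away(-0.0005, 3), -0.001)
  expect_equal(round_half_away(2.5), 3)
})
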