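#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (the spreadsheet
#' convention), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-base mitochondrial coverage profile
#'
#' Counts, for every position of the circular mitochondrial reference,
#' how many HSPs cover it — the per-site representation profile of the
#' mitochondrial genome across all detected NumtS fragments.
#'
#' @param hsps An [hsp_table()]; all mitochondrial intervals must lie
#'   within `[0, L)`.
#' @param L Mitochondrial reference length.
#' @return List of class `coverage_profile` with `L` and integer `counts`
#'   of length `L` (`counts[p+1]` = coverage of 0-based position p).
#' @export
coverage_profile <- function(hsps, L) {
  L <- as.integer(L)
  if (nrow(hsps) && any(hsps$mito_start < 0 | hsps$mito_end > L))
    stop("HSP mitochondrial interval outside [0,", L, ")")
  d <- integer(L + 1L)
  if (nrow(hsps)) {
    add <- table(hsps$mito_start + 1L)
    d[as.integer(names(add))] <- d[as.integer(names(add))] + as.integer(add)
    subx <- table(hsps$mito_end + 1L)
    d[as.integer(names(subx))] <- d[as.integer(names(subx))] - as.integer(subx)
  }
  structure(list(L = L, counts = cumsum(d)[seq_len(L)]),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> L=", x$L, ", total covered bases ",
      sum(x$counts), ", max depth ", max(x$counts), "\n", sep = "")
  invisible(x)
}

#' Per-chromosome NumtS table
#'
#' For each chromosome: NumtS count, chromosome length, total NumtS span
#' and the span as a percentage of the chromosome, rounded half away
#' from zero to 3 decimals. Chromosomes without NumtS get zero rows;
#' rows follow karyotype order. The grand-total span is attached as
#' attribute `"grand_total_span"`.
#'
#' @param assembly A `numts_assembly` (or its `numts` data frame, for
#'   envelope mode only).
#' @param chrom_lengths Data frame with columns `chrom` and `length`.
#' @param span_mode `"envelope"` sums each NumtS's outer nuclear extent
#'   (inter-block gaps included); `"member_sum"` sums member HSP lengths
#'   only.
#' @return Data frame `chrom, numts_count, chrom_length, total_span,
#'   span_percent`.
#' @export
chromosome_stats <- function(assembly, chrom_lengths,
                             span_mode = c("envelope", "member_sum")) {
  span_mode <- match.arg(span_mode)
  numts <- if (inherits(assembly, "numts_assembly")) assembly$numts
           else assembly
  if (!all(c("chrom", "length") %in% names(chrom_lengths)))
    stop("chrom_lengths needs columns 'chrom' and 'length'")
  unknown <- setdiff(unique(numts$chrom), chrom_lengths$chrom)
  if (length(unknown))
    stop("chromosome(s) not in chrom_lengths: ", paste(unknown, collapse = ", "))
  span <- if (span_mode == "envelope") numts$nuc_end - numts$nuc_start
          else {
            if (is.null(numts$member_length_sum))
              stop("member_sum mode needs a numts_assembly")
            numts$member_length_sum
          }
  o <- order(karyotype_rank(chrom_lengths$chrom))
  chroms <- chrom_lengths$chrom[o]
  lens <- chrom_lengths$length[o]
  cnt <- vapply(chroms, function(cc) sum(numts$chrom == cc), integer(1L))
  tot <- vapply(chroms, function(cc) sum(span[numts$chrom == cc]), numeric(1L))
  out <- data.frame(chrom = chroms, numts_count = cnt, chrom_length = lens,
                    total_span = as.integer(tot),
                    span_percent = round_half_away(tot / lens * 100, 3L),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "grand_total_span") <- sum(out$total_span)
  out
}

#' Pearson product-moment correlation
#'
#' Implemented from the definition (covariance over the product of
#' standard deviations); errors on vectors with zero variance, where the
#' correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stop("undefined correlation: zero variance")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Five-number summary
#'
#' Minimum, quartiles and maximum. Quartiles use linear interpolation of
#' order statistics with index `(n-1) q` (the common spreadsheet default,
#' `stats::quantile` type 7); the convention is configurable via `type`.
#'
#' @param values Non-empty numeric vector.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named list `min, q1, median, q3, max`.
#' @export
five_number_summary <- function(values, type = 7L) {
  if (length(values) == 0L) stop("five_number_summary: empty input")
  q <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = type))
  list(min = min(values), q1 = q[1L], median = q[2L], q3 = q[3L],
       max = max(values))
}

#' Nuclear/mitochondrial span differences per HSP
#'
#' `|nuclear extent - mitochondrial extent|` for each HSP; zero for
#' gapless alignments, growing with indel content.
#'
#' @param hsps An [hsp_table()].
#' @return Numeric vector.
#' @export
span_differences <- function(hsps) {
  abs((hsps$nuc_end - hsps$nuc_start) - (hsps$mito_end - hsps$mito_start))
}

#' Nuclear distances between concatenated HSPs
#'
#' For every adjacent member pair inside each multi-member assembled
#' NumtS, the signed nuclear gap `next.start - prev.end`; negative when
#' the members overlap.
#'
#' @param assembly A `numts_assembly`.
#' @return Numeric vector (length 0 if no multi-member NumtS).
#' @export
concatenation_distances <- function(assembly) {
  stopifnot(inherits(assembly, "numts_assembly"))
  m <- assembly$members
  unlist(lapply(split(seq_len(nrow(m)), m$numts_idx), function(ix) {
    if (length(ix) < 2L) return(numeric(0))
    ix <- ix[order(m$member_rank[ix])]
    m$nuc_start[ix][-1L] - m$nuc_end[ix][-length(ix)]
  }), use.names = FALSE)
}

#' Repeat content of NumtS flanking regions
#'
#' For each assembled NumtS, the fraction of its (up to) `2 * flank`
#' flanking bases — `flank` bp on each side, truncated at chromosome
#' ends — covered by the union of the supplied repeat intervals, plus the
#' cumulative distribution of those fractions over NumtS at 1% bins.
#'
#' @param assembly A `numts_assembly` (ids assigned or not).
#' @param repeats Data frame `chrom,start,end` (0-based half-open), e.g.
#'   a repeat-annotation BED read with [read_bed()].
#' @param chrom_lengths Data frame `chrom,length` for end truncation.
#' @param flank Flank width in bp (default 1000).
#' @return List with `per_numts` (`numts_idx, flank_bases, repeat_bases,
#'   fraction`) and `cumulative` (`max_content_pct, fraction_of_numts`:
#'   fraction of NumtS whose flank repeat content is <= the bin bound).
#' @export
flank_repeat_content <- function(assembly, repeats, chrom_lengths,
                                 flank = 1000L) {
  numts <- if (inherits(assembly, "numts_assembly")) assembly$numts
           else assembly
  lens <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  n <- nrow(numts)
  frac <- numeric(n); fb <- integer(n); rb <- integer(n)
  for (i in seq_len(n)) {
    cl <- lens[[numts$chrom[i]]]
    if (is.null(cl)) stop("chromosome not in chrom_lengths: ", numts$chrom[i])
    f5 <- c(max(0L, numts$nuc_start[i] - flank), numts$nuc_start[i])
    f3 <- c(numts$nuc_end[i], min(cl, numts$nuc_end[i] + flank))
    fl <- IRanges::IRanges(start = c(f5[1L], f3[1L]) + 1L,
                           end = c(f5[2L], f3[2L]))
    fl <- fl[IRanges::width(fl) > 0L]
    rp <- repeats[repeats$chrom == numts$chrom[i], , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = rp$start + 1L,
                                           end = rp$end))
    fb[i] <- sum(IRanges::width(fl))
    rb[i] <- sum(IRanges::width(IRanges::intersect(fl, ir)))
    frac[i] <- if (fb[i] > 0L) rb[i] / fb[i] else 0
  }
  bins <- 0:100
  cum <- vapply(bins, function(p) mean(frac * 100 <= p), numeric(1L))
  list(per_numts = data.frame(numts_idx = numts$numts_idx,
                              flank_bases = fb, repeat_bases = rb,
                              fraction = frac),
       cumulative = data.frame(max_content_pct = bins,
                               fraction_of_numts = if (n) cum else
                                 rep(NA_real_, length(bins))))
}

#' Percentage breakdown of a count table
#'
#' Adds a percentage-of-total column (rounded half away from zero to
#' `digits` decimals) to a table of category counts — the bookkeeping
#' used for validation summaries.
#'
#' @param counts Data frame with a `count` column (other columns kept).
#' @param total Denominator; defaults to `sum(counts$count)`.
#' @param digits Decimals for the percentage.
#' @return The input with a `percent` column appended.
#' @export
count_percentages <- function(counts, total = sum(counts$count), digits = 2L) {
  counts$percent <- round_half_away(counts$count / total * 100, digits)
  counts
}
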