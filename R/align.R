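#' BLASTN-style scoring scheme
#'
#' Scoring used throughout the pipeline: match reward +2, mismatch penalty
#' -3, gap opening -5, gap extension -2 (a gap of length g costs
#' 5 + 2 g), with an E-value threshold of 1e-3 for externally computed HSP
#' tables. For the internal seed-and-extend aligner, significance
#' filtering uses a raw-score cutoff (default 62, which under a
#' Karlin-Altschul approximation with these parameters corresponds to
#' E of about 1e-3 against a mitochondrial-genome x mammalian-genome
#' search space); `lambda` and `K` are exposed for users who want the
#' approximate E-values the aligner reports.
#'
#' @param match_reward Positive match score.
#' @param mismatch_penalty Negative mismatch score.
#' @param gap_open,gap_extend Negative affine gap penalties.
#' @param evalue_threshold Keep parsed HSPs with E-value strictly below this.
#' @param min_raw_score Minimum raw alignment score for the internal aligner.
#' @param word_size Exact-match seed length k (BLASTN default 11).
#' @param band_pad Extra diagonals allowed around a seed cluster during
#'   gapped extension (absorbs indel drift).
#' @param margin Bases of extension allowed beyond the outermost seeds.
#' @param lambda,karlin_k Karlin-Altschul parameters for approximate
#'   E-values (`lambda` solved from the ungapped stationarity condition for
#'   +2/-3 on uniform base composition).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match_reward = 2L, mismatch_penalty = -3L,
                           gap_open = -5L, gap_extend = -2L,
                           evalue_threshold = 1e-3, min_raw_score = 62L,
                           word_size = 11L, band_pad = 150L, margin = 1000L,
                           lambda = 0.6343, karlin_k = 0.41) {
  if (match_reward <= 0) stop("match_reward must be positive")
  if (mismatch_penalty >= 0 || gap_open >= 0 || gap_extend >= 0)
    stop("mismatch and gap penalties must be negative")
  if (evalue_threshold <= 0) stop("evalue_threshold must be positive")
  if (word_size < 4L || word_size > 15L) stop("word_size must be in [4,15]")
  structure(list(match_reward = as.integer(match_reward),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 evalue_threshold = evalue_threshold,
                 min_raw_score = as.integer(min_raw_score),
                 word_size = as.integer(word_size),
                 band_pad = as.integer(band_pad),
                 margin = as.integer(margin),
                 lambda = lambda, karlin_k = karlin_k),
            class = "scoring_scheme")
}

#' Construct an HSP data frame
#'
#' The internal HSP ("HSP_NumtS") representation: one row per local
#' alignment between the mitochondrial query and a nuclear chromosome.
#' Coordinates are 0-based half-open; the nuclear interval is always on
#' the chromosome forward strand (min < max) with orientation in `strand`,
#' and the mitochondrial interval is always on the mitochondrial plus
#' strand.
#'
#' @param chrom,nuc_start,nuc_end,strand,mito_start,mito_end,percent_identity
#'   Core fields, recycled to common length.
#' @param alignment_length,mismatches,gap_opens,evalue,bit_score,raw_score
#'   Alignment bookkeeping (NA where unknown).
#' @param hsp_id Optional ids; generated as `HSP_0001...` when `NULL`.
#' @param query_id Query (mitochondrial) sequence id.
#' @return Data frame of class `c("hsp_table","data.frame")`.
#' @export
hsp_table <- function(chrom, nuc_start, nuc_end, strand,
                      mito_start, mito_end, percent_identity,
                      alignment_length = NA_integer_,
                      mismatches = NA_integer_, gap_opens = NA_integer_,
                      evalue = NA_real_, bit_score = NA_real_,
                      raw_score = NA_integer_, hsp_id = NULL,
                      query_id = "chrM") {
  n <- length(chrom)
  if (n == 0L) { # zero-row table: truncate scalar defaults
    alignment_length <- alignment_length[0]; mismatches <- mismatches[0]
    gap_opens <- gap_opens[0]; evalue <- evalue[0]
    bit_score <- bit_score[0]; raw_score <- raw_score[0]
    query_id <- query_id[0]
  }
  df <- data.frame(chrom = as.character(chrom),
                   nuc_start = as.integer(nuc_start),
                   nuc_end = as.integer(nuc_end),
                   strand = as.character(strand),
                   mito_start = as.integer(mito_start),
                   mito_end = as.integer(mito_end),
                   percent_identity = as.numeric(percent_identity),
                   alignment_length = as.integer(alignment_length),
                   mismatches = as.integer(mismatches),
                   gap_opens = as.integer(gap_opens),
                   evalue = as.numeric(evalue),
                   bit_score = as.numeric(bit_score),
                   raw_score = as.integer(raw_score),
                   query_id = as.character(query_id),
                   stringsAsFactors = FALSE)
  if (is.null(hsp_id)) hsp_id <- sprintf("HSP_%04d", seq_len(nrow(df)))
  df <- cbind(hsp_id = as.character(hsp_id), df)
  class(df) <- c("hsp_table", "data.frame")
  validate_hsps(df)
  df
}

empty_hsp_table <- function() {
  hsp_table(chrom = character(), nuc_start = integer(), nuc_end = integer(),
            strand = character(), mito_start = integer(),
            mito_end = integer(), percent_identity = numeric(),
            query_id = character(), hsp_id = character())
}

#' Validate an HSP data frame
#'
#' Checks the structural invariants of the internal HSP representation
#' (coordinate ordering, strand values, identity range, E-value sign).
#'
#' @param hsps Candidate HSP data frame.
#' @param mito_length Optional circular reference length; when given,
#'   mitochondrial intervals must fit within it.
#' @return `hsps`, invisibly; errors on violation.
#' @export
validate_hsps <- function(hsps, mito_length = NULL) {
  need <- c("hsp_id", "chrom", "nuc_start", "nuc_end", "strand",
            "mito_start", "mito_end", "percent_identity")
  miss <- setdiff(need, names(hsps))
  if (length(miss)) stop("HSP table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(hsps)) {
    if (any(hsps$nuc_start >= hsps$nuc_end))
      stop("HSP with nuclear start >= end")
    if (any(hsps$mito_start >= hsps$mito_end))
      stop("HSP with mitochondrial start >= end")
    if (!all(hsps$strand %in% c("+", "-"))) stop("HSP strand must be + or -")
    if (any(hsps$percent_identity <= 0 | hsps$percent_identity > 100))
      stop("HSP percent identity outside (0,100]")
    if (any(!is.na(hsps$evalue) & hsps$evalue < 0))
      stop("HSP with negative evalue")
    if (!is.null(mito_length) && any(hsps$mito_end > mito_length))
      stop("HSP mitochondrial interval exceeds reference length ", mito_length)
  }
  invisible(hsps)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Find HSPs between a mitochondrial genome and a nuclear sequence
#'
#' Seed-and-extend local alignment: exact `word_size`-mers of the
#' mitochondrial query are located in the chromosome, clustered by
#' diagonal, and each cluster is extended by banded affine-gap local
#' dynamic programming under the scheme in `scoring`. Alignments with raw
#' score below `min_raw_score` are discarded. The minus strand is searched
#' by aligning against the reverse complement of the chromosome and
#' mapping coordinates back to the forward strand, so reported nuclear
#' intervals always have start < end and the mitochondrial interval is
#' always on the mitochondrial plus strand. Overlapping hits are
#' de-duplicated keeping the highest score (ties: leftmost nuclear start).
#'
#' Reported E-values are the Karlin-Altschul approximation
#' `K m n exp(-lambda S)`; the significance filter itself is the raw-score
#' cutoff.
#'
#' @param mito [sequence_record()] used as query.
#' @param chrom [sequence_record()] nuclear subject.
#' @param scoring A [scoring_scheme()].
#' @param search_both_strands Search the chromosome minus strand too.
#' @return An [hsp_table()] sorted by nuclear start. Sequences shorter
#'   than the seed length, or without any shared seed, give an empty
#'   table.
#' @export
find_hsps <- function(mito, chrom, scoring = scoring_scheme(),
                      search_both_strands = TRUE) {
  stopifnot(inherits(mito, "sequence_record"),
            inherits(chrom, "sequence_record"))
  q <- mito$sequence
  s <- chrom$sequence
  m <- nchar(s)
  run <- function(subject) {
    cpp_seed_extend(q, subject,
                    scoring$match_reward, scoring$mismatch_penalty,
                    -scoring$gap_open, -scoring$gap_extend,
                    scoring$word_size, scoring$min_raw_score,
                    scoring$band_pad, scoring$margin,
                    60L, 16L, 64L, 3000L)
  }
  plus <- run(s)
  res <- list()
  if (nrow(plus)) {
    res[[length(res) + 1L]] <- data.frame(
      plus, strand = "+", nuc_start = plus$s_start, nuc_end = plus$s_end)
  }
  if (search_both_strands) {
    minus <- run(reverse_complement(s))
    if (nrow(minus)) {
      res[[length(res) + 1L]] <- data.frame(
        minus, strand = "-",
        nuc_start = m - minus$s_end, nuc_end = m - minus$s_start)
    }
  }
  if (!length(res)) return(empty_hsp_table())
  d <- do.call(rbind, res)
  evalue <- scoring$karlin_k * nchar(q) * m * exp(-scoring$lambda * d$score)
  out <- hsp_table(
    chrom = chrom$id, nuc_start = d$nuc_start, nuc_end = d$nuc_end,
    strand = d$strand, mito_start = d$q_start, mito_end = d$q_end,
    percent_identity = 100 * d$matches / d$align_len,
    alignment_length = d$align_len, mismatches = d$mismatches,
    gap_opens = d$gap_opens, evalue = evalue, raw_score = d$score,
    query_id = mito$id, hsp_id = NA)
  out <- out[order(out$nuc_start, out$mito_start), , drop = FALSE]
  out$hsp_id <- sprintf("HSP_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("hsp_table", "data.frame")
  out
}

#' Global alignment of two near-identical sequences
#'
#' Needleman-Wunsch-style global alignment with affine gaps under the same
#' scoring scheme as HSP detection, computed within a diagonal band and
#' decomposed into co-linear gapless blocks. Intended for pairs of
#' homologous mitochondrial references (the substrate of liftover maps).
#'
#' @param a,b [sequence_record()]s.
#' @param scoring A [scoring_scheme()].
#' @param max_combined_length Refuse inputs whose combined length exceeds
#'   this cap (banded DP memory guard).
#' @param band_pad Diagonals allowed either side of the main band; must
#'   exceed the total indel drift between the sequences.
#' @return List of class `alignment_blocks`: `score`, `matches`,
#'   `align_len`, and `blocks` (data frame `a_start,a_end,b_start,b_end`,
#'   0-based half-open, equal-length pairs, strictly increasing).
#' @export
global_align <- function(a, b, scoring = scoring_scheme(),
                         max_combined_length = 100000L, band_pad = 200L) {
  stopifnot(inherits(a, "sequence_record"), inherits(b, "sequence_record"))
  if (nchar(a$sequence) + nchar(b$sequence) > max_combined_length)
    stop("combined sequence length exceeds ", max_combined_length,
         " bp; global alignment refused")
  res <- cpp_global_align(a$sequence, b$sequence,
                          scoring$match_reward, scoring$mismatch_penalty,
                          -scoring$gap_open, -scoring$gap_extend,
                          as.integer(band_pad))
  res$a_id <- a$id
  res$b_id <- b$id
  res$a_length <- nchar(a$sequence)
  res$b_length <- nchar(b$sequence)
  class(res) <- "alignment_blocks"
  res
}

#' @export
print.alignment_blocks <- function(x, ...) {
  cat("<alignment_blocks> ", x$a_id, " vs ", x$b_id, ": score ", x$score,
      ", ", nrow(x$blocks), " gapless block(s), ",
      sprintf("%.2f%%", 100 * x$matches / x$align_len), " identity\n",
      sep = "")
  invisible(x)
}
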