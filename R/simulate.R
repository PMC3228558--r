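BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Synthetic circular mitochondrial reference
#'
#' A seeded random sequence of rCRS-like length, used as a stand-in
#' circular mitochondrial reference for simulations and examples (no real
#' mitochondrial sequence ships with the package). Clearly synthetic: it
#' shares nothing but its length with any real reference.
#'
#' @param length Reference length (default 16569, rCRS-like).
#' @param seed RNG seed for reproducibility.
#' @param id Sequence id.
#' @return A [sequence_record()].
#' @export
synthetic_mito_genome <- function(length = 16569L, seed = 2011L,
                                  id = "chrM_synthetic") {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  sequence_record(id, random_dna(length))
}

#' Simulation parameters
#'
#' Controls for the synthetic-genome generator. Defaults emulate the
#' composition of the reference human NumtS catalogue: fragment lengths
#' spanning 31 bp to 15 kb, similarity to the mitochondrial reference
#' between 63 and 100 percent, both orientations, occasional implants
#' split into 2-4 blocks by short (< 2 kb) non-mitochondrial spacers, and
#' occasional fragments spanning the circular origin (control-region
#' junction).
#'
#' @param nuclear_length Background chromosome length (bp).
#' @param n_implants Number of implanted fragments.
#' @param fragment_length_range Inclusive length range, sampled uniformly.
#' @param target_identity_range Target percent identity range, sampled
#'   uniformly; realized identity is tracked from the mutation log.
#' @param indel_rate Per-base indel event probability (insertion or
#'   deletion, equally likely; lengths geometric, dominated by 1).
#' @param p_minus_strand Probability an implant is reverse-complemented.
#' @param p_split Probability an implant is emitted as 2-4 sub-blocks
#'   separated by spacers shorter than the assembly nuclear gap bound.
#' @param p_junction_spanning Probability a fragment crosses the circular
#'   origin of the mitochondrial reference.
#' @param rng_seed Integer seed; the whole simulation is a deterministic
#'   function of parameters and seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(nuclear_length = 1000000L, n_implants = 20L,
                              fragment_length_range = c(31L, 15000L),
                              target_identity_range = c(63, 100),
                              indel_rate = 0.001, p_minus_strand = 0.5,
                              p_split = 0.2, p_junction_spanning = 0.05,
                              rng_seed = 1L) {
  probs <- c(p_minus_strand, p_split, p_junction_spanning)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0,1)")
  if (fragment_length_range[1L] <= 0 ||
      fragment_length_range[2L] < fragment_length_range[1L])
    stop("fragment_length_range must be positive and ordered")
  if (target_identity_range[1L] > target_identity_range[2L] ||
      target_identity_range[1L] <= 0 || target_identity_range[2L] > 100)
    stop("target_identity_range must be ordered within (0,100]")
  if (nuclear_length <= 0 || n_implants < 0) stop("invalid sizes")
  structure(list(nuclear_length = as.integer(nuclear_length),
                 n_implants = as.integer(n_implants),
                 fragment_length_range = as.integer(fragment_length_range),
                 target_identity_range = as.numeric(target_identity_range),
                 indel_rate = indel_rate,
                 p_minus_strand = p_minus_strand, p_split = p_split,
                 p_junction_spanning = p_junction_spanning,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_params")
}

#' Mutate a sequence with substitutions and indels
#'
#' Applies i.i.d. per-base substitutions (to a uniformly chosen different
#' base) at `substitution_rate` and indel events at `indel_rate` (insertion
#' or deletion with equal probability; lengths `1 + Geometric(0.7)`, so
#' single-base events dominate). Realized identity is computed from the
#' mutation log — matches over alignment columns, where every surviving,
#' deleted or inserted base contributes one column — not from re-alignment,
#' so ground truth never depends on the aligner under test.
#'
#' @param seq Nucleotide string.
#' @param substitution_rate,indel_rate Per-base rates in `[0,1)`.
#' @param seed Optional seed for standalone deterministic use; when
#'   `NULL` the surrounding RNG stream is used.
#' @return List: `sequence`, `identity` (percent), `n_sub`, `n_ins`,
#'   `n_del`.
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate, seed = NULL) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0,1)")
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  if (n * (1 - substitution_rate) * (1 - indel_rate) < 10)
    stop("mutation rates would destroy the sequence ",
         "(expected surviving length < 10)")
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sub_mask <- runif(n) < substitution_rate
  if (any(sub_mask)) {
    ch[sub_mask] <- vapply(ch[sub_mask],
                           function(b) sample(setdiff(BASES, b), 1L),
                           character(1L), USE.NAMES = FALSE)
  }
  ev <- which(runif(n) < indel_rate)
  is_ins <- runif(length(ev)) < 0.5
  lens <- 1L + rgeom(length(ev), 0.7)
  keep <- rep(TRUE, n)
  ins_str <- character(n)
  ins_str[] <- ""
  for (j in seq_along(ev)) {
    i <- ev[j]
    if (is_ins[j]) {
      ins_str[i] <- paste(sample(BASES, lens[j], replace = TRUE),
                          collapse = "")
    } else {
      keep[i:min(n, i + lens[j] - 1L)] <- FALSE
    }
  }
  body <- paste0(ifelse(keep, ch, ""), ins_str)
  mutated <- paste(body, collapse = "")
  n_del <- sum(!keep)
  n_sub <- sum(sub_mask & keep)
  n_ins <- sum(nchar(ins_str))
  columns <- n + n_ins
  list(sequence = mutated,
       identity = 100 * (n - n_del - n_sub) / columns,
       n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}

circular_fragment <- function(mito_seq, start, len) {
  L <- nchar(mito_seq)
  if (start + len <= L) return(substr(mito_seq, start + 1L, start + len))
  paste0(substr(mito_seq, start + 1L, L),
         substr(mito_seq, 1L, start + len - L))
}

#' Simulate a nuclear chromosome with implanted mitochondrial fragments
#'
#' Generates an i.i.d. uniform ACGT background and implants `n_implants`
#' mutated mitochondrial fragments, sampled circularly from the reference
#' (junction-spanning when requested), optionally reverse-complemented
#' and/or split into blocks separated by short non-mitochondrial spacers.
#' Implants never overlap and are kept at least 2500 bp apart so that
#' distinct implants cannot merge during assembly. The returned truth
#' table fully describes every implant.
#'
#' @param mito [sequence_record()] circular mitochondrial reference.
#' @param params [simulation_params()].
#' @param chrom_id Name for the simulated chromosome.
#' @return List: `genome` (a [sequence_record()]) and `truth` (data frame
#'   `implant_id, chrom, nuclear_start, nuclear_end, strand, mito_start,
#'   mito_end, wraps_junction, realized_identity, n_blocks`).
#' @export
simulate_genome <- function(mito, params = simulation_params(),
                            chrom_id = "chr1") {
  stopifnot(inherits(mito, "sequence_record"),
            inherits(params, "simulation_params"))
  set.seed(params$rng_seed)
  L <- nchar(mito$sequence)
  n <- params$n_implants
  background <- random_dna(params$nuclear_length)
  if (n == 0L)
    return(list(genome = sequence_record(chrom_id, background),
                truth = empty_truth()))

  implants <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(params$fragment_length_range[1L]:
                    min(params$fragment_length_range[2L], L - 1L), 1L)
    junction <- runif(1L) < params$p_junction_spanning && len >= 64L
    if (junction) {
      tail_len <- sample(32L:(len - 32L), 1L)
      mito_start <- L - tail_len
      mito_end <- len - tail_len # wrapped: start > end
    } else {
      mito_start <- sample(0L:(L - len), 1L)
      mito_end <- mito_start + len
    }
    fragment <- circular_fragment(mito$sequence, mito_start, len)
    target <- runif(1L, params$target_identity_range[1L],
                    params$target_identity_range[2L])
    sub_rate <- max(0, (100 - target) / 100 - params$indel_rate)
    mut <- mutate_sequence(fragment, sub_rate, params$indel_rate)
    strand <- if (runif(1L) < params$p_minus_strand) "-" else "+"
    body <- if (strand == "-") reverse_complement(mut$sequence) else
      mut$sequence
    blen <- nchar(body)
    split_it <- runif(1L) < params$p_split && blen >= 128L
    if (split_it) {
      nb <- sample(2:4, 1L)
      cuts <- sort(sample(32L:(blen - 32L), nb - 1L))
      while (any(diff(c(0L, cuts, blen)) < 32L)) {
        cuts <- sort(sample(32L:(blen - 32L), nb - 1L))
      }
      pieces <- substring(body, c(1L, cuts + 1L), c(cuts, blen))
      spacers <- vapply(seq_len(nb - 1L),
                        function(...) random_dna(sample(50:1999, 1L)),
                        character(1L))
      body <- paste0(paste0(pieces[-nb], spacers, collapse = ""),
                     pieces[nb])
    } else nb <- 1L
    implants[[i]] <- list(seq = body, strand = strand,
                          mito_start = mito_start, mito_end = mito_end,
                          wraps = junction, identity = mut$identity,
                          n_blocks = nb)
  }

  # non-overlapping placement with a 2500 bp separation margin
  placed_start <- integer(0); placed_end <- integer(0)
  order_i <- sample(seq_len(n))
  pos <- integer(n)
  for (i in order_i) {
    tl <- nchar(implants[[i]]$seq)
    if (tl + 1L > params$nuclear_length)
      stop("implant longer than the background; increase nuclear_length")
    ok <- FALSE
    for (try in seq_len(500L)) {
      p <- sample.int(params$nuclear_length - tl + 1L, 1L) - 1L
      if (!any(p < placed_end + 2500L & placed_start - 2500L < p + tl)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not place implants without overlap at this density; ",
           "increase nuclear_length or reduce n_implants")
    placed_start <- c(placed_start, p); placed_end <- c(placed_end, p + tl)
    pos[i] <- p
  }
  for (i in seq_len(n)) {
    substr(background, pos[i] + 1L, pos[i] + nchar(implants[[i]]$seq)) <-
      implants[[i]]$seq
  }
  truth <- data.frame(
    implant_id = sprintf("IMP_%03d", seq_len(n)),
    chrom = chrom_id,
    nuclear_start = pos,
    nuclear_end = pos + vapply(implants, function(x) nchar(x$seq),
                               integer(1L)),
    strand = vapply(implants, function(x) x$strand, character(1L)),
    mito_start = vapply(implants, function(x) x$mito_start, integer(1L)),
    mito_end = vapply(implants, function(x) as.integer(x$mito_end),
                      integer(1L)),
    wraps_junction = vapply(implants, function(x) x$wraps, logical(1L)),
    realized_identity = vapply(implants, function(x) x$identity,
                               numeric(1L)),
    n_blocks = vapply(implants, function(x) x$n_blocks, integer(1L)),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$nuclear_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = sequence_record(chrom_id, background), truth = truth)
}

empty_truth <- function() {
  data.frame(implant_id = character(), chrom = character(),
             nuclear_start = integer(), nuclear_end = integer(),
             strand = character(), mito_start = integer(),
             mito_end = integer(), wraps_junction = logical(),
             realized_identity = numeric(), n_blocks = integer(),
             stringsAsFactors = FALSE)
}

#' Score pipeline recovery against simulation ground truth
#'
#' Matches detected assembled NumtS to truth implants by reciprocal
#' nuclear-interval overlap of at least `min_overlap_frac`, assigning
#' greedily by decreasing overlap (one-to-one). Reports precision and
#' recall, merge accuracy (fraction of split implants recovered as
#' exactly one assembled NumtS), and the same single-NumtS rate for
#' junction-spanning implants. With no detections, precision is reported
#' as 1.0 with `zero_detection = TRUE` (a documented convention: no
#' detections means no false positives).
#'
#' @param detected A `numts_assembly` or its `numts` data frame.
#' @param truth Truth table from [simulate_genome()].
#' @param min_overlap_frac Reciprocal-overlap threshold in `(0,1]`.
#' @return List: `precision`, `recall`, `merge_accuracy`,
#'   `junction_single_rate`, `n_detected`, `n_truth`, `zero_detection`,
#'   and the `matches` data frame.
#' @export
evaluate_recovery <- function(detected, truth, min_overlap_frac = 0.5) {
  numts <- if (inherits(detected, "numts_assembly")) detected$numts
           else detected
  nd <- nrow(numts); nt <- nrow(truth)
  pairs <- NULL
  if (nd && nt) {
    grid <- expand.grid(d = seq_len(nd), t = seq_len(nt))
    ov <- pmin(numts$nuc_end[grid$d], truth$nuclear_end[grid$t]) -
      pmax(numts$nuc_start[grid$d], truth$nuclear_start[grid$t])
    same <- numts$chrom[grid$d] == truth$chrom[grid$t]
    rec <- pmin(ov / (numts$nuc_end[grid$d] - numts$nuc_start[grid$d]),
                ov / (truth$nuclear_end[grid$t] - truth$nuclear_start[grid$t]))
    keep <- same & ov > 0 & rec >= min_overlap_frac
    pairs <- data.frame(d = grid$d[keep], t = grid$t[keep],
                        overlap = ov[keep], reciprocal = rec[keep])
    pairs <- pairs[order(-pairs$overlap, pairs$d, pairs$t), , drop = FALSE]
  }
  used_d <- logical(nd); used_t <- logical(nt)
  match_d <- integer(0); match_t <- integer(0)
  if (!is.null(pairs)) for (r in seq_len(nrow(pairs))) {
    d <- pairs$d[r]; t <- pairs$t[r]
    if (!used_d[d] && !used_t[t]) {
      used_d[d] <- TRUE; used_t[t] <- TRUE
      match_d <- c(match_d, d); match_t <- c(match_t, t)
    }
  }
  tp <- length(match_d)
  zero_detection <- nd == 0L
  precision <- if (zero_detection) 1.0 else tp / nd
  recall <- if (nt == 0L) 1.0 else tp / nt

  single_hit <- function(ti) {
    ov <- pmin(numts$nuc_end, truth$nuclear_end[ti]) -
      pmax(numts$nuc_start, truth$nuclear_start[ti])
    sum(numts$chrom == truth$chrom[ti] & ov > 0) == 1L && ti %in% match_t
  }
  split_i <- which(truth$n_blocks > 1L)
  merge_accuracy <- if (length(split_i))
    mean(vapply(split_i, single_hit, logical(1L))) else NA_real_
  junc_i <- which(truth$wraps_junction)
  junction_single_rate <- if (length(junc_i))
    mean(vapply(junc_i, single_hit, logical(1L))) else NA_real_

  list(precision = precision, recall = recall,
       merge_accuracy = merge_accuracy,
       junction_single_rate = junction_single_rate,
       n_detected = nd, n_truth = nt, zero_detection = zero_detection,
       matches = data.frame(detected = match_d, truth = match_t))
}
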