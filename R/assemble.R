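#' Assembly parameters
#'
#' Thresholds of the NumtS joining protocol: two HSPs on the same
#' chromosome merge when they lie *less than* `nuclear_gap_max` bp apart
#' on the chromosome (strict bound), their mitochondrial fragments are
#' *not more than* `mito_gap_max` bp apart (inclusive bound) in the
#' orientation of the alignment, and they point in the same direction.
#' The asymmetry of the bounds follows the protocol's wording and both
#' are configurable. Mitochondrial gaps are evaluated circularly on a
#' reference of length `mito_length`, so chains spanning the
#' control-region junction (the D-loop, annotated as the end of the
#' linearized sequence followed by its start) merge without special
#' casing.
#'
#' @param nuclear_gap_max Exclusive upper bound on the nuclear gap (bp).
#' @param mito_gap_max Inclusive upper bound on the oriented
#'   mitochondrial gap (bp).
#' @param mito_length Circular mitochondrial reference length (16569 for
#'   an rCRS-like reference).
#' @param require_same_orientation Only merge same-strand HSPs.
#' @param max_chain_span Optional cap on the nuclear extent of a chain
#'   (`Inf` = none).
#' @return An `assembly_params` list.
#' @export
assembly_params <- function(nuclear_gap_max = 2000L, mito_gap_max = 2000L,
                            mito_length = 16569L,
                            require_same_orientation = TRUE,
                            max_chain_span = Inf) {
  if (nuclear_gap_max < 0 || mito_gap_max < 0) stop("gap bounds must be >= 0")
  if (mito_length <= 0) stop("mito_length must be positive")
  structure(list(nuclear_gap_max = as.integer(nuclear_gap_max),
                 mito_gap_max = as.integer(mito_gap_max),
                 mito_length = as.integer(mito_length),
                 require_same_orientation = isTRUE(require_same_orientation),
                 max_chain_span = max_chain_span),
            class = "assembly_params")
}

oriented_mito_gap <- function(h1, h2, L) {
  # nuclear-downstream neighbour h2: on + the alignment advances along the
  # mito plus strand, on - it descends, so the oriented gap flips.
  g <- ifelse(h1$strand == "+",
              h2$mito_start - h1$mito_end,
              h1$mito_start - h2$mito_end)
  pmin(g, g %% L)
}

#' Can two HSPs be merged into one NumtS?
#'
#' Applies the joining rule of [assembly_params()] to a nuclear-ordered
#' pair of HSPs on the same chromosome. Overlapping HSPs (negative gaps)
#' always satisfy the corresponding bound. The mitochondrial gap is the
#' minimum of the linear oriented gap and its value modulo the circular
#' length, which is what lets D-loop-junction-spanning chains merge.
#'
#' @param h1,h2 Single-row HSP data frames (or lists) with
#'   `h1$nuc_start <= h2$nuc_start`; the pair is reordered if not.
#' @param params [assembly_params()].
#' @return `TRUE` or `FALSE`.
#' @export
mergeable <- function(h1, h2, params = assembly_params()) {
  if (h1$chrom != h2$chrom)
    stop("mergeable() requires HSPs on the same chromosome (got '",
         h1$chrom, "' and '", h2$chrom, "')")
  if (h1$nuc_start > h2$nuc_start) { tmp <- h1; h1 <- h2; h2 <- tmp }
  if (params$require_same_orientation && h1$strand != h2$strand)
    return(FALSE)
  nuc_gap <- h2$nuc_start - h1$nuc_end
  if (nuc_gap >= params$nuclear_gap_max) return(FALSE)
  mito_gap <- oriented_mito_gap(h1, h2, params$mito_length)
  mito_gap <= params$mito_gap_max
}

# circular cover of a set of intervals: complement of the largest
# uncovered circular gap; start > end (wrapped) when the cover crosses 0
circular_mito_span <- function(starts, ends, L) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  merged_s <- integer(0); merged_e <- integer(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
           ms <- starts[i]; me <- ends[i] }
  }
  merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
  n <- length(merged_s)
  if (n == 1L) {
    gap_start <- merged_e; gap_end <- merged_s + L
  } else {
    gap_start <- merged_e
    gap_end <- c(merged_s[-1L], merged_s[1L] + L)
  }
  big <- which.max(gap_end - gap_start)
  span_start <- gap_end[big] %% L
  span_end <- gap_start[big]
  if (gap_end[big] - gap_start[big] <= 0) # intervals cover the whole circle
    return(list(start = 0L, end = L, wraps = FALSE))
  wraps <- span_start >= span_end
  list(start = as.integer(span_start), end = as.integer(span_end),
       wraps = wraps)
}

#' Assemble HSPs into NumtS
#'
#' Groups HSPs by (chromosome, strand) and merges them into chains by
#' transitive closure of the pairwise [mergeable()] relation (connected
#' components of the mergeability graph), so that chains interrupted by
#' long intervening elements are still joined whenever any two members
#' satisfy the rule. Each HSP belongs to exactly one assembled NumtS;
#' singletons are allowed. Output is sorted by chromosome in karyotype
#' order (1..22, X, Y, then others lexicographically) and nuclear start,
#' and is invariant to the input row order.
#'
#' @param hsps An [hsp_table()].
#' @param params [assembly_params()].
#' @return A `numts_assembly`: list with `numts` (one row per assembled
#'   NumtS: chrom, strand, nuclear envelope, member count, circular
#'   mitochondrial span with `wraps_junction` flag, alignment-length
#'   weighted `aggregate_identity`) and `members` (the input HSPs with
#'   `numts_idx` and nuclear-order `member_rank`), plus `params`.
#' @export
assemble_numts <- function(hsps, params = assembly_params()) {
  validate_hsps(hsps, mito_length = params$mito_length)
  n <- nrow(hsps)
  if (n == 0L) {
    return(structure(list(numts = empty_numts_df(), members = hsps,
                          params = params), class = "numts_assembly"))
  }
  hsps <- hsps[order(karyotype_rank(hsps$chrom), hsps$strand,
                     hsps$nuc_start, hsps$nuc_end, hsps$mito_start), ,
               drop = FALSE]
  rownames(hsps) <- NULL
  comp <- integer(n)
  next_comp <- 0L
  groups <- split(seq_len(n),
                  if (params$require_same_orientation)
                    paste(hsps$chrom, hsps$strand) else hsps$chrom)
  L <- params$mito_length
  for (idx in groups) {
    # vectorized transitive closure of the pairwise mergeable() relation;
    # rows are nuclear-sorted, so for each i only the run of j with
    # nuclear gap < bound needs the mitochondrial test
    ns <- hsps$nuc_start[idx]; ne <- hsps$nuc_end[idx]
    ms <- hsps$mito_start[idx]; me <- hsps$mito_end[idx]
    parent <- seq_along(idx)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    k <- length(idx)
    if (k > 1L) {
      for (i in 1L:(k - 1L)) {
        j <- which(ns[(i + 1L):k] - ne[i] < params$nuclear_gap_max) + i
        if (!length(j)) next
        g <- if (hsps$strand[idx[i]] == "+") ms[j] - me[i] else ms[i] - me[j]
        ok <- pmin(g, g %% L) <= params$mito_gap_max
        for (jj in j[ok]) {
          ri <- find(i); rj <- find(jj)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(k), find, integer(1L))
    for (r in unique(roots)) {
      next_comp <- next_comp + 1L
      comp[idx[roots == r]] <- next_comp
    }
  }
  # optional cap on chain nuclear extent: split over-long chains greedily
  if (is.finite(params$max_chain_span)) {
    comp <- split_long_chains(hsps, comp, params$max_chain_span)
  }

  members <- hsps
  members$numts_idx <- comp
  rows <- lapply(sort(unique(comp)), function(ci) {
    mi <- which(comp == ci)
    mi <- mi[order(hsps$nuc_start[mi], hsps$nuc_end[mi])]
    h <- hsps[mi, , drop = FALSE]
    span <- circular_mito_span(h$mito_start, h$mito_end, params$mito_length)
    w <- if (all(is.na(h$alignment_length))) rep(1, nrow(h)) else
      ifelse(is.na(h$alignment_length), 1L, h$alignment_length)
    data.frame(numts_idx = ci, chrom = h$chrom[1L], strand = h$strand[1L],
               nuc_start = min(h$nuc_start), nuc_end = max(h$nuc_end),
               n_members = nrow(h),
               mito_start = span$start, mito_end = span$end,
               wraps_junction = span$wraps,
               aggregate_identity =
                 sum(h$percent_identity * w) / sum(w),
               member_length_sum = sum(h$nuc_end - h$nuc_start),
               stringsAsFactors = FALSE)
  })
  numts <- do.call(rbind, rows)
  o <- order(karyotype_rank(numts$chrom), numts$nuc_start, numts$nuc_end)
  numts <- numts[o, , drop = FALSE]
  remap <- setNames(seq_len(nrow(numts)), numts$numts_idx)
  numts$numts_idx <- seq_len(nrow(numts))
  members$numts_idx <- unname(remap[as.character(members$numts_idx)])
  members <- members[order(members$numts_idx, members$nuc_start,
                           members$nuc_end), , drop = FALSE]
  members$member_rank <- unlist(lapply(split(seq_len(nrow(members)),
                                             members$numts_idx),
                                       seq_along), use.names = FALSE)
  rownames(numts) <- rownames(members) <- NULL
  structure(list(numts = numts, members = members, params = params),
            class = "numts_assembly")
}

empty_numts_df <- function() {
  data.frame(numts_idx = integer(), chrom = character(), strand = character(),
             nuc_start = integer(), nuc_end = integer(),
             n_members = integer(), mito_start = integer(),
             mito_end = integer(), wraps_junction = logical(),
             aggregate_identity = numeric(), member_length_sum = integer(),
             stringsAsFactors = FALSE)
}

split_long_chains <- function(hsps, comp, cap) {
  out <- comp
  next_id <- max(comp)
  for (ci in unique(comp)) {
    mi <- which(comp == ci)
    mi <- mi[order(hsps$nuc_start[mi])]
    start <- hsps$nuc_start[mi[1L]]
    cur <- ci
    first <- TRUE
    for (i in mi) {
      if (!first && hsps$nuc_end[i] - start > cap) {
        next_id <- next_id + 1L
        cur <- next_id
        start <- hsps$nuc_start[i]
      }
      out[i] <- cur
      first <- FALSE
    }
  }
  out
}

#' Assign stable NumtS ids
#'
#' Ids follow the `<prefix>_xxx` convention with a zero-padded three-digit
#' ordinal in sort order (width grows to 4 and beyond past 999). Member
#' HSPs of multi-member NumtS get a `_bN` block suffix in nuclear order
#' (`HSA_NumtS_014_b5` = 5th block of the 14th NumtS); single-member
#' NumtS carry the bare id.
#'
#' @param assembly A `numts_assembly` from [assemble_numts()].
#' @param prefix Id prefix (default `"HSA_NumtS"`, HSA = *H. sapiens*).
#' @return The assembly with `numts$numts_id` and `members$member_id`
#'   filled in.
#' @export
assign_ids <- function(assembly, prefix = "HSA_NumtS") {
  stopifnot(inherits(assembly, "numts_assembly"))
  n <- nrow(assembly$numts)
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf("%s_%0*d", prefix, width, seq_len(n))
  assembly$numts$numts_id <- if (n) ids else character(0)
  m <- assembly$members
  if (nrow(m)) {
    nid <- ids[m$numts_idx]
    multi <- assembly$numts$n_members[m$numts_idx] > 1L
    m$member_id <- ifelse(multi, paste0(nid, "_b", m$member_rank), nid)
    m$numts_id <- nid
  } else {
    m$member_id <- character(0)
    m$numts_id <- character(0)
  }
  assembly$members <- m
  assembly
}

#' @export
print.numts_assembly <- function(x, ...) {
  cat("<numts_assembly> ", nrow(x$numts), " assembled NumtS from ",
      nrow(x$members), " HSPs\n", sep = "")
  invisible(x)
}

#' Write an assembled-NumtS report
#'
#' One row per member HSP carrying its parent NumtS id, mirroring the
#' layout of a NumtS compilation spreadsheet (NumtS id, HSP id,
#' chromosome, strand, nuclear and mitochondrial positions, identity).
#'
#' @param assembly An id-assigned `numts_assembly`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_numts_report <- function(assembly, path) {
  m <- assembly$members
  if (is.null(m$member_id)) stop("assign_ids() must be called first")
  df <- data.frame(numts_id = m$numts_id, hsp_id = m$member_id,
                   chrom = m$chrom, strand = m$strand,
                   nuc_start = m$nuc_start, nuc_end = m$nuc_end,
                   mito_start = m$mito_start, mito_end = m$mito_end,
                   percent_identity = round(m$percent_identity, 2))
  write_tsv_report(df, path)
}

#' Karyotype sort rank for chromosome names
#'
#' Orders `1..22, X, Y` (with or without a `chr` prefix) ahead of any
#' other names, which sort lexicographically after them.
#'
#' @param chrom Character vector of chromosome names.
#' @return Numeric rank usable in `order()`.
#' @export
karyotype_rank <- function(chrom) {
  base <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.numeric(base))
  r[base == "X"] <- 23
  r[base == "Y"] <- 24
  other <- is.na(r)
  r[other] <- 25 + as.numeric(factor(base[other], levels = sort(unique(base[other]))))
  r
}
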