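#' Build a liftover map between two mitochondrial references
#'
#' Globally aligns two homologous reference sequences (e.g. an rCRS-like
#' reference and a browser reference that differs by a few insertions)
#' with [global_align()] and stores the co-linear gapless blocks as a
#' block-wise coordinate correspondence. Indels appear as gaps between
#' blocks. Refuses pairs whose global alignment identity falls below
#' `min_identity`, signalling that the inputs are not homologous
#' references.
#'
#' @param source,target [sequence_record()]s.
#' @param scoring A [scoring_scheme()].
#' @param min_identity Identity floor (percent) for accepting the map.
#' @param band_pad Passed to [global_align()].
#' @return A `liftover_map`: `source_id`, `target_id`, `source_length`,
#'   `target_length`, `identity`, and `blocks` (`a_*` = source,
#'   `b_*` = target, 0-based half-open).
#' @export
build_liftover_map <- function(source, target, scoring = scoring_scheme(),
                               min_identity = 90, band_pad = 200L) {
  aln <- global_align(source, target, scoring, band_pad = band_pad)
  identity <- 100 * aln$matches / aln$align_len
  if (identity < min_identity)
    stop(sprintf(paste0("global alignment identity %.1f%% below the %.1f%% ",
                        "floor: '%s' and '%s' do not look like homologous ",
                        "references"),
                 identity, min_identity, source$id, target$id))
  structure(list(source_id = source$id, target_id = target$id,
                 source_length = nchar(source$sequence),
                 target_length = nchar(target$sequence),
                 identity = identity, score = aln$score,
                 blocks = aln$blocks),
            class = "liftover_map")
}

#' @export
print.liftover_map <- function(x, ...) {
  cat("<liftover_map> ", x$source_id, " (", x$source_length, " bp) -> ",
      x$target_id, " (", x$target_length, " bp), ", nrow(x$blocks),
      " block(s), ", sprintf("%.2f%%", x$identity), " identity\n", sep = "")
  invisible(x)
}

#' Invert a liftover map
#'
#' Swaps source and target, giving the map for the reverse direction.
#'
#' @param map A `liftover_map`.
#' @return A `liftover_map` from target to source.
#' @export
invert_map <- function(map) {
  structure(list(source_id = map$target_id, target_id = map$source_id,
                 source_length = map$target_length,
                 target_length = map$source_length,
                 identity = map$identity, score = map$score,
                 blocks = data.frame(a_start = map$blocks$b_start,
                                     a_end = map$blocks$b_end,
                                     b_start = map$blocks$a_start,
                                     b_end = map$blocks$a_end)),
            class = "liftover_map")
}

# lift a single source position; NA if it falls between blocks
lift_position <- function(p, blocks) {
  i <- which(blocks$a_start <= p & p < blocks$a_end)
  if (length(i) == 0L) return(NA_integer_)
  i <- i[1L]
  blocks$b_start[i] + (p - blocks$a_start[i])
}

#' Lift intervals through a liftover map
#'
#' Endpoints are lifted independently. An endpoint falling in an
#' alignment gap snaps *outward* to the nearest mapped position (start
#' endpoints leftward, end endpoints rightward), so lifted annotations
#' never shrink across indels; such intervals are flagged `"snapped"`.
#' Intervals wholly inside a source-only deletion are `"unmapped"` (with
#' NA coordinates).
#'
#' @param intervals Data frame with columns `start`, `end` (0-based
#'   half-open) or a length-2 numeric vector.
#' @param map A `liftover_map` from [build_liftover_map()].
#' @return Data frame `start`, `end`, `status` in
#'   `c("mapped","snapped","unmapped")`, one row per input interval.
#' @export
lift_interval <- function(intervals, map) {
  stopifnot(inherits(map, "liftover_map"))
  if (is.numeric(intervals) && length(intervals) == 2L)
    intervals <- data.frame(start = intervals[1L], end = intervals[2L])
  b <- map$blocks
  out <- data.frame(start = rep(NA_integer_, nrow(intervals)),
                    end = NA_integer_, status = "unmapped",
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(intervals))) {
    s <- intervals$start[r]; e <- intervals$end[r]
    if (s < 0 || e > map$source_length || s >= e)
      stop("interval [", s, ",", e, ") outside source bounds [0,",
           map$source_length, ") or empty")
    covered <- any(b$a_start < e & s < b$a_end)
    if (!covered) next # wholly inside a source-only deletion
    snapped <- FALSE
    ts <- lift_position(s, b)
    if (is.na(ts)) { # snap start leftward to the end of the previous block
      snapped <- TRUE
      prev <- which(b$a_end <= s)
      ts <- if (length(prev)) b$b_end[max(prev)] else b$b_start[1L]
    }
    te_pos <- lift_position(e - 1L, b)
    if (is.na(te_pos)) { # snap end rightward to the start of the next block
      snapped <- TRUE
      nxt <- which(b$a_start >= e - 1L)
      te <- if (length(nxt)) b$b_start[min(nxt)] else b$b_end[nrow(b)]
    } else te <- te_pos + 1L
    out$start[r] <- ts
    out$end[r] <- te
    out$status[r] <- if (snapped) "snapped" else "mapped"
  }
  out
}

#' Summarize a liftover map
#'
#' One row per gapless block with the source/target gap (indel) lengths
#' preceding it, the flat-file form of the map.
#'
#' @param map A `liftover_map`.
#' @return Data frame `a_start,a_end,b_start,b_end,source_gap_before,
#'   target_gap_before`.
#' @export
liftover_summary <- function(map) {
  b <- map$blocks
  n <- nrow(b)
  data.frame(b,
             source_gap_before = c(b$a_start[1L],
                                   if (n > 1L) b$a_start[-1L] - b$a_end[-n]),
             target_gap_before = c(b$b_start[1L],
                                   if (n > 1L) b$b_start[-1L] - b$b_end[-n]))
}
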