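#' Create a sequence record
#'
#' A minimal container for a named nucleotide sequence. Sequences are
#' normalized to uppercase and restricted to the alphabet `A,C,G,T,N`;
#' other IUPAC ambiguity codes are rejected (or masked to `N` with
#' `ambiguous = "mask"`), since alignment scoring is defined only on the
#' unambiguous alphabet plus `N`.
#'
#' @param id Sequence identifier (non-empty string).
#' @param sequence Nucleotide string; lowercase is folded to uppercase.
#' @param ambiguous Either `"error"` (default) to reject ambiguity codes
#'   other than `N`, or `"mask"` to replace them with `N`.
#' @return An object of class `sequence_record` with fields `id` and
#'   `sequence`.
#' @export
sequence_record <- function(id, sequence, ambiguous = c("error", "mask")) {
  ambiguous <- match.arg(ambiguous)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string (record '", id, "')")
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    if (ambiguous == "mask") {
      sequence <- gsub("[^ACGTN]", "N", sequence)
    } else {
      stop("record '", id, "' contains characters outside {A,C,G,T,N}: '",
           substr(bad, 1L, 10L), "'; use ambiguous = \"mask\" to N-mask them")
    }
  }
  structure(list(id = id, sequence = sequence), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat("<sequence_record> ", x$id, " (", nchar(x$sequence), " bp)\n", sep = "")
  invisible(x)
}

seq_len_bp <- function(rec) nchar(rec$sequence)

#' Read a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file into a list of
#' [sequence_record()]s, in file order. Parsing is done by
#' `Biostrings::readDNAStringSet()` after a light structural check that
#' reports the offending line on malformed input.
#'
#' @param path Path to a FASTA file.
#' @inheritParams sequence_record
#' @return A list of `sequence_record`s (empty list for an empty file).
#' @export
read_fasta <- function(path, ambiguous = c("error", "mask")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  if (!startsWith(lines[nonblank[1L]], ">"))
    stop("malformed FASTA: line ", nonblank[1L], " of '", path,
         "' does not start a record header")
  hdr <- which(startsWith(lines, ">"))
  for (h in hdr) {
    if (!nzchar(trimws(sub("^>", "", lines[h]))))
      stop("malformed FASTA: empty header at line ", h, " of '", path, "'")
    nxt <- hdr[hdr > h]
    block_end <- if (length(nxt)) nxt[1L] - 1L else length(lines)
    if (h == block_end || !any(nzchar(trimws(lines[(h + 1L):block_end]))))
      stop("malformed FASTA: record at line ", h, " of '", path,
           "' has an empty sequence")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    sequence_record(ids[i], as.character(set[[i]]), ambiguous = ambiguous)
  })
}

#' Write sequence records as FASTA
#'
#' Writes records wrapped at 60 columns. Round-trips losslessly with
#' [read_fasta()].
#'
#' @param records A `sequence_record` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1L))
  names(seqs) <- vapply(records, function(r) r$id, character(1L))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Parse a 12-column BLAST tabular HSP file
#'
#' Reads local-alignment hits in the BLASTN tabular ("outfmt 6") dialect:
#' `query id, subject id, % identity, alignment length, mismatches, gap
#' opens, q. start, q. end, s. start, s. end, evalue, bit score`, with the
#' query taken to be the mitochondrial genome and the subject a nuclear
#' chromosome. One-based inclusive coordinates are converted to the
#' package's 0-based half-open convention; rows whose subject coordinates
#' descend become minus-strand HSPs with normalized (min < max) subject
#' coordinates. Rows with E-value at or above `evalue_threshold` are
#' dropped, mirroring the convention that only hits below the fixed
#' threshold constitute HSPs.
#'
#' @param path Path to a tab-separated file; lines starting with `#` are
#'   ignored.
#' @param evalue_threshold Keep only rows with `evalue < evalue_threshold`
#'   (default `1e-3`).
#' @return An HSP data frame (see [hsp_table()]), possibly empty.
#' @export
parse_blast_tabular <- function(path, evalue_threshold = 1e-3) {
  if (!file.exists(path)) stop("HSP table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hsp_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L))
    stop("line ", lineno[which(ncols != 12L)[1L]],
         ": expected 12 tab-separated columns, found ", ncols[ncols != 12L][1L])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("line ", lineno[which(is.na(v))[1L]], ": non-numeric ", name)
    v
  }
  pid <- num(3L, "percent identity"); alen <- num(4L, "alignment length")
  mism <- num(5L, "mismatches"); gapo <- num(6L, "gap opens")
  qs <- num(7L, "q.start"); qe <- num(8L, "q.end")
  ss <- num(9L, "s.start"); se <- num(10L, "s.end")
  ev <- num(11L, "evalue"); bits <- num(12L, "bit score")
  if (any(ev < 0)) stop("line ", lineno[which(ev < 0)[1L]], ": negative evalue")

  minus <- ss > se
  nuc_start <- ifelse(minus, se, ss) - 1
  nuc_end <- ifelse(minus, ss, se)
  qminus <- qs > qe # tolerated: strand carried on the query side instead
  mito_start <- ifelse(qminus, qe, qs) - 1
  mito_end <- ifelse(qminus, qs, qe)
  strand <- ifelse(xor(minus, qminus), "-", "+")

  out <- hsp_table(
    chrom = m[, 2L], nuc_start = nuc_start, nuc_end = nuc_end,
    strand = strand, mito_start = mito_start, mito_end = mito_end,
    percent_identity = pid, alignment_length = as.integer(alen),
    mismatches = as.integer(mism), gap_opens = as.integer(gapo),
    evalue = ev, bit_score = bits, raw_score = NA_integer_,
    query_id = m[, 1L])
  out <- out[out$evalue < evalue_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write HSPs in the 12-column BLAST tabular dialect
#'
#' Inverse of [parse_blast_tabular()]: internal 0-based half-open
#' coordinates become 1-based inclusive, and minus-strand HSPs are written
#' with descending subject coordinates, so files written here can be fed
#' back through the parser (or mixed with external BLASTN output).
#'
#' @param hsps HSP data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hsps, path) {
  validate_hsps(hsps)
  minus <- hsps$strand == "-"
  s1 <- ifelse(minus, hsps$nuc_end, hsps$nuc_start + 1)
  s2 <- ifelse(minus, hsps$nuc_start + 1, hsps$nuc_end)
  qid <- if ("query_id" %in% names(hsps)) hsps$query_id else "chrM"
  # bit score approximated from the raw score when only that is known
  bit <- ifelse(!is.na(hsps$bit_score), hsps$bit_score,
                ifelse(!is.na(hsps$raw_score),
                       round(hsps$raw_score * 0.36, 1), 0))
  ev <- ifelse(is.na(hsps$evalue), 0, hsps$evalue)
  df <- data.frame(qid, hsps$chrom, sprintf("%.2f", hsps$percent_identity),
                   hsps$alignment_length, hsps$mismatches, hsps$gap_opens,
                   hsps$mito_start + 1, hsps$mito_end, s1, s2,
                   format(ev, digits = 3, scientific = TRUE), bit)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write features as a UCSC BED6 or BED9 file
#'
#' @param records Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` and, for BED9, `rgb` (strings like `"0,0,255"`).
#' @param path Output path.
#' @param bed_type `"BED6"` or `"BED9"`; BED9 adds thickStart/thickEnd and
#'   itemRgb columns.
#' @param track_line Optional UCSC `track ...` header line written verbatim
#'   before the features.
#' @return `path`, invisibly. Features are written 0-based half-open,
#'   sorted by (chromosome in karyotype order, start).
#' @export
write_bed <- function(records, path, bed_type = c("BED6", "BED9"),
                      track_line = NULL) {
  bed_type <- match.arg(bed_type)
  need <- c("chrom", "start", "end", "name", "score", "strand")
  if (bed_type == "BED9") need <- c(need, "rgb")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("BED records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(records)) {
    if (any(records$start >= records$end))
      stop("BED validation: start >= end at row ",
           which(records$start >= records$end)[1L])
    if (any(records$score < 0 | records$score > 1000))
      stop("BED validation: score outside [0,1000] at row ",
           which(records$score < 0 | records$score > 1000)[1L])
    if (!all(records$strand %in% c("+", "-", ".")))
      stop("BED validation: invalid strand")
    if (bed_type == "BED9" &&
        !all(grepl("^\\d{1,3},\\d{1,3},\\d{1,3}$", records$rgb)))
      stop("BED validation: itemRgb must be 'R,G,B'")
    records <- records[order(karyotype_rank(records$chrom), records$start), ,
                       drop = FALSE]
  }
  cols <- data.frame(records$chrom, records$start, records$end,
                     records$name, as.integer(round(records$score)),
                     records$strand)
  if (bed_type == "BED9")
    cols <- cbind(cols, records$start, records$end, records$rgb)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  if (nrow(cols))
    write.table(cols, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6/BED9 file
#'
#' Companion reader for [write_bed()] (used for round-trips and for user
#' supplied repeat annotations). `track` and `browser` header lines are
#' skipped.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom,start,end,name,score,strand`
#'   and, when present, `rgb`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- min(lengths(fields))
  if (nc < 3L) stop("BED line with fewer than 3 columns")
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, character(1L))
  out <- data.frame(
    chrom = get(1L, ""),
    start = as.integer(get(2L, NA_character_)),
    end = as.integer(get(3L, NA_character_)),
    name = get(4L, "."),
    score = suppressWarnings(as.numeric(get(5L, "0"))),
    strand = get(6L, "."))
  if (nc >= 9L) out$rgb <- get(9L, "0,0,0")
  out
}

#' Write a per-base profile as bedGraph
#'
#' Consecutive equal values are run-length collapsed.
#'
#' @param counts Integer vector of per-position values (position 1 = base 0).
#' @param path Output path.
#' @param chrom Chromosome/sequence name for column 1.
#' @param track_line Optional header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(counts, path, chrom = "chrM", track_line = NULL) {
  r <- rle(as.integer(counts))
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  write.table(data.frame(chrom, starts, ends, r$values), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as a TSV report with a header row
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
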