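#' Track configuration
#'
#' Names, descriptions, score mapping and chromosome colors for the four
#' NumtS browser tracks. The chromosome color table follows the UCSC
#' Genome Browser chromosome-coloring convention and ships as an editable
#' TSV (`inst/extdata/ucsc_chrom_colors.tsv`); pass your own file to
#' override.
#'
#' @param colors_path TSV with columns `chrom` and `rgb` (`"R,G,B"`).
#' @param score_mode `"identity"` shades items by percent identity
#'   (default); `"bit_score"` shades by BLAST bit score capped at 1000.
#' @param names Character vector of the four track names.
#' @return A `track_config` list.
#' @export
track_config <- function(colors_path = system.file("extdata",
                                                   "ucsc_chrom_colors.tsv",
                                                   package = "numtsr"),
                         score_mode = c("identity", "bit_score"),
                         names = c("NumtS", "NumtS assembled",
                                   "NumtS on mitochondrion",
                                   "NumtS on mitochondrion with chromosome placement")) {
  score_mode <- match.arg(score_mode)
  if (length(unique(names)) != 4L) stop("four distinct track names required")
  colors <- read.delim(colors_path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "rgb") %in% colnames(colors)))
    stop("color table needs columns 'chrom' and 'rgb'")
  if (!all(grepl("^\\d{1,3},\\d{1,3},\\d{1,3}$", colors$rgb)))
    stop("color table rgb values must be 'R,G,B' triples")
  structure(list(names = names, score_mode = score_mode,
                 colors = setNames(colors$rgb, colors$chrom)),
            class = "track_config")
}

#' Map percent identity to a BED score
#'
#' Linear mapping `round(identity * 10)` clipped to `[0, 1000]`, so item
#' shading in a `useScore` track reflects alignment similarity and is
#' comparable across datasets (not rescaled to the observed range).
#'
#' @param percent_identity Numeric in `(0, 100]`.
#' @return Integer score in `[0, 1000]`, monotone in identity.
#' @export
identity_to_bed_score <- function(percent_identity) {
  if (any(percent_identity <= 0 | percent_identity > 100))
    stop("percent identity outside (0,100]")
  pmin(1000L, pmax(0L, as.integer(round_half_away(percent_identity * 10))))
}

track_score <- function(identity, bit_score, config) {
  if (config$score_mode == "bit_score" && !all(is.na(bit_score)))
    pmin(1000L, pmax(0L, as.integer(round_half_away(bit_score))))
  else identity_to_bed_score(identity)
}

#' Write the two nuclear NumtS tracks
#'
#' Track 1 ("NumtS"): one BED6 item per HSP, named by its member id,
#' shaded by similarity, with the strand arrow from the alignment
#' orientation. Track 2 ("NumtS assembled"): one BED6 item per assembled
#' NumtS shaded by its aggregate identity.
#'
#' @param assembly An id-assigned `numts_assembly` (see [assign_ids()]).
#' @param config A [track_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly;
#'   the feature data frames are attached as attribute `"features"`.
#' @export
make_nuclear_tracks <- function(assembly, config = track_config(),
                                dir = ".") {
  m <- assembly$members
  a <- assembly$numts
  if (is.null(m$member_id) || is.null(a$numts_id))
    stop("unnamed items: call assign_ids() before writing tracks")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hsp_bed <- data.frame(chrom = m$chrom, start = m$nuc_start,
                        end = m$nuc_end, name = m$member_id,
                        score = track_score(m$percent_identity, m$bit_score,
                                            config),
                        strand = m$strand)
  asm_bed <- data.frame(chrom = a$chrom, start = a$nuc_start,
                        end = a$nuc_end, name = a$numts_id,
                        score = identity_to_bed_score(a$aggregate_identity),
                        strand = a$strand)
  p1 <- file.path(dir, "numts_hsp.bed")
  p2 <- file.path(dir, "numts_assembled.bed")
  write_bed(hsp_bed, p1, "BED6",
            track_line = sprintf(
              'track name="%s" description="HSP NumtS mapped on the nuclear genome" useScore=1',
              config$names[1L]))
  write_bed(asm_bed, p2, "BED6",
            track_line = sprintf(
              'track name="%s" description="Assembled NumtS" useScore=1',
              config$names[2L]))
  out <- c(numts_hsp = p1, numts_assembled = p2)
  attr(out, "features") <- list(hsp = hsp_bed, assembled = asm_bed)
  invisible(out)
}

#' Write the two mitochondrial NumtS tracks
#'
#' Both tracks place each HSP on the mitochondrial genome (individual
#' HSPs never wrap the control-region junction; a junction-spanning
#' NumtS appears as its flanking member HSPs, joinable by name). The
#' BED6 track is shaded by similarity; the BED9 track colors each item
#' by the chromosome the HSP comes from, using the configured chromosome
#' color table. Item names are member ids, so nuclear and mitochondrial
#' items cross-reference by name.
#'
#' @param assembly An id-assigned `numts_assembly`.
#' @param config A [track_config()].
#' @param dir Output directory.
#' @param mito_id Sequence name for the mitochondrial reference.
#' @return Named character vector of the two file paths, invisibly, with
#'   feature frames in attribute `"features"`.
#' @export
make_mito_tracks <- function(assembly, config = track_config(), dir = ".",
                             mito_id = "chrM") {
  m <- assembly$members
  if (is.null(m$member_id))
    stop("unnamed items: call assign_ids() before writing tracks")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  missing_col <- setdiff(unique(m$chrom), names(config$colors))
  if (length(missing_col))
    stop("no color configured for chromosome(s): ",
         paste(missing_col, collapse = ", "))
  bed6 <- data.frame(chrom = mito_id, start = m$mito_start,
                     end = m$mito_end, name = m$member_id,
                     score = track_score(m$percent_identity, m$bit_score,
                                         config),
                     strand = m$strand)
  bed9 <- cbind(bed6, rgb = unname(config$colors[m$chrom]))
  p1 <- file.path(dir, "numts_on_mito.bed")
  p2 <- file.path(dir, "numts_on_mito_chrom_colors.bed")
  write_bed(bed6, p1, "BED6",
            track_line = sprintf(
              'track name="%s" description="HSP NumtS mapped on the mitochondrial genome" useScore=1',
              config$names[3L]))
  write_bed(bed9, p2, "BED9",
            track_line = sprintf(
              'track name="%s" description="HSP NumtS on the mitochondrial genome, colored by source chromosome" itemRgb="On"',
              config$names[4L]))
  out <- c(numts_on_mito = p1, numts_on_mito_chrom_colors = p2)
  attr(out, "features") <- list(bed6 = bed6, bed9 = bed9)
  invisible(out)
}

#' Cross-reference table between nuclear and mitochondrial placements
#'
#' One row per HSP with its member id and both locus strings — the
#' flat-file stand-in for the browser's reciprocal item links.
#'
#' @param assembly An id-assigned `numts_assembly`.
#' @param path Optional TSV output path.
#' @param mito_id Mitochondrial sequence name for the mito locus string.
#' @return Data frame `member_id, nuclear_locus, mito_locus` with locus
#'   strings `chrom:start-end:strand`.
#' @export
make_crosslink_table <- function(assembly, path = NULL, mito_id = "chrM") {
  m <- assembly$members
  if (is.null(m$member_id))
    stop("unnamed items: call assign_ids() before the crosslink table")
  df <- data.frame(
    member_id = m$member_id,
    nuclear_locus = sprintf("%s:%d-%d:%s", m$chrom, m$nuc_start,
                            m$nuc_end, m$strand),
    mito_locus = sprintf("%s:%d-%d:%s", mito_id, m$mito_start,
                         m$mito_end, m$strand),
    stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv_report(df, path)
  df
}

#' Parse a locus string back to coordinates
#'
#' Inverse of the locus strings written by [make_crosslink_table()].
#'
#' @param locus Strings of the form `chrom:start-end:strand`.
#' @return Data frame `chrom,start,end,strand`.
#' @export
parse_locus <- function(locus) {
  m <- regmatches(locus, regexec("^(.+):(\\d+)-(\\d+):([+-])$", locus))
  if (any(lengths(m) != 5L)) stop("malformed locus string")
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             strand = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}
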