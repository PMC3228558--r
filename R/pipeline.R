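#' Pipeline configuration
#'
#' Bundles the sub-configurations of the pipeline stages and round-trips
#' through a single human-editable YAML file.
#'
#' @param scoring A [scoring_scheme()].
#' @param assembly An [assembly_params()].
#' @param simulation A [simulation_params()].
#' @param track_colors_path Chromosome color table for [track_config()].
#' @param seed Integer seed for any stochastic stage.
#' @param verbosity 0 = quiet, 1 = stage messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scoring = scoring_scheme(),
                            assembly = assembly_params(),
                            simulation = simulation_params(),
                            track_colors_path = NULL,
                            seed = 1L, verbosity = 1L) {
  structure(list(scoring = scoring, assembly = assembly,
                 simulation = simulation,
                 track_colors_path = track_colors_path,
                 seed = as.integer(seed), verbosity = verbosity),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_config()] (missing keys take
#'   their defaults).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  fill <- function(ctor, part) do.call(ctor, part[!vapply(part, is.null,
                                                          logical(1L))])
  pipeline_config(
    scoring = fill(scoring_scheme, y$scoring %||% list()),
    assembly = fill(assembly_params, y$assembly %||% list()),
    simulation = fill(simulation_params, y$simulation %||% list()),
    track_colors_path = y$track_colors_path,
    seed = y$seed %||% 1L, verbosity = y$verbosity %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(config, ..., con = NULL) {
  msg <- paste0(format(Sys.time(), "[%H:%M:%S] "), ...)
  if (!is.null(con)) writeLines(msg, con)
  if (isTRUE(config$verbosity >= 1)) message(msg)
  invisible(NULL)
}

#' Find HSPs across a genome
#'
#' Runs [find_hsps()] for the mitochondrial reference against every
#' chromosome of a genome FASTA (one aligner run per chromosome), or —
#' when `hsp_table_path` is given instead — loads a pre-computed BLAST
#' tabular file through [parse_blast_tabular()], so external BLASTN runs
#' and the internal aligner are interchangeable upstream of assembly.
#'
#' @param mito_fasta Path to the mitochondrial reference FASTA (single
#'   record; the first record is used).
#' @param genome_fasta Path to a (multi-record) nuclear FASTA, or `NULL`.
#' @param hsp_table_path Path to a 12-column BLAST tabular file, or
#'   `NULL`. Exactly one of `genome_fasta`/`hsp_table_path` is required.
#' @param config A [pipeline_config()].
#' @param out Optional path to also write the HSPs as BLAST tabular.
#' @return An [hsp_table()] over all chromosomes.
#' @export
run_find <- function(mito_fasta, genome_fasta = NULL, hsp_table_path = NULL,
                     config = pipeline_config(), out = NULL) {
  if (is.null(genome_fasta) == is.null(hsp_table_path))
    stop("usage error: supply exactly one of genome_fasta or hsp_table_path")
  if (!is.null(hsp_table_path)) {
    hsps <- parse_blast_tabular(hsp_table_path,
                                config$scoring$evalue_threshold)
    pipeline_log(config, "find: loaded ", nrow(hsps),
                 " HSPs from table ", hsp_table_path)
  } else {
    mito <- read_fasta(mito_fasta)[[1L]]
    chroms <- read_fasta(genome_fasta)
    if (!length(chroms)) stop("usage error: genome FASTA has no records")
    per <- lapply(chroms, function(cc) {
      h <- find_hsps(mito, cc, config$scoring)
      pipeline_log(config, "find: ", cc$id, ": ", nrow(h), " HSPs")
      h
    })
    hsps <- do.call(rbind, per)
    hsps <- hsps[order(karyotype_rank(hsps$chrom), hsps$nuc_start), ,
                 drop = FALSE]
    if (nrow(hsps)) hsps$hsp_id <- sprintf("HSP_%04d", seq_len(nrow(hsps)))
    rownames(hsps) <- NULL
    class(hsps) <- c("hsp_table", "data.frame")
  }
  if (!is.null(out)) write_blast_tabular(hsps, out)
  hsps
}

#' Run the whole NumtS pipeline
#'
#' Detection (or table import), assembly, id assignment, statistics,
#' mitochondrial coverage and the four browser tracks, written to an
#' output directory with a fixed file manifest and a run log.
#' Deterministic given identical inputs and configuration.
#'
#' @inheritParams run_find
#' @param out_dir Output directory (created).
#' @param repeats_bed Optional repeat-annotation BED for flank analysis.
#' @param mito_id Mitochondrial sequence name used in outputs.
#' @return Invisibly, a named list: `hsps`, `assembly`, `stats`, and
#'   `manifest` (named vector of output paths).
#' @export
run_all <- function(mito_fasta, genome_fasta = NULL, hsp_table_path = NULL,
                    out_dir = "numts_out", config = pipeline_config(),
                    repeats_bed = NULL, mito_id = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, "w"); on.exit(close(con))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  pipeline_log(config, "pipeline start (numtsr ",
               as.character(utils::packageVersion("numtsr")), ")", con = con)
  if (!is.null(mito_fasta) && !file.exists(mito_fasta))
    stop("stage 'find' failed: mitochondrial FASTA not found: ", mito_fasta)
  mito <- stage("find", read_fasta(mito_fasta)[[1L]])
  if (is.null(mito_id)) mito_id <- mito$id
  L <- nchar(mito$sequence)
  config$assembly$mito_length <- L

  hsps <- stage("find", run_find(mito_fasta, genome_fasta, hsp_table_path,
                                 config))
  pipeline_log(config, "find: ", nrow(hsps), " HSPs total", con = con)
  manifest <- c(hsps = file.path(out_dir, "hsps.tsv"))
  write_blast_tabular(hsps, manifest[["hsps"]])

  assembly <- stage("assemble",
                    assign_ids(assemble_numts(hsps, config$assembly)))
  pipeline_log(config, "assemble: ", nrow(assembly$numts),
               " assembled NumtS", con = con)
  manifest[["numts"]] <- file.path(out_dir, "numts.tsv")
  write_numts_report(assembly, manifest[["numts"]])

  chrom_lengths <- if (!is.null(genome_fasta)) {
    g <- read_fasta(genome_fasta)
    data.frame(chrom = vapply(g, `[[`, "", "id"),
               length = vapply(g, seq_len_bp, integer(1L)))
  } else {
    data.frame(chrom = unique(hsps$chrom),
               length = vapply(unique(hsps$chrom), function(cc)
                 max(hsps$nuc_end[hsps$chrom == cc]), integer(1L)))
  }
  st <- stage("stats", chromosome_stats(assembly, chrom_lengths))
  manifest[["chrom_stats"]] <- file.path(out_dir, "chrom_stats.tsv")
  write_tsv_report(st, manifest[["chrom_stats"]])
  pipeline_log(config, "stats: total NumtS span ",
               attr(st, "grand_total_span"), " bp", con = con)

  tab1 <- stage("stats", {
    fv <- function(v) if (length(v)) five_number_summary(v) else
      list(min = NA, q1 = NA, median = NA, q3 = NA, max = NA)
    sims <- fv(hsps$percent_identity)
    lens <- fv(hsps$alignment_length)
    dspan <- fv(span_differences(hsps))
    cdist <- fv(concatenation_distances(assembly))
    data.frame(statistic = c("min", "q1", "median", "q3", "max"),
               hsp_similarity = unlist(sims),
               hsp_length = unlist(lens),
               span_difference = unlist(dspan),
               concatenation_distance = unlist(cdist))
  })
  manifest[["hsp_stats"]] <- file.path(out_dir, "hsp_stats.tsv")
  write_tsv_report(tab1, manifest[["hsp_stats"]])

  cov <- stage("stats", coverage_profile(hsps, L))
  manifest[["coverage"]] <- file.path(out_dir, "mito_coverage.bedGraph")
  write_bedgraph(cov$counts, manifest[["coverage"]], chrom = mito_id,
                 track_line = 'track type=bedGraph name="NumtS mtDNA coverage"')

  tc <- stage("tracks", if (is.null(config$track_colors_path))
    track_config() else track_config(config$track_colors_path))
  nt <- stage("tracks", make_nuclear_tracks(assembly, tc, out_dir))
  mt <- stage("tracks", make_mito_tracks(assembly, tc, out_dir,
                                         mito_id = mito_id))
  manifest <- c(manifest, nt, mt)
  manifest[["crosslinks"]] <- file.path(out_dir, "crosslinks.tsv")
  stage("tracks", make_crosslink_table(assembly, manifest[["crosslinks"]],
                                       mito_id = mito_id))

  stats_out <- list(chrom_stats = st, hsp_stats = tab1, coverage = cov)
  if (!is.null(repeats_bed)) {
    rep_df <- stage("stats", read_bed(repeats_bed))
    fl <- stage("stats", flank_repeat_content(assembly, rep_df,
                                              chrom_lengths))
    manifest[["flank_repeats"]] <- file.path(out_dir, "flank_repeats.tsv")
    write_tsv_report(fl$per_numts, manifest[["flank_repeats"]])
    manifest[["flank_cumulative"]] <- file.path(out_dir,
                                                "flank_cumulative.tsv")
    write_tsv_report(fl$cumulative, manifest[["flank_cumulative"]])
    stats_out$flanks <- fl
  }
  manifest[["log"]] <- log_path
  pipeline_log(config, "pipeline done: ", length(manifest), " outputs in ",
               out_dir, con = con)
  invisible(list(hsps = hsps, assembly = assembly, stats = stats_out,
                 manifest = manifest))
}
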