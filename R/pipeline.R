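# End-to-end orchestration: filter -> pileup -> normalize/average ->
# call-tss -> classify -> rep-scan, with a run manifest recording every
# parameter and input checksum. Logs go to stderr; machine-readable outputs
# are TSV/bedGraph files plus the returned report bundle.

#' Pipeline configuration
#'
#' @param genome path to the genome FASTA.
#' @param annotation path to the GFF3 annotation.
#' @param replicates \code{data.frame} with one row per replicate: columns
#'   \code{condition}, \code{replicate}, \code{sam} (alignment path) and
#'   optionally \code{fastq} (raw reads; enables the read-level stage).
#' @param predicted_tss optional BED file of predicted TSS positions.
#' @param outdir output directory.
#' @param adapter 3' adapter for the read-level stage.
#' @param min_len minimum read length (default 16).
#' @param window,min_height TSS-calling parameters (defaults 300 bp, 5
#'   normalized counts).
#' @param tolerance concordance tolerance in bp (default 0).
#' @param rep_params list of REP-screen parameters passed to
#'   [rep_transcription_report()].
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genome, annotation, replicates,
                            predicted_tss = NULL, outdir,
                            adapter = "AGATCGGAAGA", min_len = 16L,
                            window = 300L, min_height = 5, tolerance = 0L,
                            rep_params = list()) {
  paths <- c(genome, annotation, replicates$sam,
             if (!is.null(replicates$fastq)) replicates$fastq[!is.na(replicates$fastq)],
             predicted_tss)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input path(s): ", paste(missing, collapse = ", "))
  stopifnot(all(c("condition", "replicate", "sam") %in% names(replicates)))
  structure(list(
    genome = genome, annotation = annotation, replicates = replicates,
    predicted_tss = predicted_tss, outdir = outdir, adapter = adapter,
    min_len = as.integer(min_len), window = as.integer(window),
    min_height = min_height, tolerance = as.integer(tolerance),
    rep_params = rep_params
  ), class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[divtss %s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

#' Intergenic regions between consecutive collinear genes
#'
#' @param annotation feature table.
#' @param min_width smallest IGR reported (default 50 bp).
#' @return \code{data.frame} with \code{start}, \code{end}, \code{strand}
#'   (of the flanking genes), \code{left}, \code{right}.
#' @export
collinear_igrs <- function(annotation, min_width = 50L) {
  g <- annotation[annotation$kind == "protein_coding", , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(g) - 1L)) {
    if (g$strand[i] != g$strand[i + 1L]) next
    s <- g$end[i] + 1L; e <- g$start[i + 1L] - 1L
    if (e - s + 1L < min_width) next
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e, strand = g$strand[i],
      left = g$name[i], right = g$name[i + 1L], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), left = character(0),
                      right = character(0)))
  }
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' Executes, per replicate: optional read-level trimming/length filtering
#' (when a FASTQ is given), perfect-match SAM filtering, and 5'-end pileup;
#' then per condition: depth normalization and replicate averaging, TSS
#' calling for every annotated ncRNA with offsets and optional concordance;
#' then arrangement classification with the inter-TSS distance summary, and
#' the REP screen over every REP-containing collinear intergenic region.
#' All tables are written to \code{outdir} along with per-condition
#' bedGraphs and a manifest recording parameters and input checksums. Any
#' stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return the report bundle (invisibly): list with \code{filter_report},
#'   \code{groups}, \code{tracks}, \code{tss_calls}, \code{arrangements},
#'   \code{distance_summary}, \code{rep_reports}, \code{rep_table},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load-inputs"
  bundle <- tryCatch({
    genome <- read_genome_fasta(config$genome)
    annotation <- read_annotation_gff3(config$annotation)
    predicted <- if (!is.null(config$predicted_tss))
      read_predicted_tss_bed(config$predicted_tss) else NULL
    log_stage(stage, sprintf("genome %s (%d bp), %d features",
                             genome$id, genome$length, nrow(annotation)))

    stage <- "filter"
    reps <- config$replicates
    tracks <- vector("list", nrow(reps))
    stats_rows <- list()
    for (i in seq_len(nrow(reps))) {
      n_trim <- NA_integer_
      if (!is.null(reps$fastq) && !is.na(reps$fastq[i])) {
        pr <- process_reads(read_fastq(reps$fastq[i]), config$adapter,
                            config$min_len)
        n_trim <- pr$n_after_trim_and_length
      }
      recs <- read_sam(reps$sam[i])
      pf <- perfect_match_filter(recs, n_after_trim_and_length = n_trim)
      stage <- "pileup"
      tracks[[i]] <- build_track(pf$records, ref_id = genome$id,
                                 genome_length = genome$length)
      stats_rows[[i]] <- data.frame(
        condition = reps$condition[i], replicate = reps$replicate[i],
        n_input = pf$stats$n_input,
        n_after_trim_and_length = pf$stats$n_after_trim_and_length,
        n_mapped = pf$stats$n_mapped, n_perfect = pf$stats$n_perfect)
      log_stage("filter/pileup",
                sprintf("%s rep %s: %d records, %d perfect", reps$condition[i],
                        reps$replicate[i], pf$stats$n_input, pf$stats$n_perfect))
      stage <- "filter"
    }

    stage <- "normalize"
    conds <- unique(reps$condition)
    groups <- lapply(conds, function(cc) {
      condition_group(cc, tracks[reps$condition == cc])
    })
    names(groups) <- conds
    cond_tracks <- lapply(groups, normalize_and_average)
    norm_rep <- normalization_report(groups)
    for (cc in conds) {
      log_stage(stage, sprintf("%s: N_av = %.1f, c = %s", cc,
                               groups[[cc]]$n_av,
                               paste(sprintf("%.4f", groups[[cc]]$coefficients),
                                     collapse = ", ")))
      for (s in c("+", "-")) {
        write_track_bedgraph(cond_tracks[[cc]], s,
          file.path(config$outdir,
                    sprintf("%s_%s.bedgraph", gsub("\\W+", "_", cc),
                            if (s == "+") "plus" else "minus")))
      }
    }

    stage <- "call-tss"
    ncs <- annotation[annotation$kind == "ncRNA", , drop = FALSE]
    calls <- list()
    for (cc in conds) {
      for (i in seq_len(nrow(ncs))) {
        cl <- call_tss(cond_tracks[[cc]], ncs[i, , drop = FALSE],
                       window = config$window, min_height = config$min_height,
                       condition = cc, ref_id = genome$id)
        if (nrow(cl)) calls[[length(calls) + 1L]] <- cl
      }
    }
    tss_calls <- if (length(calls)) do.call(rbind, calls) else NULL
    if (!is.null(tss_calls) && !is.null(predicted)) {
      tss_calls <- concordance(tss_calls, predicted, config$tolerance)
    }
    log_stage(stage, sprintf("%d TSS call(s) for %d ncRNA(s)",
                             if (is.null(tss_calls)) 0L else nrow(tss_calls),
                             nrow(ncs)))

    stage <- "classify"
    arrangements <- classify_all(annotation)
    dist_summary <- summarize_distances(arrangements)
    log_stage(stage, sprintf(
      "%d pair(s); divergent inter-TSS distance min/median/max = %d/%g/%d bp",
      nrow(arrangements), dist_summary$min, dist_summary$median,
      dist_summary$max))

    stage <- "rep-scan"
    igrs <- collinear_igrs(annotation)
    consensus <- do.call(builtin_rep_consensus,
                         config$rep_params[intersect(names(config$rep_params),
                                                     c("max_mismatches", "max_spacer"))])
    rp_extra <- config$rep_params[setdiff(names(config$rep_params),
                                          c("max_mismatches", "max_spacer"))]
    rep_reports <- list(); rep_rows <- list()
    for (cc in conds) {
      for (i in seq_len(nrow(igrs))) {
        igr <- c(igrs$start[i], igrs$end[i])
        quick <- scan_rep(genome_subseq(genome, igr[1L], igr[2L]), consensus,
                          offset = igr[1L] - 1L)
        if (!nrow(quick)) next
        rep <- do.call(rep_transcription_report,
                       c(list(igr = igr, annotation = annotation,
                              track = cond_tracks[[cc]], genome = genome,
                              consensus = consensus,
                              min_height = config$min_height), rp_extra))
        rep_reports[[length(rep_reports) + 1L]] <- rep
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          condition = cc, igr_start = igr[1L], igr_end = igr[2L],
          rna_strand = rep$rna_strand, n_rep = nrow(rep$rep_matches),
          tss = if (is.null(rep$divergent_tss)) NA_integer_
                else rep$divergent_tss$position,
          tss_to_rep_distance = rep$tss_to_rep_distance,
          n_tn = nrow(rep$tn_tracks),
          terminator_candidate = rep$terminator_candidate,
          read_through = rep$read_through)
      }
    }
    rep_table <- if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame()
    log_stage(stage, sprintf("%d REP-containing IGR report(s)",
                             length(rep_reports)))

    stage <- "write-report"
    filter_report <- do.call(rbind, stats_rows)
    # coefficients in replicate order per condition
    filter_report$coefficient <- NA_real_
    for (cc in conds) {
      filter_report$coefficient[filter_report$condition == cc] <-
        round(groups[[cc]]$coefficients, 4L)
    }
    write_tsv(filter_report, file.path(config$outdir, "filter_stats.tsv"))
    if (!is.null(tss_calls))
      write_tsv(tss_calls, file.path(config$outdir, "tss_calls.tsv"))
    write_tsv(arrangements, file.path(config$outdir, "arrangements.tsv"))
    write_tsv(dist_summary, file.path(config$outdir, "distance_summary.tsv"))
    if (nrow(rep_table))
      write_tsv(rep_table, file.path(config$outdir, "rep_report.tsv"))

    manifest <- c(
      sprintf("divtss_version\t%s",
              as.character(utils::packageVersion("divtss"))),
      sprintf("genome\t%s\t%s", config$genome,
              unname(tools::md5sum(config$genome))),
      sprintf("annotation\t%s\t%s", config$annotation,
              unname(tools::md5sum(config$annotation))),
      sprintf("sam\t%s\t%s", config$replicates$sam,
              unname(tools::md5sum(config$replicates$sam))),
      sprintf("param\tadapter\t%s", config$adapter),
      sprintf("param\tmin_len\t%d", config$min_len),
      sprintf("param\twindow\t%d", config$window),
      sprintf("param\tmin_height\t%g", config$min_height),
      sprintf("param\ttolerance\t%d", config$tolerance),
      sprintf("param\trep_params\t%s",
              if (length(config$rep_params))
                paste(names(config$rep_params), unlist(config$rep_params),
                      sep = "=", collapse = ";") else "defaults"),
      sprintf("stage\t%s\tcompleted",
              c("filter", "pileup", "normalize", "call-tss", "classify",
                "rep-scan"))
    )
    writeLines(manifest, file.path(config$outdir, "manifest.tsv"))

    list(filter_report = filter_report, groups = groups,
         tracks = cond_tracks, tss_calls = tss_calls,
         arrangements = arrangements, distance_summary = dist_summary,
         rep_reports = rep_reports, rep_table = rep_table,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(bundle)
}
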