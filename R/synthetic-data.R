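# Deterministic desk-scale fixture generator: a genome with planted
# ncRNA/gene pairs in all three arrangements, planted REP loci with and
# without terminator elements, 5'-enriched reads concentrated at the planted
# TSSs with per-replicate depth variation, a minority of mismatching reads,
# 3' adapter contamination and sub-16-nt truncations, plus an alignment
# oracle writing SAM directly from read provenance. Everything is a pure
# function of the configuration seed.

#' Simulation configuration
#'
#' Defines the synthetic study: genome size, the planted locus plan, the
#' condition/replicate structure and the read-level noise processes. The
#' defaults describe the standard fixture: a 50 kb genome carrying twelve
#' ncRNA/gene pairs (five divergent with inter-TSS distances 7/84/84/170/290
#' bp, four codirected, three 5'-overlapping) with planted TSS shifts
#' including -26 (extension) and +60 (shortening), four REP intergenic loci
#' (read-through, terminated, TSS-less, and poly-T-without-hairpin), two
#' growth conditions with two replicates each, and unequal replicate depths
#' so normalization is exercised.
#'
#' @param genome_length genome size in bp (default 50000).
#' @param seed integer seed; together with the other fields it fully
#'   determines every output byte.
#' @param conditions character vector of condition labels.
#' @param n_replicates replicates per condition.
#' @param reads_per_replicate base read count per replicate (> 0).
#' @param depth_multipliers per-replicate depth factors (recycled to
#'   \code{n_replicates}); unequal values make the N_i differ.
#' @param mismatch_read_fraction fraction of surviving reads receiving 1-2
#'   substitutions (removed later by the perfect-match filter).
#' @param adapter 3' adapter sequence appended to a fraction of reads.
#' @param adapter_contamination_fraction fraction of reads with the adapter
#'   appended.
#' @param short_read_fraction fraction of reads truncated below 16 nt
#'   (removed by the length filter).
#' @param read_length sequenced read length in nt (default 30).
#' @param tss_jitter geometric 5'-end jitter probability; 0 (default) plants
#'   every read exactly at its TSS.
#' @param loci optional locus plan (advanced); default
#'   [default_locus_plan()].
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(genome_length = 50000L, seed = 1L,
                              conditions = c("exp", "stat"),
                              n_replicates = 2L,
                              reads_per_replicate = 5000L,
                              depth_multipliers = c(1.0, 1.6),
                              mismatch_read_fraction = 0,
                              adapter = "AGATCGGAAGA",
                              adapter_contamination_fraction = 0.1,
                              short_read_fraction = 0.05,
                              read_length = 30L,
                              tss_jitter = 0,
                              loci = NULL) {
  fr <- c(mismatch_read_fraction, adapter_contamination_fraction,
          short_read_fraction, tss_jitter)
  stopifnot(all(fr >= 0 & fr <= 1))
  stopifnot(genome_length >= 1000L, read_length >= 16L)
  cfg <- structure(list(
    genome_length = as.integer(genome_length), seed = as.integer(seed),
    conditions = conditions, n_replicates = as.integer(n_replicates),
    reads_per_replicate = as.integer(reads_per_replicate),
    depth_multipliers = rep_len(depth_multipliers, n_replicates),
    mismatch_read_fraction = mismatch_read_fraction,
    adapter = toupper(adapter),
    adapter_contamination_fraction = adapter_contamination_fraction,
    short_read_fraction = short_read_fraction,
    read_length = as.integer(read_length), tss_jitter = tss_jitter,
    loci = loci
  ), class = "simulation_config")
  if (is.null(cfg$loci)) cfg$loci <- default_locus_plan(cfg)
  cfg
}

#' Default planted-locus plan
#'
#' Lays the standard fixture out in 3 kb blocks: twelve ncRNA/gene pairs
#' covering the three arrangements with chosen inter-TSS distances and TSS
#' shifts, and four REP intergenic loci exercising the terminator logic.
#' The stretches between a planted TSS and its REP element are overwritten
#' with a fixed A-free periodic fill so that poly-T tracks and hairpins
#' occur exactly where planted.
#'
#' @param config a partially built [simulation_config()] (only
#'   \code{genome_length} and \code{conditions} are consulted).
#' @return a locus plan: list with \code{feats}, \code{signals},
#'   \code{fills}, \code{inserts}, \code{pair_truth}, \code{rep_truth}.
#' @export
default_locus_plan <- function(config) {
  conds <- config$conditions
  blocks <- list(
    list(kind = "div", d = 7L, off = 0L),
    list(kind = "codir", off = 0L),
    list(kind = "ovl", off = 60L),
    list(kind = "div", d = 84L, off = -26L),
    list(kind = "codir", off = 43L),
    list(kind = "ovl", off = 0L),
    list(kind = "div", d = 84L, off = 0L),
    list(kind = "codir", off = 0L),
    list(kind = "rep", rep_type = "readthrough"),
    list(kind = "div", d = 290L, off = 0L),
    list(kind = "codir", off = -65L),
    list(kind = "ovl", off = 29L),
    list(kind = "div", d = 170L, off = -27L),
    list(kind = "rep", rep_type = "terminated"),
    list(kind = "rep", rep_type = "no_tss"),
    list(kind = "rep", rep_type = "tn_no_hairpin")
  )
  block_size <- 3000L
  stopifnot(length(blocks) * block_size <= config$genome_length)
  feats <- list(); signals <- list(); fills <- list(); inserts <- list()
  pair_truth <- list(); rep_truth <- list()
  rep35 <- "TGCCGGATGCGGCGTAAACGCCTTATCCGGCCTAC"
  wcols <- function(w) stats::setNames(as.list(rep(w, length(conds))),
                                       paste0("w_", conds))
  sig <- function(name, strand, pos, w) {
    c(list(name = name, strand = strand, pos = as.integer(pos)), wcols(w))
  }
  for (i in seq_along(blocks)) {
    b <- (i - 1L) * block_size
    bl <- blocks[[i]]
    gname <- sprintf("gene%02d", i); nname <- sprintf("ncr%02d", i)
    if (bl$kind == "div") {
      ann5 <- b + 1200L
      feats[[length(feats) + 1L]] <- data.frame(
        name = c(gname, nname), kind = c("protein_coding", "ncRNA"),
        start = c(ann5 + bl$d, b + 1070L), end = c(ann5 + bl$d + 900L, ann5),
        strand = c("+", "-"), mrna_tss = NA_integer_)
      true_tss <- ann5 - bl$off
      signals[[length(signals) + 1L]] <- sig(nname, "-", true_tss, 10)
      signals[[length(signals) + 1L]] <- sig(gname, "+", ann5 + bl$d, 3)
      pair_truth[[length(pair_truth) + 1L]] <- data.frame(
        ncrna = nname, neighbor = gname, arrangement = "divergent",
        bona_fide = TRUE, antisense_overlap = 0L,
        inter_tss_distance = bl$d, annotated_5p = ann5,
        true_tss = true_tss, tss_offset = bl$off)
    } else if (bl$kind == "codir") {
      ann5 <- b + 1600L
      feats[[length(feats) + 1L]] <- data.frame(
        name = c(gname, nname), kind = c("protein_coding", "ncRNA"),
        start = c(b + 400L, ann5), end = c(b + 1300L, b + 1750L),
        strand = "+", mrna_tss = NA_integer_)
      true_tss <- ann5 + bl$off
      signals[[length(signals) + 1L]] <- sig(nname, "+", true_tss, 10)
      signals[[length(signals) + 1L]] <- sig(gname, "+", b + 400L, 3)
      pair_truth[[length(pair_truth) + 1L]] <- data.frame(
        ncrna = nname, neighbor = gname, arrangement = "codirected",
        bona_fide = TRUE, antisense_overlap = 0L,
        inter_tss_distance = NA_integer_, annotated_5p = ann5,
        true_tss = true_tss, tss_offset = bl$off)
    } else if (bl$kind == "ovl") {
      ann5 <- b + 1500L
      mtss <- b + 1460L
      feats[[length(feats) + 1L]] <- data.frame(
        name = c(gname, nname), kind = c("protein_coding", "ncRNA"),
        start = c(b + 1600L, b + 1380L), end = c(b + 2500L, ann5),
        strand = c("+", "-"), mrna_tss = c(mtss, NA_integer_))
      true_tss <- ann5 - bl$off
      signals[[length(signals) + 1L]] <- sig(nname, "-", true_tss, 10)
      signals[[length(signals) + 1L]] <- sig(gname, "+", mtss, 3)
      pair_truth[[length(pair_truth) + 1L]] <- data.frame(
        ncrna = nname, neighbor = gname, arrangement = "overlapping_5prime",
        bona_fide = FALSE, antisense_overlap = 41L,
        inter_tss_distance = NA_integer_, annotated_5p = ann5,
        true_tss = true_tss, tss_offset = bl$off)
    } else { # rep locus between two collinear plus-strand genes
      feats[[length(feats) + 1L]] <- data.frame(
        name = c(sprintf("gene%02dL", i), sprintf("gene%02dR", i)),
        kind = "protein_coding",
        start = c(b + 200L, b + 1900L), end = c(b + 1100L, b + 2800L),
        strand = "+", mrna_tss = NA_integer_)
      igr <- c(b + 1101L, b + 1899L)
      t <- b + 1700L                    # divergent (minus-strand) TSS
      rep_end <- b + 1600L              # REP boundary proximal to the TSS
      rep_start <- rep_end - nchar(rep35) + 1L
      has_tss <- bl$rep_type != "no_tss"
      inserts[[length(inserts) + 1L]] <- data.frame(start = rep_start, seq = rep35)
      # A-free fill between REP and TSS: no spurious poly-T on the
      # minus-strand transcript, no spurious hairpin
      fills[[length(fills) + 1L]] <- data.frame(start = rep_end + 1L, end = t - 1L)
      has_tn <- bl$rep_type %in% c("terminated", "tn_no_hairpin")
      has_hairpin <- bl$rep_type == "terminated"
      if (has_tn) {
        inserts[[length(inserts) + 1L]] <- data.frame(start = b + 1640L,
                                                      seq = "AAAAAA")
      }
      if (has_hairpin) {
        inserts[[length(inserts) + 1L]] <- data.frame(start = b + 1646L,
                                                      seq = "GGCGCCACGCGCC")
      }
      if (has_tss) {
        signals[[length(signals) + 1L]] <- sig(sprintf("repTSS%02d", i), "-", t, 10)
      }
      rep_truth[[length(rep_truth) + 1L]] <- data.frame(
        igr_start = igr[1L], igr_end = igr[2L], rna_strand = "-",
        rep_start = rep_start, rep_end = rep_end,
        has_tss = has_tss, tss_pos = if (has_tss) t else NA_integer_,
        tss_to_rep_distance = if (has_tss) t - rep_end else NA_integer_,
        has_tn = has_tn, has_hairpin = has_hairpin,
        read_through = has_tss && !has_hairpin)
    }
  }
  list(
    feats = do.call(rbind, feats),
    signals = do.call(rbind, lapply(signals, as.data.frame)),
    fills = do.call(rbind, fills),
    inserts = do.call(rbind, inserts),
    pair_truth = do.call(rbind, pair_truth),
    rep_truth = do.call(rbind, rep_truth)
  )
}

#' Generate the synthetic genome and annotation
#'
#' Draws a uniform random background sequence, overwrites the planned fill
#' regions with an A-free periodic sequence, writes the planted REP / poly-T
#' / hairpin inserts, and validates that no two planted features overlap on
#' one strand. Deterministic given \code{config$seed}.
#'
#' @param config a [simulation_config()].
#' @return list with \code{genome} (a [genome_seq()]), \code{annotation}
#'   (feature table) and \code{truth} (list with \code{pairs},
#'   \code{rep_loci}, \code{signals}, \code{replicates}).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  chars <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)
  plan <- config$loci
  if (!is.null(plan$fills)) {
    fill <- c("C", "G", "T")
    for (i in seq_len(nrow(plan$fills))) {
      ix <- plan$fills$start[i]:plan$fills$end[i]
      chars[ix] <- fill[((ix - plan$fills$start[i]) %% 3L) + 1L]
    }
  }
  if (!is.null(plan$inserts)) {
    for (i in seq_len(nrow(plan$inserts))) {
      s <- strsplit(plan$inserts$seq[i], "")[[1L]]
      chars[plan$inserts$start[i] + seq_along(s) - 1L] <- s
    }
  }
  genome <- genome_seq("synthetic_chr", paste(chars, collapse = ""))
  ann <- validate_features(plan$feats, config$genome_length)
  # planted same-strand features must not overlap
  for (s in c("+", "-")) {
    f <- ann[ann$strand == s, , drop = FALSE]
    if (nrow(f) > 1L) {
      f <- f[order(f$start), , drop = FALSE]
      if (any(f$start[-1L] <= f$end[-nrow(f)]))
        stop("overlapping planted features on the same strand")
    }
  }
  reps <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = config$conditions,
                      stringsAsFactors = FALSE)[, 2:1]
  reps$intended_n <- as.integer(round(config$reads_per_replicate *
                                      config$depth_multipliers[reps$replicate]))
  list(
    genome = genome, annotation = ann,
    truth = list(pairs = plan$pair_truth, rep_loci = plan$rep_truth,
                 signals = plan$signals, replicates = reps)
  )
}

#' Generate 5'-enriched reads for every replicate
#'
#' Read 5' ends are drawn multinomially over the planted TSS signals with
#' per-condition weights; each read copies the transcribed-strand genome
#' sequence from its TSS. A seeded fraction of reads then receives 1-2
#' substitutions (to be removed by perfect-match filtering), a fraction gets
#' the 3' adapter appended, and a fraction is truncated below 16 nt.
#' Replicate depths follow \code{depth_multipliers}, so the intended N_i
#' differ between replicates.
#'
#' @param config a [simulation_config()].
#' @param sim output of [generate_genome()] for the same config.
#' @return a \code{data.frame} with one row per read: \code{id},
#'   \code{condition}, \code{replicate}, \code{seq}, \code{qual} (the
#'   sequenced read, noise applied), plus provenance columns
#'   \code{origin_pos} (planted 5'-end genome position), \code{strand},
#'   \code{aligned_seq} (post-trim read), \code{n_mismatch},
#'   \code{is_short}, \code{has_adapter}, \code{signal}.
#' @export
generate_reads <- function(config, sim) {
  if (config$reads_per_replicate == 0L) stop("reads_per_replicate must be > 0")
  set.seed(config$seed + 1L)
  genome <- sim$genome
  signals <- sim$truth$signals
  L <- config$read_length
  out <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    w <- signals[[paste0("w_", cond)]]
    for (r in seq_len(config$n_replicates)) {
      n <- as.integer(round(config$reads_per_replicate *
                            config$depth_multipliers[r]))
      pick <- sample.int(nrow(signals), n, replace = TRUE, prob = w)
      pos <- signals$pos[pick]
      strand <- signals$strand[pick]
      if (config$tss_jitter > 0) {
        jit <- stats::rgeom(n, prob = 1 - config$tss_jitter)
        pos <- ifelse(strand == "+", pos + jit, pos - jit)
      }
      seqs <- character(n)
      plus <- strand == "+"
      for (i in which(plus)) seqs[i] <- substr(genome$seq, pos[i], pos[i] + L - 1L)
      for (i in which(!plus)) {
        seqs[i] <- reverse_complement(substr(genome$seq, pos[i] - L + 1L, pos[i]))
      }
      is_short <- stats::runif(n) < config$short_read_fraction
      n_mm <- integer(n)
      do_mm <- !is_short & stats::runif(n) < config$mismatch_read_fraction
      for (i in which(do_mm)) {
        k <- 1L + (stats::runif(1) < 0.3)
        at <- sample.int(L, k)
        s <- strsplit(seqs[i], "")[[1L]]
        for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
        n_mm[i] <- k
      }
      aligned <- seqs
      has_ad <- !is_short & stats::runif(n) < config$adapter_contamination_fraction
      seqs[has_ad] <- paste0(seqs[has_ad], config$adapter)
      short_len <- 8L + sample.int(8L, n, replace = TRUE) - 1L   # 8..15 nt
      seqs[is_short] <- substr(seqs[is_short], 1L, short_len[is_short])
      aligned[is_short] <- NA_character_
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("r_%s_%d_%06d", cond, r, seq_len(n)),
        condition = cond, replicate = r,
        seq = seqs, qual = strrep("I", nchar(seqs)),
        origin_pos = as.integer(pos), strand = strand,
        aligned_seq = aligned, n_mismatch = n_mm,
        is_short = is_short, has_adapter = has_ad,
        signal = signals$name[pick], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write an alignment oracle SAM from read provenance
#'
#' Emits a valid SAM for the reads that survive trimming and the length
#' filter, with the correct position, strand flag and CIGAR for each read's
#' planted origin and with NM/XM tags equal to the planted substitution
#' count -- so tests need no external aligner.
#'
#' @param reads read table from [generate_reads()], restricted to one
#'   replicate (or any subset).
#' @param genome the [genome_seq()] the reads came from.
#' @param path output SAM file.
#' @return \code{path}, invisibly.
#' @export
generate_alignments <- function(reads, genome, path) {
  if (is.null(reads$aligned_seq)) stop("reads lack provenance columns")
  keep <- !reads$is_short
  r <- reads[keep, , drop = FALSE]
  L <- nchar(r$aligned_seq)
  minus <- r$strand == "-"
  pos <- ifelse(minus, r$origin_pos - L + 1L, r$origin_pos)
  flag <- ifelse(minus, 16L, 0L)
  seq_fwd <- r$aligned_seq
  if (any(minus)) seq_fwd[minus] <- reverse_complement(r$aligned_seq[minus])
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome$length),
    sprintf("%s\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t%s\tXM:i:%d\tNM:i:%d",
            r$id, flag, genome$id, as.integer(pos), L, seq_fwd,
            strrep("I", L), r$n_mismatch, r$n_mismatch)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete dataset, optionally writing it to disk
#'
#' Runs [generate_genome()], [generate_reads()] and [generate_alignments()]
#' and, when \code{outdir} is given, writes genome FASTA, annotation GFF3,
#' per-replicate FASTQ and SAM, and truth-table TSVs.
#'
#' @param config a [simulation_config()].
#' @param outdir optional output directory (created if missing).
#' @return list with \code{genome}, \code{annotation}, \code{truth},
#'   \code{reads}, and \code{sam_paths}/\code{fastq_paths} when written.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  sim <- generate_genome(config)
  reads <- generate_reads(config, sim)
  res <- c(sim, list(reads = reads))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
    write_annotation_gff3(sim$annotation, file.path(outdir, "annotation.gff3"),
                          sim$genome$id)
    fq <- character(0); sm <- character(0)
    for (cond in config$conditions) {
      for (r in seq_len(config$n_replicates)) {
        sub <- reads[reads$condition == cond & reads$replicate == r, , drop = FALSE]
        tag <- sprintf("%s_rep%d", cond, r)
        f <- file.path(outdir, paste0(tag, ".fastq"))
        write_fastq(sub[, c("id", "seq", "qual")], f)
        s <- file.path(outdir, paste0(tag, ".sam"))
        generate_alignments(sub, sim$genome, s)
        fq <- c(fq, f); sm <- c(sm, s)
      }
    }
    write_tsv(sim$truth$pairs, file.path(outdir, "truth_pairs.tsv"))
    write_tsv(sim$truth$rep_loci, file.path(outdir, "truth_rep_loci.tsv"))
    write_tsv(sim$truth$replicates, file.path(outdir, "truth_replicates.tsv"))
    res$fastq_paths <- fq
    res$sam_paths <- sm
  }
  res
}
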