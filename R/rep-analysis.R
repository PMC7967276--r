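# REP (repetitive extragenic palindromic) element screen: degenerate
# consensus scanning of intergenic regions, divergent-TSS evidence, poly-T
# tracks and candidate intrinsic-terminator hairpins between the TSS and the
# REP, and TSS-to-REP distances.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  # an N in the genome matches nothing unless the pattern code is N
  N = c("A", "C", "G", "T", "N")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' REP consensus pattern
#'
#' A degenerate (IUPAC) DNA pattern with a mismatch budget. Pattern
#' ambiguity codes match their base sets in the genome; a genome \code{N}
#' matches only a pattern \code{N}.
#'
#' @param name pattern label.
#' @param pattern IUPAC DNA string, length >= 10.
#' @param max_mismatches allowed mismatches per hit (default 3).
#' @return an object of class \code{rep_consensus}.
#' @export
rep_consensus <- function(name, pattern, max_mismatches = 3L) {
  pattern <- toupper(pattern)
  stopifnot(nchar(pattern) >= 10L)
  bad <- regexpr(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), pattern)
  if (bad > 0L) stop("non-IUPAC code at pattern position ", bad)
  structure(list(name = name, pattern = pattern,
                 max_mismatches = as.integer(max_mismatches)),
            class = "rep_consensus")
}

iupac_reverse_complement <- function(pattern) {
  paste(rev(IUPAC_COMPLEMENT[strsplit(pattern, "")[[1L]]]), collapse = "")
}

#' Built-in REP consensus set
#'
#' Three encodings of the enterobacterial REP motif: the 35/36-nt literal
#' variants reported for the *E. coli* genome, and the symmetric degenerate
#' consensus \code{GCKGATGGCGRGCK...RCGYCTTATCMGGCCTAC} whose unspecified
#' centre is modelled as a bounded spacer of 0 to \code{max_spacer} \code{N}
#' positions (one concrete pattern per spacer width).
#'
#' @param max_mismatches mismatch budget applied to every pattern.
#' @param max_spacer largest spacer width for the symmetric consensus
#'   (default 3, giving the canonical 35-bp total length at the maximum).
#' @return a list of [rep_consensus()] objects.
#' @export
builtin_rep_consensus <- function(max_mismatches = 3L, max_spacer = 3L) {
  half1 <- "GCKGATGGCGRGCK"
  half2 <- "RCGYCTTATCMGGCCTAC"
  sym <- lapply(0:max_spacer, function(k) {
    rep_consensus(sprintf("REP_sym_s%d", k),
                  paste0(half1, strrep("N", k), half2), max_mismatches)
  })
  c(
    list(
      rep_consensus("REP_35", "TGCCGGATGCGGCGTAAACGCCTTATCCGGCCTAC", max_mismatches),
      rep_consensus("REP_36", "GCCGGATGCGGCGTGAACGCCTTATCCGGCCTACGA", max_mismatches)
    ),
    sym
  )
}

#' Scan a sequence for REP consensus matches
#'
#' Finds all placements, on both strands, where the degenerate pattern
#' matches with at most \code{max_mismatches} mismatches under IUPAC
#' compatibility. A minus-strand match is a placement of the
#' reverse-complemented pattern on the given (plus-strand) sequence and is
#' reported in the same coordinates.
#'
#' @param seq plus-strand DNA string of the region to scan.
#' @param consensus a [rep_consensus()] or list of them.
#' @param max_mismatches override of the consensus mismatch budget.
#' @param offset added to reported coordinates (use \code{start - 1} when
#'   \code{seq} was cut from a genome).
#' @return \code{data.frame} with \code{start}, \code{end}, \code{strand},
#'   \code{mismatches}, \code{consensus_name}; zero rows when nothing
#'   matches.
#' @export
scan_rep <- function(seq, consensus, max_mismatches = NULL, offset = 0L) {
  if (inherits(consensus, "rep_consensus")) consensus <- list(consensus)
  seq <- toupper(seq)
  check_dna(seq)
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  one <- function(pattern, budget, strand, name) {
    L <- nchar(pattern)
    if (n < L) return(NULL)
    pat <- strsplit(pattern, "")[[1L]]
    nw <- n - L + 1L
    mm <- integer(nw)
    for (j in seq_len(L)) {
      mm <- mm + !(chars[j:(nw + j - 1L)] %in% IUPAC_SETS[[pat[j]]])
    }
    hit <- which(mm <= budget)
    if (!length(hit)) return(NULL)
    data.frame(start = hit + offset, end = hit + L - 1L + offset,
               strand = strand, mismatches = mm[hit],
               consensus_name = name, stringsAsFactors = FALSE)
  }
  out <- lapply(consensus, function(cs) {
    budget <- if (is.null(max_mismatches)) cs$max_mismatches
              else as.integer(max_mismatches)
    rbind(one(cs$pattern, budget, "+", cs$name),
          one(iupac_reverse_complement(cs$pattern), budget, "-", cs$name))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      consensus_name = character(0), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand, out$consensus_name), , drop = FALSE]
}

#' Find maximal poly-T tracks on the transcribed strand
#'
#' Maximal runs of at least \code{min_run} consecutive T on the transcribed
#' strand. For minus-strand transcription the T runs appear as A runs on the
#' supplied plus-strand sequence; coordinates are always reported on the
#' plus-strand (genome) axis. Returned runs are maximal and pairwise
#' non-overlapping by construction.
#'
#' @param seq plus-strand DNA string of the region.
#' @param min_run minimum run length (default 4).
#' @param strand transcription strand, \code{"+"} or \code{"-"}.
#' @param offset added to reported coordinates.
#' @return \code{data.frame} with \code{start}, \code{end}, \code{length}.
#' @export
find_tn_tracks <- function(seq, min_run = 4L, strand = "+", offset = 0L) {
  stopifnot(min_run >= 1L)
  base <- if (strand == "+") "T" else "A"
  m <- gregexpr(sprintf("%s{%d,}", base, min_run), toupper(seq))[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) + offset,
             end = as.integer(m) + len - 1L + offset,
             length = as.integer(len))
}

#' Is a poly-T track preceded by a hairpin?
#'
#' Searches the \code{search_window} bases immediately upstream (in the
#' transcription direction) of a T track for two reverse-complementary
#' stretches of length >= \code{min_stem} separated by a loop of
#' \code{min_loop} to \code{max_loop} bases -- the self-complementary stem
#' required for a candidate intrinsic (rho-independent) terminator.
#'
#' @param genome a [genome_seq()].
#' @param t_track length-2 vector \code{c(start, end)} of the T track
#'   (plus-strand coordinates).
#' @param strand transcription strand.
#' @param min_stem minimum stem length (default 4).
#' @param max_loop maximum loop length (default 8).
#' @param search_window window size upstream of the track (default 20).
#' @param min_loop minimum loop length (default 3, the physical minimum for
#'   a hairpin turn).
#' @return logical: TRUE when a qualifying stem-loop exists.
#' @export
hairpin_upstream <- function(genome, t_track, strand = "+", min_stem = 4L,
                             max_loop = 8L, search_window = 20L, min_loop = 3L) {
  if (strand == "+") {
    ws <- max(1L, t_track[1L] - search_window); we <- t_track[1L] - 1L
  } else {
    ws <- t_track[2L] + 1L; we <- min(genome$length, t_track[2L] + search_window)
  }
  if (we < ws) return(FALSE)
  w <- genome_subseq(genome, ws, we)  # strand-symmetric test; plus-strand seq
  has_stem_loop(w, min_stem, min_loop, max_loop)
}

# existence of a stem >= min_stem with loop in [min_loop, max_loop] reduces
# to existence of a stem of exactly min_stem (trim a longer stem from the
# outside; the loop is unchanged)
has_stem_loop <- function(seq, min_stem, min_loop, max_loop) {
  n <- nchar(seq)
  m <- as.integer(min_stem)
  if (n < 2L * m + min_loop) return(FALSE)
  chars <- strsplit(toupper(seq), "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  for (a in seq_len(n - 2L * m - min_loop + 1L)) {
    arm1 <- chars[a:(a + m - 1L)]
    for (l in min_loop:max_loop) {
      b <- a + m + l
      if (b + m - 1L > n) break
      arm2 <- chars[b:(b + m - 1L)]
      if (all(rev(arm2) == comp[arm1])) return(TRUE)
    }
  }
  FALSE
}

#' Screen one intergenic region for divergent REP transcription
#'
#' For an intergenic region (IGR) between two collinear protein-coding
#' genes: scans the IGR for REP matches, looks for a divergent TSS (a 5'-end
#' peak on the strand opposite to the flanking genes), reports the
#' TSS-to-REP distance measured in the transcription direction from the TSS
#' to the nearest REP boundary at or downstream of it, finds poly-T tracks
#' on the transcribed strand between TSS and REP, flags tracks preceded by a
#' hairpin, and gives the read-through verdict (no hairpin+T-track
#' terminator candidate intervening).
#'
#' @param igr length-2 vector \code{c(start, end)} of the IGR.
#' @param annotation feature table; the IGR must be flanked by two
#'   protein-coding genes (one ending before it, one starting after it) on
#'   one strand.
#' @param track averaged normalized [five_prime_track()].
#' @param genome a [genome_seq()].
#' @param consensus REP consensus set (default [builtin_rep_consensus()]).
#' @param min_height TSS peak threshold (default 5 normalized counts).
#' @param min_run,min_stem,max_loop,search_window,min_loop terminator
#'   heuristics, see [find_tn_tracks()] and [hairpin_upstream()].
#' @param max_mismatches optional override of the consensus mismatch budget.
#' @return an object of class \code{rep_locus_report}: a list with
#'   \code{igr}, \code{rna_strand}, \code{rep_matches}, \code{divergent_tss}
#'   (1-row data frame or NULL), \code{tss_to_rep_distance},
#'   \code{tn_tracks} (with a \code{hairpin} column),
#'   \code{terminator_candidate} and \code{read_through}.
#' @export
rep_transcription_report <- function(igr, annotation, track, genome,
                                     consensus = builtin_rep_consensus(),
                                     min_height = 5, min_run = 4L,
                                     min_stem = 4L, max_loop = 8L,
                                     search_window = 20L, min_loop = 3L,
                                     max_mismatches = NULL) {
  genes <- annotation[annotation$kind == "protein_coding", , drop = FALSE]
  left <- genes[genes$end < igr[1L], , drop = FALSE]
  right <- genes[genes$start > igr[2L], , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L)
    stop("IGR is not flanked by two annotated genes")
  left <- left[which.max(left$end), , drop = FALSE]
  right <- right[which.min(right$start), , drop = FALSE]
  gene_strand <- right$strand
  # downstream flanking gene in its own transcription direction
  downstream_gene <- if (gene_strand == "+") right else left
  rna_strand <- if (downstream_gene$strand == "+") "-" else "+"

  seq <- genome_subseq(genome, igr[1L], igr[2L])
  reps <- scan_rep(seq, consensus, max_mismatches = max_mismatches,
                   offset = igr[1L] - 1L)
  # collapse overlapping hits from different consensus encodings
  reps <- collapse_rep_matches(reps)

  peaks <- peaks_in_interval(track, rna_strand, igr[1L], igr[2L], min_height)
  tss <- if (nrow(peaks)) peaks[which.max(peaks$height), , drop = FALSE] else NULL

  dist <- NA_integer_
  tn <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                   hairpin = logical(0))
  terminator <- FALSE
  if (!is.null(tss) && nrow(reps)) {
    t <- tss$position
    if (rna_strand == "+") {
      down <- reps[reps$start >= t, , drop = FALSE]
      if (nrow(down)) {
        rep5 <- min(down$start)
        dist <- rep5 - t
        span <- c(t + 1L, rep5 - 1L)
      }
    } else {
      down <- reps[reps$end <= t, , drop = FALSE]
      if (nrow(down)) {
        rep5 <- max(down$end)
        dist <- t - rep5
        span <- c(rep5 + 1L, t - 1L)
      }
    }
    if (!is.na(dist) && dist > 1L && span[1L] <= span[2L]) {
      tn0 <- find_tn_tracks(genome_subseq(genome, span[1L], span[2L]),
                            min_run = min_run, strand = rna_strand,
                            offset = span[1L] - 1L)
      if (nrow(tn0)) {
        tn0$hairpin <- vapply(seq_len(nrow(tn0)), function(i) {
          hairpin_upstream(genome, c(tn0$start[i], tn0$end[i]),
                           strand = rna_strand, min_stem = min_stem,
                           max_loop = max_loop, search_window = search_window,
                           min_loop = min_loop)
        }, logical(1L))
        tn <- tn0
        terminator <- any(tn$hairpin)
      }
    }
  }
  structure(list(
    igr = as.integer(igr), rna_strand = rna_strand, rep_matches = reps,
    divergent_tss = tss, tss_to_rep_distance = dist, tn_tracks = tn,
    terminator_candidate = terminator,
    read_through = !is.null(tss) && nrow(reps) > 0L && !is.na(dist) && !terminator
  ), class = "rep_locus_report")
}

# keep, per strand, the best-scoring hit among mutually overlapping hits
collapse_rep_matches <- function(reps) {
  if (nrow(reps) < 2L) return(reps)
  keep <- logical(nrow(reps))
  for (s in unique(reps$strand)) {
    ix <- which(reps$strand == s)
    sub <- reps[ix, , drop = FALSE]
    o <- order(sub$mismatches, sub$start)
    taken <- integer(0)
    for (i in o) {
      if (!any(sub$start[i] <= sub$end[taken] &
               sub$end[i] >= sub$start[taken])) {
        taken <- c(taken, i)
      }
    }
    keep[ix[taken]] <- TRUE
  }
  out <- reps[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# local maxima above min_height on one strand inside [start, end]
peaks_in_interval <- function(track, strand, start, end, min_height) {
  v <- if (strand == "+") track$plus else track$minus
  pos <- as.integer(names(v))
  inw <- pos >= start & pos <= end
  pos <- pos[inw]; val <- unname(v[inw])
  if (!length(pos)) {
    return(data.frame(position = integer(0), height = numeric(0)))
  }
  o <- order(pos); pos <- pos[o]; val <- val[o]
  left <- track_value(track, strand, pos - 1L)
  right <- track_value(track, strand, pos + 1L)
  ok <- val >= min_height & val >= left & val >= right
  data.frame(position = pos[ok], height = val[ok])
}

#' @export
print.rep_locus_report <- function(x, ...) {
  cat(sprintf("<rep_locus_report> IGR %d..%d (RNA strand %s): %d REP match(es), TSS %s, dist %s, terminator %s, read-through %s\n",
              x$igr[1L], x$igr[2L], x$rna_strand, nrow(x$rep_matches),
              if (is.null(x$divergent_tss)) "absent"
              else as.character(x$divergent_tss$position),
              as.character(x$tss_to_rep_distance),
              x$terminator_candidate, x$read_through))
  invisible(x)
}
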