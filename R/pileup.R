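# Strand-specific 5'-end pileups and replicate depth normalization.
#
# The per-replicate scaling is the ratio c_i = N_av / N_i, where N_i is the
# replicate's perfect-match read count and N_av the mean over the replicates
# of one growth-condition group; the condition track is the per-position mean
# of the scaled replicate counts.

#' Reference span of a CIGAR string
#'
#' Number of reference bases consumed by an alignment: the summed lengths of
#' the M, D, N, = and X operations. Soft/hard clips and insertions consume no
#' reference.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of spans.
#' @export
cigar_reference_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
      stop("malformed CIGAR: ", cg)
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substring(ops, nchar(ops))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L), USE.NAMES = FALSE)
}

#' 5'-end position and strand of alignments
#'
#' For a plus-strand alignment the 5' end is the leftmost reference position;
#' for a minus-strand alignment it is \code{pos + reference_span - 1}, the
#' rightmost aligned base. Soft-clipped bases do not shift the counted
#' position (the aligned end is used); with perfect-match filtering upstream,
#' clipping is rare anyway.
#'
#' @param records an alignment table (mapped records).
#' @return a \code{data.frame} with columns \code{pos} (1-based 5'-end
#'   position) and \code{strand}.
#' @export
five_prime_position <- function(records) {
  span <- cigar_reference_span(records$cigar)
  if (any(span < 1L)) stop("CIGAR with zero reference span")
  minus <- is_minus(records$flag)
  data.frame(
    pos = as.integer(ifelse(minus, records$pos + span - 1L, records$pos)),
    strand = ifelse(minus, "-", "+"),
    stringsAsFactors = FALSE
  )
}

#' Five-prime track container
#'
#' A sparse per-strand map of genome position to 5'-end count: raw integer
#' counts for a single replicate, or normalized/averaged float counts for a
#' condition. Positions carry their counts as named numeric vectors keyed by
#' position.
#'
#' @param ref_id reference sequence identifier.
#' @param plus,minus named numeric vectors (names = 1-based positions,
#'   values >= 0).
#' @param total_perfect_reads the replicate's perfect-match read count N_i
#'   (NA for derived tracks).
#' @return an object of class \code{five_prime_track}.
#' @export
five_prime_track <- function(ref_id, plus = numeric(0), minus = numeric(0),
                             total_perfect_reads = NA_integer_) {
  stopifnot(all(plus >= 0), all(minus >= 0))
  structure(
    list(ref_id = ref_id, plus = plus, minus = minus,
         total_perfect_reads = total_perfect_reads),
    class = "five_prime_track"
  )
}

#' @export
print.five_prime_track <- function(x, ...) {
  cat(sprintf("<five_prime_track> %s: %d (+) / %d (-) positions; total N = %s\n",
              x$ref_id, length(x$plus), length(x$minus),
              as.character(x$total_perfect_reads)))
  invisible(x)
}

#' Sparse counts of one strand as a data frame
#'
#' @param track a [five_prime_track()].
#' @param strand \code{"+"} or \code{"-"}.
#' @return \code{data.frame} with \code{pos} (sorted) and \code{count}.
#' @export
track_counts <- function(track, strand) {
  v <- if (strand == "+") track$plus else track$minus
  pos <- as.integer(names(v))
  o <- order(pos)
  data.frame(pos = pos[o], count = unname(v)[o])
}

#' Value of a track at given positions
#'
#' @param track a [five_prime_track()].
#' @param strand \code{"+"} or \code{"-"}.
#' @param pos integer positions.
#' @return numeric counts (0 where absent).
#' @export
track_value <- function(track, strand, pos) {
  v <- if (strand == "+") track$plus else track$minus
  out <- unname(v[as.character(pos)])
  out[is.na(out)] <- 0
  out
}

#' Build a raw 5'-end track from filtered alignments
#'
#' Distributes the 5' ends of (already perfect-match-filtered) alignments
#' along both strands. The sum of all counts equals the number of records.
#'
#' @param records an alignment table; all rows must share one reference.
#' @param ref_id expected reference id; records on any other reference are an
#'   error.
#' @param genome_length optional length used to validate positions.
#' @return a raw [five_prime_track()] with
#'   \code{total_perfect_reads = nrow(records)}.
#' @export
build_track <- function(records, ref_id = NULL, genome_length = NULL) {
  if (nrow(records) == 0L) {
    return(five_prime_track(ref_id %||% NA_character_, total_perfect_reads = 0L))
  }
  refs <- unique(records$rname)
  if (is.null(ref_id)) ref_id <- refs[1L]
  if (!all(refs == ref_id))
    stop("alignment on unknown reference: ", paste(setdiff(refs, ref_id), collapse = ","))
  fp <- five_prime_position(records)
  if (!is.null(genome_length) && any(fp$pos < 1L | fp$pos > genome_length))
    stop("5'-end position outside the genome")
  tab <- function(p) {
    if (!length(p)) return(numeric(0))
    t <- table(p)
    stats::setNames(as.numeric(t), names(t))
  }
  five_prime_track(
    ref_id,
    plus = tab(fp$pos[fp$strand == "+"]),
    minus = tab(fp$pos[fp$strand == "-"]),
    total_perfect_reads = nrow(records)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-replicate normalization coefficients N_av / N_i
#'
#' The scaling factor for each replicate of a condition group: the mean
#' perfect-match read count over the group's replicates divided by the
#' replicate's own count. Computed at full precision; round only in reports.
#'
#' @param n_reads numeric vector of perfect-match read counts N_i (all > 0).
#' @return numeric vector of coefficients c_i = mean(n_reads) / n_reads.
#' @export
normalization_coefficients <- function(n_reads) {
  stopifnot(length(n_reads) >= 1L)
  if (any(n_reads == 0)) stop("N_i == 0: empty replicate cannot be normalized")
  mean(n_reads) / n_reads
}

#' Group replicate tracks by growth condition
#'
#' The "series of experiments" over which N_av is taken is the condition
#' group: the biological replicates sharing one growth condition. The group
#' stores N_av and the per-replicate coefficients.
#'
#' @param label condition label, e.g. \code{"LB 0.4"}.
#' @param replicates list of raw [five_prime_track()]s with
#'   \code{total_perfect_reads} set.
#' @return an object of class \code{condition_group}.
#' @export
condition_group <- function(label, replicates) {
  stopifnot(length(replicates) >= 1L)
  refs <- unique(vapply(replicates, function(t) t$ref_id, character(1L)))
  if (length(refs) != 1L) stop("replicate tracks have mismatched ref_id")
  n <- vapply(replicates, function(t) as.numeric(t$total_perfect_reads), numeric(1L))
  if (anyNA(n)) stop("replicate without total_perfect_reads")
  structure(
    list(label = label, replicates = replicates,
         n_av = mean(n), n_reads = n,
         coefficients = normalization_coefficients(n)),
    class = "condition_group"
  )
}

#' @export
print.condition_group <- function(x, ...) {
  cat(sprintf("<condition_group> %s: %d replicates, N_av = %.1f, c = %s\n",
              x$label, length(x$replicates), x$n_av,
              paste(sprintf("%.4f", x$coefficients), collapse = ", ")))
  invisible(x)
}

#' Normalize replicates and average them into a condition track
#'
#' Per position and strand, the condition value is the mean over replicates
#' of (raw count x c_i); a position absent from a replicate contributes 0 to
#' that replicate's term. The result is invariant under replicate reordering.
#'
#' @param group a [condition_group()].
#' @return a float-valued [five_prime_track()].
#' @export
normalize_and_average <- function(group) {
  stopifnot(inherits(group, "condition_group"))
  k <- length(group$replicates)
  avg_strand <- function(strand) {
    acc <- numeric(0)
    for (i in seq_len(k)) {
      v <- if (strand == "+") group$replicates[[i]]$plus else group$replicates[[i]]$minus
      if (!length(v)) next
      scaled <- v * group$coefficients[i]
      new <- setdiff(names(scaled), names(acc))
      if (length(new)) acc[new] <- 0
      acc[names(scaled)] <- acc[names(scaled)] + scaled
    }
    acc / k
  }
  five_prime_track(group$replicates[[1L]]$ref_id,
                   plus = avg_strand("+"), minus = avg_strand("-"))
}

#' Normalization report table
#'
#' One row per replicate with its label, read count after trimming/length
#' filtering, perfect-match read count, and the normalization coefficient
#' rounded to 4 decimal places (full precision is kept internally).
#'
#' @param groups list of [condition_group()]s.
#' @param n_trimmed optional list (parallel to \code{groups}) of per-replicate
#'   post-trim read counts.
#' @return a \code{data.frame}.
#' @export
normalization_report <- function(groups, n_trimmed = NULL) {
  rows <- lapply(seq_along(groups), function(g) {
    grp <- groups[[g]]
    data.frame(
      condition = grp$label,
      replicate = seq_along(grp$replicates),
      n_after_trim_and_length = if (is.null(n_trimmed)) NA_integer_
                                else as.integer(n_trimmed[[g]]),
      n_perfect = as.integer(grp$n_reads),
      coefficient = round(grp$coefficients, 4L),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
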