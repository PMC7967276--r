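# Read-level processing: 3' adapter trimming, minimum-length filtering, and
# perfect-match selection of SAM alignments by their XM/NM tags.

#' Trim a 3' adapter from reads
#'
#' If the full adapter sequence occurs anywhere in a read, the read is
#' truncated at the leftmost occurrence: everything from the adapter's first
#' base onward is removed, and qualities are trimmed in step. Reads without a
#' full-adapter occurrence are returned unchanged. Matching is exact
#' full-string search (no partial 3'-prefix matching, no error tolerance),
#' which makes trimming deterministic and idempotent once the trimmed
#' sequence no longer contains the adapter.
#'
#' @param reads a read table (\code{id}, \code{seq}, optional \code{qual}).
#' @param adapter non-empty adapter DNA string, e.g. \code{"AGATCGGAAGA"} or
#'   \code{"AAAAAAAAAA"}.
#' @return the read table with trimmed \code{seq} (and \code{qual}).
#' @export
trim_adapter <- function(reads, adapter) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nzchar(adapter))
  hit <- regexpr(adapter, reads$seq, fixed = TRUE)
  cut <- as.integer(hit) - 1L        # new length; -2 when no hit
  keep_len <- ifelse(hit > 0L, cut, nchar(reads$seq))
  reads$seq <- substr(reads$seq, 1L, keep_len)
  if (!is.null(reads$qual)) reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

#' Remove reads below a minimum length
#'
#' @param reads a read table.
#' @param min_len minimum retained length in nt (default 16).
#' @return the read table restricted to reads with
#'   \code{nchar(seq) >= min_len}, original order preserved.
#' @export
length_filter <- function(reads, min_len = 16L) {
  stopifnot(min_len >= 1L)
  reads[nchar(reads$seq) >= min_len, , drop = FALSE]
}

#' Read a SAM file into an alignment table
#'
#' Parses a SAM text file (via Rsamtools) into a plain data frame with one
#' row per record and the fields the pipeline needs: \code{qname},
#' \code{flag}, \code{rname}, \code{pos}, \code{cigar} and the integer
#' aligner tags \code{XM} (mismatches) and \code{NM} (edit distance), NA when
#' the tag is absent.
#'
#' @param path SAM (or BAM) file.
#' @return an alignment \code{data.frame}.
#' @export
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("XM", "NM")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(x$qname)
  tagv <- function(t) {
    v <- x$tag[[t]]
    if (is.null(v)) rep(NA_integer_, n) else as.integer(v)
  }
  data.frame(
    qname = x$qname,
    flag = as.integer(x$flag),
    rname = as.character(x$rname),
    pos = as.integer(x$pos),
    cigar = as.character(x$cigar),
    XM = tagv("XM"),
    NM = tagv("NM"),
    stringsAsFactors = FALSE
  )
}

is_unmapped <- function(flag) bitwAnd(flag, 0x4L) != 0L
is_minus <- function(flag) bitwAnd(flag, 0x10L) != 0L
is_secondary_or_supplementary <- function(flag) bitwAnd(flag, 0x900L) != 0L

#' Select alignments perfectly matching the genome
#'
#' Keeps exactly the primary, mapped records carrying both tags
#' \code{XM:i:0} and \code{NM:i:0}. Secondary and supplementary alignments
#' (flags 0x100/0x800) are excluded before filtering so a read can never be
#' counted twice; unmapped records and records missing either tag fail the
#' filter (both labels must be present).
#'
#' @param records an alignment table from [read_sam()].
#' @param n_after_trim_and_length optional read count after trimming and
#'   length filtering, carried into the returned stats.
#' @return a list with \code{records} (the perfect-match subset) and
#'   \code{stats}, a [filter_stats()] object.
#' @export
perfect_match_filter <- function(records, n_after_trim_and_length = NA_integer_) {
  primary <- records[!is_secondary_or_supplementary(records$flag), , drop = FALSE]
  mapped <- primary[!is_unmapped(primary$flag), , drop = FALSE]
  ok <- !is.na(mapped$XM) & !is.na(mapped$NM) & mapped$XM == 0L & mapped$NM == 0L
  kept <- mapped[ok, , drop = FALSE]
  list(
    records = kept,
    stats = filter_stats(
      n_input = nrow(records),
      n_after_trim_and_length = n_after_trim_and_length,
      n_mapped = nrow(mapped),
      n_perfect = nrow(kept)
    )
  )
}

#' Filtering statistics
#'
#' Bookkeeping counts for one replicate: reads in, reads surviving adapter
#' trimming and the length filter, mapped alignments, and perfect-match
#' alignments. \code{n_perfect} is the replicate's N_i used downstream for
#' depth normalization.
#'
#' @param n_input,n_after_trim_and_length,n_mapped,n_perfect integer counts.
#' @return an object of class \code{filter_stats}.
#' @export
filter_stats <- function(n_input, n_after_trim_and_length, n_mapped, n_perfect) {
  s <- list(
    n_input = as.integer(n_input),
    n_after_trim_and_length = as.integer(n_after_trim_and_length),
    n_mapped = as.integer(n_mapped),
    n_perfect = as.integer(n_perfect)
  )
  if (!is.na(s$n_after_trim_and_length) && s$n_input < s$n_after_trim_and_length)
    stop("n_input must be >= n_after_trim_and_length")
  if (s$n_mapped < s$n_perfect) stop("n_mapped must be >= n_perfect")
  structure(s, class = "filter_stats")
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(sprintf("<filter_stats> input %d | post-trim/length %s | mapped %d | perfect %d\n",
              x$n_input,
              ifelse(is.na(x$n_after_trim_and_length), "NA",
                     as.character(x$n_after_trim_and_length)),
              x$n_mapped, x$n_perfect))
  invisible(x)
}

#' Run the read-level stages on one FASTQ replicate
#'
#' Convenience wrapper applying [trim_adapter()] then [length_filter()] and
#' reporting the surviving reads plus counts.
#'
#' @param reads a read table from [read_fastq()].
#' @param adapter adapter sequence.
#' @param min_len minimum post-trim length (default 16).
#' @return list with \code{reads} (surviving) and counts \code{n_input},
#'   \code{n_after_trim_and_length}.
#' @export
process_reads <- function(reads, adapter, min_len = 16L) {
  n0 <- nrow(reads)
  out <- length_filter(trim_adapter(reads, adapter), min_len)
  list(reads = out, n_input = n0, n_after_trim_and_length = nrow(out))
}
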