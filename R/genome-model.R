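#' Genome sequence container
#'
#' Holds a single (typically bacterial) chromosome as a plain DNA string over
#' the alphabet \{A, C, G, T, N\}, together with its sequence identifier and a
#' circularity flag. Coordinates throughout the package are 1-based and
#' inclusive on both ends, matching how genome positions are conventionally
#' printed for bacterial genomes; 0-based half-open conversion happens only
#' inside the BED/bedGraph readers and writers.
#'
#' Circularity is recorded but interval arithmetic across the origin is not
#' supported: any feature or interval must satisfy
#' \code{1 <= start <= end <= length}.
#'
#' @param id sequence identifier, e.g. \code{"NC_000913.3"}.
#' @param seq DNA string (single character scalar) over \{A,C,G,T,N\}.
#'   Lower-case input is accepted and upper-cased.
#' @param circular logical flag; defaults to \code{TRUE} (bacterial
#'   chromosome).
#' @return an object of class \code{genome_seq} with fields \code{id},
#'   \code{seq}, \code{length} and \code{circular}.
#' @export
genome_seq <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("genome sequence must be non-empty")
  check_dna(seq)
  structure(
    list(id = id, seq = seq, length = nchar(seq), circular = isTRUE(circular)),
    class = "genome_seq"
  )
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

check_dna <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("non-DNA character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  }
  invisible(TRUE)
}

FEATURE_KINDS <- c("protein_coding", "ncRNA", "REP", "predicted_TSS")

#' Construct an annotation feature table
#'
#' Features are stored as a plain data frame with one row per feature and
#' columns \code{name}, \code{kind}, \code{start}, \code{end}, \code{strand}
#' and \code{mrna_tss}. \code{mrna_tss} is the experimentally supported mRNA
#' transcription start of a protein-coding gene; it may lie upstream of the
#' coding start and then defines a 5'UTR. For ncRNAs the annotated 5' end is
#' taken to coincide with the TSS, so no separate field is needed.
#'
#' @param name character vector of feature names.
#' @param kind one of \code{"protein_coding"}, \code{"ncRNA"}, \code{"REP"},
#'   \code{"predicted_TSS"} (recycled).
#' @param start,end 1-based inclusive coordinates, \code{start <= end}.
#' @param strand \code{"+"} or \code{"-"} (recycled).
#' @param mrna_tss optional integer vector (NA where unset); for a plus-strand
#'   gene it must satisfy \code{mrna_tss <= start}, for a minus-strand gene
#'   \code{mrna_tss >= end}.
#' @param genome_length optional genome length used to validate coordinates.
#' @return a \code{data.frame} with the columns above.
#' @export
features <- function(name, kind, start, end, strand, mrna_tss = NA_integer_,
                     genome_length = NULL) {
  n <- length(name)
  df <- data.frame(
    name = as.character(name),
    kind = rep_len(as.character(kind), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    mrna_tss = suppressWarnings(as.integer(rep_len(mrna_tss, n))),
    stringsAsFactors = FALSE
  )
  validate_features(df, genome_length)
  df
}

validate_features <- function(df, genome_length = NULL) {
  stopifnot(all(df$kind %in% FEATURE_KINDS))
  stopifnot(all(df$strand %in% c("+", "-")))
  if (any(df$start < 1L) || any(df$start > df$end))
    stop("feature coordinates must satisfy 1 <= start <= end")
  if (!is.null(genome_length) && any(df$end > genome_length))
    stop("feature end exceeds genome length")
  has_tss <- !is.na(df$mrna_tss)
  bad_plus <- has_tss & df$strand == "+" & df$mrna_tss > df$start
  bad_minus <- has_tss & df$strand == "-" & df$mrna_tss < df$end
  if (any(bad_plus | bad_minus))
    stop("mrna_tss must lie at or upstream of the coding span (<= start on '+', >= end on '-')")
  invisible(df)
}

#' 5' end of a feature
#'
#' The transcription start of an annotated feature: \code{start} on the plus
#' strand, \code{end} on the minus strand. For ncRNAs the annotated 5' end is
#' taken to coincide with the TSS. Vectorised over rows of a feature table.
#'
#' @param feature one or more feature rows (a data frame as returned by
#'   [features()]).
#' @param use_mrna_tss if \code{TRUE}, a non-NA \code{mrna_tss} overrides the
#'   coding-span end, giving the transcript (mRNA) 5' end rather than the CDS
#'   5' end.
#' @return integer vector of 1-based positions.
#' @export
five_prime_end <- function(feature, use_mrna_tss = FALSE) {
  p <- ifelse(feature$strand == "+", feature$start, feature$end)
  if (use_mrna_tss) {
    has <- !is.na(feature$mrna_tss)
    p[has] <- feature$mrna_tss[has]
  }
  as.integer(p)
}

#' 3' end of a feature
#'
#' \code{end} on the plus strand, \code{start} on the minus strand.
#'
#' @inheritParams five_prime_end
#' @return integer vector of 1-based positions.
#' @export
three_prime_end <- function(feature) {
  as.integer(ifelse(feature$strand == "+", feature$end, feature$start))
}

#' Transcript span of a feature
#'
#' The genomic interval covered by the (presumed) transcript: the annotated
#' span, extended to \code{mrna_tss} when set (i.e. including the 5'UTR of a
#' protein-coding gene).
#'
#' @param feature a single feature row.
#' @return a length-2 integer vector \code{c(start, end)}.
#' @export
transcript_span <- function(feature) {
  stopifnot(nrow(feature) == 1L)
  s <- feature$start; e <- feature$end
  if (!is.na(feature$mrna_tss)) {
    if (feature$strand == "+") s <- feature$mrna_tss else e <- feature$mrna_tss
  }
  c(as.integer(s), as.integer(e))
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; \code{N} maps to \code{N}.
#' Implemented via [Biostrings::reverseComplement()] after validating the
#' alphabet so that a non-DNA character is rejected with its position
#' reported.
#'
#' @param seq character vector of DNA strings over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  out <- vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    check_dna(toupper(s))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
  }, character(1L), USE.NAMES = FALSE)
  out
}

#' Number of shared positions of two closed intervals
#'
#' Symmetric in its arguments; strand is deliberately ignored (callers decide
#' whether strand matters). Returns 0 for disjoint intervals.
#'
#' @param a,b length-2 vectors \code{c(start, end)} of 1-based inclusive
#'   coordinates.
#' @return integer number of shared base pairs.
#' @export
overlap_length <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
  max(0L, as.integer(min(a[2], b[2]) - max(a[1], b[1]) + 1L))
}

#' Extract a genomic subsequence
#'
#' @param genome a [genome_seq()] object.
#' @param start,end 1-based inclusive coordinates within the genome.
#' @param strand if \code{"-"}, the reverse complement of the region is
#'   returned (the transcribed-strand sequence read 5' to 3').
#' @return a DNA string.
#' @export
genome_subseq <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_seq"))
  if (start < 1L || end > genome$length || start > end)
    stop("region outside genome (no wrap-around across the origin is supported)")
  s <- substr(genome$seq, start, end)
  if (identical(strand, "-")) s <- reverse_complement(s)
  s
}
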