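# Classification of ncRNAs against their neighbouring genes: codirected
# (head-to-tail), divergent (head-to-head), or overlapping over the 5'
# termini; bona fide flagging; inter-TSS distances of divergent pairs.
#
# Convergent (tail-to-tail) pairs fall outside the three-way taxonomy of
# divergently transcribed ncRNAs but occur in real annotations, so they are
# reported under their own label rather than rejected.

#' Nearest protein-coding neighbour of an ncRNA
#'
#' The protein-coding feature whose transcript 5' end (mrna_tss when set,
#' else the CDS 5' end) lies closest to the ncRNA's 5' end; equidistant
#' candidates are resolved toward the ncRNA's upstream side. This makes the
#' pairing of each ncRNA with "its" divergent or codirected partner
#' reproducible.
#'
#' @param ncrna a single ncRNA feature row.
#' @param annotation feature table containing at least one
#'   \code{protein_coding} feature.
#' @return the selected neighbour (one feature row).
#' @export
nearest_neighbor <- function(ncrna, annotation) {
  stopifnot(nrow(ncrna) == 1L)
  cand <- annotation[annotation$kind == "protein_coding", , drop = FALSE]
  if (nrow(cand) == 0L) stop("no protein-coding feature on the reference")
  nc5 <- five_prime_end(ncrna)
  c5 <- five_prime_end(cand, use_mrna_tss = TRUE)
  d <- abs(c5 - nc5)
  upstream <- if (ncrna$strand == "+") c5 < nc5 else c5 > nc5
  i <- order(d, !upstream)[1L]
  cand[i, , drop = FALSE]
}

#' Classify the arrangement of an ncRNA and its neighbour
#'
#' Same strand gives \code{codirected} (head-to-tail). On opposite strands
#' the pair is head-to-head when the two transcription directions point away
#' from each other (the plus-strand member's span midpoint lies at or right
#' of the minus-strand member's): disjoint transcript spans then give
#' \code{divergent}, intersecting spans \code{overlapping_5prime}. Opposite
#' strands transcribing toward each other give \code{convergent}. The
#' neighbour's transcript span includes its 5'UTR whenever \code{mrna_tss} is
#' set -- this is exactly what turns some nominally divergent ncRNAs into
#' antisense RNAs overlapping the partner mRNA's 5'UTR.
#'
#' \code{bona_fide} is TRUE when the ncRNA span overlaps no opposite-strand
#' transcript span (checked against the full \code{annotation} when given,
#' else against the neighbour alone).
#'
#' @param ncrna,neighbor single feature rows on one reference.
#' @param annotation optional feature table for the bona-fide check.
#' @return a one-row \code{data.frame}: \code{ncrna}, \code{neighbor},
#'   \code{arrangement}, \code{bona_fide}, \code{antisense_overlap} (bp),
#'   \code{inter_tss_distance} (bp, divergent pairs only, from annotated 5'
#'   ends).
#' @export
classify_arrangement <- function(ncrna, neighbor, annotation = NULL) {
  stopifnot(nrow(ncrna) == 1L, nrow(neighbor) == 1L)
  nc_span <- c(ncrna$start, ncrna$end)
  nb_span <- transcript_span(neighbor)
  if (ncrna$strand == neighbor$strand) {
    arrangement <- "codirected"
    ov <- 0L
  } else {
    ov <- overlap_length(nc_span, nb_span)
    p_mid <- if (ncrna$strand == "+") mean(nc_span) else mean(nb_span)
    m_mid <- if (ncrna$strand == "-") mean(nc_span) else mean(nb_span)
    head_to_head <- p_mid >= m_mid
    arrangement <- if (!head_to_head) "convergent"
                   else if (ov > 0L) "overlapping_5prime"
                   else "divergent"
  }
  others <- if (is.null(annotation)) neighbor
            else annotation[annotation$strand != ncrna$strand &
                            annotation$kind != "predicted_TSS" &
                            annotation$name != ncrna$name, , drop = FALSE]
  bona_fide <- TRUE
  for (i in seq_len(nrow(others))) {
    if (others$strand[i] == ncrna$strand) next
    if (overlap_length(nc_span, transcript_span(others[i, , drop = FALSE])) > 0L) {
      bona_fide <- FALSE
      break
    }
  }
  d <- if (arrangement == "divergent") {
    abs(five_prime_end(ncrna) - five_prime_end(neighbor, use_mrna_tss = TRUE))
  } else NA_integer_
  data.frame(
    ncrna = ncrna$name, neighbor = neighbor$name, arrangement = arrangement,
    bona_fide = bona_fide, antisense_overlap = as.integer(ov),
    inter_tss_distance = as.integer(d), stringsAsFactors = FALSE
  )
}

#' Antisense overlap between an ncRNA and an opposite-strand neighbour
#'
#' Length in bp of the overlap between the ncRNA transcript span and the
#' neighbour's transcript span (mrna_tss .. CDS end when the mRNA start is
#' known). A refined TSS, when supplied, replaces the ncRNA's annotated 5'
#' end, so an upstream-shifted TSS can only grow the overlap.
#'
#' @param ncrna,neighbor single feature rows on opposite strands.
#' @param refined_tss optional refined ncRNA TSS position.
#' @return integer overlap in bp (0 if disjoint).
#' @export
antisense_overlap_length <- function(ncrna, neighbor, refined_tss = NULL) {
  stopifnot(nrow(ncrna) == 1L, nrow(neighbor) == 1L)
  if (ncrna$strand == neighbor$strand)
    stop("antisense overlap requires opposite strands")
  nc_span <- c(ncrna$start, ncrna$end)
  if (!is.null(refined_tss)) {
    # the refined TSS replaces the annotated 5' end outright (it may extend
    # or shorten the transcript)
    if (ncrna$strand == "+") nc_span[1L] <- as.integer(refined_tss)
    else nc_span[2L] <- as.integer(refined_tss)
    if (nc_span[1L] > nc_span[2L]) stop("refined TSS beyond the 3' end")
  }
  overlap_length(nc_span, transcript_span(neighbor))
}

#' Distance between the TSSs of a divergent pair
#'
#' Simple absolute difference of the two start positions (no +/-1
#' convention); only meaningful -- and only allowed -- for divergent
#' (head-to-head) pairs.
#'
#' @param arrangement arrangement label of the pair (must be
#'   \code{"divergent"}).
#' @param tss_a,tss_b the two TSS positions.
#' @return distance in bp.
#' @export
inter_tss_distance <- function(arrangement, tss_a, tss_b) {
  if (!identical(arrangement, "divergent"))
    stop("inter-TSS distance is defined for divergent pairs only")
  abs(as.integer(tss_a) - as.integer(tss_b))
}

#' Summarize inter-TSS distances of divergent pairs
#'
#' @param calls arrangement table from [classify_arrangement()] rows (or any
#'   data frame with \code{arrangement} and \code{inter_tss_distance}).
#' @return a one-row \code{data.frame}: \code{n_pairs}, \code{min},
#'   \code{median}, \code{max} (bp; even counts use the mean of the central
#'   pair).
#' @export
summarize_distances <- function(calls) {
  d <- calls$inter_tss_distance[calls$arrangement == "divergent"]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no divergent pairs with inter-TSS distances")
  data.frame(n_pairs = length(d), min = min(d),
             median = stats::median(d), max = max(d))
}

#' Classify every ncRNA in an annotation
#'
#' Pairs each ncRNA with its [nearest_neighbor()] and classifies the pair,
#' using the full annotation for the bona-fide check.
#'
#' @param annotation feature table with ncRNAs and protein-coding genes.
#' @return arrangement table, one row per ncRNA.
#' @export
classify_all <- function(annotation) {
  ncs <- annotation[annotation$kind == "ncRNA", , drop = FALSE]
  rows <- lapply(seq_len(nrow(ncs)), function(i) {
    nc <- ncs[i, , drop = FALSE]
    nb <- nearest_neighbor(nc, annotation)
    classify_arrangement(nc, nb, annotation = annotation)
  })
  do.call(rbind, rows)
}
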