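# TSS peak calling around annotated 5' ends, primary/secondary ranking,
# signed shifts against the annotation, and concordance with an external
# predicted-TSS track.
#
# Peak calling is an explicit, reproducible rule (local maximum above a
# height threshold inside a window centred on the annotated 5' end) standing
# in for by-eye curation of superimposed profiles. Window and threshold are
# deliberately exposed: they are analysis parameters, not facts about the
# organism.

#' Signed TSS offset relative to the annotated 5' end
#'
#' The sign convention is fixed so that a negative offset always means the
#' transcript got longer (the called start lies upstream of the annotated 5'
#' end in the direction of transcription) and a positive offset means
#' shortening: on the plus strand \code{offset = called - annotated}, on the
#' minus strand \code{offset = annotated - called}.
#'
#' @param position called TSS position(s).
#' @param feature a single feature row; its strand must match the call's.
#' @param strand optional strand of the call; an explicit mismatch with the
#'   feature strand is an error (a TSS on the other strand has no offset).
#' @return signed integer offset(s) in bp.
#' @export
tss_offset <- function(position, feature, strand = NULL) {
  stopifnot(nrow(feature) == 1L)
  if (!is.null(strand) && !all(strand == feature$strand))
    stop("call strand does not match feature strand")
  ann <- five_prime_end(feature)
  if (feature$strand == "+") as.integer(position - ann) else as.integer(ann - position)
}

#' Call TSS peaks near an annotated feature 5' end
#'
#' Finds, on the feature's strand, all local maxima of the averaged
#' normalized 5'-end track with height >= \code{min_height} within
#' \code{[annotated 5' end - window, annotated 5' end + window]}. A position
#' is a local maximum when its value is >= both neighbouring positions
#' (absent positions count as 0); a plateau of equal adjacent values yields
#' one call at the plateau position closest to the annotated 5' end (tie
#' broken upstream). The highest peak is ranked \code{primary} (ties broken
#' toward the annotated position, then upstream), all others
#' \code{secondary}, sorted by height descending.
#'
#' @param track averaged normalized [five_prime_track()].
#' @param feature a single feature row (the ncRNA or gene of interest).
#' @param window half-width of the search window in bp (default 300, wide
#'   enough to cover the largest shifts seen in refined annotations with
#'   margin).
#' @param min_height minimum peak height in normalized counts (default 5).
#' @param condition optional condition label recorded in the output.
#' @param ref_id optional reference id check against \code{track$ref_id}.
#' @return a \code{data.frame} of TSS calls: \code{feature}, \code{condition},
#'   \code{position}, \code{strand}, \code{height}, \code{rank},
#'   \code{offset}; zero rows if no peak qualifies.
#' @export
call_tss <- function(track, feature, window = 300L, min_height = 5,
                     condition = NA_character_, ref_id = NULL) {
  stopifnot(window >= 1L, nrow(feature) == 1L)
  if (!is.null(ref_id) && !identical(track$ref_id, ref_id))
    stop("feature reference '", ref_id, "' not on track '", track$ref_id, "'")
  ann <- five_prime_end(feature)
  v <- if (feature$strand == "+") track$plus else track$minus
  empty <- data.frame(
    feature = character(0), condition = character(0), position = integer(0),
    strand = character(0), height = numeric(0), rank = character(0),
    offset = integer(0), stringsAsFactors = FALSE
  )
  if (!length(v)) return(empty)
  pos <- as.integer(names(v))
  inw <- pos >= ann - window & pos <= ann + window
  pos <- pos[inw]; val <- unname(v[inw])
  if (!length(pos)) return(empty)
  o <- order(pos); pos <- pos[o]; val <- val[o]
  left <- track_value(track, feature$strand, pos - 1L)
  right <- track_value(track, feature$strand, pos + 1L)
  cand <- val >= min_height & val >= left & val >= right
  pos <- pos[cand]; val <- val[cand]
  if (!length(pos)) return(empty)
  # collapse plateaus: runs of adjacent candidate positions with equal value
  run <- cumsum(c(TRUE, !(diff(pos) == 1L & diff(val) == 0)))
  rep_of_run <- vapply(split(seq_along(pos), run), function(ix) {
    p <- pos[ix]
    d <- abs(p - ann)
    ix[order(d, if (feature$strand == "+") p else -p)][1L]
  }, integer(1L))
  pos <- pos[rep_of_run]; val <- val[rep_of_run]
  off <- tss_offset(pos, feature)
  # primary: highest; ties -> smaller |offset|, then upstream (negative offset)
  ord <- order(-val, abs(off), off)
  pos <- pos[ord]; val <- val[ord]; off <- off[ord]
  data.frame(
    feature = feature$name, condition = condition, position = pos,
    strand = feature$strand, height = val,
    rank = c("primary", rep("secondary", length(pos) - 1L)),
    offset = off, stringsAsFactors = FALSE
  )
}

#' Transcript length variants implied by multiple TSSs
#'
#' Each distinct called TSS, together with the annotated 3' end, defines one
#' transcript variant; pairwise length differences therefore equal pairwise
#' TSS separations (e.g. two TSSs 26 bp apart give transcripts differing by
#' 26 nt).
#'
#' @param calls TSS call table from [call_tss()] (same feature).
#' @param feature a single feature row providing the annotated 3' end.
#' @return a \code{data.frame} with \code{position}, \code{rank} and
#'   \code{length} (nt) per distinct TSS.
#' @export
transcript_variants <- function(calls, feature) {
  stopifnot(nrow(feature) == 1L)
  if (nrow(calls) == 0L) stop("no TSS calls given")
  tp <- three_prime_end(feature)
  len <- if (feature$strand == "+") tp - calls$position + 1L
         else calls$position - tp + 1L
  if (any(len < 1L)) stop("TSS downstream of the annotated 3' end")
  out <- data.frame(position = calls$position, rank = calls$rank,
                    length = as.integer(len), stringsAsFactors = FALSE)
  out[!duplicated(out$position), , drop = FALSE]
}

#' Concordance of TSS calls with a predicted-TSS track
#'
#' Matches each call to the nearest same-strand prediction; a call is
#' \code{matched} when that distance is at most \code{tolerance} bp.
#'
#' @param calls TSS call table.
#' @param predicted feature table of kind \code{predicted_TSS}.
#' @param tolerance maximum distance (bp) counted as agreement (default 0:
#'   exact coincidence).
#' @return the call table extended by \code{predicted_position},
#'   \code{distance} and \code{matched} (predictions absent on a strand give
#'   NA distance and \code{matched = FALSE}).
#' @export
concordance <- function(calls, predicted, tolerance = 0L) {
  pp <- if (nrow(predicted)) five_prime_end(predicted) else integer(0)
  ps <- predicted$strand
  res <- lapply(seq_len(nrow(calls)), function(i) {
    cand <- pp[ps == calls$strand[i]]
    if (!length(cand)) {
      return(data.frame(predicted_position = NA_integer_, distance = NA_integer_,
                        matched = FALSE))
    }
    d <- abs(cand - calls$position[i])
    j <- which.min(d)
    data.frame(predicted_position = cand[j], distance = d[j],
               matched = d[j] <= tolerance)
  })
  cbind(calls, do.call(rbind, res))
}
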