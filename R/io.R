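# File-format frontends. FASTA/FASTQ go through Biostrings, GFF3/BED/bedGraph
# through rtracklayer; only the 1-based <-> 0-based bookkeeping and the
# mapping onto the package's plain containers lives here.

#' Read a genome from a FASTA file
#'
#' Reads the first (or named) record of a FASTA file into a [genome_seq()].
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record allowed).
#' @param id optional record id to select; default: first record.
#' @param circular passed to [genome_seq()].
#' @return a \code{genome_seq}.
#' @export
read_genome_fasta <- function(path, id = NULL, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(set))
  i <- if (is.null(id)) 1L else match(id, nm)
  if (is.na(i)) stop("record '", id, "' not found in ", path)
  genome_seq(nm[i], as.character(set[[i]]), circular = circular)
}

#' Write a genome to a FASTA file
#'
#' @param genome a [genome_seq()].
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome$seq)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an annotation from GFF3
#'
#' GFF3 is the canonical annotation dialect. Column 3 feature types are mapped
#' onto the package's kinds: \code{gene} -> \code{protein_coding},
#' \code{ncRNA}/\code{sRNA} -> \code{ncRNA}, \code{repeat_region} ->
#' \code{REP}, \code{TSS} -> \code{predicted_TSS}; other types are dropped.
#' The \code{Name} attribute provides the feature name and an optional
#' \code{mrna_tss} attribute the experimentally supported mRNA start.
#'
#' @param path GFF3 file.
#' @return a feature table (see [features()]).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  kind <- c(gene = "protein_coding", ncRNA = "ncRNA", sRNA = "ncRNA",
            repeat_region = "REP", TSS = "predicted_TSS")[type]
  keep <- !is.na(kind)
  gr <- gr[keep]; kind <- kind[keep]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  tss <- rep(NA_integer_, length(gr))
  if (!is.null(gr$mrna_tss)) tss <- suppressWarnings(as.integer(gr$mrna_tss))
  features(
    name = nm, kind = kind,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    mrna_tss = tss
  )
}

#' Write an annotation to GFF3
#'
#' Inverse of [read_annotation_gff3()]; kinds map back to GFF3 types and
#' \code{mrna_tss} is written as an attribute when set.
#'
#' @param feats a feature table.
#' @param path output GFF3 file.
#' @param ref_id sequence identifier for column 1.
#' @export
write_annotation_gff3 <- function(feats, path, ref_id) {
  type <- c(protein_coding = "gene", ncRNA = "ncRNA", REP = "repeat_region",
            predicted_TSS = "TSS")[feats$kind]
  gr <- GenomicRanges::GRanges(
    seqnames = ref_id,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand
  )
  gr$type <- type
  gr$Name <- feats$name
  if (any(!is.na(feats$mrna_tss))) gr$mrna_tss <- feats$mrna_tss
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a predicted-TSS track from BED6
#'
#' BED is 0-based half-open; positions are converted to 1-based inclusive on
#' input. Each BED interval becomes a \code{predicted_TSS} feature (for a
#' single-position prediction the interval has width 1).
#'
#' @param path BED6 file.
#' @return a feature table of kind \code{predicted_TSS}.
#' @export
read_predicted_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("pTSS_%d", seq_along(gr))
  features(
    name = nm, kind = "predicted_TSS",
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (4-line records).
#' @return a \code{data.frame} with columns \code{id}, \code{seq},
#'   \code{qual}.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    seq = as.character(set),
    qual = as.character(S4Vectors::mcols(set)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table to FASTQ
#'
#' @param reads a read table (\code{id}, \code{seq}, \code{qual}).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$qual) == nchar(reads$seq)))
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write one strand of a five-prime track as bedGraph
#'
#' Values are the (averaged, normalized) per-position 5'-end counts; the
#' 1-based inclusive positions are converted to bedGraph's 0-based half-open
#' convention by rtracklayer.
#'
#' @param track a [five_prime_track()].
#' @param strand \code{"+"} or \code{"-"}.
#' @param path output bedGraph file.
#' @export
write_track_bedgraph <- function(track, strand, path) {
  v <- track_counts(track, strand)
  gr <- GenomicRanges::GRanges(
    seqnames = track$ref_id,
    ranges = IRanges::IRanges(v$pos, v$pos),
    score = v$count
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write REP matches or T-tracks as BED6
#'
#' @param df data frame with columns \code{start}, \code{end}, \code{strand}
#'   and optionally \code{name} and \code{score}.
#' @param path output BED file.
#' @param ref_id sequence identifier.
#' @export
write_intervals_bed <- function(df, path, ref_id) {
  gr <- GenomicRanges::GRanges(
    seqnames = ref_id,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = if (!is.null(df$strand)) df$strand else "*"
  )
  gr$name <- if (!is.null(df$name)) df$name else sprintf("iv_%d", seq_len(nrow(df)))
  gr$score <- if (!is.null(df$score)) df$score else 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
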