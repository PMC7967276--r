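# Independent oracles and tiny fixture builders shared by the tests. The
# oracles deliberately avoid the package's code paths: the SAM oracle is a
# minimal line-by-line text parser, the 5'-end recount walks CIGAR strings
# with its own arithmetic, and the motif oracle compares the pattern at
# every offset character by character.

# -- minimal SAM text parser (independent of Rsamtools) ----------------------
oracle_parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  recs <- strsplit(lines, "\t", fixed = TRUE)
  get_tag <- function(fields, tag) {
    hit <- grep(paste0("^", tag, ":i:"), fields[-(1:11)], value = TRUE)
    if (!length(hit)) return(NA_integer_)
    as.integer(sub(".*:i:", "", hit[1]))
  }
  data.frame(
    qname = vapply(recs, `[[`, "", 1L),
    flag = as.integer(vapply(recs, `[[`, "", 2L)),
    rname = vapply(recs, `[[`, "", 3L),
    pos = as.integer(vapply(recs, `[[`, "", 4L)),
    cigar = vapply(recs, `[[`, "", 6L),
    XM = vapply(recs, get_tag, 0L, "XM"),
    NM = vapply(recs, get_tag, 0L, "NM"),
    stringsAsFactors = FALSE
  )
}

# reference span by explicit character walk (no regex machinery shared with
# the implementation)
oracle_ref_span <- function(cigar) {
  total <- 0L; num <- 0L
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") {
      num <- num * 10L + as.integer(ch)
    } else {
      if (ch %in% c("M", "D", "N", "=", "X")) total <- total + num
      num <- 0L
    }
  }
  total
}

# brute-force 5'-end recount straight from a SAM file: keep primary mapped
# records with XM==0 and NM==0, then tabulate 5' ends per strand
oracle_pileup <- function(path) {
  r <- oracle_parse_sam(path)
  keep <- bitwAnd(r$flag, 0x904L) == 0L & !is.na(r$XM) & !is.na(r$NM) &
    r$XM == 0L & r$NM == 0L
  r <- r[keep, , drop = FALSE]
  plus <- integer(0); minus <- integer(0)
  for (i in seq_len(nrow(r))) {
    if (bitwAnd(r$flag[i], 0x10L)) {
      minus <- c(minus, r$pos[i] + oracle_ref_span(r$cigar[i]) - 1L)
    } else {
      plus <- c(plus, r$pos[i])
    }
  }
  list(plus = table(plus), minus = table(minus), n = nrow(r))
}

# -- character-by-character IUPAC scanner (naive, every offset) --------------
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A","G"), Y = c("C","T"),
  S = c("C","G"), W = c("A","T"), K = c("G","T"), M = c("A","C"),
  B = c("C","G","T"), D = c("A","G","T"), H = c("A","C","T"),
  V = c("A","C","G"), N = c("A","C","G","T","N")
)

oracle_scan_one_strand <- function(seq, pattern, max_mm) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc); n <- length(sc)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  if (n < L) return(hits)
  for (i in seq_len(n - L + 1L)) {
    mm <- 0L
    for (j in seq_len(L)) {
      if (!(sc[i + j - 1L] %in% ORACLE_IUPAC[[pc[j]]])) mm <- mm + 1L
      if (mm > max_mm) break
    }
    if (mm <= max_mm) hits <- rbind(hits, data.frame(start = i, mismatches = mm))
  }
  hits
}

# -- Biostrings exhaustive matcher as a second, library-based oracle ---------
oracle_scan_biostrings <- function(seq, pattern, max_mm) {
  subj <- Biostrings::DNAString(seq)
  one <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mm,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    if (!length(m)) return(NULL)
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
               strand = strand, stringsAsFactors = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  out <- rbind(one(pattern, "+"), one(rc, "-"))
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0), strand = character(0))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# -- tiny builders -----------------------------------------------------------
feat <- function(name = "f", kind = "ncRNA", start, end, strand = "+",
                 mrna_tss = NA_integer_) {
  features(name, kind, start, end, strand, mrna_tss)
}

make_track <- function(plus = numeric(0), minus = numeric(0), ref = "chr") {
  five_prime_track(ref, plus = plus, minus = minus)
}

sparse <- function(...) {
  v <- c(...)
  stats::setNames(as.numeric(v), names(v))
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

# write a SAM file from a record data frame (qname, flag, pos, cigar, XM, NM)
write_test_sam <- function(recs, path, ref = "chr", ln = 100000L,
                           seqs = NULL) {
  body <- vapply(seq_len(nrow(recs)), function(i) {
    sp <- oracle_ref_span(recs$cigar[i])
    s <- if (!is.null(seqs)) seqs[i] else strrep("A", max(sp, 1L))
    tags <- character(0)
    if (!is.na(recs$XM[i])) tags <- c(tags, sprintf("XM:i:%d", recs$XM[i]))
    if (!is.na(recs$NM[i])) tags <- c(tags, sprintf("NM:i:%d", recs$NM[i]))
    paste(c(recs$qname[i], recs$flag[i], ref, recs$pos[i], 42, recs$cigar[i],
            "*", 0, 0, s, strrep("I", nchar(s)), tags), collapse = "\t")
  }, character(1))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref, ln), body), path)
  path
}

# mirror a feature table through the point genome_length + 1 (coordinate
# reflection plus strand flip)
mirror_features <- function(feats, genome_length) {
  out <- feats
  out$start <- genome_length + 1L - feats$end
  out$end <- genome_length + 1L - feats$start
  out$strand <- ifelse(feats$strand == "+", "-", "+")
  out$mrna_tss <- ifelse(is.na(feats$mrna_tss), NA_integer_,
                         genome_length + 1L - feats$mrna_tss)
  out
}

mirror_track <- function(track, genome_length) {
  flip <- function(v) {
    if (!length(v)) return(numeric(0))
    stats::setNames(unname(v), as.character(genome_length + 1L - as.integer(names(v))))
  }
  five_prime_track(track$ref_id, plus = flip(track$minus),
                   minus = flip(track$plus))
}
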