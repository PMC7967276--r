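REP35 <- "TGCCGGATGCGGCGTAAACGCCTTATCCGGCCTAC"

test_that("rep_consensus validates IUPAC patterns", {
  expect_error(rep_consensus("x", "ACGTACGTA"), "nchar")  # too short
  expect_error(rep_consensus("x", "ACGTACGTACGQ"), "position 12")
  cs <- rep_consensus("x", "gckgatggcgrgck")
  expect_equal(cs$pattern, "GCKGATGGCGRGCK")
  expect_length(builtin_rep_consensus(), 6L)
})

test_that("scan_rep finds planted motifs on both strands", {
  set.seed(41)
  cs <- rep_consensus("REP_35", REP35, max_mismatches = 0L)
  bg <- rand_dna(400)
  seq_plus <- paste0(substr(bg, 1, 100), REP35, substr(bg, 136, 400))
  hits <- scan_rep(seq_plus, cs)
  planted <- hits[hits$start == 101L & hits$strand == "+", ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$end, 135L)
  expect_equal(planted$mismatches, 0L)

  seq_minus <- paste0(substr(bg, 1, 100), reverse_complement(REP35),
                      substr(bg, 136, 400))
  hitm <- scan_rep(seq_minus, cs)
  expect_true(any(hitm$start == 101L & hitm$strand == "-"))

  # one substitution: invisible at budget 0, found with mismatches==1 at 1
  mut <- REP35
  substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "A") "C" else "A"
  seq_mut <- paste0(substr(bg, 1, 100), mut, substr(bg, 136, 400))
  expect_false(any(scan_rep(seq_mut, cs)$start == 101L))
  h1 <- scan_rep(seq_mut, cs, max_mismatches = 1L)
  expect_equal(h1$mismatches[h1$start == 101L & h1$strand == "+"], 1L)
  # brute-force all-offsets oracle agrees
  oracle <- oracle_scan_one_strand(seq_mut, REP35, 1L)
  impl <- scan_rep(seq_mut, cs, max_mismatches = 1L)
  expect_setequal(impl$start[impl$strand == "+"], oracle$start)
})

test_that("scan_rep agrees with independent oracles on random sequences", {
  set.seed(43)
  cs <- builtin_rep_consensus(max_mismatches = 3L)
  for (i in 1:5) {
    s <- rand_dna(800)
    # plant a motif with 2 mismatches to make hits likely
    mut <- strsplit(REP35, "")[[1]]
    for (p in sample(35, 2)) mut[p] <- sample(setdiff(c("A","C","G","T"), mut[p]), 1)
    s <- paste0(substr(s, 1, 300), paste(mut, collapse = ""), substr(s, 336, 800))
    for (pat in cs[c(1, 3)]) {
      impl <- scan_rep(s, pat)
      ref <- oracle_scan_biostrings(s, pat$pattern, pat$max_mismatches)
      expect_equal(impl$start, ref$start)
      expect_equal(impl$strand, ref$strand)
      # naive per-offset scanner on the plus strand
      naive <- oracle_scan_one_strand(s, pat$pattern, pat$max_mismatches)
      expect_setequal(impl$start[impl$strand == "+"], naive$start)
    }
  }
})

test_that("scanning a reverse-complemented region mirrors strands", {
  set.seed(47)
  cs <- rep_consensus("REP_35", REP35, max_mismatches = 2L)
  s <- paste0(rand_dna(60), REP35, rand_dna(60))
  fwd <- scan_rep(s, cs)
  rev <- scan_rep(reverse_complement(s), cs)
  n <- nchar(s)
  expect_equal(sort(n + 1L - fwd$end[fwd$strand == "+"]),
               sort(rev$start[rev$strand == "-"]))
  expect_equal(sort(n + 1L - rev$end[rev$strand == "+"]),
               sort(fwd$start[fwd$strand == "-"]))
})

test_that("find_tn_tracks returns maximal non-overlapping runs", {
  t1 <- find_tn_tracks("ACTTTTTGA", min_run = 4)
  expect_equal(nrow(t1), 1L)
  expect_equal(c(t1$start, t1$end, t1$length), c(3L, 7L, 5L))
  expect_equal(nrow(find_tn_tracks("ACTTTGA", min_run = 4)), 0L)
  t8 <- find_tn_tracks("TTTTTTTT", min_run = 4)
  expect_equal(nrow(t8), 1L)
  expect_equal(t8$length, 8L)
  # minus-strand transcription: T runs appear as A runs on the plus strand
  tm <- find_tn_tracks("CCAAAAACC", min_run = 4, strand = "-")
  expect_equal(c(tm$start, tm$end), c(3L, 7L))
  expect_equal(nrow(find_tn_tracks("CCAAAAACC", min_run = 4, strand = "+")), 0L)
  # property: maximality and pairwise disjointness on random sequences
  set.seed(53)
  for (i in 1:30) {
    s <- paste(sample(c("A", "T", "C"), 200, TRUE, prob = c(2, 4, 2)),
               collapse = "")
    tt <- find_tn_tracks(s, min_run = 4)
    if (nrow(tt) == 0) next
    ch <- strsplit(s, "")[[1]]
    for (j in seq_len(nrow(tt))) {
      expect_true(all(ch[tt$start[j]:tt$end[j]] == "T"))
      if (tt$start[j] > 1) expect_false(ch[tt$start[j] - 1] == "T")
      if (tt$end[j] < 200) expect_false(ch[tt$end[j] + 1] == "T")
    }
    if (nrow(tt) > 1)
      expect_true(all(tt$start[-1] > tt$end[-nrow(tt)]))
  }
})

test_that("hairpin detection requires a qualifying stem-loop upstream", {
  # hairpin (5-bp stem, 4-nt loop) directly before the T track
  g <- genome_seq("h", paste0("CAGCAG", "GGCGC", "TTTT", "GCGCC", "TTTTT", "CAGCAG"))
  t_track <- c(21L, 25L)
  expect_true(hairpin_upstream(g, t_track, strand = "+"))
  # poly-A upstream window: no self-complementarity
  g2 <- genome_seq("h", paste0(strrep("A", 20), "TTTTT", "CAGCAG"))
  expect_false(hairpin_upstream(g2, c(21L, 25L), strand = "+"))
  # stem of 3 fails min_stem = 4
  g3 <- genome_seq("h", paste0("CAGCAGCAG", "GGC", "TTTT", "GCC", "TTTTT", "CAG"))
  expect_false(hairpin_upstream(g3, c(20L, 24L), strand = "+", min_stem = 4L))
  expect_true(hairpin_upstream(g3, c(20L, 24L), strand = "+", min_stem = 3L))
  # minus-strand transcription searches downstream coordinates
  gm <- genome_seq("h", paste0("CAGCAG", "AAAAA", "GGCGC", "CACA", "GCGCC", "CAG"))
  expect_true(hairpin_upstream(gm, c(7L, 11L), strand = "-"))
})

test_that("rep_transcription_report combines TSS, REP, T-track and hairpin", {
  # layout on the minus strand: geneL ... [REP] fill [Tn hairpin]? TSS ... geneR
  build_locus <- function(with_tn, with_hairpin, with_tss) {
    fill <- function(n) strrep("CGT", ceiling(n / 3))
    left <- substr(fill(300), 1, 300)
    rep_block <- REP35                                   # 301..335
    mid <- substr(fill(64), 1, 64)                       # 336..399
    tn <- if (with_tn) "AAAAAA" else substr(fill(6), 1, 6)       # 400..405
    hp <- if (with_hairpin) "GGCGCCACGCGCC" else substr(fill(13), 1, 13) # 406..418
    right <- substr(fill(300), 1, 282)                   # up to 700
    seq <- paste0(left, rep_block, mid, tn, hp, right)
    genome <- genome_seq("locus", paste0(seq, strrep("CGT", 200)))
    ann <- rbind(
      feat("gL", "protein_coding", 10, 250, "+"),
      feat("gR", "protein_coding", 600, 900, "+")
    )
    track <- if (with_tss) make_track(minus = sparse("500" = 40), ref = "locus")
             else make_track(ref = "locus")
    rep_transcription_report(c(251L, 599L), ann, track, genome,
                             consensus = builtin_rep_consensus())
  }
  # divergent TSS, no terminator: read-through, distance TSS -> REP end
  r1 <- build_locus(FALSE, FALSE, TRUE)
  expect_equal(r1$rna_strand, "-")
  expect_equal(r1$divergent_tss$position, 500L)
  expect_equal(r1$tss_to_rep_distance, 500L - 335L)
  expect_false(r1$terminator_candidate)
  expect_true(r1$read_through)

  # TSS, then hairpin + T6 before the REP: terminator candidate, no read-through
  r2 <- build_locus(TRUE, TRUE, TRUE)
  expect_equal(nrow(r2$tn_tracks), 1L)
  expect_true(r2$tn_tracks$hairpin[1])
  expect_true(r2$terminator_candidate)
  expect_false(r2$read_through)

  # T track without a hairpin is not a terminator candidate
  r3 <- build_locus(TRUE, FALSE, TRUE)
  expect_equal(nrow(r3$tn_tracks), 1L)
  expect_false(r3$tn_tracks$hairpin[1])
  expect_false(r3$terminator_candidate)
  expect_true(r3$read_through)

  # no TSS in the IGR: report without TSS or distance
  r0 <- build_locus(FALSE, FALSE, FALSE)
  expect_null(r0$divergent_tss)
  expect_true(is.na(r0$tss_to_rep_distance))
  expect_false(r0$read_through)

  expect_error(
    rep_transcription_report(c(10L, 50L), feat("g", "protein_coding", 100, 200, "+"),
                             make_track(ref = "locus"),
                             genome_seq("locus", rand_dna(300))),
    "flanked")
})
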