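test_that("the generator is deterministic: same seed, identical bytes", {
  cfg <- simulation_config(seed = 99, reads_per_replicate = 300L,
                           conditions = "exp", n_replicates = 2L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  # a different seed changes the reads
  d3 <- tempfile()
  simulate_dataset(simulation_config(seed = 100, reads_per_replicate = 300L,
                                     conditions = "exp", n_replicates = 2L), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "exp_rep1.fastq"))),
                         unname(tools::md5sum(file.path(d3, "exp_rep1.fastq")))))
})

test_that("configuration contracts are enforced", {
  expect_error(simulation_config(mismatch_read_fraction = 1.2))
  cfg <- simulation_config(reads_per_replicate = 0L)
  expect_error(generate_reads(cfg, generate_genome(cfg)), "reads_per_replicate")
  # overlapping planted features on one strand are rejected
  bad <- simulation_config()
  bad$loci$feats$start[2] <- bad$loci$feats$start[1]
  bad$loci$feats$end[2] <- bad$loci$feats$end[1] + 10L
  bad$loci$feats$strand[2] <- bad$loci$feats$strand[1]
  expect_error(generate_genome(bad), "overlapping planted features")
})

test_that("planted geometry shows up in the annotation", {
  sim <- generate_genome(simulation_config(seed = 5))
  truth <- sim$truth$pairs
  div <- truth[truth$arrangement == "divergent", ]
  # a planted divergent pair at separation 84 reproduces separation 84
  expect_true(84L %in% div$inter_tss_distance)
  for (i in seq_len(nrow(div))) {
    nc <- sim$annotation[sim$annotation$name == div$ncrna[i], ]
    nb <- sim$annotation[sim$annotation$name == div$neighbor[i], ]
    expect_equal(abs(five_prime_end(nc) - five_prime_end(nb, use_mrna_tss = TRUE)),
                 div$inter_tss_distance[i])
  }
  # the planted REP sequence is really in the genome
  for (i in seq_len(nrow(sim$truth$rep_loci))) {
    rl <- sim$truth$rep_loci[i, ]
    expect_equal(genome_subseq(sim$genome, rl$rep_start, rl$rep_end),
                 "TGCCGGATGCGGCGTAAACGCCTTATCCGGCCTAC")
  }
})

test_that("reads concentrate at planted TSSs and depths differ", {
  cfg <- simulation_config(seed = 11, reads_per_replicate = 400L,
                           conditions = "exp",
                           short_read_fraction = 0,
                           adapter_contamination_fraction = 0)
  # concentrate all weight on one signal
  cfg$loci$signals$w_exp <- c(1, rep(0, nrow(cfg$loci$signals) - 1))
  sim <- generate_genome(cfg)
  reads <- generate_reads(cfg, sim)
  target <- sim$truth$signals[1, ]
  expect_true(all(reads$origin_pos == target$pos))
  sub <- reads[reads$replicate == 1L, ]
  sam <- tempfile(fileext = ".sam")
  generate_alignments(sub, sim$genome, sam)
  tr <- build_track(perfect_match_filter(read_sam(sam))$records)
  v <- if (target$strand == "+") tr$plus else tr$minus
  expect_equal(names(which.max(v)), as.character(target$pos))
  # intended depths differ between replicates -> coefficients 1.5 / 0.75
  # analogue: two replicates with N = [100, 200]
  expect_equal(normalization_coefficients(c(100, 200)), c(1.5, 0.75))
  nr <- table(reads$replicate)
  expect_equal(unname(nr / nr[1])[2], cfg$depth_multipliers[2],
               tolerance = 1e-6)
})

test_that("noise fractions drive the filters as planted", {
  cfg <- simulation_config(seed = 19, reads_per_replicate = 2000L,
                           conditions = "exp", n_replicates = 1L,
                           mismatch_read_fraction = 0,
                           adapter_contamination_fraction = 0.3,
                           short_read_fraction = 0.2)
  sim <- generate_genome(cfg)
  reads <- generate_reads(cfg, sim)
  pr <- process_reads(reads[, c("id", "seq", "qual")], cfg$adapter)
  # with no mismatching reads, post-filter count equals trim/length survivors
  expect_equal(pr$n_after_trim_and_length, sum(!reads$is_short))
  expect_true(all(nchar(pr$reads$seq) == cfg$read_length))
  sam <- tempfile(fileext = ".sam")
  generate_alignments(reads, sim$genome, sam)
  out <- perfect_match_filter(read_sam(sam),
                              n_after_trim_and_length = pr$n_after_trim_and_length)
  expect_equal(out$stats$n_perfect, pr$n_after_trim_and_length)
  expect_setequal(out$records$qname, pr$reads$id)
})

test_that("the alignment oracle writes correct SAM records", {
  g <- genome_seq("chrS", rand_dna(400))
  prov <- data.frame(
    id = c("p1", "m1", "x1"),
    seq = NA, qual = NA,
    origin_pos = c(100L, 119L, 200L),
    strand = c("+", "-", "+"),
    n_mismatch = c(0L, 0L, 1L),
    is_short = FALSE, has_adapter = FALSE, stringsAsFactors = FALSE
  )
  prov$aligned_seq <- c(
    genome_subseq(g, 100, 119),
    genome_subseq(g, 100, 119, strand = "-"),
    sub("^A", "C", sub("^G", "A", genome_subseq(g, 200, 219)))
  )
  sam <- tempfile(fileext = ".sam")
  generate_alignments(prov, g, sam)
  r <- oracle_parse_sam(sam)
  # perfect plus-strand read: pos = 5' end, flag 0, full-length match
  expect_equal(r$pos[r$qname == "p1"], 100L)
  expect_equal(r$flag[r$qname == "p1"], 0L)
  expect_equal(r$cigar[r$qname == "p1"], "20M")
  expect_equal(r$NM[r$qname == "p1"], 0L)
  # minus-strand read with 5' end at 119, length 20: pos 100, flag 16
  expect_equal(r$pos[r$qname == "m1"], 100L)
  expect_equal(r$flag[r$qname == "m1"], 16L)
  # one planted substitution: NM:i:1 and XM:i:1
  expect_equal(r$NM[r$qname == "x1"], 1L)
  expect_equal(r$XM[r$qname == "x1"], 1L)
  expect_error(generate_alignments(prov[, 1:3], g, sam), "provenance")
})
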