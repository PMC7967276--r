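test_that("nearest_neighbor picks the closest 5' end, ties upstream", {
  nc <- feat("nc", "ncRNA", 1000, 1100, "+")
  g1 <- feat("only", "protein_coding", 5000, 5900, "+")
  expect_equal(nearest_neighbor(nc, g1)$name, "only")

  # equidistant candidates resolve to the ncRNA's upstream side
  ann <- rbind(feat("up", "protein_coding", 100, 900, "+"),     # 5' at 100
               feat("down", "protein_coding", 1900, 2700, "+")) # 5' at 1900
  nc2 <- feat("nc", "ncRNA", 1000, 1100, "+")                   # 5' at 1000
  expect_equal(nearest_neighbor(nc2, ann)$name, "up")

  # exhaustive distance comparison over three candidates
  ann3 <- rbind(feat("a", "protein_coding", 1050, 1500, "+"),   # d = 50
                feat("b", "protein_coding", 1300, 2100, "-"),   # 5' 2100, d = 1100
                feat("c", "protein_coding", 1900, 2500, "+"))   # d = 900
  d <- abs(five_prime_end(ann3, use_mrna_tss = TRUE) - 1000L)
  expect_equal(ann3$name[which.min(d)], "a")
  expect_equal(nearest_neighbor(nc, ann3)$name, "a")
  expect_error(nearest_neighbor(nc, nc), "protein-coding")
})

test_that("classify_arrangement reproduces the three-way taxonomy", {
  # disjoint head-to-head
  d <- classify_arrangement(feat("nc", "ncRNA", 3000, 3100, "-"),
                            feat("g", "protein_coding", 3200, 4000, "+"))
  expect_equal(d$arrangement, "divergent")
  expect_true(d$bona_fide)
  expect_equal(d$antisense_overlap, 0L)
  expect_equal(d$inter_tss_distance, abs(3100L - 3200L))

  co <- classify_arrangement(feat("nc", "ncRNA", 100, 200, "+"),
                             feat("g", "protein_coding", 300, 900, "+"))
  expect_equal(co$arrangement, "codirected")
  expect_true(co$bona_fide)

  # 41-bp 5'UTR duplex: transcript span 100..140 shared
  ov <- classify_arrangement(feat("nc", "ncRNA", 60, 140, "-"),
                             feat("g", "protein_coding", 200, 900, "+",
                                  mrna_tss = 100))
  expect_equal(ov$arrangement, "overlapping_5prime")
  expect_equal(ov$antisense_overlap,
               length(intersect(60:140, 100:900)))  # brute-force enumeration
  expect_equal(ov$antisense_overlap, 41L)
  expect_false(ov$bona_fide)

  # without the 5'UTR knowledge the same pair looks divergent
  ov2 <- classify_arrangement(feat("nc", "ncRNA", 60, 140, "-"),
                              feat("g", "protein_coding", 200, 900, "+"))
  expect_equal(ov2$arrangement, "divergent")

  # tail-to-tail gets its own label outside the three-way enum
  cv <- classify_arrangement(feat("nc", "ncRNA", 100, 200, "+"),
                             feat("g", "protein_coding", 600, 900, "-"))
  expect_equal(cv$arrangement, "convergent")
})

test_that("classification is total and bona_fide implies zero overlap", {
  set.seed(31)
  labels <- c("codirected", "divergent", "overlapping_5prime", "convergent")
  for (i in 1:200) {
    a <- sort(sample(1:60, 2)); b <- sort(sample(1:60, 2))
    s1 <- sample(c("+", "-"), 1); s2 <- sample(c("+", "-"), 1)
    cl <- classify_arrangement(feat("nc", "ncRNA", a[1], a[2], s1),
                               feat("g", "protein_coding", b[1], b[2], s2))
    expect_true(cl$arrangement %in% labels)
    if (cl$bona_fide) expect_equal(cl$antisense_overlap, 0L)
    if (cl$arrangement == "overlapping_5prime")
      expect_gt(cl$antisense_overlap, 0L)
    if (cl$arrangement == "codirected") expect_equal(s1, s2)
    if (cl$arrangement %in% c("divergent", "overlapping_5prime", "convergent"))
      expect_true(s1 != s2)
  }
})

test_that("classification is invariant under genome mirroring", {
  set.seed(37)
  L <- 5000L
  for (i in 1:100) {
    a <- sort(sample(1:4000, 2)); b <- sort(sample(1:4000, 2))
    nc <- feat("nc", "ncRNA", a[1], a[2], sample(c("+", "-"), 1))
    g <- feat("g", "protein_coding", b[1], b[2], sample(c("+", "-"), 1))
    cl <- classify_arrangement(nc, g)
    clm <- classify_arrangement(mirror_features(nc, L), mirror_features(g, L))
    expect_equal(clm$arrangement, cl$arrangement)
    expect_equal(clm$antisense_overlap, cl$antisense_overlap)
    expect_equal(clm$inter_tss_distance, cl$inter_tss_distance)
    expect_equal(clm$bona_fide, cl$bona_fide)
  }
})

test_that("antisense overlap uses transcript spans and refined TSSs", {
  nc <- feat("nc", "ncRNA", 500, 575, "-")
  g <- feat("g", "protein_coding", 700, 1500, "+", mrna_tss = 450)
  # ncRNA fully inside the neighbour's transcript span: entire length
  expect_equal(antisense_overlap_length(nc, g), 76L)

  # disjoint spans
  far <- feat("g", "protein_coding", 700, 1500, "+")
  expect_equal(antisense_overlap_length(nc, far), 0L)

  # an upstream-refined TSS grows the overlap monotonically
  nc2 <- feat("nc", "ncRNA", 300, 440, "-")
  base <- antisense_overlap_length(nc2, g)
  expect_equal(base, 0L)
  grown <- antisense_overlap_length(nc2, g, refined_tss = 470L)
  expect_equal(grown, 21L)
  expect_gt(grown, base)
  expect_error(antisense_overlap_length(nc, feat("x", "protein_coding",
                                                 700, 900, "-")),
               "opposite strands")
})

test_that("inter-TSS distances summarize with the even-n median rule", {
  expect_equal(inter_tss_distance("divergent", 100, 184), 84L)
  expect_equal(inter_tss_distance("divergent", 100, 107), 7L)
  expect_equal(inter_tss_distance("divergent", 100, 100), 0L)
  expect_error(inter_tss_distance("codirected", 1, 2), "divergent")

  calls <- data.frame(arrangement = "divergent",
                      inter_tss_distance = c(7L, 84L, 290L))
  s <- summarize_distances(calls)
  expect_equal(unlist(s), c(n_pairs = 3, min = 7, median = 84, max = 290))
  s2 <- summarize_distances(data.frame(arrangement = "divergent",
                                       inter_tss_distance = c(10L, 20L)))
  expect_equal(s2$median, 15)
  s1 <- summarize_distances(data.frame(arrangement = "divergent",
                                       inter_tss_distance = 42L))
  expect_true(s1$min == 42 && s1$median == 42 && s1$max == 42)
  expect_error(summarize_distances(data.frame(arrangement = "codirected",
                                              inter_tss_distance = NA_integer_)),
               "no divergent")
})

test_that("classify_all recovers planted arrangements on the fixture", {
  cfg <- simulation_config(seed = 3)
  sim <- generate_genome(cfg)
  calls <- classify_all(sim$annotation)
  truth <- sim$truth$pairs
  m <- merge(calls, truth, by = "ncrna", suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$arrangement, m$arrangement.t)
  expect_equal(m$neighbor, m$neighbor.t)
  expect_equal(m$bona_fide, m$bona_fide.t)
  expect_equal(m$antisense_overlap, m$antisense_overlap.t)
  div <- !is.na(m$inter_tss_distance.t)
  expect_equal(m$inter_tss_distance[div], m$inter_tss_distance.t[div])
})
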