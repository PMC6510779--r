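test_that("consensus pattern validation names the bad position", {
  p <- consensus_pattern()
  expect_equal(p$length, 16)
  expect_equal(p$allowed[[6]], c("A", "C", "G", "T"))
  expect_equal(sort(p$allowed[[16]]), c("A", "T"))
  expect_error(consensus_pattern("TGGCAXNNNNNTTGCW"), "position 6")
})

test_that("scanner finds planted instances and nothing in motif-free sequence", {
  g <- AnnotatedGenome(c(ctg1 = "AATGGCAAAAAAATTGCTAA"))
  h <- scan_consensus(g)
  expect_equal(nrow(h), 1)
  expect_equal(h$start + 1L, 3)   # 1-based position 3
  expect_equal(h$strand, "+")
  expect_equal(h$match, "TGGCAAAAAAATTGCT")

  expect_equal(nrow(scan_consensus(AnnotatedGenome(c(c1 = strrep("C", 300))))), 0)

  inst <- "TGGCATTTTTTTTGCA"
  no_feats <- feature_row("x", 0, 3)[0, ]
  g2 <- toy_genome(400, no_feats, seed = 8)
  while (nrow(scan_consensus(g2)) > 0) g2 <- toy_genome(400, no_feats)
  g2 <- plant(g2, "ctg1", 150, revcomp_oracle(inst))
  h2 <- scan_consensus(g2)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 150)
  expect_equal(h2$match, inst)
})

test_that("ambiguity codes in the genome never match", {
  g <- AnnotatedGenome(c(ctg1 = "AATGGCANAAAAATTGCTAA"))
  expect_equal(nrow(scan_consensus(g)), 0)
})

test_that("scanner is equivalent to a brute-force oracle on random sequences", {
  set.seed(500)
  for (i in 1:500) {
    n <- sample(500:3000, 1)
    s <- random_dna(n, gc = runif(1, 0.3, 0.6))
    # spike some near-matches and exact matches to exercise both outcomes
    if (i %% 3 == 0) {
      inst <- "TGGCAACGTACTTGCT"
      substr(s, 100, 100 + nchar(inst) - 1) <- inst
    }
    g <- AnnotatedGenome(c(ctg1 = s))
    got <- scan_consensus(g)
    want <- oracle_scan(s, "TGGCANNNNNNTTGCW")
    expect_identical(got$start[got$strand == "+"], want$plus)
    expect_identical(got$start[got$strand == "-"], want$minus)
  }
})

test_that("scanner agrees with the position-by-position oracle", {
  set.seed(77)
  for (i in 1:15) {
    s <- random_dna(300)
    substr(s, 50, 65) <- "TGGCAGTCGACTTGCA"
    got <- scan_consensus(AnnotatedGenome(c(ctg1 = s)), strands = "+")
    expect_identical(got$start, oracle_scan_slow(s, "TGGCANNNNNNTTGCW"))
  }
})

test_that("upstream-window assignment respects the inclusive 500 bp boundary", {
  inst <- "TGGCAGGGGGGTTGCA"
  base <- function(d) {
    f <- feature_row("g1", 1000, 1600, "+")
    g <- toy_genome(2000, f, seed = 21)
    while (nrow(scan_consensus(g)) > 0) g <- toy_genome(2000, f)
    plant(g, "ctg1", 1000 - d - 16, inst)
  }
  g <- base(120)
  a <- assign_regulon(scan_consensus(g), g)
  expect_equal(a$gene_id, "g1")
  expect_equal(a$distance, 120)

  a <- assign_regulon(scan_consensus(base(500)), base(500))
  expect_equal(a$distance, 500)

  a <- assign_regulon(scan_consensus(base(501)), base(501))
  expect_true(is.na(a$gene_id))
})

test_that("assignment is strand-matched and never crosses contigs", {
  inst <- "TGGCAGGGGGGTTGCA"
  f <- feature_row("gminus", 1000, 1600, "-")
  g <- toy_genome(2000, f, seed = 22)
  while (nrow(scan_consensus(g)) > 0) g <- toy_genome(2000, f)
  g <- plant(g, "ctg1", 900, inst)  # plus-strand motif upstream of minus gene
  a <- assign_regulon(scan_consensus(g), g)
  expect_true(is.na(a$gene_id))

  # CDS on another contig just downstream in coordinates is ignored
  g2 <- AnnotatedGenome(
    c(ctgA = paste0(strrep("C", 100), inst, strrep("C", 100)),
      ctgB = strrep("C", 2000)),
    feature_row("far", 150, 450, "+", contig = "ctgB"))
  a2 <- assign_regulon(scan_consensus(g2), g2)
  expect_true(is.na(a2$gene_id))
})

test_that("mirrored genomes yield mirrored assignments", {
  sim <- generate_genome(genome_sim_config(), seed = 13)
  a <- assign_regulon(scan_consensus(sim$genome), sim$genome)
  m <- mirror_genome(sim$genome)
  am <- assign_regulon(scan_consensus(m), m)
  expect_equal(sort(am$gene_id), sort(a$gene_id))
  expect_equal(am$distance[order(am$gene_id)], a$distance[order(a$gene_id)])
})

test_that("operon extension matches a brute-force gap-check oracle", {
  f <- rbind(feature_row("a", 100, 400, "+"), feature_row("b", 420, 700, "+"),
             feature_row("c", 720, 900, "+"), feature_row("d", 1100, 1300, "+"))
  g <- toy_genome(2000, f, seed = 31)
  expect_equal(extend_operon(g, "a", max_gap = 50), c("a", "b", "c"))

  f2 <- rbind(feature_row("a", 100, 400, "+"), feature_row("b", 420, 700, "-"))
  g2 <- toy_genome(1000, f2, seed = 32)
  expect_equal(extend_operon(g2, "a", max_gap = 50), "a")

  oracle_unit <- function(feats, id, max_gap) {
    feats <- feats[order(feats$start), ]
    i <- which(feats$feature_id == id)
    dir <- if (feats$strand[i] == "+") 1 else -1
    unit <- id
    while (TRUE) {
      j <- i + dir
      if (j < 1 || j > nrow(feats)) break
      if (feats$strand[j] != feats$strand[i]) break
      gap <- if (dir == 1) feats$start[j] - feats$end[i]
             else feats$start[i] - feats$end[j]
      if (gap > max_gap) break
      unit <- c(unit, feats$feature_id[j]); i <- j
    }
    unit
  }
  set.seed(200)
  for (trial in 1:200) {
    k <- sample(3:10, 1)
    starts <- sort(sample(seq(0, 4000, by = 10), k))
    lens <- sample(seq(30, 300, by = 3), k, replace = TRUE)
    ends <- pmin(starts + lens, c(starts[-1] - 1, 5000))
    ok <- ends > starts
    feats <- do.call(rbind, lapply(which(ok), function(i)
      feature_row(paste0("g", i), starts[i], ends[i],
                  sample(c("+", "-"), 1))))
    g <- AnnotatedGenome(c(ctg1 = strrep("A", 5000)), feats)
    id <- sample(feats$feature_id, 1)
    mg <- sample(c(10, 50, 200), 1)
    expect_equal(extend_operon(g, id, max_gap = mg),
                 oracle_unit(feats, id, mg))
  }
})

test_that("EBP vicinity flags follow product keywords and span", {
  f <- rbind(feature_row("tgt", 1000, 1400, "+"),
             feature_row("act", 1500, 1900, "+",
                         product = "enhancer binding protein"))
  g <- toy_genome(3000, f, seed = 41)
  while (nrow(scan_consensus(g)) > 0) g <- toy_genome(3000, f)
  g <- plant(g, "ctg1", 900, "TGGCAGGGGGGTTGCA")
  a <- flag_ebp_vicinity(assign_regulon(scan_consensus(g), g), g)
  expect_true(a$ebp_nearby)
  expect_equal(a$ebp_gene_id, "act")
  a2 <- flag_ebp_vicinity(assign_regulon(scan_consensus(g), g), g, span = 50)
  expect_false(a2$ebp_nearby)
  g$features$product[2] <- "plain old kinase"
  a3 <- flag_ebp_vicinity(assign_regulon(scan_consensus(g), g), g)
  expect_false(a3$ebp_nearby)
})

test_that("planted EBP placement is recovered from generator truth", {
  sim <- generate_genome(genome_sim_config(), seed = 3)
  a <- flag_ebp_vicinity(assign_regulon(scan_consensus(sim$genome),
                                        sim$genome), sim$genome)
  u <- sim$truth$units
  for (i in seq_len(nrow(a))) {
    expect_equal(a$ebp_nearby[i], u$ebp_nearby[u$unit == a$gene_id[i]])
    if (a$ebp_nearby[i])
      expect_true(a$ebp_gene_id[i] %in% sim$truth$ebp_genes)
  }
})

test_that("closed-form hit expectation matches the degenerate-position count", {
  g <- AnnotatedGenome(c(c1 = strrep("A", 1000)))
  st <- scan_statistics(scan_consensus(g), g)
  expect_equal(st$expected_hits_random, 2 * (1000 - 15) / 524288)
  st2 <- scan_statistics(data.frame(), g, pattern = strrep("N", 16))
  expect_equal(st2$expected_hits_random, 2 * (1000 - 15))
})
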