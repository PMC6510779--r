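test_that("deletions shorten contigs by exactly the deleted length", {
  g <- toy_genome(10000, feature_row("x", 100, 400), seed = 61)
  d <- deletion_design("ctg1", 2001, 2736)   # 736 bp, 1-based inclusive
  expect_equal(d$length, 736)
  ed <- apply_deletion(g, d)
  expect_equal(nchar(ed$contigs[[1]]), 9264)
  # zero-length deletion leaves the genome unchanged
  d0 <- deletion_design("ctg1", 2001, 2000)
  ed0 <- apply_deletion(g, d0)
  expect_equal(ed0$contigs, g$contigs)
  expect_error(apply_deletion(g, deletion_design("ctg1", 9000, 10500)),
               "outside contig")
})

test_that("features shift and truncate per a hand-shift oracle", {
  f <- rbind(feature_row("up", 100, 400),
             feature_row("span", 900, 1500),
             feature_row("down", 3000, 3300))
  g <- toy_genome(5000, f, seed = 62)
  d <- deletion_design("ctg1", 1001, 1200)   # internal [1000, 1200)
  ed <- apply_deletion(g, d)
  ef <- ed$features
  expect_equal(ef[ef$feature_id == "up", c("start", "end")],
               data.frame(start = 100L, end = 400L, row.names = 1L))
  expect_equal(unlist(ef[ef$feature_id == "down", c("start", "end")]),
               c(start = 2800L, end = 3100L))
  sp <- ef[ef$feature_id == "span", ]
  expect_true(sp$truncated)
  expect_equal(unlist(sp[c("start", "end")]), c(start = 900L, end = 1300L))
  # fully swallowed features are dropped and reported
  d2 <- deletion_design("ctg1", 801, 1600)
  ed2 <- apply_deletion(g, d2)
  expect_equal(attr(ed2, "removed"), "span")
  expect_false("span" %in% ed2$features$feature_id)
})

test_that("the deletion fixture reproduces knockout verification arithmetic", {
  fx <- deletion_locus_fixture(seed = 2)
  wt <- in_silico_pcr(fx$genome, fx$forward, fx$reverse)
  expect_equal(wt$length, 1406)
  ed <- apply_deletion(fx$genome, fx$design)
  expect_equal(in_silico_pcr(ed, fx$forward, fx$reverse)$length, 670)
  expect_equal(wt$length - 670, fx$design$length)
  cds <- extract_cds(fx$genome, fx$cds_id)
  expect_equal(nchar(translate_cds(cds)) - 1L, 463)  # full-length protein
  expect_equal(residual_orf(cds, fx$cds_deletion[1], fx$cds_deletion[2]), 13L)
})

test_that("adjacent facing primers give the minimal amplicon", {
  set.seed(63)
  fwd <- "ACGTACGTGGATCCAA"
  rev <- "TTGGCCAATTGGCCTT"
  s <- paste0(random_dna(200), fwd, revcomp_oracle(rev), random_dna(200))
  g <- AnnotatedGenome(c(ctg1 = s))
  r <- in_silico_pcr(g, fwd, rev)
  expect_equal(r$length, nchar(fwd) + nchar(rev))
})

test_that("non-unique or absent binding sites are errors listing sites", {
  set.seed(64)
  fwd <- "ACGTACGTGGATCCAA"
  rev <- "TTGGCCAATTGGCCTT"
  s <- paste0(fwd, random_dna(100), fwd, random_dna(100),
              revcomp_oracle(rev))
  g <- AnnotatedGenome(c(ctg1 = s))
  expect_error(in_silico_pcr(g, fwd, rev), "binds 2 site")
  expect_error(in_silico_pcr(g, "GGGGGGGGGGGGCCCC", rev), "binds 0 site")
})

test_that("amplicon lengths equal a substring-search oracle on random loci", {
  set.seed(65)
  for (trial in 1:100) {
    n <- sample(1500:4000, 1)
    s <- random_dna(n)
    a <- sample(seq(1, n - 1000), 1)
    b <- a + sample(300:900, 1)
    fwd <- substr(s, a, a + 19)
    rev <- revcomp_oracle(substr(s, b - 19, b))
    g <- AnnotatedGenome(c(ctg1 = s))
    fhits <- gregexpr(fwd, s, fixed = TRUE)[[1]]
    rhits <- gregexpr(revcomp_oracle(rev), s, fixed = TRUE)[[1]]
    if (length(fhits) != 1 || length(rhits) != 1) next
    expect_equal(in_silico_pcr(g, fwd, rev)$length, b - a + 1)
  }
})

test_that("WT and edited amplicons differ by the deleted length", {
  set.seed(66)
  for (trial in 1:20) {
    s <- random_dna(6000)
    fwd <- substr(s, 501, 520)
    rev <- revcomp_oracle(substr(s, 4481, 4500))
    g <- AnnotatedGenome(c(ctg1 = s))
    ok <- length(gregexpr(fwd, s, fixed = TRUE)[[1]]) == 1 &&
      length(gregexpr(revcomp_oracle(rev), s, fixed = TRUE)[[1]]) == 1
    if (!ok) next
    len <- sample(100:1000, 1)
    d <- deletion_design("ctg1", 1001, 1000 + len)
    wt <- in_silico_pcr(g, fwd, rev)$length
    ed <- in_silico_pcr(apply_deletion(g, d), fwd, rev)$length
    expect_equal(wt - ed, len)
  }
})

test_that("protospacer enumeration matches an exhaustive two-strand oracle", {
  ps_oracle <- function(s, s0, e0) {
    out <- list()
    for (i in 0:(nchar(s) - 23)) {
      w <- substr(s, i + 1, i + 23)
      if (grepl("[^ACGT]", w)) next
      if (substr(w, 22, 23) == "GG") {       # plus strand: spacer then NGG
        cut0 <- i + 16
        if (cut0 >= s0 && cut0 < e0)
          out[[length(out) + 1]] <- data.frame(
            sequence = substr(w, 1, 20), strand = "+", start = i)
      }
      if (substr(w, 1, 2) == "CC") {         # minus strand: CCN then spacer
        cut0 <- i + 23 - 17
        if (cut0 >= s0 && cut0 < e0)
          out[[length(out) + 1]] <- data.frame(
            sequence = revcomp_oracle(substr(w, 4, 23)), strand = "-",
            start = i + 3)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  set.seed(67)
  s <- random_dna(2000)
  g <- AnnotatedGenome(c(ctg1 = s))
  got <- enumerate_protospacers(g, "ctg1", 501, 1500)
  want <- ps_oracle(s, 500, 1500)
  expect_equal(nrow(got), nrow(want))
  key <- function(x) sort(paste(x$sequence, x$strand, x$start))
  expect_equal(key(got), key(want))
})

test_that("constructed PAM contexts behave at the boundaries", {
  spacer <- "ACGTACGTACGTACGTACGT"
  s <- paste0(strrep("A", 50), spacer, "AGG", strrep("A", 50))
  g <- AnnotatedGenome(c(ctg1 = s))
  got <- enumerate_protospacers(g, "ctg1", 60, 70)
  expect_true(any(got$sequence == spacer & got$strand == "+"))
  # no GG/CC anywhere: no protospacers at all
  g2 <- AnnotatedGenome(c(ctg1 = strrep("AT", 500)))
  expect_equal(nrow(enumerate_protospacers(g2, "ctg1", 100, 900)), 0)
})

test_that("residual ORF counting follows splice-translate-scan", {
  set.seed(68)
  # in-frame deletion of k codons with no new stop: n - k residues remain
  codons <- c("ATG", sample(setdiff(names(CODON_TABLE_ORACLE),
                                    c("TAA", "TAG", "TGA")), 120,
                            replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  n <- length(codons) - 1   # residues in the full protein
  k <- 10
  del_start <- 3 * 20 + 1
  expect_equal(residual_orf(cds, del_start, del_start + 3 * k - 1), n - k)

  oracle <- function(cds, a, b) {
    sp <- paste0(substr(cds, 1, a - 1), substr(cds, b + 1, nchar(cds)))
    sp <- substr(sp, 1, nchar(sp) - nchar(sp) %% 3)
    aa <- strsplit(oracle_translate(sp), "")[[1]]
    st <- which(aa == "X")
    if (length(st)) st[1] - 1L else length(aa)
  }
  for (trial in 1:500) {
    nc <- sample(30:150, 1)
    cds <- paste(c("ATG", sample(names(CODON_TABLE_ORACLE), nc - 2,
                                 replace = TRUE), "TAA"), collapse = "")
    a <- sample(4:(3 * nc - 10), 1)
    b <- sample(a:(3 * nc), 1)
    expect_equal(residual_orf(cds, a, b), oracle(cds, a, b))
  }
  expect_message(r <- residual_orf(cds, 2, 30), "no ORF")
  expect_true(is.na(r))
})
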