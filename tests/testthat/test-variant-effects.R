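# a CDS of 400 CAA codons with selected codons overwritten
patterned_cds <- function(n_codons = 400, at = list()) {
  codons <- rep("CAA", n_codons)
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  for (i in names(at)) codons[as.integer(i)] <- at[[i]]
  paste(codons, collapse = "")
}

cds_genome <- function(cds, strand = "+", offset = 500) {
  n <- nchar(cds)
  g <- toy_genome(offset + n + 500,
                  feature_row("gene1", offset, offset + n, strand,
                              product = "sigma-54 factor"))
  plant(g, "ctg1", offset, if (strand == "+") cds else revcomp_oracle(cds))
}

test_that("a serine-to-phenylalanine codon edit reports S -> F at codon 366", {
  cds <- patterned_cds(400, at = list(`366` = "TCT"))
  g <- cds_genome(cds)
  # CDS position 1097 = codon 366, offset 2: TCT -> TTT
  r <- annotate_variant(g, "ctg1", 500 + 1097, "C", "T")
  expect_equal(r$cds_position, 1097)
  expect_equal(r$aa_change, "S -> F")
  expect_equal(r$protein_effect, "Substitution")
  expect_equal(r$locus_tag, "gene1")
})

test_that("nonsense, synonymous and intergenic classes classify correctly", {
  cds <- patterned_cds(400, at = list(`100` = "CAA", `200` = "CTG"))
  g <- cds_genome(cds)
  r <- annotate_variant(g, "ctg1", 500 + 3 * 99 + 1, "C", "T")  # CAA -> TAA
  expect_equal(r$aa_change, "Q -> X")
  expect_equal(r$protein_effect, "Truncation")
  r2 <- annotate_variant(g, "ctg1", 500 + 3 * 199 + 1, "C", "T") # CTG -> TTG
  expect_equal(r2$protein_effect, "None")
  expect_equal(r2$aa_change, "none")
  r3 <- annotate_variant(g, "ctg1", 100,
                         substr(g$contigs[[1]], 100, 100),
                         setdiff(c("A", "C", "G", "T"),
                                 substr(g$contigs[[1]], 100, 100))[1])
  expect_equal(r3$protein_effect, "Intergenic")
  expect_true(is.na(r3$cds_position))
  expect_equal(r3$locus_tag, "N/A")
})

test_that("minus-strand variants are complemented before codon substitution", {
  cds <- patterned_cds(400, at = list(`366` = "TCT"))
  g <- cds_genome(cds, strand = "-", offset = 500)
  # coding C at CDS position 1097 is genomic G on the plus strand
  pos1 <- (500 + 1200) - 1097 + 1
  expect_equal(substr(g$contigs[[1]], pos1, pos1), "G")
  r <- annotate_variant(g, "ctg1", pos1, "G", "A")
  expect_equal(r$cds_position, 1097)
  expect_equal(r$aa_change, "S -> F")
  expect_equal(r$protein_effect, "Substitution")
})

test_that("reference mismatches and indels are rejected informatively", {
  g <- cds_genome(patterned_cds(50))
  pos <- 500 + 4
  obs <- substr(g$contigs[[1]], pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), obs)[1]
  other <- setdiff(c("A", "C", "G", "T"), c(obs, wrong))[1]
  expect_error(annotate_variant(g, "ctg1", pos, wrong, other),
               paste0("genome has ", obs))
  expect_error(annotate_variant(g, "ctg1", pos, obs, "TT"),
               "single-nucleotide")
})

test_that("variants in overlapping CDS annotate once per feature", {
  cds <- patterned_cds(100)
  f <- rbind(feature_row("ga", 500, 800, "+"),
             feature_row("gb", 600, 900, "+"))
  g <- toy_genome(2000, f, seed = 51)
  g <- plant(g, "ctg1", 500, paste0(substr(cds, 1, 300)))
  pos <- 701
  r <- annotate_variant(g, "ctg1", pos, substr(g$contigs[[1]], pos, pos),
                        setdiff(c("A", "G"),
                                substr(g$contigs[[1]], pos, pos))[1])
  expect_equal(sort(r$locus_tag), c("ga", "gb"))
})

test_that("tables deduplicate, order by position and aggregate errors", {
  g <- cds_genome(patterned_cds(100, at = list(`50` = "CAA")))
  v <- data.frame(contig_id = "ctg1",
                  genome_position = c(500 + 148, 500 + 148, 100),
                  ref_base = c("C", "C", substr(g$contigs[[1]], 100, 100)),
                  alt_base = c("T", "T", "N"))
  v$alt_base[3] <- setdiff(c("A", "C", "G", "T"),
                           substr(g$contigs[[1]], 100, 100))[1]
  expect_warning(tab <- annotate_table(g, v), "duplicate")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$genome_position, sort(tab$genome_position))

  empty <- annotate_table(g, v[0, ])
  expect_equal(nrow(empty), 0)

  v2 <- data.frame(contig_id = "ctg1", genome_position = 500 + 148,
                   ref_base = "G", alt_base = "A")
  tab2 <- suppressWarnings(annotate_table(g, v2))
  expect_equal(nrow(tab2), 0)
  expect_match(attr(tab2, "errors"), "reference mismatch")
})

test_that("VCF round trip preserves variants; multi-allelic records split", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "v.vcf")
  v <- data.frame(contig_id = "c1", genome_position = c(10, 20),
                  ref_base = c("A", "C"), alt_base = c("G", "T"))
  write_variants_vcf(v, p)
  expect_equal(read_variants_vcf(p), v)
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "c1\t5\t.\tC\tT,G\t.\t.\t."), p)
  expect_warning(v2 <- read_variants_vcf(p), "multi-allelic")
  expect_equal(v2$alt_base, "T")
})

test_that("planted variants round-trip through the annotator", {
  sim <- generate_genome(genome_sim_config(), seed = 23)
  gv <- generate_variants(sim$genome,
                          counts = c(Substitution = 10, Truncation = 1,
                                     None = 2, Intergenic = 2), seed = 23)
  expect_equal(nrow(gv$variants), 15)
  tab <- annotate_table(sim$genome, gv$variants)
  expect_equal(tab$protein_effect, gv$truth$class)
  expect_equal(as.integer(table(tab$protein_effect)[
    c("Substitution", "Truncation", "None", "Intergenic")]),
    c(10L, 1L, 2L, 2L))
  # every Substitution row satisfies the codon arithmetic invariant
  sub <- tab[tab$protein_effect == "Substitution", ]
  ci <- (sub$cds_position - 1) %/% 3 + 1
  expect_true(all(ci >= 1))
  expect_equal(3 * (ci - 1) + ((sub$cds_position - 1) %% 3 + 1),
               sub$cds_position)
})

test_that("effects are invariant under genome mirroring", {
  sim <- generate_genome(genome_sim_config(), seed = 29)
  gv <- generate_variants(sim$genome,
                          counts = c(Substitution = 5, Truncation = 1,
                                     None = 2, Intergenic = 1), seed = 29)
  tab <- annotate_table(sim$genome, gv$variants)
  m <- mirror_genome(sim$genome)
  L <- nchar(sim$genome$contigs[[1]])
  mv <- gv$variants
  mv$genome_position <- L - mv$genome_position + 1
  mv$ref_base <- revcomp_oracle(mv$ref_base)
  mv$alt_base <- revcomp_oracle(mv$alt_base)
  mtab <- annotate_table(m, mv)
  expect_equal(mtab$protein_effect[order(mtab$cds_position)],
               tab$protein_effect[order(tab$cds_position)])
  expect_equal(sort(mtab$aa_change), sort(tab$aa_change))
})
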