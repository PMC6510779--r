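# Independent oracles, deliberately implemented on different machinery than
# the package (regex / plain-R loops / hand-typed tables).

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

pattern_to_regex <- function(pattern) {
  paste(IUPAC_REGEX[strsplit(pattern, "")[[1]]], collapse = "")
}

revcomp_oracle <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(strsplit(x, ""), function(ch)
           paste(rev(ch), collapse = ""), character(1)))
}

# overlap-aware regex scan of both strands; returns 0-based starts per strand
oracle_scan <- function(seq, pattern) {
  rx <- pattern_to_regex(pattern)
  find <- function(p, s) {
    m <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m) - 1L
  }
  list(plus = find(rx, seq),
       minus = find(pattern_to_regex(revcomp_oracle(pattern)), seq))
}

# character-by-character sliding window scan (one strand)
oracle_scan_slow <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  pat <- strsplit(pattern, "")[[1]]
  k <- length(pat)
  hits <- integer()
  for (i in seq_len(max(0, length(chars) - k + 1))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      b <- chars[i + j - 1]
      if (!b %in% c("A", "C", "G", "T") || !b %in% sets[[pat[j]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# hand-typed bacterial/standard codon table (stop as X)
CODON_TABLE_ORACLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "X", TAG = "X",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "X", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(CODON_TABLE_ORACLE[codons], collapse = "")
}

oracle_ddcq <- function(cq, reference, calibrator) {
  mean_cq <- aggregate(cq ~ sample_id + target_id, cq, mean)
  g <- function(s, t) mean_cq$cq[mean_cq$sample_id == s &
                                   mean_cq$target_id == t]
  out <- list()
  for (s in unique(cq$sample_id)) {
    for (t in setdiff(unique(cq$target_id), reference)) {
      ddcq <- (g(s, t) - g(calibrator, t)) -
        (g(s, reference) - g(calibrator, reference))
      out[[length(out) + 1]] <- data.frame(sample_id = s, target_id = t,
                                           ratio = 2^(-ddcq))
    }
  }
  do.call(rbind, out)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# genome whose features are specified directly over a random backbone
toy_genome <- function(length, features, seed = NULL, contig = "ctg1") {
  if (!is.null(seed)) set.seed(seed)
  AnnotatedGenome(setNames(random_dna(length), contig), features)
}

feature_row <- function(id, start, end, strand = "+", kind = "CDS",
                        product = "", contig = "ctg1") {
  data.frame(feature_id = id, contig_id = contig, start = start, end = end,
             strand = strand, kind = kind, product = product,
             stringsAsFactors = FALSE)
}

# plant a subsequence into a contig at a 0-based offset
plant <- function(genome, contig, at0, what) {
  s <- genome$contigs[[contig]]
  substr(s, at0 + 1, at0 + nchar(what)) <- what
  genome$contigs[[contig]] <- s
  genome
}

# mirror a genome: reverse-complement contigs, flip features
mirror_genome <- function(genome) {
  L <- nchar(genome$contigs)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    len <- L[[f$contig_id[i]]]
    s <- f$start[i]
    f$start[i] <- len - f$end[i]
    f$end[i] <- len - s
    f$strand[i] <- if (f$strand[i] == "+") "-" else "+"
  }
  AnnotatedGenome(vapply(genome$contigs, function(s)
    revcomp_oracle(s), character(1)), f, genome$source_label)
}
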