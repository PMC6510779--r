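#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   readDNAStringSet writeXStringSet reverseComplement translate getGeneticCode
#'   matchPattern
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics start end strand
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom S4Vectors mcols
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Coordinates: internal representation is 0-based half-open [start, end);
# every file and report boundary (GFF3, VCF, Table-1-style TSV) is 1-based
# inclusive. to_file()/to_internal() are the only conversion points.
to_internal_start <- function(start1) as.integer(start1) - 1L
to_file_start <- function(start0) as.integer(start0) + 1L

#' Construct an annotated genome
#'
#' Container for one or more contig sequences plus strand-aware gene/CDS
#' features, the common currency of all downstream stages (motif scanning,
#' variant annotation, deletion simulation).
#'
#' @param contigs named character vector of uppercase nucleotide sequences
#'   (IUPAC codes allowed; `N` never matches the consensus scanner).
#' @param features data.frame with columns `feature_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `kind` (`"gene"` or
#'   `"CDS"`), `product` (free text).
#' @param source_label free-text provenance label, e.g. a strain name.
#' @return an object of class `AnnotatedGenome`.
#' @export
AnnotatedGenome <- function(contigs, features = empty_features(),
                            source_label = "") {
  stopifnot(is.character(contigs), length(contigs) >= 1)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must be uniquely named")
  contigs[] <- toupper(contigs)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", contigs)
  if (any(bad))
    stop("contig ", names(contigs)[bad][1], " contains non-IUPAC characters")
  features <- as_feature_frame(features)
  clen <- nchar(contigs)
  if (nrow(features)) {
    unknown <- setdiff(features$contig_id, names(contigs))
    if (length(unknown))
      stop("feature contig id not in genome: ", unknown[1])
    out <- features$start < 0 | features$end > clen[features$contig_id]
    if (any(out))
      stop("feature outside contig bounds: ", features$feature_id[out][1])
    if (any(features$start >= features$end))
      stop("feature with start >= end: ",
           features$feature_id[features$start >= features$end][1])
  }
  structure(list(contigs = contigs, features = features,
                 source_label = source_label),
            class = "AnnotatedGenome")
}

empty_features <- function() {
  data.frame(feature_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             kind = character(), product = character(),
             stringsAsFactors = FALSE)
}

as_feature_frame <- function(features) {
  need <- c("feature_id", "contig_id", "start", "end", "strand", "kind",
            "product")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features missing columns: ",
                         paste(miss, collapse = ", "))
  features <- as.data.frame(features, stringsAsFactors = FALSE)[need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  if (!all(features$kind %in% c("gene", "CDS")))
    stop("feature kind must be 'gene' or 'CDS'")
  rownames(features) <- NULL
  features
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf("AnnotatedGenome '%s': %d contig(s), %s bp, %d feature(s)\n",
              x$source_label, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

cds_features <- function(genome) {
  genome$features[genome$features$kind == "CDS", , drop = FALSE]
}

get_feature <- function(genome, feature_id, kind = NULL) {
  f <- genome$features
  if (!is.null(kind)) f <- f[f$kind == kind, , drop = FALSE]
  i <- match(feature_id, f$feature_id)
  if (is.na(i)) stop("unknown feature id: ", feature_id)
  f[i, , drop = FALSE]
}

#' Reverse complement of a nucleotide string
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Load an annotated genome from files
#'
#' Reads a FASTA plus a GFF3 annotation, or a GenBank flat file (which may
#' carry its own sequence, in which case `fasta_path` may be `NULL`).
#' File coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention. GFF3 feature ids are taken from `ID`, falling back to
#' `locus_tag`; GenBank CDS ids come from `locus_tag`. Records of other types
#' are skipped and listed in the `skipped` attribute of the result.
#'
#' @param fasta_path path to a (multi-record) FASTA file, or `NULL` for a
#'   sequence-bearing GenBank file.
#' @param annotation_path path to the GFF3 or GenBank annotation.
#' @param dialect `"gff3"` or `"genbank"`.
#' @param source_label free-text label stored on the genome.
#' @return an [AnnotatedGenome]; attribute `skipped` holds a character vector
#'   describing skipped annotation records.
#' @export
load_genome <- function(fasta_path, annotation_path,
                        dialect = c("gff3", "genbank"), source_label = "") {
  dialect <- match.arg(dialect)
  if (dialect == "genbank") {
    gb <- read_genbank_flat(annotation_path)
    contigs <- gb$contigs
    if (!length(contigs)) {
      if (is.null(fasta_path)) stop("GenBank file carries no sequence and no FASTA given")
      contigs <- read_fasta_contigs(fasta_path)
    }
    feats <- gb$features
    skipped <- gb$skipped
  } else {
    if (is.null(fasta_path)) stop("GFF3 dialect requires a FASTA file")
    contigs <- read_fasta_contigs(fasta_path)
    gr <- rtracklayer::import(annotation_path, format = "gff3")
    keep <- as.character(gr$type) %in% c("gene", "CDS")
    skipped <- if (any(!keep))
      sprintf("%s record(s) of type %s skipped", sum(!keep),
              paste(unique(as.character(gr$type)[!keep]), collapse = "/"))
    else character()
    gr <- gr[keep]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
    if (!is.null(gr$locus_tag))
      ids <- ifelse(is.na(ids) | ids == "", as.character(gr$locus_tag), ids)
    if (anyNA(ids)) stop("GFF3 record without ID or locus_tag")
    feats <- data.frame(
      feature_id = ids,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = to_internal_start(GenomicRanges::start(gr)),
      end = as.integer(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      kind = as.character(gr$type),
      product = if (!is.null(gr$product)) as.character(gr$product) else "",
      stringsAsFactors = FALSE)
    feats$product[is.na(feats$product)] <- ""
    if (any(!feats$strand %in% c("+", "-")))
      stop("unstranded annotation record: ",
           feats$feature_id[!feats$strand %in% c("+", "-")][1])
  }
  unknown <- setdiff(feats$contig_id, names(contigs))
  if (length(unknown)) stop("annotation contig id not found in sequence: ",
                            unknown[1])
  g <- AnnotatedGenome(contigs, feats, source_label = source_label)
  attr(g, "skipped") <- skipped
  g
}

read_fasta_contigs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(as.character(ss), names(ss))
}

#' Write a genome as FASTA + GFF3
#'
#' Inverse of [load_genome] for the GFF3 dialect; coordinates are emitted
#' 1-based inclusive.
#'
#' @param genome an [AnnotatedGenome].
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs),
                              fasta_path)
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    f$contig_id,
    IRanges::IRanges(to_file_start(f$start), f$end),
    strand = f$strand)
  gr$type <- f$kind
  gr$ID <- f$feature_id
  gr$locus_tag <- f$feature_id
  gr$product <- f$product
  suppressWarnings(rtracklayer::export(gr, gff3_path, format = "gff3"))
  invisible(genome)
}

# Minimal GenBank flat-file reader: LOCUS name, gene/CDS features with
# locus_tag and complement() spans, ORIGIN sequence. Joins are rejected
# (bacterial CDS are unspliced).
read_genbank_flat <- function(path) {
  lines <- readLines(path)
  loci <- grep("^LOCUS", lines)
  if (!length(loci)) stop("not a GenBank flat file: no LOCUS line")
  ends <- c(loci[-1] - 1L, length(lines))
  contigs <- character()
  feats <- list()
  skipped <- character()
  for (k in seq_along(loci)) {
    block <- lines[loci[k]:ends[k]]
    name <- strsplit(trimws(sub("^LOCUS", "", block[1])), "\\s+")[[1]][1]
    ori <- grep("^ORIGIN", block)
    seq <- ""
    if (length(ori)) {
      seqlines <- block[(ori[1] + 1):length(block)]
      seqlines <- seqlines[!grepl("^//", seqlines)]
      seq <- toupper(gsub("[^a-zA-Z]", "", paste(seqlines, collapse = "")))
    }
    if (nzchar(seq)) contigs[name] <- seq
    fstart <- grep("^FEATURES", block)
    if (!length(fstart)) next
    fend <- if (length(ori)) ori[1] - 1L else length(block)
    flines <- block[(fstart + 1):fend]
    # a feature record starts at column 6; qualifiers are indented further
    starts <- grep("^ {5}\\S", flines)
    for (j in seq_along(starts)) {
      to <- if (j < length(starts)) starts[j + 1] - 1L else length(flines)
      rec <- flines[starts[j]:to]
      head1 <- trimws(rec[1])
      kind <- sub("\\s.*$", "", head1)
      locstr <- trimws(sub("^\\S+\\s+", "", head1))
      if (!kind %in% c("gene", "CDS")) {
        skipped <- c(skipped, sprintf("%s feature skipped (%s)", kind, name))
        next
      }
      if (grepl("join", locstr)) stop("joined locations unsupported: ", locstr)
      strand <- if (grepl("^complement", locstr)) "-" else "+"
      nums <- as.integer(regmatches(locstr, gregexpr("[0-9]+", locstr))[[1]])
      if (length(nums) != 2) stop("cannot parse location: ", locstr)
      qual <- paste(trimws(rec[-1]), collapse = " ")
      tag <- sub('.*?/locus_tag="([^"]*)".*', "\\1", qual)
      if (identical(tag, qual)) tag <- NA_character_
      prod <- sub('.*?/product="([^"]*)".*', "\\1", qual)
      if (identical(prod, qual)) prod <- ""
      feats[[length(feats) + 1]] <- data.frame(
        feature_id = tag, contig_id = name,
        start = to_internal_start(nums[1]), end = nums[2],
        strand = strand, kind = kind, product = prod,
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  if (nrow(features) && anyNA(features$feature_id))
    stop("GenBank CDS without locus_tag")
  list(contigs = contigs, features = features, skipped = skipped)
}

#' Extract the coding-strand sequence of a CDS
#'
#' @param genome an [AnnotatedGenome].
#' @param feature_id locus tag of a CDS feature.
#' @return nucleotide string, reverse-complemented for minus-strand features so
#'   that position 1 is the first base of the start codon.
#' @export
extract_cds <- function(genome, feature_id) {
  f <- get_feature(genome, feature_id, kind = "CDS")
  s <- substr(genome$contigs[[f$contig_id]], f$start + 1L, f$end)
  if (f$strand == "-") s <- revcomp(s)
  s
}

# genetic-code tables cached per NCBI id; start codons are not handled
# specially (effect classification does not need them)
.genetic_codes <- new.env(parent = emptyenv())
genetic_code_lookup <- function(table) {
  key <- paste0("t", table)
  if (is.null(.genetic_codes[[key]]))
    .genetic_codes[[key]] <- Biostrings::getGeneticCode(table)
  .genetic_codes[[key]]
}

#' Translate a coding sequence (bacterial code, table 11)
#'
#' Stop codons are rendered as `"X"`, the truncation sentinel used in the
#' mutation-effect reports (a nonsense change prints as e.g. `Q -> X`).
#' Codons containing ambiguity codes also render `"X"`. Internal stops are
#' permitted and flagged via the `internal_stops` attribute.
#'
#' @param sequence nucleotide string, length divisible by 3.
#' @param table NCBI translation table id; only `"11"` is supported.
#' @return amino-acid string; attribute `internal_stops` gives positions of
#'   stops before the final codon.
#' @export
translate_cds <- function(sequence, table = "11") {
  n <- nchar(sequence)
  if (n %% 3 != 0)
    stop("sequence length ", n, " not divisible by 3 (remainder ", n %% 3, ")")
  if (n == 0) return("")
  code <- genetic_code_lookup(table)
  codons <- substring(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
  aas <- unname(code[codons])
  aas[is.na(aas)] <- "X"       # codons carrying ambiguity codes
  aa <- chartr("*", "X", paste(aas, collapse = ""))
  stops <- which(strsplit(aa, "")[[1]] == "X")
  internal <- stops[stops < nchar(aa)]
  if (length(internal)) attr(aa, "internal_stops") <- internal
  aa
}

#' Codon arithmetic for a 1-based CDS position
#'
#' @param cds_position 1-based nucleotide offset within a coding sequence.
#' @return list with `cds_position`, `codon_index` (1-based residue number)
#'   and `offset_in_codon` (1, 2 or 3).
#' @export
codon_position <- function(cds_position) {
  stopifnot(cds_position >= 1)
  cds_position <- as.integer(cds_position)
  list(cds_position = cds_position,
       codon_index = (cds_position - 1L) %/% 3L + 1L,
       offset_in_codon = (cds_position - 1L) %% 3L + 1L)
}

#' Locate a genomic position within CDS features
#'
#' Maps a 1-based genomic position to CDS coordinates of every CDS containing
#' it. For minus-strand features the CDS position counts from the 5' end of
#' the coding strand.
#'
#' @param genome an [AnnotatedGenome].
#' @param contig_id contig of the queried position.
#' @param genome_position 1-based genomic coordinate.
#' @return `"intergenic"` if no CDS contains the position, otherwise a
#'   data.frame with one row per containing CDS: `feature_id`, `cds_position`,
#'   `codon_index`, `offset_in_codon`.
#' @export
locate_in_cds <- function(genome, contig_id, genome_position) {
  if (!contig_id %in% names(genome$contigs))
    stop("unknown contig: ", contig_id)
  p0 <- as.integer(genome_position) - 1L
  cds <- cds_features(genome)
  hit <- cds[cds$contig_id == contig_id & cds$start <= p0 & cds$end > p0, ,
             drop = FALSE]
  if (!nrow(hit)) return("intergenic")
  cds_pos <- ifelse(hit$strand == "+", p0 - hit$start + 1L, hit$end - p0)
  out <- data.frame(feature_id = hit$feature_id,
                    cds_position = as.integer(cds_pos),
                    stringsAsFactors = FALSE)
  cp <- lapply(out$cds_position, codon_position)
  out$codon_index <- vapply(cp, `[[`, integer(1), "codon_index")
  out$offset_in_codon <- vapply(cp, `[[`, integer(1), "offset_in_codon")
  rownames(out) <- NULL
  out
}
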