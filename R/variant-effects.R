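#' Annotate a single point mutation
#'
#' Classifies the consequence of a single-nucleotide substitution against
#' every CDS containing the position (one result row per overlapping CDS).
#' For minus-strand genes the reference and alternate bases are complemented
#' before the codon substitution. Stop codons render as `"X"`, so a nonsense
#' change prints as e.g. `Q -> X`.
#'
#' Effect classes: `Substitution` (missense; stop-loss is a Substitution
#' carrying `stop_loss = TRUE`), `Truncation` (alt codon is a stop, ref is
#' not), `None` (synonymous), `Intergenic` (no CDS contains the position),
#' `Ambiguous` (the reference codon contains an ambiguity code).
#'
#' @param genome an [AnnotatedGenome].
#' @param contig_id contig of the variant.
#' @param genome_position 1-based position.
#' @param ref_base,alt_base single reference/alternate bases (plus strand of
#'   the genome). The reference base is checked against the genome; a
#'   mismatch is a hard error carrying the observed base, since it signals
#'   an assembly or coordinate mismatch.
#' @return data.frame with columns `locus_tag`, `description`, `change`,
#'   `genome_position`, `cds_position`, `aa_change`, `protein_effect`,
#'   `stop_loss`.
#' @export
annotate_variant <- function(genome, contig_id, genome_position,
                             ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (nchar(ref_base) != 1 || nchar(alt_base) != 1)
    stop("only single-nucleotide substitutions are supported ",
         "(got ", ref_base, " -> ", alt_base, ")")
  if (ref_base == alt_base) stop("ref and alt base are identical")
  observed <- substr(genome$contigs[[contig_id]], genome_position,
                     genome_position)
  if (observed != ref_base)
    stop("reference mismatch at ", contig_id, ":", genome_position,
         ": expected ", ref_base, ", genome has ", observed)
  change <- paste(ref_base, "->", alt_base)
  loc <- locate_in_cds(genome, contig_id, genome_position)
  if (identical(loc, "intergenic"))
    return(data.frame(locus_tag = "N/A", description = "Intergenic",
                      change = change,
                      genome_position = as.integer(genome_position),
                      cds_position = NA_integer_, aa_change = "N/A",
                      protein_effect = "Intergenic", stop_loss = FALSE,
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(loc)), function(i) {
    f <- get_feature(genome, loc$feature_id[i], kind = "CDS")
    cds <- extract_cds(genome, f$feature_id)
    rb <- ref_base; ab <- alt_base
    if (f$strand == "-") { rb <- revcomp(rb); ab <- revcomp(ab) }
    cp <- codon_position(loc$cds_position[i])
    cstart <- 3L * (cp$codon_index - 1L) + 1L
    ref_codon <- substr(cds, cstart, cstart + 2L)
    if (nchar(ref_codon) < 3 || grepl("[^ACGT]", ref_codon)) {
      ref_aa <- "?"; alt_aa <- "?"; effect <- "Ambiguous"
    } else {
      alt_codon <- ref_codon
      substr(alt_codon, cp$offset_in_codon, cp$offset_in_codon) <- ab
      ref_aa <- translate_cds(ref_codon)
      alt_aa <- translate_cds(alt_codon)
      effect <- if (ref_aa == alt_aa) "None"
        else if (alt_aa == "X") "Truncation"
        else "Substitution"
    }
    data.frame(locus_tag = f$feature_id, description = f$product,
               change = change,
               genome_position = as.integer(genome_position),
               cds_position = loc$cds_position[i],
               aa_change = if (effect %in% c("None"))
                 "none" else paste(ref_aa, "->", alt_aa),
               protein_effect = effect,
               stop_loss = identical(ref_aa, "X") && !identical(alt_aa, "X"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # stop-loss has no Truncation analogue: classify as Substitution, flagged
  out$protein_effect[out$stop_loss] <- "Substitution"
  out
}

#' Annotate a table of point mutations
#'
#' One report row per variant (per overlapping CDS), ordered by genome
#' position, in the column layout of a mutation report: locus tag,
#' description, change, genome position, CDS position, amino-acid change,
#' protein effect. Duplicated variants are dropped with a warning;
#' per-variant errors (e.g. reference mismatches) are collected into the
#' `errors` attribute and annotation continues.
#'
#' @param genome an [AnnotatedGenome].
#' @param variants data.frame with columns `contig_id`, `genome_position`
#'   (1-based), `ref_base`, `alt_base`.
#' @return effect table (data.frame); attribute `errors` lists failed
#'   variants.
#' @export
annotate_table <- function(genome, variants) {
  cols <- c("contig_id", "genome_position", "ref_base", "alt_base")
  if (!all(cols %in% names(variants)))
    stop("variants need columns: ", paste(cols, collapse = ", "))
  if (!nrow(variants))
    return(data.frame(locus_tag = character(), description = character(),
                      change = character(), genome_position = integer(),
                      cds_position = integer(), aa_change = character(),
                      protein_effect = character(), stop_loss = logical(),
                      stringsAsFactors = FALSE))
  key <- do.call(paste, variants[cols])
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate variant(s) removed")
    variants <- variants[!duplicated(key), , drop = FALSE]
  }
  errs <- character()
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    tryCatch(
      annotate_variant(genome, v$contig_id, v$genome_position, v$ref_base,
                       v$alt_base),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- annotate_table(genome, variants[0, , drop = FALSE])
  out <- out[order(out$genome_position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- errs
  out
}

#' Read point mutations from a VCF file
#'
#' Minimal VCF v4.x support: CHROM/POS/REF/ALT. Only the first ALT allele of
#' a multi-allelic record is used (the record is split with a warning);
#' indels are rejected downstream by [annotate_variant].
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return data.frame with `contig_id`, `genome_position`, `ref_base`,
#'   `alt_base`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alt <- fix$ALT
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s): first ALT allele used")
    alt <- sub(",.*$", "", alt)
  }
  data.frame(contig_id = fix$CHROM,
             genome_position = as.integer(fix$POS),
             ref_base = fix$REF, alt_base = alt,
             stringsAsFactors = FALSE)
}

#' Read point mutations from a TSV file
#'
#' @param path TSV with columns `contig_id`, `genome_position`, `ref_base`,
#'   `alt_base`.
#' @return data.frame in the [annotate_table] input layout.
#' @export
read_variants_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  cols <- c("contig_id", "genome_position", "ref_base", "alt_base")
  if (!all(cols %in% names(tab)))
    stop("variant TSV needs columns: ", paste(cols, collapse = ", "))
  tab[cols]
}

#' Write an effect table as TSV
#' @param effects data.frame from [annotate_table].
#' @param path output path.
#' @export
write_effects_tsv <- function(effects, path) {
  write.table(effects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
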