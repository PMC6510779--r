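#' Describe a genomic deletion design
#'
#' @param contig_id contig carrying the deletion.
#' @param start,end 1-based inclusive genomic span to remove (file
#'   convention, as in a design TSV).
#' @param arm_length homology-arm length in bp on each side (default 500);
#'   the arms abut the deleted interval and never overlap it.
#' @return object of class `DeletionDesign` with the internal 0-based
#'   half-open interval and the two arm intervals.
#' @export
deletion_design <- function(contig_id, start, end, arm_length = 500) {
  s0 <- to_internal_start(start); e0 <- as.integer(end)
  if (s0 > e0) stop("deletion start after end")
  structure(list(contig_id = contig_id, start = s0, end = e0,
                 length = e0 - s0,
                 arm_left = c(max(0L, s0 - as.integer(arm_length)), s0),
                 arm_right = c(e0, e0 + as.integer(arm_length))),
            class = "DeletionDesign")
}

#' Apply a designed deletion to a genome
#'
#' Splices the deletion interval out of the contig; features entirely
#' downstream are shifted left by the deleted length, features overlapping
#' the cut are truncated to the remaining portion and flagged in a
#' `truncated` column. Features entirely inside the deletion are removed
#' (listed in the `removed` attribute).
#'
#' @param genome an [AnnotatedGenome].
#' @param design a [deletion_design].
#' @return edited `AnnotatedGenome` whose contig is shorter by
#'   `design$length`.
#' @export
apply_deletion <- function(genome, design) {
  seq <- genome$contigs[[design$contig_id]]
  if (is.null(seq)) stop("unknown contig: ", design$contig_id)
  if (design$end > nchar(seq) || design$start < 0)
    stop("deletion interval outside contig (length ", nchar(seq), ")")
  len <- design$length
  newseq <- paste0(substr(seq, 1, design$start),
                   substr(seq, design$end + 1L, nchar(seq)))
  f <- genome$features
  f$truncated <- logical(nrow(f))
  removed <- character()
  keep <- rep(TRUE, nrow(f))
  for (i in seq_len(nrow(f))) {
    if (f$contig_id[i] != design$contig_id) next
    s <- f$start[i]; e <- f$end[i]
    if (e <= design$start) next                       # fully upstream
    if (s >= design$end) {                            # fully downstream
      f$start[i] <- s - len; f$end[i] <- e - len; next
    }
    if (s >= design$start && e <= design$end) {       # swallowed
      removed <- c(removed, f$feature_id[i]); keep[i] <- FALSE; next
    }
    # overlap: clip to surviving part(s), coordinates in edited genome
    ns <- if (s < design$start) s else design$start
    ne <- if (e > design$end) e - len else design$start
    f$start[i] <- ns; f$end[i] <- ne; f$truncated[i] <- TRUE
  }
  f <- f[keep, , drop = FALSE]
  contigs <- genome$contigs
  contigs[[design$contig_id]] <- newseq
  g <- AnnotatedGenome(contigs, f[names(f) != "truncated"],
                       source_label = paste0(genome$source_label, " (edited)"))
  g$features$truncated <- f$truncated
  attr(g, "removed") <- removed
  g
}

#' In-silico PCR amplicon prediction
#'
#' Exact-match binding model: the forward primer must occur exactly once on
#' the plus strand and the reverse complement of the reverse primer exactly
#' once downstream of it. The amplicon runs from the forward primer's 5' end
#' to the reverse primer's 5' end, inclusive, so colony-PCR band sizes are
#' pure coordinate arithmetic.
#'
#' @param genome an [AnnotatedGenome].
#' @param forward,reverse primer sequences (each at least 12 nt).
#' @param names optional primer names for error messages.
#' @return list: `length` (bp), `sequence`, `contig_id`, `start`, `end`
#'   (0-based half-open amplicon interval).
#' @export
in_silico_pcr <- function(genome, forward, reverse,
                          names = c("fwd", "rev")) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 12 || nchar(reverse) < 12)
    stop("primers must be at least 12 nt")
  find_sites <- function(primer) {
    sites <- list()
    for (ctg in names(genome$contigs)) {
      m <- Biostrings::matchPattern(primer,
                                    Biostrings::DNAString(genome$contigs[[ctg]]))
      if (length(m))
        sites[[length(sites) + 1]] <- data.frame(
          contig_id = ctg, start = BiocGenerics::start(m) - 1L,
          end = BiocGenerics::end(m), stringsAsFactors = FALSE)
    }
    if (length(sites)) do.call(rbind, sites)
    else data.frame(contig_id = character(), start = integer(),
                    end = integer())
  }
  fs <- find_sites(forward)
  rs <- find_sites(revcomp(reverse))
  describe <- function(x) paste(sprintf("%s:%d", x$contig_id, x$start + 1L),
                                collapse = ", ")
  if (nrow(fs) != 1)
    stop("primer ", names[1], " binds ", nrow(fs), " site(s)",
         if (nrow(fs)) paste0(" [", describe(fs), "]"))
  if (nrow(rs) != 1)
    stop("primer ", names[2], " binds ", nrow(rs), " site(s)",
         if (nrow(rs)) paste0(" [", describe(rs), "]"))
  if (fs$contig_id != rs$contig_id || rs$end <= fs$start)
    stop("primers not in amplifying orientation (forward site must precede ",
         "the reverse site on the same contig)")
  amp <- substr(genome$contigs[[fs$contig_id]], fs$start + 1L, rs$end)
  list(length = rs$end - fs$start, sequence = amp,
       contig_id = fs$contig_id, start = fs$start, end = rs$end)
}

#' Enumerate SpCas9 protospacers cutting inside an interval
#'
#' Scans both strands for 20-mers followed by an NGG PAM. Cas9 cuts bluntly
#' 3 bp 5' of the PAM, i.e. between protospacer positions 17 and 18; a
#' protospacer is reported when the base at its position 17 lies inside the
#' target interval. Every reported protospacer re-validates its PAM.
#'
#' @param genome an [AnnotatedGenome].
#' @param contig_id contig to scan.
#' @param start,end target interval, 1-based inclusive.
#' @param pam PAM pattern, default `"NGG"`.
#' @param length protospacer length, default 20.
#' @return data.frame: `sequence` (protospacer, 5'->3'), `strand`, `start`,
#'   `end` (0-based half-open genomic span of the protospacer), `pam`,
#'   `cut_after` (1-based genomic base immediately 5' of the blunt cut).
#' @export
enumerate_protospacers <- function(genome, contig_id, start, end,
                                   pam = "NGG", length = 20) {
  seq <- genome$contigs[[contig_id]]
  if (is.null(seq)) stop("unknown contig: ", contig_id)
  s0 <- to_internal_start(start); e0 <- as.integer(end)
  k <- as.integer(length); pl <- nchar(pam)
  subj <- Biostrings::DNAString(seq)
  res <- list()
  scan_strand <- function(strand) {
    p <- paste0(strrep("N", k), pam)
    if (strand == "-") p <- revcomp(p)
    m <- Biostrings::matchPattern(p, subj, fixed = "subject")
    if (!length(m)) return(NULL)
    hs <- BiocGenerics::start(m) - 1L
    win <- as.character(m)
    ok <- !grepl("[^ACGT]", win)
    hs <- hs[ok]; win <- win[ok]
    if (!base::length(hs)) return(NULL)
    if (strand == "+") {
      ps <- hs; pe <- hs + k
      spacer <- substr(win, 1, k)
      pamseq <- substr(win, k + 1, k + pl)
      cut0 <- ps + 17L - 1L              # 0-based index of position 17
    } else {
      ps <- hs + pl; pe <- hs + pl + k
      spacer <- revcomp(substr(win, pl + 1, pl + k))
      pamseq <- revcomp(substr(win, 1, pl))
      cut0 <- pe - 17L                   # genomic index of spacer pos 17
    }
    keep <- cut0 >= s0 & cut0 < e0
    if (!any(keep)) return(NULL)
    data.frame(sequence = spacer[keep], strand = strand, start = ps[keep],
               end = pe[keep], pam = pamseq[keep],
               cut_after = cut0[keep] + 1L, stringsAsFactors = FALSE)
  }
  out <- rbind(scan_strand("+"), scan_strand("-"))
  if (is.null(out))
    return(data.frame(sequence = character(), strand = character(),
                      start = integer(), end = integer(), pam = character(),
                      cut_after = integer(), stringsAsFactors = FALSE))
  bad <- substr(out$pam, 2, 3) != "GG"
  if (any(bad)) stop("internal error: enumerated protospacer without NGG PAM")
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a synthetic deletion-verification locus
#'
#' Builds a single-contig genome carrying one designed CDS together with a
#' primer pair and an in-gene deletion design, dimensioned like a typical
#' sigL knockout verification: the wild-type colony-PCR amplicon has a
#' prescribed size, the deletion removes a prescribed number of bases from
#' the CDS, and the residual ORF is engineered to stop at a prescribed
#' codon (a stop codon is written at the splice point in the shifted
#' frame). All sequence outside these constraints is random.
#'
#' @param n_codons CDS length in codons, stop codon included (default 464,
#'   i.e. a 463-residue protein).
#' @param deletion_length deleted span in bp (default 736).
#' @param amplicon_length wild-type amplicon size in bp (default 1406).
#' @param truncate_at_codon codon index at which the residual ORF stops
#'   (default 14, i.e. 13 residues remain).
#' @param primer_length primer size in nt (default 20).
#' @param seed RNG seed for the random backbone.
#' @return list: `genome`, `cds_id`, `forward`/`reverse` primers, `design`
#'   (a [deletion_design] in genomic coordinates), `cds_deletion`
#'   (1-based inclusive deleted span within the CDS).
#' @export
deletion_locus_fixture <- function(n_codons = 464, deletion_length = 736,
                                   amplicon_length = 1406,
                                   truncate_at_codon = 14,
                                   primer_length = 20, seed = 1) {
  set.seed(seed)
  del_start <- 3L * (truncate_at_codon - 1L) + 1L  # first deleted CDS base
  del_end <- del_start + deletion_length - 1L
  cds_len <- 3L * n_codons
  if (del_end + 3 > cds_len)
    stop("deletion does not fit inside the CDS")
  cds <- paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 2L,
                                    replace = TRUE), collapse = ""), "TAA")
  # stop codon met immediately after the splice point in the new frame
  substr(cds, del_end + 1L, del_end + 3L) <- "TAA"
  pad5 <- sample_background(3000, 0.5)
  pad3 <- sample_background(3000, 0.5)
  contig <- paste0(pad5, cds, pad3)
  cds_start0 <- nchar(pad5)
  feats <- data.frame(feature_id = "sigL_like", contig_id = "locus",
                      start = cds_start0, end = cds_start0 + cds_len,
                      strand = "+", kind = "CDS",
                      product = "RNA polymerase sigma-54 factor",
                      stringsAsFactors = FALSE)
  genome <- AnnotatedGenome(c(locus = contig), feats,
                            source_label = "deletion fixture")
  fwd_start0 <- cds_start0 - 200L
  amp_end0 <- fwd_start0 + amplicon_length
  if (amp_end0 - primer_length <= cds_start0 + del_end)
    stop("amplicon too short to span the deletion")
  forward <- substr(contig, fwd_start0 + 1L, fwd_start0 + primer_length)
  reverse <- revcomp(substr(contig, amp_end0 - primer_length + 1L, amp_end0))
  design <- deletion_design("locus", cds_start0 + del_start, cds_start0 + del_end)
  list(genome = genome, cds_id = "sigL_like", forward = forward,
       reverse = reverse, design = design,
       cds_deletion = c(del_start, del_end))
}

#' Residual ORF length after a deletion within a CDS
#'
#' Splices the deleted interval out of the coding sequence, translates from
#' the original start codon, and counts residues before the first stop
#' (frameshifting deletions naturally produce early stops). The count
#' excludes the stop itself, so a protein truncated at codon 14 reports 13
#' residues.
#'
#' @param cds_sequence coding-strand CDS nucleotide string.
#' @param del_start,del_end deleted span within the CDS, 1-based inclusive.
#' @return integer residue count, or `NA` (with a message) when the deletion
#'   removes the start codon, i.e. no ORF remains.
#' @export
residual_orf <- function(cds_sequence, del_start, del_end) {
  n <- nchar(cds_sequence)
  if (del_start < 1 || del_end > n || del_start > del_end)
    stop("deletion interval outside CDS (length ", n, ")")
  if (del_start <= 3) {
    message("deletion removes the start codon: no ORF")
    return(NA_integer_)
  }
  spliced <- paste0(substr(cds_sequence, 1, del_start - 1),
                    substr(cds_sequence, del_end + 1, n))
  usable <- nchar(spliced) - nchar(spliced) %% 3
  if (usable == 0) return(0L)
  aa <- strsplit(translate_cds(substr(spliced, 1, usable)), "")[[1]]
  stop_at <- which(aa == "X")
  if (length(stop_at)) stop_at[1] - 1L else length(aa)
}
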