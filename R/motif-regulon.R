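# sigma-54 (-12/-24) promoter consensus after Barrios et al.; W = A/T.
SIGMA54_CONSENSUS <- "TGGCANNNNNNTTGCW"

IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

#' Validated IUPAC consensus pattern
#'
#' @param pattern IUPAC string; default is the sigma-54 binding-site consensus
#'   `TGGCANNNNNNTTGCW`.
#' @return object of class `ConsensusPattern` with the pattern string, its
#'   length and the per-position allowed-base sets.
#' @export
consensus_pattern <- function(pattern = SIGMA54_CONSENSUS) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad))
    stop("invalid IUPAC character '", chars[bad][1], "' at position ",
         which(bad)[1])
  structure(list(pattern = paste(chars, collapse = ""),
                 length = length(chars),
                 allowed = IUPAC_SETS[chars]),
            class = "ConsensusPattern")
}

as_pattern <- function(pattern) {
  if (inherits(pattern, "ConsensusPattern")) pattern
  else consensus_pattern(pattern)
}

#' Scan a genome for exact consensus matches
#'
#' Exact (no-mismatch) degenerate matching of an IUPAC consensus on one or
#' both strands of every contig. Ambiguity codes in the genome (e.g. `N`)
#' never match. Reverse-strand hits are reported in forward coordinates with
#' strand `-`, and their matched sequence in coding-strand orientation.
#' Overlapping matches are all reported.
#'
#' @param genome an [AnnotatedGenome].
#' @param pattern IUPAC string or [consensus_pattern] object.
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return data.frame of hits (`contig_id`, `start`, `end` 0-based half-open,
#'   `strand`, `match`), sorted by contig, start, strand.
#' @export
scan_consensus <- function(genome, pattern = SIGMA54_CONSENSUS,
                           strands = "both") {
  pat <- as_pattern(pattern)
  strands <- match.arg(strands, c("both", "+", "-"))
  want <- if (strands == "both") c("+", "-") else strands
  res <- list()
  for (ctg in names(genome$contigs)) {
    subj <- Biostrings::DNAString(genome$contigs[[ctg]])
    for (std in want) {
      p <- if (std == "+") pat$pattern else revcomp(pat$pattern)
      m <- Biostrings::matchPattern(p, subj, fixed = "subject")
      if (!length(m)) next
      s0 <- BiocGenerics::start(m) - 1L
      win <- as.character(m)
      # pattern ambiguity letters also match themselves literally in the
      # subject; drop windows containing any ambiguity code
      ok <- !grepl("[^ACGT]", win)
      if (!any(ok)) next
      res[[length(res) + 1]] <- data.frame(
        contig_id = ctg, start = s0[ok], end = s0[ok] + pat$length,
        strand = std,
        match = if (std == "+") win[ok] else revcomp(win[ok]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$contig_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# distance (bp) from a hit's promoter-proximal (3') edge to a CDS start,
# both on the same strand; negative when the CDS start lies upstream of the
# motif edge. 0-based half-open arithmetic.
hit_to_start_distance <- function(hit_start, hit_end, hit_strand,
                                  cds_start, cds_end) {
  if (hit_strand == "+") cds_start - hit_end else hit_start - cds_end
}

#' Assign motif hits to downstream transcriptional units
#'
#' Each hit is assigned to the nearest downstream CDS start on the same
#' strand within the upstream window (inclusive at both ends: a motif ending
#' exactly `window` bp before the start still qualifies). Assignment never
#' crosses contig boundaries. Additional same-strand CDS starts within the
#' window are listed as alternatives. The transcriptional unit of the
#' assigned gene is computed with [extend_operon]. Motifs overlapping any CDS
#' are kept but flagged.
#'
#' @param hits data.frame from [scan_consensus].
#' @param genome an [AnnotatedGenome].
#' @param window maximum distance in bp from the motif 3' end to the CDS
#'   start (default 500).
#' @param max_gap operon-extension intergenic gap limit in bp (default 50).
#' @return data.frame with one row per hit: hit coordinates, `gene_id`
#'   (`NA` when unassigned), `distance`, `alternatives` (comma-separated),
#'   `transcriptional_unit` (comma-separated gene ids), `overlaps_cds` flag,
#'   plus `ebp_nearby`/`ebp_gene_id` placeholders filled by
#'   [flag_ebp_vicinity].
#' @export
assign_regulon <- function(hits, genome, window = 500, max_gap = 50) {
  cds <- cds_features(genome)
  n <- nrow(hits)
  out <- cbind(hits, data.frame(
    gene_id = rep(NA_character_, n), distance = rep(NA_integer_, n),
    alternatives = rep("", n), transcriptional_unit = rep("", n),
    overlaps_cds = rep(FALSE, n), ebp_nearby = rep(NA, n),
    ebp_gene_id = rep(NA_character_, n), stringsAsFactors = FALSE))
  if (!n) return(out)
  for (i in seq_len(n)) {
    h <- hits[i, ]
    cand <- cds[cds$contig_id == h$contig_id & cds$strand == h$strand, ,
                drop = FALSE]
    out$overlaps_cds[i] <- any(cds$contig_id == h$contig_id &
                                 cds$start < h$end & cds$end > h$start)
    if (!nrow(cand)) next
    d <- hit_to_start_distance(h$start, h$end, h$strand, cand$start, cand$end)
    ok <- d >= 0 & d <= window
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    d <- d[ok]
    ord <- order(d, cand$feature_id)
    out$gene_id[i] <- cand$feature_id[ord[1]]
    out$distance[i] <- d[ord[1]]
    if (length(ord) > 1)
      out$alternatives[i] <- paste(cand$feature_id[ord[-1]], collapse = ",")
    out$transcriptional_unit[i] <- paste(
      extend_operon(genome, out$gene_id[i], max_gap = max_gap),
      collapse = ",")
  }
  out
}

#' Extend a gene into its transcriptional unit
#'
#' Maximal run of co-directional, consecutive CDS starting at `gene_id` and
#' walking downstream (in the gene's transcription direction), allowing
#' intergenic gaps up to `max_gap` bp. Any intervening feature on the
#' opposite strand, or a larger gap, terminates the unit.
#'
#' @param genome an [AnnotatedGenome].
#' @param gene_id CDS locus tag opening the unit.
#' @param max_gap maximum intergenic distance in bp (default 50).
#' @return character vector of gene ids in transcription order.
#' @export
extend_operon <- function(genome, gene_id, max_gap = 50) {
  f <- get_feature(genome, gene_id)
  cds <- cds_features(genome)
  cds <- cds[cds$contig_id == f$contig_id, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  i <- which(cds$feature_id == gene_id)
  unit <- gene_id
  step <- if (f$strand == "+") 1L else -1L
  repeat {
    j <- i + step
    if (j < 1 || j > nrow(cds)) break
    if (cds$strand[j] != f$strand) break
    gap <- if (f$strand == "+") cds$start[j] - cds$end[i]
           else cds$start[i] - cds$end[j]
    if (gap > max_gap) break
    unit <- c(unit, cds$feature_id[j])
    i <- j
  }
  unit
}

#' Flag enhancer-binding-protein genes near a regulon unit
#'
#' sigma-54 holoenzymes cannot form an open complex without an enhancer
#' binding protein (EBP), typically encoded near its target unit; an
#' assignment is flagged when a feature whose product annotation matches an
#' EBP keyword lies within `span` bp of the transcriptional unit's extent.
#'
#' @param assignments data.frame from [assign_regulon].
#' @param genome an [AnnotatedGenome].
#' @param keywords character vector of product keywords (fixed substrings,
#'   case-insensitive).
#' @param span distance in bp from the unit within which an EBP gene counts
#'   as "in the vicinity" (default 3000, matching the generator's placement
#'   span).
#' @return `assignments` with `ebp_nearby` and `ebp_gene_id` filled in.
#' @export
flag_ebp_vicinity <- function(assignments, genome,
                              keywords = c("sigma-54 dependent", "enhancer",
                                           "PAS", "AAA"),
                              span = 3000) {
  stopifnot(length(keywords) >= 1)
  feats <- genome$features
  is_ebp <- Reduce(`|`, lapply(keywords, function(k)
    grepl(k, feats$product, ignore.case = TRUE, fixed = FALSE)))
  ebp <- feats[is_ebp, , drop = FALSE]
  for (i in seq_len(nrow(assignments))) {
    gid <- assignments$gene_id[i]
    if (is.na(gid)) { assignments$ebp_nearby[i] <- NA; next }
    unit <- strsplit(assignments$transcriptional_unit[i], ",")[[1]]
    uf <- genome$features[genome$features$feature_id %in% unit, , drop = FALSE]
    lo <- min(uf$start) - span
    hi <- max(uf$end) + span
    near <- ebp[ebp$contig_id == uf$contig_id[1] & ebp$start < hi &
                  ebp$end > lo & !ebp$feature_id %in% unit, , drop = FALSE]
    assignments$ebp_nearby[i] <- nrow(near) > 0
    assignments$ebp_gene_id[i] <-
      if (nrow(near)) near$feature_id[which.min(near$start)] else NA_character_
  }
  assignments
}

#' Hit-count statistics against the i.i.d. background expectation
#'
#' Under an i.i.d. equal-frequency base model the probability that one window
#' on one strand matches the consensus is the product over positions of
#' (allowed set size)/4; the expected genome-wide count over both strands is
#' `2 * sum(L - k + 1) * p` across contigs of length L for a k-long pattern.
#' For the default 16-mer consensus p = (1/4)^9 * (1/2) = 1/524288.
#'
#' @param hits data.frame from [scan_consensus].
#' @param genome an [AnnotatedGenome].
#' @param pattern IUPAC string or [consensus_pattern].
#' @return list: `n_hits`, `genome_length`, `expected_hits_random`,
#'   `enrichment_ratio`.
#' @export
scan_statistics <- function(hits, genome, pattern = SIGMA54_CONSENSUS) {
  pat <- as_pattern(pattern)
  p <- prod(lengths(pat$allowed) / 4)
  L <- nchar(genome$contigs)
  windows <- sum(pmax(L - pat$length + 1, 0))
  expected <- 2 * windows * p
  list(n_hits = nrow(hits), genome_length = sum(L),
       expected_hits_random = expected,
       enrichment_ratio = if (expected > 0) nrow(hits) / expected else NA_real_)
}

#' Write motif hits as BED6
#'
#' @param hits data.frame from [scan_consensus] (already 0-based half-open,
#'   the BED convention).
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$contig_id, hits$start, hits$end,
                    name = paste0("hit", seq_len(nrow(hits))),
                    score = 0L, strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a regulon report TSV (1-based inclusive coordinates)
#'
#' @param assignments data.frame from [assign_regulon] /
#'   [flag_ebp_vicinity].
#' @param path output path.
#' @export
write_regulon_tsv <- function(assignments, path) {
  rep_ <- assignments
  rep_$start <- to_file_start(rep_$start)
  write.table(rep_, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
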