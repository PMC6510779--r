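# Seeded generators for every input the pipeline consumes, with stored
# ground truth. Layout is structural: each regulon unit is packed as one
# block carrying its own planted consensus instance immediately upstream of
# the first transcribed gene, inter-block gaps are kept > window so an
# assignment can never be claimed by a neighbouring block, and intra-unit
# gaps stay <= max_gap so operon extension reconstructs the unit exactly.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

UNIT_PRODUCTS <- c(
  "alcohol dehydrogenase", "secondary alcohol dehydrogenase",
  "2,3-butanediol dehydrogenase", "dihydroxyacetone kinase subunit",
  "beta-glucosidase", "beta-galactosidase", "polyol dehydrogenase",
  "transketolase", "ribulose-phosphate epimerase",
  "PTS system transporter subunit", "oxidoreductase", "phosphomannomutase")

SINGLE_PRODUCTS <- c(
  "conserved protein of unknown function", "ABC transporter permease",
  "histidine kinase", "short chain acyl-CoA transferase",
  "dihydroxy-acid dehydratase", "binding-protein-dependent transport protein",
  "putative hydrolase", "NMT1/THI5-like protein")

EBP_PRODUCTS <- c(
  "sigma-54 dependent transcriptional regulator",
  "enhancer binding protein with AAA+ ATPase domain")

#' Configuration for the synthetic-genome generator
#'
#' Defaults emulate a desk-scale slice of a clostridial chromosome: one
#' contig, 30 genes of 300-1500 bp on either strand, 5 sigma-54 regulon
#' units whose consensus instances are planted 0-500 bp upstream of the
#' first transcribed gene (degenerate positions randomised per instance),
#' 2 enhancer-binding-protein genes placed in the vicinity of regulon units,
#' and a motif-free background enforced by rejection-resampling.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param n_genes total CDS count (regulon members + EBP genes + singletons).
#' @param gene_length_range CDS length bounds in bp (rounded to codons).
#' @param strand_prob probability a block lies on the plus strand.
#' @param n_regulon_units number of planted promoter-unit pairs.
#' @param genes_per_unit_range operon size bounds for regulon units.
#' @param window upstream window in bp from which planted motif distances
#'   are drawn uniformly.
#' @param max_gap maximum intra-operon intergenic gap in bp.
#' @param n_ebp number of EBP genes, attached near distinct regulon units.
#' @param ebp_span maximum distance in bp from an EBP gene to its unit.
#' @param gc background G+C fraction (0.5 = uniform; 0.30 approximates a
#'   low-GC Clostridium chromosome).
#' @param background_motif_free if `TRUE`, regenerate until the only
#'   consensus matches are the planted ones (retry cap 1000).
#' @param pattern IUPAC consensus to plant.
#' @return a `GenomeSimConfig` list.
#' @export
genome_sim_config <- function(n_contigs = 1, contig_length = 50000,
                              n_genes = 30, gene_length_range = c(300, 1200),
                              strand_prob = 0.5, n_regulon_units = 5,
                              genes_per_unit_range = c(1, 3), window = 500,
                              max_gap = 50, n_ebp = 2, ebp_span = 3000,
                              gc = 0.5, background_motif_free = TRUE,
                              pattern = SIGMA54_CONSENSUS) {
  cfg <- as.list(environment())
  class(cfg) <- "GenomeSimConfig"
  cfg
}

sample_background <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

sample_cds <- function(len_range) {
  n_codons <- max(3L, round(runif(1, len_range[1], len_range[2]) / 3))
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

realize_pattern <- function(pattern) {
  pat <- as_pattern(pattern)
  paste(vapply(pat$allowed, function(s) sample(s, 1), character(1)),
        collapse = "")
}

# One block = optional planted motif + operon genes + optional EBP gene,
# described in transcription orientation; `strand` flips the whole block.
make_unit_block <- function(cfg, with_ebp, with_motif = TRUE) {
  k <- sample(seq(cfg$genes_per_unit_range[1], cfg$genes_per_unit_range[2]), 1)
  genes <- replicate(k, list(
    seq = sample_cds(cfg$gene_length_range),
    product = sample(UNIT_PRODUCTS, 1), is_ebp = FALSE), simplify = FALSE)
  block <- list(type = "unit",
                strand = if (runif(1) < cfg$strand_prob) "+" else "-",
                genes = genes,
                gaps = if (k > 1) sample(5:cfg$max_gap, k - 1, replace = TRUE)
                       else integer(),
                motif = if (with_motif)
                  list(distance = sample(0:cfg$window, 1),
                       instance = realize_pattern(cfg$pattern))
                  else NULL)
  if (with_ebp) {
    span_hi <- min(800L, cfg$ebp_span)
    block$genes <- c(block$genes, list(list(
      seq = sample_cds(cfg$gene_length_range),
      product = sample(EBP_PRODUCTS, 1), is_ebp = TRUE)))
    # gap > max_gap so the EBP gene never merges into the unit
    block$gaps <- c(block$gaps, sample((cfg$max_gap + 50):span_hi, 1))
  }
  block
}

make_single_block <- function(cfg) {
  list(type = "single",
       strand = if (runif(1) < cfg$strand_prob) "+" else "-",
       genes = list(list(seq = sample_cds(cfg$gene_length_range),
                         product = sample(SINGLE_PRODUCTS, 1),
                         is_ebp = FALSE)),
       gaps = integer(), motif = NULL)
}

# Render a block to a sequence string plus local 0-based features.
render_block <- function(block, gc) {
  seqs <- character(); pos <- 0L
  feats <- data.frame(start = integer(), end = integer(),
                      product = character(), is_ebp = logical(),
                      tx_order = integer(), stringsAsFactors = FALSE)
  motif_local <- NULL
  if (!is.null(block$motif)) {
    seqs <- c(seqs, block$motif$instance)
    motif_local <- c(pos, pos + nchar(block$motif$instance))
    pos <- pos + nchar(block$motif$instance)
    seqs <- c(seqs, sample_background(block$motif$distance, gc))
    pos <- pos + block$motif$distance
  }
  cds_seqs <- character()
  for (i in seq_along(block$genes)) {
    g <- block$genes[[i]]
    feats <- rbind(feats, data.frame(
      start = pos, end = pos + nchar(g$seq), product = g$product,
      is_ebp = g$is_ebp, tx_order = i, stringsAsFactors = FALSE))
    cds_seqs <- c(cds_seqs, g$seq)
    seqs <- c(seqs, g$seq)
    pos <- pos + nchar(g$seq)
    if (i <= length(block$gaps)) {
      seqs <- c(seqs, sample_background(block$gaps[i], gc))
      pos <- pos + block$gaps[i]
    }
  }
  s <- paste(seqs, collapse = "")
  L <- nchar(s)
  strand <- block$strand
  if (strand == "-") {
    s <- revcomp(s)
    new_start <- L - feats$end
    feats$end <- L - feats$start
    feats$start <- new_start
    if (!is.null(motif_local)) motif_local <- c(L - motif_local[2],
                                                L - motif_local[1])
  }
  feats$strand <- strand
  feats$cds_seq <- cds_seqs
  list(seq = s, features = feats, motif_local = motif_local,
       motif_instance = if (is.null(block$motif)) NA_character_
                        else block$motif$instance,
       motif_distance = if (is.null(block$motif)) NA_integer_
                        else block$motif$distance,
       strand = strand, type = block$type)
}

layout_blocks <- function(blocks, cfg, prefix) {
  n_per <- ceiling(length(blocks) / cfg$n_contigs)
  contig_ids <- sprintf("%s_ctg%d", tolower(prefix), seq_len(cfg$n_contigs))
  assign_ctg <- rep(seq_len(cfg$n_contigs), each = n_per)[seq_along(blocks)]
  contigs <- setNames(rep("", cfg$n_contigs), contig_ids)
  feat_rows <- list(); motif_rows <- list(); block_no <- 0L
  for (ci in seq_len(cfg$n_contigs)) {
    pos <- 0L; parts <- character()
    for (b in blocks[assign_ctg == ci]) {
      block_no <- block_no + 1L
      gap <- sample(600:800, 1)
      parts <- c(parts, sample_background(gap, cfg$gc)); pos <- pos + gap
      r <- render_block(b, cfg$gc)
      f <- r$features
      f$start <- f$start + pos; f$end <- f$end + pos
      f$contig_id <- contig_ids[ci]
      f$block_type <- r$type
      f$block_id <- block_no
      feat_rows[[length(feat_rows) + 1]] <- f
      if (!is.null(r$motif_local))
        motif_rows[[length(motif_rows) + 1]] <- data.frame(
          contig_id = contig_ids[ci], start = r$motif_local[1] + pos,
          end = r$motif_local[2] + pos, strand = r$strand,
          match = r$motif_instance, distance = r$motif_distance,
          head_start = f$start[f$tx_order == 1],
          stringsAsFactors = FALSE)
      parts <- c(parts, r$seq); pos <- pos + nchar(r$seq)
    }
    if (pos > cfg$contig_length)
      stop("infeasible packing: content ", pos, " bp exceeds contig length ",
           cfg$contig_length)
    parts <- c(parts, sample_background(cfg$contig_length - pos, cfg$gc))
    contigs[ci] <- paste(parts, collapse = "")
  }
  feats <- do.call(rbind, feat_rows)
  ord <- order(feats$contig_id, feats$start)
  feats <- feats[ord, , drop = FALSE]
  feats$feature_id <- sprintf("%s_%04d", prefix, seq_len(nrow(feats)))
  features <- data.frame(feature_id = feats$feature_id,
                         contig_id = feats$contig_id, start = feats$start,
                         end = feats$end, strand = feats$strand,
                         kind = "CDS", product = feats$product,
                         stringsAsFactors = FALSE)
  genome <- AnnotatedGenome(contigs, features,
                            source_label = paste0("synthetic-", prefix))
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows)
            else data.frame(contig_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            match = character(), distance = integer(),
                            head_start = integer(), stringsAsFactors = FALSE)
  if (nrow(motifs)) {
    motifs$gene_id <- feats$feature_id[
      match(paste(motifs$contig_id, motifs$head_start),
            paste(feats$contig_id, feats$start))]
    motifs$head_start <- NULL
    motifs <- motifs[order(motifs$contig_id, motifs$start), , drop = FALSE]
    rownames(motifs) <- NULL
  }
  # transcriptional units and their EBP annotation, from block bookkeeping
  by_block <- split(feats, feats$block_id)
  by_block <- by_block[vapply(by_block, function(g)
    g$block_type[1] == "unit", logical(1))]
  truth_units <- do.call(rbind, lapply(by_block,
    function(g) {
      core <- g[!g$is_ebp, , drop = FALSE]
      core <- core[order(core$tx_order), , drop = FALSE]
      data.frame(unit = core$feature_id[1],
                 genes = paste(core$feature_id, collapse = ","),
                 ebp_gene_id = if (any(g$is_ebp))
                   g$feature_id[g$is_ebp][1] else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  rownames(truth_units) <- NULL
  # geometric EBP-vicinity flag: any EBP gene within ebp_span of the unit
  # extent (including EBPs attached to neighbouring blocks)
  if (!is.null(truth_units) && nrow(truth_units)) {
    ebp <- feats[feats$is_ebp, , drop = FALSE]
    truth_units$ebp_nearby <- vapply(seq_len(nrow(truth_units)), function(i) {
      ids <- strsplit(truth_units$genes[i], ",")[[1]]
      uf <- feats[feats$feature_id %in% ids, , drop = FALSE]
      any(ebp$contig_id == uf$contig_id[1] &
            ebp$start < max(uf$end) + cfg$ebp_span &
            ebp$end > min(uf$start) - cfg$ebp_span)
    }, logical(1))
  }
  truth <- list(motifs = motifs, units = truth_units,
                cds_seqs = setNames(feats$cds_seq, feats$feature_id),
                ebp_genes = feats$feature_id[feats$is_ebp])
  list(genome = genome, truth = truth)
}

#' Generate a synthetic annotated genome with planted sigma-54 sites
#'
#' Builds a genome per the configuration and records complete ground truth:
#' planted motif loci (strand, realised instance, upstream distance, target
#' gene), transcriptional-unit composition, EBP gene placement and every CDS
#' sequence. With `background_motif_free = TRUE` the whole genome is
#' rejection-resampled until the consensus scanner finds exactly the planted
#' sites. Fully deterministic for a given `(config, seed)`.
#'
#' @param config a [genome_sim_config].
#' @param seed integer RNG seed.
#' @return list with `genome` (an [AnnotatedGenome]) and `truth` (motifs,
#'   units, cds_seqs, ebp_genes).
#' @export
generate_genome <- function(config = genome_sim_config(), seed = 1) {
  set.seed(seed)
  for (attempt in seq_len(1000)) {
    sim <- generate_genome_once(config)
    if (!config$background_motif_free) return(sim)
    hits <- scan_consensus(sim$genome, config$pattern)
    planted <- sim$truth$motifs
    if (nrow(hits) == nrow(planted) &&
        all(paste(hits$contig_id, hits$start, hits$strand) %in%
            paste(planted$contig_id, planted$start, planted$strand)))
      return(sim)
  }
  stop("rejection-resampling cap reached: could not build a motif-free ",
       "background")
}

generate_genome_once <- function(cfg) {
  n_unit_genes_max <- cfg$n_regulon_units * cfg$genes_per_unit_range[2]
  with_ebp <- rep(FALSE, cfg$n_regulon_units)
  if (cfg$n_ebp > 0) {
    if (cfg$n_ebp > cfg$n_regulon_units)
      stop("n_ebp cannot exceed n_regulon_units")
    with_ebp[sample(cfg$n_regulon_units, cfg$n_ebp)] <- TRUE
  }
  blocks <- lapply(seq_len(cfg$n_regulon_units), function(i)
    make_unit_block(cfg, with_ebp = with_ebp[i]))
  n_used <- sum(vapply(blocks, function(b) length(b$genes), integer(1)))
  n_singles <- cfg$n_genes - n_used
  if (n_singles < 0)
    stop("n_genes too small for the requested units and EBP genes (need >= ",
         n_used, ")")
  blocks <- c(blocks, replicate(n_singles, make_single_block(cfg),
                                simplify = FALSE))
  blocks <- blocks[sample(length(blocks))]
  layout_blocks(blocks, cfg, prefix = "SYN")
}

#' Generate a family of genomes with prescribed regulon conservation
#'
#' Genome A is built with [generate_genome]; each further genome reuses A's
#' gene sequences (so reciprocal-best-hit orthology is unambiguous) but
#' realises a prescribed conservation status per regulon unit:
#' `conserved-with-motif` keeps the unit and replants a consensus upstream,
#' `conserved-gene-only` keeps the genes without a motif, and `absent` drops
#' the unit entirely. Block order, strands, gaps and background are
#' redrawn per genome.
#'
#' @param config a [genome_sim_config].
#' @param statuses list of character vectors (one per additional genome,
#'   each of length `n_regulon_units`) with values
#'   `conserved-with-motif` / `conserved-gene-only` / `absent`.
#' @param seed integer RNG seed.
#' @return list: `genomes` (A first), `truths`, `statuses` (as prescribed,
#'   named by A's unit head gene), `gene_maps` (data.frames mapping A gene
#'   ids to each derived genome's ids).
#' @export
generate_genome_family <- function(config = genome_sim_config(),
                                   statuses, seed = 1) {
  stopifnot(is.list(statuses))
  a <- generate_genome(config, seed)
  units <- a$truth$units
  if (any(vapply(statuses, length, integer(1)) != nrow(units)))
    stop("each status vector needs one entry per regulon unit (",
         nrow(units), ")")
  genomes <- list(a$genome); truths <- list(a$truth)
  gene_maps <- list(); status_tabs <- list()
  for (gi in seq_along(statuses)) {
    st <- statuses[[gi]]
    if (!all(st %in% c("conserved-with-motif", "conserved-gene-only",
                       "absent")))
      stop("unknown conservation status in prescription")
    prefix <- sprintf("SYN%s", LETTERS[gi + 1])
    blocks <- list(); origin <- list()
    for (ui in seq_len(nrow(units))) {
      if (st[ui] == "absent") next
      genes_a <- strsplit(units$genes[ui], ",")[[1]]
      if (!is.na(units$ebp_gene_id[ui]))
        genes_a <- c(genes_a, units$ebp_gene_id[ui])
      cds <- a$truth$cds_seqs[genes_a]
      b <- make_unit_block(config, with_ebp = FALSE,
                           with_motif = st[ui] == "conserved-with-motif")
      b$genes <- lapply(genes_a, function(id) list(
        seq = unname(cds[[id]]),
        product = a$genome$features$product[
          a$genome$features$feature_id == id],
        is_ebp = id %in% a$truth$ebp_genes))
      k <- length(b$genes)
      is_ebp <- vapply(b$genes, `[[`, logical(1), "is_ebp")
      gaps <- if (k > 1) sample(5:config$max_gap, k - 1, replace = TRUE)
              else integer()
      if (k > 1 && is_ebp[k])
        gaps[k - 1] <- sample((config$max_gap + 50):
                                min(800L, config$ebp_span), 1)
      b$gaps <- gaps
      blocks[[length(blocks) + 1]] <- b
      origin[[length(origin) + 1]] <- genes_a
    }
    singles <- setdiff(names(a$truth$cds_seqs),
                       c(unlist(strsplit(units$genes, ",")),
                         units$ebp_gene_id[!is.na(units$ebp_gene_id)]))
    for (id in singles) {
      b <- make_single_block(config)
      b$genes[[1]]$seq <- unname(a$truth$cds_seqs[[id]])
      b$genes[[1]]$product <- a$genome$features$product[
        a$genome$features$feature_id == id]
      blocks[[length(blocks) + 1]] <- b
      origin[[length(origin) + 1]] <- id
    }
    sh <- sample(length(blocks))
    blocks <- blocks[sh]; origin <- origin[sh]
    out <- NULL
    for (attempt in seq_len(1000)) {
      cand <- layout_blocks(blocks, config, prefix = prefix)
      if (!config$background_motif_free) { out <- cand; break }
      h <- scan_consensus(cand$genome, config$pattern)
      pl <- cand$truth$motifs
      if (nrow(h) == nrow(pl) &&
          all(paste(h$contig_id, h$start, h$strand) %in%
              paste(pl$contig_id, pl$start, pl$strand))) {
        out <- cand
        break
      }
    }
    if (is.null(out))
      stop("rejection-resampling cap reached for derived genome ", prefix)
    # map A ids -> derived ids via block origin bookkeeping: features are
    # re-labelled in genomic order, so recover by matching CDS sequences
    map <- data.frame(gene_a = names(a$truth$cds_seqs), stringsAsFactors = FALSE)
    map$gene_b <- names(out$truth$cds_seqs)[
      match(a$truth$cds_seqs[map$gene_a], out$truth$cds_seqs)]
    gene_maps[[gi]] <- map
    status_tabs[[gi]] <- setNames(st, units$unit)
    genomes[[gi + 1]] <- out$genome
    truths[[gi + 1]] <- out$truth
  }
  list(genomes = genomes, truths = truths, statuses = status_tabs,
       gene_maps = gene_maps)
}

codon_single_edits <- function(codon) {
  ref_aa <- translate_cds(codon)
  out <- list()
  for (off in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, off, off))) {
      alt <- codon
      substr(alt, off, off) <- b
      alt_aa <- translate_cds(alt)
      cls <- if (ref_aa == alt_aa) "None"
        else if (alt_aa == "X") "Truncation"
        else "Substitution"
      out[[length(out) + 1]] <- data.frame(
        offset = off, alt_coding = b, ref_aa = ref_aa, alt_aa = alt_aa,
        class = cls, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate point mutations realising requested effect classes
#'
#' Samples single-nucleotide variants against a genome so that each variant
#' annotates to a requested class: `Substitution` (non-synonymous codon
#' edit), `Truncation` (stop-creating edit), `None` (synonymous edit),
#' `Intergenic` (position outside every CDS). Variant records are expressed
#' on the plus strand, as in a VCF.
#'
#' @param genome an [AnnotatedGenome] with CDS features.
#' @param counts named integer vector over the four classes, e.g.
#'   `c(Substitution = 10, Truncation = 1, None = 2, Intergenic = 2)`.
#' @param seed integer RNG seed.
#' @return list: `variants` (data.frame `contig_id`, `genome_position`
#'   1-based, `ref_base`, `alt_base`) sorted by position, and `truth`
#'   (`class`, `gene_id`) aligned row-wise with `variants`.
#' @export
generate_variants <- function(genome,
                              counts = c(Substitution = 10, Truncation = 1,
                                         None = 2, Intergenic = 2),
                              seed = 1) {
  set.seed(seed)
  classes <- c("Substitution", "Truncation", "None", "Intergenic")
  counts <- counts[intersect(names(counts), classes)]
  cds <- cds_features(genome)
  if (!nrow(cds) && any(counts[setdiff(names(counts), "Intergenic")] > 0))
    stop("genome has no CDS features")
  used <- integer()
  rows <- list(); truth <- list()
  for (cls in names(counts)) {
    for (r in seq_len(counts[[cls]])) {
      v <- NULL
      for (try in seq_len(500)) {
        if (cls == "Intergenic") {
          ctg <- sample(names(genome$contigs), 1)
          pos1 <- sample(nchar(genome$contigs[[ctg]]), 1)
          if (!identical(locate_in_cds(genome, ctg, pos1), "intergenic"))
            next
          ref <- substr(genome$contigs[[ctg]], pos1, pos1)
          if (!ref %in% c("A", "C", "G", "T") || pos1 %in% used) next
          v <- list(contig_id = ctg, genome_position = pos1, ref_base = ref,
                    alt_base = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                    gene_id = NA_character_)
          break
        }
        f <- cds[sample(nrow(cds), 1), ]
        n_codons <- (f$end - f$start) %/% 3
        if (n_codons < 4) next
        j <- sample(2:(n_codons - 1), 1)
        codon_start <- 3L * (j - 1L) + 1L
        seq <- extract_cds(genome, f$feature_id)
        codon <- substr(seq, codon_start, codon_start + 2L)
        if (grepl("[^ACGT]", codon)) next
        edits <- codon_single_edits(codon)
        edits <- edits[edits$class == cls, , drop = FALSE]
        if (!nrow(edits)) next
        e <- edits[sample(nrow(edits), 1), ]
        p <- codon_start + e$offset - 1L        # coding-strand CDS position
        pos1 <- if (f$strand == "+") f$start + p else f$end - p + 1L
        if (pos1 %in% used) next
        ref <- substr(genome$contigs[[f$contig_id]], pos1, pos1)
        alt <- if (f$strand == "+") e$alt_coding else revcomp(e$alt_coding)
        v <- list(contig_id = f$contig_id, genome_position = pos1,
                  ref_base = ref, alt_base = alt, gene_id = f$feature_id)
        break
      }
      if (is.null(v))
        stop("could not realise effect class ", cls, " in this genome")
      used <- c(used, v$genome_position)
      rows[[length(rows) + 1]] <- data.frame(
        contig_id = v$contig_id, genome_position = v$genome_position,
        ref_base = v$ref_base, alt_base = v$alt_base,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        class = cls, gene_id = v$gene_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(variants = data.frame(contig_id = character(),
                                      genome_position = integer(),
                                      ref_base = character(),
                                      alt_base = character()),
                truth = data.frame(class = character(),
                                   gene_id = character())))
  variants <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  ord <- order(variants$contig_id, variants$genome_position)
  list(variants = variants[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE])
}

#' Generate a noisy Cq table with known expression ratios
#'
#' Inverts the efficiency-corrected quantification relation: sample loading
#' factors and per-target baseline cycles are drawn, true template amounts
#' follow the prescribed ratios, and
#' `Cq = Cq0_t - log(amount) / log(E_t)` plus Gaussian replicate noise.
#' [relative_expression] on the noiseless table returns the true ratios
#' exactly.
#'
#' @param true_ratios data.frame (`sample_id`, `target_id`, `ratio`) of
#'   fold-changes relative to the calibrator, or a named numeric vector for
#'   a single test sample called `"test"`.
#' @param efficiencies named fold-per-cycle efficiencies covering every
#'   target plus the reference.
#' @param noise_sd Gaussian Cq noise standard deviation in cycles
#'   (default 0.15).
#' @param replicates technical replicates per (sample, target) (default 2).
#' @param reference reference (housekeeping) target id (default `"ref"`).
#' @param calibrator calibrator sample id (default `"calibrator"`).
#' @param seed integer RNG seed.
#' @return list: `cq` (data.frame `sample_id`, `target_id`, `replicate`,
#'   `cq`), `truth` (the true ratio table), `efficiencies`.
#' @export
generate_cq_table <- function(true_ratios, efficiencies, noise_sd = 0.15,
                              replicates = 2, reference = "ref",
                              calibrator = "calibrator", seed = 1) {
  set.seed(seed)
  if (!is.data.frame(true_ratios))
    true_ratios <- data.frame(sample_id = "test",
                              target_id = names(true_ratios),
                              ratio = unname(true_ratios),
                              stringsAsFactors = FALSE)
  if (any(true_ratios$ratio <= 0)) stop("true ratios must be positive")
  targets <- unique(c(true_ratios$target_id, reference))
  miss <- setdiff(targets, names(efficiencies))
  if (length(miss)) stop("no efficiency for: ", paste(miss, collapse = ", "))
  samples <- unique(c(calibrator, true_ratios$sample_id))
  cq0 <- setNames(runif(length(targets), 18, 26), targets)
  loading <- setNames(2^runif(length(samples), -1, 1), samples)
  loading[calibrator] <- 1
  rows <- list()
  for (s in samples) {
    for (t in targets) {
      amount <- if (t == reference || s == calibrator) 1
        else true_ratios$ratio[true_ratios$sample_id == s &
                                 true_ratios$target_id == t]
      if (!length(amount)) next
      mu <- cq0[[t]] - log(loading[[s]] * amount) / log(efficiencies[[t]])
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, target_id = t, replicate = seq_len(replicates),
        cq = mu + rnorm(replicates, 0, noise_sd), stringsAsFactors = FALSE)
    }
  }
  list(cq = do.call(rbind, rows), truth = true_ratios,
       efficiencies = efficiencies[targets])
}

#' Write a variant list as a minimal VCF v4.2 file
#'
#' @param variants data.frame with `contig_id`, `genome_position`,
#'   `ref_base`, `alt_base`.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    body <- data.frame(variants$contig_id, variants$genome_position, ".",
                       variants$ref_base, variants$alt_base, ".", ".", ".")
    write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Write the full fixture set for a simulated study
#'
#' Emits FASTA + GFF3 for the genome, a VCF for the variants and TSV truth
#' tables into a directory.
#'
#' @param sim output of [generate_genome].
#' @param dir output directory (created if needed).
#' @param variants optional output of [generate_variants].
#' @return invisibly, the directory.
#' @export
write_fixtures <- function(sim, dir, variants = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fasta"),
               file.path(dir, "genome.gff3"))
  m <- sim$truth$motifs
  m$start <- to_file_start(m$start)
  write.table(m, file.path(dir, "truth_motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$units, file.path(dir, "truth_units.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(variants)) {
    write_variants_vcf(variants$variants, file.path(dir, "variants.vcf"))
    write.table(cbind(variants$variants, variants$truth),
                file.path(dir, "truth_variants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
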