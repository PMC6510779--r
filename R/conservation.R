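#' Translated proteome of a genome
#'
#' @param genome an [AnnotatedGenome].
#' @return named character vector of amino-acid sequences, one per CDS whose
#'   length is a multiple of 3 (others are skipped with a warning); trailing
#'   stop sentinels are removed.
#' @export
proteome <- function(genome) {
  cds <- cds_features(genome)
  out <- character()
  for (id in cds$feature_id) {
    s <- extract_cds(genome, id)
    if (nchar(s) %% 3 != 0) {
      warning("CDS ", id, " length not a multiple of 3; skipped")
      next
    }
    aa <- translate_cds(s)
    out[id] <- sub("X$", "", aa)
  }
  out
}

#' Reciprocal-best-hit orthology between two proteomes
#'
#' All-vs-all Smith-Waterman local alignment (BLOSUM62, affine gaps) reduced
#' to mutual best-scoring pairs: gene a in A pairs with gene b in B iff b is
#' a's best hit and a is b's best hit, and the score reaches `min_score`.
#' Ties are broken by longer alignment, then lexicographic gene id.
#'
#' @param proteome_a,proteome_b named character vectors of protein sequences
#'   (see [proteome]).
#' @param gap_opening,gap_extension affine gap penalties (defaults 11 / 1).
#' @param min_score minimum alignment score for a pair (default 50).
#' @param substitution_matrix scoring matrix name (default `"BLOSUM62"`).
#' @return list of class `OrthologMap`: `pairs` (data.frame `gene_a`,
#'   `gene_b`, `score`), `unmatched_a`, `unmatched_b`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 gap_opening = 11, gap_extension = 1,
                                 min_score = 50,
                                 substitution_matrix = "BLOSUM62") {
  if (!length(proteome_a) || !length(proteome_b))
    stop("empty proteome")
  a_set <- Biostrings::AAStringSet(proteome_a)
  scores <- matrix(NA_real_, length(proteome_a), length(proteome_b),
                   dimnames = list(names(proteome_a), names(proteome_b)))
  widths <- scores
  for (j in seq_along(proteome_b)) {
    al <- Biostrings::pairwiseAlignment(
      a_set, Biostrings::AAString(proteome_b[[j]]),
      type = "local", substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension)
    scores[, j] <- Biostrings::score(al)
    widths[, j] <- Biostrings::nchar(al)
  }
  best <- function(v, w, ids) {
    # best score; ties -> longer alignment -> lexicographic id
    o <- order(-v, -w, ids)
    o[1]
  }
  best_ab <- vapply(seq_len(nrow(scores)), function(i)
    best(scores[i, ], widths[i, ], colnames(scores)), integer(1))
  best_ba <- vapply(seq_len(ncol(scores)), function(j)
    best(scores[, j], widths[, j], rownames(scores)), integer(1))
  pairs <- list()
  for (i in seq_len(nrow(scores))) {
    j <- best_ab[i]
    if (best_ba[j] == i && scores[i, j] >= min_score)
      pairs[[length(pairs) + 1]] <- data.frame(
        gene_a = rownames(scores)[i], gene_b = colnames(scores)[j],
        score = scores[i, j], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(gene_a = character(), gene_b = character(),
                           score = numeric(), stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(names(proteome_a), pairs$gene_a),
                 unmatched_b = setdiff(names(proteome_b), pairs$gene_b)),
            class = "OrthologMap")
}

#' Read an externally supplied ortholog table
#'
#' Lets users replay real genome pairs with orthology computed elsewhere
#' (e.g. a synteny platform) instead of the built-in aligner.
#'
#' @param path TSV with columns `gene_a`, `gene_b` and optional `score`.
#' @return an `OrthologMap`.
#' @export
read_ortholog_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("ortholog table needs columns gene_a, gene_b")
  if (is.null(tab$score)) tab$score <- NA_real_
  structure(list(pairs = tab[c("gene_a", "gene_b", "score")],
                 unmatched_a = character(), unmatched_b = character()),
            class = "OrthologMap")
}

regulon_units <- function(assignments) {
  ok <- !is.na(assignments$gene_id)
  unique(assignments$transcriptional_unit[ok])
}

#' Conservation of predicted regulon units across genomes
#'
#' For every transcriptional unit of the query regulon, decides against a
#' target regulon: `conserved-with-motif` if any member gene's ortholog is
#' itself part of a motif-assigned unit in the target;
#' `conserved-gene-only` if an ortholog exists but carries no assigned
#' motif; `absent` if no member gene has an ortholog (the pattern of a
#' strain-specific gene).
#'
#' @param regulon_a,regulon_b assignment tables from [assign_regulon] for
#'   the query and target genomes.
#' @param ortholog_map an `OrthologMap` with `gene_a` from the query genome
#'   and `gene_b` from the target.
#' @return data.frame of class addition `ConservationReport`: `unit` (first
#'   gene id), `genes`, `status`.
#' @export
compare_regulons <- function(regulon_a, regulon_b, ortholog_map) {
  units_a <- regulon_units(regulon_a)
  genes_b_regulon <- unique(unlist(strsplit(
    regulon_b$transcriptional_unit[!is.na(regulon_b$gene_id)], ",")))
  map <- ortholog_map$pairs
  out <- data.frame(unit = character(), genes = character(),
                    status = character(), stringsAsFactors = FALSE)
  for (u in units_a) {
    members <- strsplit(u, ",")[[1]]
    orth <- map$gene_b[map$gene_a %in% members]
    status <- if (!length(orth)) "absent"
      else if (any(orth %in% genes_b_regulon)) "conserved-with-motif"
      else "conserved-gene-only"
    out <- rbind(out, data.frame(unit = members[1], genes = u,
                                 status = status, stringsAsFactors = FALSE))
  }
  class(out) <- c("ConservationReport", class(out))
  out
}
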