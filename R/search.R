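# Six-frame translated search of a protein query against genome DNA, and
# ranking of genomes by best normalized hit. The search is native: each
# frame's translation is split at stop codons into blocks, each block >= 10
# residues is locally aligned to the query, and the best-scoring hit position
# is mapped back to genomic coordinates, frame- and strand-aware.

#' Search parameters
#'
#' @param min_norm_score Minimal normalized score in percent; the orthology
#'   discriminant, accepted range `[10, 100]`, default 30.
#' @param mode `"best_hit"` (one hit per genome, the default) or `"all_hits"`.
#' @return A `search_params` object.
#' @export
search_params <- function(min_norm_score = 30, mode = c("best_hit", "all_hits")) {
  mode <- match.arg(mode)
  if (!is.numeric(min_norm_score) || length(min_norm_score) != 1L ||
      min_norm_score < 10 || min_norm_score > 100)
    stop("min_norm_score must be a single value in [10, 100]")
  structure(list(min_norm_score = as.numeric(min_norm_score), mode = mode),
            class = "search_params")
}

#' Self-alignment score of the query
#'
#' The query is compared to itself once; all later hit scores are expressed
#' relative to this denominator.
#'
#' @param query Cleaned protein string of length >= 10.
#' @param params An [align_params()] object.
#' @return Strictly positive integer score.
#' @export
self_score <- function(query, params = align_params()) {
  if (nchar(query) < 10L)
    stop("query too short after cleaning (", nchar(query), " < 10 residues)")
  s <- sw_gotoh(query, query, params)$score
  stopifnot(s > 0)
  s
}

# Stop-delimited translated blocks of all six frames.
# Returns a data.frame: frame (+-1..3), aa_start (0-based residue offset
# within the frame translation), protein. Blocks < min_len residues dropped.
six_frame_blocks <- function(genome, min_len = 10L) {
  L <- genome$length_bp
  out <- list()
  gc11 <- .genetic_code_11()
  fwd <- Biostrings::DNAString(genome$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  for (strand in c(1L, -1L)) {
    dna <- if (strand > 0) fwd else rev
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3L
      if (n_codons < 1L) next
      sub <- Biostrings::subseq(dna, off + 1L, off + 3L * n_codons)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(sub, genetic.code = gc11, if.fuzzy.codon = "X")))
      # split at stops, keeping residue offsets
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
      starts <- cumsum(c(0L, nchar(pieces) + 1L))
      keep <- nchar(pieces) >= min_len
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          frame = strand * (off + 1L),
          aa_start = starts[seq_along(pieces)][keep],
          protein = pieces[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), aa_start = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Map an aa interval [aa_from, aa_to) of a frame translation back to genomic
# nucleotide coordinates (0-based half-open on the forward strand).
.frame_to_genomic <- function(frame, aa_from, aa_to, L) {
  off <- abs(frame) - 1L
  nt_from <- off + 3L * aa_from
  nt_to <- off + 3L * aa_to
  if (frame > 0) c(nt_from, nt_to) else c(L - nt_to, L - nt_from)
}

#' Six-frame translated search of a protein against one genome
#'
#' The genome DNA is translated in all six reading frames; stop codons split
#' each frame into blocks, and every block of at least 10 residues is locally
#' aligned to the query. Hits at or above the normalized-score threshold are
#' returned sorted by decreasing normalized score, with the hit midpoint
#' mapped back to genomic coordinates.
#'
#' @param query Cleaned protein string.
#' @param genome A [genome_record()].
#' @param sparams A [search_params()] object.
#' @param aparams An [align_params()] object.
#' @param query_self Optional precomputed [self_score()] of the query.
#' @return Data frame of hits: `accession`, `center_bp`, `frame`,
#'   `raw_score`, `norm_score`.
#' @export
translated_search <- function(query, genome, sparams = search_params(),
                              aparams = align_params(), query_self = NULL) {
  if (is.null(query_self)) query_self <- self_score(query, aparams)
  empty <- data.frame(accession = character(), center_bp = integer(),
                      frame = integer(), raw_score = numeric(),
                      norm_score = numeric(), stringsAsFactors = FALSE)
  if (genome$length_bp < 3L) return(empty)
  blocks <- six_frame_blocks(genome)
  if (!nrow(blocks)) return(empty)
  raw <- sw_scores(blocks$protein, query, aparams)
  norm <- normalized_score(raw, query_self)
  keep <- which(norm >= sparams$min_norm_score)
  if (!length(keep)) return(empty)
  hits <- lapply(keep, function(i) {
    al <- sw_gotoh(blocks$protein[i], query, aparams)
    span <- .frame_to_genomic(blocks$frame[i],
                              blocks$aa_start[i] + al$query_span[1],
                              blocks$aa_start[i] + al$query_span[2],
                              genome$length_bp)
    data.frame(accession = genome$accession,
               center_bp = as.integer((span[1] + span[2] - 1L) %/% 2L),
               frame = blocks$frame[i], raw_score = raw[i],
               norm_score = norm[i], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$norm_score, hits$center_bp), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Merge hits whose windows of `width` bp would overlap by more than 50%,
# keeping the higher-scoring center (all-hits mode).
merge_overlapping_hits <- function(hits, width) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- logical(nrow(hits))
  kept_centers <- integer(0)
  for (i in seq_len(nrow(hits))) {        # hits already sorted by score desc
    c_i <- hits$center_bp[i]
    if (!length(kept_centers) || all(abs(kept_centers - c_i) > width / 2)) {
      keep[i] <- TRUE
      kept_centers <- c(kept_centers, c_i)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Rank genomes by their best normalized hit
#'
#' @param hits_by_genome Named list: accession to hit data frame (already
#'   threshold-filtered, as returned by [translated_search()]).
#' @return List with `ranking` (data frame: `accession`, `best` hit fields,
#'   sorted by decreasing best normalized score, ties broken by ascending
#'   accession) and `not_found` (accessions without hits).
#' @export
rank_genomes <- function(hits_by_genome) {
  has_hit <- vapply(hits_by_genome, function(h) nrow(h) > 0L, logical(1))
  not_found <- sort(names(hits_by_genome)[!has_hit])
  if (!any(has_hit))
    return(list(ranking = data.frame(accession = character(),
                                     center_bp = integer(), frame = integer(),
                                     raw_score = numeric(), norm_score = numeric(),
                                     stringsAsFactors = FALSE),
                not_found = not_found))
  best <- do.call(rbind, lapply(hits_by_genome[has_hit],
                                function(h) h[1L, , drop = FALSE]))
  best <- best[order(-best$norm_score, best$accession), , drop = FALSE]
  rownames(best) <- NULL
  list(ranking = best, not_found = not_found)
}
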