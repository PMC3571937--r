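# Window extraction and star-topology ortholog coloring.
#
# The top-ranked genome's best segment is the reference: its proteins are
# compared all-vs-all (connected components of the thresholded normalized
# score matrix give the colors; paralogs share a color), and every other
# segment's proteins are compared only to the reference (star topology),
# inheriting the color of their best reference match.

#' Extract a fixed-width genomic window around a coordinate
#'
#' Linear replicons clip the window at the ends; circular replicons return
#' exactly `width` bp with wrap-around, re-linearized for display. Genes
#' overlapping the window by at least 1 bp are kept with their full
#' (unclipped) coordinates; clipping happens at render time.
#'
#' @param genome A [genome_record()].
#' @param center_bp 0-based window center.
#' @param width Window width in bp (default 15000).
#' @param anchor Optional one-row hit data frame (from
#'   [translated_search()]) recorded as the segment's anchor.
#' @return A `segment` object.
#' @export
extract_segment <- function(genome, center_bp, width = 15000L, anchor = NULL) {
  L <- genome$length_bp
  stopifnot(center_bp >= 0, center_bp < L)
  half <- width / 2
  if (genome$is_circular && width < L) {
    ws <- as.integer(floor(center_bp - half)) %% L
    we <- (ws + as.integer(width)) %% L
    wrapped <- we <= ws
    wlen <- as.integer(width)
  } else {
    ws <- max(0L, as.integer(floor(center_bp - half)))
    we <- min(L, as.integer(floor(center_bp + half)))
    wrapped <- FALSE
    wlen <- we - ws
  }
  f <- genome$features
  if (nrow(f)) {
    if (!wrapped) {
      keep <- f$end > ws & f$start < we
    } else {
      keep <- (f$end > ws) | (f$start < we)
    }
    genes <- f[keep, , drop = FALSE]
  } else genes <- f
  if (nrow(genes)) {
    miss <- which(is.na(genes$translation))
    for (i in miss) genes$translation[i] <- translate_cds(genes[i, ], genome)
    # display coordinates relative to the window start, wrap-aware
    genes$display_start <- if (wrapped) (genes$start - ws) %% L else genes$start - ws
    genes$display_end <- genes$display_start + (genes$end - genes$start)
    genes <- genes[order(genes$display_start), , drop = FALSE]
    genes$color <- NA_integer_
    genes$norm_vs_ref <- NA_real_
    rownames(genes) <- NULL
  } else {
    genes$display_start <- integer(); genes$display_end <- integer()
    genes$color <- integer(); genes$norm_vs_ref <- numeric()
  }
  structure(list(accession = genome$accession, organism = genome$organism,
                 window_start = ws, window_end = we, window_len = wlen,
                 wrapped = wrapped, genes = genes, anchor = anchor,
                 non_syntenic = FALSE),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> %s [%d, %d) %d bp, %d genes\n", x$accession,
              x$window_start, x$window_end, x$window_len, nrow(x$genes)))
  invisible(x)
}

# Pairwise normalized score of two proteins: raw local score over the
# self-score of the longer sequence, so a fusion scores moderately (not 100)
# against each of its parts.
.pair_norm_matrix <- function(proteins, selfs, aparams) {
  n <- length(proteins)
  raw <- matrix(0, n, n)
  for (i in seq_len(n))
    raw[i, ] <- sw_scores(proteins, proteins[i], aparams)
  lens <- nchar(proteins)
  denom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    longer <- if (lens[i] > lens[j]) i else if (lens[j] > lens[i]) j else
      if (selfs[i] >= selfs[j]) i else j
    denom[i, j] <- selfs[longer]
  }
  norm <- 100 * raw / denom
  norm[norm < 0] <- 0
  norm[norm > 100] <- 100
  norm
}

#' Color the reference segment's proteins
#'
#' All-vs-all normalized scores among the reference proteins (each pair
#' normalized by the self-score of the longer sequence); pairs at or above
#' the threshold are edges, connected components get one color each (so
#' paralogs share a color) and singletons get singleton colors. Colors are
#' assigned in left-to-right gene order starting at 1.
#'
#' @param reference A [extract_segment()] result with at least one gene.
#' @param threshold Normalized-score threshold in percent.
#' @param aparams An [align_params()] object.
#' @return A `color_map`: list with `reference_colors` (integer per reference
#'   gene), `proteins`, `self_scores`, `n_colors`.
#' @export
build_reference_colors <- function(reference, threshold = 30,
                                   aparams = align_params()) {
  genes <- reference$genes
  if (!nrow(genes)) stop("reference segment has no genes")
  proteins <- genes$translation
  selfs <- vapply(proteins, function(p) sw_gotoh(p, p, aparams)$score,
                  numeric(1), USE.NAMES = FALSE)
  norm <- .pair_norm_matrix(proteins, selfs, aparams)
  adj <- norm >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  colors <- integer(length(comp))
  next_id <- 1L
  for (i in order(genes$display_start)) {     # left-to-right assignment
    members <- which(comp == comp[i])
    if (colors[i] == 0L) {
      colors[members] <- next_id
      next_id <- next_id + 1L
    }
  }
  structure(list(reference_colors = colors, proteins = proteins,
                 self_scores = selfs, n_colors = next_id - 1L,
                 reference_accession = reference$accession),
            class = "color_map")
}

#' Propagate reference colors to another segment
#'
#' Each protein of `other` is aligned to every reference protein; when the
#' best normalized score (normalized by the longer sequence's self-score)
#' reaches the threshold, the gene inherits that reference protein's color,
#' ties resolved toward the leftmost reference gene. Genes without a match
#' stay uncolored; a segment with no colored gene is flagged non-syntenic.
#' Segments are never compared to each other, only to the reference.
#'
#' @param colors A [build_reference_colors()] result.
#' @param reference The reference segment the colors were built on.
#' @param other Segment to color.
#' @param threshold Normalized-score threshold in percent.
#' @param aparams An [align_params()] object.
#' @return `other`, with `genes$color`, `genes$norm_vs_ref` and
#'   `non_syntenic` filled in.
#' @export
propagate_colors <- function(colors, reference, other, threshold = 30,
                             aparams = align_params()) {
  ref_prot <- colors$proteins
  ref_selfs <- colors$self_scores
  ref_lens <- nchar(ref_prot)
  ref_order <- order(reference$genes$display_start)
  genes <- other$genes
  for (i in seq_len(nrow(genes))) {
    p <- genes$translation[i]
    raw <- sw_scores(ref_prot, p, aparams)
    self_p <- sw_gotoh(p, p, aparams)$score
    lp <- nchar(p)
    denom <- ifelse(ref_lens > lp, ref_selfs,
                    ifelse(lp > ref_lens, self_p, pmax(ref_selfs, self_p)))
    norm <- pmin(100, pmax(0, 100 * raw / denom))
    best <- max(norm)
    if (best >= threshold) {
      cand <- which(norm == best)
      # leftmost reference gene wins ties
      left <- cand[which.min(match(cand, ref_order))]
      genes$color[i] <- colors$reference_colors[left]
      genes$norm_vs_ref[i] <- best
    }
  }
  other$genes <- genes
  other$non_syntenic <- nrow(genes) == 0L || all(is.na(genes$color))
  other
}

#' Run the full synteny pipeline
#'
#' Orchestrates: query self-score, six-frame translated search per genome,
#' genome ranking, window extraction per retained hit (best hit only, or all
#' merged hits in all-hits mode), reference coloring on the top-ranked
#' genome's best segment, and color propagation to every other segment.
#'
#' @param query Query protein, raw text or FASTA; cleaned with
#'   [clean_query()].
#' @param genomes List of [genome_record()] objects (at most 100).
#' @param sparams A [search_params()] object.
#' @param aparams An [align_params()] object.
#' @param width Window width in bp (default 15000).
#' @return A `synteny_report`: query, parameters, ordered colored segments
#'   (`rows`), `not_found` genome table, the `color_map`.
#' @export
run_synteny <- function(query, genomes, sparams = search_params(),
                        aparams = align_params(), width = 15000L) {
  if (length(genomes) < 1L) stop("at least one genome is required")
  if (length(genomes) > 100L)
    stop("at most 100 genomes can be analyzed in one job (got ",
         length(genomes), ")")
  accs <- vapply(genomes, function(g) g$accession, character(1))
  if (anyDuplicated(accs)) stop("duplicate genome accessions")
  query <- clean_query(query)
  qself <- self_score(query, aparams)

  hits_by_genome <- lapply(genomes, function(g)
    translated_search(query, g, sparams, aparams, query_self = qself))
  names(hits_by_genome) <- accs
  ranked <- rank_genomes(hits_by_genome)

  org_of <- stats::setNames(vapply(genomes, function(g) g$organism,
                                   character(1)), accs)
  not_found <- data.frame(accession = ranked$not_found,
                          organism = unname(org_of[ranked$not_found]),
                          stringsAsFactors = FALSE)

  rows <- list(); color_map <- NULL; reference <- NULL
  if (nrow(ranked$ranking)) {
    genome_of <- stats::setNames(genomes, accs)
    for (r in seq_len(nrow(ranked$ranking))) {
      acc <- ranked$ranking$accession[r]
      g <- genome_of[[acc]]
      hits <- hits_by_genome[[acc]]
      if (sparams$mode == "best_hit") hits <- hits[1L, , drop = FALSE]
      else hits <- merge_overlapping_hits(hits, width)
      for (h in seq_len(nrow(hits))) {
        seg <- extract_segment(g, hits$center_bp[h], width,
                               anchor = hits[h, , drop = FALSE])
        seg$rank <- r
        rows[[length(rows) + 1L]] <- seg
      }
    }
    # reference: best-scoring window of the top-ranked genome
    reference <- rows[[1L]]
    color_map <- build_reference_colors(reference, sparams$min_norm_score,
                                        aparams)
    rows[[1L]]$genes$color <- color_map$reference_colors
    rows[[1L]]$genes$norm_vs_ref <- 100 * color_map$self_scores /
      color_map$self_scores
    if (length(rows) > 1L)
      for (i in 2:length(rows))
        rows[[i]] <- propagate_colors(color_map, reference, rows[[i]],
                                      sparams$min_norm_score, aparams)
  }
  structure(list(query = query, query_length = nchar(query),
                 query_self_score = qself,
                 params = list(min_norm_score = sparams$min_norm_score,
                               mode = sparams$mode, width = as.integer(width),
                               gap_open = aparams$gap_open,
                               gap_extend = aparams$gap_extend),
                 rows = rows, not_found = not_found, color_map = color_map),
            class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf("<synteny_report> query %d aa | %d segment row(s) | %d not found\n",
              x$query_length, length(x$rows), nrow(x$not_found)))
  for (s in x$rows)
    cat(sprintf("  %2d. %s (%s): %d genes, %d colored\n", s$rank, s$accession,
                s$organism, nrow(s$genes), sum(!is.na(s$genes$color))))
  if (nrow(x$not_found))
    cat("  not found in:", paste(x$not_found$accession, collapse = ", "), "\n")
  invisible(x)
}
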