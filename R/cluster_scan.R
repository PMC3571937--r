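# Multi-query gene-cluster scanner: genomes are scored for co-occurrence of
# hits to several query proteins within a bounded inter-hit distance
# (center-to-center, strictly below max_gap). This is how rare complete
# clusters -- e.g. the four-gene tRNA-modification complex operon -- are
# detected across a genome library.

#' Scan one genome for a multi-query gene cluster
#'
#' All above-threshold hits of all queries are pooled, sorted by genomic
#' center, and greedily chained while the distance between consecutive
#' centers stays strictly below `max_gap`. Each maximal chain is reported;
#' a chain is complete when every query is represented at least once.
#' Paralogous hits of one query may appear multiple times in a chain.
#'
#' @param queries Named list/character vector of protein strings (>= 2).
#' @param genome A [genome_record()].
#' @param max_gap Maximal center-to-center distance in bp (default 8000,
#'   strict `<`).
#' @param min_norm Normalized-score threshold in percent (default 30).
#' @param aparams An [align_params()] object.
#' @return List of `cluster_hit` objects: `accession`, `members` (data frame
#'   `query_id`, `center_bp`, `norm_score`, `frame`), `span` (0-based
#'   half-open interval over member centers), `complete`.
#' @export
scan_clusters <- function(queries, genome, max_gap = 8000L, min_norm = 30,
                          aparams = align_params()) {
  if (length(queries) < 2L) stop("at least 2 queries are required")
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    names(queries) <- paste0("q", seq_along(queries))
  sp <- search_params(min_norm_score = min_norm, mode = "all_hits")
  pooled <- do.call(rbind, lapply(names(queries), function(id) {
    q <- clean_query(queries[[id]])
    h <- translated_search(q, genome, sp, aparams)
    if (nrow(h)) cbind(query_id = id, h, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(pooled) || !nrow(pooled)) return(list())
  pooled <- pooled[order(pooled$center_bp, pooled$query_id), , drop = FALSE]
  gaps <- diff(pooled$center_bp)
  chain_id <- cumsum(c(1L, as.integer(gaps >= max_gap)))
  lapply(split(pooled, chain_id), function(m) {
    rownames(m) <- NULL
    structure(list(accession = genome$accession, organism = genome$organism,
                   members = m[, c("query_id", "center_bp", "norm_score",
                                   "frame")],
                   span = c(min(m$center_bp), max(m$center_bp) + 1L),
                   complete = all(names(queries) %in% m$query_id)),
              class = "cluster_hit")
  })
}

#' @export
print.cluster_hit <- function(x, ...) {
  cat(sprintf("<cluster_hit> %s [%d, %d) %s: %s\n", x$accession, x$span[1],
              x$span[2], if (x$complete) "complete" else "partial",
              paste(x$members$query_id, collapse = "+")))
  invisible(x)
}

#' Scan a genome library for a multi-query cluster
#'
#' Runs [scan_clusters()] on every genome and tabulates the best chain per
#' genome, sorted by completeness first and then by increasing span.
#'
#' @param queries Named list of protein strings.
#' @param genomes List of [genome_record()] objects with unique accessions.
#' @param max_gap,min_norm,aparams Passed to [scan_clusters()].
#' @return Data frame: `accession`, `organism`, `n_chains`, `complete`,
#'   `n_members`, `n_queries_found`, `span_start`, `span_end`. The full
#'   chain lists are attached as the `clusters` attribute (named by
#'   accession).
#' @export
scan_library <- function(queries, genomes, max_gap = 8000L, min_norm = 30,
                         aparams = align_params()) {
  accs <- vapply(genomes, function(g) g$accession, character(1))
  if (!length(genomes)) {
    tab <- data.frame(accession = character(), organism = character(),
                      n_chains = integer(), complete = logical(),
                      n_members = integer(), n_queries_found = integer(),
                      span_start = integer(), span_end = integer(),
                      stringsAsFactors = FALSE)
    attr(tab, "clusters") <- list()
    return(tab)
  }
  if (anyDuplicated(accs))
    stop("duplicate genome accessions: ",
         paste(unique(accs[duplicated(accs)]), collapse = ", "))
  all_chains <- lapply(genomes, function(g)
    scan_clusters(queries, g, max_gap, min_norm, aparams))
  names(all_chains) <- accs
  rows <- lapply(seq_along(genomes), function(i) {
    ch <- all_chains[[i]]
    if (!length(ch))
      return(data.frame(accession = accs[i], organism = genomes[[i]]$organism,
                        n_chains = 0L, complete = FALSE, n_members = 0L,
                        n_queries_found = 0L, span_start = NA_integer_,
                        span_end = NA_integer_, stringsAsFactors = FALSE))
    # best chain: complete first, then most queries, then tightest span
    score <- vapply(ch, function(x)
      x$complete * 1e9 + length(unique(x$members$query_id)) * 1e6 -
        (x$span[2] - x$span[1]) * 1e-3, numeric(1))
    best <- ch[[which.max(score)]]
    data.frame(accession = accs[i], organism = genomes[[i]]$organism,
               n_chains = length(ch), complete = best$complete,
               n_members = nrow(best$members),
               n_queries_found = length(unique(best$members$query_id)),
               span_start = best$span[1], span_end = best$span[2],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  span <- ifelse(is.na(tab$span_start), Inf, tab$span_end - tab$span_start)
  tab <- tab[order(-tab$complete, -tab$n_queries_found, span, tab$accession), ,
             drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "clusters") <- all_chains
  tab
}
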