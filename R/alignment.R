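# Affine-gap Smith-Waterman-Gotoh protein alignment and normalized scores.
#
# A gap of length k costs gap_open + k * gap_extend, matching the classic
# Gotoh formulation (and Biostrings' gapOpening/gapExtension convention).

.pkg_cache <- new.env(parent = emptyenv())

#' Amino-acid alphabet accepted throughout the package
#'
#' The 20 standard residues plus `X` (unknown). `X` and the stop symbol `*`
#' score zero against everything so annotation artifacts cannot create
#' spurious orthology.
#'
#' @return Character vector of single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c(strsplit("ARNDCQEGHILKMFPSTWYV", "", fixed = TRUE)[[1]], "X")
}

#' Default substitution matrix (BLOSUM62, X/* neutralized)
#'
#' BLOSUM62 restricted to the 20 standard residues plus `X` and `*`, with the
#' `X` and `*` rows and columns set to zero.
#'
#' @return Integer matrix with dimnames over the residue alphabet.
#' @export
default_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment())[1], envir = environment())
    keep <- c(aa_alphabet(), "*")
    mat <- mat[keep, keep]
    mat["X", ] <- 0L; mat[, "X"] <- 0L
    mat["*", ] <- 0L; mat[, "*"] <- 0L
    storage.mode(mat) <- "integer"
    .pkg_cache$blosum62 <- mat
  }
  .pkg_cache$blosum62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI matrix layout: `#` comment lines, a header row of
#' residue codes, then one labelled row of integers per residue.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(vals) <- list(labels, header)
  vals
}

#' Alignment parameters
#'
#' @param matrix Substitution matrix (symmetric, residue dimnames). Default
#'   [default_matrix()].
#' @param gap_open Positive gap-opening penalty (default 11).
#' @param gap_extend Positive per-position gap-extension penalty (default 1);
#'   must not exceed `gap_open`.
#' @param mode `"local"` (Smith-Waterman-Gotoh, the default) or `"global"`
#'   (Needleman-Wunsch-Gotoh, retained for auditability).
#' @return An `align_params` object.
#' @export
align_params <- function(matrix = default_matrix(), gap_open = 11L,
                         gap_extend = 1L, mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!is.matrix(matrix) || is.null(dimnames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must be square with identical row/col names")
  if (!isTRUE(all(matrix == t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), mode = mode),
            class = "align_params")
}

.check_protein <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]),
                 c(aa_alphabet(), "*"))
  if (length(bad))
    stop("invalid residue(s) in ", what, ": ", paste(bad, collapse = ", "))
  invisible(x)
}

#' Smith-Waterman-Gotoh alignment of two proteins
#'
#' Optimal affine-gap alignment; local by default so that unrelated sequences
#' score zero rather than accumulating uninterpretable negative scores.
#'
#' @param a,b Protein strings over the 20-letter alphabet plus `X`.
#' @param params An [align_params()] object.
#' @return List with `score` (non-negative integer in local mode) and
#'   `query_span`/`target_span`, 0-based half-open intervals (`c(0, 0)` when
#'   no positive-scoring alignment exists).
#' @export
sw_gotoh <- function(a, b, params = align_params()) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(list(score = 0, query_span = c(0L, 0L), target_span = c(0L, 0L)))
  .check_protein(a, "query"); .check_protein(b, "target")
  type <- if (params$mode == "local") "local" else "global"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = params$matrix, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = type)
  sc <- Biostrings::score(pa)
  if (params$mode == "local" && sc <= 0)
    return(list(score = 0, query_span = c(0L, 0L), target_span = c(0L, 0L)))
  list(score = sc,
       query_span = c(Biostrings::start(Biostrings::pattern(pa)) - 1L,
                      Biostrings::end(Biostrings::pattern(pa))),
       target_span = c(Biostrings::start(Biostrings::subject(pa)) - 1L,
                       Biostrings::end(Biostrings::subject(pa))))
}

# Vectorized score-only alignment of many patterns against one subject.
# Internal fast path used by the translated search and coloring steps.
sw_scores <- function(patterns, subject, params = align_params()) {
  if (length(patterns) == 0L) return(numeric(0))
  empties <- !nzchar(patterns) | !nzchar(subject)
  out <- numeric(length(patterns))
  if (nchar(subject) > 0L && any(!empties)) {
    type <- if (params$mode == "local") "local" else "global"
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns[!empties]),
      Biostrings::AAString(subject),
      substitutionMatrix = params$matrix, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = type, scoreOnly = TRUE)
    if (params$mode == "local") sc <- pmax(sc, 0)
    out[!empties] <- sc
  }
  out
}

#' Normalized alignment score
#'
#' Lerat-style self-normalization: the raw pairwise score over a
#' self-alignment score, as a percentage, clipped to `[0, 100]`. A self-match
#' is exactly 100 and the ratio is substitution-matrix-scale invariant enough
#' to threshold for orthology.
#'
#' @param hit_score Non-negative raw alignment score.
#' @param self_score Strictly positive self-alignment score used as the
#'   denominator.
#' @return A percentage in `[0, 100]`.
#' @export
normalized_score <- function(hit_score, self_score) {
  if (any(self_score <= 0)) stop("self_score must be strictly positive")
  if (any(hit_score < 0)) stop("hit_score must be non-negative")
  pmin(100, pmax(0, 100 * hit_score / self_score))
}
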