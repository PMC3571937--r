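# GenBank flat-file reading/writing and CDS translation.
#
# Internal coordinates are 0-based half-open; GenBank's 1-based inclusive
# coordinates are converted at the parse boundary and back at write time.
# Origin-spanning CDS on circular replicons are rotated out at parse time so
# all downstream window arithmetic stays linear.

#' Construct an annotated replicon record
#'
#' @param accession Accession string.
#' @param organism Organism name (genus + species + strain).
#' @param sequence DNA string over `A`,`C`,`G`,`T`,`N`.
#' @param is_circular Logical; circular replicon.
#' @param features Data frame with columns `locus_tag`, `product`, `start`,
#'   `end` (0-based half-open), `strand` (+1/-1), `translation` (may be `NA`,
#'   filled by [translate_cds()]).
#' @param rotation_offset Bases the sequence was rotated at parse time to
#'   linearize origin-spanning features (0 for untouched records).
#' @return A `genome_record` object.
#' @export
genome_record <- function(accession, organism, sequence, is_circular = FALSE,
                          features = empty_features(), rotation_offset = 0L) {
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("sequence of ", accession, " contains unsupported ambiguity code(s): ",
         paste(bad, collapse = ", "))
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  rec <- structure(list(accession = accession, organism = organism,
                        length_bp = nchar(sequence), sequence = sequence,
                        is_circular = isTRUE(is_circular), features = features,
                        rotation_offset = as.integer(rotation_offset)),
                   class = "genome_record")
  validate_genome_record(rec)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s | %s | %d bp (%s) | %d CDS\n",
              x$accession, x$organism, x$length_bp,
              if (x$is_circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

empty_features <- function() {
  data.frame(locus_tag = character(), product = character(),
             start = integer(), end = integer(), strand = integer(),
             translation = character(), stringsAsFactors = FALSE)
}

validate_genome_record <- function(rec) {
  f <- rec$features
  if (nrow(f)) {
    stopifnot(all(f$start >= 0), all(f$start < f$end),
              all(f$end <= rec$length_bp), all(f$strand %in% c(-1L, 1L)),
              !is.unsorted(f$start))
  }
  stopifnot(rec$length_bp == nchar(rec$sequence))
  rec
}

# ---- parsing ---------------------------------------------------------------

# Resolve a GenBank location string to 0-based half-open start/end + strand.
# join() spans are collapsed to their envelope; an origin-spanning join on a
# circular replicon yields start > end, normalized by rotation afterwards.
.parse_location <- function(loc, length_bp, line_no) {
  strand <- 1L
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc))
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", parts))
  single <- regmatches(parts, regexec("^(\\d+)$", parts))
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(parts)) {
    if (length(m[[i]]) == 3L) {
      starts <- c(starts, as.integer(m[[i]][2])); ends <- c(ends, as.integer(m[[i]][3]))
    } else if (length(single[[i]]) == 2L) {
      starts <- c(starts, as.integer(single[[i]][2])); ends <- c(ends, as.integer(single[[i]][2]))
    } else {
      stop("malformed feature location at line ", line_no, ": ", loc)
    }
  }
  # 1-based inclusive -> 0-based half-open
  s <- min(starts) - 1L; e <- max(ends)
  wraps <- length(parts) > 1L && ends[length(ends)] < starts[1L]
  if (wraps) { s <- starts[1L] - 1L; e <- ends[length(ends)] }  # start > end form
  list(start = s, end = e, strand = strand, wraps = wraps)
}

.extract_qualifier <- function(block, name) {
  pat <- paste0('/', name, '="')
  i <- regexpr(pat, block, fixed = TRUE)
  if (i < 0) {
    # unquoted form
    m <- regmatches(block, regexec(paste0("/", name, "=([^\\s\"]+)"), block))[[1]]
    return(if (length(m) == 2L) m[2] else NA_character_)
  }
  rest <- substr(block, i + attr(i, "match.length"), nchar(block))
  j <- regexpr('"', rest, fixed = TRUE)
  if (j < 0) return(NA_character_)
  val <- substr(rest, 1L, j - 1L)
  gsub("\\s+", " ", trimws(val))
}

#' Parse a GenBank flat file
#'
#' Reads one or more `LOCUS` entries into [genome_record()] objects. CDS
#' locations in `join()`/`complement()` form are resolved to start/end/strand;
#' CDS lacking a `/translation` qualifier are translated with
#' [translate_cds()] (genetic code 11). Origin-spanning CDS on circular
#' replicons are linearized by rotating the sequence; the applied offset is
#' recorded in `rotation_offset`.
#'
#' @param path Path to a GenBank flat file, or a character vector of its
#'   lines via `text =`.
#' @param text Optional character scalar/vector of file content, used instead
#'   of `path`.
#' @return List of `genome_record` objects, one per `LOCUS`.
#' @export
parse_genbank <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (!length(locus_at)) stop("malformed GenBank file: no LOCUS line (line 1)")
  end_at <- grep("^//\\s*$", lines)
  if (length(end_at) < length(locus_at))
    stop("malformed GenBank file: LOCUS entry without terminating // (line ",
         locus_at[length(locus_at)], ")")
  records <- vector("list", length(locus_at))
  for (k in seq_along(locus_at)) {
    lo <- locus_at[k]
    hi <- end_at[end_at > lo][1L]
    records[[k]] <- .parse_one_entry(lines[lo:hi], lo)
  }
  records
}

.parse_one_entry <- function(lines, offset) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  accession <- locus[2]
  is_circular <- any(tolower(locus) == "circular")
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    acc <- strsplit(trimws(acc_line[1]), "\\s+")[[1]]
    if (length(acc) >= 2L) accession <- acc[2]
  }
  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at))
    stop("malformed GenBank file: entry at line ", offset, " has no ORIGIN block")
  seq_lines <- lines[(origin_at[1] + 1L):(length(lines) - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  length_bp <- nchar(sequence)

  feat_at <- grep("^FEATURES", lines)
  organism <- accession
  feats <- empty_features()
  if (length(feat_at)) {
    fstart <- feat_at[1] + 1L
    fend <- origin_at[1] - 1L
    flines <- lines[fstart:fend]
    # feature starts: exactly 5 leading spaces then a key
    key_at <- grep("^ {5}\\S", flines)
    key_at <- c(key_at, length(flines) + 1L)
    for (i in seq_len(length(key_at) - 1L)) {
      block_lines <- flines[key_at[i]:(key_at[i + 1L] - 1L)]
      key <- sub("^ {5}(\\S+).*$", "\\1", block_lines[1])
      loc <- sub("^ {5}\\S+\\s+", "", block_lines[1])
      cont <- block_lines[-1]
      # location may continue on lines without a '/'
      qual_start <- grep("^ {21}/", cont)
      loc_cont <- if (length(qual_start)) cont[seq_len(qual_start[1] - 1L)] else cont
      loc <- paste0(loc, paste(trimws(loc_cont), collapse = ""))
      block <- paste(trimws(block_lines), collapse = " ")
      line_no <- offset + feat_at[1] + key_at[i] - 1L
      if (key == "source") {
        org <- .extract_qualifier(block, "organism")
        if (!is.na(org)) organism <- org
      } else if (key == "CDS") {
        pl <- .parse_location(loc, length_bp, line_no)
        tr <- .extract_qualifier(block, "translation")
        if (!is.na(tr)) tr <- gsub(" ", "", tr)
        if (!pl$wraps && pl$end > length_bp) {
          warning("CDS at line ", line_no, " exceeds sequence bounds; skipped")
          next
        }
        feats <- rbind(feats, data.frame(
          locus_tag = .extract_qualifier(block, "locus_tag"),
          product = .extract_qualifier(block, "product"),
          start = pl$start, end = if (pl$wraps) pl$end + length_bp else pl$end,
          strand = pl$strand,
          translation = if (is.na(tr)) NA_character_ else tr,
          wraps = pl$wraps, stringsAsFactors = FALSE))
      }
    }
  }

  rotation <- 0L
  if (nrow(feats) && any(feats$wraps)) {
    if (!is_circular)
      stop("origin-spanning CDS at entry line ", offset,
           " on a non-circular replicon")
    rotation <- feats$start[feats$wraps][1L]
    sequence <- paste0(substr(sequence, rotation + 1L, length_bp),
                       substr(sequence, 1L, rotation))
    feats$start <- (feats$start - rotation) %% length_bp
    feats$end <- feats$end - rotation
    feats$end <- ifelse(feats$end <= 0L, feats$end + length_bp, feats$end)
    feats$end <- ifelse(feats$end < feats$start, feats$end + length_bp, feats$end)
    if (any(feats$end > length_bp))
      stop("cannot linearize features of entry at line ", offset,
           ": multiple origin-spanning CDS")
  }
  if (nrow(feats)) feats$wraps <- NULL

  rec <- genome_record(accession, organism, sequence, is_circular, feats,
                       rotation)
  # fill missing translations from the sequence
  missing <- which(is.na(rec$features$translation))
  for (i in missing)
    rec$features$translation[i] <- translate_cds(rec$features[i, ], rec)
  rec
}

# ---- translation -----------------------------------------------------------

.genetic_code_11 <- function() {
  if (is.null(.pkg_cache$gc11))
    .pkg_cache$gc11 <- Biostrings::getGeneticCode("11")
  .pkg_cache$gc11
}

#' Translate a CDS feature under the bacterial/archaeal code
#'
#' Extracts the feature interval, reverse-complements on the minus strand,
#' and translates with genetic code table 11. The trailing stop is removed;
#' internal stops are preserved (the annotation is authoritative). An
#' interval whose length is not a multiple of 3 is translated codon by codon
#' up to the last complete codon, with a warning.
#'
#' @param feature One row of a `genome_record` feature table.
#' @param genome The owning [genome_record()].
#' @return Amino-acid string.
#' @export
translate_cds <- function(feature, genome) {
  start <- feature$start; end <- feature$end
  stopifnot(start >= 0, end <= genome$length_bp, end - start >= 3L)
  nt <- substr(genome$sequence, start + 1L, end)
  if ((end - start) %% 3L != 0L) {
    warning("CDS ", feature$locus_tag, " length not a multiple of 3; ",
            "translating ", (end - start) %/% 3L, " codons")
    nt <- substr(nt, 1L, ((end - start) %/% 3L) * 3L)
  }
  dna <- Biostrings::DNAString(nt)
  if (feature$strand < 0) dna <- Biostrings::reverseComplement(dna)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(dna, genetic.code = .genetic_code_11(),
                          if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

# ---- writing ---------------------------------------------------------------

#' Write a genome record as GenBank flat-file text
#'
#' Emits a minimal but valid GenBank entry (LOCUS, ACCESSION, FEATURES with
#' `source` and `CDS`, ORIGIN) that round-trips through [parse_genbank()].
#'
#' @param record A [genome_record()].
#' @param path Optional output path; when `NULL` the text is returned.
#' @return The GenBank text, invisibly when written to `path`.
#' @export
write_genbank <- function(record, path = NULL) {
  topo <- if (record$is_circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                   record$accession, record$length_bp, topo),
           sprintf("DEFINITION  %s.", record$organism),
           sprintf("ACCESSION   %s", record$accession),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", record$length_bp),
           sprintf("                     /organism=\"%s\"", record$organism))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] < 0) loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     CDS             %s", loc),
             sprintf("                     /locus_tag=\"%s\"", f$locus_tag[i]),
             sprintf("                     /product=\"%s\"", f$product[i]))
    tr <- f$translation[i]
    if (!is.na(tr)) {
      chunks <- substring(tr, seq(1L, nchar(tr), 44L),
                          pmin(seq(1L, nchar(tr), 44L) + 43L, nchar(tr)))
      tr_lines <- paste0("                     ",
                         c(paste0("/translation=\"", chunks[1]),
                           if (length(chunks) > 1L) chunks[-1]))
      tr_lines[length(tr_lines)] <- paste0(tr_lines[length(tr_lines)], "\"")
      out <- c(out, tr_lines)
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq(1L, nchar(s), 60L)
  for (st in starts) {
    line <- substr(s, st, min(st + 59L, nchar(s)))
    groups <- substring(line, seq(1L, nchar(line), 10L),
                        pmin(seq(1L, nchar(line), 10L) + 9L, nchar(line)))
    out <- c(out, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(text)) }
  text
}
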