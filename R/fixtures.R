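# Seeded synthetic genomes with planted ortholog clusters, paralogs, fusions
# and decoys. These emulate the inputs of a real run: annotated replicons in
# which a query protein (and its neighbors) are encoded verbatim, surrounded
# by random intergenic background guaranteed free of planted 30-mers.

# Run code under a local RNG state so fixture generation is deterministic
# without disturbing the caller's random stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw a random protein sequence
#'
#' Uniform over the 20 standard residues, prefixed with `M`.
#'
#' @param length Total length in residues (>= 2).
#' @return Protein string.
#' @export
random_protein <- function(length) {
  stopifnot(length >= 2)
  paste0("M", paste(sample(setdiff(aa_alphabet(), "X"), length - 1L,
                           replace = TRUE), collapse = ""))
}

# Reverse table-11 codon choice: one uniformly drawn synonymous codon per
# residue, plus a fixed TAA stop.
back_translate <- function(protein) {
  gc <- .genetic_code_11()
  by_aa <- split(names(gc), gc)
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot back-translate residue: ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.kmers <- function(x, k = 30L) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

#' Generate a synthetic annotated genome with planted genes
#'
#' Builds a deterministic (for fixed `seed`) genome record plus its GenBank
#' text in which each listed protein is planted verbatim as a CDS
#' (back-translated under genetic code 11, fixed TAA stop). Fusion genes are
#' expressed by passing a concatenated protein. The intergenic background is
#' random sequence verified free of 30-mers of any planted CDS (either
#' strand) and is resampled on the astronomically rare collision.
#'
#' @param spec List with elements `accession`, `organism`, `length_bp`,
#'   optional `is_circular` (default `FALSE`), optional `gc` background GC
#'   fraction (default 0.5), and `genes`: a list of lists with `protein`,
#'   `start` (0-based CDS start), `strand` (+1/-1), optional `locus_tag`,
#'   `product`.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   GenBank text.
#' @return List with `record` (a [genome_record()]) and `text` (GenBank
#'   flat-file text).
#' @export
make_fixture_genome <- function(spec, seed) {
  stopifnot(is.list(spec), !is.null(spec$length_bp))
  genes <- spec$genes %||% list()
  with_local_seed(seed, {
    L <- as.integer(spec$length_bp)
    gcf <- spec$gc %||% 0.5
    cds <- character(length(genes))
    ivs <- matrix(0L, nrow = length(genes), ncol = 2L)
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      cds[i] <- back_translate(g$protein)
      len <- nchar(cds[i])
      ivs[i, ] <- c(g$start, g$start + len)
      if (ivs[i, 2L] > L)
        stop("planted gene ", i, " exceeds genome length")
    }
    if (length(genes) > 1L) {
      o <- order(ivs[, 1L])
      if (any(ivs[o, 1L][-1L] < ivs[o, 2L][-length(genes)]))
        stop("planted genes overlap")
    }
    planted_kmers <- unique(unlist(lapply(cds, function(d)
      c(.kmers(d), .kmers(.revcomp_chr(d))))))
    for (attempt in 1:20) {
      bg <- .random_dna(L, gcf)
      seq_chars <- strsplit(bg, "", fixed = TRUE)[[1]]
      for (i in seq_along(genes)) {
        ins <- if (genes[[i]]$strand < 0) .revcomp_chr(cds[i]) else cds[i]
        seq_chars[(ivs[i, 1L] + 1L):ivs[i, 2L]] <-
          strsplit(ins, "", fixed = TRUE)[[1]]
      }
      genome_seq <- paste(seq_chars, collapse = "")
      if (!length(planted_kmers)) break
      in_gene <- logical(L)
      for (i in seq_along(genes))
        in_gene[(ivs[i, 1L] + 1L):ivs[i, 2L]] <- TRUE
      all_k <- .kmers(genome_seq)
      # a window is background-contaminated if it is not fully inside a gene
      win_in_gene <- vapply(seq_along(all_k), function(j)
        all(in_gene[j:(j + 29L)]), logical(1))
      # planted_kmers holds both strands, so scanning the forward strand
      # covers reverse-complement collisions too
      clash <- all_k[!win_in_gene] %in% planted_kmers
      if (!any(clash)) break
      if (attempt == 20L) stop("could not build a collision-free background")
    }
    feats <- empty_features()
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      feats <- rbind(feats, data.frame(
        locus_tag = g$locus_tag %||% sprintf("%s_%04d", spec$accession %||% "FIX", i),
        product = g$product %||% "hypothetical protein",
        start = ivs[i, 1L], end = ivs[i, 2L], strand = as.integer(g$strand),
        translation = g$protein, stringsAsFactors = FALSE))
    }
    rec <- genome_record(spec$accession %||% "FIX0001",
                         spec$organism %||% "Synthetica fixturensis",
                         genome_seq, isTRUE(spec$is_circular), feats)
    list(record = rec, text = write_genbank(rec))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a library of fixture genomes
#'
#' Convenience wrapper: one [make_fixture_genome()] call per spec, with
#' per-genome seeds derived from `seed`.
#'
#' @param specs List of genome specs.
#' @param seed Base integer seed.
#' @return List of `genome_record` objects.
#' @export
make_fixture_library <- function(specs, seed) {
  lapply(seq_along(specs), function(i)
    make_fixture_genome(specs[[i]], seed = (seed * 131L + i) %% 2147483647L)$record)
}
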