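# Constant depth-7 lineage normalization and the selectable taxonomic tree.
#
# Lineages are kept at a fixed rank depth of 7 (superkingdom, phylum, class,
# order, family, genus, species). Incomplete lineages with a known
# superkingdom fall under <superkingdom>:unclassified, keeping the phylum in
# the third slot when available; lineages lacking even the superkingdom fall
# under Prokaryote:unclassified. Placeholders keep every leaf at depth 7.

TAX_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
               "genus", "species")

#' Normalize a raw lineage to the constant 7-rank form
#'
#' @param raw Named character vector of available ranks (any subset of
#'   `superkingdom`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species`).
#' @param organism Organism name; supplies the genus/species fallback (first
#'   two whitespace tokens, with a leading `Candidatus` stripped).
#' @return A `lineage` object: named 7-element character vector of ranks plus
#'   a `source_organism` attribute.
#' @export
normalize_lineage <- function(raw = character(), organism) {
  if (missing(organism) || is.null(organism) || !nzchar(trimws(organism %||% "")))
    stop("organism name is required to name the species leaf")
  raw <- raw[nzchar(raw)]
  toks <- strsplit(trimws(organism), "\\s+")[[1]]
  if (length(toks) && tolower(toks[1]) == "candidatus") toks <- toks[-1]
  rk <- function(nm) if (nm %in% names(raw)) raw[[nm]] else NA_character_
  genus <- rk("genus") %||NA% (if (length(toks) >= 1L) toks[1] else NA)
  species <- rk("species") %||NA% (if (length(toks) >= 2L) toks[2] else NA)
  if (is.na(genus) || is.na(species))
    stop("cannot derive genus/species from organism name: ", organism)

  sk <- rk("superkingdom")
  internal <- c("phylum", "class", "order", "family")
  have <- internal %in% names(raw)
  if (is.na(sk)) {
    ranks <- c("Prokaryote", rep("unclassified", 4L), genus, species)
  } else if (all(have)) {
    ranks <- c(sk, rk("phylum"), rk("class"), rk("order"),
               rk("family"), genus, species)
  } else {
    # shortened form: <sk>:unclassified, phylum kept in the third slot
    ranks <- c(sk, "unclassified",
               rk("phylum") %||NA% "unclassified",
               "unclassified", "unclassified", genus, species)
  }
  names(ranks) <- TAX_RANKS
  structure(ranks, source_organism = organism, class = "lineage")
}

`%||NA%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' @export
print.lineage <- function(x, ...) {
  cat(paste(unclass(x), collapse = " / "), "\n")
  invisible(x)
}

#' Read a lineage table
#'
#' Tab-separated dialect: `accession<TAB>organism<TAB>rank=value;rank=value`.
#' Each row is normalized with [normalize_lineage()].
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `accession`, `organism` and a `lineage`
#'   list-column of normalized lineages.
#' @export
read_lineage_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("accession", "organism", "ranks"),
                           quote = "")
  tab$lineage <- lapply(seq_len(nrow(tab)), function(i) {
    pairs <- strsplit(tab$ranks[i], ";", fixed = TRUE)[[1]]
    pairs <- pairs[nzchar(trimws(pairs))]
    kv <- strsplit(pairs, "=", fixed = TRUE)
    raw <- stats::setNames(vapply(kv, function(p) trimws(p[2]), character(1)),
                           vapply(kv, function(p) trimws(p[1]), character(1)))
    normalize_lineage(raw, tab$organism[i])
  })
  tab$ranks <- NULL
  tab
}

# ---- tree ------------------------------------------------------------------

.new_node <- function(name, level) {
  list(name = name, level = level, children = list(), accessions = character())
}

#' Build the selectable taxonomic tree
#'
#' Prefix-merges normalized 7-rank lineages into a hierarchy whose leaves are
#' species carrying genome accessions. Duplicate species merge into one leaf
#' holding all accessions. Children are kept name-sorted, so the tree is
#' independent of input order.
#'
#' @param lineages List of [normalize_lineage()] results.
#' @param accessions Character vector of genome accessions, parallel to
#'   `lineages`.
#' @return A `taxon_tree` object.
#' @export
build_taxon_tree <- function(lineages, accessions = NULL) {
  if (is.null(accessions))
    accessions <- vapply(lineages, function(l) attr(l, "source_organism"),
                         character(1))
  stopifnot(length(lineages) == length(accessions))
  root <- .new_node("root", 0L)
  for (i in seq_along(lineages)) {
    ranks <- unclass(lineages[[i]])
    root <- .insert_lineage(root, ranks, accessions[i])
  }
  root <- .sort_children(root)
  structure(list(root = root, lineages = lineages, accessions = accessions),
            class = "taxon_tree")
}

.insert_lineage <- function(node, ranks, accession) {
  if (!length(ranks)) {
    node$accessions <- sort(unique(c(node$accessions, accession)))
    return(node)
  }
  nm <- ranks[[1]]
  child <- node$children[[nm]]
  if (is.null(child)) child <- .new_node(nm, node$level + 1L)
  node$children[[nm]] <- .insert_lineage(child, ranks[-1], accession)
  node
}

.sort_children <- function(node) {
  if (length(node$children)) {
    node$children <- node$children[order(names(node$children))]
    node$children <- lapply(node$children, .sort_children)
  }
  node
}

#' @export
print.taxon_tree <- function(x, ...) {
  n_leaves <- length(select_node(x, character()))
  cat(sprintf("<taxon_tree> %d lineages, %d genome references\n",
              length(x$lineages), n_leaves))
  invisible(x)
}

.resolve_path <- function(node, path) {
  for (i in seq_along(path)) {
    child <- node$children[[path[i]]]
    if (is.null(child)) {
      near <- names(node$children)
      hit <- near[grepl(tolower(path[i]), tolower(near), fixed = TRUE)]
      stop("no taxon named '", path[i], "' under '", node$name, "'",
           if (length(hit)) paste0("; nearest match: ", hit[1]) else
             paste0("; available: ", paste(utils::head(near, 5), collapse = ", ")))
    }
    node <- child
  }
  node
}

#' Select all genomes under a tree node
#'
#' Selecting a node selects recursively every descendant species; parent
#' nodes themselves carry no genomes. An empty path selects the whole tree.
#'
#' @param tree A [build_taxon_tree()] result.
#' @param path Character vector of node names from the root down (e.g.
#'   `c("Bacteria", "Firmicutes")`).
#' @return Sorted character vector of genome accessions.
#' @export
select_node <- function(tree, path = character()) {
  node <- .resolve_path(tree$root, path)
  collect <- function(n) c(n$accessions, unlist(lapply(n$children, collect),
                                                use.names = FALSE))
  sort(unique(collect(node)))
}

#' Search the taxonomy for a term
#'
#' Case-insensitive substring match against every rank name of every stored
#' lineage; each match returns the full 7-rank lineage.
#'
#' @param tree A [build_taxon_tree()] result.
#' @param term Non-empty search string.
#' @return List of matching lineages, sorted lexicographically by their
#'   7-tuples.
#' @export
search_taxa <- function(tree, term) {
  stopifnot(nzchar(term))
  hits <- Filter(function(l) any(grepl(tolower(term), tolower(unclass(l)),
                                       fixed = TRUE)),
                 tree$lineages)
  keys <- vapply(hits, function(l) paste(unclass(l), collapse = "\r"),
                 character(1))
  unique(hits[order(keys)])
}

#' Export a taxonomic tree as JSON
#'
#' @param tree A [build_taxon_tree()] result.
#' @param path Optional output file.
#' @return JSON string, invisibly when written to `path`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(n) {
    out <- list(name = n$name, level = n$level)
    if (length(n$accessions)) out$accessions <- n$accessions
    if (length(n$children)) out$children <- lapply(unname(n$children), strip)
    out
  }
  js <- jsonlite::toJSON(strip(tree$root), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
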