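# Shared planted-cluster fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx_gene <- function(p, s, st = 1L, lt, prod = "hypothetical protein")
  list(protein = p, start = s, strand = st, locus_tag = lt, product = prod)

# A 5-protein cluster planted in three genomes (one with a paralog pair, one
# with a fusion of proteins 2+3), plus one cluster-free decoy genome.
cluster_scenario <- function() {
  if (!is.null(.fx_cache$scenario)) return(.fx_cache$scenario)
  set.seed(402)
  P <- lapply(c(110, 95, 100, 120, 85), random_protein)
  ch <- strsplit(P[[4]], "", fixed = TRUE)[[1]]
  idx <- sample(2:length(ch), 8)
  ch[idx] <- sample(setdiff(aa_alphabet(), "X"), 8, replace = TRUE)
  paralog4 <- paste(ch, collapse = "")
  fusion <- paste0(P[[2]], P[[3]])
  specs <- list(
    list(accession = "GA01", organism = "Synthetica prima", length_bp = 30000,
         genes = list(fx_gene(P[[1]], 5000, 1L, "A1"),
                      fx_gene(P[[2]], 6000, 1L, "A2"),
                      fx_gene(P[[3]], 7000, 1L, "A3"),
                      fx_gene(P[[4]], 8000, -1L, "A4"),
                      fx_gene(paralog4, 9000, 1L, "A4p"),
                      fx_gene(P[[5]], 10000, 1L, "A5"))),
    list(accession = "GB01", organism = "Synthetica secunda", length_bp = 30000,
         genes = list(fx_gene(P[[1]], 15000, 1L, "B1"),
                      fx_gene(P[[2]], 16000, 1L, "B2"),
                      fx_gene(P[[3]], 17000, 1L, "B3"),
                      fx_gene(P[[4]], 18000, 1L, "B4"),
                      fx_gene(P[[5]], 19000, 1L, "B5"))),
    list(accession = "GC01", organism = "Synthetica tertia", length_bp = 30000,
         genes = list(fx_gene(P[[1]], 12000, 1L, "C1"),
                      fx_gene(fusion, 13000, 1L, "Cfus", "fusion protein"),
                      fx_gene(P[[4]], 14000, 1L, "C4"),
                      fx_gene(P[[5]], 15000, 1L, "C5"))),
    list(accession = "GD01", organism = "Synthetica quarta",
         length_bp = 30000, genes = list()))
  genomes <- make_fixture_library(specs, seed = 11)
  .fx_cache$scenario <- list(P = P, paralog4 = paralog4, fusion = fusion,
                             specs = specs, genomes = genomes)
  .fx_cache$scenario
}

cluster_report <- function() {
  if (is.null(.fx_cache$report)) {
    sc <- cluster_scenario()
    .fx_cache$report <- run_synteny(sc$P[[1]], sc$genomes)
  }
  .fx_cache$report
}

# Minimal hand-written GenBank entry used by the parser tests.
handwritten_genbank <- function() {
  paste(c(
    "LOCUS       TST00001 600 bp    DNA     circular   BCT",
    "DEFINITION  Testus manualis.",
    "ACCESSION   TST00001",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "                     /organism=\"Testus manualis\"",
    "     CDS             complement(101..400)",
    "                     /locus_tag=\"T0001\"",
    "                     /product=\"reverse protein, with comma\"",
    "     CDS             451..465",
    "                     /locus_tag=\"T0002\"",
    "                     /product=\"tiny protein\"",
    "     CDS             21..80",
    "                     /locus_tag=\"T0003\"",
    "                     /product=\"leading protein\"",
    "ORIGIN",
    NULL), collapse = "\n")
}

handwritten_sequence <- function() {
  set.seed(77)
  paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
}

handwritten_genbank_full <- function() {
  s <- tolower(handwritten_sequence())
  starts <- seq(1, 600, 60)
  lines <- vapply(starts, function(st) {
    line <- substr(s, st, st + 59)
    groups <- substring(line, seq(1, 60, 10), seq(10, 60, 10))
    sprintf("%9d %s", st, paste(groups, collapse = " "))
  }, character(1))
  paste(c(handwritten_genbank(), lines, "//"), collapse = "\n")
}
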