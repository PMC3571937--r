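test_that("GenBank coordinates convert to 0-based half-open at the boundary", {
  recs <- parse_genbank(text = handwritten_genbank_full())
  expect_length(recs, 1)
  rec <- recs[[1]]
  expect_equal(rec$accession, "TST00001")
  expect_equal(rec$organism, "Testus manualis")
  expect_true(rec$is_circular)
  expect_equal(nrow(rec$features), 3)
  # features come back sorted by start regardless of file order
  expect_equal(rec$features$locus_tag, c("T0003", "T0001", "T0002"))
  # complement(101..400): 1-based inclusive -> start 100, end 400, strand -1
  rev_cds <- rec$features[rec$features$locus_tag == "T0001", ]
  expect_equal(rev_cds$start, 100)
  expect_equal(rev_cds$end, 400)
  expect_equal(rev_cds$strand, -1L)
})

test_that("parsing rejects malformed files with a line reference", {
  expect_error(parse_genbank(text = "FOO\nBAR"), "LOCUS")
  no_origin <- sub("ORIGIN", "NOTHING", handwritten_genbank_full())
  expect_error(parse_genbank(text = no_origin), "ORIGIN")
})

test_that("a CDS beyond the sequence bounds is skipped with a warning", {
  txt <- sub("451\\.\\.465", "451..1465", handwritten_genbank_full())
  expect_warning(recs <- parse_genbank(text = txt), "bounds")
  expect_equal(nrow(recs[[1]]$features), 2)
})

test_that("CDS translation follows genetic code 11 with annotation authority", {
  seqs <- paste0("ATGGCTTAA", "ATG", paste(rep("G", 9), collapse = ""))
  g <- genome_record("T1", "Testus codonis", seqs)
  plus <- data.frame(locus_tag = "x", product = "p", start = 0L, end = 9L,
                     strand = 1L, translation = NA, stringsAsFactors = FALSE)
  expect_equal(translate_cds(plus[1, ], g), "MA")     # trailing stop removed
  single <- transform(plus, start = 9L, end = 12L)
  expect_equal(translate_cds(single[1, ], g), "M")
  # minus strand over the reverse complement of ATG GCT TAA
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGCTTAA")))
  g2 <- genome_record("T2", "Testus codonis", paste0(rc, "AAAAAA"))
  minus <- transform(plus, end = 9L, strand = -1L)
  expect_equal(translate_cds(minus[1, ], g2), "MA")
  # length not a multiple of 3: floor(len/3) codons, with a warning
  ragged <- transform(plus, end = 10L)
  expect_warning(aa <- translate_cds(ragged[1, ], g), "multiple of 3")
  expect_equal(aa, "MA")
  # internal stops are preserved
  g3 <- genome_record("T3", "Testus codonis", "ATGTAAGCTTAA")
  full <- transform(plus, end = 12L)
  expect_equal(translate_cds(full[1, ], g3), "M*A")
})

test_that("ambiguity codes other than N are rejected at parse time", {
  expect_error(genome_record("T1", "Testus", "ACGTRY"), "ambiguity")
  expect_silent(genome_record("T1", "Testus", "ACGTN"))
})

test_that("fixture genomes are deterministic and exactly recoverable", {
  set.seed(11)
  p <- random_protein(60)
  spec <- list(accession = "FX01", organism = "Synthetica una",
               length_bp = 4000,
               genes = list(fx_gene(p, 1000, 1L, "G1"),
                            fx_gene(p, 2500, -1L, "G2")))
  a <- make_fixture_genome(spec, seed = 5)
  b <- make_fixture_genome(spec, seed = 5)
  expect_identical(a$text, b$text)                      # byte-identical
  expect_equal(nrow(a$record$features), 2)
  # planted proteins recoverable from the DNA on both strands
  for (i in 1:2)
    expect_equal(translate_cds(a$record$features[i, ], a$record), p)
  c_ <- make_fixture_genome(spec, seed = 6)
  expect_false(identical(a$text, c_$text))
})

test_that("fixture specs with overlapping genes are rejected", {
  set.seed(12)
  p <- random_protein(60)
  spec <- list(accession = "FX02", organism = "Synthetica una",
               length_bp = 4000,
               genes = list(fx_gene(p, 1000, 1L, "G1"),
                            fx_gene(p, 1050, 1L, "G2")))
  expect_error(make_fixture_genome(spec, seed = 5), "overlap")
})

test_that("a fusion spec produces one CDS translating to the concatenation", {
  set.seed(13)
  p1 <- random_protein(40); p2 <- random_protein(50)
  spec <- list(accession = "FX03", organism = "Synthetica una",
               length_bp = 3000,
               genes = list(fx_gene(paste0(p1, p2), 1000, 1L, "FUS")))
  fx <- make_fixture_genome(spec, seed = 9)
  expect_equal(nrow(fx$record$features), 1)
  expect_equal(translate_cds(fx$record$features[1, ], fx$record),
               paste0(p1, p2))
})

test_that("write + parse round-trips fixture genomes", {
  sc <- cluster_scenario()
  for (rec in sc$genomes[1:2]) {
    back <- parse_genbank(text = write_genbank(rec))[[1]]
    expect_identical(back$sequence, rec$sequence)
    expect_identical(back$accession, rec$accession)
    expect_identical(back$organism, rec$organism)
    expect_identical(back$is_circular, rec$is_circular)
    expect_equal(back$features[, c("locus_tag", "start", "end", "strand",
                                   "translation")],
                 rec$features[, c("locus_tag", "start", "end", "strand",
                                  "translation")])
    # input /translation qualifiers agree with recomputed translations
    for (i in seq_len(nrow(back$features)))
      expect_equal(translate_cds(back$features[i, ], back),
                   back$features$translation[i])
  }
})

test_that("origin-spanning CDS on circular replicons are rotated out", {
  set.seed(14)
  p <- random_protein(40)
  spec <- list(accession = "FX04", organism = "Synthetica rotunda",
               length_bp = 2000, is_circular = TRUE,
               genes = list(fx_gene(p, 500, 1L, "G1")))
  fx <- make_fixture_genome(spec, seed = 21)
  rec <- fx$record
  # rebuild the entry with the gene split across the origin
  L <- rec$length_bp
  cut <- 560L  # inside the CDS
  rotated_seq <- paste0(substr(rec$sequence, cut + 1, L),
                        substr(rec$sequence, 1, cut))
  s1 <- rec$features$start[1] - cut + L  # now wraps
  e1 <- rec$features$end[1] - cut       # 1-based end after origin
  txt <- paste(c(
    sprintf("LOCUS       FX04 %d bp    DNA     circular   BCT", L),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    "                     /organism=\"Synthetica rotunda\"",
    sprintf("     CDS             join(%d..%d,1..%d)", s1 + 1, L, e1),
    "                     /locus_tag=\"G1\"",
    "ORIGIN",
    paste0("        1 ", tolower(rotated_seq)),
    "//"), collapse = "\n")
  back <- parse_genbank(text = txt)[[1]]
  expect_gt(back$rotation_offset, 0)
  f <- back$features
  expect_true(all(f$start < f$end & f$end <= back$length_bp))
  expect_equal(translate_cds(f[1, ], back), p)
})
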