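bare_genome <- function(L, circular = FALSE, feats = empty_features(),
                        seed = 88, acc = "WIN01") {
  with_local_seed(seed, genome_record(
    acc, "Synthetica fenestrae",
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    is_circular = circular, features = feats))
}

test_that("window extraction follows the centered-width rule", {
  g <- bare_genome(30000)
  s <- extract_segment(g, 15000, 15000)
  expect_equal(c(s$window_start, s$window_end), c(7500, 22500))
  expect_equal(s$window_len, 15000)

  g2 <- bare_genome(10000)
  s2 <- extract_segment(g2, 2000, 15000)
  expect_equal(c(s2$window_start, s2$window_end), c(0, 9500))
  expect_equal(s2$window_len, 9500)
})

test_that("circular windows wrap to exactly the requested width", {
  g <- bare_genome(20000, circular = TRUE)
  s <- extract_segment(g, 100, 15000)
  expect_true(s$wrapped)
  expect_equal(s$window_len, 15000)
  expect_equal(c(s$window_start, s$window_end), c(12600, 7600))
  # oracle: double the sequence and slice the same 15 kb
  doubled <- paste0(g$sequence, g$sequence)
  expected <- substr(doubled, 12600 + 1, 12600 + 15000)
  got <- paste0(substr(g$sequence, 12601, 20000), substr(g$sequence, 1, 7600))
  expect_identical(got, expected)
})

test_that("windows keep genes overlapping by at least 1 bp, wrap-aware", {
  set.seed(55)
  p <- random_protein(40)
  fx <- make_fixture_genome(list(
    accession = "CIR1", organism = "Synthetica rotunda", length_bp = 20000,
    is_circular = TRUE,
    genes = list(fx_gene(p, 19000, 1L, "GW"),   # inside the wrapped arc
                 fx_gene(p, 9000, 1L, "GOUT"))  # outside the window
  ), seed = 77)
  s <- extract_segment(fx$record, 100, 15000)
  expect_equal(s$genes$locus_tag, "GW")
  expect_equal(s$genes$display_start, 19000 - 12600)
})

test_that("every non-clipped window is exactly width bp", {
  g <- bare_genome(40000)
  for (c_ in c(7500, 13000, 20000, 32499))
    expect_equal(extract_segment(g, c_, 15000)$window_len, 15000)
})

mkseg <- function(proteins, acc = "REF1") {
  n <- length(proteins)
  feats <- data.frame(
    locus_tag = sprintf("L%02d", seq_len(n)), product = "p",
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 3L * (nchar(proteins) + 1L),
    strand = 1L, translation = proteins, stringsAsFactors = FALSE)
  g <- bare_genome(max(feats$end) + 1000L, feats = feats, acc = acc)
  extract_segment(g, max(feats$end) %/% 2L, width = 2L * max(feats$end))
}

test_that("reference coloring groups paralogs and isolates singletons", {
  set.seed(61)
  A <- random_protein(80)
  B <- local({  # ~50% diverged copy of A, still above threshold 30
    ch <- strsplit(A, "", fixed = TRUE)[[1]]
    i <- sample(2:80, 28)
    ch[i] <- sample(setdiff(aa_alphabet(), "X"), 28, replace = TRUE)
    paste(ch, collapse = "")
  })
  C <- random_protein(80)
  seg <- mkseg(c(A, B, C))
  cm <- build_reference_colors(seg, threshold = 30)
  expect_equal(cm$reference_colors[1], cm$reference_colors[2])
  expect_false(cm$reference_colors[3] == cm$reference_colors[1])
  expect_equal(cm$n_colors, 2)

  # mutually unrelated -> n distinct colors, assigned left to right
  set.seed(62)
  ps <- vapply(1:5, function(i) random_protein(70), character(1))
  cm2 <- build_reference_colors(mkseg(ps), threshold = 30)
  expect_equal(cm2$reference_colors, 1:5)

  # perfect paralogs -> same color at any threshold
  cm3 <- build_reference_colors(mkseg(c(A, A)), threshold = 100)
  expect_equal(cm3$reference_colors, c(1L, 1L))
})

test_that("reference partition equals brute-force connected components", {
  set.seed(63)
  for (rep_i in 1:6) {
    n <- sample(2:8, 1)
    # families: some proteins derived from shared parents, some fresh
    parents <- vapply(1:3, function(i) random_protein(60), character(1))
    ps <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.6) {
        p <- parents[sample(3, 1)]
        ch <- strsplit(p, "", fixed = TRUE)[[1]]
        k <- sample(5:25, 1)
        idx <- sample(2:60, k)
        ch[idx] <- sample(setdiff(aa_alphabet(), "X"), k, replace = TRUE)
        paste(ch, collapse = "")
      } else random_protein(60)
    }, character(1))
    seg <- mkseg(ps)
    cm <- build_reference_colors(seg, threshold = 30)
    # oracle: brute-force BFS on the thresholded normalized score matrix
    selfs <- vapply(ps, function(p) sw_gotoh(p, p)$score, numeric(1))
    n_ <- length(ps)
    adj <- matrix(FALSE, n_, n_)
    for (i in seq_len(n_)) for (j in seq_len(n_)) {
      raw <- sw_gotoh(ps[i], ps[j])$score
      longer <- if (nchar(ps[i]) > nchar(ps[j])) selfs[i]
                else if (nchar(ps[j]) > nchar(ps[i])) selfs[j]
                else max(selfs[i], selfs[j])
      adj[i, j] <- 100 * raw / longer >= 30
    }
    diag(adj) <- TRUE
    expect_true(same_partition(cm$reference_colors, bf_components(adj)),
                info = paste("case", rep_i))
  }
})

test_that("propagation inherits colors from the best reference match", {
  set.seed(64)
  ps <- vapply(1:3, function(i) random_protein(80), character(1))
  ref <- mkseg(ps, acc = "REF1")
  cm <- build_reference_colors(ref, threshold = 30)
  # exact copy of reference gene 2 inherits its color
  other <- mkseg(c(random_protein(75), ps[2]), acc = "OTH1")
  out <- propagate_colors(cm, ref, other, threshold = 30)
  expect_equal(out$genes$color[2], cm$reference_colors[2])
  expect_equal(out$genes$norm_vs_ref[2], 100)
  expect_true(is.na(out$genes$color[1]))
  expect_false(out$non_syntenic)
  # a fusion of genes 1+2 inherits the better-scoring half's color
  fus <- mkseg(paste0(ps[1], ps[2]), acc = "OTH2")
  outf <- propagate_colors(cm, ref, fus, threshold = 30)
  expect_true(outf$genes$color[1] %in% cm$reference_colors[1:2])
  expect_lt(outf$genes$norm_vs_ref[1], 100)  # moderate, not a self-match
  # unrelated segment stays uncolored and is flagged non-syntenic
  far <- mkseg(c(random_protein(70)), acc = "OTH3")
  outn <- propagate_colors(cm, ref, far, threshold = 30)
  expect_true(all(is.na(outn$genes$color)))
  expect_true(outn$non_syntenic)
})

test_that("at threshold 100 only identically scoring matches inherit colors", {
  set.seed(65)
  ps <- vapply(1:2, function(i) random_protein(70), character(1))
  ref <- mkseg(ps, acc = "REF1")
  cm <- build_reference_colors(ref, threshold = 100)
  mut <- sub("^(M.)(.)", "\\1A", ps[1])  # one substitution
  other <- mkseg(c(ps[1], mut), acc = "OTH1")
  out <- propagate_colors(cm, ref, other, threshold = 100)
  expect_equal(out$genes$color[1], cm$reference_colors[1])
  expect_true(is.na(out$genes$color[2]))
})

test_that("the full pipeline recovers a planted cluster across genomes", {
  sc <- cluster_scenario()
  rep <- cluster_report()
  expect_length(rep$rows, 3)
  expect_equal(rep$not_found$accession, "GD01")
  expect_equal(rep$rows[[1]]$genes$color[rep$rows[[1]]$genes$locus_tag == "A4"],
               rep$rows[[1]]$genes$color[rep$rows[[1]]$genes$locus_tag == "A4p"])
  # the 5 planted ortholog colors propagate to the complete second genome
  ref_genes <- rep$rows[[1]]$genes
  ref_color_of <- function(lt) ref_genes$color[ref_genes$locus_tag == lt]
  second <- rep$rows[[which(vapply(rep$rows, function(s)
    s$accession == "GB01", logical(1)))]]
  for (i in 1:5)
    expect_equal(second$genes$color[i],
                 ref_color_of(paste0("A", i)))
})

test_that("permuting non-reference genomes never changes segment colors", {
  sc <- cluster_scenario()
  rep1 <- cluster_report()
  rep2 <- run_synteny(sc$P[[1]], sc$genomes[c(1, 4, 3, 2)])
  by_acc <- function(r) {
    out <- lapply(r$rows, function(s) s$genes[, c("locus_tag", "color")])
    names(out) <- vapply(r$rows, function(s) s$accession, character(1))
    out[order(names(out))]
  }
  expect_identical(by_acc(rep1), by_acc(rep2))
})

test_that("the genome cap is enforced before any computation", {
  sc <- cluster_scenario()
  fake <- lapply(1:101, function(i) {
    g <- sc$genomes[[4]]; g$accession <- sprintf("Z%03d", i); g
  })
  expect_error(run_synteny(sc$P[[1]], fake), "100 genomes")
  expect_error(run_synteny(sc$P[[1]], list()), "at least one")
  expect_error(run_synteny(sc$P[[1]], sc$genomes[c(1, 1)]), "duplicate")
})

test_that("a single genome yields a colored reference and no propagation", {
  sc <- cluster_scenario()
  rep <- run_synteny(sc$P[[1]], sc$genomes[1])
  expect_length(rep$rows, 1)
  expect_true(all(!is.na(rep$rows[[1]]$genes$color)))
  expect_equal(nrow(rep$not_found), 0)
})

test_that("a hitless query yields empty rows and a full not-found list", {
  set.seed(66)
  q <- random_protein(80)
  sc <- cluster_scenario()
  rep <- run_synteny(q, sc$genomes[4])
  expect_length(rep$rows, 0)
  expect_equal(rep$not_found$accession, "GD01")
})
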