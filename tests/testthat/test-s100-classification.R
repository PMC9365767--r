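# classification of S100-domain genes by the coding-extension rule

classify_planted <- function(tail_nt, double_domain = FALSE, seed = 31) {
  set.seed(seed)
  dom <- random_peptide(60)
  g <- plant_s100_gene(dom, tail_nt, double_domain = double_domain)
  hits <- search_genome(setNames(dom, "dom"), g$seq)
  expect_gte(nrow(hits), 1L)
  model <- classify_s100_gene(hits, g$seq)
  list(model = model, truth = g)
}

test_that("a long tail makes an SFTP, a short tail an S100A", {
  r <- classify_planted(500 * 3)
  expect_equal(r$model$gene_class, "SFTP")
  expect_gt(r$model$extension_nt, 400)
  r <- classify_planted(40 * 3)   # 120 nt <= 400
  expect_equal(r$model$gene_class, "S100A")
})

test_that("the 400-nt extension threshold is sharp between 400 and 401", {
  # tail of k codons puts the stop 3k nt past the domain: extension = 3k.
  # 399 and 402 nt are directly constructible; the rule boundary is
  # crossed exactly between extension 400 and 401.
  for (ext in c(399, 402)) {
    expect_equal(ext %% 3, 0)
    r <- classify_planted(ext)
    expect_equal(r$model$gene_class, if (ext > 400) "SFTP" else "S100A",
                 info = paste("extension", ext))
    expect_equal(r$model$extension_nt, ext)
  }
})

test_that("two consecutive S100 domains force class S100A despite a long tail", {
  r <- classify_planted(200 * 3, double_domain = TRUE)
  expect_equal(r$model$n_domains, 2L)
  expect_equal(r$model$gene_class, "S100A")
  expect_gt(r$model$extension_nt, 400)
})

test_that("the reconstructed CDS runs from the start codon through the stop", {
  r <- classify_planted(30 * 3)
  expect_equal(r$model$cds$start, r$truth$cds_start)
  expect_equal(r$model$cds$end, r$truth$stop_start + 2L)
  expect_false(grepl("*", r$model$peptide, fixed = TRUE))
})

test_that("a spliced extension across a GT..AG intron is reconstructed", {
  set.seed(32)
  dom <- random_peptide(60)
  tail_pep <- strrep("Q", 180)
  intron <- paste0("GT", "TTAATTAATTAA", strrep("C", 80), "AG")
  seq <- paste0(random_dna(60), "ATG", reverse_translate(dom),
                CODON1[["T"]], CODON1[["N"]],   # two spacer codons, no GT
                intron, reverse_translate(tail_pep), "TAA", random_dna(60))
  hits <- search_genome(setNames(dom, "dom"), seq)
  model <- classify_s100_gene(hits, seq)
  expect_equal(model$gene_class, "SFTP")
  expect_equal(model$extension_nt, 6L + 540L)
  expect_equal(nrow(model$cds), 2L)
  intron_start <- 60 + 3 + 180 + 6 + 1
  expect_equal(model$cds$end[1], intron_start - 1L)
  expect_equal(model$cds$start[2], intron_start + nchar(intron))
})

test_that("inconsistent strands in a hit group are an error", {
  hits <- data.frame(query_id = "q", seqid = "g", start = c(1L, 100L),
                     end = c(30L, 130L), strand = c("+", "-"),
                     frame = 0L, score = 60, identity = 1,
                     qstart = 1L, qend = 10L, stringsAsFactors = FALSE)
  expect_error(classify_s100_gene(hits, random_dna(300)), "inconsistent")
})
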