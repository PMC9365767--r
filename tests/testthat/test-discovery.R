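# locus-level discovery: anchors, SEDC calling rules, exon-1 annotation

test_that("anchors are located and the inter-anchor interval matches truth", {
  sd <- default_sim(7)
  sim <- sd$sim
  anch <- locate_anchors(sim$genome, sim$queries[c("S100A11", "S100A16")])
  expect_equal(anch$interval, sim$inter_anchor)
  expect_setequal(anch$anchor_ids, c("S100A11", "S100A16"))
})

test_that("a missing anchor raises an error naming the query", {
  sd <- default_sim(7)
  qs <- sd$sim$queries[c("S100A11", "S100A16")]
  qs[[2]] <- Biostrings::AAString(random_peptide(60))   # unrelated sequence
  expect_error(locate_anchors(sd$sim$genome, qs), "S100A16")
})

test_that("discovery recovers all planted genes on the default simulation", {
  sd <- default_sim(7)
  scan <- edc_scan(sd$sim$genome, sd$sim$queries[c("S100A11", "S100A16")],
                   sd$sim$queries["S100_SFTP_domain"], sd$reads$reads)
  v <- validate_against_truth(scan, sd$sim)
  expect_true(all(v$per_class$precision == 1))
  expect_true(all(v$per_class$recall == 1))
  expect_equal(unname(scan$counts), c(2L, 2L, 2L))
  # every called gene is validated by reads: TATA + canonical splice sites
  rep <- summary(scan)
  expect_true(all(rep$tata_found))
  expect_true(all(rep$spanning_reads > 0))
  # no called SEDC overlaps any other called coding sequence
  cds <- scan$features[scan$features$type == "CDS", ]
  sedc <- cds[cds$gene_class == "SEDC", ]
  other <- cds[cds$gene_class != "SEDC", ]
  for (i in seq_len(nrow(sedc)))
    expect_false(any(sedc$start[i] <= other$end & sedc$end[i] >= other$start))
})

test_that("reverse-complementing the locus yields the mirrored gene models", {
  sd <- default_sim(7)
  g <- as.character(sd$sim$genome)
  n <- nchar(g)
  scan_f <- edc_scan(sd$sim$genome, sd$sim$queries[c("S100A11", "S100A16")],
                     sd$sim$queries["S100_SFTP_domain"], sd$reads$reads)
  rc <- Biostrings::DNAStringSet(setNames(revcomp(g), "locus_sim"))
  scan_r <- edc_scan(rc, sd$sim$queries[c("S100A11", "S100A16")],
                     sd$sim$queries["S100_SFTP_domain"], sd$reads$reads)
  key <- function(s) {
    cds <- s$features[s$features$type == "CDS", ]
    sort(sprintf("%s:%d-%d:%s", cds$gene_class, cds$start, cds$end, cds$strand))
  }
  cds_f <- scan_f$features[scan_f$features$type == "CDS", ]
  mirrored <- sprintf("%s:%d-%d:%s", cds_f$gene_class,
                      n - cds_f$end + 1L, n - cds_f$start + 1L,
                      ifelse(cds_f$strand == "+", "-", "+"))
  expect_setequal(key(scan_r), sort(mirrored))
})

# a hand-built single-gene locus for exon-1 annotation tests
make_exon1_fixture <- function(donor = "GT") {
  utr2 <- "CCTCCTCCTCCT"                          # 12 nt, no AG/ATG
  pep <- paste0("M", strrep("K", 69))
  cds <- paste0(reverse_translate(pep), "TAA")
  pad <- paste0("TTTTTT", "TATAAA", strrep("C", 24))  # TATA 30 nt upstream
  exon1 <- "ACCTTCACCTCTTCAACTCACCTTCTCACTCCACTTCAACCCTACTCTCAACTTCCCTT"
  intron <- paste0(donor, strrep("C", 86), "AG")
  genome <- paste0(pad, exon1, intron, utr2, cds, strrep("C", 40))
  e1s <- nchar(pad) + 1L
  e1e <- nchar(pad) + nchar(exon1)
  e2s <- e1e + nchar(intron) + 1L
  cds_s <- e2s + nchar(utr2)
  list(genome = genome, e1 = c(e1s, e1e), e2s = e2s,
       cds = c(cds_s, cds_s + nchar(cds) - 1L),
       gene = list(gene_class = "SEDC", strand = "+",
                   cds = data.frame(start = cds_s,
                                    end = cds_s + nchar(cds) - 1L),
                   peptide = pep, composition_class = "none",
                   acceptor_offset = 12L, tata_found = FALSE,
                   tata_interval = NULL, splice_donor_ok = FALSE,
                   splice_acceptor_ok = FALSE, exon1 = NULL,
                   spanning_read_ids = character(0), gene_id = "g1"))
}

test_that("junction-spanning reads recover exon 1, TATA box and splice sites", {
  fx <- make_exon1_fixture()
  g <- fx$genome
  exon1_seq <- substr(g, fx$e1[1], fx$e1[2])
  exon2_seq <- substr(g, fx$e2s, fx$e2s + 59L)
  reads <- Biostrings::DNAStringSet(c(
    span1 = paste0(substr(exon1_seq, 31, 60), substr(exon2_seq, 1, 30)),
    span_full = paste0(exon1_seq, substr(exon2_seq, 1, 20)),
    plain = substr(exon2_seq, 5, 44)))
  out <- annotate_exon1(fx$gene, g, reads)
  expect_equal(out$exon1, fx$e1)
  expect_true(out$splice_donor_ok)
  expect_true(out$splice_acceptor_ok)
  expect_true(out$tata_found)
  expect_equal(out$tata_interval, c(7L, 12L))
  expect_setequal(out$spanning_read_ids, c("span1", "span_full"))
  expect_equal(nrow(out$exons), 2L)
  expect_equal(unlist(out$exons[1, ], use.names = FALSE), fx$e1)
})

test_that("reads from the coding exon alone leave exon 1 unannotated", {
  fx <- make_exon1_fixture()
  exon2_seq <- substr(fx$genome, fx$e2s, fx$e2s + 79L)
  reads <- Biostrings::DNAStringSet(c(a = substr(exon2_seq, 1, 40),
                                      b = substr(exon2_seq, 21, 60)))
  out <- annotate_exon1(fx$gene, fx$genome, reads)
  expect_null(out$exon1)
  expect_false(out$splice_donor_ok)
  expect_equal(out$gene_class, "SEDC")   # class retained
})

test_that("a read spanning a non-canonical GC intron is rejected as evidence", {
  fx <- make_exon1_fixture(donor = "GC")
  exon1_seq <- substr(fx$genome, fx$e1[1], fx$e1[2])
  exon2_seq <- substr(fx$genome, fx$e2s, fx$e2s + 59L)
  reads <- Biostrings::DNAStringSet(c(
    span = paste0(substr(exon1_seq, 31, 60), substr(exon2_seq, 1, 30))))
  out <- annotate_exon1(fx$gene, fx$genome, reads)
  expect_null(out$exon1)
  expect_false(out$splice_donor_ok)
})

test_that("SEDC calling enforces acceptor and transcription rules", {
  set.seed(71)
  pep <- paste0("M", strrep("Q", 79))
  cds <- paste0(reverse_translate(pep), "TAA")
  # candidate A: acceptor present; candidate B: no AG within the window
  regA <- paste0(strrep("C", 60), "AG", strrep("C", 10), cds)
  regB <- paste0(strrep("C", 72), cds)
  filler <- strrep("CT", 400)
  genome <- paste0(filler, regA, filler, regB, filler)
  a_start <- nchar(filler) + 73L
  reads_hit <- Biostrings::DNAStringSet(
    c(r1 = substr(genome, a_start, a_start + 99L)))
  # with a read covering candidate A: only A is called
  models <- call_sedc_genes(genome, c(1L, nchar(genome)), NULL,
                            list(skin = reads_hit))
  expect_length(models, 1L)
  expect_equal(models[[1]]$cds$start, a_start)
  expect_length(attr(models, "untranscribed"), 0L)
  # with no reads anywhere: A is flagged untranscribed, nothing is called
  models <- call_sedc_genes(genome, c(1L, nchar(genome)), NULL,
                            list(skin = Biostrings::DNAStringSet()))
  expect_length(models, 0L)
  untx <- attr(models, "untranscribed")
  expect_length(untx, 1L)
  expect_equal(untx[[1]]$cds$start, a_start)
})
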