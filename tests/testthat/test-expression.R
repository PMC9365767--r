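test_that("make_query extracts 1-based inclusive spans", {
  p <- setNames(paste(rep(AA20, 3), collapse = ""), "prot")  # 60-mer
  q <- make_query(p, 41, 60)
  expect_equal(nchar(q$residues), 20L)
  expect_equal(q$residues, unname(substr(p, 41, 60)))
  expect_equal(q$source_positions, c(41L, 60L))
  q <- make_query(setNames(substr(p, 1, 50), "prot"), 1, 50)
  expect_equal(nchar(q$residues), 50L)
  expect_error(make_query(p, 0, 10), "out of range")
  expect_error(make_query(p, 41, 61), "out of range")
})

test_that("perfect-identity counting: strand rule and zero-mismatch rule", {
  set.seed(41)
  q <- make_query(setNames(random_peptide(20), "g"), 1, 20)
  coding <- reverse_translate(q$residues)
  reads <- Biostrings::DNAStringSet(c(fwd = coding, rev = revcomp(coding)))
  expect_equal(count_perfect_hits(q, reads), 2L)
  # one substituted residue -> no hit
  mut <- q$residues
  substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "A") "V" else "A"
  reads <- Biostrings::DNAStringSet(c(m = reverse_translate(mut)))
  expect_equal(count_perfect_hits(q, reads), 0L)
})

test_that("edge overlaps count from min_overlap_aa residues", {
  set.seed(42)
  q <- make_query(setNames(random_peptide(50), "g"), 1, 50)
  # read covering only the last L residues of the query plus flanking junk
  for (L in c(15, 16, 30)) {
    suffix_dna <- reverse_translate(substr(q$residues, 50 - L + 1, 50))
    read <- paste0(suffix_dna, strrep("C", 60))
    cnt <- count_perfect_hits(q, Biostrings::DNAStringSet(c(r = read)))
    expect_equal(cnt, as.integer(L >= 16), info = paste("overlap", L))
  }
})

test_that("count_perfect_hits equals the brute-force oracle", {
  set.seed(43)
  sd <- default_sim(7)
  prot <- as.character(sd$sim$proteins[["SEDC1"]])
  q <- make_query(setNames(prot, "SEDC1"), 1, min(50, nchar(prot)))
  reads <- sd$reads$reads$skin[1:4000]
  got <- count_perfect_hits(q, reads)
  want <- count_hits_oracle(q$residues, reads)
  expect_equal(got, want)
  expect_gt(got, 0L)
})

test_that("adding reads never decreases a count", {
  set.seed(44)
  sd <- default_sim(7)
  prot <- as.character(sd$sim$proteins[["SFTP1"]])
  q <- make_query(setNames(prot, "SFTP1"), 1, 50)
  r1 <- sd$reads$reads$skin[1:2000]
  r2 <- sd$reads$reads$skin[1:6000]   # superset of r1
  expect_gte(count_perfect_hits(q, r2), count_perfect_hits(q, r1))
})

test_that("in containment counting, shortening a query never decreases
           its count", {
  # a read whose translation contains the long query contains every
  # sub-span of it; checked with reads long enough to hold the query
  set.seed(46)
  sd <- default_sim(7)
  tx <- as.character(sd$sim$transcripts[["SEDC1"]])
  starts <- seq(1, nchar(tx) - 150, by = 7)
  reads <- Biostrings::DNAStringSet(setNames(
    substring(tx, starts, starts + 149), paste0("r", seq_along(starts))))
  prot <- as.character(sd$sim$proteins[["SEDC1"]])
  q40 <- make_query(setNames(prot, "SEDC1"), 1, 40)
  q25 <- make_query(setNames(prot, "SEDC1"), 1, 25)
  c40 <- count_perfect_hits(q40, reads, min_overlap_aa = 40)
  c25 <- count_perfect_hits(q25, reads, min_overlap_aa = 25)
  expect_gt(c40, 0L)
  expect_gte(c25, c40)
})

test_that("expression table has one record per query x tissue with library sizes", {
  set.seed(45)
  reads <- list(
    skin = Biostrings::DNAStringSet(c(a = random_dna(60), b = random_dna(60))),
    liver = Biostrings::DNAStringSet(c(c = random_dna(60))))
  qs <- Biostrings::AAStringSet(c(g1 = random_peptide(30),
                                  g2 = random_peptide(30)))
  tab <- expression_table(qs, reads)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$tissue, c("skin", "liver"))
  expect_equal(unique(tab$library_reads[tab$tissue == "skin"]), 2L)
  expect_equal(unique(tab$library_bases[tab$tissue == "skin"]), 120)
})
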