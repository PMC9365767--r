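test_that("composition percentages are exact and sum to 100", {
  prof <- aa_composition(c(p = "QQQQQ"))
  expect_equal(unname(prof$percent["Q"]), 100)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-12)
  prof <- aa_composition("GSGS")
  expect_equal(unname(prof$percent[c("G", "S")]), c(50, 50))
  prof <- aa_composition(paste(AA20, collapse = ""))
  expect_true(all(abs(prof$percent - 5) < 1e-12))
  expect_error(aa_composition("MKV*"), "stop")
})

test_that("composition is permutation-invariant", {
  set.seed(51)
  p <- random_peptide(120)
  shuffled <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(aa_composition(p)$percent, aa_composition(shuffled)$percent)
})

test_that("align_repeats segments perfect tandems and recovers the phase", {
  units <- align_repeats("PKQPKQPKQ", 3)
  expect_equal(as.character(units), rep("PKQ", 3))
  expect_equal(attr(units, "identity"), 1.0)
  units <- align_repeats("APKQPKQPKQ", 3)     # leading residue shifts phase
  expect_equal(attr(units, "phase"), 1L)
  expect_equal(attr(units, "identity"), 1.0)
  expect_error(align_repeats("ACDEFG", 5), "fewer than 2 units")
})

test_that("perfect tandems of random units always reach identity 1", {
  set.seed(52)
  for (i in 1:20) {
    u <- random_peptide(sample(3:12, 1))
    k <- sample(3:6, 1)
    phase <- sample(0:(nchar(u) - 1), 1)
    pep <- paste0(substr(random_peptide(nchar(u)), 1, phase), strrep(u, k))
    units <- align_repeats(pep, nchar(u))
    expect_equal(attr(units, "identity"), 1.0,
                 info = paste(u, k, phase))
  }
})

test_that("logo information content matches the closed forms", {
  logo <- build_logo(rep("Q", 10))
  expect_equal(logo$ic_bits, log2(20), tolerance = 1e-12)
  logo <- build_logo(AA20)                     # uniform over 20 residues
  expect_equal(logo$ic_bits, 0, tolerance = 1e-12)
  logo <- build_logo(c(rep("Q", 5), rep("K", 5)))
  expect_equal(logo$ic_bits, log2(20) - 1, tolerance = 1e-12)
  expect_equal(logo$freq["Q", 1], 0.5)
})

test_that("logo frequencies sum to 1 per column; gaps are excluded", {
  logo <- build_logo(c("QK", "Q-", "QK"))
  expect_equal(colSums(logo$freq), c(`1` = 1, `2` = 1))
  expect_equal(logo$freq["K", 2], 1)           # gap dropped from column 2
  expect_error(build_logo(c("QK", "QKX")), "equal length")
  expect_error(build_logo("QK"), "at least 2")
})

test_that("composition report flags notable residues and appends references", {
  prots <- Biostrings::AAStringSet(c(a = strrep("Q", 40),
                                     b = paste0(strrep("G", 30), strrep("A", 70))))
  refs <- Biostrings::AAStringSet(c(SPRR1A_like = strrep("P", 30)))
  tab <- composition_report(prots, refs)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$notable_residues[1], "Q")
  expect_true(tab$is_reference[3])
  expect_true(all(abs(rowSums(tab[, AA20]) - 100) < 1e-9))
  tab2 <- composition_report(prots)
  expect_equal(nrow(tab2), 2L)
})
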