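test_that("a planted ORF is recovered at its exact coordinates", {
  set.seed(21)
  pep <- paste0("M", random_peptide(79))
  dna <- paste0(reverse_translate(pep), "TAA")
  # ATG-free upstream flank so the planted start codon is the 5'-most
  flank1 <- strrep("CT", 200); flank2 <- random_dna(400)
  region <- paste0(flank1, dna, flank2)
  orfs <- scan_orfs(region, min_aa = 50)
  planted <- orfs[orfs$strand == "+" & orfs$start == 401L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$end, 400L + 240L)
  expect_equal(planted$peptide, pep)
  expect_equal(planted$length_aa, 80L)
})

test_that("the 50-residue threshold is sharp", {
  for (len in c(49, 50)) {
    pep <- paste0("M", strrep("K", len - 1))
    region <- paste0("CCCCCC", reverse_translate(pep), "TAA", "CCCCCC")
    orfs <- scan_orfs(region, min_aa = 50)
    hit <- any(orfs$length_aa == len & orfs$strand == "+")
    expect_equal(hit, len >= 50, info = paste("len", len))
  }
})

test_that("scan_orfs equals brute-force enumeration on random sequences", {
  set.seed(22)
  for (i in 1:12) {
    dna <- random_dna(3000)
    got <- scan_orfs(dna, min_aa = 20)
    want <- orf_oracle(dna, min_aa = 20)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("start", "end", "strand", "length_aa", "peptide")],
                 want[, c("start", "end", "strand", "length_aa", "peptide")])
  }
})

test_that("composition classes follow the threshold arithmetic", {
  expect_equal(classify_composition(strrep("Q", 60)), "involucrin_like")
  expect_equal(classify_composition(strrep("GS", 30)), "loricrin_like")
  # 20% P, 5% Q, rest neutral: only the SPRR threshold is met
  pep <- paste0(strrep("P", 20), strrep("Q", 5), strrep("A", 75))
  expect_equal(classify_composition(pep), "sprr_like")
  # largest content/threshold ratio wins when several thresholds are met
  pep <- paste0(strrep("C", 30), strrep("P", 20), strrep("A", 50))
  expect_equal(classify_composition(pep), "edcrp_like")  # 3.0 vs 1.33
  expect_error(classify_composition(""), "empty")
})

test_that("uniform random peptides are rarely class-biased, at the
           binomially expected rate", {
  # under the default thresholds the binding constraint for a uniform
  # 100-mer is cysteine >= 10%: P(Binom(100, 0.05) >= 10) ~ 0.0282; the
  # other classes contribute < 1e-4. Expect the hit count within 4 sd.
  set.seed(23)
  n <- 1000
  hits <- sum(vapply(seq_len(n), function(i)
    classify_composition(random_peptide(100)) != "none", logical(1)))
  p <- pbinom(9, 100, 0.05, lower.tail = FALSE)
  expect_lt(abs(hits - n * p), 4 * sqrt(n * p * (1 - p)))
})

test_that("splice acceptor window arithmetic is exact", {
  pep <- paste0("M", strrep("K", 59))
  cds <- paste0(reverse_translate(pep), "TAA")
  # AG ending exactly `off` nt before the ATG; C-filler contains no AG
  for (off in c(0, 10, 50, 51)) {
    region <- paste0(strrep("C", 60), "AG", strrep("C", off), cds, "CCC")
    orfs <- scan_orfs(region, min_aa = 50)
    orf <- orfs[orfs$strand == "+", ][1, ]
    out <- check_splice_acceptor(region, orf, window = 50)
    if (off <= 50) {
      expect_true(out$acceptor_found, info = paste("offset", off))
      expect_equal(out$acceptor_offset, off)
    } else {
      expect_false(out$acceptor_found)
    }
  }
  # no AG anywhere upstream
  region <- paste0(strrep("C", 80), cds, "CCC")
  orf <- scan_orfs(region, min_aa = 50)[1, ]
  expect_false(check_splice_acceptor(region, orf)$acceptor_found)
})

test_that("splice acceptor check respects the minus strand", {
  pep <- paste0("M", strrep("K", 59))
  cds <- paste0(reverse_translate(pep), "TAA")
  region <- paste0(strrep("C", 60), "AG", strrep("C", 7), cds, "CCC")
  region_rc <- revcomp(region)
  orfs <- scan_orfs(region_rc, min_aa = 50)
  orf <- orfs[orfs$strand == "-", ][1, ]
  out <- check_splice_acceptor(region_rc, orf, window = 50)
  expect_true(out$acceptor_found)
  expect_equal(out$acceptor_offset, 7L)
})
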