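test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_locus(locus_config(n_sedc = 2, n_sftp = 2, seed = 7))
  s2 <- simulate_locus(locus_config(n_sedc = 2, n_sftp = 2, seed = 7))
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$features, s2$features)
  s3 <- simulate_locus(locus_config(seed = 8))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("truth features match the configured gene counts and structure", {
  for (seed in c(3, 9)) {
    sim <- simulate_locus(locus_config(n_sedc = 3, n_sftp = 2, seed = seed))
    genes <- sim$features[sim$features$type == "gene", ]
    expect_equal(sum(genes$gene_class == "SEDC"), 3L)
    expect_equal(sum(genes$gene_class == "SFTP"), 2L)
    expect_equal(sum(genes$gene_class == "S100A"), 2L)
    ex <- sim$features[sim$features$type == "exon", ]
    cds <- sim$features[sim$features$type == "CDS", ]
    for (gid in genes$ID[genes$gene_class == "SEDC"]) {
      expect_equal(sum(ex$Parent == gid), 2L)    # non-coding + coding exon
      expect_equal(sum(cds$Parent == gid), 1L)
    }
    for (gid in genes$ID[genes$gene_class == "SFTP"]) {
      expect_equal(sum(ex$Parent == gid), 3L)    # non-coding + two coding
      expect_equal(sum(cds$Parent == gid), 2L)
    }
  }
})

test_that("structural invariants hold across seeds: GT..AG introns, TATA
           placement, SEDC product length, acceptor distance", {
  for (seed in 1:10) {
    sim <- simulate_locus(locus_config(seed = seed))
    g <- unname(as.character(sim$genome))
    f <- sim$features
    introns <- f[f$type == "intron", ]
    for (i in seq_len(nrow(introns))) {
      s <- substr(g, introns$start[i], introns$end[i])
      if (introns$strand[i] == "-") s <- revcomp(s)
      expect_equal(substr(s, 1, 2), "GT")
      expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
    }
    tata <- f[f$type == "TATA_box", ]
    exons <- f[f$type == "exon", ]
    for (i in seq_len(nrow(tata))) {
      gid <- tata$Parent[i]
      ex <- exons[exons$Parent == gid, ]
      if (tata$strand[i] == "+") {
        e1s <- min(ex$start)
        dist <- e1s - tata$start[i]
      } else {
        e1s <- max(ex$end)
        dist <- tata$end[i] - e1s
      }
      expect_true(dist >= 25 && dist <= 35, info = paste(gid, dist))
    }
    peps <- as.character(sim$proteins)
    expect_true(all(nchar(peps[grepl("SEDC", names(peps))]) >= 50))
    # splice acceptor AG within 50 nt upstream of each SEDC start codon
    cds <- f[f$type == "CDS", ]
    for (gid in names(peps)[grepl("SEDC", names(peps))]) {
      ci <- cds[cds$Parent == gid, ]
      orf <- data.frame(start = ci$start, end = ci$end - 3L,
                        strand = ci$strand, stringsAsFactors = FALSE)
      if (ci$strand == "-") orf <- data.frame(start = ci$start + 3L,
                                              end = ci$end, strand = "-")
      out <- check_splice_acceptor(g, orf, window = 50)
      expect_true(out$acceptor_found, info = gid)
    }
  }
})

test_that("read sets have the configured size and tissue restriction", {
  sd <- default_sim(7)
  expr <- expression_config(seed = 7)
  expect_setequal(names(sd$reads$reads), expr$tissues)
  for (t in expr$tissues)
    expect_equal(length(sd$reads$reads[[t]]), expr$reads_per_tissue)
  cnt <- sd$reads$counts
  edc <- grepl("^(SFTP|SEDC)", rownames(cnt))
  expect_true(all(cnt[edc, colnames(cnt) != "skin"] == 0))
  expect_true(all(cnt[edc, "skin"] > 0))
})

test_that("skin read counts stay within 4 binomial standard deviations", {
  for (seed in c(7, 15)) {
    sim <- simulate_locus(locus_config(seed = seed))
    expr <- expression_config(seed = seed)
    rd <- simulate_reads(sim, expr)
    n <- expr$reads_per_tissue; p <- expr$edc_skin_fraction
    sdv <- sqrt(n * p * (1 - p))
    for (gid in grep("^SEDC", rownames(rd$counts), value = TRUE))
      expect_lt(abs(rd$counts[gid, "skin"] - n * p), 4 * sdv)
  }
})

test_that("reads are exact transcript substrings and include a junction-
           spanning read per expressed gene", {
  sd <- default_sim(7)
  tx <- as.character(sd$sim$transcripts)
  skin <- sd$reads$reads$skin
  gene_of <- sub("^skin_([^_]+)_.*$", "\\1", names(skin))
  for (gid in names(tx)) {
    rs <- as.character(skin[gene_of == gid])
    expect_gt(length(rs), 0)
    some <- rs[seq(1, length(rs), length.out = min(50, length(rs)))]
    expect_true(all(vapply(some, function(r)
      grepl(r, tx[[gid]], fixed = TRUE), logical(1))), info = gid)
    # at least one read spans the exon1/exon2 junction by >= 8 nt each side
    ex <- sd$sim$features[sd$sim$features$type == "exon" &
                          sd$sim$features$Parent == gid, ]
    st <- ex$strand[1]
    u1 <- if (st == "+") ex$end[which.min(ex$start)] - min(ex$start) + 1L
          else max(ex$end) - ex$start[which.max(ex$end)] + 1L
    pos <- vapply(rs, function(r) regexpr(r, tx[[gid]], fixed = TRUE)[1],
                  numeric(1))
    spans <- pos <= u1 - 7 & pos + nchar(rs) - 1 >= u1 + 8
    expect_true(any(spans), info = gid)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(locus_config(n_sftp = 0), "n_sftp")
  expect_error(locus_config(sedc_class_mix = c(loricrin_like = 0.5,
                                               involucrin_like = 0.2,
                                               sprr_like = 0.2,
                                               edcrp_like = 0.2)), "sum to 1")
  expect_error(locus_config(intron_len_range = c(10L, 20L)), "40 nt")
  expect_error(expression_config(read_len = 2), "read_len")
  sim <- simulate_locus(locus_config(seed = 1))
  expect_error(simulate_reads(sim, expression_config(read_len = 100000L)),
               "exceeds the shortest transcript")
})
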