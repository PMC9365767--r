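# Synthetic EDC locus and multi-tissue read simulator. Generates a genome
# laid out as [flank][S100A anchor][intergenic][SFTPs][intergenic][SEDCs]
# [intergenic][S100A anchor][flank] with known truth annotations, plus
# error-free reads drawn from the spliced transcripts with skin-dominant
# abundance for the EDC genes.
#
# Sequence-design notes (what makes recovery well-posed):
#  * every intron begins GT, carries stop codons in all three forward frames
#    just after the donor, contains no internal AG, and ends AG, so the
#    spliced coding extension of an SFTP has a unique maximal solution;
#  * SFTP carboxy-terminal tails are encoded with an AG-free codon alphabet
#    (P/Q/K/S/T-rich, matching the proline-glutamine-lysine bias of these
#    proteins) so no spurious acceptor lies between donor and acceptor;
#  * coding bodies carry periodic "frame blocker" dipeptides that place stop
#    codons in the two shifted forward frames and the reverse frames,
#    keeping spurious overlapping ORFs short;
#  * 5' UTR segments within coding exons are free of AG and ATG so the
#    splice acceptor nearest the start codon is the real one;
#  * intergenic sequence has every ORF of >= 50 codons (all six frames)
#    destroyed by planted in-frame stops.

# ---- configuration ----------------------------------------------------------

#' Configuration for the synthetic locus
#'
#' Defaults describe the study condition used throughout the package tests:
#' a caecilian-like EDC with two S100A anchors, two SFTP genes and two SEDC
#' genes.
#'
#' @param n_sedc,n_sftp Numbers of SEDC and SFTP genes (`n_sftp >= 1`).
#' @param sedc_class_mix Named proportions over the four composition classes
#'   used to draw SEDC classes; must sum to 1.
#' @param intergenic_len_range,intron_len_range,sedc_cds_aa_range,
#'   sftp_tail_aa_range Integer ranges (nt, nt, aa, aa).
#' @param flank_len Flanking sequence outside the anchors, nt.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A validated list of class `locus_config`.
#' @export
locus_config <- function(n_sedc = 2L, n_sftp = 2L,
                         sedc_class_mix = c(loricrin_like = 0.25,
                                            involucrin_like = 0.25,
                                            sprr_like = 0.25,
                                            edcrp_like = 0.25),
                         intergenic_len_range = c(1500L, 3000L),
                         intron_len_range = c(90L, 300L),
                         sedc_cds_aa_range = c(80L, 160L),
                         sftp_tail_aa_range = c(200L, 350L),
                         flank_len = 800L,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$sedc_class_mix) - 1) > 1e-9)
    .stopf("locus_config: sedc_class_mix must sum to 1")
  if (cfg$n_sftp < 1L) .stopf("locus_config: n_sftp must be >= 1")
  if (cfg$n_sedc < 0L) .stopf("locus_config: n_sedc must be >= 0")
  ranges <- cfg[c("intergenic_len_range", "intron_len_range",
                  "sedc_cds_aa_range", "sftp_tail_aa_range")]
  if (any(vapply(ranges, function(r) length(r) != 2L || any(r <= 0) ||
                 r[1] > r[2], logical(1))))
    .stopf("locus_config: ranges must be positive increasing pairs")
  if (cfg$intron_len_range[1] < 40L)
    .stopf("locus_config: introns must be at least 40 nt to fit the mandated motifs")
  if (cfg$sedc_cds_aa_range[1] < 50L)
    .stopf("locus_config: SEDC products must be at least 50 aa")
  class(cfg) <- "locus_config"
  cfg
}

#' Configuration for simulated tissue read sets
#'
#' @param tissues Tissue names; the first is the skin-like tissue where EDC
#'   genes are expressed.
#' @param reads_per_tissue Reads per tissue library.
#' @param edc_skin_fraction Per-gene transcript abundance of each SFTP/SEDC
#'   gene in skin.
#' @param edc_other_fraction Abundance of each SFTP/SEDC gene in non-skin
#'   tissues (default 0).
#' @param housekeeping_fraction Per-gene abundance of the anchor (S100A)
#'   genes, uniform across tissues; they double as housekeeping controls.
#' @param read_len Read length, nt.
#' @param n_background Number of random background transcripts sharing the
#'   remaining abundance.
#' @param seed Integer seed.
#' @return A validated list of class `expression_config`.
#' @export
expression_config <- function(tissues = c("skin", "liver", "lung",
                                          "foregut", "kidney", "spleen"),
                              reads_per_tissue = 50000L,
                              edc_skin_fraction = 0.02,
                              edc_other_fraction = 0,
                              housekeeping_fraction = 0.02,
                              read_len = 100L,
                              n_background = 20L,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$read_len < 3L) .stopf("expression_config: read_len must be >= 3")
  fr <- c(cfg$edc_skin_fraction, cfg$edc_other_fraction, cfg$housekeeping_fraction)
  if (any(fr < 0 | fr > 1)) .stopf("expression_config: fractions must lie in [0, 1]")
  class(cfg) <- "expression_config"
  cfg
}

# ---- sequence building blocks ----------------------------------------------

.BASES <- c("A", "C", "G", "T")

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# remove occurrences of short motifs by rewriting their second character to C
.sanitize <- function(s, pats) {
  repeat {
    hit <- FALSE
    for (p in pats) {
      m <- regexpr(p, s, fixed = TRUE)[1]
      if (m > 0) {
        substr(s, m + 1L, m + 1L) <- "C"
        hit <- TRUE
      }
    }
    if (!hit) return(s)
  }
}

# codon choices; general table for ordinary coding sequence
.CODONS <- list(
  A = c("GCT", "GCA"), C = c("TGT", "TGC"), D = c("GAT", "GAC"),
  E = c("GAA", "GAG"), F = c("TTT", "TTC"), G = c("GGA", "GGT"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC"), K = c("AAA", "AAG"),
  L = c("CTT", "TTA"), M = "ATG", N = c("AAT", "AAC"),
  P = c("CCA", "CCT"), Q = c("CAA", "CAG"), R = c("AGA", "CGT"),
  S = c("TCA", "TCT"), T = c("ACT", "ACA"), V = c("GTT", "GTA"),
  W = "TGG", Y = c("TAT", "TAC"))

# AG-free table (no codon starts with G or contains AG; codon boundaries
# cannot form AG either) used for SFTP tails and pre-donor codons
.CODONS_AGFREE <- list(
  P = c("CCA", "CCT"), Q = "CAA", K = "AAA", S = c("TCA", "TCT"),
  T = c("ACA", "ACT"), L = c("CTT", "TTA"), H = "CAT", N = "AAT",
  I = "ATT", F = "TTT", C = "TGT", Y = "TAT")

.encode <- function(aa, table) {
  vapply(aa, function(a) {
    cs <- table[[a]]
    if (is.null(cs)) .stopf("no codon for residue %s in this table", a)
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

# frame-blocker dipeptides: fixed codons that put a stop codon into the +1
# or +2 frame and into a reverse frame, while translating to ordinary
# residues in frame 0
.BLOCKERS <- list(list(aa = c("L", "A"), dna = "TTAGCA"),   # +1 TAG, rev TAA
                  list(aa = c("T", "N"), dna = "ACTAAT"))   # +2 TAA, rev TAG
.BLOCKERS_AGFREE <- list(list(aa = c("L", "I"), dna = "TTAATT"),
                         list(aa = c("T", "N"), dna = "ACTAAT"))

# residue pools per composition class
.CLASS_POOLS <- list(
  loricrin_like = c(G = .32, S = .22, C = .04, Q = .06, K = .07, P = .04,
                    A = .06, V = .05, Y = .04, F = .03, T = .07),
  sprr_like = c(P = .30, K = .12, Q = .12, C = .07, V = .07, E = .06,
                T = .07, S = .06, A = .05, I = .04, Y = .04),
  edcrp_like = c(C = .22, G = .14, S = .12, Q = .10, R = .07, P = .08,
                 L = .07, Y = .05, A = .07, T = .08),
  sftp_tail = c(Q = .22, P = .18, K = .14, S = .16, T = .10, L = .06,
                H = .05, N = .05, F = .02, C = .02))

# sample a class-biased body (no initial M) with frame blockers every 10
# residues; returns list(aa, codons)
.sample_body <- function(class, len, agfree = FALSE) {
  blockers <- if (agfree) .BLOCKERS_AGFREE else .BLOCKERS
  table <- if (agfree) .CODONS_AGFREE else .CODONS
  for (attempt in 1:40) {
    if (class == "involucrin_like") {
      aa <- character(0)
      other <- c(E = .14, K = .17, L = .12, P = .11, G = .11, A = .10,
                 V = .07, H = .07, S = .11)
      while (length(aa) < len) {
        if (runif(1) < 0.35) aa <- c(aa, rep("Q", sample(3:5, 1L)))
        else aa <- c(aa, sample(names(other), 1L, prob = other))
      }
      aa <- aa[1:len]
    } else {
      pool <- .CLASS_POOLS[[class]]
      aa <- sample(names(pool), len, replace = TRUE, prob = pool)
    }
    codons <- .encode(aa, table)
    bpos <- seq(5L, len - 2L, by = 10L)
    for (bi in seq_along(bpos)) {
      b <- blockers[[1L + (bi %% 2L)]]
      j <- bpos[bi]
      aa[j:(j + 1L)] <- b$aa
      codons[j] <- substr(b$dna, 1L, 3L)
      codons[j + 1L] <- substr(b$dna, 4L, 6L)
    }
    target <- if (class == "sftp_tail") NULL else class
    if (is.null(target)) return(list(aa = aa, codons = codons))
    pep <- paste(c("M", aa), collapse = "")
    if (classify_composition(pep) == target) return(list(aa = aa, codons = codons))
  }
  .stopf("failed to sample a %s-composition body", class)
}

# canonical intron: GT | stop block (stops in all 3 forward frames) |
# AG-free interior | AG
.make_intron <- function(len) {
  stopifnot(len >= 20L)
  block <- "TTAATTAATTAA"
  interior <- .sanitize(paste0(block, .rand_dna(len - nchar(block) - 4L)),
                        c("AG", "ATG"))
  paste0("GT", interior, "AG")
}

# 5' UTR inside a coding exon: no AG (so the planted acceptor is nearest)
# and no ATG (so the CDS start is unambiguous)
.make_utr2 <- function(len) .sanitize(.rand_dna(len), c("AG", "ATG"))

.runi <- function(range) sample(range[1]:range[2], 1L)

# a random protein domain; family members are derived from a shared base
.mutate_pep <- function(pep, rate) {
  aa <- strsplit(pep, "")[[1]]
  k <- which(runif(length(aa)) < rate)
  aa[k] <- sample(setdiff(names(.CODONS), "M"), length(k), replace = TRUE)
  paste(aa, collapse = "")
}

# ---- gene cassettes ---------------------------------------------------------

# every cassette is built on the + strand as
#   [pad+TATA][exon1][intron1][ downstream parts ... ]
# where `parts` interleaves exon/intron segments in genomic order and
# `cds_rel` gives CDS intervals relative to the concatenated parts
.build_cassette <- function(gene_id, gene_class, parts, part_types, cds_rel,
                            u1_len, intron1_len, peptide) {
  d <- sample(25:35, 1L)                       # TATA start .. exon1 start
  pre <- .runi(c(6L, 14L))
  pad <- paste0(.rand_dna(pre), "TATAAA", .rand_dna(d - 6L))
  exon1 <- .rand_dna(u1_len)
  intron1 <- .make_intron(intron1_len)
  seqs <- c(pad, exon1, intron1, parts)
  seq <- paste(seqs, collapse = "")
  off <- cumsum(c(0L, nchar(seqs)))            # off[i] = chars before seqs[i]
  tata_s <- pre + 1L
  e1 <- c(off[2] + 1L, off[2] + u1_len)
  i1 <- c(off[3] + 1L, off[3] + nchar(intron1))
  region0 <- off[4]                            # offset of the parts region
  feats <- list(
    list(type = "gene", start = e1[1], end = off[length(off)]),
    list(type = "TATA_box", start = tata_s, end = tata_s + 5L),
    list(type = "exon", start = e1[1], end = e1[2]),
    list(type = "intron", start = i1[1], end = i1[2]))
  exonic <- list(e1)
  for (i in seq_along(parts)) {
    iv <- c(off[3 + i] + 1L, off[3 + i] + nchar(parts[i]))
    feats <- c(feats, list(list(type = part_types[i], start = iv[1], end = iv[2])))
    if (part_types[i] == "exon") exonic <- c(exonic, list(iv))
  }
  for (iv in cds_rel) feats <- c(feats, list(list(type = "CDS",
                                                  start = iv[1] + region0,
                                                  end = iv[2] + region0)))
  transcript <- paste(vapply(exonic, function(iv)
    substr(seq, iv[1], iv[2]), character(1)), collapse = "")
  list(gene_id = gene_id, gene_class = gene_class, seq = seq, feats = feats,
       transcript = transcript, peptide = peptide, u1_len = u1_len,
       strand = "+")
}

.cassette_sedc <- function(gene_id, class, cfg) {
  len_body <- .runi(cfg$sedc_cds_aa_range) - 1L
  body <- .sample_body(class, len_body)
  utr2 <- .make_utr2(.runi(c(10L, 40L)))
  utr3 <- .rand_dna(.runi(c(20L, 60L)))
  cds_dna <- paste0("ATG", paste(body$codons, collapse = ""), "TAA")
  exon2 <- paste0(utr2, cds_dna, utr3)
  .build_cassette(gene_id, "SEDC", exon2, "exon",
                  list(c(nchar(utr2) + 1L, nchar(utr2) + nchar(cds_dna))),
                  u1_len = .runi(c(60L, 90L)),
                  intron1_len = .runi(cfg$intron_len_range),
                  peptide = paste(c("M", body$aa), collapse = ""))
}

.cassette_sftp <- function(gene_id, domain_pep, cfg) {
  dom_aa <- strsplit(domain_pep, "")[[1]]
  dom_dna <- paste(.encode(dom_aa, .CODONS), collapse = "")
  n_extra <- sample(2:5, 1L)
  extra_aa <- sample(c("T", "N", "P", "H"), n_extra, replace = TRUE)
  extra_dna <- paste(.encode(extra_aa, .CODONS_AGFREE), collapse = "")
  tail_len <- .runi(cfg$sftp_tail_aa_range)
  tail <- .sample_body("sftp_tail", tail_len, agfree = TRUE)
  utr2 <- .make_utr2(.runi(c(10L, 40L)))
  utr3 <- .rand_dna(.runi(c(20L, 60L)))
  exon2 <- paste0(utr2, "ATG", dom_dna, extra_dna)
  intron2 <- .make_intron(.runi(cfg$intron_len_range))
  exon3 <- paste0(paste(tail$codons, collapse = ""), "TAA", utr3)
  cds1 <- c(nchar(utr2) + 1L, nchar(exon2))
  i2e <- nchar(exon2) + nchar(intron2)
  cds2 <- c(i2e + 1L, i2e + 3L * tail_len + 3L)
  .build_cassette(gene_id, "SFTP", c(exon2, intron2, exon3),
                  c("exon", "intron", "exon"), list(cds1, cds2),
                  u1_len = .runi(c(60L, 90L)),
                  intron1_len = .runi(cfg$intron_len_range),
                  peptide = paste(c("M", dom_aa, extra_aa, tail$aa), collapse = ""))
}

.cassette_anchor <- function(gene_id, domain_pep, cfg, double_domain = FALSE) {
  dom_aa <- strsplit(domain_pep, "")[[1]]
  if (double_domain) dom_aa <- c(dom_aa, dom_aa)
  tail_len <- .runi(c(20L, 28L))
  tail_aa <- sample(setdiff(names(.CODONS), "M"), tail_len, replace = TRUE)
  cds_dna <- paste0("ATG",
                    paste(.encode(dom_aa, .CODONS), collapse = ""),
                    paste(.encode(tail_aa, .CODONS), collapse = ""), "TAA")
  utr2 <- .make_utr2(.runi(c(10L, 40L)))
  utr3 <- .rand_dna(.runi(c(20L, 60L)))
  exon2 <- paste0(utr2, cds_dna, utr3)
  .build_cassette(gene_id, "S100A", exon2, "exon",
                  list(c(nchar(utr2) + 1L, nchar(utr2) + nchar(cds_dna))),
                  u1_len = .runi(c(60L, 90L)),
                  intron1_len = .runi(cfg$intron_len_range),
                  peptide = paste(c("M", dom_aa, tail_aa), collapse = ""))
}

# destroy every ORF of >= min_aa codons (all six frames) in a standalone
# segment by planting an in-frame stop at the ORF midpoint
.destroy_orfs <- function(seg, min_aa = 50L) {
  n <- nchar(seg)
  for (attempt in 1:20) {
    for (iter in 1:25) {
      orfs <- scan_orfs(seg, min_aa = min_aa)
      if (nrow(orfs) == 0L) return(seg)
      for (i in seq_len(nrow(orfs))) {
        mid <- orfs$length_aa[i] %/% 2L
        if (orfs$strand[i] == "+") {
          p <- orfs$start[i] + 3L * mid
          substr(seg, p, p + 2L) <- "TAA"
        } else {
          p <- orfs$end[i] - 3L * mid - 2L
          substr(seg, p, p + 2L) <- "TTA"   # reverse-complement of TAA
        }
      }
    }
    # rare pathological case (stop planting re-created an ATG at a
    # boundary): draw a fresh segment
    seg <- .rand_dna(n)
  }
  .stopf("failed to clear chance ORFs from background sequence")
}

# mirror a cassette onto the minus strand: sequence reverse-complemented,
# relative feature coordinates flipped
.flip_cassette <- function(cass) {
  n <- nchar(cass$seq)
  cass$seq <- .revcomp(cass$seq)
  cass$feats <- lapply(cass$feats, function(f) {
    iv <- .mirror_interval(f$start, f$end, n)
    f$start <- iv[1]; f$end <- iv[2]; f
  })
  cass$strand <- "-"
  cass
}

#' Simulate an EDC-like locus with known truth
#'
#' Builds a genome laid out as flank, S100A anchor A, SFTP genes, SEDC
#' genes, S100A anchor B, flank, with intergenic background in between.
#' Each gene has a TATA box 25-35 nt upstream of its non-coding exon 1,
#' canonical GT..AG introns, and gene-class-appropriate coding sequence.
#' Gene orientations are drawn at random. Intergenic and flanking sequence
#' is cleared of chance ORFs of 50+ codons so that discovery precision is a
#' meaningful target. Deterministic given `config$seed`.
#'
#' @param config A [locus_config()].
#' @return An object of class `edc_sim`: list with `genome` (named
#'   `DNAStringSet`), `features` (truth annotation data.frame), `transcripts`
#'   and `proteins` (per gene), `queries` (anchor and SFTP S100-domain
#'   peptides for the search), `inter_anchor` (interval between the anchor
#'   coding sequences), `config`.
#' @export
simulate_locus <- function(config = locus_config()) {
  stopifnot(inherits(config, "locus_config"))
  set.seed(config$seed)
  base_dom <- paste(sample(setdiff(names(.CODONS), "M"), 60L, replace = TRUE),
                    collapse = "")
  doms <- list(anchor_a = .mutate_pep(base_dom, 0.35),
               anchor_b = .mutate_pep(base_dom, 0.35),
               sftp = .mutate_pep(base_dom, 0.35))

  sedc_classes <- sample(names(config$sedc_class_mix), config$n_sedc,
                         replace = TRUE, prob = config$sedc_class_mix)
  cassettes <- list(.cassette_anchor("S100A11", doms$anchor_a, config))
  for (i in seq_len(config$n_sftp))
    cassettes <- c(cassettes, list(.cassette_sftp(sprintf("SFTP%d", i),
                                                  doms$sftp, config)))
  for (i in seq_len(config$n_sedc))
    cassettes <- c(cassettes, list(.cassette_sedc(sprintf("SEDC%d", i),
                                                  sedc_classes[i], config)))
  cassettes <- c(cassettes, list(.cassette_anchor("S100A16", doms$anchor_b,
                                                  config)))
  cassettes <- lapply(cassettes, function(cs)
    if (runif(1) < 0.5) .flip_cassette(cs) else cs)

  # assemble: flank | cass | intergenic | ... | cass | flank
  segs <- list(.destroy_orfs(.rand_dna(config$flank_len)))
  seg_is_gene <- FALSE
  for (i in seq_along(cassettes)) {
    segs <- c(segs, list(cassettes[[i]]$seq))
    seg_is_gene <- c(seg_is_gene, TRUE)
    filler_len <- if (i < length(cassettes)) .runi(config$intergenic_len_range)
                  else config$flank_len
    segs <- c(segs, list(.destroy_orfs(.rand_dna(filler_len))))
    seg_is_gene <- c(seg_is_gene, FALSE)
  }
  genome_chr <- paste(unlist(segs), collapse = "")
  offs <- cumsum(c(0L, vapply(segs, nchar, integer(1))))
  gene_seg_idx <- which(seg_is_gene)

  feat_rows <- list()
  for (k in seq_along(cassettes)) {
    cs <- cassettes[[k]]
    off <- offs[gene_seg_idx[k]]
    st <- cs$strand
    for (f in cs$feats) {
      id <- if (f$type == "gene") cs$gene_id
            else sprintf("%s_%s_%d", cs$gene_id, f$type, f$start)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        seqid = "locus_sim", type = f$type,
        start = f$start + off, end = f$end + off, strand = st,
        ID = id,
        Parent = if (f$type == "gene") NA_character_ else cs$gene_id,
        gene_class = if (f$type %in% c("gene", "CDS")) cs$gene_class
                     else NA_character_,
        validated_tata = NA_character_, validated_splice = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feat_rows)

  transcripts <- Biostrings::DNAStringSet(setNames(
    vapply(cassettes, `[[`, character(1), "transcript"),
    vapply(cassettes, `[[`, character(1), "gene_id")))
  proteins <- Biostrings::AAStringSet(setNames(
    vapply(cassettes, `[[`, character(1), "peptide"),
    vapply(cassettes, `[[`, character(1), "gene_id")))
  queries <- Biostrings::AAStringSet(c(S100A11 = doms$anchor_a,
                                       S100A16 = doms$anchor_b,
                                       S100_SFTP_domain = doms$sftp))

  cds <- features[features$type == "CDS", ]
  a_cds <- cds[cds$Parent == "S100A11", ]
  b_cds <- cds[cds$Parent == "S100A16", ]
  inter_anchor <- c(max(a_cds$end) + 1L, min(b_cds$start) - 1L)

  structure(list(genome = Biostrings::DNAStringSet(c(locus_sim = genome_chr)),
                 features = features, transcripts = transcripts,
                 proteins = proteins, queries = queries,
                 inter_anchor = inter_anchor, config = config),
            class = "edc_sim")
}

#' @export
print.edc_sim <- function(x, ...) {
  genes <- x$features[x$features$type == "gene", ]
  cat("Synthetic EDC locus (", Biostrings::width(x$genome), " nt, seed ",
      x$config$seed, ")\n", sep = "")
  cat("  genes:", paste(sprintf("%s[%s,%s]", genes$ID, genes$gene_class,
                                genes$strand), collapse = " "), "\n")
  cat("  inter-anchor region: ", x$inter_anchor[1], "-", x$inter_anchor[2],
      "\n", sep = "")
  invisible(x)
}

#' Simulate tissue read sets from a synthetic locus
#'
#' Error-free reads are exact substrings of the spliced transcripts with
#' uniform start positions. Per-tissue gene read counts are multinomial with
#' the configured abundances: SFTP/SEDC genes are expressed at
#' `edc_skin_fraction` in the first tissue and `edc_other_fraction`
#' elsewhere; the anchor S100A genes act as housekeeping controls with
#' uniform abundance; the rest of each library comes from random background
#' transcripts. Whenever a gene has reads in a tissue and geometry allows,
#' at least one read spans the exon-1/exon-2 junction with at least 8 nt on
#' each side. Deterministic given `expr$seed`.
#'
#' @param truth An `edc_sim` from [simulate_locus()].
#' @param expr An [expression_config()].
#' @return List with `reads` (named list tissue -> `DNAStringSet`),
#'   `counts` (gene x tissue matrix of realized read counts) and
#'   `fractions` (the expected abundance matrix).
#' @export
simulate_reads <- function(truth, expr = expression_config()) {
  stopifnot(inherits(truth, "edc_sim"), inherits(expr, "expression_config"))
  set.seed(expr$seed)
  rl <- expr$read_len
  tx <- as.character(truth$transcripts)
  if (any(nchar(tx) < rl))
    .stopf("read_len %d exceeds the shortest transcript (%d nt)",
           rl, min(nchar(tx)))
  genes <- names(tx)
  is_edc <- grepl("^(SFTP|SEDC)", genes)
  tissues <- expr$tissues
  frac <- matrix(0, length(genes), length(tissues),
                 dimnames = list(genes, tissues))
  frac[is_edc, 1L] <- expr$edc_skin_fraction
  if (length(tissues) > 1L)
    frac[is_edc, -1L] <- expr$edc_other_fraction
  frac[!is_edc, ] <- expr$housekeeping_fraction
  if (any(colSums(frac) > 1))
    .stopf("per-tissue abundance fractions exceed 1")

  bg <- setNames(vapply(sample(500:1500, expr$n_background, replace = TRUE),
                        .rand_dna, character(1)),
                 sprintf("background%02d", seq_len(expr$n_background)))
  u1 <- setNames(rep(NA_integer_, length(genes)), genes)
  exons <- truth$features[truth$features$type == "exon", ]
  for (gid in genes) {
    ex <- exons[exons$Parent == gid, ]
    st <- ex$strand[1]
    first <- if (st == "+") which.min(ex$start) else which.max(ex$end)
    u1[gid] <- ex$end[first] - ex$start[first] + 1L
  }

  out <- list()
  counts <- matrix(0L, length(genes), length(tissues),
                   dimnames = list(genes, tissues))
  for (t in seq_along(tissues)) {
    p <- c(frac[, t], rep((1 - sum(frac[, t])) / length(bg), length(bg)))
    src <- c(tx, bg)
    n_by_src <- as.integer(rmultinom(1L, expr$reads_per_tissue, p))
    seqs <- character(0); ids <- character(0)
    for (s in seq_along(src)) {
      k <- n_by_src[s]
      if (k == 0L) next
      L <- nchar(src[s])
      starts <- sample.int(L - rl + 1L, k, replace = TRUE)
      nm <- names(src)[s]
      if (s <= length(genes)) {
        counts[nm, t] <- k
        j <- u1[nm]                      # last base of exon 1 in the transcript
        lo <- max(1L, j - rl + 9L); hi <- min(L - rl + 1L, j - 7L)
        if (!is.na(j) && hi >= lo && !any(starts >= lo & starts <= hi))
          starts[1] <- max(lo, min(hi, j - rl %/% 2L))
      }
      seqs <- c(seqs, substring(src[s], starts, starts + rl - 1L))
      ids <- c(ids, sprintf("%s_%s_r%05d", tissues[t], nm, seq_len(k)))
    }
    ord <- sample.int(length(seqs))
    out[[tissues[t]]] <- Biostrings::DNAStringSet(setNames(seqs[ord], ids[ord]))
  }
  list(reads = out, counts = counts, fractions = frac)
}
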