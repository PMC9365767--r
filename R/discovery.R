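# Locus-level discovery operations: anchor location, exon-1 annotation from
# junction-spanning reads, SEDC calling, and orthology assignment.

#' Locate the S100A anchor genes delimiting an EDC locus
#'
#' Searches the genome with two anchor protein queries (e.g. S100A11 and
#' S100A16 domains), reconstructs the anchor gene models, and returns the
#' interval strictly between their coding sequences, orientation-normalized
#' so anchor A precedes anchor B on the chromosome.
#'
#' @param genome DNA sequence.
#' @param anchor_queries Named `AAStringSet` (or named character vector) with
#'   two distinct anchor queries.
#' @param params Parameters from [edc_params()].
#' @param seqid Sequence name for reporting.
#' @return List with `interval` (c(start, end) of the inter-anchor region),
#'   `anchor_models` (two gene models, left then right), `anchor_ids`.
#' @export
locate_anchors <- function(genome, anchor_queries, params = edc_params(),
                           seqid = "genome") {
  qn <- names(anchor_queries)
  if (length(anchor_queries) < 2L || is.null(qn) || anyDuplicated(qn[1:2]))
    .stopf("locate_anchors: two anchor queries with distinct ids are required")
  g <- .as_seq_chr(genome)
  models <- list()
  for (i in 1:2) {
    q <- setNames(as.character(anchor_queries[[i]]), qn[i])
    hits <- search_genome(q, g, min_score = params$min_score,
                          min_identity = params$min_identity, seqid = seqid)
    if (nrow(hits) == 0L)
      .stopf("anchor '%s' not found in %s", qn[i], seqid)
    best <- max(hits$score)
    top <- hits[hits$score == best, ]
    if (nrow(top) > 1L && length(unique(paste(top$start, top$strand))) > 1L)
      .stopf("anchor '%s' is ambiguous: %d equally scoring best hits",
             qn[i], nrow(top))
    groups <- group_hits(hits, max_gap = params$group_max_gap)
    sel <- which(vapply(groups, function(gr)
      any(gr$start == top$start[1] & gr$strand == top$strand[1]), logical(1)))[1]
    m <- classify_s100_gene(groups[[sel]], g, params)
    m$gene_id <- qn[i]
    models[[i]] <- m
  }
  pos <- vapply(models, function(m) min(m$cds$start), numeric(1))
  ord <- order(pos)
  models <- models[ord]
  left_end <- max(models[[1]]$cds$end)
  right_start <- min(models[[2]]$cds$start)
  if (right_start - left_end < 2L)
    .stopf("anchor coding sequences overlap; no inter-anchor region")
  list(interval = c(left_end + 1L, right_start - 1L),
       anchor_models = models,
       anchor_ids = vapply(models, `[[`, character(1), "gene_id"))
}

# ---- transcription evidence -------------------------------------------------

# build a fast exact-matching index over a read set; uses a PDict when read
# widths are uniform, otherwise falls back to per-read matching
.read_index <- function(reads) {
  w <- Biostrings::width(reads)
  if (length(reads) && length(unique(w)) == 1L) {
    list(pdict = Biostrings::PDict(reads), chr = NULL, n = length(reads))
  } else {
    list(pdict = NULL, chr = as.character(reads), n = length(reads))
  }
}

# number of reads matching exactly (full read length) within dna, either strand
.count_contained_reads <- function(index, dna) {
  if (index$n == 0L) return(0L)
  targets <- c(dna, .revcomp(dna))
  if (!is.null(index$pdict)) {
    sum(vapply(targets, function(t)
      sum(Biostrings::countPDict(index$pdict, Biostrings::DNAString(t))),
      numeric(1)))
  } else {
    sum(vapply(index$chr, function(r)
      any(vapply(targets, function(t) grepl(r, t, fixed = TRUE), logical(1))),
      logical(1)))
  }
}

# ---- SEDC calling -----------------------------------------------------------

#' Call single-coding-exon EDC (SEDC) genes in a region
#'
#' Implements the SEDC discovery pipeline: scan the region for ORFs of at
#' least `min_orf_aa` residues, keep those with a biased composition
#' ([classify_composition()] not `"none"`), require a splice acceptor `AG`
#' within `acceptor_window` nt upstream of the start codon
#' ([check_splice_acceptor()]), require read evidence of transcription in at
#' least one tissue, discard candidates overlapping already-placed
#' S100A/SFTP coding sequence, and resolve overlapping candidates in
#' different frames (the higher composition ratio wins, then the longer
#' ORF).
#'
#' @param genome Full DNA sequence.
#' @param region_interval c(start, end) of the region to scan (the
#'   inter-anchor interval).
#' @param blocked_cds Data.frame of genomic CDS intervals (`start`, `end`)
#'   of already-placed genes; overlapping candidates are discarded.
#' @param reads_by_tissue Named list of `DNAStringSet` read sets.
#' @param params Parameters from [edc_params()].
#' @return List of SEDC gene models (see [classify_s100_gene()] for the
#'   shape); candidates failing only the transcription check are returned in
#'   the `untranscribed` attribute.
#' @export
call_sedc_genes <- function(genome, region_interval, blocked_cds,
                            reads_by_tissue, params = edc_params()) {
  g <- .as_seq_chr(genome)
  a <- region_interval[1]; b <- region_interval[2]
  region <- substr(g, a, b)
  orfs <- scan_orfs(region, min_aa = params$min_orf_aa)
  if (nrow(orfs) == 0L) return(structure(list(), untranscribed = list()))
  orfs$start <- orfs$start + a - 1L
  orfs$end <- orfs$end + a - 1L

  # discard overlaps with existing coding sequence (any strand)
  if (!is.null(blocked_cds) && nrow(blocked_cds)) {
    keep <- vapply(seq_len(nrow(orfs)), function(i)
      !any(orfs$start[i] <= blocked_cds$end & orfs$end[i] >= blocked_cds$start),
      logical(1))
    orfs <- orfs[keep, , drop = FALSE]
  }
  if (nrow(orfs) == 0L) return(structure(list(), untranscribed = list()))

  # composition filter
  orfs$composition_class <- vapply(orfs$peptide, classify_composition,
                                   character(1),
                                   thresholds = params$composition_thresholds)
  orfs <- orfs[orfs$composition_class != "none", , drop = FALSE]
  if (nrow(orfs) == 0L) return(structure(list(), untranscribed = list()))
  orfs$ratio <- vapply(seq_len(nrow(orfs)), function(i) {
    aa <- strsplit(orfs$peptide[i], "")[[1]]
    cl <- orfs$composition_class[i]
    (sum(aa %in% .class_residues[[cl]]) / length(aa)) /
      params$composition_thresholds[[cl]]
  }, numeric(1))

  # splice-acceptor rule (on the full genome so the window is never clipped
  # by the region boundary)
  orfs <- do.call(rbind, lapply(seq_len(nrow(orfs)), function(i)
    check_splice_acceptor(g, orfs[i, ], window = params$acceptor_window,
                          require_ppt = params$require_ppt)))
  orfs <- orfs[orfs$acceptor_found, , drop = FALSE]
  if (nrow(orfs) == 0L) return(structure(list(), untranscribed = list()))

  # overlap resolution: cluster overlapping candidates, keep the best
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  cl <- integer(nrow(orfs)); cl[1] <- 1L
  if (nrow(orfs) > 1L) {
    cur_end <- orfs$end[1]
    for (i in 2:nrow(orfs)) {
      cl[i] <- cl[i - 1L] + as.integer(orfs$start[i] > cur_end)
      cur_end <- max(cur_end, orfs$end[i])
    }
  }
  pick <- vapply(split(seq_len(nrow(orfs)), cl), function(ix) {
    o <- order(-orfs$ratio[ix], -orfs$length_aa[ix], orfs$start[ix])
    ix[o[1]]
  }, integer(1))
  orfs <- orfs[pick, , drop = FALSE]

  # transcription check (>= min_transcribed_reads perfect read match in any
  # tissue); indexes built lazily, first tissue first
  idx_env <- new.env(parent = emptyenv())
  get_index <- function(tis) {
    if (is.null(idx_env[[tis]])) idx_env[[tis]] <- .read_index(reads_by_tissue[[tis]])
    idx_env[[tis]]
  }
  models <- list(); untx <- list()
  for (i in seq_len(nrow(orfs))) {
    cds_iv <- if (orfs$strand[i] == "+") c(orfs$start[i], orfs$end[i] + 3L)
              else c(orfs$start[i] - 3L, orfs$end[i])
    cds_dna <- substr(g, cds_iv[1], cds_iv[2])
    transcribed <- FALSE
    nhit <- 0L
    for (tis in names(reads_by_tissue)) {
      nhit <- nhit + .count_contained_reads(get_index(tis), cds_dna)
      if (nhit >= params$min_transcribed_reads) { transcribed <- TRUE; break }
    }
    model <- list(gene_class = "SEDC", strand = orfs$strand[i],
                  cds = data.frame(start = cds_iv[1], end = cds_iv[2]),
                  extension_nt = NA_integer_, n_domains = 0L,
                  s100_domains = NULL, peptide = orfs$peptide[i],
                  composition_class = orfs$composition_class[i],
                  acceptor_offset = orfs$acceptor_offset[i],
                  tata_found = FALSE, tata_interval = NULL,
                  splice_donor_ok = FALSE, splice_acceptor_ok = FALSE,
                  exon1 = NULL, spanning_read_ids = character(0))
    if (transcribed) models[[length(models) + 1L]] <- model
    else untx[[length(untx) + 1L]] <- model
  }
  structure(models, untranscribed = untx)
}

# ---- exon 1 annotation ------------------------------------------------------

#' Annotate the non-coding exon 1 of a gene model from RNA-seq reads
#'
#' Detects junction-spanning reads by exact two-block matching: a read is
#' split into a prefix and a suffix such that the suffix matches the genome
#' starting at the coding exon's acceptor-adjacent start, the prefix matches
#' the genome ending at an upstream donor, and the skipped genomic interval
#' begins `GT` and ends `AG` (canonical intron). Exon 1 is the maximal
#' read-supported interval upstream of the donor; a TATA box is then looked
#' for upstream of exon 1. Reads are examined in both orientations.
#'
#' When no spanning read is found the gene keeps its class and exon 1 is
#' left unannotated with the validation flags `FALSE`.
#'
#' @param gene A gene model (from [classify_s100_gene()] or
#'   [call_sedc_genes()]).
#' @param genome DNA sequence.
#' @param reads `DNAStringSet` of reads used as evidence (typically the skin
#'   library).
#' @param params Parameters from [edc_params()].
#' @return The updated gene model with `exon1`, `exons`, `tata_found`,
#'   `tata_interval`, `splice_donor_ok`, `splice_acceptor_ok`,
#'   `spanning_read_ids` filled in.
#' @export
annotate_exon1 <- function(gene, genome, reads, params = edc_params()) {
  g0 <- .as_seq_chr(genome)
  n <- nchar(g0)
  st <- gene$strand
  g <- if (st == "+") g0 else .revcomp(g0)
  cds <- gene$cds
  if (st == "-") {
    mi <- t(vapply(seq_len(nrow(cds)), function(i)
      .mirror_interval(cds$start[i], cds$end[i], n), integer(2)))
    cds <- data.frame(start = mi[, 1], end = mi[, 2])
    cds <- cds[order(cds$start), , drop = FALSE]
  }
  cds_start <- min(cds$start)

  if (length(reads) == 0L) return(gene)
  rid <- names(reads)
  if (is.null(rid)) rid <- paste0("read", seq_along(reads))
  allreads <- c(as.character(reads),
                as.character(Biostrings::reverseComplement(reads)))
  allids <- c(rid, rid)
  seedlen <- min(12L, params$min_block)

  spanning <- NULL
  e2_used <- NA_integer_
  for (off in 0:params$acceptor_window) {
    e2 <- cds_start - off
    if (e2 < params$min_intron + 3L) break
    if (substr(g, e2 - 2L, e2 - 1L) != "AG") next
    gsuf_end <- min(n, e2 + max(nchar(allreads)) - 2L)
    seed <- substr(g, e2, e2 + seedlen - 1L)
    if (nchar(seed) < seedlen) next
    cand <- which(grepl(seed, allreads, fixed = TRUE))
    recs <- list()
    for (ci in cand) {
      r <- allreads[ci]; rl <- nchar(r)
      for (pos in as.integer(gregexpr(seed, r, fixed = TRUE)[[1]])) {
        k <- pos - 1L
        if (k < params$min_block) next
        suf <- substr(r, pos, rl)
        if (nchar(suf) < params$min_block) next
        if (suf != substr(g, e2, e2 + nchar(suf) - 1L)) next
        prefix <- substr(r, 1L, k)
        d_min <- e2 - 1L - params$max_intron
        d_max <- e2 - 1L - params$min_intron
        ws <- max(1L, d_min - k + 1L)
        wseg <- substr(g, ws, d_max)
        for (m in as.integer(gregexpr(prefix, wseg, fixed = TRUE)[[1]])) {
          if (m < 0) next
          d <- ws + m + k - 2L        # genomic end of the prefix block
          if (d < d_min || d > d_max) next
          if (substr(g, d + 1L, d + 2L) != "GT") next
          recs[[length(recs) + 1L]] <- list(id = allids[ci], d = d, k = k)
        }
      }
    }
    if (length(recs)) {
      spanning <- recs
      e2_used <- e2
      break
    }
  }

  if (is.null(spanning)) {
    gene$exons <- if (st == "+") gene$cds else gene$cds  # coding exons only
    return(gene)
  }

  ds <- vapply(spanning, `[[`, numeric(1), "d")
  tab <- table(ds)
  d_star <- as.integer(names(tab)[order(-tab, -as.integer(names(tab)))][1])
  keep <- which(ds == d_star)
  exon1_end <- d_star
  exon1_start <- min(vapply(spanning[keep], function(r)
    r$d - r$k + 1L, numeric(1)))

  # extend exon 1 upstream with reads matching the genome exactly
  for (iter in 1:20) {
    seed2 <- substr(g, exon1_start, exon1_start + seedlen - 1L)
    cand <- which(grepl(seed2, allreads, fixed = TRUE))
    improved <- FALSE
    for (ci in cand) {
      r <- allreads[ci]; rl <- nchar(r)
      for (pos in as.integer(gregexpr(seed2, r, fixed = TRUE)[[1]])) {
        rs <- exon1_start - pos + 1L
        if (rs < 1L || rs >= exon1_start) next
        if (r == substr(g, rs, rs + rl - 1L) && rs + rl - 1L <= exon1_end) {
          exon1_start <- rs; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }

  # TATA box upstream of exon 1
  up_s <- max(1L, exon1_start - params$tata_search_window)
  up <- substr(g, up_s, exon1_start - 1L)
  tata <- NULL
  if (nchar(up) >= nchar(params$tata_pattern)) {
    m <- Biostrings::matchPattern(params$tata_pattern, Biostrings::DNAString(up),
                                  max.mismatch = params$tata_max_mismatch)
    if (length(m)) {
      tata <- c(up_s + Biostrings::start(m)[1] - 1L,
                up_s + Biostrings::end(m)[1] - 1L)
    }
  }

  exon1 <- c(exon1_start, exon1_end)
  exon_rows <- rbind(data.frame(start = exon1[1], end = exon1[2]),
                     data.frame(start = c(e2_used, if (nrow(cds) > 1L) cds$start[-1]),
                                end = cds$end))
  back <- function(iv) {
    if (st == "+") iv else .mirror_interval(iv[1], iv[2], n)
  }
  gene$exon1 <- back(exon1)
  ex <- t(apply(exon_rows, 1L, function(r) back(c(r[1], r[2]))))
  ex <- data.frame(start = ex[, 1], end = ex[, 2])
  gene$exons <- ex[order(ex$start), , drop = FALSE]
  gene$tata_found <- !is.null(tata)
  gene$tata_interval <- if (!is.null(tata)) back(tata) else NULL
  gene$splice_donor_ok <- TRUE
  gene$splice_acceptor_ok <- TRUE
  gene$spanning_read_ids <- unique(vapply(spanning[keep], `[[`, character(1), "id"))
  gene
}

# ---- orthology --------------------------------------------------------------

#' Reciprocal-best-hit orthology with synteny
#'
#' Scores all pairs of peptides between two loci with [local_align()],
#' reports a pair when each member is the other's best hit, and checks
#' shared local synteny: among the reciprocal best hits, the
#' highest-scoring chain of pairs with consistent positional order is kept
#' as the ortholog set, and crossing pairs are reported separately as
#' synteny conflicts. Genes without a reciprocal partner are listed as
#' lineage-specific.
#'
#' @param peptides_a,peptides_b Named character vectors (or `AAStringSet`s)
#'   of peptides, in positional order within each locus.
#' @return A list with `orthologs` (data.frame `id_a`, `id_b`, `pos_a`,
#'   `pos_b`, `score`), `synteny_conflicts` (same shape), and
#'   `lineage_specific_a` / `lineage_specific_b` (character vectors).
#' @export
reciprocal_best_hits <- function(peptides_a, peptides_b) {
  pa <- setNames(as.character(peptides_a), names(peptides_a))
  pb <- setNames(as.character(peptides_b), names(peptides_b))
  if (!length(pa) || !length(pb)) .stopf("reciprocal_best_hits: empty gene set")
  sc <- matrix(0, length(pa), length(pb), dimnames = list(names(pa), names(pb)))
  for (i in seq_along(pa)) for (j in seq_along(pb))
    sc[i, j] <- local_align(pa[[i]], pb[[j]])$score
  best_b <- apply(sc, 1L, which.max)   # best partner in B for each a
  best_a <- apply(sc, 2L, which.max)
  pairs <- do.call(rbind, lapply(seq_along(pa), function(i) {
    j <- best_b[i]
    if (best_a[j] == i && sc[i, j] > 0)
      data.frame(id_a = names(pa)[i], id_b = names(pb)[j],
                 pos_a = i, pos_b = j, score = sc[i, j],
                 stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) pairs <- data.frame(id_a = character(), id_b = character(),
                                          pos_a = integer(), pos_b = integer(),
                                          score = numeric())
  # best non-crossing chain (weighted longest increasing subsequence on pos_b)
  keep <- rep(TRUE, nrow(pairs))
  if (nrow(pairs) > 1L) {
    ord <- order(pairs$pos_a)
    p <- pairs[ord, ]
    npair <- nrow(p)
    wt <- p$score; bestw <- wt; prev <- rep(NA_integer_, npair)
    for (i in seq_len(npair)) {
      for (j in seq_len(i - 1L)) {
        if (p$pos_b[j] < p$pos_b[i] && bestw[j] + wt[i] > bestw[i]) {
          bestw[i] <- bestw[j] + wt[i]; prev[i] <- j
        }
      }
    }
    chain <- integer(0); i <- which.max(bestw)
    while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
    keep <- logical(npair); keep[chain] <- TRUE
    keep <- keep[order(ord)]
  }
  orth <- pairs[keep, , drop = FALSE]
  conf <- pairs[!keep, , drop = FALSE]
  list(orthologs = orth, synteny_conflicts = conf,
       lineage_specific_a = setdiff(names(pa), pairs$id_a),
       lineage_specific_b = setdiff(names(pb), pairs$id_b))
}
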