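# The core inference: classify S100-domain genes as S100A vs SFTP by the
# 400-nt coding-extension rule, discover SEDC candidates by
# composition-biased ORF scanning with the 50-nt splice-acceptor rule,
# annotate the non-coding exon 1 from junction-spanning reads, and assign
# orthology by reciprocal best hits with synteny.

#' Default analysis parameters
#'
#' All thresholds of the discovery procedure in one place. The biological
#' rules are: an S100-domain gene is an SFTP when its coding sequence
#' extends more than `extension_threshold` (400) nucleotides past the end of
#' the S100 domain (unless it encodes two consecutive S100 domains, which
#' makes it an S100A gene); SEDC candidates are open reading frames of at
#' least `min_orf_aa` (50) residues with a biased amino-acid composition, a
#' splice acceptor `AG` within `acceptor_window` (50) nucleotides upstream
#' of the start codon, and read evidence of transcription.
#'
#' @param min_score,min_identity Hit acceptance for the translated search.
#' @param min_domain_coverage Fraction of the S100-domain query that a hit
#'   group must cover (union of aligned query spans) to be classified as a
#'   gene; short chance alignments never cover most of a domain.
#' @param group_max_gap Maximum nucleotide gap between hits grouped into one
#'   candidate S100-domain gene.
#' @param extension_threshold SFTP coding-extension rule, in nucleotides.
#' @param splice_stop_window If translation runs into a stop within this many
#'   nucleotides of the domain end, a spliced (GT..AG) extension is
#'   attempted.
#' @param min_orf_aa Minimum ORF product length in residues.
#' @param acceptor_window Splice-acceptor search window upstream of the start
#'   codon, in nucleotides.
#' @param require_ppt If `TRUE`, a splice acceptor additionally requires at
#'   least 8 pyrimidines in the 12 nt preceding the `AG`.
#' @param composition_thresholds Named fractions for the four composition
#'   classes.
#' @param tata_pattern,tata_max_mismatch,tata_search_window TATA-box scan.
#' @param min_intron,max_intron Intron length bounds for spliced extensions
#'   and junction-read matching.
#' @param min_transcribed_reads Reads required to accept a candidate as
#'   transcribed.
#' @param min_block Minimum exact block length (nt) on each side of a
#'   junction for a read to count as exon-spanning.
#' @return A named list of parameters.
#' @export
edc_params <- function(min_score = 50, min_identity = 0.35,
                       min_domain_coverage = 0.6,
                       group_max_gap = 1000L,
                       extension_threshold = 400L,
                       splice_stop_window = 50L,
                       min_orf_aa = 50L,
                       acceptor_window = 50L,
                       require_ppt = FALSE,
                       composition_thresholds = c(loricrin_like = 0.30,
                                                  involucrin_like = 0.20,
                                                  sprr_like = 0.15,
                                                  edcrp_like = 0.10),
                       tata_pattern = "TATAAA",
                       tata_max_mismatch = 1L,
                       tata_search_window = 100L,
                       min_intron = 20L, max_intron = 2000L,
                       min_transcribed_reads = 1L,
                       min_block = 8L) {
  as.list(environment())
}

# residues whose content defines each composition class
.class_residues <- list(loricrin_like = c("G", "S"),
                        involucrin_like = "Q",
                        sprr_like = "P",
                        edcrp_like = "C")

#' Classify a peptide by amino-acid composition bias
#'
#' A class is assigned when the relevant content reaches its threshold
#' (defaults: G+S >= 0.30 loricrin-like, Q >= 0.20 involucrin-like,
#' P >= 0.15 SPRR-like, C >= 0.10 EDCRP-like). When several thresholds are
#' met the class with the largest observed-content / threshold ratio wins.
#'
#' @param peptide Protein sequence.
#' @param thresholds Named numeric vector of class thresholds.
#' @return The class name, or `"none"`.
#' @export
classify_composition <- function(peptide,
                                 thresholds = edc_params()$composition_thresholds) {
  p <- .as_seq_chr(peptide)
  if (nchar(p) == 0L) .stopf("classify_composition: empty peptide")
  aa <- strsplit(p, "")[[1]]
  n <- length(aa)
  ratios <- vapply(names(.class_residues), function(cl) {
    content <- sum(aa %in% .class_residues[[cl]]) / n
    content / thresholds[[cl]]
  }, numeric(1))
  ok <- ratios >= 1
  if (!any(ok)) return("none")
  names(ratios)[ok][which.max(ratios[ok])]
}

# internal single-strand ORF scan of a character sequence (plus strand of
# the provided orientation); returns peptide-space coordinates
.scan_orfs_one <- function(g, min_aa) {
  n <- nchar(g)
  rows <- list()
  for (frame in 0:2) {
    pep <- .translate_chr(substr(g, frame + 1L, n))
    if (nchar(pep) == 0L) next
    aa <- strsplit(pep, "")[[1]]
    stops <- which(aa == "*")
    seg_start <- 1L
    for (s in stops) {
      if (s > seg_start) {
        seg <- aa[seg_start:(s - 1L)]
        m <- which(seg == "M")
        if (length(m)) {
          i <- seg_start + m[1] - 1L          # 5'-most ATG of the segment
          len <- s - i
          if (len >= min_aa) {
            rows[[length(rows) + 1L]] <- list(
              frame = frame, pep_start = i, pep_end = s - 1L,
              peptide = paste(aa[i:(s - 1L)], collapse = ""))
          }
        }
      }
      seg_start <- s + 1L
    }
  }
  rows
}

#' Scan a DNA region for open reading frames
#'
#' All six frames are scanned. An ORF runs from an `ATG` to the next
#' in-frame stop codon (which must exist); among nested ATGs sharing a stop,
#' the 5'-most (longest product) is reported. Only products of at least
#' `min_aa` residues are kept.
#'
#' @param region DNA sequence.
#' @param min_aa Minimum product length in residues (default 50).
#' @return A data.frame of candidates: `start`, `end` (genomic interval of
#'   the codons from start codon through the last sense codon, stop
#'   excluded), `strand`, `frame`, `length_aa`, `peptide`.
#' @export
scan_orfs <- function(region, min_aa = 50L) {
  g <- .as_seq_chr(region)
  n <- nchar(g)
  out <- list()
  for (st in c("+", "-")) {
    s <- if (st == "+") g else .revcomp(g)
    for (r in .scan_orfs_one(s, min_aa)) {
      gi <- .pep_span_to_genome(r$pep_start, r$pep_end, r$frame, st, n)
      out[[length(out) + 1L]] <- data.frame(
        start = gi[1], end = gi[2], strand = st, frame = r$frame,
        length_aa = nchar(r$peptide), peptide = r$peptide,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), length_aa = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Check for a splice acceptor upstream of an ORF
#'
#' An ORF is SEDC-like only if an `AG` dinucleotide on the coding strand
#' ends within `window` nucleotides upstream of the start codon (offset 0 =
#' immediately adjacent; offsets up to and including `window` are accepted).
#' Optionally a polypyrimidine tract (>= 8 pyrimidines in the 12 nt
#' preceding the `AG`) is also required.
#'
#' @param region DNA sequence containing the ORF (same coordinates as the
#'   ORF row).
#' @param orf One row of the [scan_orfs()] data.frame (or an equivalent
#'   list with `start`, `end`, `strand`).
#' @param window Search window in nucleotides (default 50).
#' @param require_ppt Require the polypyrimidine tract (default `FALSE`).
#' @return The ORF as a one-row data.frame with `acceptor_found` and
#'   `acceptor_offset` (NA when not found) added.
#' @export
check_splice_acceptor <- function(region, orf, window = 50L,
                                  require_ppt = FALSE) {
  g <- .as_seq_chr(region)
  n <- nchar(g)
  orf <- as.data.frame(orf, stringsAsFactors = FALSE)
  if (orf$strand == "-") {
    mi <- .mirror_interval(orf$start, orf$end, n)
    g2 <- .revcomp(g); cstart <- mi[1]
  } else {
    g2 <- g; cstart <- orf$start
  }
  found <- FALSE; offset <- NA_integer_
  for (off in 0:window) {
    e <- cstart - 1L - off          # AG would end at position e
    if (e < 2L) break
    if (substr(g2, e - 1L, e) == "AG") {
      if (require_ppt) {
        up <- substr(g2, max(1L, e - 13L), e - 2L)
        if (nchar(up) < 12L ||
            sum(strsplit(up, "")[[1]] %in% c("C", "T")) < 8L) next
      }
      found <- TRUE; offset <- off
      break
    }
  }
  orf$acceptor_found <- found
  orf$acceptor_offset <- offset
  orf
}

# read codons of g starting at `from` (frame 0 of that position) until the
# first stop; returns list(ext_nt = sense nucleotides before the stop,
# stop_start = position of the stop codon or NA)
.extend_to_stop <- function(g, from, limit = 9000L) {
  n <- nchar(g)
  if (from > n) return(list(ext_nt = 0L, stop_start = NA_integer_))
  chunk_end <- min(n, from + limit - 1L)
  pep <- .translate_chr(substr(g, from, chunk_end))
  stop_at <- regexpr("*", pep, fixed = TRUE)[1]
  if (stop_at < 0) {
    list(ext_nt = (nchar(pep)) * 3L, stop_start = NA_integer_)
  } else {
    list(ext_nt = (stop_at - 1L) * 3L, stop_start = from + (stop_at - 1L) * 3L)
  }
}

# all positions i where substr(g, i, i+1) == pat within [from, to]
.dinuc_positions <- function(g, pat, from, to) {
  if (to < from) return(integer(0))
  seg <- substr(g, from, min(to + 1L, nchar(g)))
  m <- gregexpr(pat, seg, fixed = TRUE)[[1]]
  if (m[1] < 0) return(integer(0))
  # overlapping occurrences are impossible for GT/AG (distinct letters)
  pos <- as.integer(m) + from - 1L
  pos[pos <= to]
}

#' Classify a candidate S100-domain gene as S100A or SFTP
#'
#' Reconstructs the coding sequence around a group of S100-domain hits and
#' applies the coding-extension rule: the reading frame is extended 3' from
#' the end of the S100-domain region to the first stop codon; if a stop
#' occurs within `splice_stop_window` nucleotides, a spliced extension
#' across one canonical GT..AG intron is attempted (the donor/acceptor pair
#' maximizing the extension wins). Genes whose coding sequence extends more
#' than `extension_threshold` (400) nucleotides past the domain are SFTPs;
#' genes with two consecutive S100 domains, or a shorter extension, are
#' S100A genes. The CDS 5' end is the nearest in-frame `ATG` upstream of the
#' domain with no intervening stop.
#'
#' @param hit_group Data.frame of hits for one candidate gene (one element
#'   of [group_hits()]).
#' @param genome DNA sequence the hits refer to.
#' @param params Parameter list from [edc_params()].
#' @return A gene model: list with `gene_class` (`"S100A"`/`"SFTP"`),
#'   `strand`, `cds` (data.frame of genomic CDS segments including the stop
#'   codon), `extension_nt`, `n_domains`, `s100_domains` (genomic
#'   intervals), `peptide`.
#' @export
classify_s100_gene <- function(hit_group, genome, params = edc_params()) {
  if (length(unique(hit_group$strand)) != 1L)
    .stopf("classify_s100_gene: hit group with inconsistent strands")
  st <- hit_group$strand[1]
  g0 <- .as_seq_chr(genome)
  n <- nchar(g0)
  g <- if (st == "+") g0 else .revcomp(g0)
  # hits in coding-strand coordinates
  h <- hit_group
  if (st == "-") {
    mi <- t(vapply(seq_len(nrow(h)), function(i)
      .mirror_interval(h$start[i], h$end[i], n), integer(2)))
    h$start <- mi[, 1]; h$end <- mi[, 2]
  }
  h <- h[order(h$start), ]
  # assemble domains: a new domain starts when the query span restarts
  dom_id <- integer(nrow(h)); dom_id[1] <- 1L
  if (nrow(h) > 1L) {
    for (i in 2:nrow(h)) {
      restart <- h$qstart[i] <= h$qend[i - 1L] - 10L
      dom_id[i] <- dom_id[i - 1L] + as.integer(restart)
    }
  }
  n_domains <- max(dom_id)
  dom_end <- max(h$end)
  dom_start <- min(h$start)

  # 3' extension, with at most one spliced GT..AG intron
  direct <- .extend_to_stop(g, dom_end + 1L)
  ext <- direct$ext_nt
  stop_start <- direct$stop_start
  intron <- NULL
  if (!is.na(direct$stop_start) && direct$ext_nt <= params$splice_stop_window) {
    donors <- .dinuc_positions(g, "GT", dom_end + 1L, direct$stop_start + 2L)
    best <- NULL
    for (p in donors) {
      # exon part between domain end and donor must keep frame bookkeeping:
      # splice joins g[dom_end+1 .. p-1] to g[q+1 ..]
      acc <- .dinuc_positions(g, "AG", p + params$min_intron - 1L,
                              min(nchar(g) - 1L, p + params$max_intron - 2L))
      for (q in acc + 1L) {          # q = last intron base (the G of AG)
        e1 <- if (p - 1L >= dom_end + 1L) substr(g, dom_end + 1L, p - 1L) else ""
        rest_from <- q + 1L
        phase <- nchar(e1) %% 3L
        # translate the spliced continuation
        tail_seq <- substr(g, rest_from, min(nchar(g), rest_from + 9000L))
        pep <- .translate_chr(paste0(e1, tail_seq))
        stop_at <- regexpr("*", pep, fixed = TRUE)[1]
        tot <- if (stop_at < 0) nchar(pep) * 3L else (stop_at - 1L) * 3L
        if (tot <= nchar(e1)) next   # stop before or at the junction
        cand <- list(ext = tot, donor = p, acceptor_end = q,
                     exon1_extra = nchar(e1))
        if (is.null(best) || cand$ext > best$ext) best <- cand
      }
    }
    if (!is.null(best) && best$ext > ext) {
      ext <- best$ext
      intron <- c(best$donor, best$acceptor_end)
      # stop codon position after splice
      tail_nt <- best$ext - best$exon1_extra
      stop_start <- best$acceptor_end + 1L + tail_nt
    }
  }

  # 5' extension: nearest in-frame ATG upstream of the domain, no stop between
  cds_start <- dom_start
  j <- dom_start - 3L
  while (j >= 1L) {
    codon <- substr(g, j, j + 2L)
    if (codon %in% c("TAA", "TAG", "TGA")) break
    if (codon == "ATG") { cds_start <- j; break }
    j <- j - 3L
  }

  cds_end <- if (!is.na(stop_start)) stop_start + 2L else nchar(g)
  if (is.null(intron)) {
    segs <- data.frame(start = cds_start, end = cds_end)
  } else {
    segs <- data.frame(start = c(cds_start, intron[2] + 1L),
                       end = c(intron[1] - 1L, cds_end))
  }
  coding <- paste(vapply(seq_len(nrow(segs)), function(i)
    substr(g, segs$start[i], segs$end[i]), character(1)), collapse = "")
  pep <- sub("\\*$", "", .translate_chr(coding))

  gene_class <- if (n_domains >= 2L) "S100A"
                else if (ext > params$extension_threshold) "SFTP" else "S100A"

  doms <- do.call(rbind, lapply(split(h, dom_id), function(d)
    data.frame(start = min(d$start), end = max(d$end))))
  # back to genomic coordinates
  to_genomic <- function(df) {
    if (st == "+") return(df)
    mi <- t(vapply(seq_len(nrow(df)), function(i)
      .mirror_interval(df$start[i], df$end[i], n), integer(2)))
    out <- data.frame(start = mi[, 1], end = mi[, 2])
    out[order(out$start), , drop = FALSE]
  }
  list(gene_class = gene_class, strand = st,
       cds = to_genomic(segs), extension_nt = ext,
       n_domains = n_domains, s100_domains = to_genomic(doms),
       peptide = pep, composition_class = NA_character_,
       acceptor_offset = NA_integer_,
       tata_found = FALSE, tata_interval = NULL,
       splice_donor_ok = FALSE, splice_acceptor_ok = FALSE,
       exon1 = NULL, spanning_read_ids = character(0))
}
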