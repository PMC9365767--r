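# Protein-to-genome homology search: six-frame translation plus
# Smith-Waterman local alignment with BLOSUM62 and affine gaps (open 11,
# extend 1, the tBLASTn defaults). No low-complexity masking and no e-value
# statistics: at single-locus scale a raw score threshold replaces them.

#' Translate a DNA sequence in all six reading frames
#'
#' Uses the standard genetic code; stop codons are rendered `*` and any codon
#' containing `N` translates to `X` (an assembly gap never terminates an
#' open reading frame).
#'
#' @param dna A DNA sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @return A data.frame with one row per frame: `strand` (`+`/`-`), `frame`
#'   (0, 1, 2: offset of the first codon on the reading strand), and
#'   `peptide`.
#' @export
six_frame_translate <- function(dna) {
  g <- .as_seq_chr(dna)
  if (grepl("[^ACGTN]", g)) .stopf("six_frame_translate: input is not DNA")
  rc <- .revcomp(g)
  out <- expand.grid(strand = c("+", "-"), frame = 0:2,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$strand == "-", out$frame), ]
  out$peptide <- vapply(seq_len(nrow(out)), function(k) {
    s <- if (out$strand[k] == "+") g else rc
    .translate_chr(substr(s, out$frame[k] + 1L, nchar(s)))
  }, character(1))
  rownames(out) <- NULL
  out
}

.load_submat <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman alignment under an affine gap model where a gap of length
#' L costs `gap_open + gap_extend * L`. When no positive-scoring local path
#' exists the score is 0 and the spans are empty.
#'
#' @param query,target Protein sequences (character or `AAString`); `*` is a
#'   legal residue (scored by the matrix) so frame translations can be
#'   aligned directly.
#' @param matrix_name Substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1).
#' @return A list with `score`, `query_start`, `query_end`, `target_start`,
#'   `target_end`, `identity` (fraction of identical aligned positions).
#' @export
local_align <- function(query, target, matrix_name = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  q <- .as_seq_chr(query); t <- .as_seq_chr(target)
  if (nchar(q) == 0L || nchar(t) == 0L) .stopf("local_align: empty sequence")
  mat <- .load_submat(matrix_name)
  al <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(score = 0, query_start = 0L, query_end = -1L,
                target_start = 0L, target_end = -1L, identity = NA_real_))
  }
  pat <- Biostrings::pattern(al); sub <- Biostrings::subject(al)
  alen <- nchar(as.character(pat))
  list(score = sc,
       query_start = Biostrings::start(pat), query_end = Biostrings::end(pat),
       target_start = Biostrings::start(sub), target_end = Biostrings::end(sub),
       identity = Biostrings::nmatch(al) / alen)
}

.empty_hits <- function() {
  data.frame(query_id = character(), seqid = character(),
             start = integer(), end = integer(), strand = character(),
             frame = integer(), score = numeric(), identity = numeric(),
             qstart = integer(), qend = integer(), stringsAsFactors = FALSE)
}

#' Search a genome with a protein query in all six frames
#'
#' The stand-in for a tBLASTn search at locus scale: every frame translation
#' is aligned to the query by iterated Smith-Waterman (each optimal hit is
#' masked and the frame re-searched, so multiple copies of a domain are all
#' found). Low-complexity filtering is never applied.
#'
#' @param query A named protein sequence (character or `AAStringSet` of
#'   length 1).
#' @param genome DNA sequence to search.
#' @param min_score Minimum alignment score to report (default 50).
#' @param min_identity Minimum identity fraction (default 0.35).
#' @param seqid Name used for the genomic sequence in the output.
#' @param max_hits_per_frame Safety cap on iterated masking.
#' @return A data.frame of hits sorted by genomic start: `query_id`,
#'   `seqid`, `start`, `end`, `strand`, `frame`, `score`, `identity`,
#'   `qstart`, `qend`. Genomic intervals cover whole codons.
#' @export
search_genome <- function(query, genome, min_score = 50, min_identity = 0.35,
                          seqid = "genome", max_hits_per_frame = 16L) {
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  q <- .as_seq_chr(query)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", q)) .stopf("search_genome: query is not protein")
  g <- .as_seq_chr(genome)
  n <- nchar(g)
  frames <- six_frame_translate(g)
  mat <- .load_submat("BLOSUM62")
  rows <- list()
  for (k in seq_len(nrow(frames))) {
    pep <- frames$peptide[k]
    if (nchar(pep) < 2L) next
    for (iter in seq_len(max_hits_per_frame)) {
      al <- Biostrings::pairwiseAlignment(q, pep, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(al)
      if (sc < min_score) break
      sub <- Biostrings::subject(al); pat <- Biostrings::pattern(al)
      ts <- Biostrings::start(sub); te <- Biostrings::end(sub)
      gi <- .pep_span_to_genome(ts, te, frames$frame[k], frames$strand[k], n)
      ident <- Biostrings::nmatch(al) / nchar(as.character(pat))
      if (ident >= min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, seqid = seqid, start = gi[1], end = gi[2],
          strand = frames$strand[k], frame = frames$frame[k],
          score = sc, identity = ident,
          qstart = Biostrings::start(pat), qend = Biostrings::end(pat),
          stringsAsFactors = FALSE)
      }
      # mask the aligned span and search the frame again
      substr(pep, ts, te) <- paste(rep("*", te - ts + 1L), collapse = "")
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  merge_hits(hits)
}

#' Merge overlapping hits within a frame
#'
#' Overlapping hits on the same strand and frame are reduced to the
#' highest-scoring one. Idempotent.
#'
#' @param hits Hit data.frame as returned by [search_genome()].
#' @return The reduced data.frame, sorted by genomic start.
#' @export
merge_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$strand, hits$frame, hits$start, -hits$score), ]
  keep <- logical(nrow(hits))
  i <- 1L
  while (i <= nrow(hits)) {
    j <- i; cur_end <- hits$end[i]; best <- i
    while (j + 1L <= nrow(hits) &&
           hits$strand[j + 1L] == hits$strand[i] &&
           hits$frame[j + 1L] == hits$frame[i] &&
           hits$start[j + 1L] <= cur_end) {
      j <- j + 1L
      cur_end <- max(cur_end, hits$end[j])
      if (hits$score[j] > hits$score[best]) best <- j
    }
    keep[best] <- TRUE
    i <- j + 1L
  }
  out <- hits[keep, ]
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Group hits into candidate gene regions
#'
#' Hits on a consistent strand separated by at most `max_gap` nucleotides are
#' grouped into one candidate gene, so that a domain split across the coding
#' exons of a two-coding-exon gene (hits in different frames) is treated as
#' one gene, while neighboring paralogs separated by intergenic sequence are
#' not.
#'
#' @param hits Hit data.frame.
#' @param max_gap Maximum intra-gene gap in nucleotides (default 1000).
#' @return A list of hit data.frames, one per candidate gene, ordered by
#'   genomic start.
#' @export
group_hits <- function(hits, max_gap = 1000L) {
  if (nrow(hits) == 0L) return(list())
  out <- list()
  for (st in unique(hits$strand)) {
    h <- hits[hits$strand == st, ]
    h <- h[order(h$start), ]
    # new group whenever the gap from the previous group's end exceeds max_gap
    grp <- integer(nrow(h)); gid <- 1L; grp[1] <- 1L
    if (nrow(h) > 1L) {
      prev_end <- h$end[1]
      for (i in 2:nrow(h)) {
        if (h$start[i] - prev_end - 1L > max_gap) gid <- gid + 1L
        grp[i] <- gid
        prev_end <- max(prev_end, h$end[i])
      }
    }
    out <- c(out, split(h, grp))
  }
  out <- out[order(vapply(out, function(x) min(x$start), numeric(1)))]
  unname(out)
}
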