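# Semiquantitative expression analysis: count, per tissue, the reads whose
# six-frame translation contains a 100%-identity match to a gene-specific
# peptide query. No low-complexity masking and no normalization: raw counts
# are reported next to library sizes, and comparisons are meaningful within
# one gene across tissues, not between genes.

#' Build a peptide query from a protein
#'
#' Extracts the sub-span `start_aa..end_aa` (1-based, inclusive) of a
#' protein, the way tissue-expression queries are constructed (e.g. residues
#' 1-50 of a SEDC protein).
#'
#' @param protein A protein sequence (character or `AAStringSet` of length
#'   1); its name becomes the query's `gene_id`.
#' @param start_aa,end_aa 1-based inclusive residue positions.
#' @return A list of class `peptide_query`: `gene_id`, `residues`,
#'   `source_positions`.
#' @export
make_query <- function(protein, start_aa, end_aa) {
  gid <- if (!is.null(names(protein))) names(protein)[1] else "query"
  p <- .as_seq_chr(protein)
  n <- nchar(p)
  if (start_aa < 1L || end_aa > n || start_aa > end_aa)
    .stopf("make_query: span %d-%d out of range for a %d-residue protein",
           start_aa, end_aa, n)
  res <- unname(substr(p, start_aa, end_aa))
  if (grepl("*", res, fixed = TRUE))
    .stopf("make_query: query span contains a stop")
  structure(list(gene_id = gid, residues = res,
                 source_positions = c(as.integer(start_aa),
                                      as.integer(end_aa))),
            class = "peptide_query")
}

#' Precompute the six frame translations of a read set
#'
#' The translations can be reused across queries; [count_perfect_hits()]
#' accepts the result in place of the raw reads.
#'
#' @param reads A `DNAStringSet`.
#' @return An object of class `read_frames`.
#' @export
translate_read_frames <- function(reads) {
  n <- length(reads)
  w <- Biostrings::width(reads)
  peps <- vector("list", 6L)
  sets <- list(reads, Biostrings::reverseComplement(reads))
  # the fuzzy-codon machinery is costly to set up; only engage it when the
  # reads actually contain ambiguity codes
  fuzzy <- n > 0L &&
    sum(Biostrings::alphabetFrequency(reads, collapse = TRUE)[c("A", "C", "G", "T")]) <
      sum(as.numeric(w))
  k <- 0L
  for (s in 1:2) for (f in 0:2) {
    k <- k + 1L
    len <- pmax(0L, ((w - f) %/% 3L) * 3L)
    keep <- len > 0L
    out <- character(n)
    if (any(keep)) {
      sub <- Biostrings::subseq(sets[[s]][keep], start = f + 1L,
                                width = len[keep])
      out[keep] <- if (fuzzy)
        as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
      else as.character(Biostrings::translate(sub))
    }
    peps[[k]] <- unname(out)
  }
  structure(list(peptides = peps, n = n,
                 total_nt = sum(as.numeric(w))), class = "read_frames")
}

# all substrings of q of length len
.all_substrings <- function(q, len) {
  m <- nchar(q)
  if (len > m) return(character(0))
  substring(q, 1:(m - len + 1L), len:m)
}

#' Count reads with a perfect translated match to a peptide query
#'
#' A read counts (once) if any of its six frame translations matches the
#' query at 100% identity over the full overlap between the two, with the
#' overlap at least `min_overlap_aa` residues: the query contained in the
#' translation, the translation contained in the query (reads shorter than
#' the query), or a staggered overlap at either read edge.
#'
#' @param query A `peptide_query` from [make_query()], or a (named) protein
#'   string.
#' @param reads A `DNAStringSet` or a precomputed
#'   [translate_read_frames()] object.
#' @param min_overlap_aa Minimum overlap, residues (default 16).
#' @param mode `"reads"` (count matching reads, default) or `"hsps"` (count
#'   every matching window).
#' @return An integer count.
#' @export
count_perfect_hits <- function(query, reads, min_overlap_aa = 16L,
                               mode = c("reads", "hsps")) {
  mode <- match.arg(mode)
  q <- if (inherits(query, "peptide_query")) query$residues else .as_seq_chr(query)
  m <- nchar(q)
  rf <- if (inherits(reads, "read_frames")) reads else translate_read_frames(reads)
  n <- rf$n
  if (n == 0L) return(0L)
  hit <- logical(n)
  nhsp <- integer(n)
  for (p in rf$peptides) {
    w <- nchar(p)
    # query fully inside the translation
    full <- grepl(q, p, fixed = TRUE)
    # translation fully inside the query
    contained <- logical(n)
    for (len in unique(w[w < m & w >= min_overlap_aa])) {
      subs <- .all_substrings(q, len)
      contained <- contained | (w == len & p %in% subs)
    }
    # staggered overlaps at the read edges
    stag <- logical(n)
    stag_n <- integer(n)
    for (L in seq.int(min_overlap_aa, max(1L, min(m, max(w)) - 1L))) {
      if (L > m - 1L) break
      ok_w <- w > L
      left <- ok_w & endsWith(p, substr(q, 1L, L))
      right <- ok_w & startsWith(p, substr(q, m - L + 1L, m))
      stag <- stag | left | right
      stag_n <- stag_n + left + right
    }
    hit <- hit | full | contained | stag
    if (mode == "hsps") {
      nf <- integer(n)
      idx <- which(full)
      if (length(idx))
        nf[idx] <- vapply(gregexpr(q, p[idx], fixed = TRUE), function(g)
          sum(g > 0), integer(1))
      nc <- integer(n)
      idx <- which(contained)
      if (length(idx))
        nc[idx] <- vapply(idx, function(i)
          sum(.all_substrings(q, w[i]) == p[i]), integer(1))
      nhsp <- nhsp + nf + nc + stag_n
    }
  }
  if (mode == "reads") sum(hit) else sum(nhsp)
}

#' Tabulate expression of peptide queries across tissue read sets
#'
#' One record per query x tissue, with the library size columns needed to
#' interpret the counts (within-gene, across-tissue comparisons only).
#'
#' @param queries A list of `peptide_query` objects, or a named
#'   `AAStringSet`/character vector of query peptides.
#' @param tissue_read_sets Named list of `DNAStringSet` read sets.
#' @param min_overlap_aa,mode Passed to [count_perfect_hits()].
#' @return A data.frame: `gene_id`, `tissue`, `perfect_hit_reads`,
#'   `library_reads`, `library_bases`.
#' @export
expression_table <- function(queries, tissue_read_sets, min_overlap_aa = 16L,
                             mode = "reads") {
  if (!length(tissue_read_sets) || is.null(names(tissue_read_sets)))
    .stopf("expression_table: at least one named tissue read set is required")
  if (inherits(queries, "peptide_query")) queries <- list(queries)
  if (!is.list(queries)) {          # XStringSet or character vector
    qs <- as.character(queries)
    if (is.null(names(qs))) names(qs) <- sprintf("query%d", seq_along(qs))
    queries <- lapply(seq_along(qs), function(i)
      make_query(setNames(qs[[i]], names(qs)[i]), 1L, nchar(qs[[i]])))
  }
  rows <- list()
  for (tis in names(tissue_read_sets)) {
    reads <- tissue_read_sets[[tis]]
    if (length(reads) == 0L)
      warning(sprintf("tissue '%s' has an empty read set", tis))
    rf <- translate_read_frames(reads)
    for (q in queries) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = q$gene_id, tissue = tis,
        perfect_hit_reads = count_perfect_hits(q, rf,
                                               min_overlap_aa = min_overlap_aa,
                                               mode = mode),
        library_reads = length(reads),
        library_bases = rf$total_nt,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
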