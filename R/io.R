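# Reading and writing the standard formats the pipeline touches: FASTA,
# FASTQ and GFF3. Parsing is delegated to Biostrings/rtracklayer; this file
# only fixes the conventions used by the rest of the package.
#
# Features travel as a plain data.frame with columns seqid, type, start,
# end, strand, ID, Parent, gene_class, validated_tata, validated_splice
# (the last five NA where not applicable).

.feature_cols <- c("seqid", "type", "start", "end", "strand",
                   "ID", "Parent", "gene_class", "validated_tata",
                   "validated_splice")

# GFF3 phase of CDS segments: 0 for the first segment in translation
# order, then carried over by segment length
.cds_phase <- function(features) {
  phase <- rep(NA_integer_, nrow(features))
  is_cds <- features$type == "CDS"
  for (gid in unique(features$Parent[is_cds])) {
    ix <- which(is_cds & features$Parent == gid)
    ix <- ix[order(features$start[ix],
                   decreasing = features$strand[ix[1]] == "-")]
    ph <- 0L
    for (i in ix) {
      phase[i] <- ph
      len <- features$end[i] - features$start[i] + 1L
      ph <- (3L - ((len - ph) %% 3L)) %% 3L
    }
  }
  phase
}

.empty_features <- function() {
  data.frame(seqid = character(), type = character(),
             start = integer(), end = integer(), strand = character(),
             ID = character(), Parent = character(),
             gene_class = character(), validated_tata = character(),
             validated_splice = character(), stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file
#'
#' Records are returned in file order with residues upper-cased. The alphabet
#' is auto-detected: sequences consisting only of `A`, `C`, `G`, `T`, `N`
#' come back as a [Biostrings::DNAStringSet], anything else as an
#' [Biostrings::AAStringSet].
#'
#' @param path Path to a FASTA file.
#' @param type `"auto"` (default), `"DNA"` or `"AA"` to force the alphabet.
#' @return A `DNAStringSet` or `AAStringSet`.
#' @export
read_fasta <- function(path, type = c("auto", "DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) .stopf("empty FASTA file: %s", path)
  if (!startsWith(first, ">")) .stopf("malformed FASTA (no '>' header): %s", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) .stopf("FASTA file contains no records: %s", path)
  chr <- toupper(as.character(x))
  if (any(nchar(chr) == 0L)) .stopf("FASTA record with empty sequence in %s", path)
  is_dna <- !grepl("[^ACGTN]", chr)
  if (type == "DNA" || (type == "auto" && all(is_dna))) {
    if (any(!is_dna)) .stopf("non-DNA characters in %s", path)
    out <- Biostrings::DNAStringSet(chr)
  } else {
    out <- Biostrings::AAStringSet(chr)
  }
  names(out) <- names(x)
  out
}

#' Read RNA-seq reads from FASTQ or FASTA
#'
#' The format is auto-detected from the first character of the file (`@` for
#' FASTQ, `>` for FASTA). Base qualities are discarded; read identifiers are
#' preserved.
#'
#' @param path Path to the read file.
#' @return A [Biostrings::DNAStringSet] of reads.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- substr(readLines(path, n = 1L)[1], 1L, 1L)
  if (identical(first, "@")) {
    nl <- length(readLines(path))
    if (nl %% 4L != 0L) .stopf("truncated FASTQ (line count %d not a multiple of 4): %s", nl, path)
    reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else if (identical(first, ">")) {
    reads <- read_fasta(path, type = "DNA")
  } else {
    .stopf("unrecognized read file format (first character %s): %s",
           deparse(first), path)
  }
  names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

#' Write reads as FASTQ
#'
#' Placeholder qualities (`I`) are written, since all downstream analysis
#' ignores base quality.
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_reads_fastq <- function(reads, path) {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write gene features to GFF3
#'
#' @param features Feature data.frame (see [read_gff3()] for the columns).
#' @param path Output path.
#' @param seqlens Named integer vector of reference sequence lengths; features
#'   on unknown sequences or out of bounds raise an error.
#' @export
write_gff3 <- function(features, path, seqlens) {
  stopifnot(is.data.frame(features), !is.null(names(seqlens)))
  unknown <- setdiff(unique(features$seqid), names(seqlens))
  if (length(unknown))
    .stopf("features reference unknown sequence(s): %s", paste(unknown, collapse = ", "))
  bad <- features$start < 1L | features$end > seqlens[features$seqid] |
    features$start > features$end
  if (any(bad))
    .stopf("feature interval out of sequence bounds (e.g. %s:%d-%d)",
           features$seqid[bad][1], features$start[bad][1], features$end[bad][1])
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$ID
  par <- as.list(features$Parent)
  par[is.na(features$Parent)] <- list(character(0))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(par)
  for (col in c("gene_class", "validated_tata", "validated_splice"))
    S4Vectors::mcols(gr)[[col]] <- features[[col]]
  S4Vectors::mcols(gr)$phase <- if ("phase" %in% names(features))
    as.integer(features$phase) else .cds_phase(features)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into the package's feature table
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `ID`, `Parent`, `gene_class`, `validated_tata`,
#'   `validated_splice`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  getcol <- function(col) {
    if (col %in% colnames(m)) as.character(m[[col]]) else rep(NA_character_, length(gr))
  }
  parent <- if ("Parent" %in% colnames(m)) {
    vapply(as.list(m$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(m$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = getcol("ID"),
    Parent = parent,
    gene_class = getcol("gene_class"),
    validated_tata = getcol("validated_tata"),
    validated_splice = getcol("validated_splice"),
    stringsAsFactors = FALSE)
}

# write a TSV with fixed conventions
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
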