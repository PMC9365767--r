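# Shared low-level helpers. All coordinates in this package are 1-based,
# closed intervals on the forward strand of the reference sequence, the
# convention of IRanges/GRanges; GFF3 output therefore needs no conversion.

#' @importFrom Biostrings DNAString DNAStringSet AAStringSet reverseComplement
#'   translate readDNAStringSet readBStringSet writeXStringSet subseq
#'   pairwiseAlignment matchPattern vcountPattern PDict countPDict
#' @importFrom stats rmultinom setNames
#' @importFrom utils head tail write.table read.table
NULL

# coerce a single sequence (character / XString / XStringSet) to character
.as_seq_chr <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(toupper(x))
  }
  x <- as.character(x)
  if (length(x) != 1L) stop("expected a single sequence")
  toupper(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# standard genetic code as a codon -> residue lookup (fast scalar path;
# anything not in the table, e.g. codons containing N, yields X)
.CODON_MAP <- Biostrings::GENETIC_CODE

# translate a character DNA string (length need not be a multiple of 3);
# codons containing N (or any ambiguity) become X, stops are '*'
.translate_chr <- function(dna) {
  n <- nchar(dna)
  len <- (n %/% 3L) * 3L
  if (len == 0L) return("")
  codons <- substring(dna, seq.int(1L, len, 3L), seq.int(3L, len, 3L))
  aa <- .CODON_MAP[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# mirror a 1-based closed interval onto the opposite strand of a sequence of
# length n
.mirror_interval <- function(start, end, n) {
  c(n - end + 1L, n - start + 1L)
}

# map a peptide span [i, j] (1-based within a frame translation) back to the
# genomic interval of its codons; frame in 0:2, strand "+" or "-"
.pep_span_to_genome <- function(i, j, frame, strand, n) {
  if (strand == "+") {
    c(frame + 3L * (i - 1L) + 1L, frame + 3L * j)
  } else {
    c(n - frame - 3L * j + 1L, n - frame - 3L * (i - 1L))
  }
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic sub-seed derivation, kept below .Machine$integer.max
.subseed <- function(seed, k) {
  (as.integer(seed) * 1009L + as.integer(k) * 9176L) %% 2147483629L
}
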