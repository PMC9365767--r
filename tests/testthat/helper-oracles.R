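# Independent reference implementations used to check the package's fast
# paths, plus small fixture builders. Everything here is deliberately
# simple and quadratic.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# independent codon table for building fixtures (one codon per residue)
CODON1 <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
            G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
            M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGC",
            S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")
reverse_translate <- function(pep) {
  paste(CODON1[strsplit(pep, "")[[1]]], collapse = "")
}

GENCODE <- Biostrings::GENETIC_CODE
translate_chr <- function(dna) {
  len <- (nchar(dna) %/% 3) * 3
  if (len == 0) return("")
  codons <- substring(dna, seq(1, len, 3), seq(3, len, 3))
  aa <- GENCODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# ---- Smith-Waterman full-DP oracle (affine gaps, gap of length L costs
# open + ext * L) ----
sw_oracle <- function(q, t, open = 11, ext = 1, matrix_name = "BLOSUM62") {
  e <- new.env(); utils::data(list = matrix_name, package = "Biostrings", envir = e)
  S <- get(matrix_name, envir = e)
  a <- strsplit(q, "")[[1]]; b <- strsplit(t, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    prev <- max(M[i, j], Ix[i, j], Iy[i, j], 0)
    M[i + 1, j + 1] <- prev + S[a[i], b[j]]
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Iy[i + 1, j] - ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# ---- brute-force ORF enumeration: every position, every strand; ORFs run
# ATG..stop, nested starts resolved to the 5'-most per stop ----
orf_oracle <- function(dna, min_aa = 50) {
  n <- nchar(dna)
  res <- list()
  for (st in c("+", "-")) {
    s <- if (st == "+") dna else revcomp(dna)
    found <- list()   # key: stop position -> earliest start
    for (p in seq_len(n - 2)) {
      if (substr(s, p, p + 2) != "ATG") next
      j <- p
      repeat {
        if (j + 5 > n) { j <- NA; break }   # no downstream stop
        cod <- substr(s, j + 3, j + 5)
        j <- j + 3
        if (cod %in% c("TAA", "TAG", "TGA")) break
      }
      if (is.na(j)) next
      stop_start <- j
      len <- (stop_start - p) / 3
      if (len < min_aa) next
      key <- as.character(stop_start)
      if (is.null(found[[key]]) || p < found[[key]]) found[[key]] <- p
    }
    for (key in names(found)) {
      p <- found[[key]]; stop_start <- as.integer(key)
      iv <- if (st == "+") c(p, stop_start - 1)
            else c(n - (stop_start - 1) + 1, n - p + 1)
      res[[length(res) + 1]] <- data.frame(
        start = iv[1], end = iv[2], strand = st,
        length_aa = (stop_start - p) / 3,
        peptide = translate_chr(substr(s, p, stop_start - 1)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(data.frame(start = integer(), end = integer(),
                                      strand = character(),
                                      length_aa = integer(),
                                      peptide = character()))
  out <- do.call(rbind, res)
  out[order(out$start, out$end, out$strand), ]
}

# ---- brute-force perfect-hit counter: all 6 frames x all alignment
# offsets, exact match over the full overlap, overlap >= min_overlap ----
read_matches_oracle <- function(read, q, min_overlap = 16) {
  m <- nchar(q)
  for (s in c(read, revcomp(read))) {
    for (f in 0:2) {
      p <- translate_chr(substr(s, f + 1, nchar(s)))
      w <- nchar(p)
      if (w == 0) next
      for (shift in (1 - w):(m - 1)) {
        i1 <- max(1, 1 - shift); i2 <- min(w, m - shift)
        L <- i2 - i1 + 1
        if (L < min_overlap) next
        if (substr(p, i1, i2) == substr(q, i1 + shift, i2 + shift)) return(TRUE)
      }
    }
  }
  FALSE
}

count_hits_oracle <- function(q, reads, min_overlap = 16) {
  sum(vapply(as.character(reads), read_matches_oracle, logical(1),
             q = q, min_overlap = min_overlap))
}

# ---- micro-gene fixture: [pad] ATG [domain] [tail_nt extra coding] stop
# [pad]; returns the sequence and the landmark coordinates ----
plant_s100_gene <- function(domain_pep, tail_nt, pad = 60,
                            double_domain = FALSE) {
  stopifnot(tail_nt %% 3 == 0)
  dom_dna <- reverse_translate(domain_pep)
  if (double_domain) dom_dna <- paste0(dom_dna, dom_dna)
  tail_dna <- paste(rep(CODON1[["Q"]], tail_nt / 3), collapse = "")
  left <- random_dna(pad); right <- random_dna(pad)
  seq <- paste0(left, "ATG", dom_dna, tail_dna, "TAA", right)
  list(seq = seq,
       cds_start = pad + 1,
       dom_start = pad + 4,
       dom_end = pad + 3 + nchar(dom_dna),
       stop_start = pad + 4 + nchar(dom_dna) + tail_nt)
}

default_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      sim <- simulate_locus(locus_config(seed = seed))
      rd <- simulate_reads(sim, expression_config(seed = seed))
      cache[[key]] <- list(sim = sim, reads = rd)
    }
    cache[[key]]
  }
})
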