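# Protein-level characterization of EDC gene products: amino-acid
# composition profiles, tandem repeat segmentation, and sequence-logo
# position frequency / information content matrices.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid composition of a protein
#'
#' @param protein Protein sequence (character or `AAStringSet` of length 1);
#'   a `*` in the sequence is an error (translate first and strip the stop).
#' @return A list of class `composition_profile`: `protein_id`, `percent`
#'   (named vector over the 20 residues, summing to 100), `length_aa`.
#' @export
aa_composition <- function(protein) {
  pid <- if (!is.null(names(protein))) names(protein)[1] else "protein"
  p <- .as_seq_chr(protein)
  if (nchar(p) == 0L) .stopf("aa_composition: empty protein")
  if (grepl("*", p, fixed = TRUE))
    .stopf("aa_composition: sequence contains a stop ('*')")
  aa <- strsplit(p, "")[[1]]
  counts <- table(factor(aa, levels = .AA20))
  pct <- 100 * as.numeric(counts) / length(aa)
  structure(list(protein_id = pid,
                 percent = setNames(pct, .AA20),
                 length_aa = length(aa)),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Amino-acid composition of", x$protein_id,
      sprintf("(%d aa)\n", x$length_aa))
  top <- sort(x$percent[x$percent > 0], decreasing = TRUE)
  cat(paste(sprintf("%s %.1f%%", names(top), top), collapse = "  "), "\n")
  invisible(x)
}

# mean pairwise identity across equal-length units
.mean_pairwise_identity <- function(units) {
  k <- length(units)
  if (k < 2L) return(NA_real_)
  mat <- do.call(rbind, strsplit(units, ""))
  tot <- 0; np <- 0L
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    tot <- tot + mean(mat[i, ] == mat[j, ])
    np <- np + 1L
  }
  tot / np
}

#' Segment a peptide into tandem repeat units
#'
#' Cuts the peptide into consecutive windows of `unit_length` residues
#' starting at the phase (offset 0..unit_length-1) that maximizes the mean
#' pairwise identity across units; user-supplied anchor positions override
#' the automatic phasing.
#'
#' @param peptide Protein sequence.
#' @param unit_length Repeat unit length, residues (>= 2).
#' @param anchor_positions Optional integer vector of unit start positions
#'   (1-based); when given, units are cut at these positions instead.
#' @return Character vector of units, with attributes `phase` (0-based
#'   offset of the first unit) and `identity` (mean pairwise identity).
#' @export
align_repeats <- function(peptide, unit_length, anchor_positions = NULL) {
  p <- .as_seq_chr(peptide)
  n <- nchar(p)
  if (unit_length < 2L) .stopf("align_repeats: unit_length must be >= 2")
  if (n < 2L * unit_length)
    .stopf("align_repeats: peptide (%d aa) holds fewer than 2 units of %d",
           n, unit_length)
  if (!is.null(anchor_positions)) {
    if (any(anchor_positions < 1L | anchor_positions + unit_length - 1L > n))
      .stopf("align_repeats: anchor positions out of range")
    units <- substring(p, anchor_positions, anchor_positions + unit_length - 1L)
    return(structure(units, phase = anchor_positions[1] - 1L,
                     identity = .mean_pairwise_identity(units)))
  }
  best <- NULL
  for (phase in 0:(unit_length - 1L)) {
    k <- (n - phase) %/% unit_length
    if (k < 2L) next
    starts <- phase + 1L + unit_length * (0:(k - 1L))
    units <- substring(p, starts, starts + unit_length - 1L)
    ident <- .mean_pairwise_identity(units)
    if (is.null(best) || ident > best$ident) best <- list(units = units,
                                                          phase = phase,
                                                          ident = ident)
  }
  structure(best$units, phase = best$phase, identity = best$ident)
}

#' Position frequency matrix and information content of aligned units
#'
#' Computes, per column, residue frequencies over the observed residues
#' (gaps `-` excluded) and the information content
#' `IC = log2(20) - H(column)` in bits, with a uniform 20-residue
#' background and no small-sample correction, the conventions of standard
#' sequence-logo tools.
#'
#' @param aligned_units Character vector of >= 2 equal-length peptide units
#'   (gap character `-` permitted).
#' @return A list of class `logo_matrix`: `freq` (residues x columns
#'   matrix), `ic_bits` (per-column information content), `n_sequences`.
#' @export
build_logo <- function(aligned_units) {
  units <- toupper(as.character(aligned_units))
  if (length(units) < 2L) .stopf("build_logo: at least 2 units are required")
  if (length(unique(nchar(units))) != 1L)
    .stopf("build_logo: units must have equal length")
  mat <- do.call(rbind, strsplit(units, ""))
  ncol <- ncol(mat)
  freq <- matrix(0, length(.AA20), ncol,
                 dimnames = list(.AA20, seq_len(ncol)))
  ic <- numeric(ncol)
  for (j in seq_len(ncol)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (!length(col)) { ic[j] <- 0; next }
    f <- table(factor(col, levels = .AA20)) / length(col)
    freq[, j] <- as.numeric(f)
    nz <- f[f > 0]
    ic[j] <- log2(20) + sum(nz * log2(nz))
  }
  structure(list(freq = freq, ic_bits = ic, n_sequences = length(units)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("Sequence logo:", ncol(x$freq), "columns,", x$n_sequences, "units\n")
  cons <- rownames(x$freq)[apply(x$freq, 2L, which.max)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  cat("  IC (bits):", paste(sprintf("%.2f", x$ic_bits), collapse = " "), "\n")
  invisible(x)
}

# long-format data.frame of a logo matrix (the TSV the CLI writes)
logo_to_df <- function(logo) {
  df <- expand.grid(residue = rownames(logo$freq),
                    column = seq_len(ncol(logo$freq)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$frequency <- as.numeric(logo$freq[cbind(df$residue, df$column)])
  df$ic_bits <- logo$ic_bits[df$column]
  df[df$frequency > 0, c("column", "residue", "frequency", "ic_bits")]
}

#' Composition table for a set of proteins
#'
#' Per-protein percentage content of the 20 residues, optionally with
#' reference proteins appended for side-by-side comparison, and a flag
#' column listing residues whose content reaches `notable` percent.
#'
#' @param proteins Named `AAStringSet` or character vector.
#' @param reference_proteins Optional named set appended to the table.
#' @param notable Flagging threshold in percent (default 10).
#' @return A data.frame: `protein_id`, `length_aa`, one column per residue
#'   (percent), `notable_residues`, `is_reference`.
#' @export
composition_report <- function(proteins, reference_proteins = NULL,
                               notable = 10) {
  build <- function(set, ref) {
    ids <- names(set)
    if (is.null(ids)) ids <- sprintf("protein%d", seq_along(set))
    do.call(rbind, lapply(seq_along(set), function(i) {
      prof <- aa_composition(setNames(as.character(set[i]), ids[i]))
      row <- data.frame(protein_id = prof$protein_id,
                        length_aa = prof$length_aa,
                        stringsAsFactors = FALSE)
      for (r in .AA20) row[[r]] <- unname(prof$percent[r])
      flag <- names(prof$percent)[prof$percent >= notable]
      row$notable_residues <- paste(flag, collapse = ",")
      row$is_reference <- ref
      row
    }))
  }
  out <- build(proteins, FALSE)
  if (!is.null(reference_proteins) && length(reference_proteins))
    out <- rbind(out, build(reference_proteins, TRUE))
  rownames(out) <- NULL
  out
}
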