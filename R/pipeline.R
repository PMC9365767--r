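# End-to-end orchestration: anchor location -> SFTP/S100A classification ->
# SEDC discovery -> exon-1 annotation, plus artifact writing and validation
# against a simulator truth.

#' Discover and annotate EDC genes in a genomic sequence
#'
#' Runs the full discovery procedure: locate the two S100A anchor genes,
#' search the inter-anchor region with the S100-domain query and classify
#' hit groups as S100A or SFTP by the 400-nt coding-extension rule, call
#' SEDC genes by composition-biased ORF scanning with the splice-acceptor
#' and transcription rules, and annotate non-coding first exons and TATA
#' boxes from junction-spanning reads.
#'
#' @param genome DNA sequence (character, `DNAString` or named
#'   `DNAStringSet` of length 1).
#' @param anchor_queries Named `AAStringSet` with the two anchor queries
#'   (e.g. S100A11 and S100A16 domains), in chromosomal order A then B.
#' @param domain_queries Named `AAStringSet` of S100-domain queries used to
#'   find SFTP genes (may be `NULL` to skip the SFTP search).
#' @param reads Named list of `DNAStringSet` read sets per tissue; the
#'   first set (the skin library) provides the exon-1 evidence.
#' @param params Parameters from [edc_params()].
#' @return An object of class `edc_scan`: list with `models`, `features`
#'   (GFF3-ready data.frame), `locus_interval`, `anchor_ids`, `counts`
#'   (named per-class gene counts), `seqid`, `params`.
#' @export
edc_scan <- function(genome, anchor_queries, domain_queries = NULL,
                     reads = NULL, params = edc_params()) {
  seqid <- if (!is.null(names(genome))) names(genome)[1] else "genome"
  g <- .as_seq_chr(genome)

  anch <- locate_anchors(g, anchor_queries, params, seqid = seqid)
  models <- anch$anchor_models
  region <- anch$interval

  # SFTP / additional S100A genes between the anchors. Candidates are
  # ranked by hit score and accepted greedily unless their CDS overlaps an
  # already-accepted model on either strand: an antisense or paralogous
  # echo of a real domain always scores below the true gene and is dropped.
  if (!is.null(domain_queries) && length(domain_queries)) {
    sub <- substr(g, region[1], region[2])
    cands <- list()
    for (qi in seq_along(domain_queries)) {
      q <- setNames(as.character(domain_queries[[qi]]),
                    names(domain_queries)[qi])
      hits <- search_genome(q, sub, min_score = params$min_score,
                            min_identity = params$min_identity, seqid = seqid)
      if (nrow(hits) == 0L) next
      hits$start <- hits$start + region[1] - 1L
      hits$end <- hits$end + region[1] - 1L
      qlen <- nchar(q)
      for (grp in group_hits(hits, max_gap = params$group_max_gap)) {
        # a gene must contain most of the domain: union of aligned query
        # spans over the query length
        cov <- sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(grp$qstart, grp$qend)))) / qlen
        if (cov < params$min_domain_coverage) next
        m <- classify_s100_gene(grp, g, params)
        m$best_hit_score <- max(grp$score)
        cands[[length(cands) + 1L]] <- m
      }
    }
    if (length(cands)) {
      cands <- cands[order(-vapply(cands, `[[`, numeric(1), "best_hit_score"))]
      for (m in cands) {
        clash <- any(vapply(models, function(x)
          min(x$cds$start) <= max(m$cds$end) &&
            max(x$cds$end) >= min(m$cds$start), logical(1)))
        if (!clash) models[[length(models) + 1L]] <- m
      }
    }
  }

  blocked <- do.call(rbind, lapply(models, function(m)
    data.frame(start = min(m$cds$start), end = max(m$cds$end))))

  sedc <- if (!is.null(reads) && length(reads)) {
    call_sedc_genes(g, region, blocked, reads, params)
  } else list()
  models <- c(models, sedc)

  evidence <- if (!is.null(reads) && length(reads)) reads[[1]] else NULL
  if (!is.null(evidence)) {
    models <- lapply(models, annotate_exon1, genome = g, reads = evidence,
                     params = params)
  }

  # stable ids by class and genomic order
  ord <- order(vapply(models, function(m) min(m$cds$start), numeric(1)))
  models <- models[ord]
  cls <- vapply(models, `[[`, character(1), "gene_class")
  ids <- character(length(models))
  for (cl in unique(cls)) {
    ix <- which(cls == cl)
    ids[ix] <- sprintf("%s.%d", cl, seq_along(ix))
  }
  for (i in seq_along(models)) {
    if (is.null(models[[i]]$gene_id)) models[[i]]$gene_id <- ids[i]
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")

  counts <- c(n_S100A = sum(cls == "S100A"), n_SFTP = sum(cls == "SFTP"),
              n_SEDC = sum(cls == "SEDC"))
  structure(list(models = models,
                 features = .models_to_features(models, seqid),
                 locus_interval = region,
                 anchor_ids = anch$anchor_ids,
                 counts = counts, seqid = seqid, params = params,
                 genome_length = nchar(g)),
            class = "edc_scan")
}

# flatten gene models into the GFF3-ready feature table
.models_to_features <- function(models, seqid) {
  rows <- list()
  add <- function(type, start, end, strand, id, parent, gene_class = NA,
                  vt = NA, vs = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, type = type, start = as.integer(start),
      end = as.integer(end), strand = strand, ID = id, Parent = parent,
      gene_class = as.character(gene_class),
      validated_tata = as.character(vt), validated_splice = as.character(vs),
      stringsAsFactors = FALSE)
  }
  for (m in models) {
    gid <- m$gene_id
    exons <- if (!is.null(m$exons)) m$exons else m$cds
    gstart <- min(exons$start, m$cds$start)
    gend <- max(exons$end, m$cds$end)
    add("gene", gstart, gend, m$strand, gid, NA, m$gene_class,
        vt = m$tata_found,
        vs = m$splice_donor_ok && m$splice_acceptor_ok)
    for (i in seq_len(nrow(exons)))
      add("exon", exons$start[i], exons$end[i], m$strand,
          sprintf("%s_exon_%d", gid, i), gid)
    for (i in seq_len(nrow(m$cds)))
      add("CDS", m$cds$start[i], m$cds$end[i], m$strand,
          sprintf("%s_CDS_%d", gid, i), gid, m$gene_class)
    if (!is.null(m$tata_interval))
      add("TATA_box", m$tata_interval[1], m$tata_interval[2], m$strand,
          sprintf("%s_TATA", gid), gid)
  }
  if (!length(rows)) return(.empty_features())
  do.call(rbind, rows)
}

#' @export
print.edc_scan <- function(x, ...) {
  cat("EDC locus scan of", x$seqid, "\n")
  cat(sprintf("  inter-anchor region %d-%d (%d kb), anchors %s | %s\n",
              x$locus_interval[1], x$locus_interval[2],
              round(diff(x$locus_interval) / 1000), x$anchor_ids[1],
              x$anchor_ids[2]))
  cat(sprintf("  genes: %d S100A, %d SFTP, %d SEDC\n",
              x$counts["n_S100A"], x$counts["n_SFTP"], x$counts["n_SEDC"]))
  print(summary(x))
  invisible(x)
}

#' Per-gene report of an EDC locus scan
#'
#' @param object An `edc_scan`.
#' @param ... Unused.
#' @return Data.frame: `gene_id`, `class`, `strand`, `length_aa`,
#'   `composition_class`, `acceptor_offset`, `tata_found`,
#'   `spanning_reads`, `extension_nt`.
#' @export
summary.edc_scan <- function(object, ...) {
  do.call(rbind, lapply(object$models, function(m) data.frame(
    gene_id = m$gene_id, class = m$gene_class, strand = m$strand,
    length_aa = nchar(m$peptide),
    composition_class = m$composition_class,
    acceptor_offset = m$acceptor_offset,
    tata_found = m$tata_found,
    spanning_reads = length(m$spanning_read_ids),
    extension_nt = m$extension_nt,
    row.names = NULL, stringsAsFactors = FALSE)))
}

# ---- run orchestration ------------------------------------------------------

#' Run the full pipeline on simulated or provided inputs
#'
#' One reproducible run of simulate (optional) -> discover -> express ->
#' compose, writing `models.gff3`, `report.tsv`, `expression.tsv`,
#' `composition.tsv`, `summary.json` and `run.log` into `outdir` (plus
#' `truth.gff3` for simulated runs).
#'
#' @param config A list (or path to a YAML file) with optional entries:
#'   `locus` ([locus_config()] or its fields), `expression`
#'   ([expression_config()] or its fields), `params` (overrides for
#'   [edc_params()]), `genome`/`anchors`/`domains`/`reads` (file paths, used
#'   instead of the simulator when given; `reads` is a named list
#'   tissue -> path), `stages` (character subset of `c("expression",
#'   "composition")`), `seed` (overrides both simulator seeds).
#' @param outdir Output directory (created if missing); `NULL` writes no
#'   files.
#' @return An object of class `edc_run`: list with `scan`, `truth` (or
#'   `NULL`), `expression`, `composition`, `summary`, `paths`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  logl <- character(0)
  note <- function(fmt, ...) {
    logl <<- c(logl, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                             sprintf(fmt, ...)))
  }
  params <- do.call(edc_params, config$params %||% list())
  stages <- config$stages %||% c("expression", "composition")

  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$genome)) {
      stage <- "input"
      genome <- read_fasta(config$genome, type = "DNA")
      anchors <- read_fasta(config$anchors, type = "AA")
      domains <- if (!is.null(config$domains))
        read_fasta(config$domains, type = "AA") else NULL
      reads <- lapply(config$reads, read_reads)
      truth <- NULL
      note("loaded genome %s (%d nt), %d read set(s)", config$genome,
           Biostrings::width(genome)[1], length(reads))
    } else {
      stage <- "simulate"
      lcfg <- config$locus %||% list()
      ecfg <- config$expression %||% list()
      if (!is.null(config$seed)) {
        lcfg$seed <- config$seed
        ecfg$seed <- .subseed(config$seed, 1L)
      }
      if (!inherits(lcfg, "locus_config")) lcfg <- do.call(locus_config, lcfg)
      if (!inherits(ecfg, "expression_config"))
        ecfg <- do.call(expression_config, ecfg)
      truth <- simulate_locus(lcfg)
      sim <- simulate_reads(truth, ecfg)
      genome <- truth$genome
      anchors <- truth$queries[c("S100A11", "S100A16")]
      domains <- truth$queries["S100_SFTP_domain"]
      reads <- sim$reads
      note("simulated locus seed %d: %d nt, %d genes; %d tissues x %d reads",
           lcfg$seed, Biostrings::width(genome)[1],
           sum(truth$features$type == "gene"), length(reads),
           ecfg$reads_per_tissue)
    }

    stage <- "find"
    scan <- edc_scan(genome, anchors, domains, reads, params)
    note("discovery: %d S100A, %d SFTP, %d SEDC",
         scan$counts["n_S100A"], scan$counts["n_SFTP"], scan$counts["n_SEDC"])

    stage <- "expression"
    expr_tab <- NULL
    if ("expression" %in% stages) {
      if (is.null(reads) || !length(reads))
        .stopf("no reads available for the expression stage")
      queries <- lapply(scan$models, function(m)
        make_query(setNames(m$peptide, m$gene_id), 1L,
                   min(50L, nchar(m$peptide))))
      expr_tab <- expression_table(queries, reads)
      note("expression: %d queries x %d tissues", length(queries),
           length(reads))
    }

    stage <- "composition"
    comp_tab <- NULL
    if ("composition" %in% stages) {
      peps <- Biostrings::AAStringSet(vapply(scan$models, `[[`, character(1),
                                             "peptide"))
      comp_tab <- composition_report(peps)
      note("composition: %d proteins", nrow(comp_tab))
    }
    list(scan = scan, truth = truth, expression = expr_tab,
         composition = comp_tab, genome = genome)
  }, error = function(e) {
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  scan <- result$scan
  summary_list <- list(
    seqid = scan$seqid,
    counts = as.list(scan$counts),
    locus_interval = scan$locus_interval,
    genes = summary(scan),
    parameters = scan$params[vapply(scan$params, is.atomic, logical(1))])

  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    slen <- setNames(result$scan$genome_length, scan$seqid)
    paths$models <- file.path(outdir, "models.gff3")
    write_gff3(scan$features, paths$models, slen)
    paths$report <- file.path(outdir, "report.tsv")
    .write_tsv(summary(scan), paths$report)
    if (!is.null(result$truth)) {
      paths$truth <- file.path(outdir, "truth.gff3")
      write_gff3(result$truth$features, paths$truth,
                 setNames(Biostrings::width(result$truth$genome),
                          names(result$truth$genome)))
    }
    if (!is.null(result$expression)) {
      paths$expression <- file.path(outdir, "expression.tsv")
      .write_tsv(result$expression, paths$expression)
    }
    if (!is.null(result$composition)) {
      paths$composition <- file.path(outdir, "composition.tsv")
      .write_tsv(result$composition, paths$composition)
    }
    paths$summary <- file.path(outdir, "summary.json")
    jsonlite::write_json(summary_list, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths$log <- file.path(outdir, "run.log")
    writeLines(logl, paths$log)
  }
  structure(list(scan = scan, truth = result$truth,
                 expression = result$expression,
                 composition = result$composition,
                 summary = summary_list, paths = paths, log = logl),
            class = "edc_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.edc_run <- function(x, ...) {
  cat("EDC pipeline run\n")
  print(x$scan)
  if (!is.null(x$expression))
    cat("  expression table:", nrow(x$expression), "records\n")
  invisible(x)
}

# ---- validation against simulator truth -------------------------------------

# per-gene key: class | strand | sorted CDS intervals
.gene_keys <- function(features) {
  cds <- features[features$type == "CDS", ]
  genes <- features[features$type == "gene", ]
  vapply(genes$ID, function(gid) {
    g <- cds[cds$Parent == gid, ]
    g <- g[order(g$start), ]
    paste(genes$gene_class[genes$ID == gid][1], g$strand[1],
          paste(sprintf("%d-%d", g$start, g$end), collapse = ","),
          sep = "|")
  }, character(1))
}

#' Compare predicted gene models with the simulator truth
#'
#' A predicted gene matches a truth gene when it has the same class, the
#' same strand, and identical CDS intervals. Reports per-class precision
#' and recall plus the list of mismatches.
#'
#' @param predicted An `edc_scan`, feature data.frame, or path to a GFF3.
#' @param truth An `edc_sim`, feature data.frame, or path to a GFF3.
#' @return A list of class `edc_validation`: `per_class` (data.frame with
#'   `class`, `n_truth`, `n_predicted`, `tp`, `precision`, `recall`),
#'   `false_positives`, `false_negatives` (gene keys).
#' @export
validate_against_truth <- function(predicted, truth) {
  as_feats <- function(x) {
    if (inherits(x, "edc_scan")) return(x$features)
    if (inherits(x, "edc_sim")) return(x$features)
    if (is.character(x)) return(read_gff3(x))
    x
  }
  pf <- as_feats(predicted); tf <- as_feats(truth)
  pk <- .gene_keys(pf); tk <- .gene_keys(tf)
  classes <- sort(unique(c(sub("\\|.*", "", pk), sub("\\|.*", "", tk))))
  per <- do.call(rbind, lapply(classes, function(cl) {
    p <- pk[startsWith(pk, paste0(cl, "|"))]
    t <- tk[startsWith(tk, paste0(cl, "|"))]
    tp <- sum(p %in% t)
    data.frame(class = cl, n_truth = length(t), n_predicted = length(p),
               tp = tp,
               precision = if (length(p)) tp / length(p) else NA_real_,
               recall = if (length(t)) tp / length(t) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_class = per,
                 false_positives = pk[!pk %in% tk],
                 false_negatives = tk[!tk %in% pk]),
            class = "edc_validation")
}

#' @export
print.edc_validation <- function(x, ...) {
  cat("Validation against truth\n")
  print(x$per_class, row.names = FALSE)
  if (length(x$false_positives))
    cat("  false positives:", paste(names(x$false_positives), collapse = ", "), "\n")
  if (length(x$false_negatives))
    cat("  false negatives:", paste(names(x$false_negatives), collapse = ", "), "\n")
  invisible(x)
}
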