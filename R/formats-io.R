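# Readers and writers for every external format the pipeline touches.
#
# Dialects:
#  * spliced protein alignments: Exonerate --showtargetgff GFF2, or the
#    simplified tab-separated dialect documented in the README;
#  * ab initio models: Augustus GTF/GFF (CDS features, phase column honored);
#  * output: GFF3 with a gene -> mRNA -> CDS hierarchy and isgap_* attributes
#    (lossless round trip);
#  * variants: VCF 4.x with transcript ids as CHROM.

#' Construct a spliced protein-to-transcript alignment record
#'
#' @param protein_id Query protein identifier.
#' @param protein_length Query length in amino acids.
#' @param transcript_id Target transcript identifier.
#' @param strand `"+"` or `"-"` (target strand).
#' @param blocks Two-column integer matrix of aligned blocks, 0-based
#'   half-open transcript coordinates, sorted and disjoint.
#' @param phase Phase (0, 1, 2) of the first block.
#' @param percent Alignment percent score (0-100).
#' @param raw_score Raw alignment score.
#' @param query_cov Fraction of protein residues aligned (0-1).
#' @param frameshift,earlystop Flags for frame-inconsistent block patterns
#'   and premature in-frame stop codons.
#' @return An object of class `protein_alignment`.
#' @export
protein_alignment <- function(protein_id, protein_length, transcript_id,
                              strand, blocks, phase = 0L, percent = 100,
                              raw_score = 0, query_cov = 1,
                              frameshift = FALSE, earlystop = FALSE) {
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  structure(list(protein_id = as.character(protein_id),
                 protein_length = as.integer(protein_length),
                 transcript_id = as.character(transcript_id),
                 strand = strand, blocks = blocks, phase = as.integer(phase),
                 percent = as.numeric(percent),
                 raw_score = as.numeric(raw_score),
                 query_cov = as.numeric(query_cov),
                 frameshift = isTRUE(frameshift),
                 earlystop = isTRUE(earlystop)),
            class = "protein_alignment")
}

.blocks_valid <- function(blocks) {
  if (nrow(blocks) == 0L) return(FALSE)
  if (any(blocks[, 2L] <= blocks[, 1L])) return(FALSE)
  if (nrow(blocks) > 1L) {
    if (any(diff(blocks[, 1L]) <= 0)) return(FALSE)
    if (any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L])) return(FALSE)
  }
  TRUE
}

.parse_block_list <- function(txt) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(\\d+)-(\\d+)$", parts))
  if (any(lengths(m) != 3L)) stop("malformed block list '", txt, "'")
  cbind(start = as.integer(vapply(m, `[`, "", 2L)),
        end = as.integer(vapply(m, `[`, "", 3L)))
}

.format_block_list <- function(blocks) {
  paste(sprintf("%d-%d", blocks[, 1L], blocks[, 2L]), collapse = ";")
}

# Post hoc structural flags for alignments read from formats that do not
# carry them. An inter-block gap too short to be an intron whose length is
# not a multiple of 3 indicates a frameshift; an in-frame stop before the
# last codon of the implied spliced CDS indicates an early stop.
detect_alignment_flags <- function(rec, transcripts, min_intron = 20L) {
  fs <- FALSE
  if (nrow(rec$blocks) > 1L) {
    gaps <- rec$blocks[-1L, 1L] - rec$blocks[-nrow(rec$blocks), 2L]
    fs <- any(gaps < min_intron & gaps %% 3L != 0L)
  }
  es <- FALSE
  if (!is.null(transcripts) && rec$transcript_id %in% names(transcripts)) {
    m <- gene_model("tmp", rec$transcript_id, rec$strand, rec$blocks,
                    phase = rec$phase)
    es <- has_internal_stop(m, transcripts)
  }
  rec$frameshift <- fs
  rec$earlystop <- es
  rec
}

#' Read spliced protein alignments (TSV dialect)
#'
#' One alignment per line, tab- (or whitespace-) separated:
#' `protein_id protein_length transcript_id strand percent raw_score
#' blocks phase frameshift earlystop`, where `blocks` is a semicolon-
#' separated `start-end` list in 0-based half-open transcript coordinates
#' and the two flags are `-` (false) or `+` (true).
#'
#' @param path Path to the TSV file.
#' @return List of [protein_alignment()] records.
#' @export
read_alignments_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (length(f) != 10L) {
      stop(sprintf("line %d of %s: expected 10 fields, got %d",
                   i, path, length(f)))
    }
    blocks <- .parse_block_list(f[7L])
    if (!.blocks_valid(blocks)) {
      warning(sprintf("line %d of %s: unsorted/overlapping blocks; record dropped",
                      i, path))
      next
    }
    out[[i]] <- protein_alignment(
      protein_id = f[1L], protein_length = as.integer(f[2L]),
      transcript_id = f[3L], strand = f[4L],
      percent = as.numeric(f[5L]), raw_score = as.numeric(f[6L]),
      blocks = blocks, phase = as.integer(f[8L]),
      query_cov = sum(blocks[, 2L] - blocks[, 1L]) / 3 / as.integer(f[2L]),
      frameshift = f[9L] != "-", earlystop = f[10L] != "-")
    keep[i] <- TRUE
  }
  out[keep]
}

#' Write spliced protein alignments in the TSV dialect
#'
#' @param records List of [protein_alignment()] records.
#' @param path Output path.
#' @export
write_alignments_tsv <- function(records, path) {
  lines <- vapply(records, function(r) {
    paste(r$protein_id, r$protein_length, r$transcript_id, r$strand,
          format(r$percent, trim = TRUE), format(r$raw_score, trim = TRUE),
          .format_block_list(r$blocks), r$phase,
          if (r$frameshift) "+" else "-",
          if (r$earlystop) "+" else "-", sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# key/value attribute string of an Exonerate GFF2 line -> named character
.parse_gff2_attrs <- function(txt) {
  parts <- trimws(strsplit(txt, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "[ \t]+")
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = " "), "")
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Read spliced protein alignments (Exonerate `--showtargetgff` GFF2 dialect)
#'
#' Each alignment is a `gene` feature (score column carries the raw score;
#' attributes carry `sequence <protein_id>` and, optionally, `percent`,
#' `query_length` and `phase`) followed by its `exon` features and an
#' optional `similarity` feature whose `Align` triples give query coverage.
#' Exonerate's text output does not mark frameshifts or premature stops
#' explicitly; when `transcripts` is supplied both are detected post hoc
#' (frame consistency of the block pattern; translation of the implied CDS).
#'
#' @param path Path to the GFF2 file.
#' @param transcripts Optional named character vector of transcript
#'   sequences, used for post hoc flag detection.
#' @return List of [protein_alignment()] records.
#' @export
read_exonerate_gff <- function(path, transcripts = NULL) {
  lines <- readLines(path)
  recs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    blocks <- do.call(rbind, cur$blocks)
    if (!.blocks_valid(blocks)) {
      warning("alignment of '", cur$protein_id,
              "' has unsorted/overlapping blocks; record dropped")
      return(NULL)
    }
    qlen <- cur$protein_length
    qcov <- if (!is.na(qlen) && qlen > 0L) {
      sum(blocks[, 2L] - blocks[, 1L]) / 3 / qlen
    } else 1
    rec <- protein_alignment(cur$protein_id,
                             if (is.na(qlen)) 0L else qlen,
                             cur$transcript_id, cur$strand, blocks,
                             phase = cur$phase, percent = cur$percent,
                             raw_score = cur$raw_score, query_cov = qcov)
    detect_alignment_flags(rec, transcripts)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      stop(sprintf("line %d of %s: unparseable GFF2 line", i, path))
    }
    feat <- f[3L]
    if (feat == "gene") {
      r <- flush(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      at <- .parse_gff2_attrs(f[9L])
      cur <- list(
        transcript_id = f[1L], strand = f[7L],
        raw_score = suppressWarnings(as.numeric(f[6L])),
        protein_id = if ("sequence" %in% names(at)) at[["sequence"]] else NA,
        percent = if ("percent" %in% names(at)) {
          as.numeric(at[["percent"]])
        } else 100,
        protein_length = if ("query_length" %in% names(at)) {
          as.integer(at[["query_length"]])
        } else NA_integer_,
        phase = if ("phase" %in% names(at)) as.integer(at[["phase"]]) else 0L,
        blocks = list())
      if (is.na(cur$raw_score)) cur$raw_score <- 0
    } else if (feat == "exon") {
      if (is.null(cur)) {
        stop(sprintf("line %d of %s: exon feature before any gene feature",
                     i, path))
      }
      cur$blocks[[length(cur$blocks) + 1L]] <-
        cbind(as.integer(f[4L]) - 1L, as.integer(f[5L]))
    }
    # cds / intron / splice5 / splice3 / similarity features carry no extra
    # structural information for this reader and are skipped.
  }
  r <- flush(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  recs
}

#' Write spliced protein alignments in the Exonerate GFF2 dialect
#'
#' @param records List of [protein_alignment()] records.
#' @param path Output path.
#' @export
write_exonerate_gff <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# --- START OF GFF DUMP ---", con)
  for (i in seq_along(records)) {
    r <- records[[i]]
    span <- c(r$blocks[1L, 1L], r$blocks[nrow(r$blocks), 2L])
    writeLines(sprintf(
      "%s\texonerate:protein2genome:local\tgene\t%d\t%d\t%s\t%s\t.\tgene_id %d ; sequence %s ; gene_orientation %s ; percent %s ; query_length %d ; phase %d",
      r$transcript_id, span[1L] + 1L, span[2L],
      format(r$raw_score, trim = TRUE), r$strand, i, r$protein_id,
      r$strand, format(r$percent, trim = TRUE), r$protein_length, r$phase),
      con)
    for (b in seq_len(nrow(r$blocks))) {
      writeLines(sprintf(
        "%s\texonerate:protein2genome:local\texon\t%d\t%d\t.\t%s\t.\tinsertions 0 ; deletions 0",
        r$transcript_id, r$blocks[b, 1L] + 1L, r$blocks[b, 2L], r$strand),
        con)
    }
  }
  writeLines("# --- END OF GFF DUMP ---", con)
  invisible(path)
}

# GTF/GFF attribute column -> named character vector, accepting both the
# GTF `key "value";` and the GFF3 `key=value;` styles plus Augustus's bare
# group id.
.parse_flex_attrs <- function(txt) {
  txt <- trimws(txt)
  if (!grepl("[=\"]", txt)) return(c(group = txt))
  parts <- trimws(strsplit(txt, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  out <- character()
  for (p in parts) {
    if (grepl("=", p, fixed = TRUE)) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1L]]
      out[kv[1L]] <- kv[2L]
    } else {
      mm <- regmatches(p, regexec("^(\\S+)\\s+\"?([^\"]*)\"?$", p))[[1L]]
      if (length(mm) == 3L) out[mm[2L]] <- mm[3L]
    }
  }
  out
}

#' Read ab initio gene models (Augustus GTF/GFF dialect)
#'
#' CDS features are grouped by their transcript attribute (`transcript_id`,
#' `Parent`, `gene_id` or Augustus's bare group column) into single models.
#' The CDS phase column is honored: the model phase is the phase of the
#' 5'-most CDS segment in gene orientation. Groups with inconsistent strand
#' are rejected with a warning. Completeness flags are derived from CDS
#' content when `transcripts` is supplied.
#'
#' @param path Path to the GFF/GTF file.
#' @param transcripts Optional named character vector of transcript
#'   sequences.
#' @return List of `gene_model` objects with `source = "abinitio"`.
#' @export
read_abinitio_gff <- function(path, transcripts = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  groups <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stop(sprintf("line %d of %s: unparseable", i, path))
    if (!(f[3L] %in% c("CDS", "cds"))) next
    at <- .parse_flex_attrs(f[9L])
    gid <- if ("transcript_id" %in% names(at)) at[["transcript_id"]]
           else if ("Parent" %in% names(at)) at[["Parent"]]
           else if ("gene_id" %in% names(at)) at[["gene_id"]]
           else if ("group" %in% names(at)) at[["group"]]
           else stop(sprintf("line %d of %s: CDS without a group attribute",
                             i, path))
    groups[[gid]] <- c(groups[[gid]], list(list(
      seqid = f[1L], start = as.integer(f[4L]) - 1L, end = as.integer(f[5L]),
      score = suppressWarnings(as.numeric(f[6L])), strand = f[7L],
      phase = suppressWarnings(as.integer(f[8L])))))
  }
  models <- list()
  for (gid in names(groups)) {
    g <- groups[[gid]]
    strands <- unique(vapply(g, `[[`, "", "strand"))
    seqids <- unique(vapply(g, `[[`, "", "seqid"))
    if (length(strands) != 1L || length(seqids) != 1L) {
      warning("ab initio model '", gid,
              "' has inconsistent strand/seqid; rejected")
      next
    }
    exons <- cbind(vapply(g, `[[`, 0L, "start"), vapply(g, `[[`, 0L, "end"))
    o <- order(exons[, 1L])
    exons <- exons[o, , drop = FALSE]
    phases <- vapply(g, `[[`, 0L, "phase")[o]
    ph <- if (strands == "+") phases[1L] else phases[length(phases)]
    if (is.na(ph)) ph <- 0L
    scores <- vapply(g, function(x) x$score, 0)
    sc <- suppressWarnings(mean(scores, na.rm = TRUE))
    if (!is.finite(sc)) sc <- 0
    m <- tryCatch(
      gene_model(gid, seqids, strands, exons, phase = ph,
                 source = "abinitio", support = 0L, score = sc),
      error = function(e) {
        warning("ab initio model '", gid, "' rejected: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(m)) next
    if (!is.null(transcripts) && m$transcript_id %in% names(transcripts)) {
      m <- set_completeness_flags(m, transcripts)
    }
    models[[length(models) + 1L]] <- m
  }
  models
}

#' Write ab initio gene models in an Augustus-style GTF dialect
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @export
write_abinitio_gff <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    span <- model_span(m)
    tid <- paste0(m$id, ".t1")
    writeLines(sprintf("%s\tAUGUSTUS\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       m$transcript_id, span[1L] + 1L, span[2L], m$strand,
                       m$id), con)
    writeLines(sprintf("%s\tAUGUSTUS\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       m$transcript_id, span[1L] + 1L, span[2L], m$strand,
                       tid), con)
    ph <- .segment_phases(m)
    for (b in seq_len(nrow(m$exons))) {
      writeLines(sprintf(
        "%s\tAUGUSTUS\tCDS\t%d\t%d\t.\t%s\t%d\ttranscript_id \"%s\"; gene_id \"%s\";",
        m$transcript_id, m$exons[b, 1L] + 1L, m$exons[b, 2L], m$strand,
        ph[b], tid, m$id), con)
    }
  }
  invisible(path)
}

# Per-segment GFF phase column, walking segments 5'->3' in gene orientation.
.segment_phases <- function(model) {
  widths <- model$exons[, 2L] - model$exons[, 1L]
  n <- length(widths)
  gene_order <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  ph <- integer(n)
  carried <- model$phase
  for (j in gene_order) {
    ph[j] <- carried
    carried <- (3L - ((widths[j] - carried) %% 3L)) %% 3L
  }
  ph
}

#' Write gene models as GFF3
#'
#' Emits a `gene -> mRNA -> CDS` hierarchy per model with the transcript id
#' as seqid, 1-based inclusive coordinates, a correct per-segment phase
#' column (computed 5' to 3' in gene orientation) and `isgap_source`,
#' `isgap_support`, `isgap_score` and `isgap_completeness` attributes, so
#' that `read_gff3(write_gff3(M))` reproduces every model field.
#'
#' @param models List of `gene_model` objects (unique ids).
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  ids <- vapply(models, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate model ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- model_span(m)
    sc <- format(m$score, trim = TRUE)
    writeLines(sprintf("%s\tisgap\tgene\t%d\t%d\t%s\t%s\t.\tID=%s",
                       m$transcript_id, span[1L] + 1L, span[2L], sc,
                       m$strand, m$id), con)
    writeLines(sprintf(
      "%s\tisgap\tmRNA\t%d\t%d\t%s\t%s\t.\tID=%s.m;Parent=%s;isgap_source=%s;isgap_support=%d;isgap_score=%s;isgap_completeness=%s",
      m$transcript_id, span[1L] + 1L, span[2L], sc, m$strand, m$id, m$id,
      m$source, m$support, sc, model_completeness(m)), con)
    ph <- .segment_phases(m)
    for (b in seq_len(nrow(m$exons))) {
      writeLines(sprintf(
        "%s\tisgap\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.m",
        m$transcript_id, m$exons[b, 1L] + 1L, m$exons[b, 2L], m$strand,
        ph[b], m$id, m$id), con)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3 written by [write_gff3()]
#'
#' @param path Path to the GFF3 file.
#' @return List of `gene_model` objects.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  meta <- list()   # per mRNA id
  cds <- list()    # per mRNA id
  order_seen <- character()
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    at <- .parse_flex_attrs(f[9L])
    if (f[3L] == "mRNA") {
      mid <- at[["ID"]]
      gid <- at[["Parent"]]
      meta[[mid]] <- list(
        id = gid, transcript_id = f[1L], strand = f[7L],
        source = at[["isgap_source"]],
        support = as.integer(at[["isgap_support"]]),
        score = as.numeric(at[["isgap_score"]]),
        completeness = at[["isgap_completeness"]])
      order_seen <- c(order_seen, mid)
    } else if (f[3L] == "CDS") {
      mid <- at[["Parent"]]
      cds[[mid]] <- c(cds[[mid]], list(list(
        start = as.integer(f[4L]) - 1L, end = as.integer(f[5L]),
        phase = as.integer(f[8L]))))
    }
  }
  lapply(order_seen, function(mid) {
    info <- meta[[mid]]
    segs <- cds[[mid]]
    exons <- cbind(vapply(segs, `[[`, 0L, "start"),
                   vapply(segs, `[[`, 0L, "end"))
    o <- order(exons[, 1L])
    exons <- exons[o, , drop = FALSE]
    phases <- vapply(segs, `[[`, 0L, "phase")[o]
    ph <- if (info$strand == "+") phases[1L] else phases[length(phases)]
    gene_model(info$id, info$transcript_id, info$strand, exons, phase = ph,
               has_start = info$completeness %in% c("complete", "partial3"),
               has_stop = info$completeness %in% c("complete", "partial5"),
               source = info$source, support = info$support,
               score = info$score)
  })
}

#' Write the spliced CDS (or its translation) of gene models as FASTA
#'
#' @param models List of `gene_model` objects.
#' @param transcripts Named character vector of transcript sequences.
#' @param path Output path.
#' @export
write_cds_fasta <- function(models, transcripts, path) {
  seqs <- vapply(models, cds_of, "", transcripts = transcripts)
  names(seqs) <- vapply(models, `[[`, "", "id")
  write_fasta(seqs, path)
}

#' @rdname write_cds_fasta
#' @export
write_protein_fasta <- function(models, transcripts, path) {
  seqs <- vapply(models, function(m) {
    aa <- translate_dna(cds_of(m, transcripts), m$phase)
    sub("\\*$", "", aa)
  }, "")
  names(seqs) <- vapply(models, `[[`, "", "id")
  write_fasta(seqs, path)
}

#' Read variants from a VCF file
#'
#' CHROM is interpreted as a transcript id. Multi-allelic sites are split
#' into one record per ALT allele; the variant type is derived from the
#' REF/ALT lengths (SNP, INS, DEL). Depth is taken from the `DP` INFO key
#' when present.
#'
#' @param path Path to a VCF 4.x file.
#' @param transcripts Optional named character vector; records on unknown
#'   transcripts are dropped with a warning.
#' @return `data.frame` with columns `transcript_id`, `pos` (0-based),
#'   `ref`, `alt`, `vtype`, `depth`, `qual`.
#' @export
read_vcf <- function(path, transcripts = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  rows <- list()
  for (i in seq_len(nrow(fx))) {
    chrom <- fx[i, "CHROM"]
    if (!is.null(transcripts) && !(chrom %in% names(transcripts))) {
      warning("variant on unknown transcript '", chrom, "' dropped")
      next
    }
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1L]]
    info <- fx[i, "INFO"]
    dp <- NA_integer_
    m <- regmatches(info, regexec("(?:^|;)DP=(\\d+)", info))[[1L]]
    if (length(m) == 2L) dp <- as.integer(m[2L])
    for (alt in alts) {
      ref <- fx[i, "REF"]
      vtype <- if (nchar(alt) > nchar(ref)) "INS"
               else if (nchar(alt) < nchar(ref)) "DEL"
               else "SNP"
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = chrom, pos = as.integer(fx[i, "POS"]) - 1L,
        ref = ref, alt = alt, vtype = vtype, depth = dp,
        qual = suppressWarnings(as.numeric(fx[i, "QUAL"])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), depth = integer(),
                      qual = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' @param variants `data.frame` as returned by [read_vcf()].
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d",
                       variants$transcript_id, variants$pos + 1L,
                       variants$ref, variants$alt,
                       format(variants$qual, trim = TRUE), variants$depth),
               con)
  }
  invisible(path)
}
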