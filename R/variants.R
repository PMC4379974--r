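# Variant classification by transcript region, and marker-grade
# confirmation of variants by bi-directional k-mer flank matching between
# two assemblies.

#' Classify variants by transcript region
#'
#' Each variant's REF span is intersected with the final gene models on
#' its transcript: `exon` when it touches any exon block, `intron` when it
#' touches only intron gaps of gene models, `others` otherwise (precedence
#' exon > intron > others, so a span straddling a boundary counts as exon).
#' Variants on transcripts absent from the gene-model set's assembly are
#' dropped with a warning.
#'
#' @param variants `data.frame` as returned by [read_vcf()].
#' @param models List of `gene_model` objects (the final gene set).
#' @param transcripts Optional named character vector; variants on unknown
#'   transcripts are dropped.
#' @return The variant `data.frame` with a `region` column added.
#' @export
classify_variant_regions <- function(variants, models, transcripts = NULL) {
  if (!is.null(transcripts)) {
    unknown <- !(variants$transcript_id %in% names(transcripts))
    if (any(unknown)) {
      warning(sprintf("%d variant(s) on unknown transcripts dropped",
                      sum(unknown)))
      variants <- variants[!unknown, , drop = FALSE]
    }
  }
  tx_of <- vapply(models, `[[`, "", "transcript_id")
  region <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v_lo <- variants$pos[i]
    v_hi <- v_lo + nchar(variants$ref[i])
    reg <- "others"
    for (m in models[tx_of == variants$transcript_id[i]]) {
      ex <- m$exons
      if (any(ex[, 1L] < v_hi & v_lo < ex[, 2L])) {
        reg <- "exon"
        break
      }
      j <- model_junctions(m)
      if (nrow(j) > 0L && any(j[, 1L] < v_hi & v_lo < j[, 2L])) {
        reg <- "intron"
      }
    }
    region[i] <- reg
  }
  variants$region <- region
  variants
}

.hamming_le <- function(a, b, max_mm) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (max_mm == 0L) return(a == b)
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]) <= max_mm
}

#' Confirm variants by bi-directional k-mer flank matching
#'
#' For each variant, the k-mer immediately 5' and the k-mer immediately 3'
#' of its REF span are extracted from assembly A. The variant is confirmed
#' when both k-mers occur, in order, within a single transcript of
#' assembly B separated by a gap whose sequence equals the ALT allele
#' (toggle with `require_alt`). Matching is exact by default
#' (`max_mismatch` relaxes it). A flank pair found at more than one
#' location is flagged `ambiguous` and not confirmed; variants within k nt
#' of a transcript end are flagged `unconfirmable`.
#'
#' @param variants `data.frame` of variants called on assembly A.
#' @param assembly_a,assembly_b Named character vectors of transcript
#'   sequences.
#' @param k Flank length in nt (default 50).
#' @param require_alt Require the gap between the flanks to equal the ALT
#'   allele (default TRUE); otherwise any gap of the ALT's length matches.
#' @param max_mismatch Mismatches tolerated per flank (default 0).
#' @return The variant `data.frame` with `confirmed` (logical) and
#'   `confirm_flag` (`ok`, `no_match`, `ambiguous`, `unconfirmable`)
#'   columns added.
#' @export
confirm_flanks <- function(variants, assembly_a, assembly_b, k = 50L,
                           require_alt = TRUE, max_mismatch = 0L) {
  b_set <- Biostrings::DNAStringSet(assembly_b)
  confirmed <- logical(nrow(variants))
  flag <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    aseq <- assembly_a[[variants$transcript_id[i]]]
    if (is.null(aseq)) {
      flag[i] <- "unconfirmable"
      next
    }
    pos <- variants$pos[i]
    ref_len <- nchar(variants$ref[i])
    alt <- variants$alt[i]
    if (pos < k || pos + ref_len + k > nchar(aseq)) {
      flag[i] <- "unconfirmable"
      next
    }
    left <- substr(aseq, pos - k + 1L, pos)
    right <- substr(aseq, pos + ref_len + 1L, pos + ref_len + k)
    hits <- 0L
    lhits <- Biostrings::vmatchPattern(left, b_set,
                                       max.mismatch = max_mismatch)
    for (t in seq_along(lhits)) {
      starts <- Biostrings::startIndex(lhits)[[t]]
      if (is.null(starts) || length(starts) == 0L) next
      bseq <- as.character(b_set[[t]])
      for (s in starts) {
        gap_start <- s + k
        gap <- substr(bseq, gap_start, gap_start + nchar(alt) - 1L)
        right_at <- substr(bseq, gap_start + nchar(alt),
                           gap_start + nchar(alt) + k - 1L)
        if (nchar(right_at) < k) next
        gap_ok <- if (require_alt) gap == alt else nchar(gap) == nchar(alt)
        if (gap_ok && .hamming_le(right_at, right, max_mismatch)) {
          hits <- hits + 1L
        }
      }
    }
    if (hits == 1L) {
      confirmed[i] <- TRUE
      flag[i] <- "ok"
    } else if (hits > 1L) {
      flag[i] <- "ambiguous"
    } else {
      flag[i] <- "no_match"
    }
  }
  variants$confirmed <- confirmed
  variants$confirm_flag <- flag
  variants
}

#' Tabulate classified variants
#'
#' Counts SNPs and InDels per region (exon, intron, others) for the whole
#' variant set and for the confirmed subset, with row and column sums.
#'
#' @param classified `data.frame` from [classify_variant_regions()] (and
#'   optionally [confirm_flanks()]).
#' @return `data.frame` with rows `SNPs`, `INDELs`, `Total` and columns
#'   `<whole|confirmed>_<exon|intron|others|sum>`.
#' @export
variant_summary <- function(classified) {
  regions <- c("exon", "intron", "others")
  is_snp <- classified$vtype == "SNP"
  confirmed <- if ("confirmed" %in% names(classified)) {
    classified$confirmed
  } else {
    rep(FALSE, nrow(classified))
  }
  count <- function(mask) {
    vapply(regions, function(r) {
      sum(mask & classified$region == r)
    }, 0L)
  }
  rows <- list(SNPs = is_snp, INDELs = !is_snp,
               Total = rep(TRUE, nrow(classified)))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    w <- count(rows[[nm]])
    cf <- count(rows[[nm]] & confirmed)
    data.frame(class = nm,
               whole_exon = w[["exon"]], whole_intron = w[["intron"]],
               whole_others = w[["others"]], whole_sum = sum(w),
               confirmed_exon = cf[["exon"]],
               confirmed_intron = cf[["intron"]],
               confirmed_others = cf[["others"]], confirmed_sum = sum(cf),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
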