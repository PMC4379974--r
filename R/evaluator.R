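# Validation of predicted gene sets against reference-protein alignment
# regions, scored per query codon with the matched region, strand and
# frame all required to agree.

#' Select strict query regions from reference-protein alignments
#'
#' Keeps alignments with percent score >= `min_percent` and query coverage
#' >= `min_cov` that carry neither a frameshift nor an early-stop flag.
#' Redundancy is allowed: one protein may yield many query regions across
#' transcripts, and regions are never deduplicated.
#'
#' @param alignments List of [protein_alignment()] records.
#' @param min_percent Minimum percent score (default 70).
#' @param min_cov Minimum query coverage fraction (default 0.9).
#' @return List of query-region records: the retained alignments with a
#'   `query_id` and a `multiexon` flag added.
#' @export
select_query_regions <- function(alignments, min_percent = 70,
                                 min_cov = 0.9) {
  kept <- Filter(function(r) {
    r$percent >= min_percent && r$query_cov >= min_cov &&
      !r$frameshift && !r$earlystop
  }, alignments)
  lapply(seq_along(kept), function(i) {
    r <- kept[[i]]
    r$query_id <- sprintf("%s|%s|%d", r$protein_id, r$transcript_id,
                          r$blocks[1L, 1L])
    r$multiexon <- nrow(r$blocks) > 1L
    r
  })
}

# Query codons as a list-free matrix: one row per complete codon, columns
# the three forward-strand positions in gene-sense order.
.query_codons <- function(query) {
  qm <- gene_model("q", query$transcript_id, query$strand, query$blocks,
                   phase = query$phase)
  cp <- .coding_positions(qm)
  cp <- cp[!is.na(cp$codon), , drop = FALSE]
  full <- as.integer(names(which(table(cp$codon) == 3L)))
  cp <- cp[cp$codon %in% full, , drop = FALSE]
  if (nrow(cp) == 0L) return(NULL)
  matrix(cp$pos[order(cp$codon, cp$offset)], ncol = 3L, byrow = TRUE)
}

#' Codon-level representation of a query region by a gene set
#'
#' For each gene on the query's transcript, the coverage is the fraction
#' of the query's codons whose three nucleotides all fall in the gene's
#' CDS, on the same strand, grouped into a single gene codon in the same
#' frame. The best gene is the one with maximal coverage (ties broken by
#' id); `represented` is `coverage >= threshold`.
#'
#' @param query A query-region record from [select_query_regions()].
#' @param genes List of `gene_model` objects.
#' @param threshold Representation threshold (default 0.99).
#' @return One-row `data.frame`: `query_id`, `best_gene_id`, `coverage`,
#'   `represented`, `multiexon`.
#' @export
coverage_of <- function(query, genes, threshold = 0.99) {
  codons <- .query_codons(query)
  best_cov <- 0
  best_id <- ""
  if (!is.null(codons)) {
    cand <- Filter(function(g) {
      g$transcript_id == query$transcript_id && g$strand == query$strand
    }, genes)
    for (g in cand) {
      cp <- .coding_positions(g)
      i1 <- match(codons[, 1L], cp$pos)
      i2 <- match(codons[, 2L], cp$pos)
      i3 <- match(codons[, 3L], cp$pos)
      ok <- !is.na(i1) & !is.na(i2) & !is.na(i3)
      if (any(ok)) {
        c1 <- cp$codon[i1[ok]]; o1 <- cp$offset[i1[ok]]
        c2 <- cp$codon[i2[ok]]; o2 <- cp$offset[i2[ok]]
        c3 <- cp$codon[i3[ok]]; o3 <- cp$offset[i3[ok]]
        hit <- !is.na(c1) & !is.na(c2) & !is.na(c3) &
          c1 == c2 & c2 == c3 & o1 == 0L & o2 == 1L & o3 == 2L
        cov <- sum(hit) / nrow(codons)
      } else {
        cov <- 0
      }
      if (cov > best_cov || (cov == best_cov && cov > 0 && g$id < best_id)) {
        best_cov <- cov
        best_id <- g$id
      }
    }
  }
  data.frame(query_id = query$query_id, best_gene_id = best_id,
             coverage = best_cov, represented = best_cov >= threshold,
             multiexon = isTRUE(query$multiexon), stringsAsFactors = FALSE)
}

#' Score every query region against a gene set
#'
#' @param queries List of query-region records.
#' @param genes List of `gene_model` objects.
#' @param threshold Representation threshold (default 0.99).
#' @return `data.frame` with one row per query.
#' @export
evaluate_gene_set <- function(queries, genes, threshold = 0.99) {
  if (length(queries) == 0L) {
    return(data.frame(query_id = character(), best_gene_id = character(),
                      coverage = numeric(), represented = logical(),
                      multiexon = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(queries, coverage_of, genes = genes,
                        threshold = threshold))
}

.summary_row <- function(results, label) {
  n <- nrow(results)
  rep_n <- sum(results$represented)
  data.frame(
    subset = label, n_queries = n, n_represented = rep_n,
    pct_represented = if (n > 0L) 100 * rep_n / n else 0,
    n_genes = length(unique(
      results$best_gene_id[results$represented &
                             nzchar(results$best_gene_id)])),
    stringsAsFactors = FALSE)
}

#' Summarize a validation run
#'
#' Reports, overall and for the multi-exon query subset, the number of
#' query regions, the number and percentage represented, and the number
#' of distinct representing genes. In side-by-side mode (two result sets
#' for the same queries) it additionally reports the disagreement
#' breakdown: queries represented by one gene set but not the other, with
#' the distinct genes involved - the queries where the two gene sets do
#' not cover the same mapped regions.
#'
#' @param results `data.frame` from [evaluate_gene_set()].
#' @param results2 Optional second result set for the same queries.
#' @return List with `overall` (and, in side-by-side mode, `difference`)
#'   data frames.
#' @export
summarize_validation <- function(results, results2 = NULL) {
  overall <- rbind(.summary_row(results, "all"),
                   .summary_row(results[results$multiexon, , drop = FALSE],
                                "multiexon"))
  out <- list(overall = overall)
  if (!is.null(results2)) {
    stopifnot(identical(results$query_id, results2$query_id))
    differ <- results$represented != results2$represented
    d1 <- results[differ & results$represented, , drop = FALSE]
    d2 <- results2[differ & results2$represented, , drop = FALSE]
    out$difference <- data.frame(
      gene_set = c("set1", "set2"),
      n_queries_exclusive = c(nrow(d1), nrow(d2)),
      n_genes = c(length(unique(d1$best_gene_id)),
                  length(unique(d2$best_gene_id))),
      stringsAsFactors = FALSE)
  }
  out
}
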