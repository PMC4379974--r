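# Step 1: candidate gene structures from spliced protein alignments,
# junction-consensus merging, frameshift/early-stop filtering, and
# same-region overlap resolution.

# Reading-frame class of a single-exon structure, anchored so that two
# overlapping structures in the same class translate the same codons. For
# plus-strand structures this is (start + phase) mod 3; minus-strand frames
# are anchored at the forward-strand 3' end of the transcript.
.single_exon_frame <- function(start, end, phase, strand, tx_len) {
  if (strand == "+") (start + phase) %% 3L else (tx_len - end + phase) %% 3L
}

.junction_key <- function(model, transcripts) {
  j <- model_junctions(model)
  if (nrow(j) == 0L) {
    L <- nchar(.tx_seq(transcripts, model$transcript_id))
    f <- .single_exon_frame(model$exons[1L, 1L], model$exons[1L, 2L],
                            model$phase, model$strand, L)
    paste(model$transcript_id, model$strand, "SE", f, sep = "|")
  } else {
    paste(model$transcript_id, model$strand,
          paste(sprintf("%d-%d", j[, 1L], j[, 2L]), collapse = ";"),
          sep = "|")
  }
}

#' Build candidate gene structures from protein alignments
#'
#' One candidate model per retained alignment: alignments below the percent
#' threshold, or with an implied intron longer than `max_intron`, are
#' dropped (counts reported as a message). Completeness flags are computed
#' from the spliced CDS.
#'
#' @param records List of [protein_alignment()] records.
#' @param transcripts Named character vector of transcript sequences.
#' @param min_percent Minimum alignment percent score (default 30).
#' @param max_intron Maximum implied intron length in nt (default 50000).
#' @return List of `gene_model` objects with `source = "evidence"`,
#'   `support = 1`.
#' @export
structures_from_alignments <- function(records, transcripts,
                                       min_percent = 30,
                                       max_intron = 50000L) {
  n_pct <- 0L
  n_intron <- 0L
  out <- list()
  for (r in records) {
    if (r$percent < min_percent) {
      n_pct <- n_pct + 1L
      next
    }
    if (nrow(r$blocks) > 1L) {
      gaps <- r$blocks[-1L, 1L] - r$blocks[-nrow(r$blocks), 2L]
      if (any(gaps > max_intron)) {
        n_intron <- n_intron + 1L
        next
      }
    }
    m <- gene_model(sprintf("ev%05d", length(out) + 1L), r$transcript_id,
                    r$strand, r$blocks, phase = r$phase,
                    source = "evidence", support = 1L, score = r$raw_score,
                    proteins = r$protein_id)
    out[[length(out) + 1L]] <- set_completeness_flags(m, transcripts)
  }
  if (n_pct + n_intron > 0L) {
    message(sprintf("structures_from_alignments: dropped %d below percent threshold, %d with overlong introns",
                    n_pct, n_intron))
  }
  out
}

# Majority vote over one terminal boundary; ties go to the outermost value
# (minimum for a start boundary, maximum for an end boundary).
.consensus_boundary <- function(values, outermost) {
  tab <- table(values)
  best <- as.integer(names(tab)[tab == max(tab)])
  outermost(best)
}

#' Merge gene structures sharing identical exon-exon junction sets
#'
#' Structures on the same transcript and strand with the same ordered
#' (donor, acceptor) junction list collapse to one consensus model: internal
#' boundaries are the shared junctions by construction, and each terminal
#' boundary is the one supported by the most contributing alignments (ties
#' broken by the outermost, i.e. longer, boundary). Single-exon structures
#' carry no junctions; they are merged when they overlap on the same
#' transcript and strand in the same reading frame. Support becomes the
#' number of distinct contributing proteins and the score the sum of
#' contributing scores.
#'
#' @param models List of `gene_model` objects (from
#'   [structures_from_alignments()]).
#' @param transcripts Named character vector of transcript sequences.
#' @return List of `gene_model` objects with `source = "merged"`.
#' @export
merge_same_junctions <- function(models, transcripts) {
  if (length(models) == 0L) return(list())
  keys <- vapply(models, .junction_key, "", transcripts = transcripts)
  out <- list()
  for (key in unique(keys)) {
    group <- models[keys == key]
    single <- nrow(group[[1L]]$exons) == 1L
    clusters <- if (single) .overlap_clusters(group) else list(group)
    for (cl in clusters) {
      m <- .merge_cluster(cl, sprintf("mg%05d", length(out) + 1L))
      out[[length(out) + 1L]] <- set_completeness_flags(m, transcripts)
    }
  }
  out
}

# Transitive single-nucleotide span-overlap clusters of a model list
# (assumed same transcript/strand).
.overlap_clusters <- function(models) {
  spans <- t(vapply(models, model_span, integer(2L)))
  o <- order(spans[, 1L], spans[, 2L])
  clusters <- list()
  cur <- integer()
  cur_end <- -1L
  for (i in o) {
    if (length(cur) > 0L && spans[i, 1L] >= cur_end) {
      clusters[[length(clusters) + 1L]] <- models[cur]
      cur <- integer()
      cur_end <- -1L
    }
    cur <- c(cur, i)
    cur_end <- max(cur_end, spans[i, 2L])
  }
  if (length(cur) > 0L) clusters[[length(clusters) + 1L]] <- models[cur]
  clusters
}

.merge_cluster <- function(group, new_id) {
  proto <- group[[1L]]
  starts <- vapply(group, function(m) m$exons[1L, 1L], 0L)
  ends <- vapply(group, function(m) m$exons[nrow(m$exons), 2L], 0L)
  cons_start <- .consensus_boundary(starts, min)
  cons_end <- .consensus_boundary(ends, max)
  # adopt the phase of the contributors owning the consensus 5' boundary
  fivep <- if (proto$strand == "+") starts else ends
  cons_fivep <- if (proto$strand == "+") cons_start else cons_end
  owners <- group[fivep == cons_fivep]
  phases <- vapply(owners, `[[`, 0L, "phase")
  ph <- .consensus_boundary(phases, min)
  j <- model_junctions(proto)
  if (nrow(j) == 0L) {
    exons <- cbind(cons_start, cons_end)
  } else {
    exons <- cbind(c(cons_start, j[, 2L]), c(j[, 1L], cons_end))
  }
  proteins <- unique(unlist(lapply(group, `[[`, "proteins")))
  gene_model(new_id, proto$transcript_id, proto$strand, exons, phase = ph,
             source = "merged",
             support = max(1L, length(proteins)),
             score = sum(vapply(group, `[[`, 0, "score")),
             proteins = proteins)
}

#' Remove gene models with frameshifts or premature stop codons
#'
#' A model is removed when the translation of its spliced CDS contains a
#' stop before its final codon, when any inter-exon gap is too short to be
#' a plausible intron and is not a multiple of 3 (a frameshift), or when a
#' model flagged complete has a CDS length inconsistent with a whole number
#' of codons.
#'
#' @param models List of `gene_model` objects.
#' @param transcripts Named character vector of transcript sequences.
#' @param min_intron Minimum plausible intron length in nt (default 20).
#' @return Filtered list; removal counts are reported as a message.
#' @export
filter_invalid_cds <- function(models, transcripts, min_intron = 20L) {
  keep <- vapply(models, function(m) {
    if (has_internal_stop(m, transcripts)) return(FALSE)
    j <- model_junctions(m)
    if (nrow(j) > 0L) {
      gaps <- j[, 2L] - j[, 1L]
      if (any(gaps < min_intron & gaps %% 3L != 0L)) return(FALSE)
    }
    if (m$has_start && m$has_stop &&
        (model_cds_length(m) - m$phase) %% 3L != 0L) {
      return(FALSE)
    }
    TRUE
  }, NA)
  if (any(!keep)) {
    message(sprintf("filter_invalid_cds: removed %d of %d models",
                    sum(!keep), length(models)))
  }
  models[keep]
}

#' Keep one gene model per overlapping same-region cluster
#'
#' Within each transcript (and strand, unless `strandless`), models are
#' clustered by transitive single-nucleotide span overlap; in each cluster
#' exactly one model is kept, ranked by evidence support (descending), then
#' mapping score, then CDS length, then id. The output contains no
#' same-strand overlapping pair on any transcript.
#'
#' @param models List of `gene_model` objects.
#' @param strandless Cluster across strands (default FALSE).
#' @return Filtered list of `gene_model` objects.
#' @export
resolve_overlaps <- function(models, strandless = FALSE) {
  if (length(models) <= 1L) return(models)
  keys <- vapply(models, function(m) {
    if (strandless) m$transcript_id else paste(m$transcript_id, m$strand)
  }, "")
  out <- list()
  for (key in unique(keys)) {
    for (cl in .overlap_clusters(models[keys == key])) {
      out[[length(out) + 1L]] <- .rank_models(cl)[[1L]]
    }
  }
  out
}

# support desc, score desc, CDS length desc, id asc
.rank_models <- function(models) {
  sup <- vapply(models, `[[`, 0L, "support")
  sc <- vapply(models, `[[`, 0, "score")
  len <- vapply(models, model_cds_length, 0L)
  id <- vapply(models, `[[`, "", "id")
  models[order(-sup, -sc, -len, id)]
}
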