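# Steps 3-4: training-set export, ab initio filtering, evidence / ab initio
# integration, final filter hook, representative selection per locus, and
# gene-set statistics.

# Run fn with a private, seeded RNG stream; restores the caller's stream.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Select complete gene models for an external trainer
#'
#' Samples `n` complete models, deterministically for a given seed, with
#' ranked weights preferring multi-exon models and longer CDS (an external
#' ab initio trainer benefits most from spliced, full-length examples).
#' Falls back to all complete models, with a warning, when fewer than `n`
#' exist.
#'
#' @param models List of `gene_model` objects (Step 2 output).
#' @param n Number of training genes (default 2000).
#' @param seed Integer seed for the sampling.
#' @return List of complete `gene_model` objects.
#' @export
select_training_genes <- function(models, n = 2000L, seed = 1L) {
  complete <- Filter(function(m) m$has_start && m$has_stop, models)
  if (length(complete) == 0L) stop("no complete gene models to train from")
  if (length(complete) <= n) {
    if (length(complete) < n) {
      warning(sprintf("only %d complete models available (requested %d)",
                      length(complete), n))
    }
    return(complete)
  }
  w <- vapply(complete, function(m) {
    (1 + (nrow(m$exons) > 1L)) * model_cds_length(m)
  }, 0)
  idx <- with_seed(seed, function() {
    sample.int(length(complete), n, prob = w)
  })
  complete[sort(idx)]
}

#' Filter abnormal ab initio gene models
#'
#' Removes models with internal in-frame stop codons, a CDS shorter than
#' `min_cds` nt, exons out of transcript bounds, or a CDS length
#' inconsistent with the declared phase and completeness flags.
#'
#' @param models List of `gene_model` objects (`source = "abinitio"`).
#' @param transcripts Named character vector of transcript sequences.
#' @param min_cds Minimum CDS length in nt (default 150).
#' @return Filtered list.
#' @export
filter_abnormal_abinitio <- function(models, transcripts, min_cds = 150L) {
  keep <- vapply(models, function(m) {
    if (!(m$transcript_id %in% names(transcripts))) return(FALSE)
    L <- nchar(transcripts[[m$transcript_id]])
    if (any(m$exons[, 1L] < 0L) || any(m$exons[, 2L] > L)) return(FALSE)
    len <- model_cds_length(m)
    if (len < min_cds) return(FALSE)
    if (m$has_start && m$phase != 0L) return(FALSE)
    if (m$has_start && m$has_stop && (len - m$phase) %% 3L != 0L) {
      return(FALSE)
    }
    if (has_internal_stop(m, transcripts)) return(FALSE)
    TRUE
  }, NA)
  if (any(!keep)) {
    message(sprintf("filter_abnormal_abinitio: removed %d of %d models",
                    sum(!keep), length(models)))
  }
  models[keep]
}

# Forward positions of a model's coding nucleotides in gene-sense order,
# with the per-position codon index/offset implied by the model's phase.
# Returns a data.frame(pos, codon, offset); positions before the first
# complete codon carry codon = NA.
.coding_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    seq.int(model$exons[i, 1L], model$exons[i, 2L] - 1L)
  }))
  if (model$strand == "-") pos <- rev(pos)
  idx <- seq_along(pos) - 1L
  codon <- ifelse(idx >= model$phase, (idx - model$phase) %/% 3L, NA_integer_)
  offset <- ifelse(idx >= model$phase, (idx - model$phase) %% 3L, NA_integer_)
  data.frame(pos = pos, codon = codon, offset = offset)
}

# Frame compatibility of two overlapping models: at every forward position
# coded by both, the codon offsets must agree.
.frames_compatible <- function(a, b) {
  ca <- .coding_positions(a)
  cb <- .coding_positions(b)
  i <- match(ca$pos, cb$pos)
  shared <- !is.na(i)
  if (!any(shared)) return(FALSE)
  offa <- ca$offset[shared]
  offb <- cb$offset[i[shared]]
  ok <- !is.na(offa) & !is.na(offb)
  any(ok) && all(offa[ok] == offb[ok])
}

# Junction sets restricted to the shared span must be identical.
.junctions_compatible <- function(a, b) {
  sa <- model_span(a)
  sb <- model_span(b)
  lo <- max(sa[1L], sb[1L])
  hi <- min(sa[2L], sb[2L])
  ja <- model_junctions(a)
  jb <- model_junctions(b)
  ina <- ja[ja[, 1L] >= lo & ja[, 2L] <= hi, , drop = FALSE]
  inb <- jb[jb[, 1L] >= lo & jb[, 2L] <= hi, , drop = FALSE]
  nrow(ina) == nrow(inb) && all(ina == inb)
}

# Interval union of two exon sets (compatible structures assumed).
.union_exons <- function(a, b) {
  all_ex <- rbind(a, b)
  all_ex <- all_ex[order(all_ex[, 1L]), , drop = FALSE]
  out <- all_ex[1L, , drop = FALSE]
  for (i in seq_len(nrow(all_ex))[-1L]) {
    if (all_ex[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], all_ex[i, 2L])
    } else {
      out <- rbind(out, all_ex[i, , drop = FALSE])
    }
  }
  out
}

#' Integrate evidence-based and ab initio gene models
#'
#' Evidence models are the backbone. An ab initio model overlapping exactly
#' one evidence model on the same transcript and strand, with an identical
#' junction set inside the shared span and a compatible reading frame,
#' extends that evidence model to the interval union of both exon sets
#' (`source = "merged"`, support retained). A conflicting overlap (different
#' junctions in the shared span, incompatible frame, or overlap with more
#' than one evidence model - bridging is not performed) discards the ab
#' initio model; ab initio models overlapping no evidence model are added
#' unchanged. A final overlap-resolution pass guarantees the same-strand
#' non-overlap invariant.
#'
#' @param evidence_models List of `gene_model` objects (Step 2 output).
#' @param abinitio_models List of filtered ab initio `gene_model` objects.
#' @param transcripts Named character vector of transcript sequences.
#' @return Integrated list of `gene_model` objects.
#' @export
integrate_models <- function(evidence_models, abinitio_models, transcripts) {
  evid <- evidence_models
  added <- list()
  ev_key <- vapply(evid, function(m) paste(m$transcript_id, m$strand), "")
  for (ab in abinitio_models) {
    key <- paste(ab$transcript_id, ab$strand)
    span_ab <- model_span(ab)
    hits <- which(ev_key == key & vapply(evid, function(m) {
      s <- model_span(m)
      s[1L] < span_ab[2L] && span_ab[1L] < s[2L]
    }, NA))
    if (length(hits) == 0L) {
      added[[length(added) + 1L]] <- ab
    } else if (length(hits) == 1L) {
      ev <- evid[[hits]]
      if (.junctions_compatible(ev, ab) && .frames_compatible(ev, ab)) {
        evid[[hits]] <- .extend_with_abinitio(ev, ab, transcripts)
      }
      # conflicting ab initio model: discarded
    }
    # >1 evidence hit: bridging not performed; discarded
  }
  resolve_overlaps(c(evid, added))
}

.extend_with_abinitio <- function(ev, ab, transcripts) {
  exons <- .union_exons(ev$exons, ab$exons)
  # preserve the evidence frame: recompute the phase so that the first
  # coding nucleotide of the old evidence CDS keeps its codon offset
  p0 <- if (ev$strand == "+") ev$exons[1L, 1L] else ev$exons[nrow(ev$exons), 2L] - 1L
  new <- gene_model(ev$id, ev$transcript_id, ev$strand, exons, phase = 0L,
                    source = "merged", support = ev$support,
                    score = ev$score, proteins = ev$proteins)
  cp <- .coding_positions(new)
  idx0 <- which(cp$pos == p0) - 1L  # spliced gene-sense index of p0
  new$phase <- as.integer((idx0 + ev$phase) %% 3L)
  set_completeness_flags(new, transcripts)
}

#' Apply the final gene-model filter
#'
#' A pluggable hook standing in for an external homology screen: the
#' default predicate accepts every model; alternatively models are kept
#' when their id appears in a hit-list file (one id per line).
#'
#' @param models List of `gene_model` objects.
#' @param predicate Function `model -> logical`, or NULL.
#' @param hitlist Optional path to a file of retained model ids.
#' @return Filtered list; removal counts are reported as a message.
#' @export
final_filter <- function(models, predicate = NULL, hitlist = NULL) {
  if (!is.null(hitlist)) {
    if (!file.exists(hitlist)) stop("hit-list file not found: ", hitlist)
    ids <- readLines(hitlist)
    ids <- trimws(ids[nzchar(trimws(ids))])
    if (length(ids) == 0L) {
      warning("empty hit-list: all models removed")
    }
    predicate <- function(m) m$id %in% ids
  }
  if (is.null(predicate)) return(models)
  keep <- vapply(models, function(m) isTRUE(predicate(m)), NA)
  if (any(!keep)) {
    message(sprintf("final_filter: removed %d of %d models",
                    sum(!keep), length(models)))
  }
  models[keep]
}

#' Select one representative gene model per locus
#'
#' Loci are clusters of mutually overlapping models (transitive span
#' overlap on one transcript and strand). Each locus contributes exactly
#' one representative: the longest (CDS nt) complete model when any
#' complete model exists, otherwise the longest partial; ties broken by
#' higher support, then id.
#'
#' @param models List of `gene_model` objects.
#' @return List with one `gene_model` per locus.
#' @export
select_representatives <- function(models) {
  if (length(models) == 0L) return(list())
  keys <- vapply(models, function(m) paste(m$transcript_id, m$strand), "")
  out <- list()
  for (key in unique(keys)) {
    for (cl in .overlap_clusters(models[keys == key])) {
      complete <- Filter(function(m) m$has_start && m$has_stop, cl)
      pool <- if (length(complete) > 0L) complete else cl
      len <- vapply(pool, model_cds_length, 0L)
      sup <- vapply(pool, `[[`, 0L, "support")
      id <- vapply(pool, `[[`, "", "id")
      out[[length(out) + 1L]] <- pool[[order(-len, -sup, id)[1L]]]
    }
  }
  out
}

#' Summary statistics for a gene set
#'
#' @param models List of `gene_model` objects.
#' @return `data.frame` with one row: gene count, multi-exon gene count,
#'   intron count, mean exon/intron lengths (bp), total and mean CDS length
#'   (bp), and a flag marking an undefined mean intron length (no introns).
#' @export
gene_set_stats <- function(models) {
  if (length(models) == 0L) {
    return(data.frame(n_genes = 0L, n_multiexon = 0L, n_introns = 0L,
                      mean_exon_len = 0, mean_intron_len = 0,
                      total_len = 0L, mean_len = 0, no_introns = TRUE))
  }
  n_ex <- vapply(models, function(m) nrow(m$exons), 0L)
  exon_lens <- unlist(lapply(models, function(m) m$exons[, 2L] - m$exons[, 1L]))
  intron_lens <- unlist(lapply(models, function(m) {
    j <- model_junctions(m)
    j[, 2L] - j[, 1L]
  }))
  cds_lens <- vapply(models, model_cds_length, 0L)
  data.frame(
    n_genes = length(models),
    n_multiexon = sum(n_ex > 1L),
    n_introns = sum(n_ex - 1L),
    mean_exon_len = mean(exon_lens),
    mean_intron_len = if (length(intron_lens) > 0L) mean(intron_lens) else 0,
    total_len = sum(cds_lens),
    mean_len = mean(cds_lens),
    no_introns = length(intron_lens) == 0L)
}

#' Run the full annotation pipeline
#'
#' Step 1 builds candidate structures from protein alignments, merges
#' identical junction sets, removes frameshift / early-stop models and
#' resolves same-region overlaps. Step 2 extends partial models in their
#' fixed frame. Step 3 filters ab initio models and integrates them with
#' the evidence backbone. Step 4 applies the final filter hook and selects
#' one representative per locus.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param alignments List of [protein_alignment()] records.
#' @param abinitio List of ab initio `gene_model` objects (may be empty).
#' @param min_percent,max_intron Alignment retention thresholds
#'   (defaults 30 and 50000).
#' @param min_cds Minimum ab initio CDS length (default 150).
#' @param n_training,training_seed Training-set export size and seed.
#' @param predicate,hitlist Final-filter hook (see [final_filter()]).
#' @return List with elements `step1`, `step2`, `training`, `integrated`,
#'   `final`, `representatives`, `stats`.
#' @export
annotate_pipeline <- function(transcripts, alignments, abinitio = list(),
                              min_percent = 30, max_intron = 50000L,
                              min_cds = 150L, n_training = 2000L,
                              training_seed = 1L, predicate = NULL,
                              hitlist = NULL) {
  cand <- structures_from_alignments(alignments, transcripts,
                                     min_percent = min_percent,
                                     max_intron = max_intron)
  merged <- merge_same_junctions(cand, transcripts)
  clean <- filter_invalid_cds(merged, transcripts)
  step1 <- resolve_overlaps(clean)
  step2 <- lapply(step1, extend_partial, transcripts = transcripts)
  training <- tryCatch(
    select_training_genes(step2, n = n_training, seed = training_seed),
    error = function(e) list())
  ab_ok <- filter_abnormal_abinitio(abinitio, transcripts, min_cds = min_cds)
  integrated <- integrate_models(step2, ab_ok, transcripts)
  final <- final_filter(integrated, predicate = predicate, hitlist = hitlist)
  reps <- select_representatives(final)
  list(step1 = step1, step2 = step2, training = training,
       integrated = integrated, final = final, representatives = reps,
       stats = gene_set_stats(final))
}
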