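# Step 2: fixed-frame extension of partial gene models, and the classical
# six-frame translation baseline.

.is_stop <- function(codon) codon %in% STOP_CODONS

# Reflect a model onto the reverse-complemented transcript so minus-strand
# extension can reuse the plus-strand walk. Involution given the length.
.flip_model <- function(model, tx_len) {
  exons <- cbind(tx_len - rev(model$exons[, 2L]),
                 tx_len - rev(model$exons[, 1L]))
  model$exons <- matrix(as.integer(exons), ncol = 2L,
                        dimnames = list(NULL, c("start", "end")))
  model$strand <- if (model$strand == "+") "-" else "+"
  model
}

#' Extend a partial gene model in its fixed reading frame
#'
#' Walks codon-by-codon outward from the 5' and/or 3' end of a partial
#' model, in the model's established frame, without altering any junction.
#' On the 5' side (gene orientation) the first exon is extended to an
#' in-frame `ATG` if one is reached before any in-frame stop; hitting a
#' stop first leaves the boundary unchanged unless the codon immediately
#' downstream of the stop is itself `ATG`. On the 3' side the model is
#' extended through the first in-frame stop codon; reaching the transcript
#' end without one extends to the last full codon with `has_stop = FALSE`.
#' Codons containing `N` translate to `X` and never block the walk.
#' Complete models are returned unchanged; the translation of the original
#' CDS is always a substring of the extended translation.
#'
#' @param model A `gene_model`.
#' @param transcripts Named character vector of transcript sequences.
#' @return The (possibly) extended model; `source = "extended"` when a
#'   boundary or flag changed.
#' @export
extend_partial <- function(model, transcripts) {
  if (model$has_start && model$has_stop) return(model)
  seq <- .tx_seq(transcripts, model$transcript_id)
  L <- nchar(seq)
  if (model$strand == "-") {
    flipped <- .flip_model(model, L)
    ext <- .extend_plus(flipped, revcomp(seq), L)
    out <- .flip_model(ext, L)
    out$strand <- "-"
    return(out)
  }
  .extend_plus(model, seq, L)
}

.extend_plus <- function(model, seq, L) {
  changed <- FALSE
  n_ex <- nrow(model$exons)
  codon_at <- function(p) substr(seq, p + 1L, p + 3L)

  if (!model$has_start) {
    anchor <- model$exons[1L, 1L] + model$phase  # first complete codon
    k <- 1L
    repeat {
      cs <- anchor - 3L * k
      if (cs < 0L) break
      cod <- codon_at(cs)
      if (cod == START_CODON) {
        model$exons[1L, 1L] <- cs
        model$phase <- 0L
        model$has_start <- TRUE
        changed <- TRUE
        break
      }
      if (.is_stop(cod)) {
        after <- cs + 3L
        if (codon_at(after) == START_CODON && after < model$exons[1L, 1L]) {
          model$exons[1L, 1L] <- after
          model$phase <- 0L
          model$has_start <- TRUE
          changed <- TRUE
        }
        break
      }
      k <- k + 1L
    }
  }

  if (!model$has_stop) {
    cds_len <- model_cds_length(model)
    tail_nt <- (cds_len - model$phase) %% 3L
    e_last <- model$exons[n_ex, 2L]
    cs <- e_last - tail_nt  # start of the first codon crossing/after the end
    repeat {
      if (cs + 3L > L) {
        # no stop before the transcript end: extend to the last full codon
        new_end <- cs
        if (new_end > e_last) {
          model$exons[n_ex, 2L] <- new_end
          changed <- TRUE
        }
        break
      }
      if (.is_stop(codon_at(cs))) {
        model$exons[n_ex, 2L] <- cs + 3L
        model$has_stop <- TRUE
        changed <- TRUE
        break
      }
      cs <- cs + 3L
    }
  }

  if (changed) model$source <- "extended"
  model
}

#' Enumerate open reading frames in all six frames
#'
#' For every strand and frame offset, a complete ORF runs from the first
#' in-frame `ATG` following the previous stop (or the frame start) through
#' the next in-frame stop codon, inclusive. When a frame contains no
#' complete ORF, the open stretch from the frame start (or the position
#' after its last stop) to the last full codon qualifies as a partial ORF.
#' Coordinates are 0-based half-open on the forward strand; `aa_length`
#' excludes the stop codon.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param min_aa Minimum ORF length in amino acids (default 100).
#' @param mode `"longest"` (single longest ORF per transcript) or `"all"`.
#' @param require_start,require_stop Drop ORFs lacking an `ATG` start /
#'   a stop codon (defaults FALSE).
#' @return `data.frame` with columns `transcript_id`, `strand`, `frame`,
#'   `start`, `end`, `has_start`, `has_stop`, `aa_length`.
#' @export
six_frame_orfs <- function(transcripts, min_aa = 100L,
                           mode = c("longest", "all"),
                           require_start = FALSE, require_stop = FALSE) {
  mode <- match.arg(mode)
  rows <- list()
  for (tid in names(transcripts)) {
    seq <- transcripts[[tid]]
    L <- nchar(seq)
    if (L < 3L) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      for (off in 0:2) {
        aa <- translate_dna(s, off)
        npep <- nchar(aa)
        if (npep == 0L) next
        aav <- strsplit(aa, "", fixed = TRUE)[[1L]]
        stops <- which(aav == "*")
        found_complete <- FALSE
        seg_start <- 1L
        for (j in stops) {
          seg <- seg_start:j
          ms <- seg[aav[seg] == "M" & seg < j]
          if (length(ms) > 0L) {
            m0 <- ms[1L]
            rows[[length(rows) + 1L]] <- .orf_row(
              tid, strand, off, s_start = off + 3L * (m0 - 1L),
              s_end = off + 3L * j, has_start = TRUE, has_stop = TRUE,
              aa_length = j - m0, L = L)
            found_complete <- TRUE
          }
          seg_start <- j + 1L
        }
        if (!found_complete && seg_start <= npep) {
          rows[[length(rows) + 1L]] <- .orf_row(
            tid, strand, off, s_start = off + 3L * (seg_start - 1L),
            s_end = off + 3L * npep,
            has_start = aav[seg_start] == "M", has_stop = FALSE,
            aa_length = npep - seg_start + 1L, L = L)
        }
      }
    }
  }
  orfs <- if (length(rows) == 0L) .empty_orf_df() else do.call(rbind, rows)
  orfs <- orfs[orfs$aa_length >= min_aa, , drop = FALSE]
  if (require_start) orfs <- orfs[orfs$has_start, , drop = FALSE]
  if (require_stop) orfs <- orfs[orfs$has_stop, , drop = FALSE]
  if (mode == "longest" && nrow(orfs) > 0L) {
    o <- order(orfs$transcript_id, -orfs$aa_length,
               orfs$strand, orfs$frame, orfs$start)
    orfs <- orfs[o, , drop = FALSE]
    orfs <- orfs[!duplicated(orfs$transcript_id), , drop = FALSE]
  }
  rownames(orfs) <- NULL
  orfs
}

.orf_row <- function(tid, strand, off, s_start, s_end, has_start, has_stop,
                     aa_length, L) {
  if (strand == "+") {
    fs <- s_start
    fe <- s_end
  } else {
    fs <- L - s_end
    fe <- L - s_start
  }
  data.frame(transcript_id = tid, strand = strand, frame = off,
             start = fs, end = fe, has_start = has_start,
             has_stop = has_stop, aa_length = aa_length,
             stringsAsFactors = FALSE)
}

.empty_orf_df <- function() {
  data.frame(transcript_id = character(), strand = character(),
             frame = integer(), start = integer(), end = integer(),
             has_start = logical(), has_stop = logical(),
             aa_length = integer(), stringsAsFactors = FALSE)
}

#' Six-frame translation gene set
#'
#' Turns each ORF reported by [six_frame_orfs()] into a single-exon
#' `gene_model` (`source = "sixframe"`). By construction this baseline can
#' never emit a multi-exon model, which is exactly why it fails on
#' transcripts with retained introns.
#'
#' @inheritParams six_frame_orfs
#' @param ... Passed to [six_frame_orfs()].
#' @return List of single-exon `gene_model` objects.
#' @export
sixframe_gene_set <- function(transcripts, min_aa = 100L,
                              mode = c("longest", "all"), ...) {
  orfs <- six_frame_orfs(transcripts, min_aa = min_aa,
                         mode = match.arg(mode), ...)
  lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    gene_model(sprintf("sf%05d", i), o$transcript_id, o$strand,
               cbind(o$start, o$end), phase = 0L,
               has_start = o$has_start, has_stop = o$has_stop,
               source = "sixframe", support = 0L, score = o$aa_length)
  })
}
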