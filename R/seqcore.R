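# Core sequence types and codon arithmetic.
#
# All internal coordinates are 0-based, half-open, on the transcript's
# forward strand regardless of gene strand. Minus-strand models store their
# exons in forward-strand ascending order; phase is defined on the spliced,
# strand-corrected CDS. GFF I/O converts to/from 1-based inclusive.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODON <- "ATG"

# Standard genetic code, keyed by unambiguous codon. Codons containing N
# translate to 'X'; 'X' is never a stop and never blocks frame extension.
.codon_table <- Biostrings::GENETIC_CODE

.check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("non-DNA character '%s' in %s at position %d",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' Alphabet is `{A,C,G,T,N}`; `N` self-complements. `revcomp` is an
#' involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq DNA string (uppercase).
#' @return The reverse complement as a character string.
#' @export
#' @examples
#' revcomp("GATTACA")
revcomp <- function(seq) {
  .check_dna(seq)
  if (nchar(seq) == 0L) return("")
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a DNA string in a fixed frame
#'
#' Translates consecutive codons starting at offset `phase` (0, 1 or 2);
#' a trailing 1-2 nt partial codon is ignored. Stop codons are rendered as
#' `*`. Any codon containing `N` translates to `X`, which is never treated
#' as a stop.
#'
#' @param seq DNA string.
#' @param phase Integer offset of the first complete codon (0, 1 or 2).
#' @return Amino-acid string (may be empty).
#' @export
#' @examples
#' translate_dna("ATGGCTTAA")        # "MA*"
#' translate_dna("ATGGCTTAA", 1)     # "WL"
translate_dna <- function(seq, phase = 0L) {
  .check_dna(seq)
  phase <- as.integer(phase)
  stopifnot(phase %in% 0:2)
  n <- nchar(seq)
  if (n - phase < 3L) return("")
  starts <- seq.int(phase + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Construct a gene model
#'
#' A gene model is an ordered set of exon blocks on one transcript, with a
#' strand, the phase of its first complete codon, completeness flags and
#' provenance. Exons are 0-based half-open forward-strand intervals, sorted
#' ascending and pairwise disjoint; gaps between consecutive exons are
#' introns.
#'
#' @param id Unique model identifier.
#' @param transcript_id Identifier of the transcript the model lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (start, end), 0-based half-open.
#' @param phase Offset (0, 1, 2) of the first complete codon of the spliced,
#'   strand-corrected CDS.
#' @param has_start,has_stop Completeness flags.
#' @param source Provenance label (`evidence`, `merged`, `extended`,
#'   `abinitio`, `sixframe`, ...).
#' @param support Number of distinct evidence proteins behind the model.
#' @param score Numeric mapping score (sum of contributing alignment scores).
#' @param proteins Character vector of contributing protein ids.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, transcript_id, strand, exons, phase = 0L,
                       has_start = FALSE, has_stop = FALSE,
                       source = "evidence", support = 1L, score = 0,
                       proteins = character()) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  o <- order(exons[, 1L])
  exons <- exons[o, , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("exon with end <= start in model '", id, "'")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L] + 1L)) {
    # introns (gaps) must have length >= 1
    stop("overlapping or abutting exons in model '", id, "'")
  }
  stopifnot(strand %in% c("+", "-"), phase %in% 0:2)
  structure(list(id = as.character(id),
                 transcript_id = as.character(transcript_id),
                 strand = strand, exons = exons, phase = as.integer(phase),
                 has_start = isTRUE(has_start), has_stop = isTRUE(has_stop),
                 source = source, support = as.integer(support),
                 score = as.numeric(score),
                 proteins = as.character(proteins)),
            class = "gene_model")
}

#' @export
#' @method print gene_model
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %s%s %d exon(s) [%s] phase=%d %s source=%s support=%d score=%g\n",
              x$id, x$transcript_id, x$strand, nrow(x$exons),
              paste(sprintf("%d-%d", x$exons[, 1L], x$exons[, 2L]),
                    collapse = ";"),
              x$phase, model_completeness(x), x$source, x$support, x$score))
  invisible(x)
}

model_span <- function(model) {
  c(model$exons[1L, 1L], model$exons[nrow(model$exons), 2L])
}

model_cds_length <- function(model) {
  sum(model$exons[, 2L] - model$exons[, 1L])
}

#' Intron (donor, acceptor) pairs of a model
#'
#' @param model A `gene_model`.
#' @return Two-column matrix of 0-based (donor, acceptor) intron boundaries;
#'   zero rows for single-exon models.
#' @export
model_junctions <- function(model) {
  n <- nrow(model$exons)
  if (n < 2L) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("donor", "acceptor"))))
  }
  cbind(donor = model$exons[-n, 2L], acceptor = model$exons[-1L, 1L])
}

model_completeness <- function(model) {
  if (model$has_start && model$has_stop) "complete"
  else if (!model$has_start && model$has_stop) "partial5"
  else if (model$has_start && !model$has_stop) "partial3"
  else "internal"
}

.tx_seq <- function(transcripts, id) {
  s <- transcripts[[id]]
  if (is.null(s) || is.na(s)) stop("unknown transcript '", id, "'")
  s
}

#' Spliced CDS of a gene model
#'
#' Concatenates the exon substrings of the transcript in ascending order and,
#' for minus-strand models, reverse-complements the concatenation. Introns
#' never appear in the output.
#'
#' @param model A `gene_model`.
#' @param transcripts Named character vector of transcript sequences.
#' @return DNA string of the spliced, strand-corrected CDS.
#' @export
cds_of <- function(model, transcripts) {
  seq <- .tx_seq(transcripts, model$transcript_id)
  L <- nchar(seq)
  if (any(model$exons[, 1L] < 0L) || any(model$exons[, 2L] > L)) {
    stop("exon out of transcript bounds in model '", model$id, "'")
  }
  cds <- paste(substring(seq, model$exons[, 1L] + 1L, model$exons[, 2L]),
               collapse = "")
  if (model$strand == "-") revcomp(cds) else cds
}

#' Classify a model's completeness
#'
#' `complete` iff both start and stop are present, `partial5` when the start
#' is missing, `partial3` when the stop is missing, `internal` when both are.
#' The flags are checked against the spliced CDS content: a claimed start
#' requires phase 0 and an `ATG` prefix; a claimed stop requires an in-frame
#' terminal stop codon.
#'
#' @inheritParams cds_of
#' @return One of `"complete"`, `"partial5"`, `"partial3"`, `"internal"`.
#' @export
classify_completeness <- function(model, transcripts) {
  cds <- cds_of(model, transcripts)
  n <- nchar(cds)
  if (model$has_start &&
      !(model$phase == 0L && substr(cds, 1L, 3L) == START_CODON)) {
    stop("model '", model$id,
         "' claims a start codon but its CDS does not begin ATG at phase 0")
  }
  if (model$has_stop) {
    if ((n - model$phase) %% 3L != 0L ||
        !(substr(cds, n - 2L, n) %in% STOP_CODONS)) {
      stop("model '", model$id,
           "' claims a stop codon but its CDS does not end in-frame at one")
    }
  }
  model_completeness(model)
}

# Derive has_start / has_stop from CDS content (used by all builders).
set_completeness_flags <- function(model, transcripts) {
  cds <- cds_of(model, transcripts)
  n <- nchar(cds)
  model$has_start <- model$phase == 0L && substr(cds, 1L, 3L) == START_CODON
  model$has_stop <- (n - model$phase) %% 3L == 0L && n - model$phase >= 3L &&
    substr(cds, n - 2L, n) %in% STOP_CODONS
  model
}

# TRUE when the translated CDS contains a stop before its final codon.
has_internal_stop <- function(model, transcripts) {
  aa <- translate_dna(cds_of(model, transcripts), model$phase)
  n <- nchar(aa)
  if (n <= 1L) return(FALSE)
  grepl("*", substr(aa, 1L, n - 1L), fixed = TRUE)
}

#' Read a FASTA file into a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are uppercased. DNA alphabet is checked on load.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_check Validate the `{A,C,G,T,N}` alphabet (default TRUE;
#'   disable for protein FASTA).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet_check = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (any(names(seqs) == "")) stop("empty sequence id in ", path)
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in ", path)
  if (alphabet_check) {
    for (i in seq_along(seqs)) .check_dna(seqs[[i]], names(seqs)[i])
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
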