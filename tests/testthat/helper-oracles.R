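# Independent oracles and small random-object builders shared across tests.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(seq) {
  if (nchar(seq) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Independent batch translation via Biostrings (fuzzy codons -> X), each
# input trimmed to whole codons from its offset. One translate() call for
# the whole batch (the S4 path has a large per-call constant).
oracle_translate_batch <- function(seqs, phases = 0) {
  phases <- rep_len(phases, length(seqs))
  trimmed <- vapply(seq_along(seqs), function(i) {
    n <- nchar(seqs[i]) - phases[i]
    n <- n - n %% 3
    if (n < 3) "" else substr(seqs[i], phases[i] + 1, phases[i] + n)
  }, "")
  out <- character(length(seqs))
  nz <- nzchar(trimmed)
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(trimmed[nz]), if.fuzzy.codon = "solve",
      no.init.codon = TRUE))
  }
  out
}

oracle_translate <- function(seq, phase = 0) {
  oracle_translate_batch(seq, phase)
}

# Brute-force six-frame ORF enumeration, independent of the package's
# scanner: translate every frame of every sequence with Biostrings (one
# batched call), then locate complete ORFs with a first-M-to-stop regex
# and, in frames without any complete ORF, the trailing open stretch.
oracle_orfs_batch <- function(seqs, min_aa = 1) {
  meta <- list()
  subs <- character()
  for (i in seq_along(seqs)) {
    seq <- seqs[i]
    L <- nchar(seq)
    rc <- oracle_revcomp(seq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else rc
      for (off in 0:2) {
        n <- L - off
        n <- n - n %% 3
        if (n < 3) next
        subs <- c(subs, substr(s, off + 1, off + n))
        meta[[length(meta) + 1]] <- list(i = i, strand = strand, off = off,
                                         L = L)
      }
    }
  }
  peps <- if (length(subs) > 0) {
    as.character(Biostrings::translate(Biostrings::DNAStringSet(subs),
                                       if.fuzzy.codon = "solve",
                                       no.init.codon = TRUE))
  } else character()

  empty <- data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      has_start = logical(), has_stop = logical(),
                      aa_length = integer(), stringsAsFactors = FALSE)
  out <- rep(list(empty), length(seqs))
  rows <- vector("list", length(peps))
  for (j in seq_along(peps)) {
    pep <- peps[j]
    mt <- meta[[j]]
    frame_rows <- list()
    add <- function(s_start, s_end, has_start, has_stop, aa_len) {
      frame_rows[[length(frame_rows) + 1]] <<- data.frame(
        strand = mt$strand, frame = mt$off,
        start = if (mt$strand == "+") s_start else mt$L - s_end,
        end = if (mt$strand == "+") s_end else mt$L - s_start,
        has_start = has_start, has_stop = has_stop, aa_length = aa_len,
        stringsAsFactors = FALSE)
    }
    m <- gregexpr("M[^*]*\\*", pep)[[1]]
    if (m[1] != -1) {
      lens <- attr(m, "match.length")
      for (h in seq_along(m)) {
        add(mt$off + 3 * (m[h] - 1), mt$off + 3 * (m[h] - 1 + lens[h]),
            TRUE, TRUE, lens[h] - 1L)
      }
    } else {
      stars <- gregexpr("*", pep, fixed = TRUE)[[1]]
      seg_start <- if (stars[1] == -1) 1L else max(stars) + 1L
      if (seg_start <= nchar(pep)) {
        add(mt$off + 3 * (seg_start - 1), mt$off + 3 * nchar(pep),
            substr(pep, seg_start, seg_start) == "M", FALSE,
            nchar(pep) - seg_start + 1L)
      }
    }
    if (length(frame_rows) > 0) {
      out[[mt$i]] <- rbind(out[[mt$i]], do.call(rbind, frame_rows))
    }
  }
  lapply(out, function(df) df[df$aa_length >= min_aa, , drop = FALSE])
}

oracle_orfs <- function(seq, min_aa = 1) {
  oracle_orfs_batch(seq, min_aa)[[1]]
}

# Canonical string form of an ORF table for set comparison.
orf_key <- function(df) {
  sort(sprintf("%s|%d|%d|%d|%d|%d|%d", df$strand, df$frame, df$start,
               df$end, df$has_start, df$has_stop, df$aa_length))
}

# A random gene model on a random transcript id (structure only; content
# need not be biological - used for format round trips).
random_model <- function(id) {
  n_ex <- sample(1:4, 1)
  widths <- sample(30:400, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(20:200, n_ex - 1, replace = TRUE) else integer()
  starts <- sample(0:100, 1) + c(0L, cumsum(widths[-n_ex] + gaps))
  ends <- starts + widths
  gene_model(id, sprintf("T%02d", sample(1:20, 1)),
             sample(c("+", "-"), 1), cbind(starts, ends),
             phase = sample(0:2, 1),
             has_start = sample(c(TRUE, FALSE), 1),
             has_stop = sample(c(TRUE, FALSE), 1),
             source = sample(c("evidence", "merged", "abinitio", "sixframe"), 1),
             support = sample(0:9, 1), score = round(runif(1) * 1000, 1))
}

model_fields_equal <- function(a, b) {
  identical(a$id, b$id) && identical(a$transcript_id, b$transcript_id) &&
    identical(a$strand, b$strand) && identical(unname(a$exons), unname(b$exons)) &&
    identical(a$phase, b$phase) && identical(a$has_start, b$has_start) &&
    identical(a$has_stop, b$has_stop) && identical(a$source, b$source) &&
    identical(a$support, b$support) && isTRUE(all.equal(a$score, b$score))
}
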