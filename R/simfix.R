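# Synthetic fixture generator: transcripts with known gene structures,
# retained GT..AG introns, noisy evidence alignments, perturbed ab initio
# models, and a paired assembly with planted variants - every pipeline
# input, with ground truth attached.

.NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation parameters
#'
#' Defaults loosely mirror published transcriptome gene-set statistics
#' (mean intron around 300 bp) without claiming to reproduce any specific
#' data set. All rates are in `[0, 1]`; lengths are in nt. The same params
#' and seed always regenerate byte-identical fixtures.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param gene_probability Probability a transcript carries a true gene.
#' @param intron_retention_rate Fraction of genes carrying retained
#'   GT..AG introns.
#' @param introns_per_gene Integer range of introns per retaining gene.
#' @param intron_length Range of intron lengths.
#' @param cds_length Range of true CDS lengths.
#' @param partial5_rate,partial3_rate Probability a gene is truncated at
#'   its 5' / 3' end (missing start / stop codon).
#' @param n_evidence_proteins Range of evidence proteins per gene.
#' @param evidence_dropout Probability a gene receives no protein
#'   evidence (covered only ab initio).
#' @param protein_mutation_rate Residue substitution rate of evidence
#'   proteins relative to the true translation.
#' @param alignment_boundary_jitter Maximum terminal-boundary jitter of
#'   evidence alignments, in nt; jitter is frame-preserving (multiples of
#'   3) and inward, since an alignment cannot extend past its protein.
#' @param abinitio_miss_rate,abinitio_shift_rate,abinitio_spurious_rate
#'   Ab initio error rates: missed gene, terminal boundary shift, spurious
#'   model on a non-coding transcript.
#' @param variant_rate_snp,variant_rate_indel Probability (per transcript,
#'   at most one variant each) of planting a SNP / an InDel.
#' @param diverged_flank_zone_rate Fraction of planted variants whose
#'   flanking sequence is diverged in the paired assembly.
#' @param flank_k Flank length used for divergence zones.
#' @param utr_length UTR length range for complete genes.
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_transcripts = 200L, gene_probability = 0.8,
                       intron_retention_rate = 0.3,
                       introns_per_gene = c(1L, 2L),
                       intron_length = c(60L, 500L),
                       cds_length = c(300L, 1500L),
                       partial5_rate = 0.05, partial3_rate = 0.05,
                       n_evidence_proteins = c(2L, 4L),
                       evidence_dropout = 0.1,
                       protein_mutation_rate = 0.03,
                       alignment_boundary_jitter = 6L,
                       abinitio_miss_rate = 0.1,
                       abinitio_shift_rate = 0.05,
                       abinitio_spurious_rate = 0.1,
                       variant_rate_snp = 0.4,
                       variant_rate_indel = 0.1,
                       diverged_flank_zone_rate = 0.5,
                       flank_k = 50L,
                       utr_length = c(100L, 300L),
                       seed = 42L) {
  p <- as.list(environment())
  rates <- c(p$gene_probability, p$intron_retention_rate, p$partial5_rate,
             p$partial3_rate, p$evidence_dropout, p$protein_mutation_rate,
             p$abinitio_miss_rate, p$abinitio_shift_rate,
             p$abinitio_spurious_rate, p$variant_rate_snp,
             p$variant_rate_indel, p$diverged_flank_zone_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            p$cds_length[1L] >= 30L, p$intron_length[1L] >= 10L,
            p$alignment_boundary_jitter %% 3L == 0L)
  structure(p, class = "sim_params")
}

#' Preset simulation parameter sets
#'
#' `noise-free` (200 transcripts, exact alignments and ab initio models),
#' `default` (500 transcripts, boundary jitter up to 6 nt, 2-4 evidence
#' proteins per gene), `hard` (high jitter and error rates) and `variants`
#' (one planted variant per transcript, half in diverged flank zones).
#'
#' @param name Preset name.
#' @param seed Optional seed override.
#' @return A `sim_params` list.
#' @export
sim_preset <- function(name = c("noise-free", "default", "hard", "variants"),
                       seed = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    "noise-free" = sim_params(
      n_transcripts = 200L, alignment_boundary_jitter = 0L,
      protein_mutation_rate = 0, evidence_dropout = 0.2,
      abinitio_miss_rate = 0, abinitio_shift_rate = 0,
      abinitio_spurious_rate = 0, variant_rate_snp = 0,
      variant_rate_indel = 0, seed = 42L),
    "default" = sim_params(
      n_transcripts = 500L, intron_retention_rate = 0.3,
      alignment_boundary_jitter = 6L, n_evidence_proteins = c(2L, 4L),
      seed = 7L),
    "hard" = sim_params(
      n_transcripts = 500L, alignment_boundary_jitter = 12L,
      protein_mutation_rate = 0.08, evidence_dropout = 0.2,
      abinitio_miss_rate = 0.2, abinitio_shift_rate = 0.15,
      abinitio_spurious_rate = 0.2, seed = 99L),
    "variants" = sim_params(
      n_transcripts = 300L, gene_probability = 0.7,
      variant_rate_snp = 0.8, variant_rate_indel = 0.2,
      diverged_flank_zone_rate = 0.5, seed = 11L))
  if (!is.null(seed)) p$seed <- as.integer(seed)
  p
}

# One random CDS: ATG, internal sense codons, terminal stop. Codons 2..5
# avoid ATG so that fixed-frame 5' extension of an inward-jittered boundary
# always lands on the true start codon rather than an interior Met.
.rand_cds <- function(n_codons) {
  internal <- sample(.NONSTOP_CODONS, n_codons - 2L, replace = TRUE)
  guard <- seq_len(min(4L, length(internal)))
  while (any(internal[guard] == "ATG")) {
    internal[guard][internal[guard] == "ATG"] <-
      sample(setdiff(.NONSTOP_CODONS, "ATG"), sum(internal[guard] == "ATG"),
             replace = TRUE)
  }
  paste0("ATG", paste(internal, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# A retained intron: canonical GT..AG termini around random sequence with
# an embedded stop-bearing block. "TTAATTAATTAA" places a stop codon in
# every frame on both strands (it is its own reverse complement), so no
# open reading frame can run through a retained intron - the structural
# reason six-frame translation fails on these transcripts.
.rand_intron <- function(len) {
  stopifnot(len >= 20L)
  core <- "TTAATTAATTAA"
  pad <- len - 4L - nchar(core)
  left <- pad %/% 2L
  paste0("GT", .rand_dna(left), core, .rand_dna(pad - left), "AG")
}

.sample_range <- function(r) {
  if (r[1L] >= r[2L]) r[1L] else sample(seq.int(r[1L], r[2L]), 1L)
}

#' Simulate a ground-truth fixture
#'
#' Generates an assembly of transcripts in which most carry one true gene
#' (random CDS flanked by UTRs, optionally interrupted by retained GT..AG
#' introns; some genes are 5'/3'-truncated partials, some transcripts are
#' non-coding decoys), together with the evidence protein alignments, ab
#' initio models, strict evaluation queries, and a paired second assembly
#' carrying planted SNPs and InDels - plus the ground truth for all of it.
#'
#' @param params A [sim_params()] list.
#' @return A `truth_set` list: `params`, `assembly_a`, `assembly_b`,
#'   `models` (true gene models), `evidence`, `abinitio`, `queries`
#'   (alignment records), `variants` (data.frame with planted region and
#'   divergence labels).
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, function() .simulate_impl(params))
}

.simulate_impl <- function(p) {
  asm <- character()
  models <- list()
  evidence <- list()
  queries <- list()
  abinitio <- list()
  var_rows <- list()

  for (i in seq_len(p$n_transcripts)) {
    tid <- sprintf("TX%04d", i)
    is_gene <- stats::runif(1) < p$gene_probability

    if (!is_gene) {
      L <- .sample_range(c(400L, 2000L))
      seq <- .rand_dna(L)
      if (stats::runif(1) < p$abinitio_spurious_rate && L >= 400L) {
        # plant a spurious ORF for ab initio to "find"
        n_cod <- .sample_range(c(60L, 100L))
        orf <- .rand_cds(n_cod)
        at <- .sample_range(c(10L, L - nchar(orf) - 10L))
        seq <- paste0(substr(seq, 1L, at), orf,
                      substr(seq, at + nchar(orf) + 1L, L))
        abinitio[[length(abinitio) + 1L]] <- gene_model(
          sprintf("ab_%s", tid), tid, "+", cbind(at, at + nchar(orf)),
          phase = 0L, has_start = TRUE, has_stop = TRUE,
          source = "abinitio", support = 0L,
          score = round(stats::runif(1, 0.5, 1), 3))
      }
      asm[tid] <- seq
      next
    }

    n_codons <- .sample_range(round(p$cds_length / 3))
    cds <- .rand_cds(n_codons)
    partial5 <- stats::runif(1) < p$partial5_rate
    partial3 <- stats::runif(1) < p$partial3_rate
    if (partial5) cds <- substr(cds, 4L, nchar(cds))
    if (partial3) cds <- substr(cds, 1L, nchar(cds) - 3L)
    cds_len <- nchar(cds)

    # retained introns, inserted at codon-boundary or mid-codon positions
    # within the central 80% of the CDS
    intron_at <- integer()
    if (stats::runif(1) < p$intron_retention_rate && cds_len >= 120L) {
      n_int <- .sample_range(p$introns_per_gene)
      cand <- seq.int(max(15L, as.integer(0.1 * cds_len)),
                      min(cds_len - 15L, as.integer(0.9 * cds_len)))
      pts <- integer()
      for (k in seq_len(n_int)) {
        ok <- cand[vapply(cand, function(x) {
          length(pts) == 0L || min(abs(x - pts)) >= 50L
        }, NA)]
        if (length(ok) == 0L) break
        pts <- c(pts, if (length(ok) == 1L) ok else sample(ok, 1L))
      }
      intron_at <- sort(pts)
    }
    introns <- vapply(seq_along(intron_at), function(k) .rand_intron(
      max(20L, .sample_range(p$intron_length))), "")

    # gene-forward region: CDS pieces with introns interleaved
    cuts <- c(0L, intron_at, cds_len)
    pieces <- substring(cds, cuts[-length(cuts)] + 1L, cuts[-1L])
    region <- ""
    exon_rel <- matrix(integer(), ncol = 2L)
    for (k in seq_along(pieces)) {
      exon_rel <- rbind(exon_rel,
                        c(nchar(region), nchar(region) + nchar(pieces[k])))
      region <- paste0(region, pieces[k])
      if (k <= length(introns)) region <- paste0(region, introns[k])
    }

    utr5 <- if (partial5) .rand_dna(sample(0:2, 1L)) else {
      .rand_dna(.sample_range(p$utr_length))
    }
    utr3 <- if (partial3) .rand_dna(sample(0:2, 1L)) else {
      .rand_dna(.sample_range(p$utr_length))
    }
    fwd_seq <- paste0(utr5, region, utr3)
    off <- nchar(utr5)
    exons_fwd <- exon_rel + off
    L <- nchar(fwd_seq)

    strand <- sample(c("+", "-"), 1L)
    flip <- function(ex) cbind(L - rev(ex[, 2L]), L - rev(ex[, 1L]))
    seq <- if (strand == "+") fwd_seq else revcomp(fwd_seq)
    exons <- if (strand == "+") exons_fwd else flip(exons_fwd)
    asm[tid] <- seq

    truth <- gene_model(sprintf("g_%s", tid), tid, strand, exons,
                        phase = 0L, has_start = !partial5,
                        has_stop = !partial3, source = "truth",
                        support = 0L, score = 0)
    models[[length(models) + 1L]] <- truth

    # evidence alignments cover the protein, i.e. exclude the stop codon
    aligned_fwd <- exons_fwd
    if (!partial3) aligned_fwd[nrow(aligned_fwd), 2L] <-
      aligned_fwd[nrow(aligned_fwd), 2L] - 3L
    prot_len <- (cds_len - (!partial3) * 3L) %/% 3L
    prot_aa <- sub("\\*$", "", translate_dna(cds, 0L))

    queries[[length(queries) + 1L]] <- protein_alignment(
      sprintf("Q_%s", tid), prot_len, tid, strand,
      if (strand == "+") aligned_fwd else flip(aligned_fwd),
      phase = 0L, percent = 95, raw_score = 5 * prot_len, query_cov = 1)

    if (stats::runif(1) >= p$evidence_dropout) {
      n_prot <- .sample_range(p$n_evidence_proteins)
      # boundaries are usually exact; occasional inward, frame-preserving
      # truncation up to the jitter magnitude
      jit_steps <- seq.int(0L, p$alignment_boundary_jitter, by = 3L)
      jit_prob <- if (length(jit_steps) == 1L) 1 else {
        c(0.6, rep(0.4 / (length(jit_steps) - 1L), length(jit_steps) - 1L))
      }
      for (j in seq_len(n_prot)) {
        aa <- strsplit(prot_aa, "", fixed = TRUE)[[1L]]
        mut <- stats::runif(length(aa)) < p$protein_mutation_rate
        if (any(mut)) {
          aa[mut] <- sample(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1L]],
                            sum(mut), replace = TRUE)
        }
        d5 <- if (length(jit_steps) == 1L) jit_steps else {
          sample(jit_steps, 1L, prob = jit_prob)
        }
        d3 <- if (length(jit_steps) == 1L) jit_steps else {
          sample(jit_steps, 1L, prob = jit_prob)
        }
        blk <- aligned_fwd
        blk[1L, 1L] <- blk[1L, 1L] + d5
        blk[nrow(blk), 2L] <- blk[nrow(blk), 2L] - d3
        mut_frac <- mean(mut)
        evidence[[length(evidence) + 1L]] <- protein_alignment(
          sprintf("P_%s_%d", tid, j), prot_len, tid, strand,
          if (strand == "+") blk else flip(blk), phase = 0L,
          percent = round(max(50, 100 * (1 - mut_frac) -
                                stats::runif(1, 0, 2)), 1),
          raw_score = round(5 * prot_len * (1 - mut_frac)) +
            sample.int(20L, 1L),
          query_cov = sum(blk[, 2L] - blk[, 1L]) / 3 / prot_len)
      }
    }

    if (stats::runif(1) >= p$abinitio_miss_rate) {
      ab_ex <- exons
      if (stats::runif(1) < p$abinitio_shift_rate) {
        d <- sample(c(3L, 6L), 1L)
        if (stats::runif(1) < 0.5) {
          ab_ex[1L, 1L] <- ab_ex[1L, 1L] + d
        } else {
          ab_ex[nrow(ab_ex), 2L] <- ab_ex[nrow(ab_ex), 2L] - d
        }
      }
      ab <- gene_model(sprintf("ab_%s", tid), tid, strand, ab_ex,
                       phase = 0L, source = "abinitio", support = 0L,
                       score = round(stats::runif(1, 0.5, 1), 3))
      abinitio[[length(abinitio) + 1L]] <- set_completeness_flags(
        ab, structure(list(seq), names = tid))
    }
  }

  # plant at most one variant per transcript on assembly B
  k <- p$flank_k
  for (tid in names(asm)) {
    u <- stats::runif(1)
    vr <- p$variant_rate_snp + p$variant_rate_indel
    if (vr == 0 || u >= vr) next
    vtype <- if (u < p$variant_rate_snp) "SNP" else "INDEL"
    seq <- asm[[tid]]
    L <- nchar(seq)
    if (L < 2L * k + 40L) next
    pos <- .sample_range(c(k + 5L, L - k - 10L))
    if (vtype == "SNP") {
      ref <- substr(seq, pos + 1L, pos + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    } else if (stats::runif(1) < 0.5) {
      ref <- substr(seq, pos + 1L, pos + 1L)
      alt <- paste0(ref, .rand_dna(.sample_range(c(1L, 4L))))
      vtype <- "INS"
    } else {
      dl <- .sample_range(c(1L, 4L))
      ref <- substr(seq, pos + 1L, pos + 1L + dl)
      alt <- substr(ref, 1L, 1L)
      vtype <- "DEL"
    }
    var_rows[[length(var_rows) + 1L]] <- data.frame(
      transcript_id = tid, pos = pos, ref = ref, alt = alt, vtype = vtype,
      depth = sample(5:100, 1L), qual = round(stats::runif(1, 30, 60), 1),
      stringsAsFactors = FALSE)
  }
  variants <- if (length(var_rows) > 0L) {
    do.call(rbind, var_rows)
  } else {
    data.frame(transcript_id = character(), pos = integer(),
               ref = character(), alt = character(), vtype = character(),
               depth = integer(), qual = numeric(),
               stringsAsFactors = FALSE)
  }

  # ground-truth region labels from the planted gene geometry
  if (nrow(variants) > 0L) {
    tx_of <- vapply(models, `[[`, "", "transcript_id")
    variants$region <- vapply(seq_len(nrow(variants)), function(i) {
      hit <- which(tx_of == variants$transcript_id[i])
      if (length(hit) == 0L) return("others")
      m <- models[[hit[1L]]]
      lo <- variants$pos[i]
      hi <- lo + nchar(variants$ref[i])
      if (any(m$exons[, 1L] < hi & lo < m$exons[, 2L])) return("exon")
      j <- model_junctions(m)
      if (nrow(j) > 0L && any(j[, 1L] < hi & lo < j[, 2L])) return("intron")
      "others"
    }, "")
    n_div <- round(nrow(variants) * p$diverged_flank_zone_rate)
    variants$diverged <- FALSE
    if (n_div > 0L) {
      variants$diverged[sample.int(nrow(variants), n_div)] <- TRUE
    }
  } else {
    variants$region <- character()
    variants$diverged <- logical()
  }

  # paired assembly: apply variants, then diverge selected flank zones
  asm_b <- asm
  for (i in seq_len(nrow(variants))) {
    tid <- variants$transcript_id[i]
    seq <- asm_b[[tid]]
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    seq <- paste0(substr(seq, 1L, pos), alt,
                  substr(seq, pos + nchar(ref) + 1L, nchar(seq)))
    if (variants$diverged[i]) {
      mutate_window <- function(s, from, to) {
        # substitute ~10% of the window, at least one position
        idx <- seq.int(from, to)
        hitidx <- idx[stats::runif(length(idx)) < 0.1]
        if (length(hitidx) == 0L) hitidx <- idx[.sample_range(c(1L, length(idx)))]
        for (x in hitidx) {
          old <- substr(s, x, x)
          substr(s, x, x) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
        s
      }
      seq <- mutate_window(seq, pos - k + 1L, pos)
      gap_end <- pos + nchar(alt)
      seq <- mutate_window(seq, gap_end + 1L, gap_end + k)
    }
    asm_b[tid] <- seq
  }

  structure(list(params = p, assembly_a = asm, assembly_b = asm_b,
                 models = models, evidence = evidence, abinitio = abinitio,
                 queries = queries, variants = variants),
            class = "truth_set")
}

#' Write a simulated fixture to disk
#'
#' Writes `assemblyA.fa`, `assemblyB.fa`, `evidence.tsv`, `evidence.gff2`,
#' `abinitio.gff`, `queries.gff`, `planted.vcf`, `truth.gff3` and
#' `manifest.json` (the parameters and seed, for deterministic
#' regeneration).
#'
#' @param truth A `truth_set` from [simulate_truth()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_set"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  fp <- function(x) file.path(dir, x)
  write_fasta(truth$assembly_a, fp("assemblyA.fa"))
  write_fasta(truth$assembly_b, fp("assemblyB.fa"))
  write_alignments_tsv(truth$evidence, fp("evidence.tsv"))
  write_exonerate_gff(truth$evidence, fp("evidence.gff2"))
  write_abinitio_gff(truth$abinitio, fp("abinitio.gff"))
  write_exonerate_gff(truth$queries, fp("queries.gff"))
  write_vcf(truth$variants, fp("planted.vcf"))
  write_gff3(truth$models, fp("truth.gff3"))
  jsonlite::write_json(unclass(truth$params), fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Recovery of the planted truth by a predicted gene set
#'
#' For every true gene model: its junction set is recovered when some
#' predicted model on the same transcript and strand has the identical
#' (donor, acceptor) set; its CDS is recovered exactly when some predicted
#' model's spliced CDS equals the true spliced CDS.
#'
#' @param truth A `truth_set`.
#' @param predicted List of `gene_model` objects.
#' @return List with `junction_recovery` and `exact_cds_recovery`
#'   fractions plus the per-gene logical vectors.
#' @export
truth_recovery <- function(truth, predicted) {
  tx <- truth$assembly_a
  pred_key <- vapply(predicted, function(m) {
    paste(m$transcript_id, m$strand)
  }, "")
  pred_cds <- vapply(predicted, cds_of, "", transcripts = tx)
  junction_hit <- logical(length(truth$models))
  cds_hit <- logical(length(truth$models))
  for (i in seq_along(truth$models)) {
    tm <- truth$models[[i]]
    tj <- model_junctions(tm)
    key <- paste(tm$transcript_id, tm$strand)
    idx <- which(pred_key == key)
    junction_hit[i] <- any(vapply(idx, function(j) {
      pj <- model_junctions(predicted[[j]])
      nrow(pj) == nrow(tj) && all(pj == tj)
    }, NA))
    tcds <- cds_of(tm, tx)
    cds_hit[i] <- any(pred_cds[idx] == tcds)
  }
  list(junction_recovery = mean(junction_hit),
       exact_cds_recovery = mean(cds_hit),
       junction_hit = junction_hit, cds_hit = cds_hit)
}
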