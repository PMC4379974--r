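# The seqcore example transcript: CDS "ATGGCTAAATAA" split by a GT..AG
# intron at (8, 20).
ex_tx <- c(T1 = "CCATGGCTGTAAGTTTTTAGAAATAAGG")

aln <- function(pid, blocks, percent = 85, score = 400, tid = "T1",
                strand = "+") {
  protein_alignment(pid, 4, tid, strand, blocks, percent = percent,
                    raw_score = score)
}

test_that("alignment thresholds gate candidate structures", {
  recs <- list(aln("P1", rbind(c(2, 8), c(20, 26))),
               aln("P2", rbind(c(2, 8), c(20, 26)), percent = 29.9),
               protein_alignment("P3", 100, "T1", "+",
                                 rbind(c(0, 9), c(60010, 60100))))
  out <- suppressMessages(structures_from_alignments(recs, ex_tx))
  expect_length(out, 1)
  m <- out[[1]]
  expect_identical(cds_of(m, ex_tx), "ATGGCTAAATAA")
  expect_true(m$has_start && m$has_stop)
  expect_identical(m$support, 1L)
})

test_that("junction-identical structures merge with per-end consensus", {
  # tie on both ends -> outermost boundary wins
  recs <- list(aln("P1", rbind(c(2, 8), c(20, 26))),
               aln("P2", rbind(c(4, 8), c(20, 24))))
  models <- suppressMessages(structures_from_alignments(recs, ex_tx))
  merged <- merge_same_junctions(models, ex_tx)
  expect_length(merged, 1)
  m <- merged[[1]]
  expect_identical(unname(m$exons), cbind(c(2L, 20L), c(8L, 26L)))
  expect_identical(m$support, 2L)
  expect_identical(m$source, "merged")
  expect_equal(m$score, 800)

  # majority beats outermost: start 4 twice, start 2 once
  recs3 <- list(aln("P1", rbind(c(2, 8), c(20, 26))),
                aln("P2", rbind(c(4, 8), c(20, 26))),
                aln("P3", rbind(c(4, 8), c(20, 26))))
  m3 <- merge_same_junctions(
    suppressMessages(structures_from_alignments(recs3, ex_tx)), ex_tx)[[1]]
  expect_identical(unname(m3$exons[1, 1]), 4L)

  # singleton group: unchanged except source
  single <- merge_same_junctions(models[1], ex_tx)[[1]]
  expect_identical(unname(single$exons), unname(models[[1]]$exons))
  expect_identical(single$source, "merged")
})

test_that("merging never alters junctions and conserves support totals", {
  truth <- simulate_truth(sim_preset("default"))
  cand <- suppressMessages(
    structures_from_alignments(truth$evidence, truth$assembly_a))
  merged <- merge_same_junctions(cand, truth$assembly_a)
  expect_lte(length(merged), length(cand))
  expect_identical(sum(vapply(merged, function(m) m$support, 0L)),
                   length(cand))
  in_j <- unique(vapply(cand, function(m) {
    j <- model_junctions(m)
    paste(m$transcript_id, m$strand, paste(j, collapse = ","))
  }, ""))
  out_j <- unique(vapply(merged, function(m) {
    j <- model_junctions(m)
    paste(m$transcript_id, m$strand, paste(j, collapse = ","))
  }, ""))
  expect_setequal(in_j, out_j)
})

test_that("single-exon structures merge only within one reading frame", {
  tx <- c(T9 = random_dna(200))
  a <- gene_model("a", "T9", "+", cbind(12, 60), phase = 0)  # frame 0
  b <- gene_model("b", "T9", "+", cbind(24, 90), phase = 0)  # frame 0
  c <- gene_model("c", "T9", "+", cbind(25, 91), phase = 0)  # frame 1
  merged <- merge_same_junctions(list(a, b, c), tx)
  expect_length(merged, 2)
  spans <- sort(vapply(merged, function(m) model_span(m)[1], 0L))
  expect_identical(spans, c(12L, 25L))
})

test_that("frameshift and early-stop models are filtered out", {
  tx <- c(T1 = "ATGTAAGCTTAA", T2 = "ATGGCTAAATAA")
  bad <- gene_model("bad", "T1", "+", cbind(0, 12))
  good <- gene_model("good", "T2", "+", cbind(0, 12))
  kept <- suppressMessages(filter_invalid_cds(list(bad, good), tx))
  expect_identical(vapply(kept, `[[`, "", "id"), "good")

  # complete-flagged model whose exon lengths sum to 1 mod 3: frameshift
  tx2 <- c(T3 = paste0(strrep("GCA", 20), "TAA", strrep("GCA", 10)))
  fs <- gene_model("fs", "T3", "+", rbind(c(0, 6), c(33, 40)),
                   has_start = TRUE, has_stop = TRUE)
  expect_length(suppressMessages(filter_invalid_cds(list(fs), tx2)), 0)

  # short non-multiple-of-3 gap between blocks is a frameshift
  tx3 <- c(T4 = paste0("ATG", strrep("GCA", 30)))
  fs2 <- gene_model("fs2", "T4", "+", rbind(c(0, 9), c(13, 34)))
  expect_length(suppressMessages(filter_invalid_cds(list(fs2), tx3)), 0)
})

test_that("overlap resolution ranks by support, then score, length and id", {
  tx <- c(T5 = random_dna(500))
  a <- gene_model("a", "T5", "+", cbind(0, 120), support = 3, score = 500)
  b <- gene_model("b", "T5", "+", cbind(60, 300), support = 1, score = 900)
  expect_identical(resolve_overlaps(list(a, b))[[1]]$id, "a")

  c1 <- gene_model("c1", "T5", "+", cbind(0, 120), support = 2, score = 400)
  c2 <- gene_model("c2", "T5", "+", cbind(60, 300), support = 2, score = 500)
  expect_identical(resolve_overlaps(list(c1, c2))[[1]]$id, "c2")

  # opposite strands never compete
  d <- gene_model("d", "T5", "-", cbind(0, 120), support = 1, score = 1)
  expect_length(resolve_overlaps(list(a, d)), 2)
})

test_that("resolved output is an antichain under same-strand span overlap", {
  set.seed(303)
  for (rep in 1:20) {
    models <- lapply(1:15, function(i) {
      s <- sample(0:400, 1)
      gene_model(sprintf("m%02d", i), sample(c("TA", "TB"), 1),
                 sample(c("+", "-"), 1), cbind(s, s + sample(30:200, 1)),
                 support = sample(0:5, 1), score = sample(1:999, 1))
    })
    kept <- resolve_overlaps(models)
    for (i in seq_along(kept)) {
      for (j in seq_along(kept)) {
        if (i >= j) next
        a <- kept[[i]]
        b <- kept[[j]]
        if (a$transcript_id != b$transcript_id || a$strand != b$strand) next
        sa <- model_span(a)
        sb <- model_span(b)
        expect_true(sa[2] <= sb[1] || sb[2] <= sa[1])
      }
    }
  }
})

test_that("most true junction sets survive Step 1 exactly once under noise", {
  truth <- simulate_truth(sim_preset("default"))
  cand <- suppressMessages(
    structures_from_alignments(truth$evidence, truth$assembly_a))
  step1 <- resolve_overlaps(suppressMessages(
    filter_invalid_cds(merge_same_junctions(cand, truth$assembly_a),
                       truth$assembly_a)))
  covered <- vapply(truth$models, function(tm) {
    if (!any(vapply(truth$evidence, function(r) {
      r$transcript_id == tm$transcript_id
    }, NA))) {
      return(NA)  # no evidence planted for this gene
    }
    tj <- model_junctions(tm)
    hits <- sum(vapply(step1, function(pm) {
      pm$transcript_id == tm$transcript_id && pm$strand == tm$strand &&
        nrow(model_junctions(pm)) == nrow(tj) &&
        all(model_junctions(pm) == tj)
    }, NA))
    hits == 1L
  }, NA)
  expect_gte(mean(covered, na.rm = TRUE), 0.95)
})
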