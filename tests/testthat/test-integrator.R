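mk <- function(id, exons, tid = "T1", strand = "+", complete = TRUE,
               support = 1L, score = 10, source = "evidence", phase = 0L) {
  gene_model(id, tid, strand, exons, phase = phase, has_start = complete,
             has_stop = complete, source = source, support = support,
             score = score)
}

test_that("training-gene selection is complete-only, sized and deterministic", {
  set.seed(505)
  models <- c(lapply(1:50, function(i) {
    mk(sprintf("c%02d", i), cbind(0, 30 + 3 * i), tid = sprintf("T%02d", i))
  }), lapply(1:20, function(i) {
    m <- mk(sprintf("p%02d", i), cbind(0, 300), tid = sprintf("U%02d", i))
    m$has_stop <- FALSE
    m
  }))
  sel <- select_training_genes(models, n = 30, seed = 9)
  expect_length(sel, 30)
  expect_true(all(vapply(sel, function(m) m$has_start && m$has_stop, NA)))
  sel2 <- select_training_genes(models, n = 30, seed = 9)
  expect_identical(vapply(sel, `[[`, "", "id"), vapply(sel2, `[[`, "", "id"))

  expect_warning(few <- select_training_genes(models, n = 200, seed = 1),
                 "only 50")
  expect_length(few, 50)
  partials <- Filter(function(m) !(m$has_start && m$has_stop), models)
  expect_error(select_training_genes(partials, n = 10), "no complete")
})

test_that("abnormal ab initio models are removed at the documented thresholds", {
  tx <- c(T1 = paste0("ATG", strrep("GCT", 60), "TAA", random_dna(50)),
          T2 = paste0("ATG", "TAA", strrep("GCT", 60), "TAA"))
  ok <- mk("ok", cbind(0, 186), source = "abinitio", support = 0L)
  short150 <- mk("s150", cbind(0, 150), source = "abinitio", support = 0L,
                 complete = FALSE)
  short149 <- mk("s149", cbind(0, 149), source = "abinitio", support = 0L,
                 complete = FALSE)
  oob <- mk("oob", cbind(0, 5000), source = "abinitio", support = 0L,
            complete = FALSE)
  stopin <- mk("stop", cbind(0, 189), tid = "T2", source = "abinitio",
               support = 0L)
  kept <- suppressMessages(
    filter_abnormal_abinitio(list(ok, short150, short149, oob, stopin), tx))
  expect_identical(vapply(kept, `[[`, "", "id"), c("ok", "s150"))
})

test_that("integration extends, discards or adds ab initio models correctly", {
  tx <- c(T1 = random_dna(1000))
  # case c: disjoint models coexist
  ev <- mk("ev1", cbind(100, 400), complete = FALSE, support = 2)
  ab_far <- mk("ab1", cbind(600, 900), source = "abinitio", support = 0L,
               complete = FALSE)
  out <- integrate_models(list(ev), list(ab_far), tx)
  expect_setequal(vapply(out, `[[`, "", "id"), c("ev1", "ab1"))

  # same-frame single-exon overlap: union span
  ab_same <- mk("ab2", cbind(250, 700), source = "abinitio", support = 0L,
                complete = FALSE)  # 250 = 100 mod 3
  out2 <- integrate_models(list(ev), list(ab_same), tx)
  expect_length(out2, 1)
  expect_identical(unname(out2[[1]]$exons), cbind(100L, 700L))
  expect_identical(out2[[1]]$support, 2L)

  # incompatible frame: discarded
  ab_off <- mk("ab3", cbind(251, 701), source = "abinitio", support = 0L,
               complete = FALSE)
  out3 <- integrate_models(list(ev), list(ab_off), tx)
  expect_length(out3, 1)
  expect_identical(unname(out3[[1]]$exons), cbind(100L, 400L))

  # conflicting junctions in the shared span: discarded
  ev_j <- mk("ev2", rbind(c(100, 200), c(300, 400)), complete = FALSE,
             support = 2)
  ab_j <- mk("ab4", rbind(c(100, 210), c(290, 400)), source = "abinitio",
             support = 0L, complete = FALSE)
  out4 <- integrate_models(list(ev_j), list(ab_j), tx)
  expect_length(out4, 1)
  expect_identical(out4[[1]]$id, "ev2")

  # matching junctions in shared span: terminal extension keeps junctions
  ab_j2 <- mk("ab5", rbind(c(40, 200), c(300, 430)), source = "abinitio",
              support = 0L, complete = FALSE)
  out5 <- integrate_models(list(ev_j), list(ab_j2), tx)
  expect_length(out5, 1)
  expect_identical(unname(out5[[1]]$exons),
                   cbind(c(40L, 300L), c(200L, 430L)))
  expect_identical(out5[[1]]$source, "merged")
})

test_that("integration output never contains same-strand overlaps", {
  truth <- simulate_truth(sim_preset("default"))
  res <- suppressWarnings(suppressMessages(annotate_pipeline(
    truth$assembly_a, truth$evidence, truth$abinitio)))
  expect_gt(length(res$final), 100)
  for (set in list(res$integrated, res$final)) {
    key <- vapply(set, function(m) paste(m$transcript_id, m$strand), "")
    for (k in unique(key)) {
      group <- set[key == k]
      spans <- t(vapply(group, model_span, integer(2)))
      if (nrow(spans) < 2) next
      o <- order(spans[, 1])
      expect_true(all(spans[o, 1][-1] >= spans[o, 2][-nrow(spans)]))
    }
  }
})

test_that("ab initio models recover genes that lack protein evidence", {
  truth <- simulate_truth(sim_preset("default"))
  tx <- truth$assembly_a
  res <- suppressWarnings(suppressMessages(annotate_pipeline(
    tx, truth$evidence, truth$abinitio)))
  ev_tx <- unique(vapply(truth$evidence, `[[`, "", "transcript_id"))
  ab_tx <- unique(vapply(truth$abinitio, `[[`, "", "transcript_id"))
  only_ab <- Filter(function(m) {
    !(m$transcript_id %in% ev_tx) && m$transcript_id %in% ab_tx
  }, truth$models)
  expect_gt(length(only_ab), 5)
  final_cds <- vapply(res$final, cds_of, "", transcripts = tx)
  hit <- vapply(only_ab, function(m) cds_of(m, tx) %in% final_cds, NA)
  expect_gte(mean(hit), 0.9)
})

test_that("final_filter applies the hit-list and predicate hooks", {
  models <- lapply(sprintf("g%d", 1:6), function(id) mk(id, cbind(0, 90)))
  expect_identical(final_filter(models), models)

  hl <- tempfile()
  on.exit(unlink(hl))
  writeLines(c("g1", "g3", "g5"), hl)
  kept <- suppressMessages(final_filter(models, hitlist = hl))
  expect_identical(vapply(kept, `[[`, "", "id"), c("g1", "g3", "g5"))

  writeLines(character(), hl)
  expect_warning(none <- suppressMessages(final_filter(models, hitlist = hl)),
                 "empty hit-list")
  expect_length(none, 0)
  expect_error(final_filter(models, hitlist = "no/such/file"), "not found")
})

test_that("one representative per locus, preferring complete then longest", {
  tx <- "T1"
  c300 <- mk("c300", cbind(0, 300))
  c450 <- mk("c450", cbind(50, 500))
  p600 <- mk("p600", cbind(100, 700), complete = FALSE)
  reps <- select_representatives(list(c300, c450, p600))
  expect_length(reps, 1)
  expect_identical(reps[[1]]$id, "c450")

  p200 <- mk("p200", cbind(450, 650), complete = FALSE)
  reps2 <- select_representatives(list(p600, p200))
  expect_identical(reps2[[1]]$id, "p600")

  # non-overlapping models are separate loci
  far <- mk("far", cbind(900, 1200))
  expect_length(select_representatives(list(c300, far)), 2)
})

test_that("gene-set statistics count exons, introns and lengths exactly", {
  m <- mk("m", rbind(c(0, 6), c(18, 24)))
  s <- gene_set_stats(list(m))
  expect_identical(s$n_introns, 1L)
  expect_equal(s$mean_exon_len, 6)
  expect_equal(s$mean_intron_len, 12)
  expect_identical(s$total_len, 12L)

  singles <- list(mk("a", cbind(0, 9)), mk("b", cbind(0, 30), tid = "T2"))
  s2 <- gene_set_stats(singles)
  expect_identical(s2$n_multiexon, 0L)
  expect_true(s2$no_introns)
  expect_equal(s2$mean_intron_len, 0)

  # totals are additive over disjoint sets
  s12 <- gene_set_stats(c(list(m), singles))
  expect_identical(s12$n_genes, s$n_genes + s2$n_genes)
  expect_identical(s12$total_len, s$total_len + s2$total_len)
  expect_identical(s12$n_introns, s$n_introns + s2$n_introns)

  expect_identical(gene_set_stats(list())$n_genes, 0L)
})
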