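test_that("TSV alignment dialect parses fields, blocks and flags", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writeLines(c("P1\t100\tT1\t+\t85.0\t412\t2-8;20-26\t0\t-\t-",
               "P2\t50\tT2\t-\t92.5\t210\t10-40\t2\t+\t-"), path)
  recs <- read_alignments_tsv(path)
  expect_length(recs, 2)
  r <- recs[[1]]
  expect_identical(r$protein_id, "P1")
  expect_identical(unname(r$blocks), cbind(c(2L, 20L), c(8L, 26L)))
  expect_equal(r$percent, 85.0)
  expect_false(r$frameshift)
  expect_true(recs[[2]]$frameshift)
  expect_identical(recs[[2]]$phase, 2L)

  writeLines("P1\t100\tT1\t+\t85.0", path)
  expect_error(read_alignments_tsv(path), "expected 10 fields")

  writeLines("P1\t100\tT1\t+\t85.0\t412\t20-26;2-8\t0\t-\t-", path)
  expect_warning(recs <- read_alignments_tsv(path), "overlapping")
  expect_length(recs, 0)
})

test_that("TSV and Exonerate GFF2 readers agree on paired fixtures", {
  truth <- simulate_truth(sim_preset("noise-free"))
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_fixture(truth, dir)
  tx <- read_fasta(file.path(dir, "assemblyA.fa"))
  a <- read_alignments_tsv(file.path(dir, "evidence.tsv"))
  b <- read_exonerate_gff(file.path(dir, "evidence.gff2"), tx)
  expect_identical(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$protein_id, b[[i]]$protein_id)
    expect_identical(a[[i]]$transcript_id, b[[i]]$transcript_id)
    expect_identical(unname(a[[i]]$blocks), unname(b[[i]]$blocks))
    expect_identical(a[[i]]$strand, b[[i]]$strand)
    expect_equal(a[[i]]$percent, b[[i]]$percent)
    expect_equal(a[[i]]$raw_score, b[[i]]$raw_score)
    expect_identical(a[[i]]$frameshift, b[[i]]$frameshift)
    expect_identical(a[[i]]$earlystop, b[[i]]$earlystop)
  }
})

test_that("GFF2 reader detects early stops in the implied CDS post hoc", {
  # CDS "ATG TAA GCT TAA" carries an internal in-frame stop
  tx <- c(T1 = "ATGTAAGCTTAA")
  path <- tempfile(fileext = ".gff")
  on.exit(unlink(path))
  rec <- protein_alignment("P1", 4, "T1", "+", cbind(0, 12))
  write_exonerate_gff(list(rec), path)
  parsed <- read_exonerate_gff(path, tx)[[1]]
  expect_true(parsed$earlystop)
  expect_false(parsed$frameshift)
})

test_that("GFF3 write -> read is lossless on randomized model sets", {
  set.seed(202)
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path))
  for (rep in 1:20) {
    models <- lapply(sprintf("g%03d", 1:10), random_model)
    write_gff3(models, path)
    back <- read_gff3(path)
    expect_length(back, length(models))
    for (i in seq_along(models)) {
      expect_true(model_fields_equal(models[[i]], back[[i]]))
    }
  }
})

test_that("GFF3 coordinates and phases follow the spec conventions", {
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path))
  m <- gene_model("g1", "T1", "+", cbind(2, 8))
  write_gff3(list(m), path)
  cds_line <- grep("\tCDS\t", readLines(path), value = TRUE)
  expect_match(cds_line, "\t3\t8\t")

  # minus-strand 2-exon model: phases walk 3' -> 5' in transcript coords;
  # re-translation of the phase-trimmed 5' segment must begin in frame
  tx <- c(T2 = paste0("CC", revcomp("ATGGTAAGTATTAG"), "CC"))
  # gene on minus strand: exons (2,7) and (12,16) fwd; spliced revcomp CDS
  m2 <- gene_model("g2", "T2", "-", rbind(c(2, 7), c(12, 16)), phase = 0)
  write_gff3(list(m2), path)
  lines <- grep("\tCDS\t", readLines(path), value = TRUE)
  phases <- as.integer(sapply(strsplit(lines, "\t"), `[`, 8))
  # 5'-most segment (forward-last, 4 nt) has phase 0; the next segment
  # starts mid-codon with phase (3 - 4 %% 3) %% 3 = 2
  expect_identical(phases, c(2L, 0L))

  expect_error(write_gff3(list(m, m), path), "duplicate")
})

test_that("Augustus-dialect CDS features group into models with phase honored", {
  path <- tempfile(fileext = ".gff")
  on.exit(unlink(path))
  writeLines(c(
    "T1\tAUGUSTUS\tgene\t1\t100\t.\t+\t.\tg1",
    "T1\tAUGUSTUS\tCDS\t11\t40\t.\t+\t0\ttranscript_id \"g1.t1\"; gene_id \"g1\";",
    "T1\tAUGUSTUS\tCDS\t61\t90\t.\t+\t0\ttranscript_id \"g1.t1\"; gene_id \"g1\";",
    "T2\tAUGUSTUS\tCDS\t6\t35\t.\t+\t2\ttranscript_id \"g2.t1\";"), path)
  models <- read_abinitio_gff(path)
  expect_length(models, 2)
  expect_identical(nrow(models[[1]]$exons), 2L)
  expect_identical(unname(models[[1]]$exons[1, ]), c(10L, 40L))
  expect_identical(models[[2]]$phase, 2L)
  expect_identical(models[[1]]$source, "abinitio")

  writeLines(character(), path)
  expect_length(read_abinitio_gff(path), 0)

  writeLines(c(
    "T1\tAUGUSTUS\tCDS\t11\t40\t.\t+\t0\ttranscript_id \"g1.t1\";",
    "T1\tAUGUSTUS\tCDS\t61\t90\t.\t-\t0\ttranscript_id \"g1.t1\";"), path)
  expect_warning(models <- read_abinitio_gff(path), "inconsistent strand")
  expect_length(models, 0)
})

test_that("VCF reading types variants and splits multi-allelic sites", {
  path <- tempfile(fileext = ".vcf")
  on.exit(unlink(path))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "T1\t10\t.\tA\tG\t45\t.\tDP=33",
               "T1\t20\t.\tAT\tA\t50\t.\tDP=12",
               "T1\t30\t.\tA\tAGG\t50\t.\tDP=12",
               "T1\t40\t.\tA\tG,C\t60\t.\tDP=99"), path)
  v <- read_vcf(path)
  expect_identical(nrow(v), 5L)
  expect_identical(v$pos[1], 9L)
  expect_identical(v$vtype, c("SNP", "DEL", "INS", "SNP", "SNP"))
  expect_identical(v$alt[4:5], c("G", "C"))
  expect_identical(v$depth[1], 33L)

  tx <- c(T2 = "ACGT")
  w <- capture_warnings(v2 <- read_vcf(path, tx))
  expect_true(all(grepl("unknown transcript", w)))
  expect_identical(nrow(v2), 0L)
})

test_that("VCF writer round-trips through the reader", {
  truth <- simulate_truth(sim_preset("variants"))
  path <- tempfile(fileext = ".vcf")
  on.exit(unlink(path))
  write_vcf(truth$variants, path)
  back <- read_vcf(path)
  expect_identical(nrow(back), nrow(truth$variants))
  expect_identical(back$pos, truth$variants$pos)
  expect_identical(back$ref, truth$variants$ref)
  expect_identical(back$alt, truth$variants$alt)
  expect_identical(back$vtype, truth$variants$vtype)
})
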