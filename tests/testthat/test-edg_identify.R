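test_that("full containment is strict and partial needs one overlapping bp", {
  ecc <- data.frame(chrom = "chr1", start = 100, end = 1000, ecc_id = "e1")
  elems <- data.frame(chrom = "chr1",
                      start = c(200, 50, 990),
                      end = c(300, 150, 1100),
                      element_id = c("in", "left", "right"))
  full <- contained_elements(ecc, elems, "full")
  expect_equal(full$element_id, "in")
  part <- contained_elements(ecc, elems, "partial")
  expect_setequal(part$element_id, c("in", "left", "right"))

  # exactly-abutting element shares no base: not even a partial hit
  abut <- data.frame(chrom = "chr1", start = 1000, end = 1100,
                     element_id = "abut")
  expect_equal(nrow(contained_elements(ecc, abut, "partial")), 0L)
  expect_equal(nrow(contained_elements(ecc[0, ], elems)), 0L)
})

test_that("upstream padding follows the strand and clamps at zero", {
  tx <- data.frame(chrom = "chr1", start = c(200, 200, 10),
                   end = c(500, 500, 40), strand = c("+", "-", "+"))
  out <- pad_transcript(tx, 35)
  expect_equal(out$start, c(165, 200, 0))
  expect_equal(out$end, c(500, 535, 40))

  unk <- data.frame(chrom = "chr1", start = 100, end = 200, strand = "*")
  expect_error(pad_transcript(unk), "unknown strand")
  expect_warning(res <- pad_transcript(unk, assume_plus = TRUE), "padded as")
  expect_equal(res$start, 65)
})

test_that("a gene is an EEG when any padded transcript is contained", {
  ecc <- data.frame(chrom = "chr1", start = 100, end = 1000, ecc_id = "e1")
  tx <- data.frame(chrom = "chr1",
                   start = c(200, 2000, 100),
                   end = c(500, 2400, 1000),
                   strand = "+",
                   transcript_id = c("T1", "T2", "T3"),
                   gene_id = c("GA", "GA", "GB"))
  res <- call_eegs(ecc, tx)
  # GA qualifies through T1; GB's transcript is coextensive with the
  # eccDNA, so the 35 bp pad pushes its start outside: not an EEG
  expect_equal(res$genes, "GA")
  expect_equal(res$evidence$transcript_id, "T1")
  expect_equal(call_eegs(ecc[0, ], tx)$genes, character())
})

test_that("each contained enhancer nominates its single top-S_GE target", {
  ecc <- data.frame(chrom = "chr1", start = 100, end = 1000, ecc_id = "e1")
  enh <- data.frame(chrom = "chr1", start = c(200, 200, 400, 400, 600, 600),
                    end = c(300, 300, 450, 450, 660, 660),
                    enh_id = c("E1", "E1", "E2", "E2", "E3", "E3"),
                    gene_id = c("GATA3", "TP53", "MYC", "ZZZ", "B", "A"),
                    score = c(12.5, 7.1, 9, 2, 3, 3))
  res <- call_ergs(ecc, enh)
  expect_setequal(res$genes, c("GATA3", "MYC", "A"))  # A by gene-id tie-break
  expect_false("TP53" %in% res$genes)

  # two enhancers with the same top target merge into one ERG with both
  enh2 <- data.frame(chrom = "chr1", start = c(200, 400), end = c(300, 450),
                     enh_id = c("E1", "E2"), gene_id = "MYC", score = c(5, 8))
  res2 <- call_ergs(ecc, enh2)
  expect_equal(res2$genes, "MYC")
  expect_setequal(res2$evidence$enh_id, c("E1", "E2"))
})

test_that("EDG calls union EEG/ERG classes and partition by biotype", {
  ecc <- data.frame(chrom = "chr1", start = 100, end = 1000, ecc_id = "e1")
  tx <- data.frame(chrom = "chr1", start = 200, end = 400, strand = "+",
                   transcript_id = "T1", gene_id = "DUAL")
  enh <- data.frame(chrom = "chr1", start = c(500, 700), end = c(560, 760),
                    enh_id = c("E1", "E2"), gene_id = c("DUAL", "LNC"),
                    score = c(9, 9))
  bt <- c(DUAL = "protein_coding", LNC = "lncRNA")
  ct <- call_edgs(ecc, tx, enh, bt, dataset = "d")
  expect_equal(ct$calls$classes[ct$calls$gene_id == "DUAL"], "EEG;ERG")
  expect_equal(ct$coding, "DUAL")
  expect_equal(ct$non_coding, "LNC")
  expect_length(intersect(ct$coding, ct$non_coding), 0)

  # no enhancer table: catalog contains only the EEG
  ct2 <- call_edgs(ecc, tx, NULL, bt, dataset = "d")
  expect_equal(ct2$calls$classes, "EEG")

  # gene missing from the biotype map lands in non-coding with a warning
  expect_warning(ct3 <- call_edgs(ecc, tx, enh, c(DUAL = "protein_coding"),
                                  dataset = "d"),
                 "non-coding")
  expect_true("LNC" %in% ct3$non_coding)
})

test_that("common EDGs follow the dataset-fraction rule", {
  mk <- function(genes) structure(list(coding = genes), class = "edg_catalog")
  cats <- list(mk(c("A", "B")), mk(c("A", "C")), mk(c("A", "B", "D")))
  expect_equal(common_edgs(cats, 0.5, strict = TRUE), c("A", "B"))  # 2/3 > .5
  expect_false("C" %in% common_edgs(cats, 0.5))                     # 1/3
  expect_equal(common_edgs(cats, 1.0, strict = FALSE), "A")  # exact intersection
  expect_error(common_edgs(cats[1L]), ">= 2 dataset")
})

test_that("full-mode calls are a subset of partial-mode calls", {
  for (seed in 1:50) {
    fx <- small_fixture(seed)
    eeg_full <- call_eegs(fx$ecc$eccdnas, fx$ann$transcripts, mode = "full")
    eeg_part <- call_eegs(fx$ecc$eccdnas, fx$ann$transcripts, mode = "partial")
    erg_full <- call_ergs(fx$ecc$eccdnas, fx$ann$enhancers, mode = "full")
    erg_part <- call_ergs(fx$ecc$eccdnas, fx$ann$enhancers, mode = "partial")
    expect_true(all(eeg_full$genes %in% eeg_part$genes))
    expect_true(all(erg_full$genes %in% erg_part$genes))
  }
})

test_that("EDG evidence re-verifies containment under the mode used", {
  fx <- small_fixture(seed = 7)
  ct <- call_edgs(fx$ecc$eccdnas, fx$ann$transcripts, fx$ann$enhancers,
                  fx$ann$biotypes, dataset = "d")
  ecc <- fx$ecc$eccdnas
  padded <- pad_transcript(fx$ann$transcripts)
  ev <- ct$eeg$evidence
  for (i in seq_len(nrow(ev))) {
    e <- ecc[ecc$ecc_id == ev$ecc_id[i], ]
    t <- padded[padded$transcript_id == ev$transcript_id[i], ]
    expect_true(e$start <= t$start && t$end <= e$end && e$chrom == t$chrom)
  }
  ev <- ct$erg$evidence
  enh1 <- fx$ann$enhancers[!duplicated(fx$ann$enhancers$enh_id), ]
  for (i in seq_len(nrow(ev))) {
    e <- ecc[ecc$ecc_id == ev$ecc_id[i], ]
    h <- enh1[enh1$enh_id == ev$enh_id[i], ]
    expect_true(e$start <= h$start && h$end <= e$end)
  }
})

test_that("containment depends only on coordinates, not record order", {
  fx <- small_fixture(seed = 3)
  base <- call_edgs(fx$ecc$eccdnas, fx$ann$transcripts, fx$ann$enhancers,
                    fx$ann$biotypes, dataset = "d")
  set.seed(42)
  shuf <- call_edgs(fx$ecc$eccdnas[sample(nrow(fx$ecc$eccdnas)), ],
                    fx$ann$transcripts[sample(nrow(fx$ann$transcripts)), ],
                    fx$ann$enhancers,
                    fx$ann$biotypes, dataset = "d")
  expect_equal(shuf$calls, base$calls)
})

test_that("the caller recovers exactly the planted genes on synthetic data", {
  for (seed in c(2, 9, 21)) {
    fx <- small_fixture(seed)
    eeg <- call_eegs(fx$ecc$eccdnas, fx$ann$transcripts)
    erg <- call_ergs(fx$ecc$eccdnas, fx$ann$enhancers)
    expect_equal(eeg$genes, fx$ecc$truth$eeg_genes)
    expect_equal(erg$genes, fx$ecc$truth$erg_genes)
  }
})
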