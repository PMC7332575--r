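test_that("the ancestor is quadripartite with identical inverted IR copies", {
  anc <- ancFixture()
  g <- anc$genome
  ft <- genomeFeatures(g)
  irA <- ft[ft$feature_id == "irA", ]
  irB <- ft[ft$feature_id == "irB", ]
  sA <- Biostrings::subseq(genomeSeq(g), irA$start, irA$end)
  sB <- Biostrings::subseq(genomeSeq(g), irB$start, irB$end)
  expect_identical(as.character(sA),
                   as.character(Biostrings::reverseComplement(sB)))
  expect_equal(irA$end - irA$start + 1L, ancestorConfig(scale = 0.1)$ir_len)
  expect_identical(genomeTopology(g), "circular")
})

test_that("IR-compartment genes have two copies, single-copy genes one", {
  anc <- ancFixture()
  ft <- genomeFeatures(anc$genome)
  copies <- table(ft$name[ft$kind == "gene"])
  cat <- defaultGeneCatalog()
  for (nm in cat$name[cat$compartment == "IR"])
    expect_equal(unname(copies[nm]), 2L)
  for (nm in cat$name[cat$compartment != "IR"])
    expect_equal(unname(copies[nm]), 1L)
  expect_equal(countUniqueGenes(anc$genome), 112L)
})

test_that("the truth block table carries labels 1..13 in order", {
  anc <- ancFixture()
  expect_identical(anc$blocks$block_label, 1:13)
  expect_identical(anc$blocks$start[1L], 1L)
  expect_identical(anc$blocks$end[13L], anc$excised_length)
  ## blocks partition the excised frame
  expect_identical(anc$blocks$start[-1L], anc$blocks$end[-13L] + 1L)
})

test_that("IR loss removes exactly one IR copy and its gene copies", {
  anc <- ancFixture()
  ev <- applyEvents(anc$genome, list(evIRLoss("B")))
  expect_equal(genomeLength(ev$genome),
               genomeLength(anc$genome) - ancestorConfig(scale = 0.1)$ir_len)
  ft <- genomeFeatures(ev$genome)
  expect_equal(sum(ft$kind == "gene" & ft$name == "rrn16"), 1L)
  expect_equal(countUniqueGenes(ev$genome), 112L)
  ## no IR-class pair remains detectable
  prs <- classifyIR(ev$genome, min_ir_len = 2000)
  expect_length(Filter(function(p) irClass(p) == "IR", prs), 0L)
})

test_that("an inversion applied twice restores the genome", {
  anc <- ancFixture()
  b <- anc$blocks
  s <- b$start[4L]
  e <- b$end[6L]
  ## work on the IR_B-lost genome so truth coordinates apply
  g0 <- applyEvents(anc$genome, list(evIRLoss("B")))$genome
  g1 <- applyEvents(g0, list(evInversion(s, e)))$genome
  expect_false(as.character(genomeSeq(g1)) == as.character(genomeSeq(g0)))
  g2 <- applyEvents(g1, list(evInversion(s, e)))$genome
  expect_identical(as.character(genomeSeq(g2)), as.character(genomeSeq(g0)))
  f0 <- genomeFeatures(g0)
  f2 <- genomeFeatures(g2)
  expect_equal(f2[order(f2$feature_id), ], f0[order(f0$feature_id), ],
               ignore_attr = TRUE)
})

test_that("gene loss, intron loss and pseudogenization edit the annotation", {
  anc <- ancFixture()
  ev <- applyEvents(anc$genome,
                    list(evIRLoss("B"), evGeneLoss("accD"),
                         evIntronLoss("clpP", 2L), evPseudogenize("rpl20")))
  ft <- genomeFeatures(ev$genome)
  expect_false(any(ft$name == "accD"))
  expect_false(any(ft$kind == "intron" & ft$name == "clpP" &
                     ft$notes == "intron=2", na.rm = TRUE))
  expect_true(any(ft$kind == "intron" & ft$name == "clpP" &
                    ft$notes == "intron=1", na.rm = TRUE))
  pg <- ft[ft$name == "rpl20" & ft$kind == "pseudogene", ]
  expect_equal(nrow(pg), 1L)
  expect_match(pg$notes, "internal_stop")
  ## the lesion is a real in-frame stop codon
  gseq <- genomeSeq(ev$genome)
  body <- as.character(Biostrings::subseq(gseq, pg$start, pg$end))
  if (pg$strand == "-") body <- rcDNA(body)
  codons <- substring(body, seq(1, nchar(body) - 2, 3),
                      seq(3, nchar(body), 3))
  expect_true("TAA" %in% codons[-length(codons)])
  expect_equal(countUniqueGenes(ev$genome), 110L)  # accD lost, rpl20 pseudo
  expect_error(applyEvents(ev$genome, list(evGeneLoss("nosuch"))),
               "scripted-event")
})

test_that("sIR insertion plants exactly one detectable inverted pair", {
  anc <- ancFixture()
  b <- anc$blocks
  ## insertion points sit on spacer/gene boundaries, never inside features
  ev <- applyEvents(anc$genome,
                    list(evIRLoss("B"),
                         evInsertSIR(271L, c(b$start[4L] - 1L,
                                             b$start[8L] - 1L))),
                    seed = 8L)
  prs <- classifyIR(ev$genome, min_ir_len = 2000)
  expect_length(Filter(function(p) irClass(p) == "IR", prs), 0L)
  sirs <- Filter(function(p) irClass(p) == "sIR", prs)
  expect_length(sirs, 1L)
  ## the maximal hit covers the 271 bp insert; chance matches in the
  ## random flanks may extend it by a base or two
  expect_gte(irLength(sirs[[1L]]), 271L)
  expect_lte(irLength(sirs[[1L]]), 277L)
  expect_equal(genomeLength(ev$genome),
               genomeLength(anc$genome) -
                 ancestorConfig(scale = 0.1)$ir_len + 2L * 271L)
})

test_that("translocation moves a block and supports inversion", {
  anc <- ancFixture()
  g0 <- applyEvents(anc$genome, list(evIRLoss("B")))$genome
  b <- ancFixture()$blocks
  s <- b$start[13L]
  e <- b$end[13L]
  L <- e - s + 1L
  ev <- applyEvents(g0, list(evTranslocate(s, e, dest = b$end[1L],
                                           inverted = TRUE)))
  expect_equal(genomeLength(ev$genome), genomeLength(g0))
  ft <- genomeFeatures(ev$genome)
  rpl2 <- ft[ft$name == "rpl2" & ft$kind == "gene", ]
  expect_lt(rpl2$start, b$end[2L])  # now early in the genome
})

test_that("replaying the truth log reproduces the evolved genome exactly", {
  anc <- ancFixture()
  b <- anc$blocks
  script <- list(evIRLoss("B"),
                 evInversion(b$start[5L], b$end[6L]),
                 evInsertSIR(120L, c(b$start[4L] - 1L, b$start[8L] - 1L)),
                 evGeneLoss("rps16"), evPseudogenize("ndhF"))
  ev <- applyEvents(anc$genome, script, seed = 4L)
  rp <- replayTruthLog(anc$genome, ev$log)
  expect_identical(as.character(genomeSeq(rp)),
                   as.character(genomeSeq(ev$genome)))
  expect_equal(genomeFeatures(rp), genomeFeatures(ev$genome),
               ignore_attr = TRUE)
})

test_that("read simulation is deterministic and exact at zero error rate", {
  anc <- ancFixture()
  g <- anc$genome
  cfg <- readSimConfig(n_pairs = 300, read_len = 100, seed = 7)
  td <- withr::local_tempdir()
  f1a <- file.path(td, "a_1.fq"); f2a <- file.path(td, "a_2.fq")
  f1b <- file.path(td, "b_1.fq"); f2b <- file.path(td, "b_2.fq")
  rd1 <- simulateReads(g, cfg, f1a, f2a)
  rd2 <- simulateReads(g, cfg, f1b, f2b)
  expect_identical(readLines(f1a), readLines(f1b))  # byte-identical FASTQ
  expect_identical(readLines(f2a), readLines(f2b))
  s2 <- paste0(as.character(genomeSeq(g)), as.character(genomeSeq(g)))
  for (k in sample(seq_along(rd1$mate1), 50)) {
    m1 <- as.character(rd1$mate1[[k]])
    m2 <- rcDNA(as.character(rd1$mate2[[k]]))
    expect_true(grepl(m1, s2, fixed = TRUE))
    expect_true(grepl(m2, s2, fixed = TRUE))
  }
  ## inserts sit within simulated truth and sane bounds
  expect_true(all(rd1$truth$insert >= 200 & rd1$truth$insert <=
                    genomeLength(g)))
})

test_that("empirical insert mean matches the configured distribution", {
  anc <- ancFixture()
  cfg <- readSimConfig(n_pairs = 2000, read_len = 100,
                       insert_mean = 450, insert_sd = 50, seed = 11)
  rd <- simulateReads(anc$genome, cfg)
  se <- 50 / sqrt(2000)
  expect_lt(abs(mean(rd$truth$insert) - 450), 3 * se)
})
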