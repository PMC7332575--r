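test_that("GFF3 coordinates are 1-based inclusive on both sides", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fa")
  gff <- file.path(td, "g.gff3")
  g <- plastomeGenome("toy", "ACGTACGTAC", topology = "linear",
                      features = data.frame(feature_id = "g1",
                                            kind = "gene", name = "psbA",
                                            start = 1, end = 6,
                                            strand = "+"))
  writeGenome(g, fa, gff)
  lines <- readLines(gff)
  row <- strsplit(grep("\tgene\t", lines, value = TRUE), "\t")[[1L]]
  expect_equal(as.integer(row[4:5]), c(1L, 6L))
  g2 <- readGenome(fa, gff)
  ft <- genomeFeatures(g2)
  expect_equal(ft$start, 1L)
  expect_equal(ft$end, 6L)
  expect_equal(ft$end - ft$start + 1L, 6L)  # width 6: inclusive ends
})

test_that("genome validation rejects features outside the sequence", {
  expect_error(
    plastomeGenome("bad", "ACGTACGTAC",
                   features = data.frame(feature_id = "g1", kind = "gene",
                                         name = "x", start = 5, end = 12,
                                         strand = "+")),
    "within the sequence")
  expect_error(
    plastomeGenome("bad", "ACGTACGTAC",
                   features = data.frame(feature_id = "g1", kind = "gene",
                                         name = "x", start = 6, end = 3,
                                         strand = "+")),
    "start")
})

test_that("write-then-read is the identity on random annotated genomes", {
  td <- withr::local_tempdir()
  set.seed(7)
  for (r in 1:25) {
    n <- sample(200:600, 1)
    nf <- sample(0:5, 1)
    ft <- if (nf > 0) {
      starts <- sort(sample(seq_len(n - 20L), nf))
      data.frame(feature_id = sprintf("f%02d", seq_len(nf)),
                 kind = sample(c("gene", "intron", "exon"), nf, TRUE),
                 name = sprintf("gene%02d", seq_len(nf)),
                 start = starts, end = starts + sample(5:19, nf, TRUE),
                 strand = sample(c("+", "-"), nf, TRUE))
    } else NULL
    g <- plastomeGenome(sprintf("rt%02d", r), rndDNA(n),
                        topology = sample(c("circular", "linear"), 1),
                        features = ft)
    for (fmt in c("fasta+gff3", "feature-table-tsv")) {
      fa <- file.path(td, "x.fa")
      ff <- file.path(td, "x.feat")
      writeGenome(g, fa, ff, format = fmt)
      g2 <- readGenome(fa, ff, format = fmt)
      expect_equal(as.character(genomeSeq(g2)), as.character(genomeSeq(g)))
      expect_identical(genomeTopology(g2), genomeTopology(g))
      f1 <- genomeFeatures(g)
      f2 <- genomeFeatures(g2)
      o1 <- order(f1$start, f1$end, f1$feature_id)
      o2 <- order(f2$start, f2$end, f2$feature_id)
      expect_equal(f2[o2, ], f1[o1, ], ignore_attr = TRUE)
    }
  }
})

test_that("permutation reader parses the published line format", {
  td <- withr::local_tempdir()
  pf <- file.path(td, "perms.txt")
  writeLines(c("Lophopyxis maingayi: 1, 2, 3, 4, -6, -5, 7, 8, 9, 10, -13, 11, 12",
               "Balanops balansae: 1, 2, 3"), pf)
  ps <- readPermutations(pf)
  expect_named(ps, c("Lophopyxis maingayi", "Balanops balansae"))
  expect_identical(permVector(ps[["Lophopyxis maingayi"]]),
                   c(1L, 2L, 3L, 4L, -6L, -5L, 7L, 8L, 9L, 10L, -13L,
                     11L, 12L))
  ## round-trip
  writePermutations(ps, pf)
  expect_identical(lapply(readPermutations(pf), permVector),
                   lapply(ps, permVector))
})

test_that("invalid permutations are rejected with the offending label", {
  td <- withr::local_tempdir()
  pf <- file.path(td, "p.txt")
  writeLines("g: 1, 1, 2", pf)
  expect_error(readPermutations(pf), "duplicate")
  writeLines("g: 1, 3", pf)
  expect_error(readPermutations(pf), "missing label 2")
  writeLines("g: 1, a, 2", pf)
  expect_error(readPermutations(pf), "non-integer")
  expect_error(signedPermutation(c(1, 0, 2)), "nonzero")
})

test_that("loss matrices and block tables validate and round-trip", {
  td <- withr::local_tempdir()
  m <- matrix(c("1", "0", "?", "1"), 2, 2,
              dimnames = list(c("A", "B"), c("accD", "rps16")))
  mf <- file.path(td, "m.tsv")
  writeLossMatrix(m, mf)
  expect_identical(readLossMatrix(mf), m)
  expect_error(plastomeRearr:::validateLossMatrix(matrix("2", 1, 1,
                                         dimnames = list("A", "x"))),
               "states")
  bt <- data.frame(block_label = c(1L, 1L), genome_id = c("g", "g"),
                   start = c(1L, 5L), end = c(10L, 20L),
                   strand = c("+", "+"))
  expect_error(plastomeRearr:::validateBlockTable(bt), "duplicated")
  bt$block_label <- c(1L, 2L)
  expect_error(plastomeRearr:::validateBlockTable(bt), "overlapping")
})
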