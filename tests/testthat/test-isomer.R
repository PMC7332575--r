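test_that("flip-flop inversion is an involution preserving length and content", {
  fx <- sirGenomeFixture()
  g <- fx$genome
  sir <- classifyIR(g, min_sir_len = 30)[[1L]]
  expect_equal(irClass(sir), "sIR")
  flip <- flipIsomer(g, sir)
  expect_equal(genomeLength(flip), genomeLength(g))
  ## reverse complement preserves length and G+C content of the segment
  gc <- function(x) sum(strsplit(as.character(genomeSeq(x)),
                                 "")[[1L]] %in% c("G", "C"))
  expect_identical(gc(flip), gc(g))
  back <- flipIsomer(flip, sir)
  expect_identical(as.character(genomeSeq(back)), as.character(genomeSeq(g)))
  ## sIR copies themselves are untouched
  expect_identical(
    as.character(Biostrings::subseq(genomeSeq(flip), fx$a_start, fx$a_end)),
    as.character(Biostrings::subseq(genomeSeq(g), fx$a_start, fx$a_end)))
})

test_that("a marker between the sIR copies flips strand in the annotation", {
  fx <- sirGenomeFixture()
  g <- fx$genome
  mid <- (fx$a_end + fx$b_start) %/% 2L
  ft <- data.frame(feature_id = "mk", kind = "gene", name = "marker",
                   start = mid, end = mid + 50L, strand = "+")
  g@features <- plastomeRearr:::completeFeatures(ft)
  sir <- irPair(fx$a_start, fx$a_end, fx$b_start, fx$b_end, klass = "sIR")
  flip <- flipIsomer(g, sir)
  expect_identical(genomeFeatures(flip)$strand, "-")
})

test_that("insert filtering is inclusive on both window bounds", {
  pairs <- data.frame(pair_id = as.character(1:5),
                      mate1_start = 1L, mate1_end = 100L,
                      mate2_start = 300L, mate2_end = 400L,
                      proper_orientation = TRUE,
                      insert = c(300L, 330L, 450L, 600L, 601L))
  kept <- filterByInsert(pairs, c(330, 600))
  expect_equal(kept$insert, c(330L, 450L, 600L))
  expect_equal(nrow(filterByInsert(pairs[0, ], c(330, 600))), 0L)
  expect_error(filterByInsert(pairs, c(600, 330)), "lo")
  ## improperly oriented pairs never pass
  pairs$proper_orientation <- FALSE
  expect_equal(nrow(filterByInsert(pairs, c(330, 600))), 0L)
})

test_that("error-free reads map back uniquely with their true inserts", {
  fx <- sirGenomeFixture()
  g <- fx$genome
  rd <- simulateReads(g, readSimConfig(n_pairs = 300, read_len = 100,
                                       seed = 13))
  mp <- mapPairs(rd$mate1, rd$mate2, g)
  ## reads inside the sIR copies are ambiguous and dropped; the rest map
  expect_gt(nrow(mp), 250)
  truth <- rd$truth[match(mp$pair_id, rd$truth$pair_id), ]
  expect_identical(mp$insert, truth$insert)
  expect_identical(((mp$mate1_start - 1L) %% genomeLength(g)) + 1L,
                   ((truth$frag_start - 1L) %% genomeLength(g)) + 1L)
  expect_true(all(mp$proper_orientation))
})

test_that("foreign reads are dropped rather than misplaced", {
  fx <- sirGenomeFixture()
  set.seed(14)
  alien1 <- Biostrings::DNAStringSet(replicate(5, rndDNA(100)))
  alien2 <- Biostrings::DNAStringSet(replicate(5, rndDNA(100)))
  names(alien1) <- names(alien2) <- sprintf("al%02d", 1:5)
  expect_equal(nrow(mapPairs(alien1, alien2, fx$genome)), 0L)
  expect_error(mapPairs(alien1, alien2[1:3], fx$genome), "unequal")
})

test_that("the spanning predicate requires mates strictly flanking the copy", {
  sir <- irPair(1000L, 1270L, 4000L, 4270L, klass = "sIR")
  mk <- function(m1e, m2s) data.frame(pair_id = "p", mate1_start = m1e - 99L,
                                      mate1_end = m1e, mate2_start = m2s,
                                      mate2_end = m2s + 99L,
                                      proper_orientation = TRUE,
                                      insert = m2s + 100L - (m1e - 99L))
  ## mate1 ends 50 bp before the copy, mate2 starts 40 bp after it
  ev <- spanningSupport(mk(950L, 1310L), sir)
  expect_equal(ev$spanning_pairs[["A"]], 1L)
  ## a mate overlapping the copy by one base does not span
  expect_equal(spanningSupport(mk(1000L, 1310L), sir)$spanning_pairs[["A"]],
               0L)
  expect_equal(spanningSupport(mk(950L, 1270L), sir)$spanning_pairs[["A"]],
               0L)
})

test_that("reads from one isomer support it and never the flipped one", {
  fx <- sirGenomeFixture()
  g <- fx$genome
  sir <- classifyIR(g, min_sir_len = 30)[[1L]]
  rd <- simulateReads(g, readSimConfig(n_pairs = 6000, read_len = 90,
                                       insert_mean = 450, insert_sd = 50,
                                       seed = 15))
  ev <- isomerEvidence(rd$mate1, rd$mate2, g, sir, window = c(330, 600))
  expect_true(ev$supported[ev$isomer == "A"])
  expect_false(ev$supported[ev$isomer == "B"])
  expect_equal(ev$spanning_A[ev$isomer == "B"], 0L)
  expect_equal(ev$spanning_B[ev$isomer == "B"], 0L)
})

test_that("a 50/50 isomer mixture supports both configurations", {
  fx <- sirGenomeFixture()
  g <- fx$genome
  sir <- classifyIR(g, min_sir_len = 30)[[1L]]
  rdA <- simulateReads(g, readSimConfig(n_pairs = 3000, read_len = 90,
                                        seed = 16))
  rdB <- simulateReads(flipIsomer(g, sir),
                       readSimConfig(n_pairs = 3000, read_len = 90,
                                     seed = 17))
  m1 <- c(rdA$mate1, rdB$mate1)
  m2 <- c(rdA$mate2, rdB$mate2)
  names(m1) <- names(m2) <- sprintf("mix%05d", seq_along(m1))
  ev <- isomerEvidence(m1, m2, g, sir, window = c(330, 600))
  expect_true(all(ev$supported))
})

test_that("an sIR wider than the insert window can never be spanned", {
  ## with sIR length > hi - 2*read_len, filtered pairs cannot span it
  set.seed(18)
  sirseq <- rndDNA(500)
  ## flanking bases block chance extension of the maximal hit
  g <- plastomeGenome("wide",
                      paste0(rndDNA(1499), "A", sirseq, "C", rndDNA(1498),
                             "C", rcDNA(sirseq), "A", rndDNA(1499)))
  sir <- classifyIR(g, min_sir_len = 30)[[1L]]
  expect_equal(irLength(sir), 500L)
  rd <- simulateReads(g, readSimConfig(n_pairs = 4000, read_len = 90,
                                       seed = 19))
  ev <- isomerEvidence(rd$mate1, rd$mate2, g, sir, window = c(330, 600))
  expect_equal(sum(ev$spanning_A + ev$spanning_B), 0L)
})
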