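test_that("planted exact repeats of every class are found once", {
  set.seed(21)
  base <- rndDNA(500)
  seg <- rndDNA(40)
  plant <- function(second) {
    paste0(substr(base, 1, 100), seg, substr(base, 141, 300), second,
           substr(base, 341, 500))
  }
  crit <- repeatCriteria(30, 0, 1)
  cases <- list(
    forward = seg,
    palindromic = rcDNA(seg),
    reverse = paste(rev(strsplit(seg, "")[[1L]]), collapse = ""),
    complement = chartr("ACGT", "TGCA", seg))
  for (ty in names(cases)) {
    hits <- findRepeats(plant(cases[[ty]]), crit, types = ty)
    expect_equal(nrow(hits), 1L, info = ty)
    expect_equal(hits$type, ty)
    expect_gte(hits$length, 40L)
    expect_equal(hits$mismatches, 0L)
    ## the hit covers the planted copy (chance flank matches may extend it)
    expect_lte(hits$pos1, 101L)
    expect_gte(hits$pos1 + hits$length - 1L, 140L)
  }
})

test_that("a mismatched planted copy reports its Hamming distance and identity", {
  ## copies pinned to the sequence ends so the maximal hit cannot extend
  set.seed(22)
  seg <- rndDNA(40)
  seg2 <- seg
  substr(seg2, 10, 10) <- if (substr(seg, 10, 10) == "A") "C" else "A"
  substr(seg2, 25, 25) <- if (substr(seg, 25, 25) == "G") "T" else "G"
  s <- paste0(seg, rndDNA(300), seg2)
  hits <- findRepeats(s, repeatCriteria(30, 3, 0.90), types = "forward")
  hit <- hits[hits$pos1 == 1L & hits$pos2 == 341L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, 40L)
  expect_equal(hit$mismatches, 2L)
  expect_equal(hit$identity, 0.95)
})

test_that("hit sets equal the brute-force all-pairs oracle on random sequences", {
  set.seed(23)
  for (r in 1:10) {
    s <- rndDNA(sample(300:600, 1))
    crit <- repeatCriteria(10, 2, 0.8)
    a <- findRepeats(s, crit)
    b <- bruteForceRepeats(s, crit)
    o <- function(x) {
      x <- x[order(x$type, x$pos1, x$pos2, x$length), ]
      rownames(x) <- NULL
      x
    }
    expect_equal(o(a), o(b))
  }
})

test_that("every reported hit re-verifies by direct string comparison", {
  set.seed(24)
  s <- rndDNA(800)
  hits <- findRepeats(s, repeatCriteria(8, 2, 0.7))
  expect_gt(nrow(hits), 0L)
  for (r in seq_len(min(nrow(hits), 200)))
    expect_true(recheckHit(s, hits[r, ]))
})

test_that("palindromic hits are invariant under reverse-complementing the input", {
  set.seed(25)
  seg <- rndDNA(35)
  s <- paste0(rndDNA(150), seg, rndDNA(200), rcDNA(seg), rndDNA(100))
  n <- nchar(s)
  h1 <- findRepeats(s, repeatCriteria(30, 0, 1), types = "palindromic")
  h2 <- findRepeats(rcDNA(s), repeatCriteria(30, 0, 1),
                    types = "palindromic")
  expect_equal(nrow(h1), nrow(h2))
  ## positions map p -> n - (p + L - 1) + 1 under reverse complement
  m1 <- sort(c(h1$pos1, h1$pos2))
  m2 <- sort(n - c(h2$pos1 + h2$length - 1L, h2$pos2 + h2$length - 1L) + 1L)
  expect_equal(m1, m2)
})

test_that("non-ACGT bases always count as mismatches, even N vs N", {
  set.seed(26)
  seg36 <- rndDNA(36)
  copy <- paste0(seg36, "NNNN")
  s <- paste0(copy, rndDNA(200), copy)
  hits <- findRepeats(s, repeatCriteria(20, 0, 1), types = "forward")
  hit <- hits[hits$pos1 == 1L, ]
  expect_equal(hit$length, 36L)  # the shared N tail never matches
})

test_that("the large IR and a planted sIR classify correctly", {
  anc <- ancFixture()
  prs <- classifyIR(anc$genome, min_ir_len = 2000)
  irs <- Filter(function(p) irClass(p) == "IR", prs)
  expect_length(irs, 1L)
  expect_equal(irLength(irs[[1L]]), ancestorConfig(scale = 0.1)$ir_len)
  ## after IR loss plus a planted 271 bp inverted duplicate: no IR, one sIR
  b <- anc$blocks
  ev <- applyEvents(anc$genome,
                    list(evIRLoss("B"),
                         evInsertSIR(271L, c(b$start[4L] - 1L,
                                             b$start[8L] - 1L))),
                    seed = 12L)
  prs2 <- classifyIR(ev$genome, min_ir_len = 2000)
  expect_length(Filter(function(p) irClass(p) == "IR", prs2), 0L)
  sirs <- Filter(function(p) irClass(p) == "sIR", prs2)
  expect_length(sirs, 1L)
  ## the maximal hit covers the 271 bp insert; chance matches in the
  ## random flanks may extend it by a base or two
  expect_gte(irLength(sirs[[1L]]), 271L)
  expect_lte(irLength(sirs[[1L]]), 277L)
  ## a genome with no inverted duplicates yields an empty list
  set.seed(31)
  expect_length(classifyIR(plastomeGenome("r", rndDNA(2000))), 0L)
})

test_that("IR pairs spanning the origin are still detected", {
  set.seed(32)
  seg <- rndDNA(400)
  ## copy B wraps the origin: genome = [tail of B] ... A ... [head of B];
  ## copy A is kept clear of the half-rotation point
  s <- paste0(substr(rcDNA(seg), 201, 400), rndDNA(300), seg,
              rndDNA(2600), substr(rcDNA(seg), 1, 200))
  g <- plastomeGenome("wrap", s)
  prs <- classifyIR(g, min_ir_len = 5000, min_sir_len = 30)
  expect_gte(length(prs), 1L)
  expect_true(any(vapply(prs, irLength, integer(1)) >= 400L))
})

test_that("IR excision shortens the genome and removes the duplication", {
  anc <- ancFixture()
  prs <- classifyIR(anc$genome, min_ir_len = 2000)
  ir <- Filter(function(p) irClass(p) == "IR", prs)[[1L]]
  ex <- exciseIRB(anc$genome, ir)
  expect_equal(genomeLength(ex), genomeLength(anc$genome) - irLength(ir))
  expect_equal(genomeLength(ex), anc$excised_length)
  ft <- genomeFeatures(ex)
  expect_equal(sum(ft$kind == "gene" & ft$name == "rrn23"), 1L)
  expect_equal(countUniqueGenes(ex), 112L)
  ## rescan: no repeat pair at IR scale remains
  expect_length(Filter(function(p) irClass(p) == "IR",
                       classifyIR(ex, min_ir_len = 2000)), 0L)
})

test_that("unique-gene counting excludes pseudogenes and counts names once", {
  anc <- ancFixture()
  expect_equal(countUniqueGenes(anc$genome), 112L)
  lost <- c("accD", "rps7", "rps16", "ycf1", "ycf2", "rpl32")
  ev <- applyEvents(anc$genome,
                    c(list(evIRLoss("B")), lapply(lost, evGeneLoss)))
  expect_equal(countUniqueGenes(ev$genome), 106L)
  ev2 <- applyEvents(ev$genome, list(evPseudogenize("rpl20")))
  expect_equal(countUniqueGenes(ev2$genome), 105L)
})
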