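## build a bare genome from a gene-order sketch: list of (name, strand)
sketchGenome <- function(id, genes, glen = 40L * length(genes) + 40L) {
  n <- length(genes)
  starts <- 40L * (seq_len(n) - 1L) + 21L
  ft <- data.frame(feature_id = sprintf("%s_%02d", id, seq_len(n)),
                   kind = "gene",
                   name = vapply(genes, `[[`, character(1), 1L),
                   start = starts, end = starts + 9L,
                   strand = vapply(genes, `[[`, character(1), 2L))
  set.seed(1)
  plastomeGenome(id, rndDNA(glen), topology = "linear", features = ft)
}

test_that("the worked micro-example collapses into three signed blocks", {
  ref <- sketchGenome("ref", list(c("a", "+"), c("b", "+"), c("c", "+"),
                                  c("d", "+"), c("e", "+"), c("f", "+")))
  tgt <- sketchGenome("tgt", list(c("a", "+"), c("b", "+"), c("d", "-"),
                                  c("c", "-"), c("e", "+"), c("f", "+")))
  bt <- buildBlocks(list(ref, tgt), "ref")
  refrows <- bt[bt$genome_id == "ref", ]
  expect_equal(sort(unique(bt$block_label)), 1:3)
  pm <- encodePermutation(bt, "ref", "tgt", circular = FALSE)
  expect_identical(permVector(pm), c(1L, -2L, 3L))
})

test_that("identical gene orders collapse into a single block", {
  ref <- sketchGenome("ref", list(c("a", "+"), c("b", "-"), c("c", "+")))
  tgt <- sketchGenome("tgt", list(c("a", "+"), c("b", "-"), c("c", "+")))
  bt <- buildBlocks(list(ref, tgt), "ref")
  expect_equal(unique(bt$block_label), 1L)
  expect_identical(permVector(encodePermutation(bt, "ref", "tgt",
                                                circular = FALSE)), 1L)
})

test_that("encoding the reference against itself is the identity", {
  anc <- ancFixture()
  bt <- anc$blocks
  expect_identical(permVector(encodePermutation(bt, "ref", "ref")), 1:13)
})

test_that("flipping one target block flips exactly that label's sign", {
  ref <- sketchGenome("ref", list(c("a", "+"), c("b", "+"), c("c", "+"),
                                  c("d", "+")))
  tgt <- sketchGenome("tgt", list(c("a", "+"), c("b", "-"), c("c", "+"),
                                  c("d", "+")))
  bt <- buildBlocks(list(ref, tgt), "ref")
  pm <- permVector(encodePermutation(bt, "ref", "tgt", circular = FALSE))
  expect_equal(sum(pm < 0L), 1L)
  expect_equal(abs(pm), seq_along(pm))
})

test_that("swapping reference and target yields the inverse permutation", {
  ref <- sketchGenome("ref", list(c("a", "+"), c("b", "+"), c("c", "+"),
                                  c("d", "+"), c("e", "+"), c("f", "+")))
  tgt <- sketchGenome("tgt", list(c("e", "+"), c("f", "+"), c("a", "+"),
                                  c("b", "+"), c("d", "-"), c("c", "-")))
  p1 <- permVector(encodePermutation(buildBlocks(list(ref, tgt), "ref"),
                                     "ref", "tgt", circular = FALSE))
  p2 <- permVector(encodePermutation(buildBlocks(list(tgt, ref), "tgt"),
                                     "tgt", "ref", circular = FALSE))
  ## compose p1 over p2: must give the identity
  compose <- function(p, q) {
    out <- integer(length(q))
    for (t in seq_along(q)) {
      v <- p[abs(q[t])]
      out[t] <- sign(q[t]) * v
    }
    out
  }
  expect_equal(abs(compose(p1, p2)), seq_along(p1))
})

test_that("boundary-witnessing inversions recover the truth segmentation", {
  anc <- ancFixture()
  ref_ex <- exciseIRB(anc$genome,
                      Filter(function(p) irClass(p) == "IR",
                             classifyIR(anc$genome, min_ir_len = 2000))[[1L]])
  b <- anc$blocks
  mkinv <- function(bl) {
    r <- b[b$block_label == bl, ]
    evInversion(r$start, r$end)
  }
  ev <- applyEvents(anc$genome,
                    c(list(evIRLoss("B")),
                      lapply(c(2L, 4L, 6L, 8L, 10L, 12L), mkinv)))
  tg <- ev$genome
  tg@id <- "evolved"
  bt <- buildBlocks(list(ref_ex, tg), "ref")
  refrows <- bt[bt$genome_id == "ref", ]
  refrows <- refrows[order(refrows$start), ]
  ## the anchor-free intergenic block cannot be witnessed: the recovered
  ## segmentation is the 13-block truth with block 7 absorbed into block 6
  truth <- anc$blocks
  truth$end[truth$block_label == 6L] <- truth$end[truth$block_label == 7L]
  truth <- truth[truth$block_label != 7L, ]
  truth$block_label <- seq_len(nrow(truth))
  expect_equal(nrow(refrows), 12L)
  expect_equal(refrows$start, truth$start)
  expect_equal(refrows$end, truth$end)
  ## and the encoded permutation flips exactly the six inverted blocks
  pm <- permVector(encodePermutation(bt, "ref", "evolved"))
  expect_identical(abs(pm), 1:12)
  expect_identical(which(pm < 0L), c(2L, 4L, 6L, 7L, 9L, 11L))
})

test_that("block building fails without shared single-copy anchors", {
  g1 <- sketchGenome("g1", list(c("a", "+"), c("b", "+")))
  g2 <- sketchGenome("g2", list(c("x", "+"), c("y", "+")))
  expect_error(buildBlocks(list(g1, g2), "g1"), "anchor")
})
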