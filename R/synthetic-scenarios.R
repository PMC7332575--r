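#' Scripted boundary-respecting inversion scenarios
#'
#' Builds a random evolution scenario for recovery studies: optionally the
#' redundant IR copy is lost, then `k` inversions are applied whose
#' endpoints coincide with synteny-block boundaries, so each scripted
#' inversion corresponds to exactly one reversal of the block order. The
#' expected signed permutation (the composition of the scripted reversals
#' applied to the identity) is returned alongside the evolved genome, so
#' downstream block recovery and distance estimates can be checked against
#' ground truth: the reversal distance of the recovered permutation can
#' never exceed `k`.
#'
#' When the IR is retained (`ir_loss = FALSE`) inversions are restricted
#' to blocks 2..9, which lie in the LSC where coordinates are unaffected
#' by the later IR excision.
#'
#' @param anc output of [generateAncestor()].
#' @param k number of inversions.
#' @param seed integer seed.
#' @param ir_loss apply `evIRLoss("B")` before the inversions.
#' @return list: `genome` (evolved), `script`, `perm_expected` (the
#'   composed [SignedPermutation-class] over the 13 truth blocks), `k`.
#' @export
boundaryInversionScenario <- function(anc, k, seed = 1L, ir_loss = TRUE) {
  blocks <- anc$blocks[order(anc$blocks$start), ]
  nb <- nrow(blocks)
  state <- data.frame(label = blocks$block_label, start = blocks$start,
                      end = blocks$end, sign = 1L)
  perm <- seq_len(nb)
  script <- list()
  withSeed(seed, {
    if (ir_loss) script[[1L]] <- evIRLoss("B")
    lo_ok <- if (ir_loss) 1L else 2L
    hi_ok <- if (ir_loss) nb else 9L
    pick <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
    for (t in seq_len(k)) {
      i <- pick(lo_ok, hi_ok)
      j <- pick(i, hi_ok)
      s <- state$start[i]
      e <- state$end[j]
      script[[length(script) + 1L]] <- evInversion(s, e)
      ## update block spans, order and signs inside the inverted segment
      seg <- i:j
      ns <- s + (e - state$end[seg])
      ne <- s + (e - state$start[seg])
      state[seg, ] <- data.frame(label = rev(state$label[seg]),
                                 start = sort(ns), end = sort(ne),
                                 sign = rev(-state$sign[seg]))
      perm[seg] <- -rev(perm[seg])
    }
  })
  ev <- applyEvents(anc$genome, script, seed = seed + 1L)
  list(genome = ev$genome, script = script, log = ev$log,
       perm_expected = signedPermutation(perm), k = k)
}
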