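#' Detect and classify inverted-repeat pairs (IR and sIR)
#'
#' Finds exact inverted-repeat pairs (maximal palindromic hits with zero
#' mismatches) with disjoint spans. The longest pair of length
#' `>= min_ir_len` is classed `IR` (plastome IR copies are identical, so
#' exact identity between the copies is demanded); every other pair of
#' length `>= min_sir_len` is classed `sIR`, longest first. Circular
#' genomes are additionally scanned in a half-rotated frame so repeat pairs
#' spanning the origin are found; a copy that wraps the origin is reported
#' with `end > genomeLength` (positions taken modulo the length). Nested
#' variants of one physical pair (the two frames can report slightly
#' different maximal extents when a copy abuts the linearization point)
#' are suppressed, longest first.
#'
#' @param genome a [PlastomeGenome-class].
#' @param min_ir_len minimum length to call the large IR (default 10 kb,
#'   cleanly separating canonical ~25 kb IRs from kb-scale sIRs).
#' @param min_sir_len minimum sIR length (default 30, the dispersed-repeat
#'   floor; plastome sIRs down to 11 bp can be requested).
#' @return a list of [IRPair-class] objects (possibly empty, e.g. for
#'   IR-lost genomes with no sIR).
#' @examples
#' anc <- generateAncestor(ancestorConfig(scale = 0.1, seed = 1))
#' classifyIR(anc$genome)
#' @export
classifyIR <- function(genome, min_ir_len = 10000L, min_sir_len = 30L) {
  s <- as.character(genome@seq)
  n <- nchar(s)
  crit <- repeatCriteria(min_sir_len, 0L, 1)
  if (n < crit$min_len) return(list())
  shifts <- 0L
  if (genome@topology == "circular" && n >= 2L * crit$min_len)
    shifts <- c(0L, n %/% 2L)
  cand <- list()
  seen <- character()
  for (sh in shifts) {
    rs <- if (sh == 0L) s else
      paste0(substr(s, sh + 1L, n), substr(s, 1L, sh))
    hits <- findRepeats(rs, crit, types = "palindromic")
    if (nrow(hits) == 0L) next
    for (r in seq_len(nrow(hits))) {
      p1 <- (hits$pos1[r] - 1L + sh) %% n + 1L
      p2 <- (hits$pos2[r] - 1L + sh) %% n + 1L
      L <- hits$length[r]
      if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp }
      key <- paste(p1, p2, L, sep = "_")
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- c(p1, p2, L)
    }
  }
  if (length(cand) == 0L) return(list())
  m <- do.call(rbind, cand)
  ## disjoint on the circle
  disjoint <- vapply(seq_len(nrow(m)), function(r) {
    !circularOverlap(m[r, 1L], m[r, 1L] + m[r, 3L] - 1L,
                     m[r, 2L], m[r, 2L] + m[r, 3L] - 1L, n)
  }, logical(1))
  m <- m[disjoint, , drop = FALSE]
  if (nrow(m) == 0L) return(list())
  m <- m[order(-m[, 3L], m[, 1L]), , drop = FALSE]
  ## suppress nested variants of one physical pair: the two scan frames
  ## can report slightly different maximal extents of the same repeat
  ## (e.g. when a copy abuts the linearization point), so any candidate
  ## whose intervals touch an already-kept pair's copies is dropped,
  ## longest first
  kept <- matrix(integer(0), ncol = 3L)
  for (r in seq_len(nrow(m))) {
    cs <- c(m[r, 1L], m[r, 2L])
    L <- m[r, 3L]
    clash <- FALSE
    for (q in seq_len(nrow(kept))) {
      ks <- c(kept[q, 1L], kept[q, 2L])
      kL <- kept[q, 3L]
      for (a in 1:2) for (b in 1:2) {
        if (circularOverlap(cs[a], cs[a] + L - 1L,
                            ks[b], ks[b] + kL - 1L, n)) clash <- TRUE
      }
    }
    if (!clash) kept <- rbind(kept, m[r, , drop = FALSE])
  }
  m <- kept
  out <- list()
  ir_done <- FALSE
  for (r in seq_len(nrow(m))) {
    L <- m[r, 3L]
    kl <- if (!ir_done && L >= min_ir_len) { ir_done <- TRUE; "IR" }
      else if (L >= min_sir_len) "sIR" else next
    out[[length(out) + 1L]] <- irPair(m[r, 1L], m[r, 1L] + L - 1L,
                                      m[r, 2L], m[r, 2L] + L - 1L,
                                      klass = kl)
  }
  out
}

## do two (possibly origin-wrapping) intervals intersect on a circle of
## circumference n?
circularOverlap <- function(s1, e1, s2, e2, n) {
  pts1 <- ((s1:e1) - 1L) %% n
  pts2 <- ((s2:e2) - 1L) %% n
  length(intersect(pts1, pts2)) > 0L
}

#' Excise the redundant IR copy
#'
#' Removes one full copy of the large inverted repeat before comparative
#' analysis, the standard normalisation for aligning IR-bearing against
#' IR-lost plastomes. Features inside the excised copy are dropped and
#' downstream coordinates shift left; remaining IR-pair annotations are
#' removed (the surviving copy is no longer part of a repeat pair). The
#' output is shorter than the input by exactly the IR length.
#'
#' With `copy = "auto"` the copy designated "B" is the one whose following
#' single-copy region (on the circle) is the shorter one, i.e. the copy
#' sitting between the long and the short single-copy region; this fixed
#' positional convention makes output deterministic.
#'
#' @param genome a [PlastomeGenome-class].
#' @param ir an [IRPair-class] of class `"IR"` found on this genome.
#' @param copy `"auto"`, `"A"` or `"B"` (positional: A is the copy with the
#'   smaller start coordinate).
#' @return the excised [PlastomeGenome-class].
#' @export
exciseIRB <- function(genome, ir, copy = c("auto", "A", "B")) {
  copy <- match.arg(copy)
  if (irClass(ir) != "IR") stop("excision requires an IR-class pair")
  n <- genomeLength(genome)
  if (ir@b_end > 2L * n || ir@a_end > n)
    stop("IR pair does not fit this genome")
  seqA <- as.character(circularSubseq(genome@seq, ir@a_start, ir@a_end))
  seqB <- as.character(circularSubseq(genome@seq, ir@b_start, ir@b_end))
  if (seqA != revcompChar(seqB))
    stop("IR pair not found in genome: copies are not reverse complements")
  if (copy == "auto") {
    gapAB <- ir@b_start - ir@a_end - 1L                 # follows copy A
    gapBA <- (ir@a_start - 1L) + (n - min(ir@b_end, n)) # follows copy B
    copy <- if (gapAB <= gapBA) "A" else "B"
  }
  span <- if (copy == "A") c(ir@a_start, ir@a_end) else
    c(ir@b_start, ir@b_end)
  st <- list(seq = as.character(genome@seq), features = genome@features)
  if (span[2L] > n) {
    ## wrapped copy: delete tail then head
    st <- applyOp(st, list(op = "delete", start = span[1L], end = n))
    st <- applyOp(st, list(op = "delete", start = 1L, end = span[2L] - n))
  } else {
    st <- applyOp(st, list(op = "delete", start = span[1L], end = span[2L]))
  }
  st$features <- st$features[st$features$kind != "IR", ]
  plastomeGenome(genome@id, st$seq, topology = genome@topology,
                 features = st$features)
}

#' Count unique intact genes
#'
#' Distinct gene names with `kind == "gene"`: IR-duplicated genes count
#' once and pseudogenes are excluded, matching the "number of unique
#' genes" convention of plastome feature tables.
#'
#' @param genome a [PlastomeGenome-class].
#' @return integer count.
#' @export
countUniqueGenes <- function(genome) {
  ft <- genome@features
  length(unique(ft$name[ft$kind == "gene"]))
}
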