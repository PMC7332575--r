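#' Flip the segment between an sIR pair (flip-flop recombination)
#'
#' Intramolecular recombination between the two copies of an inverted
#' repeat inverts the sequence strictly between them, producing the other
#' of the two isomeric genome configurations. The repeat copies themselves
#' are left untouched (recombination exchanges them in place), genome
#' length and base composition are unchanged, and applying the flip twice
#' restores the input. Features inside the flipped segment have their
#' coordinates mirrored and strands toggled.
#'
#' @param genome a [PlastomeGenome-class].
#' @param sir an [IRPair-class] (class `"sIR"`) with both copies inside
#'   the genome and a nonempty gap between them.
#' @return the flipped [PlastomeGenome-class].
#' @export
flipIsomer <- function(genome, sir) {
  if (irClass(sir) != "sIR") stop("flip requires an sIR-class pair")
  n <- genomeLength(genome)
  if (sir@b_end > n) stop("sIR copies must lie within the linear frame")
  if (sir@a_end + 1L > sir@b_start - 1L)
    stop("sIR copies overlap or are immediately adjacent")
  st <- list(seq = as.character(genome@seq), features = genome@features)
  st <- applyOp(st, list(op = "invert", start = sir@a_end + 1L,
                         end = sir@b_start - 1L))
  plastomeGenome(genome@id, st$seq, topology = genome@topology,
                 features = st$features)
}

#' Map simulated read pairs onto a genome
#'
#' Exact-substring placement of both mates on the circular sequence (both
#' orientations). A pair is reported when both mates place uniquely on the
#' circle and face inward (FR); the insert is the outer fragment length.
#' Ambiguous or unplaced pairs are dropped. Reads crossing the origin are
#' handled by matching against the doubled sequence; coordinates of the
#' second mate may then exceed the genome length (unwrapped circular
#' coordinates).
#'
#' @param mate1,mate2 [Biostrings::DNAStringSet] of equal length, or paths
#'   to the two FASTQ files.
#' @param genome a [PlastomeGenome-class].
#' @return a `data.frame` of read-pair alignments: `pair_id`,
#'   `mate1_start`, `mate1_end`, `mate2_start`, `mate2_end`,
#'   `proper_orientation`, `insert`.
#' @export
mapPairs <- function(mate1, mate2, genome) {
  if (is.character(mate1)) mate1 <- readFastq(mate1)
  if (is.character(mate2)) mate2 <- readFastq(mate2)
  if (length(mate1) != length(mate2))
    stop("mate files of unequal length")
  n <- genomeLength(genome)
  s2 <- Biostrings::xscat(genome@seq, genome@seq)
  ## all exact start positions per read (modulo the circle), both strands
  allStarts <- function(set) {
    if (length(unique(Biostrings::width(set))) == 1L) {
      idx <- Biostrings::startIndex(
        Biostrings::matchPDict(Biostrings::PDict(unname(set)), s2))
    } else {
      idx <- lapply(seq_along(set), function(k)
        Biostrings::start(Biostrings::matchPattern(set[[k]], s2)))
    }
    lapply(idx, function(v) unique((v - 1L) %% n + 1L))
  }
  f1 <- allStarts(mate1)
  r1 <- allStarts(Biostrings::reverseComplement(mate1))
  f2 <- allStarts(mate2)
  r2 <- allStarts(Biostrings::reverseComplement(mate2))
  place <- function(fwd, rcv) {
    if (length(fwd) + length(rcv) != 1L) return(NULL)
    if (length(fwd) == 1L) list(start = fwd, strand = "+")
    else list(start = rcv, strand = "-")
  }
  rows <- list()
  ids <- names(mate1) %||% as.character(seq_along(mate1))
  ids <- sub("/[12]$", "", ids)
  w1 <- Biostrings::width(mate1)
  w2 <- Biostrings::width(mate2)
  for (k in seq_along(mate1)) {
    p1 <- place(f1[[k]], r1[[k]])
    p2 <- place(f2[[k]], r2[[k]])
    if (is.null(p1) || is.null(p2)) next
    l1 <- w1[k]
    l2 <- w2[k]
    ## orient as (forward mate, reverse mate)
    if (p1$strand == "+" && p2$strand == "-") {
      fs <- p1$start; fl <- l1; rs <- p2$start; rl <- l2
    } else if (p1$strand == "-" && p2$strand == "+") {
      fs <- p2$start; fl <- l2; rs <- p1$start; rl <- l1
    } else next
    ## inward-facing on the circle: reverse mate downstream of forward
    ## mate; unwrap across the origin when needed
    if (rs < fs) rs <- rs + n
    insert <- rs + rl - fs
    proper <- insert >= max(fl, rl) && insert <= n
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = ids[k], mate1_start = fs, mate1_end = fs + fl - 1L,
      mate2_start = rs, mate2_end = rs + rl - 1L,
      proper_orientation = proper, insert = as.integer(insert),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(pair_id = character(), mate1_start = integer(),
                      mate1_end = integer(), mate2_start = integer(),
                      mate2_end = integer(),
                      proper_orientation = logical(), insert = integer()))
  do.call(rbind, rows)
}

#' Filter read pairs by insert size
#'
#' Retains properly oriented pairs whose insert lies inside the window,
#' inclusive on both ends. The default window (330, 600) is the standard
#' short-insert filter used for visual isomer confirmation.
#'
#' @param pairs a `data.frame` from [mapPairs()].
#' @param window numeric pair `(lo, hi)`, `lo < hi`.
#' @return the filtered `data.frame`.
#' @export
filterByInsert <- function(pairs, window = c(330, 600)) {
  if (window[1L] >= window[2L]) stop("window lo must be < hi")
  pairs[pairs$proper_orientation & pairs$insert >= window[1L] &
          pairs$insert <= window[2L], , drop = FALSE]
}

#' Read-pair spanning support for an sIR-mediated isomer
#'
#' A pair spans a repeat copy when one mate ends at or before the copy's
#' start and the other starts at or after its end, i.e. the entire repeat
#' copy lies inside the inner gap between the mates; only such pairs
#' anchor the configuration of the flanks unambiguously. The isomer is
#' `supported` when any copy accumulates at least `min_support` spanning
#' pairs (default 1: existence, not abundance).
#'
#' @param pairs filtered pairs from [filterByInsert()].
#' @param sir an [IRPair-class].
#' @param min_support integer threshold.
#' @return a list of class `IsomerEvidence`: `mapped_pairs`,
#'   `filtered_pairs`, `spanning_pairs` (named vector, copies A and B),
#'   `supported`.
#' @export
spanningSupport <- function(pairs, sir, min_support = 1L) {
  ## one mate entirely before the copy, the other entirely after
  spans <- function(cs, ce) {
    sum(pairs$mate1_end < cs & pairs$mate2_start > ce)
  }
  sa <- spans(sir@a_start, sir@a_end)
  sb <- spans(sir@b_start, sir@b_end)
  structure(list(mapped_pairs = NA_integer_,
                 filtered_pairs = nrow(pairs),
                 spanning_pairs = c(A = sa, B = sb),
                 supported = max(sa, sb) >= min_support),
            class = "IsomerEvidence")
}

#' @export
print.IsomerEvidence <- function(x, ...) {
  cat("IsomerEvidence: filtered_pairs =", x$filtered_pairs,
      " spanning A =", x$spanning_pairs[["A"]],
      " B =", x$spanning_pairs[["B"]],
      " supported =", x$supported, "\n")
  invisible(x)
}

#' Quantify read-pair evidence for both isomers of an sIR
#'
#' Convenience wrapper over the full evidence chain: both isomer
#' configurations are built with [flipIsomer()], reads are mapped to each,
#' filtered by insert size, and spanning support is counted per isomer.
#'
#' @param mate1,mate2 read sets (or FASTQ paths).
#' @param genome a [PlastomeGenome-class] carrying the sIR.
#' @param sir an [IRPair-class] of class `"sIR"`.
#' @param window insert-size window, inclusive.
#' @param min_support spanning pairs required to call an isomer supported.
#' @return a `data.frame` with one row per isomer (`A` = input
#'   configuration, `B` = flipped): mapped, filtered, spanning counts and
#'   the support flag.
#' @export
isomerEvidence <- function(mate1, mate2, genome, sir,
                           window = c(330, 600), min_support = 1L) {
  isoA <- genome
  isoB <- flipIsomer(genome, sir)
  rows <- lapply(list(A = isoA, B = isoB), function(g) {
    mp <- mapPairs(mate1, mate2, g)
    fl <- filterByInsert(mp, window)
    ev <- spanningSupport(fl, sir, min_support)
    data.frame(mapped = nrow(mp), filtered = nrow(fl),
               spanning_A = ev$spanning_pairs[["A"]],
               spanning_B = ev$spanning_pairs[["B"]],
               supported = ev$supported)
  })
  out <- do.call(rbind, rows)
  out <- cbind(isomer = names(rows), out)
  rownames(out) <- NULL
  out
}
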