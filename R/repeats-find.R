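#' Dispersed-repeat search criteria
#'
#' The two criteria sets in routine plastome use are `repeatCriteria(30, 3,
#' 0.90)` (REPuter-style: minimum length 30 bp, Hamming distance up to 3,
#' identity at least 90%) and `repeatCriteria(30, 0, 1)` (exact repeats
#' only).
#'
#' @param min_len minimum repeat length in bases (>= 2).
#' @param max_hamming maximum Hamming distance between the two copies.
#' @param min_identity minimum fraction `(length - mismatches) / length`.
#' @return a list of class `RepeatCriteria`.
#' @export
repeatCriteria <- function(min_len = 30L, max_hamming = 3L,
                           min_identity = 0.90) {
  stopifnot(min_len >= 2L, max_hamming >= 0L,
            min_identity > 0, min_identity <= 1)
  structure(list(min_len = as.integer(min_len),
                 max_hamming = as.integer(max_hamming),
                 min_identity = min_identity), class = "RepeatCriteria")
}

REPEAT_TYPES <- c("forward", "palindromic", "reverse", "complement")

#' Find maximal dispersed repeats under Hamming criteria
#'
#' Enumerates every maximal repeat pair: a pair of equal-length segments
#' whose Hamming distance is at most `max_hamming` and which cannot be
#' extended one base left or right (where the sequence allows) without
#' exceeding it. The second copy is compared verbatim (`forward`), as the
#' reverse complement (`palindromic`, i.e. inverted repeats), as the plain
#' reverse (`reverse`) or as the complement (`complement`). Each unordered
#' occurrence pair is reported once with `pos1 <= pos2`; bases outside
#' A/C/G/T always count as mismatches.
#'
#' The search is exact-seed based: a window of length `min_len` holding at
#' most `max_hamming` mismatches is split by those mismatches into at most
#' `max_hamming + 1` exact runs, so by pigeonhole it contains an exact
#' match of length `ceiling((min_len - max_hamming) / (max_hamming + 1))`.
#' Only alignment diagonals carrying such a seed are scanned, and on long
#' diagonals only mismatch-bounded neighbourhoods of the seeds, so no
#' maximal hit is missed. [bruteForceRepeats()] is the independent
#' all-diagonals oracle used in tests.
#'
#' @param seq character string or [Biostrings::DNAString].
#' @param criteria a [repeatCriteria()].
#' @param types subset of `forward`, `palindromic`, `reverse`, `complement`.
#' @return a `data.frame` with columns `type`, `pos1`, `pos2` (1-based
#'   starts), `length`, `mismatches`, `identity`, sorted by decreasing
#'   length.
#' @examples
#' s <- paste0(strrep("ACGTG", 20), "TTTTACGATCGGATTGCAC",
#'             strrep("CTGAA", 20))
#' findRepeats(s, repeatCriteria(10, 0, 1), types = "forward")
#' @export
findRepeats <- function(seq, criteria = repeatCriteria(),
                        types = REPEAT_TYPES) {
  bad <- setdiff(types, REPEAT_TYPES)
  if (length(bad)) stop("unknown repeat type: ", paste(bad, collapse = ", "))
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < criteria$min_len) stop("sequence shorter than min_len")
  sv <- strsplit(s, "")[[1L]]
  res <- list()
  for (ty in types) {
    tv <- transformSeq(sv, ty)
    seeds <- seedMatches(sv, tv, criteria, self = (ty == "forward"))
    hits <- scanSeededDiagonals(sv, tv, seeds, criteria)
    res[[ty]] <- mapHits(hits, ty, n)
  }
  finishHits(do.call(rbind, res), criteria)
}

#' All-pairs oracle for [findRepeats()]
#'
#' Scans every alignment diagonal exhaustively (no seeding) and extracts
#' maximal windows by prefix-sum search, an implementation independent of
#' the production path. Intended for validation on sequences of a few kb.
#'
#' @inheritParams findRepeats
#' @return same layout as [findRepeats()].
#' @export
bruteForceRepeats <- function(seq, criteria = repeatCriteria(),
                              types = REPEAT_TYPES) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  sv <- strsplit(s, "")[[1L]]
  valid <- c("A", "C", "G", "T")
  res <- list()
  for (ty in types) {
    tv <- transformSeq(sv, ty)
    all_d <- if (ty == "forward") seq_len(n - 1L) else seq(1L - n, n - 1L)
    out <- list()
    for (d in all_d) {
      i0 <- max(1L, 1L - d)
      j0 <- i0 + d
      L <- min(n - i0, n - j0) + 1L
      if (L < criteria$min_len) next
      a <- sv[i0:(i0 + L - 1L)]
      b <- tv[j0:(j0 + L - 1L)]
      mm <- !(a == b & a %in% valid)
      w <- prefixSumWindows(mm, criteria$max_hamming)
      w <- w[w$len >= criteria$min_len, , drop = FALSE]
      if (nrow(w) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        i = i0 + w$a - 1L, j = j0 + w$a - 1L, length = w$len,
        mismatches = w$m)
    }
    hits <- if (length(out)) do.call(rbind, out) else emptyRawHits()
    res[[ty]] <- mapHits(hits, ty, n)
  }
  finishHits(do.call(rbind, res), criteria)
}

transformSeq <- function(sv, type) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  tx <- function(v) {
    out <- comp[v]
    out[is.na(out)] <- "N"
    unname(out)
  }
  switch(type,
    forward = sv,
    complement = tx(sv),
    reverse = rev(sv),
    palindromic = rev(tx(sv)))
}

seedLength <- function(criteria) {
  max(2L, as.integer(ceiling(
    (criteria$min_len - criteria$max_hamming) /
      (criteria$max_hamming + 1L))))
}

## exact q-mer matches between S and T as a list keyed by diagonal
## d = j - i; values are sorted seed start offsets i. Consecutive seeds of
## one exact run are collapsed to the run start.
seedMatches <- function(sv, tv, criteria, self = FALSE) {
  q <- seedLength(criteria)
  n <- length(sv)
  if (n < q) return(list())
  sstr <- paste(sv, collapse = "")
  tstr <- paste(tv, collapse = "")
  sk <- substring(sstr, 1:(n - q + 1L), q:(n))
  tk <- if (self) sk else substring(tstr, 1:(n - q + 1L), q:(n))
  tsplit <- split(seq_along(tk), tk)
  keys <- intersect(unique(sk), names(tsplit))
  if (length(keys) == 0L) return(list())
  ssplit <- split(seq_along(sk), sk)[keys]
  tlist <- tsplit[keys]
  ni <- lengths(ssplit)
  nj <- lengths(tlist)
  i <- rep(unlist(ssplit, use.names = FALSE), rep(nj, ni))
  j <- unlist(lapply(seq_along(keys), function(k)
    rep(tlist[[k]], times = ni[k])), use.names = FALSE)
  d <- j - i
  keep <- if (self) d > 0L else rep(TRUE, length(d))
  i <- i[keep]; d <- d[keep]
  if (length(i) == 0L) return(list())
  o <- order(d, i)
  i <- i[o]; d <- d[o]
  ## collapse runs: a seed whose predecessor on the same diagonal starts
  ## one base earlier belongs to the same exact run
  first <- c(TRUE, !(d[-1L] == d[-length(d)] & i[-1L] == i[-length(i)] + 1L))
  i <- i[first]; d <- d[first]
  keep <- prefilterSeeds(sv, tv, i, i + d, criteria)
  i <- i[keep]; d <- d[keep]
  split(i, d)
}

## vectorized seed triage: a seed can belong to a qualifying hit only if
## some min_len-window containing it has <= max_hamming mismatches; that
## window lies inside a fixed neighbourhood of half-width
## (min_len - seed length) around the seed, so one cumsum over a seed x
## neighbourhood mismatch matrix rejects chance seeds in bulk. Positions
## outside the sequence count as mismatches (no window may cross the ends).
prefilterSeeds <- function(sv, tv, i, j, criteria) {
  ns <- length(i)
  if (ns == 0L) return(logical(0))
  q <- seedLength(criteria)
  ml <- criteria$min_len
  k <- criteria$max_hamming
  if (ml <= q) return(rep(TRUE, ns))
  n <- length(sv)
  offs <- -(ml - q):(ml - 1L)        # neighbourhood relative to seed start
  W <- length(offs)
  I <- outer(i, offs, `+`)
  J <- outer(j, offs, `+`)
  oob <- I < 1L | I > n | J < 1L | J > n
  Ic <- pmin(pmax(I, 1L), n)
  Jc <- pmin(pmax(J, 1L), n)
  a <- sv[Ic]
  mmv <- !(a == tv[Jc] & a %in% c("A", "C", "G", "T")) | oob
  C <- matrix(as.integer(mmv), nrow = ns, ncol = W)
  for (cc in 2L:W) C[, cc] <- C[, cc - 1L] + C[, cc]
  keep <- rep(FALSE, ns)
  for (s in 1L:(ml - q + 1L)) {
    cnt <- C[, s + ml - 1L] - (if (s > 1L) C[, s - 1L] else 0L)
    keep <- keep | cnt <= k
    if (all(keep)) break
  }
  keep
}

## scan only seed-bearing diagonals; on long diagonals restrict to
## mismatch-bounded neighbourhoods of the seed clusters
scanSeededDiagonals <- function(sv, tv, seeds, criteria) {
  n <- length(sv)
  k <- criteria$max_hamming
  q <- seedLength(criteria)
  valid <- c("A", "C", "G", "T")
  out <- list()
  for (dname in names(seeds)) {
    d <- as.integer(dname)
    i0 <- max(1L, 1L - d)
    j0 <- i0 + d
    dlen <- min(n - i0, n - j0) + 1L
    if (dlen < criteria$min_len) next
    offs <- seeds[[dname]] - i0 + 1L  # diagonal-local, 1-based
    if (dlen <= 4096L) {
      a <- sv[i0:(i0 + dlen - 1L)]
      b <- tv[j0:(j0 + dlen - 1L)]
      mm <- !(a == b & a %in% valid)
      w <- anchoredWindows(mm, k)
      w <- w[w$len >= criteria$min_len, , drop = FALSE]
    } else {
      w <- scanDiagonalChunks(sv, tv, i0, j0, dlen, offs, q, k,
                              criteria$min_len)
    }
    if (nrow(w) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      i = i0 + w$a - 1L, j = j0 + w$a - 1L, length = w$len,
      mismatches = w$m)
  }
  if (length(out) == 0L) return(emptyRawHits())
  unique(do.call(rbind, out))
}

## chunked scan of one long diagonal around clustered seeds; each chunk is
## grown until bounded on both sides by > max_hamming mismatches (or the
## diagonal ends), which guarantees every maximal window containing one of
## the seeds is judged exactly as on the full diagonal
scanDiagonalChunks <- function(sv, tv, i0, j0, dlen, offs, q, k, min_len) {
  B <- 256L
  valid <- c("A", "C", "G", "T")
  offs <- sort(offs)
  cl <- cumsum(c(TRUE, offs[-1L] - offs[-length(offs)] > B))
  rows <- list()
  for (g in unique(cl)) {
    so <- offs[cl == g]
    lo <- max(1L, min(so) - B)
    hi <- min(dlen, max(so) + q - 1L + B)
    repeat {
      a <- sv[(i0 + lo - 1L):(i0 + hi - 1L)]
      b <- tv[(j0 + lo - 1L):(j0 + hi - 1L)]
      mm <- !(a == b & a %in% valid)
      left_ok <- lo == 1L || sum(mm[seq_len(min(so) - lo)]) > k
      right_ok <- hi == dlen ||
        sum(mm[(max(so) + q - lo):(hi - lo + 1L)]) > k
      if (left_ok && right_ok) break
      if (!left_ok) lo <- max(1L, lo - 4L * B)
      if (!right_ok) hi <- min(dlen, hi + 4L * B)
    }
    w <- anchoredWindows(mm, k)
    w <- w[w$len >= min_len, , drop = FALSE]
    if (nrow(w) == 0L) next
    w$a <- w$a + lo - 1L
    ## keep windows that contain at least one seed of this cluster; others
    ## are rediscovered (with a correctly bounded chunk) from their own seed
    covers <- vapply(seq_len(nrow(w)), function(r)
      any(so >= w$a[r] & so + q - 1L <= w$a[r] + w$len[r] - 1L),
      logical(1))
    w <- w[covers, , drop = FALSE]
    if (nrow(w) > 0L) rows[[length(rows) + 1L]] <- w
  }
  if (length(rows) == 0L)
    return(data.frame(a = integer(), len = integer(), m = integer()))
  unique(do.call(rbind, rows))
}

## maximal <= k-mismatch windows, anchored on the mismatch positions:
## with sentinels m_0 = 0 and m_{t+1} = L + 1 around the t mismatch
## positions, the maximal windows are exactly
## (m_i + 1, m_{i+k+1} - 1), i = 0..t-k, each holding k mismatches
## (or the whole stretch when t <= k). Fully vectorized.
anchoredWindows <- function(mm, k) {
  L <- length(mm)
  mpos <- which(mm)
  t <- length(mpos)
  if (t <= k) {
    if (L == 0L)
      return(data.frame(a = integer(), len = integer(), m = integer()))
    return(data.frame(a = 1L, len = L, m = t))
  }
  anchors <- c(0L, mpos, L + 1L)
  i <- 0:(t - k)
  a <- anchors[i + 1L] + 1L
  b <- anchors[i + k + 2L] - 1L
  keep <- b >= a
  data.frame(a = a[keep], len = b[keep] - a[keep] + 1L,
             m = rep(k, sum(keep)))
}

## oracle-side window extraction: prefix sums + interval search
prefixSumWindows <- function(mm, k) {
  L <- length(mm)
  P <- c(0L, cumsum(as.integer(mm)))
  bmax <- findInterval(P[seq_len(L)] + k, P) - 1L
  bmax <- pmin(bmax, L)
  keep <- bmax >= seq_len(L)
  maximal <- keep & c(TRUE, bmax[-L] < bmax[-1L])
  a <- which(maximal)
  if (length(a) == 0L)
    return(data.frame(a = integer(), len = integer(), m = integer()))
  b <- bmax[a]
  data.frame(a = a, len = b - a + 1L, m = P[b + 1L] - P[a])
}

emptyRawHits <- function() {
  data.frame(i = integer(), j = integer(), length = integer(),
             mismatches = integer())
}

## translate (i, j) matches in (S, T) space back to positions in S
mapHits <- function(hits, type, n) {
  if (nrow(hits) == 0L) {
    return(data.frame(type = character(), pos1 = integer(),
                      pos2 = integer(), length = integer(),
                      mismatches = integer()))
  }
  if (type %in% c("forward", "complement")) {
    p1 <- hits$i
    p2 <- hits$j
    sel <- p2 > p1  # unordered pairs once; drop the self diagonal
  } else {
    ## T is reversed: T[j..j+L-1] covers S[n-j-L+2 .. n-j+1]
    p1 <- hits$i
    p2 <- n - hits$j - hits$length + 2L
    sel <- rep(TRUE, length(p1))
  }
  df <- data.frame(type = type, pos1 = pmin(p1, p2), pos2 = pmax(p1, p2),
                   length = hits$length, mismatches = hits$mismatches)
  unique(df[sel, , drop = FALSE])
}

finishHits <- function(df, criteria) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(type = character(), pos1 = integer(),
                      pos2 = integer(), length = integer(),
                      mismatches = integer(), identity = numeric()))
  }
  df$identity <- (df$length - df$mismatches) / df$length
  df <- df[df$identity >= criteria$min_identity, , drop = FALSE]
  df <- df[order(-df$length, df$pos1, df$pos2, df$type), ]
  rownames(df) <- NULL
  df
}

#' Write a repeat report
#'
#' Tab-separated `type, pos1, pos2, length, mismatches, identity` with
#' 1-based inclusive positions.
#'
#' @param hits output of [findRepeats()].
#' @param path output path.
#' @export
writeRepeatReport <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
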