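#' Apply a signed reversal
#'
#' Reverses the segment `i..j` (1-based, inclusive) of the permutation and
#' flips the signs inside it. Applying the same reversal twice restores
#' the input.
#'
#' @param perm a [SignedPermutation-class].
#' @param i,j segment bounds, `1 <= i <= j <= n`.
#' @return the rearranged [SignedPermutation-class].
#' @examples
#' permVector(applyReversal(signedPermutation(c(1, 2, 3)), 1, 2))
#' @export
applyReversal <- function(perm, i, j) {
  p <- perm@perm
  n <- length(p)
  if (i < 1L || j > n || i > j) stop("reversal indices out of range")
  p[i:j] <- -rev(p[i:j])
  signedPermutation(p)
}

#' Build the breakpoint graph of a signed permutation
#'
#' Constructs the framed doubled representation and derives the quantities
#' of Hannenhalli-Pevzner theory: breakpoints `b`, cycles `c`, the
#' oriented/unoriented split of the nontrivial components, hurdles `h` and
#' the fortress flag `f`. See [BreakpointGraph-class] for the encoding and
#' [reversalDistance()] for the distance formula they certify.
#'
#' @param perm a [SignedPermutation-class].
#' @return a [BreakpointGraph-class].
#' @examples
#' buildBreakpointGraph(signedPermutation(c(1, 2, 3, 4, -6, -5, 7, 8, 9,
#'                                          10, -13, 11, 12)))
#' @export
buildBreakpointGraph <- function(perm) {
  p <- perm@perm
  n <- length(p)
  u <- framedDouble(p)          # length 2n+2, values 0..2n+1
  b <- countBreakpoints(p)
  comp <- graphComponents(u, n)
  hf <- hurdlesAndFortress(comp, n)
  new("BreakpointGraph", n = n, doubled = u, breakpoints = b,
      cycles = comp$cycles,
      oriented_components = comp$oriented,
      unoriented_components = comp$unoriented,
      hurdles = hf$h, fortress = hf$f)
}

#' Exact signed reversal distance
#'
#' The minimum number of reversals transforming the permutation into the
#' identity, computed in closed form from the breakpoint graph as
#' `d = (n + 1) - c + h + f` (cycles, hurdles, fortress). The identity has
#' `c = n + 1`, hence distance 0.
#'
#' @param perm a [SignedPermutation-class].
#' @return a [DistanceResult-class]; extract the number with
#'   [distanceValue()].
#' @examples
#' distanceValue(reversalDistance(signedPermutation(
#'   c(1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12))))
#' @export
reversalDistance <- function(perm) {
  g <- buildBreakpointGraph(perm)
  d <- (g@n + 1L) - g@cycles + g@hurdles + g@fortress
  new("DistanceResult", d = as.integer(d), graph = g)
}

#' One optimal reversal scenario
#'
#' A shortest sequence of reversals sorting the permutation to the
#' identity. At each step all O(n^2) candidate reversals are evaluated and
#' the lexicographically smallest `(i, j)` that lowers the distance by
#' exactly one is applied; Hannenhalli-Pevzner theory guarantees such a
#' reversal always exists, and the fixed tie-break makes the (non-unique)
#' optimal scenario reproducible.
#'
#' @param perm a [SignedPermutation-class].
#' @return integer matrix with columns `i`, `j`, one row per step (zero
#'   rows for the identity); attribute `"intermediates"` holds the list of
#'   permutations after each step.
#' @examples
#' optimalScenario(signedPermutation(c(-1, 2)))
#' @export
optimalScenario <- function(perm) {
  cur <- perm
  d <- distanceValue(reversalDistance(cur))
  steps <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  inter <- list()
  n <- length(cur)
  while (d > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        cand <- applyReversal(cur, i, j)
        if (distanceValue(reversalDistance(cand)) == d - 1L) {
          steps <- rbind(steps, c(i, j))
          cur <- cand
          d <- d - 1L
          inter[[length(inter) + 1L]] <- cur
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-reducing reversal found")
  }
  attr(steps, "intermediates") <- inter
  steps
}

#' Replay a reversal scenario
#'
#' @param perm starting [SignedPermutation-class].
#' @param steps matrix of `(i, j)` rows as from [optimalScenario()].
#' @return the resulting [SignedPermutation-class].
#' @export
replayScenario <- function(perm, steps) {
  for (r in seq_len(nrow(steps)))
    perm <- applyReversal(perm, steps[r, 1L], steps[r, 2L])
  perm
}

#' Exhaustive reversal-distance oracle
#'
#' Iterative-deepening search over reversal sequences, pruned by the cycle
#' lower bound `(n + 1) - c`; returns the true minimum. Exponential: meant
#' for validating [reversalDistance()] on permutations with `n <= 8`.
#'
#' @param perm a [SignedPermutation-class] with `n <= 8`.
#' @return integer distance.
#' @export
exhaustiveDistance <- function(perm) {
  p <- perm@perm
  n <- length(p)
  if (n > 8L) stop("exhaustive search refused for n > 8")
  lb0 <- cycleLowerBound(p)
  if (lb0 == 0L) return(0L)
  revs <- which(upper.tri(matrix(0L, n, n), diag = TRUE), arr.ind = TRUE)
  dfs <- function(q, g, limit) {
    lb <- cycleLowerBound(q)
    if (lb == 0L) return(TRUE)
    if (g + lb > limit) return(FALSE)
    for (r in seq_len(nrow(revs))) {
      i <- revs[r, 1L]; j <- revs[r, 2L]
      q2 <- q
      q2[i:j] <- -rev(q2[i:j])
      if (dfs(q2, g + 1L, limit)) return(TRUE)
    }
    FALSE
  }
  limit <- lb0
  repeat {
    if (dfs(p, 0L, limit)) return(limit)
    limit <- limit + 1L
  }
}

## ---- internal HP machinery -------------------------------------------

## framed doubling: 0, pairs per element, 2n+1
framedDouble <- function(p) {
  n <- length(p)
  u <- integer(2L * n + 2L)
  u[1L] <- 0L
  for (t in seq_len(n)) {
    x <- p[t]
    if (x > 0L) {
      u[2L * t] <- 2L * x - 1L
      u[2L * t + 1L] <- 2L * x
    } else {
      u[2L * t] <- -2L * x
      u[2L * t + 1L] <- -2L * x - 1L
    }
  }
  u[2L * n + 2L] <- 2L * n + 1L
  u
}

## breakpoints of the framed signed reading: consecutive framed pair
## (x, y) is an adjacency iff y == x + 1
countBreakpoints <- function(p) {
  fr <- c(0L, p, length(p) + 1L)
  sum(fr[-1L] != fr[-length(fr)] + 1L)
}

## cycles, nontrivial components and their orientation.
## Black edge t joins positions 2t-1 and 2t (values u[2t-1], u[2t]);
## gray edge v (v = 0, 2, 4, ..., 2n) joins values v and v+1. A gray edge
## is oriented iff its two endpoint positions have equal parity; a
## component is oriented iff it contains an oriented gray edge.
graphComponents <- function(u, n) {
  N <- 2L * n + 2L
  pos <- integer(N)
  pos[u + 1L] <- seq_len(N)     # pos[value + 1] = position (1-based)
  ## union-find over values for cycles
  parent <- seq_len(N)
  findp <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unionp <- function(a, b) {
    ra <- findp(a); rb <- findp(b)
    if (ra != rb) parent[ra] <<- rb
  }
  for (t in seq_len(n + 1L))            # black edges
    unionp(u[2L * t - 1L] + 1L, u[2L * t] + 1L)
  gv <- seq(0L, 2L * n, by = 2L)        # gray edge v -- v+1
  for (v in gv) unionp(v + 1L, v + 2L)
  cyc_id <- vapply(seq_len(N), findp, integer(1))
  cycles <- length(unique(cyc_id))

  ## gray edges as position intervals
  gp1 <- pos[gv + 1L]
  gp2 <- pos[gv + 2L]
  glo <- pmin(gp1, gp2)
  ghi <- pmax(gp1, gp2)
  goriented <- (gp1 %% 2L) == (gp2 %% 2L)
  gcycle <- cyc_id[gv + 1L]             # cycle of each gray edge
  ## an adjacency (trivial cycle) has exactly one gray edge; nontrivial
  ## cycles have more
  ge_per_cycle <- table(gcycle)
  nontrivial <- names(ge_per_cycle)[ge_per_cycle > 1L]
  ## union-find over cycles: interleaving gray edges join their cycles
  cyc_keys <- unique(gcycle)
  cparent <- seq_along(cyc_keys)
  names(cparent) <- cyc_keys
  cfind <- function(x) {
    while (cparent[x] != x) x <- cparent[x]
    x
  }
  cunion <- function(a, b) {
    ra <- cfind(a); rb <- cfind(b)
    if (ra != rb) cparent[ra] <<- rb
  }
  ng <- length(gv)
  if (ng > 1L) {
    for (a in seq_len(ng - 1L)) {
      for (b in (a + 1L):ng) {
        if ((glo[a] < glo[b] & glo[b] < ghi[a] & ghi[a] < ghi[b]) ||
            (glo[b] < glo[a] & glo[a] < ghi[b] & ghi[b] < ghi[a]))
          cunion(match(gcycle[a], cyc_keys), match(gcycle[b], cyc_keys))
      }
    }
  }
  comp_of_cycle <- vapply(seq_along(cyc_keys), cfind, integer(1))
  names(comp_of_cycle) <- cyc_keys
  ## components containing at least one nontrivial cycle
  comp_ids <- unique(comp_of_cycle[nontrivial])
  comp_list <- lapply(comp_ids, function(cid) {
    cyc_in <- cyc_keys[comp_of_cycle == cid]
    ge <- which(gcycle %in% as.integer(cyc_in))
    positions <- sort(unique(c(glo[ge], ghi[ge])))
    list(oriented = any(goriented[ge]), positions = positions)
  })
  list(cycles = cycles,
       oriented = sum(vapply(comp_list, `[[`, logical(1), "oriented")),
       unoriented = sum(!vapply(comp_list, `[[`, logical(1), "oriented")),
       components = comp_list)
}

## hurdles on the circle of unoriented-component positions: a hurdle is an
## unoriented component whose positions are consecutive in the circular
## order of all unoriented components' positions; a superhurdle is a
## hurdle whose removal turns another unoriented component into a hurdle;
## a fortress has an odd number of hurdles, all of them superhurdles
hurdlesAndFortress <- function(comp, n) {
  un <- Filter(function(x) !x$oriented, comp$components)
  hs <- hurdleSet(un)
  h <- length(hs)
  f <- 0L
  if (h > 0L && h %% 2L == 1L) {
    ## i is a superhurdle iff deleting it makes some previously-non-hurdle
    ## component a hurdle
    super <- vapply(hs, function(i) {
      rest_idx <- setdiff(seq_along(un), i)
      new_h <- rest_idx[hurdleSet(un[rest_idx])]
      old_h <- setdiff(hs, i)
      length(setdiff(new_h, old_h)) > 0L
    }, logical(1))
    if (all(super)) f <- 1L
  }
  list(h = as.integer(h), f = f)
}

## indices of components (within `un`) that are hurdles
hurdleSet <- function(un) {
  if (length(un) == 0L) return(integer(0))
  if (length(un) == 1L) return(1L)
  allpos <- sort(unique(unlist(lapply(un, `[[`, "positions"))))
  owner <- integer(length(allpos))
  for (i in seq_along(un))
    owner[allpos %in% un[[i]]$positions] <- i
  which(vapply(seq_along(un), function(i) {
    ## consecutive on the circle: the owner sequence, rotated so a
    ## non-i element comes first, shows i's positions in one run
    o <- owner
    if (all(o == i)) return(TRUE)
    k <- which(o != i)[1L]
    o <- c(o[k:length(o)], o[seq_len(k - 1L)])
    runs <- rle(o)$values
    sum(runs == i) == 1L
  }, logical(1)))
}

cycleLowerBound <- function(p) {
  n <- length(p)
  u <- framedDouble(p)
  N <- 2L * n + 2L
  parent <- seq_len(N)
  findp <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (t in seq_len(n + 1L)) {
    a <- findp(u[2L * t - 1L] + 1L); b <- findp(u[2L * t] + 1L)
    if (a != b) parent[a] <- b
  }
  for (v in seq(0L, 2L * n, by = 2L)) {
    a <- findp(v + 1L); b <- findp(v + 2L)
    if (a != b) parent[a] <- b
  }
  cycles <- length(unique(vapply(seq_len(N), findp, integer(1))))
  (n + 1L) - cycles
}
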