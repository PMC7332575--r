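#' Map irreversible losses onto a rooted tree (Dollo parsimony)
#'
#' For each binary character (1 = present/intact, 0 = lost or pseudogene,
#' ? = unknown) the minimum set of irreversible loss events explaining the
#' tips is placed on the tree: the root state is fixed to "present" and
#' one event is assigned to the stem of each maximal clade whose scored
#' leaves are all 0 and which contains at least one 0 (leaves scored `?`
#' are compatible with either state and never create or forbid an event).
#' When every leaf is 0 the single event sits on the root's own branch,
#' spanning all taxa.
#'
#' Taxa present in the tree but absent from the matrix are treated as `?`.
#'
#' @param tree a rooted `phylo` object (see [ape::read.tree()]).
#' @param matrix character matrix of states, taxa as rownames, characters
#'   as colnames (see [readLossMatrix()]); taxa must be a subset of the
#'   tree's leaves.
#' @return a `data.frame` with one row per character: `character`,
#'   `event_count`, `event_branches` (branches named by the sorted leaf
#'   set of the clade below, `;`-separated).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' m <- matrix(c("0", "0", "1", "1"), ncol = 1,
#'             dimnames = list(c("A", "B", "C", "D"), "accD"))
#' dolloLosses(tr, m)
#' @export
dolloLosses <- function(tree, matrix) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  matrix <- validateLossMatrix(matrix)
  miss <- setdiff(rownames(matrix), tree$tip.label)
  if (length(miss))
    stop("taxa absent from tree: ", paste(miss, collapse = ", "))
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  rows <- lapply(colnames(matrix), function(ch) {
    st <- rep("?", nt)
    names(st) <- tree$tip.label
    st[rownames(matrix)] <- matrix[, ch]
    ## bottom-up: per node, does the clade hold any 1-leaf / any 0-leaf?
    any1 <- logical(nn)
    any0 <- logical(nn)
    any1[seq_len(nt)] <- st == "1"
    any0[seq_len(nt)] <- st == "0"
    ## fixed-point sweeps instead of an explicit post-order; trees are small
    repeat {
      changed <- FALSE
      for (v in names(kids)) {
        vi <- as.integer(v)
        a1 <- any(any1[kids[[v]]])
        a0 <- any(any0[kids[[v]]])
        if (a1 != any1[vi] || a0 != any0[vi]) {
          any1[vi] <- a1
          any0[vi] <- a0
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    ## event nodes: loss-compatible (no 1 below), contain a 0, and the
    ## parent is not loss-compatible (or the node is the root)
    parent <- integer(nn)
    parent[tree$edge[, 2L]] <- tree$edge[, 1L]
    compatible <- !any1
    ev <- which(compatible & any0 &
                  (seq_len(nn) == root | !compatible[pmax(parent, 1L)]))
    labels <- vapply(ev, function(v)
      paste(sort(cladeLeaves(v, kids, nt, tree$tip.label)),
            collapse = ";"), character(1))
    data.frame(character = ch, event_count = length(ev),
               event_branches = paste(sort(labels), collapse = " | "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cladeLeaves <- function(v, kids, nt, tips) {
  if (v <= nt) return(tips[v])
  unlist(lapply(kids[[as.character(v)]], cladeLeaves, kids = kids,
                nt = nt, tips = tips))
}

#' Brute-force minimal-event oracle for Dollo mapping
#'
#' Enumerates event-branch subsets of increasing size and returns the
#' smallest number of pairwise non-nested branches such that every 0-leaf
#' lies below exactly one event, no 1-leaf lies below any, and `?` leaves
#' are unconstrained. Independent of [dolloLosses()]; for trees with up to
#' ~8 leaves.
#'
#' @inheritParams dolloLosses
#' @return integer vector of minimal event counts, one per character.
#' @export
dolloOracle <- function(tree, matrix) {
  matrix <- validateLossMatrix(matrix)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- lapply(seq_len(nn), function(v)
    match(cladeLeaves(v, kids, nt, tree$tip.label), tree$tip.label))
  masks <- vapply(below, function(lv) sum(bitwShiftL(1L, lv - 1L)),
                  integer(1))
  vapply(colnames(matrix), function(ch) {
    st <- rep("?", nt)
    names(st) <- tree$tip.label
    st[rownames(matrix)] <- matrix[, ch]
    zmask <- sum(bitwShiftL(1L, which(st == "0") - 1L))
    omask <- sum(bitwShiftL(1L, which(st == "1") - 1L))
    if (zmask == 0L) return(0L)
    ## candidate branches: no 1-leaf below
    cand <- which(vapply(masks, function(m) bitwAnd(m, omask) == 0L,
                         logical(1)))
    for (size in seq_len(length(cand))) {
      for (sel in utils::combn(cand, size, simplify = FALSE)) {
        ms <- masks[sel]
        ## pairwise disjoint and covering all zeros
        tot <- 0L
        ok <- TRUE
        for (m in ms) {
          if (bitwAnd(tot, m) != 0L) { ok <- FALSE; break }
          tot <- bitwOr(tot, m)
        }
        if (ok && bitwAnd(zmask, bitwNot(tot)) == 0L &&
            all(vapply(ms, function(m) bitwAnd(m, zmask) != 0L,
                       logical(1))))
          return(size)
      }
    }
    stop("oracle found no consistent assignment")
  }, integer(1))
}

#' Score loss characters from annotated genomes
#'
#' State 1 when an intact feature satisfying the character's predicate
#' exists in the genome (for gene characters: `kind == "gene"`, so a
#' pseudogenized copy scores 0 together with physical losses; for intron
#' characters: the intron feature exists), else 0.
#'
#' @param genomes list of [PlastomeGenome-class] objects.
#' @param watch_list named list: each element is either a gene name
#'   (character scalar, gene-presence character) or a list
#'   `list(gene =, intron =)` for an intron-presence character.
#' @return a character matrix suitable for [dolloLosses()], genomes as
#'   rows.
#' @export
charactersFromGenomes <- function(genomes, watch_list) {
  ids <- vapply(genomes, genomeId, character(1))
  m <- matrix("0", nrow = length(genomes), ncol = length(watch_list),
              dimnames = list(ids, names(watch_list)))
  for (g in seq_along(genomes)) {
    ft <- genomeFeatures(genomes[[g]])
    for (w in seq_along(watch_list)) {
      spec <- watch_list[[w]]
      present <- if (is.character(spec)) {
        any(ft$kind == "gene" & ft$name == spec)
      } else {
        tag <- sprintf("intron=%d", spec$intron)
        any(ft$kind == "intron" & ft$name == spec$gene &
              !is.na(ft$notes) & ft$notes == tag)
      }
      m[g, w] <- if (present) "1" else "0"
    }
  }
  m
}
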