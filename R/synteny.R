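#' Gene order of a genome
#'
#' The ordered list of (gene name, strand) along the genome from the
#' origin, taken from `kind == "gene"` features sorted by start.
#' Pseudogenes are excluded (they no longer anchor homology reliably).
#'
#' @param genome a [PlastomeGenome-class].
#' @return a `data.frame` with columns `name`, `strand`, `start`, `end`.
#' @export
geneOrder <- function(genome) {
  ft <- genome@features
  g <- ft[ft$kind == "gene", c("name", "strand", "start", "end")]
  g <- g[order(g$start), ]
  rownames(g) <- NULL
  g
}

#' Build synteny blocks from shared gene anchors
#'
#' A desk-scale stand-in for whole-genome-alignment block finding: genes
#' present exactly once in every genome act as signed anchors, and maximal
#' anchor runs that are consecutive with consistent relative orientation in
#' all genomes collapse into one block. Blocks are numbered `1..n` in
#' reference order. Gene-free sequence cannot be anchored and is absorbed
#' into the preceding block's span (the head of the genome joins the first
#' block); block boundaries that no compared genome breaks are invisible
#' to this method, so the segmentation is the coarsest one consistent with
#' the witnessed breakpoints.
#'
#' @param genomes list of [PlastomeGenome-class] objects (>= 2), the first
#'   or the one named by `reference_id` acting as reference.
#' @param reference_id id of the reference genome.
#' @return a block table `data.frame` (`block_label`, `genome_id`, `start`,
#'   `end`, `strand`) covering all genomes.
#' @seealso [encodePermutation()]
#' @export
buildBlocks <- function(genomes, reference_id = genomeId(genomes[[1L]])) {
  ids <- vapply(genomes, genomeId, character(1))
  names(genomes) <- ids
  if (!reference_id %in% ids) stop("reference_id not among genomes")
  orders <- lapply(genomes, geneOrder)
  ## anchors: single-copy in every genome (IR-duplicated genes excluded)
  counts <- lapply(orders, function(o) table(o$name))
  shared <- Reduce(intersect, lapply(counts, names))
  anchors <- shared[vapply(shared, function(nm)
    all(vapply(counts, function(tb) tb[[nm]] == 1L, logical(1))),
    logical(1))]
  if (length(anchors) == 0L) stop("no shared single-copy anchor genes")
  ref <- orders[[reference_id]]
  ref <- ref[ref$name %in% anchors, ]
  m <- nrow(ref)
  refidx <- seq_len(m)
  names(refidx) <- ref$name
  refsign <- ifelse(ref$strand == "+", 1L, -1L)
  names(refsign) <- ref$name
  ## a boundary between reference anchors i and i+1 is cut when some
  ## genome does not carry the two anchors adjacently in consistent
  ## relative orientation
  cut <- rep(FALSE, m - 1L)
  for (id in setdiff(ids, reference_id)) {
    o <- orders[[id]]
    o <- o[o$name %in% anchors, ]
    sgn <- ifelse(o$strand == "+", 1L, -1L) * refsign[o$name]
    idx <- refidx[o$name] * sgn
    adj <- rep(FALSE, m - 1L)
    pairs <- cbind(idx[-length(idx)], idx[-1L])
    if (genomes[[id]]@topology == "circular" && length(idx) > 1L)
      pairs <- rbind(pairs, c(idx[length(idx)], idx[1L]))
    for (t in seq_len(nrow(pairs))) {
      a <- pairs[t, 1L]; b <- pairs[t, 2L]
      ## adjacent consistent: (+r, +(r+1)) or (-(r+1), -r)
      if (b == a + 1L) {
        if (a > 0L) adj[a] <- TRUE else adj[abs(b)] <- TRUE
      }
    }
    cut <- cut | !adj
  }
  block_of <- c(1L, 1L + cumsum(cut))
  nblocks <- max(block_of)
  rows <- list()
  for (id in ids) {
    o <- orders[[id]]
    o <- o[o$name %in% anchors, ]
    b <- block_of[refidx[o$name]]
    s <- ifelse(o$strand == "+", 1L, -1L) * refsign[o$name]
    glen <- genomeLength(genomes[[id]])
    ## runs of one block along this genome
    runs <- c(0L, cumsum(b[-1L] != b[-length(b)]))
    rows[[id]] <- do.call(rbind, lapply(split(seq_along(b), runs),
      function(ix) {
        data.frame(block_label = b[ix[1L]], genome_id = id,
                   start = min(o$start[ix]), end = max(o$end[ix]),
                   strand = if (s[ix[1L]] > 0L) "+" else "-",
                   stringsAsFactors = FALSE)
      }))
  }
  bt <- do.call(rbind, rows)
  rownames(bt) <- NULL
  absorbSpans(bt, genomes)
}

## anchor-free sequence attaches to the preceding block: each block ends
## just before the next block's first anchor; the genome head joins the
## first block and the last block runs to the genome end
absorbSpans <- function(bt, genomes) {
  out <- list()
  for (id in unique(bt$genome_id)) {
    sub <- bt[bt$genome_id == id, ]
    sub <- sub[order(sub$start), ]
    glen <- genomeLength(genomes[[id]])
    sub$end <- c(sub$start[-1L] - 1L, glen)
    sub$start[1L] <- 1L
    out[[id]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Encode a genome as a signed permutation of block labels
#'
#' Blocks are listed in target coordinate order; each label's sign is the
#' product of the block's strand in the target and in the reference, so
#' the reference itself encodes as the identity. Circular genomes are
#' linearized at block 1: the target's block order is rotated so the block
#' labeled 1 comes first, and read in the orientation that makes that
#' block positive (the convention under which published block orders all
#' begin with "1").
#'
#' @param blocks a block table as from [buildBlocks()] or
#'   [readBlockTable()].
#' @param reference_id,target_id genome ids present in the table; the two
#'   genomes must carry identical block-label sets.
#' @param circular rotate/orient as described (set `FALSE` for genomes
#'   whose linearization is already meaningful).
#' @return a [SignedPermutation-class].
#' @export
encodePermutation <- function(blocks, reference_id, target_id,
                              circular = TRUE) {
  ref <- blocks[blocks$genome_id == reference_id, ]
  tgt <- blocks[blocks$genome_id == target_id, ]
  if (nrow(ref) == 0L) stop("reference ", reference_id, " not in table")
  if (nrow(tgt) == 0L) stop("target ", target_id, " not in table")
  miss <- setdiff(ref$block_label, tgt$block_label)
  extra <- setdiff(tgt$block_label, ref$block_label)
  if (length(miss) || length(extra))
    stop("block-label sets differ (missing: ",
         paste(miss, collapse = ","), "; extra: ",
         paste(extra, collapse = ","), ")")
  ref <- ref[order(ref$start), ]
  ## relabel so the reference reads 1..n
  relabel <- seq_len(nrow(ref))
  names(relabel) <- as.character(ref$block_label)
  refsign <- ifelse(ref$strand == "+", 1L, -1L)
  names(refsign) <- as.character(ref$block_label)
  tgt <- tgt[order(tgt$start), ]
  lab <- relabel[as.character(tgt$block_label)]
  sgn <- ifelse(tgt$strand == "+", 1L, -1L) *
    refsign[as.character(tgt$block_label)]
  p <- unname(lab * sgn)
  if (circular && length(p) > 1L) {
    k <- which(abs(p) == 1L)
    p <- c(p[k:length(p)], p[seq_len(k - 1L)])[seq_along(p)]
    if (p[1L] < 0L) p <- rev(-p)
    if (p[1L] != 1L) p <- c(p[which(p == 1L):length(p)],
                            p[seq_len(which(p == 1L) - 1L)])
  }
  signedPermutation(p)
}
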