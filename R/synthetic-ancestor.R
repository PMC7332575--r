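#' Generate a synthetic quadripartite plastome ancestor
#'
#' Assembles a circular genome `LSC | IR_B | SSC | IR_A` in which the two
#' IR copies are exact reverse complements of each other, genes are placed
#' per the catalog with i.i.d. random intergenic spacers, protein genes are
#' clean ORFs (ATG ... stop, no internal stop codons), and intron-bearing
#' genes carry annotated exon/intron sub-features. Because spacers and gene
#' bodies are uniform random DNA, the only repeats in the genome are the
#' ones constructed deliberately, which makes planted-repeat tests exact.
#'
#' The redundant copy (the one excised before comparative analysis, named
#' `IR_B` as it precedes the short single-copy region) sits between LSC
#' and SSC; the retained copy follows the SSC, so that the IR_B-excised
#' genome reads synteny blocks 1..13 in order. The returned truth block
#' table is expressed in the coordinates of that excised frame.
#'
#' @param config an [ancestorConfig()].
#' @param id genome identifier.
#' @return a list with elements `genome` (a [PlastomeGenome-class] with
#'   both IR copies), `blocks` (the 13-row truth synteny-block table on the
#'   IR_B-excised frame), and `excised_length`.
#' @examples
#' anc <- generateAncestor(ancestorConfig(scale = 0.1, seed = 1))
#' countUniqueGenes(anc$genome)
#' @export
generateAncestor <- function(config = ancestorConfig(), id = "ancestor") {
  stopifnot(inherits(config, "AncestorConfig"))
  cat <- config$catalog
  withSeed(config$seed, {
    lsc_genes <- cat[cat$compartment == "LSC", ]
    ssc_genes <- cat[cat$compartment == "SSC", ]
    ir_genes <- cat[cat$compartment == "IR", ]
    lsc <- assembleRegion(lsc_genes, config$lsc_len, config$spacer_len_range,
                          config$intron_len, idp = "L", with_lcb7 = TRUE)
    ssc <- assembleRegion(ssc_genes, config$ssc_len, config$spacer_len_range,
                          config$intron_len, idp = "S")
    ir <- assembleRegion(ir_genes, config$ir_len, config$spacer_len_range,
                         config$intron_len, idp = "R")
  })
  R <- nchar(ir$seq)
  lscL <- nchar(lsc$seq)
  sscL <- nchar(ssc$seq)

  ## excised frame: LSC | SSC | IR (retained copy)
  ex_len <- lscL + sscL + R
  feats_ex <- rbind(shiftFeatures(lsc$features, 0L),
                    shiftFeatures(ssc$features, lscL),
                    shiftFeatures(ir$features, lscL + sscL))
  blocks <- truthBlocks(cat, feats_ex, ex_len, id)

  ## full ancestor: LSC | revcomp(IR) (= IR_B, redundant) | SSC | IR (= IR_A)
  irB_seq <- revcompChar(ir$seq)
  seq <- paste0(lsc$seq, irB_seq, ssc$seq, ir$seq)
  irB_feats <- mirrorFeatures(ir$features, R)
  irB_feats$feature_id <- paste0(irB_feats$feature_id, ".ir2")
  feats <- rbind(
    shiftFeatures(lsc$features, 0L),
    shiftFeatures(irB_feats, lscL),
    shiftFeatures(ssc$features, lscL + R),
    shiftFeatures(ir$features, lscL + R + sscL),
    data.frame(feature_id = c("irB", "irA"), kind = "IR",
               name = c("IR_B", "IR_A"),
               start = c(lscL + 1L, lscL + R + sscL + 1L),
               end = c(lscL + R, lscL + 2L * R + sscL),
               strand = "+", paired_id = c("irA", "irB"),
               notes = NA_character_, stringsAsFactors = FALSE))
  feats <- feats[order(feats$start, feats$end), ]
  genome <- plastomeGenome(id, seq, topology = "circular", features = feats)
  list(genome = genome, blocks = blocks, excised_length = ex_len)
}

## Place genes in order with random spacers; spacer lengths are drawn
## uniformly from `range` then adjusted uniformly so the region length hits
## `target` exactly. Returns seq (character) + feature table (1-based,
## relative to the region).
assembleRegion <- function(genes, target, range, intron_len, idp,
                           with_lcb7 = FALSE) {
  inst <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    geneInstance(g$name, g$length, g$n_introns, g$coding, g$strand,
                 intron_len, sprintf("%s%03d", idp, i))
  })
  spans <- vapply(inst, function(x) nchar(x$seq), integer(1))
  lcb7_len <- 0L
  lcb7_after <- NA_integer_
  if (with_lcb7) {
    ## the gene-free intergenic block sits between blocks 6 and 8
    lcb7_len <- max(200L, as.integer(round(mean(range) * 4)))
    lcb7_after <- max(which(genes$block <= 6L))
  }
  n_sp <- nrow(genes) + 1L
  need <- target - sum(spans) - lcb7_len
  if (need < n_sp)
    stop("catalog too large for configured region length (", target, " bp)")
  u <- sample(seq(range[1L], range[2L]), n_sp, replace = TRUE)
  ## rescale the draws so spacers sum exactly to the remaining bases
  sp <- pmax(1L, as.integer(floor(u * need / sum(u))))
  rem <- need - sum(sp)
  while (rem != 0L) {
    if (rem > 0L) {
      k <- min(rem, n_sp)
      sp[seq_len(k)] <- sp[seq_len(k)] + 1L
      rem <- rem - k
    } else {
      room <- which(sp > 1L)
      if (length(room) == 0L)
        stop("catalog too large for configured region length (",
             target, " bp)")
      k <- min(-rem, length(room))
      sp[room[seq_len(k)]] <- sp[room[seq_len(k)]] - 1L
      rem <- rem + k
    }
  }
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_len(nrow(genes))) {
    pieces <- c(pieces, randomDNA(sp[i]))
    pos <- pos + sp[i]
    fi <- inst[[i]]$features
    fi$start <- fi$start + pos
    fi$end <- fi$end + pos
    feats[[length(feats) + 1L]] <- fi
    pieces <- c(pieces, inst[[i]]$seq)
    pos <- pos + spans[i]
    if (with_lcb7 && i == lcb7_after) {
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = "lcb7", kind = "spacer", name = "LCB7_intergenic",
        start = pos + 1L, end = pos + lcb7_len, strand = "+",
        paired_id = NA_character_, notes = "block=7",
        stringsAsFactors = FALSE)
      pieces <- c(pieces, randomDNA(lcb7_len))
      pos <- pos + lcb7_len
    }
  }
  pieces <- c(pieces, randomDNA(sp[n_sp]))
  list(seq = paste(pieces, collapse = ""), features = do.call(rbind, feats))
}

## one gene instance: sense-strand parts (exons/introns), then mirrored if
## the gene lies on the minus strand
geneInstance <- function(name, len, n_introns, coding, strand, intron_len,
                         fid) {
  if (coding) {
    orf <- randomORF(len)
    if (n_introns > 0L) {
      per <- (len %/% 3L %/% (n_introns + 1L)) * 3L
      exon_lens <- c(rep(per, n_introns), len - per * n_introns)
    } else exon_lens <- len
  } else {
    orf <- randomDNA(len)
    exon_lens <- len
  }
  parts <- list()
  seqparts <- character(0)
  pos <- 0L
  off <- 0L
  for (k in seq_along(exon_lens)) {
    el <- exon_lens[k]
    seqparts <- c(seqparts, substr(orf, off + 1L, off + el))
    off <- off + el
    if (length(exon_lens) > 1L)
      parts[[length(parts) + 1L]] <- data.frame(
        feature_id = sprintf("%s.e%d", fid, k), kind = "exon", name = name,
        start = pos + 1L, end = pos + el, strand = "+",
        paired_id = NA_character_, notes = NA_character_,
        stringsAsFactors = FALSE)
    pos <- pos + el
    if (k < length(exon_lens)) {
      iseq <- paste0("GT", randomDNA(intron_len - 4L), "AG")
      seqparts <- c(seqparts, iseq)
      parts[[length(parts) + 1L]] <- data.frame(
        feature_id = sprintf("%s.i%d", fid, k), kind = "intron", name = name,
        start = pos + 1L, end = pos + intron_len, strand = "+",
        paired_id = NA_character_, notes = sprintf("intron=%d", k),
        stringsAsFactors = FALSE)
      pos <- pos + intron_len
    }
  }
  span <- pos
  gene_row <- data.frame(feature_id = fid, kind = "gene", name = name,
                         start = 1L, end = span, strand = "+",
                         paired_id = NA_character_, notes = NA_character_,
                         stringsAsFactors = FALSE)
  ft <- rbind(gene_row, do.call(rbind, parts) %||% emptyFeatures()[0, ])
  seq <- paste(seqparts, collapse = "")
  if (strand == "-") {
    seq <- revcompChar(seq)
    ft <- mirrorFeatures(ft, span)
  }
  list(seq = seq, features = ft)
}

shiftFeatures <- function(ft, off) {
  if (nrow(ft) == 0L) return(ft)
  ft$start <- ft$start + as.integer(off)
  ft$end <- ft$end + as.integer(off)
  ft
}

## reflect features of a region of length L (reverse complement of the
## region): coordinates mirror, strands flip
mirrorFeatures <- function(ft, L) {
  if (nrow(ft) == 0L) return(ft)
  s <- L - ft$end + 1L
  e <- L - ft$start + 1L
  ft$start <- s
  ft$end <- e
  ft$strand <- ifelse(ft$strand == "+", "-", "+")
  ft[order(ft$start, ft$end), ]
}

## 13-block truth table on the excised frame; block i runs from its first
## feature to just before block i+1's first feature (gene-free sequence is
## absorbed leftward; block 1 absorbs the head, the last block runs to the
## end of the genome)
truthBlocks <- function(cat, feats_ex, ex_len, id) {
  blocks <- sort(unique(cat$block))
  blocks <- sort(unique(c(blocks, 7L)))
  firsts <- vapply(blocks, function(b) {
    if (b == 7L) {
      feats_ex$start[feats_ex$feature_id == "lcb7"]
    } else {
      nm <- cat$name[cat$block == b]
      min(feats_ex$start[feats_ex$kind == "gene" & feats_ex$name %in% nm])
    }
  }, integer(1))
  ord <- order(firsts)
  blocks <- blocks[ord]
  firsts <- firsts[ord]
  starts <- c(1L, firsts[-1L])
  ends <- c(firsts[-1L] - 1L, ex_len)
  data.frame(block_label = blocks, genome_id = id, start = starts,
             end = ends, strand = "+", stringsAsFactors = FALSE)
}
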