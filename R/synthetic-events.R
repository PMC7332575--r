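#' Evolutionary event constructors
#'
#' Build the elements of an event script for [applyEvents()]. Events apply
#' left to right and every coordinate is validated against the genome state
#' at the moment the event applies (1-based closed coordinates).
#'
#' * `evInversion(start, end)` reverse-complements the segment and flips
#'   contained feature strands; segment bounds must not split a feature.
#' * `evIRLoss(copy)` deletes the full span of the named IR copy
#'   (`"A"` or `"B"`) together with the features inside it.
#' * `evGeneLoss(name)` deletes every copy of the named gene (span and
#'   sub-features).
#' * `evIntronLoss(gene, intron_index)` deletes the named intron's span.
#' * `evPseudogenize(name)` substitutes an in-frame internal stop codon
#'   (TAA) early in the coding sequence and re-classes the feature as a
#'   pseudogene, recording the lesion position in `notes`.
#' * `evInsertSIR(len, positions)` inserts a fresh random segment at the
#'   first position and its reverse complement at the second, annotating
#'   the two copies as a paired sIR.
#' * `evTranslocate(start, end, dest, inverted)` cuts the segment and
#'   reinserts it after position `dest` (expressed in post-excision
#'   coordinates), optionally inverted.
#'
#' @param start,end,dest 1-based coordinates.
#' @param copy `"A"` or `"B"`.
#' @param name,gene gene name in the annotation.
#' @param intron_index which intron of the gene (1-based).
#' @param len inserted repeat length in bases.
#' @param positions integer pair of insertion points (bases after which to
#'   insert), both in the pre-event coordinate frame, first < second.
#' @param inverted logical; reinsert the segment reverse-complemented.
#' @return an event object (a tagged list) for use in a script.
#' @name event-constructors
NULL

#' @rdname event-constructors
#' @export
evInversion <- function(start, end)
  list(type = "inversion", start = as.integer(start), end = as.integer(end))

#' @rdname event-constructors
#' @export
evIRLoss <- function(copy = c("B", "A"))
  list(type = "ir_loss", copy = match.arg(copy))

#' @rdname event-constructors
#' @export
evGeneLoss <- function(name) list(type = "gene_loss", name = name)

#' @rdname event-constructors
#' @export
evIntronLoss <- function(gene, intron_index = 1L)
  list(type = "intron_loss", gene = gene,
       intron_index = as.integer(intron_index))

#' @rdname event-constructors
#' @export
evPseudogenize <- function(name) list(type = "pseudogenize", name = name)

#' @rdname event-constructors
#' @export
evInsertSIR <- function(len, positions)
  list(type = "insert_sir", len = as.integer(len),
       positions = as.integer(positions))

#' @rdname event-constructors
#' @export
evTranslocate <- function(start, end, dest, inverted = FALSE)
  list(type = "translocate", start = as.integer(start),
       end = as.integer(end), dest = as.integer(dest),
       inverted = isTRUE(inverted))

#' Apply an evolutionary event script
#'
#' Events apply sequentially; each is resolved against the current genome
#' state into primitive sequence operations (invert / delete / insert /
#' substitute / re-class) which are recorded in the returned truth log.
#' [replayTruthLog()] re-applies those primitives to the ancestor and
#' reproduces the evolved genome exactly, byte for byte.
#'
#' @param genome a [PlastomeGenome-class].
#' @param script list of events from the `ev*` constructors.
#' @param seed integer seed for the randomness of `insert_sir` sequence
#'   draws.
#' @return a list with `genome` (evolved) and `log` (a `TruthLog`).
#' @examples
#' anc <- generateAncestor(ancestorConfig(scale = 0.1, seed = 1))
#' ev <- applyEvents(anc$genome, list(evIRLoss("B"), evGeneLoss("accD")))
#' genomeLength(ev$genome) < genomeLength(anc$genome)
#' @export
applyEvents <- function(genome, script, seed = 1L) {
  st <- list(seq = as.character(genome@seq), features = genome@features)
  log <- list()
  withSeed(seed, {
    for (k in seq_along(script)) {
      ev <- script[[k]]
      res <- resolveEvent(st, ev)
      for (op in res$ops) st <- applyOp(st, op)
      log[[k]] <- list(type = ev$type, event = ev, ops = res$ops)
    }
  })
  out <- plastomeGenome(genome@id, st$seq, topology = genome@topology,
                        features = st$features)
  structure(list(genome = out, log = structure(log, class = "TruthLog")),
            class = "EvolvedGenome")
}

#' @rdname applyEvents
#' @param ancestor the genome the log was produced from.
#' @param log a `TruthLog`.
#' @export
replayTruthLog <- function(ancestor, log) {
  st <- list(seq = as.character(ancestor@seq), features = ancestor@features)
  for (entry in log) for (op in entry$ops) st <- applyOp(st, op)
  plastomeGenome(ancestor@id, st$seq, topology = ancestor@topology,
                 features = st$features)
}

#' @export
print.TruthLog <- function(x, ...) {
  cat("TruthLog of", length(x), "events:\n")
  for (e in x) cat("  -", e$type, sprintf("(%d primitive ops)\n",
                                          length(e$ops)))
  invisible(x)
}

## ---- event resolution -------------------------------------------------

resolveEvent <- function(st, ev) {
  switch(ev$type,
    inversion = {
      checkSpan(st, ev$start, ev$end, "inversion")
      list(ops = list(list(op = "invert", start = ev$start, end = ev$end)))
    },
    ir_loss = {
      ft <- st$features
      hit <- ft[ft$kind == "IR" & ft$name == paste0("IR_", ev$copy), ]
      if (nrow(hit) != 1L)
        stop("scripted-event error: IR copy ", ev$copy, " not present")
      partner <- hit$paired_id
      list(ops = list(
        list(op = "delete", start = hit$start, end = hit$end),
        list(op = "drop_features", ids = partner)))
    },
    gene_loss = {
      ft <- st$features
      hits <- ft[ft$kind == "gene" & ft$name == ev$name, ]
      if (nrow(hits) == 0L)
        stop("scripted-event error: no intact gene ", ev$name)
      hits <- hits[order(-hits$start), ]
      list(ops = lapply(seq_len(nrow(hits)), function(i)
        list(op = "delete", start = hits$start[i], end = hits$end[i])))
    },
    intron_loss = {
      ft <- st$features
      tag <- sprintf("intron=%d", ev$intron_index)
      hits <- ft[ft$kind == "intron" & ft$name == ev$gene &
                   !is.na(ft$notes) & ft$notes == tag, ]
      if (nrow(hits) == 0L)
        stop("scripted-event error: no intron ", ev$intron_index,
             " in gene ", ev$gene)
      hits <- hits[order(-hits$start), ]
      list(ops = lapply(seq_len(nrow(hits)), function(i)
        list(op = "delete", start = hits$start[i], end = hits$end[i])))
    },
    pseudogenize = resolvePseudogenize(st, ev),
    insert_sir = resolveInsertSIR(st, ev),
    translocate = resolveTranslocate(st, ev),
    stop("unknown event type: ", ev$type)
  )
}

resolvePseudogenize <- function(st, ev) {
  ft <- st$features
  hits <- ft[ft$kind == "gene" & ft$name == ev$name, ]
  if (nrow(hits) == 0L)
    stop("scripted-event error: no intact gene ", ev$name)
  ops <- list()
  for (i in seq_len(nrow(hits))) {
    g <- hits[i, ]
    ## first coding exon in the gene's own reading frame
    ex <- ft[ft$kind == "exon" & ft$name == ev$name &
               ft$start >= g$start & ft$end <= g$end, ]
    exon1_len <- if (nrow(ex) > 0L) {
      if (g$strand == "+") ex$end[which.min(ex$start)] - min(ex$start) + 1L
      else max(ex$end) - ex$start[which.max(ex$end)] + 1L
    } else g$end - g$start + 1L
    k <- max(1L, min(5L, exon1_len %/% 3L - 1L))
    if (k < 1L) stop("gene ", ev$name, " too short to pseudogenize")
    if (g$strand == "+") {
      pos <- g$start + 3L * k
      ops[[length(ops) + 1L]] <- list(op = "substitute", pos = pos,
                                      value = "TAA")
    } else {
      pos <- g$end - 3L * k - 2L
      ops[[length(ops) + 1L]] <- list(op = "substitute", pos = pos,
                                      value = "TTA")
    }
    ops[[length(ops) + 1L]] <- list(
      op = "reclass", id = g$feature_id, kind = "pseudogene",
      notes = sprintf("internal_stop=codon%d", k + 1L))
  }
  list(ops = ops)
}

resolveInsertSIR <- function(st, ev) {
  n <- nchar(st$seq)
  p <- ev$positions
  if (length(p) != 2L || p[1L] >= p[2L] || p[1L] < 0L || p[2L] > n)
    stop("scripted-event error: insert_sir positions invalid")
  sir_seq <- randomDNA(ev$len)
  k <- sum(st$features$kind == "sIR") / 2 + 1
  ida <- sprintf("sir%d_a", k)
  idb <- sprintf("sir%d_b", k)
  fa <- data.frame(feature_id = ida, kind = "sIR", name = sprintf("sIR%d", k),
                   start = 1L, end = ev$len, strand = "+", paired_id = idb,
                   notes = NA_character_, stringsAsFactors = FALSE)
  fb <- fa
  fb$feature_id <- idb
  fb$strand <- "-"
  fb$paired_id <- ida
  list(ops = list(
    list(op = "insert", pos = p[1L], seq = sir_seq, features = fa),
    list(op = "insert", pos = p[2L] + ev$len, seq = revcompChar(sir_seq),
         features = fb)))
}

resolveTranslocate <- function(st, ev) {
  checkSpan(st, ev$start, ev$end, "translocate")
  n <- nchar(st$seq)
  L <- ev$end - ev$start + 1L
  if (ev$dest < 0L || ev$dest > n - L)
    stop("scripted-event error: translocation destination out of range")
  seg <- substr(st$seq, ev$start, ev$end)
  ft <- st$features
  inside <- ft$start >= ev$start & ft$end <= ev$end
  seg_ft <- ft[inside, ]
  seg_ft$start <- seg_ft$start - ev$start + 1L
  seg_ft$end <- seg_ft$end - ev$start + 1L
  if (ev$inverted) {
    seg <- revcompChar(seg)
    seg_ft <- mirrorFeatures(seg_ft, L)
  }
  list(ops = list(
    list(op = "delete", start = ev$start, end = ev$end),
    list(op = "insert", pos = ev$dest, seq = seg, features = seg_ft)))
}

checkSpan <- function(st, s, e, what) {
  n <- nchar(st$seq)
  if (s < 1L || e > n || s > e)
    stop("scripted-event error: ", what, " span [", s, ",", e,
         "] outside genome of length ", n)
  ft <- st$features
  straddle <- (ft$start < s & ft$end >= s) | (ft$start <= e & ft$end > e)
  if (any(straddle))
    stop("scripted-event error: ", what, " span splits feature(s) ",
         paste(utils::head(ft$feature_id[straddle], 3), collapse = ", "))
  invisible(TRUE)
}

## ---- primitive operations --------------------------------------------

applyOp <- function(st, op) {
  switch(op$op,
    invert = {
      s <- op$start; e <- op$end
      seg <- revcompChar(substr(st$seq, s, e))
      st$seq <- paste0(substr(st$seq, 1L, s - 1L), seg,
                       substr(st$seq, e + 1L, nchar(st$seq)))
      ft <- st$features
      inside <- ft$start >= s & ft$end <= e
      if (any(inside)) {
        ns <- s + (e - ft$end[inside])
        ne <- s + (e - ft$start[inside])
        ft$start[inside] <- ns
        ft$end[inside] <- ne
        ft$strand[inside] <- ifelse(ft$strand[inside] == "+", "-", "+")
      }
      st$features <- ft[order(ft$start, ft$end), ]
      st
    },
    delete = {
      s <- op$start; e <- op$end
      L <- e - s + 1L
      ft <- st$features
      ## a feature fully containing the span (e.g. a gene losing an
      ## intron) shrinks; partial overlap is an error
      contains <- ft$start < s & ft$end > e
      straddle <- !contains &
        ((ft$start < s & ft$end >= s) | (ft$start <= e & ft$end > e))
      if (any(straddle))
        stop("scripted-event error: deletion [", s, ",", e,
             "] splits feature(s) ",
             paste(utils::head(ft$feature_id[straddle], 3), collapse = ", "))
      ft <- ft[!(ft$start >= s & ft$end <= e), ]
      after <- ft$start > e
      ft$start[after] <- ft$start[after] - L
      ft$end[after] <- ft$end[after] - L
      shrink <- ft$start < s & ft$end > e & !after
      ft$end[shrink] <- ft$end[shrink] - L
      st$seq <- paste0(substr(st$seq, 1L, s - 1L),
                       substr(st$seq, e + 1L, nchar(st$seq)))
      st$features <- ft
      st
    },
    insert = {
      pos <- op$pos
      L <- nchar(op$seq)
      ft <- st$features
      straddle <- ft$start <= pos & ft$end > pos
      if (any(straddle))
        stop("scripted-event error: insertion at ", pos,
             " splits feature(s) ",
             paste(utils::head(ft$feature_id[straddle], 3), collapse = ", "))
      after <- ft$start > pos
      ft$start[after] <- ft$start[after] + L
      ft$end[after] <- ft$end[after] + L
      newft <- op$features
      if (!is.null(newft) && nrow(newft) > 0L) {
        newft$start <- newft$start + pos
        newft$end <- newft$end + pos
        ft <- rbind(ft, newft)
      }
      st$seq <- paste0(substr(st$seq, 1L, pos), op$seq,
                       substr(st$seq, pos + 1L, nchar(st$seq)))
      st$features <- ft[order(ft$start, ft$end), ]
      st
    },
    substitute = {
      L <- nchar(op$value)
      st$seq <- paste0(substr(st$seq, 1L, op$pos - 1L), op$value,
                       substr(st$seq, op$pos + L, nchar(st$seq)))
      st
    },
    reclass = {
      i <- which(st$features$feature_id == op$id)
      st$features$kind[i] <- op$kind
      st$features$notes[i] <- op$notes
      st
    },
    drop_features = {
      st$features <- st$features[!st$features$feature_id %in% op$ids, ]
      st
    },
    stop("unknown primitive op: ", op$op)
  )
}
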