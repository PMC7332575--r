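#' Bin repeat hits by length
#'
#' The conventional report bins are 30-60, 60-100 and 100-500 bp plus a
#' \code{>=1000} bp class; lengths of 500-999 bp fall between the
#' conventional bins and are reported in an explicit `500-1000bp` column
#' rather than silently folded elsewhere. All bins are half-open,
#' low-inclusive. The bin counts plus the `<30bp` remainder always sum to
#' the total number of hits.
#'
#' @param hits `data.frame` from [findRepeats()].
#' @return named integer vector: `30-60bp`, `60-100bp`, `100-500bp`,
#'   `500-1000bp`, `>1000bp`, `total`.
#' @examples
#' binRepeats(data.frame(length = c(35, 60, 120, 1200)))
#' @export
binRepeats <- function(hits) {
  L <- hits$length
  c("30-60bp" = sum(L >= 30 & L < 60),
    "60-100bp" = sum(L >= 60 & L < 100),
    "100-500bp" = sum(L >= 100 & L < 500),
    "500-1000bp" = sum(L >= 500 & L < 1000),
    ">1000bp" = sum(L >= 1000),
    total = length(L))
}

#' Run the full comparative pipeline
#'
#' Stage order mirrors the comparative-plastome workflow: IR
#' classification, excision of the redundant IR copy where a pair is
#' present, synteny-block construction from gene anchors (or direct
#' ingestion of printed permutations), exact reversal distances against
#' the reference, dispersed-repeat enumeration on the IR-excised
#' sequences, optional Dollo loss mapping, and optional sIR isomer
#' evidence. Every stage emits one structured, machine-parsable log line
#' with its parameters and timing; identical inputs and seed give
#' byte-identical reports.
#'
#' @param genomes list of [PlastomeGenome-class] objects.
#' @param reference_id id of the reference genome (its own distance is
#'   reported as `"-"`).
#' @param criteria dispersed-repeat [repeatCriteria()].
#' @param min_ir_len,min_sir_len IR classification thresholds
#'   (see [classifyIR()]).
#' @param permutations optional named list of
#'   [SignedPermutation-class] objects (e.g. from [readPermutations()]);
#'   when given, block building is skipped and distances are computed on
#'   these directly.
#' @param tree,watch_list optional `phylo` + watch list for
#'   [dolloLosses()] via [charactersFromGenomes()].
#' @param reads optional list `list(genome_id =, mate1 =, mate2 =)` for
#'   isomer evidence on that genome's longest sIR.
#' @param insert_window insert-size window for the isomer stage.
#' @param with_scenarios also compute one optimal reversal scenario per
#'   non-reference genome.
#' @param stages which stages to run after IR classification/excision:
#'   any of `"blocks"`, `"distance"`, `"repeats"` (skipping `"repeats"`
#'   is useful in large simulation studies where only the rearrangement
#'   readout matters).
#' @param out_dir optional directory; per-stage TSV reports are written
#'   there.
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return a `ComparisonReport` (list): `table` (per-genome summary),
#'   `permutations`, `distances`, `scenarios`, `repeats`, `repeat_bins`,
#'   `blocks`, `loss`, `isomer`, `log`.
#' @export
runComparison <- function(genomes, reference_id,
                          criteria = repeatCriteria(),
                          min_ir_len = 10000L, min_sir_len = 30L,
                          permutations = NULL, tree = NULL,
                          watch_list = NULL, reads = NULL,
                          insert_window = c(330, 600),
                          with_scenarios = FALSE,
                          stages = c("blocks", "distance", "repeats"),
                          out_dir = NULL, seed = 1L) {
  ids <- vapply(genomes, genomeId, character(1))
  names(genomes) <- ids
  if (!reference_id %in% ids) stop("reference_id must be among the inputs")
  log <- character()
  stamp <- function(stage, ...) {
    line <- sprintf("stage=%s %s seed=%d", stage,
                    paste(..., sep = " "), as.integer(seed))
    log <<- c(log, line)
  }
  runStage <- function(stage, input, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed on input '", input, "': ",
           conditionMessage(e), call. = FALSE))
    stamp(stage, sprintf("input=%s elapsed=%.3fs", input,
                         as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  ## IR classification + excision
  irpairs <- lapply(ids, function(id)
    runStage("classify_ir", id,
             classifyIR(genomes[[id]], min_ir_len, min_sir_len)))
  names(irpairs) <- ids
  excised <- lapply(ids, function(id) {
    prs <- irpairs[[id]]
    irs <- Filter(function(p) irClass(p) == "IR", prs)
    if (length(irs) == 0L) return(genomes[[id]])
    runStage("excise_irb", id, exciseIRB(genomes[[id]], irs[[1L]]))
  })
  names(excised) <- ids

  ## blocks + permutations
  blocks <- NULL
  if (is.null(permutations) && !"blocks" %in% stages) {
    permutations <- list()
  } else if (is.null(permutations)) {
    blocks <- runStage("build_blocks", paste(ids, collapse = ","),
                       buildBlocks(excised, reference_id))
    permutations <- lapply(ids, function(id)
      runStage("encode_permutation", id,
               encodePermutation(blocks, reference_id, id,
                                 circular = genomes[[id]]@topology ==
                                   "circular")))
    names(permutations) <- ids
  } else {
    stamp("import_permutations",
          sprintf("n=%d", length(permutations)))
  }

  ## distances and scenarios
  distances <- list()
  if ("distance" %in% stages && length(permutations)) {
    distances <- lapply(names(permutations), function(id)
      runStage("distance", id, reversalDistance(permutations[[id]])))
    names(distances) <- names(permutations)
  }
  scenarios <- NULL
  if (with_scenarios) {
    scenarios <- lapply(setdiff(names(permutations), reference_id),
                        function(id)
      runStage("scenario", id, optimalScenario(permutations[[id]])))
    names(scenarios) <- setdiff(names(permutations), reference_id)
  }

  ## dispersed repeats on IR-excised sequences
  repeats <- NULL
  repeat_bins <- NULL
  if ("repeats" %in% stages) {
    repeats <- lapply(ids, function(id)
      runStage("repeats", id, findRepeats(genomeSeq(excised[[id]]),
                                          criteria)))
    names(repeats) <- ids
    repeat_bins <- t(vapply(repeats, binRepeats, integer(6)))
  }

  ## loss mapping
  loss <- NULL
  if (!is.null(tree) && !is.null(watch_list)) {
    chars <- charactersFromGenomes(genomes, watch_list)
    loss <- runStage("dollo", "all", dolloLosses(tree, chars))
  }

  ## isomer evidence
  isomer <- NULL
  if (!is.null(reads)) {
    gid <- reads$genome_id
    sirs <- Filter(function(p) irClass(p) == "sIR", irpairs[[gid]])
    if (length(sirs) == 0L)
      stop("pipeline stage 'isomers' failed on input '", gid,
           "': no sIR pair")
    isomer <- runStage("isomers", gid,
                       isomerEvidence(reads$mate1, reads$mate2,
                                      genomes[[gid]], sirs[[1L]],
                                      window = insert_window))
  }

  tab <- do.call(rbind, lapply(ids, function(id) {
    prs <- irpairs[[id]]
    klass <- vapply(prs, irClass, character(1))
    irlen <- if (any(klass == "IR"))
      irLength(prs[[which(klass == "IR")[1L]]]) else NA_integer_
    sirlens <- vapply(prs[klass == "sIR"], irLength, integer(1))
    pm <- permutations[[id]]
    data.frame(
      genome_id = id,
      size_bp = genomeLength(genomes[[id]]),
      ir_bp = ifelse(is.na(irlen), "n.a.", as.character(irlen)),
      unique_genes = countUniqueGenes(genomes[[id]]),
      sir_bp = if (length(sirlens)) paste(sirlens, collapse = ",")
        else "np",
      permutation = if (!is.null(pm)) paste(permVector(pm),
                                            collapse = ", ") else "",
      distance = if (id == reference_id) "-" else
        if (!is.null(pm) && !is.null(distances[[id]]))
          as.character(distanceValue(distances[[id]])) else "",
      stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  rep_out <- structure(
    list(table = tab, permutations = permutations, distances = distances,
         scenarios = scenarios, repeats = repeats,
         repeat_bins = repeat_bins, blocks = blocks, loss = loss,
         isomer = isomer, log = log),
    class = "ComparisonReport")
  if (!is.null(out_dir)) writeComparisonReport(rep_out, out_dir)
  rep_out
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport (", nrow(x$table), " genomes)\n", sep = "")
  print(x$table, row.names = FALSE)
  if (!is.null(x$repeat_bins)) {
    cat("\nRepeat bins:\n")
    print(x$repeat_bins)
  }
  if (!is.null(x$loss)) {
    cat("\nLoss mapping:\n")
    print(x$loss, row.names = FALSE)
  }
  if (!is.null(x$isomer)) {
    cat("\nIsomer evidence:\n")
    print(x$isomer, row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `summary.tsv`, `repeat_bins.tsv`, per-genome repeat tables,
#' `permutations.txt`, the block table, loss mapping, isomer evidence and
#' the stage log under `out_dir`.
#'
#' @param report a `ComparisonReport`.
#' @param out_dir output directory (created if needed).
#' @export
writeComparisonReport <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(report$table, "summary.tsv")
  if (!is.null(report$repeat_bins))
    utils::write.table(report$repeat_bins,
                       file.path(out_dir, "repeat_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE,
                       col.names = NA)
  for (id in names(report$repeats))
    writeRepeatReport(report$repeats[[id]],
                      file.path(out_dir, sprintf("repeats_%s.tsv", id)))
  if (length(report$permutations))
    writePermutations(report$permutations,
                      file.path(out_dir, "permutations.txt"))
  if (!is.null(report$blocks)) writeBlockTable(report$blocks,
                                               file.path(out_dir,
                                                         "blocks.tsv"))
  if (!is.null(report$loss)) w(report$loss, "loss_mapping.tsv")
  if (!is.null(report$isomer)) w(report$isomer, "isomer_evidence.tsv")
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
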