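#' Read an annotated genome
#'
#' Two on-disk layouts are supported: `"fasta+gff3"` (a FASTA file plus a
#' GFF3 file with 1-based inclusive coordinates, the interchange dialect)
#' and `"feature-table-tsv"` (a FASTA plus a tab-separated feature table in
#' the package's own column layout). Coordinates are 1-based closed both on
#' disk and internally, so no shifting occurs on either path.
#'
#' Topology is carried in the FASTA header as `topology=circular` /
#' `topology=linear` and defaults to circular when absent.
#'
#' @param fasta path to the FASTA sequence file.
#' @param features path to the GFF3 or TSV feature file; `NULL` for a
#'   feature-less record.
#' @param format `"fasta+gff3"` or `"feature-table-tsv"`.
#' @return a [PlastomeGenome-class].
#' @seealso [writeGenome()]
#' @export
readGenome <- function(fasta, features = NULL, format = c("fasta+gff3",
                                                          "feature-table-tsv")) {
  format <- match.arg(format)
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L)
    stop("expected exactly one FASTA record in ", fasta)
  header <- names(ss)[1L]
  topo <- if (grepl("topology=linear", header)) "linear" else "circular"
  id <- sub("\\s.*$", "", header)
  ft <- emptyFeatures()
  if (!is.null(features)) {
    ft <- switch(format,
      "fasta+gff3" = readFeaturesGFF3(features),
      "feature-table-tsv" = readFeaturesTSV(features))
  }
  plastomeGenome(id, ss[[1L]], topology = topo, features = ft)
}

readFeaturesGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(emptyFeatures())
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm, default) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else
      rep(default, length(gr))
  }
  data.frame(
    feature_id = getcol("ID", NA_character_),
    kind = as.character(mc$type),
    name = getcol("Name", NA_character_),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    paired_id = getcol("paired_id", NA_character_),
    notes = getcol("notes", NA_character_),
    stringsAsFactors = FALSE)
}

readFeaturesTSV <- function(path) {
  ft <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("feature_id", "kind", "name", "start", "end", "strand")
  miss <- setdiff(need, names(ft))
  if (length(miss))
    stop("feature table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  ft$start <- as.integer(ft$start)
  ft$end <- as.integer(ft$end)
  completeFeatures(ft)
}

#' Write an annotated genome
#'
#' FASTA is wrapped at 80 columns with the topology recorded in the header;
#' features go to GFF3 (1-based inclusive, strand column, `ID`/`Name`
#' attributes; a circular feature wrapped around the origin emits two lines
#' sharing one `ID`) or to the package TSV layout.
#'
#' @param genome a [PlastomeGenome-class].
#' @param fasta,features output paths (`features` may be `NULL` to skip).
#' @inheritParams readGenome
#' @return invisibly, the genome.
#' @export
writeGenome <- function(genome, fasta, features = NULL,
                        format = c("fasta+gff3", "feature-table-tsv")) {
  format <- match.arg(format)
  ss <- Biostrings::DNAStringSet(list(genome@seq))
  names(ss) <- sprintf("%s topology=%s", genome@id, genome@topology)
  Biostrings::writeXStringSet(ss, fasta, width = 80L)
  if (!is.null(features)) {
    ft <- genome@features
    if (format == "fasta+gff3" && nrow(ft) == 0L) {
      writeLines("##gff-version 3", features)
    } else if (format == "fasta+gff3") {
      gr <- GenomicRanges::GRanges(
        seqnames = rep(genome@id, nrow(ft)),
        ranges = IRanges::IRanges(ft$start, ft$end),
        strand = ft$strand)
      S4Vectors::mcols(gr)$type <- ft$kind
      S4Vectors::mcols(gr)$ID <- ft$feature_id
      S4Vectors::mcols(gr)$Name <- ft$name
      S4Vectors::mcols(gr)$paired_id <- ft$paired_id
      S4Vectors::mcols(gr)$notes <- ft$notes
      S4Vectors::mcols(gr)$source <- rep("plastomeRearr", nrow(ft))
      rtracklayer::export(gr, features, format = "gff3")
    } else {
      utils::write.table(ft, features, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  invisible(genome)
}

#' Read and write signed-permutation lists
#'
#' The text format is one genome per line, `name: s1, s2, ..., sn`, the
#' layout in which comparative studies print per-genome block orders.
#' Each permutation is validated: every absolute label `1..n` must occur
#' exactly once.
#'
#' @param path file path.
#' @return `readPermutations`: a named list of
#'   [SignedPermutation-class] objects.
#' @examples
#' tf <- tempfile()
#' writeLines("g1: 1, -3, 2", tf)
#' permVector(readPermutations(tf)$g1)
#' @export
readPermutations <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.+)$", ln))[[1L]]
    if (length(m) != 3L)
      stop("malformed permutation line: ", ln)
    nm <- trimws(m[2L])
    vals <- suppressWarnings(as.integer(trimws(
      strsplit(m[3L], ",")[[1L]])))
    if (anyNA(vals))
      stop("non-integer label in permutation line: ", ln)
    out[[nm]] <- signedPermutation(vals)
  }
  out
}

#' @rdname readPermutations
#' @param perms named list of [SignedPermutation-class] objects.
#' @export
writePermutations <- function(perms, path) {
  lines <- vapply(names(perms), function(nm) {
    sprintf("%s: %s", nm, paste(perms[[nm]]@perm, collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write synteny-block tables
#'
#' Tab-separated with columns `block_label`, `genome_id`, `start`, `end`,
#' `strand`; coordinates 1-based inclusive. Each `(block_label, genome_id)`
#' pair may appear at most once and intervals within a genome must not
#' overlap.
#'
#' @param path file path.
#' @return a `data.frame` block table.
#' @export
readBlockTable <- function(path) {
  bt <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateBlockTable(bt)
}

#' @rdname readBlockTable
#' @param blocks a block table `data.frame`.
#' @export
writeBlockTable <- function(blocks, path) {
  utils::write.table(validateBlockTable(blocks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateBlockTable <- function(bt) {
  need <- c("block_label", "genome_id", "start", "end", "strand")
  miss <- setdiff(need, names(bt))
  if (length(miss))
    stop("block table lacks columns: ", paste(miss, collapse = ", "))
  bt$block_label <- as.integer(bt$block_label)
  bt$start <- as.integer(bt$start)
  bt$end <- as.integer(bt$end)
  if (any(bt$block_label < 1L)) stop("block labels must be positive")
  if (anyDuplicated(bt[c("block_label", "genome_id")]))
    stop("duplicated (block_label, genome_id) pair")
  for (g in unique(bt$genome_id)) {
    sub <- bt[bt$genome_id == g, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L && any(sub$end[-nrow(sub)] >= sub$start[-1L]))
      stop("overlapping block intervals in genome ", g)
  }
  bt
}

#' Read and write binary loss-character matrices
#'
#' Taxa in rows, characters in columns, states `1` (present/intact), `0`
#' (lost or pseudogene) or `?` (unknown). Stored as a character matrix.
#'
#' @param path file path.
#' @return a character matrix with taxa as rownames.
#' @export
readLossMatrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   colClasses = "character",
                                   check.names = FALSE))
  validateLossMatrix(m)
}

#' @rdname readLossMatrix
#' @param m character matrix of states.
#' @export
writeLossMatrix <- function(m, path) {
  m <- validateLossMatrix(m)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateLossMatrix <- function(m) {
  m <- as.matrix(m)
  mode(m) <- "character"
  if (is.null(rownames(m))) stop("loss matrix needs taxon rownames")
  if (!all(m %in% c("0", "1", "?")))
    stop("loss-matrix states must be 0, 1 or ?")
  m
}
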