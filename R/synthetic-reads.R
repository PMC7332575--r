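#' Paired-end read simulation configuration
#'
#' Reads are simulated FR (inward-facing); the insert is the outer fragment
#' length, matching the SAM TLEN convention, so the 330-600 insert-size
#' filter of the isomer-evidence module has an exact semantics. Defaults
#' (150 bp reads, 450 +/- 50 bp inserts, no errors) centre the insert
#' distribution inside that window.
#'
#' @param n_pairs number of read pairs.
#' @param read_len read length in bases.
#' @param insert_mean,insert_sd normal insert-size parameters; the draw is
#'   truncated to `[2*read_len, genome length]`. `insert_mean` must be at
#'   least `2*read_len`.
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param seed integer seed.
#' @return a list of class `ReadSimConfig`.
#' @export
readSimConfig <- function(n_pairs = 1000L, read_len = 150L,
                          insert_mean = 450, insert_sd = 50,
                          error_rate = 0, seed = 1L) {
  if (insert_mean < 2 * read_len)
    stop("insert_mean must be >= 2*read_len")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  structure(list(n_pairs = as.integer(n_pairs),
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "ReadSimConfig")
}

#' Simulate paired-end reads from a genome
#'
#' Fragment start is uniform on the circle; the insert length is drawn from
#' a normal distribution truncated at `[2*read_len, genome length]`. Mate 1
#' is the fragment start read forward; mate 2 is the reverse complement of
#' the fragment end (FR orientation). Deterministic under a fixed seed.
#'
#' @param genome a [PlastomeGenome-class]; its length must exceed
#'   `insert_mean + 6*insert_sd`.
#' @param config a [readSimConfig()].
#' @param fastq1,fastq2 optional output paths; when given, mates are also
#'   written as FASTQ (constant quality).
#' @return a list with `mate1`, `mate2` ([Biostrings::DNAStringSet]),
#'   `truth` (a `data.frame` of fragment start and insert length per pair).
#' @export
simulateReads <- function(genome, config = readSimConfig(),
                          fastq1 = NULL, fastq2 = NULL) {
  n <- genomeLength(genome)
  if (n <= config$insert_mean + 6 * config$insert_sd)
    stop("genome too short for the configured insert distribution")
  rl <- config$read_len
  withSeed(config$seed, {
    starts <- sample.int(n, config$n_pairs, replace = TRUE)
    ins <- round(stats::rnorm(config$n_pairs, config$insert_mean,
                              config$insert_sd))
    ins <- pmin(pmax(ins, 2L * rl), n)
    ## doubled sequence makes circular fragment extraction a plain substring
    s2 <- paste0(as.character(genome@seq), as.character(genome@seq))
    m1 <- substring(s2, starts, starts + rl - 1L)
    m2raw <- substring(s2, starts + ins - rl, starts + ins - 1L)
    m2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(m2raw)))
    if (config$error_rate > 0) {
      m1 <- addSubstitutions(m1, config$error_rate)
      m2 <- addSubstitutions(m2, config$error_rate)
    }
  })
  ids <- sprintf("%s_pair%05d", genomeId(genome), seq_along(starts))
  mate1 <- Biostrings::DNAStringSet(m1)
  mate2 <- Biostrings::DNAStringSet(m2)
  names(mate1) <- paste0(ids, "/1")
  names(mate2) <- paste0(ids, "/2")
  if (!is.null(fastq1)) writeSimpleFastq(mate1, fastq1)
  if (!is.null(fastq2)) writeSimpleFastq(mate2, fastq2)
  list(mate1 = mate1, mate2 = mate2,
       truth = data.frame(pair_id = ids, frag_start = starts,
                          insert = as.integer(ins)))
}

addSubstitutions <- function(reads, rate) {
  vapply(reads, function(r) {
    hit <- which(stats::runif(nchar(r)) < rate)
    if (length(hit) == 0L) return(r)
    ch <- strsplit(r, "")[[1L]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

writeSimpleFastq <- function(reads, path) {
  q <- strrep("I", Biostrings::width(reads))
  lines <- as.vector(rbind(paste0("@", names(reads)), as.character(reads),
                           "+", q))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE)
}
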