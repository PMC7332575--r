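## Run expr with a private RNG stream; the caller's .Random.seed is
## untouched. All stochastic operations in the package route through this,
## so identical seeds give identical output regardless of session state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## uniform random DNA as a character string
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random protein-coding sequence: ATG + non-stop codons + TAA, length L
## (L must be a positive multiple of 3, >= 9)
randomORF <- function(L) {
  stopifnot(L %% 3 == 0, L >= 9)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  inner <- sample(codons, L / 3 - 2, replace = TRUE)
  paste0("ATG", paste(inner, collapse = ""), "TAA")
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
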