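## shared fixtures, built once per test run

## desk-scale ancestor (about 15.5 kb): full 13-block catalog, IR ~2.7 kb
ancFixture <- local({
  anc <- NULL
  function() {
    if (is.null(anc))
      anc <<- generateAncestor(ancestorConfig(seed = 42, scale = 0.1),
                               id = "ref")
    anc
  }
})

## published block orders (Table-2-style inputs to the distance engine)
lophopyxisPerm <- function()
  signedPermutation(c(1, 2, 3, 4, -6, -5, 7, 8, 9, 10, -13, 11, 12))
drypetesPerm <- function()
  signedPermutation(c(1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12))

## uniform random DNA string (test-local; independent of package internals)
rndDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## small genome with one planted sIR pair of the given length; the bases
## flanking the copies are chosen so the maximal palindromic hit cannot
## extend by chance (an extension pair (X, X) never matches under
## reverse complement)
sirGenomeFixture <- function(sir_len = 271, left = 2000, mid = 2200,
                             right = 2300, seed = 9) {
  set.seed(seed)
  sir <- rndDNA(sir_len)
  lf <- paste0(rndDNA(left - 1L), "A")
  md <- paste0("C", rndDNA(mid - 2L), "C")
  rt <- paste0("A", rndDNA(right - 1L))
  g <- plastomeGenome("iso", paste0(lf, sir, md, rcDNA(sir), rt))
  list(genome = g,
       a_start = left + 1L, a_end = left + sir_len,
       b_start = left + sir_len + mid + 1L,
       b_end = left + sir_len + mid + sir_len)
}

## random signed permutation of size n
rndSignedPerm <- function(n) {
  signedPermutation(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

## all signed permutations of 1..n
allSignedPerms <- function(n) {
  perms <- list(integer(0))
  for (k in seq_len(n)) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(seq_len(length(p) + 1L), function(pos) append(p, k, pos - 1L))
    }), recursive = FALSE)
  }
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- list()
  for (p in perms) for (r in seq_len(nrow(signs)))
    out[[length(out) + 1L]] <- p * signs[r, ]
  out
}

## independent recheck of one repeat hit by direct string comparison
recheckHit <- function(s, hit) {
  n <- nchar(s)
  c1 <- substr(s, hit$pos1, hit$pos1 + hit$length - 1L)
  c2 <- substr(s, hit$pos2, hit$pos2 + hit$length - 1L)
  c2 <- switch(hit$type,
    forward = c2,
    complement = chartr("ACGT", "TGCA", c2),
    reverse = paste(rev(strsplit(c2, "")[[1L]]), collapse = ""),
    palindromic = rcDNA(c2))
  mm <- sum(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  mm == hit$mismatches
}
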