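#' Construct an annotated plastome genome
#'
#' @param id genome identifier.
#' @param seq character string or [Biostrings::DNAString].
#' @param topology `"circular"` (default) or `"linear"`.
#' @param features feature table; see [PlastomeGenome-class]. Missing
#'   columns are filled with defaults.
#' @return a [PlastomeGenome-class] object.
#' @examples
#' g <- plastomeGenome("toy", "ACGTACGTAC",
#'   features = data.frame(feature_id = "g1", kind = "gene", name = "psbA",
#'                         start = 1, end = 6, strand = "+"))
#' genomeLength(g)
#' @export
plastomeGenome <- function(id, seq, topology = "circular",
                           features = emptyFeatures()) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  features <- completeFeatures(features)
  new("PlastomeGenome", id = as.character(id), seq = seq,
      topology = topology, features = features)
}

#' @rdname plastomeGenome
#' @export
emptyFeatures <- function() {
  data.frame(feature_id = character(), kind = character(),
             name = character(), start = integer(), end = integer(),
             strand = character(), paired_id = character(),
             notes = character(), stringsAsFactors = FALSE)
}

completeFeatures <- function(ft) {
  if (is.null(ft) || nrow(ft) == 0L) return(emptyFeatures())
  ft <- as.data.frame(ft, stringsAsFactors = FALSE)
  if (is.null(ft$paired_id)) ft$paired_id <- NA_character_
  if (is.null(ft$notes)) ft$notes <- NA_character_
  if (is.null(ft$feature_id)) ft$feature_id <- sprintf("f%04d", seq_len(nrow(ft)))
  ft$start <- as.integer(ft$start)
  ft$end <- as.integer(ft$end)
  rownames(ft) <- NULL
  ft[c("feature_id", "kind", "name", "start", "end", "strand",
       "paired_id", "notes")]
}

#' Accessors for PlastomeGenome
#'
#' @param x a [PlastomeGenome-class].
#' @return `genomeId` the identifier; `genomeSeq` the [Biostrings::DNAString];
#'   `genomeLength` the length in bases; `genomeTopology` the topology;
#'   `genomeFeatures` the feature table.
#' @name genome-accessors
NULL

#' @rdname genome-accessors
#' @export
genomeId <- function(x) x@id

#' @rdname genome-accessors
#' @export
genomeSeq <- function(x) x@seq

#' @rdname genome-accessors
#' @export
genomeLength <- function(x) length(x@seq)

#' @rdname genome-accessors
#' @export
genomeTopology <- function(x) x@topology

#' @rdname genome-accessors
#' @export
genomeFeatures <- function(x) x@features

setMethod("show", "PlastomeGenome", function(object) {
  ft <- object@features
  cat(sprintf("PlastomeGenome '%s' (%s), %d bp, %d features\n",
              object@id, object@topology, length(object@seq), nrow(ft)))
  if (nrow(ft) > 0L) {
    tab <- table(ft$kind)
    cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
})

#' Construct a signed permutation
#'
#' @param perm integer vector of signed block labels; absolute values must
#'   be exactly `1..n`, each appearing once.
#' @return a [SignedPermutation-class].
#' @examples
#' signedPermutation(c(1, 2, 3, 4, -6, -5, 7, 8, 9, 10, -13, 11, 12))
#' @export
signedPermutation <- function(perm) {
  new("SignedPermutation", perm = as.integer(perm))
}

#' @rdname signedPermutation
#' @param x a `SignedPermutation`.
#' @export
permVector <- function(x) x@perm

setMethod("length", "SignedPermutation", function(x) length(x@perm))

setMethod("show", "SignedPermutation", function(object) {
  cat("SignedPermutation: ", paste(object@perm, collapse = ", "), "\n",
      sep = "")
})

#' Construct an inverted-repeat pair
#'
#' @param a_start,a_end,b_start,b_end 1-based closed interval bounds;
#'   copy A must precede copy B and the copies must be disjoint.
#' @param klass `"IR"` or `"sIR"`.
#' @return an [IRPair-class].
#' @export
irPair <- function(a_start, a_end, b_start, b_end, klass = "sIR") {
  new("IRPair", a_start = as.integer(a_start), a_end = as.integer(a_end),
      b_start = as.integer(b_start), b_end = as.integer(b_end),
      length = as.integer(a_end - a_start + 1), klass = klass)
}

#' @rdname irPair
#' @param x an `IRPair`.
#' @export
irLength <- function(x) x@length

#' @rdname irPair
#' @export
irClass <- function(x) x@klass

#' @rdname irPair
#' @export
irIntervals <- function(x) {
  data.frame(copy = c("A", "B"), start = c(x@a_start, x@b_start),
             end = c(x@a_end, x@b_end))
}

setMethod("show", "IRPair", function(object) {
  cat(sprintf("%s pair: A=[%d,%d] B=[%d,%d] length=%d\n", object@klass,
              object@a_start, object@a_end, object@b_start, object@b_end,
              object@length))
})

setMethod("show", "BreakpointGraph", function(object) {
  cat(sprintf(
    "BreakpointGraph: n=%d b=%d c=%d oriented=%d unoriented=%d h=%d f=%d\n",
    object@n, object@breakpoints, object@cycles, object@oriented_components,
    object@unoriented_components, object@hurdles, object@fortress))
})

setMethod("show", "DistanceResult", function(object) {
  g <- object@graph
  cat(sprintf("Reversal distance d = %d  [(n+1)-c=%d, h=%d, f=%d]\n",
              object@d, g@n + 1L - g@cycles, g@hurdles, g@fortress))
})

#' @rdname reversalDistance
#' @param x a `DistanceResult`.
#' @export
distanceValue <- function(x) x@d

#' @rdname reversalDistance
#' @export
distanceGraph <- function(x) x@graph

## subsequence on the circle, 1-based closed; end may exceed length(seq)
## (wraps around the origin)
circularSubseq <- function(seq, start, end) {
  n <- length(seq)
  if (end <= n) return(Biostrings::subseq(seq, start, end))
  Biostrings::xscat(Biostrings::subseq(seq, start, n),
                    Biostrings::subseq(seq, 1L, end - n))
}
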