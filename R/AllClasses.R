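#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Annotated plastome sequence
#'
#' A circular or linear DNA sequence together with typed features (genes,
#' exons, introns, IR/sIR copies, pseudogenes). Coordinates are 1-based and
#' closed, the native Bioconductor convention; features on a circular genome
#' that wrap the origin are stored as two rows sharing one `feature_id`.
#'
#' @slot id single genome identifier.
#' @slot seq a [Biostrings::DNAString] over A, C, G, T, N.
#' @slot topology `"circular"` or `"linear"`.
#' @slot features a `data.frame` with columns `feature_id`, `kind`
#'   (gene, exon, intron, IR, sIR, pseudogene), `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `paired_id` (the partner of an IR/sIR copy,
#'   `NA` otherwise) and `notes` (free-text key=value annotations,
#'   e.g. the inactivating lesion of a pseudogene).
#'
#' @seealso [plastomeGenome()], [readGenome()], [generateAncestor()]
#' @export
setClass("PlastomeGenome",
  representation(
    id = "character",
    seq = "DNAString",
    topology = "character",
    features = "data.frame"
  )
)

#' Signed permutation of synteny-block labels
#'
#' The ordered, signed block labels of one genome relative to a reference
#' whose own order is the identity `1..n`. Signs encode strand: a block
#' aligned to the reference in inverted orientation carries a minus.
#'
#' @slot perm integer vector; absolute values are exactly `1..n`, each once.
#' @seealso [signedPermutation()], [encodePermutation()], [reversalDistance()]
#' @export
setClass("SignedPermutation", representation(perm = "integer"))

#' One inverted-repeat pair (IR or sIR)
#'
#' Two disjoint intervals whose sequences are exact reverse complements of
#' one another. The large ~25 kb plastome repeat is classed `"IR"`; shorter
#' pairs capable of mediating flip-flop recombination are classed `"sIR"`.
#' Coordinates are 1-based closed on the linearized genome.
#'
#' @slot a_start,a_end,b_start,b_end interval bounds; A precedes B.
#' @slot length repeat length in bases (`a_end - a_start + 1`).
#' @slot klass `"IR"` or `"sIR"`.
#' @seealso [classifyIR()], [exciseIRB()], [flipIsomer()]
#' @export
setClass("IRPair",
  representation(
    a_start = "integer", a_end = "integer",
    b_start = "integer", b_end = "integer",
    length = "integer", klass = "character"
  )
)

#' Breakpoint graph of a framed signed permutation
#'
#' The framed, doubled representation underlying the Hannenhalli-Pevzner
#' reversal distance: each signed element x becomes the ordered pair
#' (2x-1, 2x) (or (2x, 2x-1) when negative), framed by 0 and 2n+1. Black
#' edges join the two endpoints inside each frame slot; gray edges join the
#' endpoints of consecutive values. Cycle and unoriented-component structure
#' determine the exact distance d = (n+1) - c + h + f.
#'
#' @slot n number of blocks.
#' @slot doubled integer vector of length 2n+2, the framed doubling.
#' @slot breakpoints count b of non-adjacencies in the framed signed reading.
#' @slot cycles cycle count c (adjacency 1-cycles included).
#' @slot oriented_components,unoriented_components counts of nontrivial
#'   components by orientation.
#' @slot hurdles hurdle count h among unoriented components.
#' @slot fortress 1 when the hurdles form a fortress (odd number, all
#'   superhurdles), else 0.
#' @seealso [buildBreakpointGraph()], [reversalDistance()]
#' @export
setClass("BreakpointGraph",
  representation(
    n = "integer", doubled = "integer",
    breakpoints = "integer", cycles = "integer",
    oriented_components = "integer", unoriented_components = "integer",
    hurdles = "integer", fortress = "integer"
  )
)

#' Exact reversal distance with its certificate
#'
#' @slot d minimum number of reversals to the identity.
#' @slot graph the [BreakpointGraph-class] the distance was read from.
#' @seealso [reversalDistance()], [optimalScenario()]
#' @export
setClass("DistanceResult",
  representation(d = "integer", graph = "BreakpointGraph")
)

setValidity("PlastomeGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) < 1L)
    msg <- c(msg, "sequence must be non-empty")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  ft <- object@features
  need <- c("feature_id", "kind", "name", "start", "end", "strand",
            "paired_id", "notes")
  if (!all(need %in% names(ft))) {
    msg <- c(msg, paste("features must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(ft) > 0L) {
    if (any(ft$start < 1L) || any(ft$end > length(object@seq)))
      msg <- c(msg, "feature intervals must lie within the sequence")
    if (any(ft$start > ft$end))
      msg <- c(msg, "feature start must be <= end")
    if (!all(ft$kind %in% c("gene", "exon", "intron", "IR", "sIR",
                            "pseudogene", "spacer")))
      msg <- c(msg, "unknown feature kind")
    if (!all(ft$strand %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
    ## wrapped circular features may share an id across exactly two rows
    dup <- table(ft$feature_id)
    if (any(dup > 2L))
      msg <- c(msg, "a feature_id may appear at most twice (origin wrap)")
    if (any(dup > 1L) && object@topology != "circular")
      msg <- c(msg, "duplicated feature_id only allowed on circular genomes")
  }
  if (length(msg)) msg else TRUE
})

setValidity("SignedPermutation", function(object) {
  p <- object@perm
  if (length(p) == 0L) return("permutation must be non-empty")
  if (anyNA(p) || any(p == 0L)) return("labels must be nonzero integers")
  a <- sort(abs(p))
  if (anyDuplicated(abs(p)))
    return(sprintf("duplicate label |%d|", abs(p)[duplicated(abs(p))][1L]))
  if (!identical(a, seq_len(length(p))))
    return(sprintf("missing label %d",
                   setdiff(seq_len(max(a)), a)[1L]))
  TRUE
})

setValidity("IRPair", function(object) {
  if (object@a_start > object@a_end || object@b_start > object@b_end)
    return("interval bounds out of order")
  if (object@a_end >= object@b_start)
    return("IR copies must be disjoint with A before B")
  if (object@length != object@a_end - object@a_start + 1L)
    return("length does not match interval A")
  if (object@length != object@b_end - object@b_start + 1L)
    return("the two copies must have equal length")
  if (!object@klass %in% c("IR", "sIR"))
    return("klass must be 'IR' or 'sIR'")
  TRUE
})
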