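#' Default plastome gene catalog
#'
#' The ordered gene content of the synthetic quadripartite ancestor: 112
#' distinct gene names laid out in 13 synteny blocks. Blocks 1-10 sit in
#' the Large Single Copy region (LSC), block 11 spans the Small Single Copy
#' region (SSC) plus the start of the inverted repeat (IR), and blocks 12
#' and 13 complete the IR. Block 7 is a gene-free intergenic block. The IR
#' compartment holds 4 rRNA genes, 7 tRNA genes and 5 protein-coding genes,
#' each present in two identical, inverted copies in the assembled ancestor.
#'
#' Lengths are desk-scale approximations of typical angiosperm plastome
#' gene sizes (protein genes are multiples of 3 and generated as clean
#' ORFs). `scale` shrinks gene and intron lengths proportionally for fast
#' simulation studies, preserving block structure and gene counts.
#'
#' @param scale length multiplier in (0, 1]; protein lengths are re-rounded
#'   to multiples of 3 with a floor of 30, RNA genes floored at 40.
#' @return a `data.frame` with columns `name`, `block`, `compartment`
#'   (`LSC`, `SSC`, `IR`), `strand`, `length`, `n_introns`, `coding`
#'   (TRUE for protein genes).
#' @seealso [generateAncestor()]
#' @export
defaultGeneCatalog <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  e <- function(name, block, comp, len, introns = 0L) {
    data.frame(name = name, block = block, compartment = comp,
               length = len, n_introns = introns, stringsAsFactors = FALSE)
  }
  cat <- rbind(
    ## block 1 (LSC)
    e("trnH-GUG", 1L, "LSC", 75L), e("psbA", 1L, "LSC", 1062L),
    e("trnK-UUU", 1L, "LSC", 75L), e("matK", 1L, "LSC", 1530L),
    e("rps16", 1L, "LSC", 264L, 1L),
    ## block 2
    e("trnQ-UUG", 2L, "LSC", 72L), e("psbK", 2L, "LSC", 186L),
    e("psbI", 2L, "LSC", 111L),
    ## block 3
    e("trnS-GCU", 3L, "LSC", 88L), e("trnG-UCC", 3L, "LSC", 72L),
    e("trnR-UCU", 3L, "LSC", 72L), e("atpA", 3L, "LSC", 1524L),
    e("atpF", 3L, "LSC", 555L, 1L), e("atpH", 3L, "LSC", 246L),
    e("atpI", 3L, "LSC", 744L), e("rps2", 3L, "LSC", 711L),
    e("rpoC2", 3L, "LSC", 4143L), e("rpoC1", 3L, "LSC", 2046L),
    e("rpoB", 3L, "LSC", 3213L), e("trnC-GCA", 3L, "LSC", 71L),
    e("petN", 3L, "LSC", 90L), e("psbM", 3L, "LSC", 105L),
    e("trnD-GUC", 3L, "LSC", 74L), e("trnY-GUA", 3L, "LSC", 84L),
    e("trnE-UUC", 3L, "LSC", 73L), e("trnT-GGU", 3L, "LSC", 72L),
    e("psbD", 3L, "LSC", 1062L), e("psbC", 3L, "LSC", 1422L),
    e("trnS-UGA", 3L, "LSC", 93L), e("psbZ", 3L, "LSC", 189L),
    e("trnfM-CAU", 3L, "LSC", 74L), e("rps14", 3L, "LSC", 303L),
    e("psaB", 3L, "LSC", 2205L), e("psaA", 3L, "LSC", 2253L),
    e("ycf3", 3L, "LSC", 507L, 1L), e("trnS-GGA", 3L, "LSC", 87L),
    ## block 4
    e("rps4", 4L, "LSC", 606L), e("trnT-UGU", 4L, "LSC", 73L),
    ## block 5
    e("trnL-UAA", 5L, "LSC", 80L), e("trnF-GAA", 5L, "LSC", 73L),
    e("ndhJ", 5L, "LSC", 477L), e("ndhK", 5L, "LSC", 678L),
    e("ndhC", 5L, "LSC", 363L),
    ## block 6
    e("trnV-UAC", 6L, "LSC", 74L), e("trnM-CAU", 6L, "LSC", 73L),
    e("atpE", 6L, "LSC", 402L), e("atpB", 6L, "LSC", 1497L),
    ## block 7 is a gene-free intergenic block (see generateAncestor)
    ## block 8
    e("rbcL", 8L, "LSC", 1428L), e("accD", 8L, "LSC", 1467L),
    e("psaI", 8L, "LSC", 111L), e("ycf4", 8L, "LSC", 555L),
    e("cemA", 8L, "LSC", 690L), e("petA", 8L, "LSC", 963L),
    e("psbJ", 8L, "LSC", 123L), e("psbL", 8L, "LSC", 117L),
    e("psbF", 8L, "LSC", 120L), e("psbE", 8L, "LSC", 252L),
    e("petL", 8L, "LSC", 96L),
    ## block 9
    e("petG", 9L, "LSC", 114L), e("trnW-CCA", 9L, "LSC", 74L),
    e("trnP-UGG", 9L, "LSC", 74L), e("psaJ", 9L, "LSC", 135L),
    e("rpl33", 9L, "LSC", 201L), e("rps18", 9L, "LSC", 306L),
    e("rpl20", 9L, "LSC", 354L), e("rps12", 9L, "LSC", 372L, 1L),
    e("clpP", 9L, "LSC", 591L, 2L),
    ## block 10
    e("psbB", 10L, "LSC", 1527L), e("psbT", 10L, "LSC", 108L),
    e("psbN", 10L, "LSC", 132L), e("psbH", 10L, "LSC", 222L),
    e("petB", 10L, "LSC", 648L), e("petD", 10L, "LSC", 483L),
    e("rpoA", 10L, "LSC", 1014L), e("rps11", 10L, "LSC", 417L),
    e("rpl36", 10L, "LSC", 114L), e("infA", 10L, "LSC", 234L),
    e("rps8", 10L, "LSC", 399L), e("rpl14", 10L, "LSC", 369L),
    e("rpl16", 10L, "LSC", 408L), e("rps3", 10L, "LSC", 657L),
    e("rpl22", 10L, "LSC", 462L), e("rps19", 10L, "LSC", 279L),
    ## block 11, SSC part
    e("ndhF", 11L, "SSC", 2241L), e("rpl32", 11L, "SSC", 174L),
    e("trnL-UAG", 11L, "SSC", 80L), e("ccsA", 11L, "SSC", 966L),
    e("ndhD", 11L, "SSC", 1503L), e("psaC", 11L, "SSC", 246L),
    e("ndhE", 11L, "SSC", 306L), e("ndhG", 11L, "SSC", 531L),
    e("ndhI", 11L, "SSC", 543L), e("ndhA", 11L, "SSC", 1092L, 1L),
    e("ndhH", 11L, "SSC", 1182L), e("rps15", 11L, "SSC", 273L),
    e("ycf1", 11L, "SSC", 5385L),
    ## block 11, IR part
    e("trnN-GUU", 11L, "IR", 72L), e("trnR-ACG", 11L, "IR", 74L),
    e("rrn5", 11L, "IR", 121L), e("rrn4.5", 11L, "IR", 103L),
    e("rrn23", 11L, "IR", 2810L), e("trnA-UGC", 11L, "IR", 73L),
    e("trnI-GAU", 11L, "IR", 72L), e("rrn16", 11L, "IR", 1491L),
    e("trnV-GAC", 11L, "IR", 72L), e("rps7", 11L, "IR", 468L),
    e("ndhB", 11L, "IR", 1533L, 1L), e("trnL-CAA", 11L, "IR", 81L),
    e("ycf2", 11L, "IR", 6912L),
    ## block 12 (IR)
    e("trnI-CAU", 12L, "IR", 74L),
    ## block 13 (IR)
    e("rpl23", 13L, "IR", 282L), e("rpl2", 13L, "IR", 1491L, 1L)
  )
  cat$coding <- !grepl("^(trn|rrn)", cat$name)
  cat$strand <- "+"
  ## sprinkle minus-strand genes deterministically for realism
  minus <- c("psbA", "matK", "rpoC2", "rpoC1", "rpoB", "atpA", "atpF",
             "atpH", "atpI", "rps2", "petN", "ndhC", "ndhK", "ndhJ",
             "atpB", "atpE", "accD", "cemA", "petA", "clpP", "rps12",
             "rpl20", "ndhF", "ndhD", "ndhE", "ndhG", "ndhI", "ndhA",
             "ndhH", "rps15", "ycf1", "rpl23", "rpl2", "trnK-UUU",
             "trnQ-UUG", "trnC-GCA", "trnN-GUU")
  cat$strand[cat$name %in% minus] <- "-"
  if (scale < 1) {
    cat$length <- ifelse(cat$coding,
                         pmax(30L, as.integer(round(cat$length * scale / 3)) * 3L),
                         pmax(40L, as.integer(round(cat$length * scale))))
  }
  cat$n_introns <- as.integer(cat$n_introns)
  cat$block <- as.integer(cat$block)
  cat
}

#' Synthetic-ancestor configuration
#'
#' Bundles the knobs of [generateAncestor()]. Defaults emulate a canonical
#' angiosperm plastome: ~86 kb LSC, ~16 kb SSC and a ~26.7 kb IR present in
#' two inverted copies (total ~155 kb), with the 13-block
#' [defaultGeneCatalog()]. `scale` shrinks the whole genome proportionally
#' for fast simulation studies.
#'
#' @param lsc_len,ssc_len,ir_len compartment lengths in bases (IR length is
#'   per copy; two copies are assembled). `ir_len` must be >= 1000.
#' @param catalog gene catalog as from [defaultGeneCatalog()].
#' @param spacer_len_range integer pair: intergenic spacers are drawn
#'   uniformly from this range, then adjusted uniformly so each compartment
#'   hits its configured length exactly.
#' @param intron_len length of each simulated intron.
#' @param seed integer seed; all randomness in generation flows from it.
#' @param scale length multiplier in (0, 1] applied to compartments,
#'   catalog and introns alike.
#' @return a list of class `AncestorConfig`.
#' @export
ancestorConfig <- function(lsc_len = 86000L, ssc_len = 16000L,
                           ir_len = 26700L,
                           catalog = defaultGeneCatalog(scale),
                           spacer_len_range = c(30L, 700L),
                           intron_len = 500L, seed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  if (scale < 1) {
    lsc_len <- as.integer(round(lsc_len * scale))
    ssc_len <- as.integer(round(ssc_len * scale))
    ir_len <- as.integer(round(ir_len * scale))
    intron_len <- max(20L, as.integer(round(intron_len * scale)))
  }
  if (ir_len < 1000L) stop("ir_len must be >= 1000")
  total <- lsc_len + ssc_len + 2L * ir_len
  if (total > 200000L) stop("total configured length exceeds 200 kb")
  structure(list(lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len),
                 catalog = catalog,
                 spacer_len_range = as.integer(spacer_len_range),
                 intron_len = as.integer(intron_len),
                 seed = as.integer(seed)),
            class = "AncestorConfig")
}
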