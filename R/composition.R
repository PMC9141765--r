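# Base composition, skews, codon usage (counts, CDpT, RSCU), p-distance.

#' Base composition and strand skews
#'
#' Counts A/C/G/T (N and other ambiguity codes excluded), AT percentage, and
#' the strand-asymmetry skews AT-skew = (A - T)/(A + T) and
#' GC-skew = (G - C)/(G + C), computed from raw counts on the given strand.
#' A skew with zero denominator is returned as NA and flagged.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param regionClass label for the counted region, one of
#'   "whole", "PCGs", "rRNAs", "tRNAs", "CR".
#' @return one-row data.frame: region_class, A, C, G, T, at_percent,
#'   at_skew, gc_skew, skew_undefined.
#' @export
computeComposition <- function(seq,
                               regionClass = c("whole", "PCGs", "rRNAs",
                                               "tRNAs", "CR")) {
  regionClass <- match.arg(regionClass)
  ch <- .seqChars(seq)
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(ch)) stop("empty effective sequence (no unambiguous bases)")
  a <- sum(ch == "A"); c_ <- sum(ch == "C")
  g <- sum(ch == "G"); t <- sum(ch == "T")
  tot <- a + c_ + g + t
  atden <- a + t; gcden <- g + c_
  data.frame(region_class = regionClass, A = a, C = c_, G = g, T = t,
             at_percent = (a + t) / tot * 100,
             at_skew = if (atden > 0) (a - t) / atden else NA_real_,
             gc_skew = if (gcden > 0) (g - c_) / gcden else NA_real_,
             skew_undefined = (atden == 0 || gcden == 0),
             stringsAsFactors = FALSE)
}

# Synonymous family of each codon under the vertebrate mitochondrial code.
# Leucine and serine are split by codon box (CUN vs UUR; UCN vs AGY): the two
# boxes are not reachable by third-position exchange and are presented as
# separate families.
.codonFamilies <- function() {
  code <- .mitoCode()
  codons <- names(code)
  aa <- unname(code)
  fam <- aa
  fam[aa == "L"] <- ifelse(substr(codons[aa == "L"], 1, 1) == "C",
                           "L(CUN)", "L(UUR)")
  fam[aa == "S"] <- ifelse(substr(codons[aa == "S"], 1, 1) == "T",
                           "S(UCN)", "S(AGY)")
  fam[aa == "*"] <- "Ter"
  stats::setNames(fam, codons)
}

#' Codon usage: counts, CDpT, and RSCU
#'
#' Pools codon counts across a set of in-frame coding sequences under the
#' vertebrate mitochondrial genetic code. Trailing incomplete codons
#' (truncated stops T-- / TA--) are trimmed before counting. CDpT (codons per
#' thousand codons) is count/total x 1000 over all codons including stops;
#' RSCU is count / (family total / family size) within each synonymous
#' family, with stop codons excluded (RSCU = NA).
#'
#' @param cdsList character vector, list of character, or
#'   \code{DNAStringSet} of coding sequences (5'->3', in frame).
#' @return data.frame with one row per codon: codon, amino_acid, family,
#'   count, cdpt, rscu; attribute \code{total_codons} holds the codon total.
#'   Internal stop codons trigger a warning naming sequence and codon index.
#' @export
computeCodonUsage <- function(cdsList) {
  if (methods::is(cdsList, "DNAStringSet"))
    cdsList <- as.character(cdsList)
  cdsList <- as.list(cdsList)
  if (!length(cdsList)) stop("empty CDS input")
  code <- .mitoCode()
  fam <- .codonFamilies()
  counts <- stats::setNames(integer(length(code)), names(code))
  for (si in seq_along(cdsList)) {
    s <- .asChar(cdsList[[si]])
    n <- nchar(s) - nchar(s) %% 3L   # trim incomplete terminal codon
    if (n < 3L) next
    cods <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    cods <- cods[grepl("^[ACGT]{3}$", cods)]
    stops <- which(code[cods] == "*")
    if (length(stops) && any(stops < length(cods)))
      warning("internal stop codon in CDS ", si, " at codon position ",
              paste(stops[stops < length(cods)], collapse = ", "),
              call. = FALSE)
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  total <- sum(counts)
  if (total == 0L) stop("no complete unambiguous codons in input")
  famTotals <- tapply(counts, fam[names(counts)], sum)
  famSizes <- table(fam[names(counts)])
  rscu <- vapply(names(counts), function(cd) {
    f <- fam[cd]
    if (f == "Ter") return(NA_real_)
    ft <- famTotals[[f]]
    if (ft == 0) return(NA_real_)
    counts[[cd]] / (ft / famSizes[[f]])
  }, numeric(1))
  out <- data.frame(codon = names(counts),
                    amino_acid = unname(code[names(counts)]),
                    family = unname(fam[names(counts)]),
                    count = unname(counts),
                    cdpt = unname(counts) / total * 1000,
                    rscu = unname(rscu),
                    stringsAsFactors = FALSE)
  attr(out, "total_codons") <- total
  out
}

#' Uncorrected p-distance
#'
#' Proportion of differing sites between two aligned sequences, excluding
#' every site where either sequence has a gap or an ambiguous base.
#'
#' @param seqA,seqB aligned sequences of equal length.
#' @return numeric scalar in [0, 1].
#' @export
pDistance <- function(seqA, seqB) {
  a <- .seqChars(seqA); b <- .seqChars(seqB)
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length (", length(a), " vs ",
         length(b), ")")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no retained sites (all gapped or ambiguous)")
  sum(a[keep] != b[keep]) / sum(keep)
}
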