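#' Canonical mitochondrial gene vocabulary
#'
#' The 37 canonical vertebrate mitochondrial genes plus the two non-coding
#' landmarks (light-strand replication origin \code{OL} and control region
#' \code{CR}), in the canonical gene order starting from tRNA-Phe. tRNA names
#' follow the trnX convention with \code{trnL1}/\code{trnL2} for Leu(CUN)/
#' Leu(UUR) and \code{trnS1}/\code{trnS2} for Ser(AGN)/Ser(UCN).
#'
#' @return character vector of 39 feature names in canonical order.
#' @export
canonicalGeneOrder <- function() {
  c("trnF", "rrnS", "trnV", "rrnL", "trnL2", "ND1", "trnI", "trnQ", "trnM",
    "ND2", "trnW", "trnA", "trnN", "OL", "trnC", "trnY", "COI", "trnS2",
    "trnD", "COII", "trnK", "ATP8", "ATP6", "COIII", "trnG", "ND3", "trnR",
    "ND4L", "ND4", "trnH", "trnS1", "trnL1", "ND5", "ND6", "trnE", "CYTB",
    "trnT", "trnP", "CR")
}

#' Genes encoded on the light strand
#'
#' ND6 and the eight light-strand tRNAs; all other canonical genes lie on the
#' heavy strand.
#'
#' @return character vector of gene names.
#' @export
lightStrandGenes <- function() {
  c("ND6", "trnQ", "trnA", "trnN", "trnC", "trnY", "trnS2", "trnE", "trnP")
}

.canonicalNames <- function() canonicalGeneOrder()

.emptyFeatures <- function() {
  data.frame(name = character(), strand = character(),
             start = integer(), end = integer(),
             wraps_origin = logical(), type = character(),
             mapped = logical(), raw_name = character(),
             stringsAsFactors = FALSE)
}

#' Mitogenome class
#'
#' An annotated (usually circular) mitochondrial genome: the heavy-strand
#' reference sequence plus a typed feature table. Feature coordinates are
#' 0-based half-open on the H-strand; a feature crossing the sequence origin
#' carries \code{wraps_origin = TRUE} and an \code{end} interpreted modulo the
#' genome length.
#'
#' @slot recordId character scalar, the record/locus identifier.
#' @slot sequence \code{DNAString}, the H-strand sequence (uppercase).
#' @slot circular logical scalar.
#' @slot features data.frame with columns \code{name}, \code{strand} (H/L),
#'   \code{start}, \code{end} (0-based half-open), \code{wraps_origin},
#'   \code{type} (PCG/tRNA/rRNA/OL/CR/other), \code{mapped} (whether the name
#'   was resolved to the canonical vocabulary), \code{raw_name}.
#' @slot taxon character scalar, optional taxon label ("" if unknown).
#'
#' @export
setClass("Mitogenome",
  representation(recordId = "character", sequence = "ANY",
                 circular = "logical", features = "data.frame",
                 taxon = "character"),
  prototype(recordId = "", sequence = NULL, circular = TRUE,
            features = NULL, taxon = ""))

setValidity("Mitogenome", function(object) {
  msgs <- character()
  if (length(object@recordId) != 1L) msgs <- c(msgs, "recordId must be scalar")
  if (!methods::is(object@sequence, "DNAString"))
    msgs <- c(msgs, "sequence must be a DNAString")
  else if (length(object@sequence) == 0L)
    msgs <- c(msgs, "sequence must be non-empty")
  ft <- object@features
  need <- c("name", "strand", "start", "end", "wraps_origin", "type",
            "mapped", "raw_name")
  if (!all(need %in% names(ft)))
    msgs <- c(msgs, paste("features must have columns:",
                          paste(need, collapse = ", ")))
  else if (nrow(ft)) {
    L <- length(object@sequence)
    if (any(ft$start < 0L) || any(ft$start >= L))
      msgs <- c(msgs, "feature starts must lie in [0, genome length)")
    bad <- !ft$wraps_origin & (ft$end <= ft$start | ft$end > L)
    if (any(bad))
      msgs <- c(msgs, "non-wrapping features need start < end <= genome length")
    if (any(ft$wraps_origin) && !object@circular)
      msgs <- c(msgs, "wrapping features require a circular genome")
    if (!all(ft$strand %in% c("H", "L")))
      msgs <- c(msgs, "strand must be H or L")
    canon <- ft$name[ft$mapped & ft$name %in% .canonicalNames()]
    if (anyDuplicated(canon))
      msgs <- c(msgs, paste("duplicated canonical gene(s):",
                            paste(unique(canon[duplicated(canon)]),
                                  collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Mitogenome
#'
#' @param recordId record identifier.
#' @param sequence DNA sequence (character or \code{DNAString}); normalized
#'   to uppercase.
#' @param features feature data.frame (see \linkS4class{Mitogenome}); missing
#'   bookkeeping columns are filled in.
#' @param circular logical.
#' @param taxon optional taxon label.
#'
#' @return a \code{Mitogenome} object.
#' @export
Mitogenome <- function(recordId, sequence, features = .emptyFeatures(),
                       circular = TRUE, taxon = "") {
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(toupper(sequence))
  features <- .completeFeatures(features)
  methods::new("Mitogenome", recordId = as.character(recordId),
               sequence = sequence, circular = isTRUE(circular),
               features = features, taxon = as.character(taxon))
}

.featureType <- function(name) {
  pcg <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6", "ATP6", "ATP8",
           "COI", "COII", "COIII", "CYTB")
  ifelse(name %in% pcg, "PCG",
    ifelse(grepl("^trn", name), "tRNA",
      ifelse(name %in% c("rrnS", "rrnL"), "rRNA",
        ifelse(name == "OL", "OL", ifelse(name == "CR", "CR", "other")))))
}

.completeFeatures <- function(ft) {
  if (is.null(ft)) ft <- .emptyFeatures()
  if (is.null(ft$wraps_origin)) ft$wraps_origin <- rep(FALSE, nrow(ft))
  if (is.null(ft$type)) ft$type <- .featureType(ft$name)
  if (is.null(ft$mapped)) ft$mapped <- ft$name %in% .canonicalNames()
  if (is.null(ft$raw_name)) ft$raw_name <- ft$name
  ft$start <- as.integer(ft$start)
  ft$end <- as.integer(ft$end)
  rownames(ft) <- NULL
  ft[c("name", "strand", "start", "end", "wraps_origin", "type", "mapped",
       "raw_name")]
}

#' ControlRegion class
#'
#' The control region of a mitogenome: the H-strand interval running from the
#' 3' end of tRNA-Pro to the 5' start of tRNA-Phe, possibly wrapping the
#' sequence origin on circular genomes.
#'
#' @slot recordId character scalar.
#' @slot sequence \code{DNAString}, the CR sequence in H-strand orientation.
#' @slot start,end 0-based half-open genome coordinates; when
#'   \code{wrapsOrigin} is TRUE, \code{end} is the coordinate after wrapping
#'   (i.e. \code{end <= start}).
#' @slot wrapsOrigin logical.
#' @slot genomeLength integer, length of the source genome.
#'
#' @export
setClass("ControlRegion",
  representation(recordId = "character", sequence = "ANY",
                 start = "integer", end = "integer",
                 wrapsOrigin = "logical", genomeLength = "integer"))

setValidity("ControlRegion", function(object) {
  msgs <- character()
  if (!methods::is(object@sequence, "DNAString"))
    msgs <- c(msgs, "sequence must be a DNAString")
  else if (length(object@sequence) == 0L)
    msgs <- c(msgs, "control region must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' @rdname mitoCR-generics
#' @export
setMethod("recordId", "Mitogenome", function(x) x@recordId)
#' @rdname mitoCR-generics
#' @export
setMethod("recordId", "ControlRegion", function(x) x@recordId)
#' @rdname mitoCR-generics
#' @export
setMethod("genomeSeq", "Mitogenome", function(x) x@sequence)
#' @rdname mitoCR-generics
#' @export
setMethod("mtFeatures", "Mitogenome", function(x) x@features)
#' @rdname mitoCR-generics
#' @export
setMethod("taxonName", "Mitogenome", function(x) x@taxon)
#' @rdname mitoCR-generics
#' @export
setMethod("isCircularGenome", "Mitogenome", function(x) x@circular)
#' @rdname mitoCR-generics
#' @export
setMethod("crSeq", "ControlRegion", function(x) x@sequence)
#' @rdname mitoCR-generics
#' @export
setMethod("crLength", "ControlRegion", function(x) length(x@sequence))
#' @rdname mitoCR-generics
#' @export
setMethod("crBounds", "ControlRegion", function(x)
  c(start = x@start, end = x@end, wraps_origin = as.integer(x@wrapsOrigin)))

setMethod("show", "Mitogenome", function(object) {
  ft <- object@features
  cat("Mitogenome '", object@recordId, "' (",
      if (object@circular) "circular" else "linear", ", ",
      length(object@sequence), " bp)\n", sep = "")
  if (nzchar(object@taxon)) cat("  taxon: ", object@taxon, "\n", sep = "")
  cat("  features: ", nrow(ft), " (", sum(ft$type == "PCG"), " PCG, ",
      sum(ft$type == "tRNA"), " tRNA, ", sum(ft$type == "rRNA"), " rRNA)\n",
      sep = "")
  invisible(object)
})

setMethod("show", "ControlRegion", function(object) {
  cat("ControlRegion of '", object@recordId, "': ", length(object@sequence),
      " bp [", object@start, ", ", object@end, ")",
      if (object@wrapsOrigin) " (wraps origin)" else "", "\n", sep = "")
  invisible(object)
})
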