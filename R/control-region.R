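#' Extract the control region of a mitogenome
#'
#' The control region is taken as the H-strand interval running from the 3'
#' end of tRNA-Pro to the 5' start of tRNA-Phe (the canonical vertebrate
#' orientation), wrapping the sequence origin when the genome is circular and
#' tRNA-Phe precedes tRNA-Pro in sequence coordinates.
#'
#' @param record a \linkS4class{Mitogenome} containing \code{trnP} and
#'   \code{trnF} features.
#' @return a \linkS4class{ControlRegion}.
#' @export
extractControlRegion <- function(record) {
  stopifnot(methods::is(record, "Mitogenome"))
  ft <- mtFeatures(record)
  L <- length(genomeSeq(record))
  pro <- ft[ft$name == "trnP", , drop = FALSE]
  phe <- ft[ft$name == "trnF", , drop = FALSE]
  if (!nrow(pro)) stop("cannot locate control region: missing tRNA-Pro (trnP)")
  if (!nrow(phe)) stop("cannot locate control region: missing tRNA-Phe (trnF)")
  proEnd <- if (pro$wraps_origin[1L]) pro$end[1L] else pro$end[1L] %% L
  pheStart <- phe$start[1L]
  crLen <- (pheStart - proEnd) %% L
  if (crLen == 0L)
    stop("zero-length control region between tRNA-Pro and tRNA-Phe")
  wraps <- pheStart <= proEnd
  if (wraps && !isCircularGenome(record))
    stop("control region would wrap the origin of a non-circular genome")
  seq <- if (wraps) .circularSubseq(genomeSeq(record), proEnd, pheStart)
         else substr(.asChar(genomeSeq(record)), proEnd + 1L, pheStart)
  methods::new("ControlRegion", recordId = recordId(record),
               sequence = Biostrings::DNAString(seq),
               start = as.integer(proEnd), end = as.integer(pheStart),
               wrapsOrigin = wraps, genomeLength = as.integer(L))
}
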