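# Gene-overlap and O_L motif scanning.

#' Conserved overlap motifs at the ATP8/ATP6 junction
#'
#' The two conserved overlap motifs observed at the ATP8/ATP6 junction in
#' lacertids, with N wildcards.
#'
#' @return named character vector of motifs.
#' @export
overlapMotifs <- function() {
  c(ATGGNNNTAA = "ATGGNNNTAA", ATGANTAA = "ATGANTAA")
}

#' Light-strand replication origin motifs
#'
#' The two O_L stem motifs (26 nt with five N, 25 nt with four N); the two
#' differ by a single base (one N of the wildcard run).
#'
#' @return named character vector of the two patterns.
#' @export
olMotifs <- function() {
  c(ol26 = "TTCCCCCGTTANNNNNAAAACGGGGG",
    ol25 = "TTCCCCCGTTANNNNAAAACGGGGG")
}

# Split a (possibly wrapping) feature into linear 0-based half-open intervals.
.linearIntervals <- function(start, end, wraps, L) {
  if (!wraps) data.frame(s = start, e = end)
  else data.frame(s = c(start, 0L), e = c(L, end))
}

.matchesWildcard <- function(seq, motif) {
  if (nchar(seq) != nchar(motif)) return(FALSE)
  s <- strsplit(seq, "")[[1L]]
  m <- strsplit(motif, "")[[1L]]
  all(m == "N" | m == s)
}

.classifyOverlapMotif <- function(seq) {
  for (motif in overlapMotifs()) {
    if (.matchesWildcard(seq, motif)) return(motif)
  }
  "none"
}

#' Scan a mitogenome for gene overlaps
#'
#' Reports every pair of features (same or opposite strand) whose H-strand
#' intervals intersect, with the overlap length, sequence, and the overlap
#' motif class (\code{ATGGNNNTAA}, \code{ATGANTAA}, or \code{none}).
#' Wrapping features are handled by splitting at the origin.
#'
#' @param record a \linkS4class{Mitogenome}.
#' @param includeNoncoding if FALSE (default), CR and OL landmark features
#'   are excluded from the pairwise scan.
#' @return data.frame with columns record_id, gene_a, gene_b, overlap_length,
#'   overlap_sequence, motif_class (empty if no overlaps).
#' @export
scanGeneOverlaps <- function(record, includeNoncoding = FALSE) {
  ft <- mtFeatures(record)
  if (!includeNoncoding) ft <- ft[!ft$type %in% c("CR", "OL"), , drop = FALSE]
  ft <- ft[order(ft$start), , drop = FALSE]
  L <- length(genomeSeq(record))
  out <- list()
  n <- nrow(ft)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      ia <- .linearIntervals(ft$start[i], ft$end[i], ft$wraps_origin[i], L)
      for (j in (i + 1L):n) {
        ib <- .linearIntervals(ft$start[j], ft$end[j], ft$wraps_origin[j], L)
        for (a in seq_len(nrow(ia))) for (b in seq_len(nrow(ib))) {
          s <- max(ia$s[a], ib$s[b]); e <- min(ia$e[a], ib$e[b])
          if (e > s) {
            seq <- substr(.asChar(genomeSeq(record)), s + 1L, e)
            out[[length(out) + 1L]] <- data.frame(
              record_id = recordId(record),
              gene_a = ft$name[i], gene_b = ft$name[j],
              overlap_length = e - s, overlap_sequence = seq,
              motif_class = .classifyOverlapMotif(seq),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(record_id = character(), gene_a = character(),
                      gene_b = character(), overlap_length = integer(),
                      overlap_sequence = character(),
                      motif_class = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Scan for the O_L motif
#'
#' Searches the H-strand for both printed O_L patterns with N matching any
#' base. On circular genomes the scan transiently appends a prefix of length
#' (motif length - 1) so matches crossing the origin are found; coordinates
#' are reported modulo the genome length.
#'
#' @param record a \linkS4class{Mitogenome}, \code{DNAString}, or character
#'   sequence.
#' @return data.frame with columns start, end (0-based half-open),
#'   matched_motif, pattern_length; zero rows when nothing matches.
#' @export
scanOLMotif <- function(record) {
  if (methods::is(record, "Mitogenome")) {
    s <- .asChar(genomeSeq(record))
    circular <- isCircularGenome(record)
  } else {
    s <- .asChar(record)
    circular <- FALSE
  }
  L <- nchar(s)
  out <- list()
  for (mi in seq_along(olMotifs())) {
    motif <- olMotifs()[[mi]]
    w <- nchar(motif)
    subject <- if (circular && L > w) paste0(s, substr(s, 1L, w - 1L)) else s
    hits <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                     Biostrings::DNAString(subject),
                                     fixed = "subject")
    st <- BiocGenerics::start(hits) - 1L
    st <- st[st < L]   # de-duplicate wrapped copies
    for (p in st) {
      e <- if (circular && p + w > L) (p + w) %% L else p + w
      out[[length(out) + 1L]] <- data.frame(
        start = p, end = e,
        matched_motif = names(olMotifs())[mi], pattern_length = w,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      matched_motif = character(), pattern_length = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$pattern_length), , drop = FALSE]
}
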