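# Tandem-repeat detection in control regions.
#
# Hit semantics (deliberately simple and fully declarative so an exhaustive
# oracle can re-derive them): for a candidate period p, consider the binary
# period-p self-match vector m[j] = (s[j] == s[j + p]). Candidate loci are
# the containment-maximal intervals whose self-match identity (mean of m
# over the interval's m-positions) is >= min_identity; within each locus the
# reported array is the maximum-scoring core under weights
# match = +(1 - min_identity), mismatch = -min_identity (score ties broken
# by shortest, then leftmost), so array boundaries sit on self-matches and
# chance matches in the flanking background are not absorbed. Cores failing
# the length/copy constraints are dropped, the per-column majority consensus
# is built, hits whose consensus identity falls below min_identity are
# dropped, and overlapping hits across periods are pruned keeping the
# highest (array length, identity, smallest period, smallest start).

#' Genus-diagnostic tandem-repeat motifs
#'
#' Repeat-unit segments diagnostic for Eremias ("TAGCGGCTTTTTTG"),
#' Takydromus ("GCGGCTT", "TTTTCC") and Darevskia ("CAAAACTTTTAA").
#'
#' @return character vector of motifs.
#' @export
diagnosticTrMotifs <- function() {
  c("TAGCGGCTTTTTTG", "GCGGCTT", "TTTTCC", "CAAAACTTTTAA")
}

# Identity thresholds are handled as exact rationals num/den so that
# boundary ties are deterministic and bit-identical between this
# implementation and the exhaustive test oracle: a position weight is
# den*m - num (integer), and "identity >= theta" is "integer sum >= 0".
.identityWeights <- function(theta) {
  den <- 10000
  list(num = round(theta * den), den = den)
}

# All containment-maximal intervals of a binary vector with mean >= theta
# (theta = num/den). Returns a data.frame of m-index intervals [a, b]
# (1-based inclusive). A maximal interval must start right after a strict
# prefix minimum of the shifted prefix sums and end at the last index still
# at or above that minimum; thresholds decrease over successive prefix
# minima, so a single forward pointer over the non-increasing suffix maxima
# finds all right endpoints in linear time.
.maximalIdentityRuns <- function(m, wt) {
  n <- length(m)
  if (!n) return(data.frame(a = integer(), b = integer()))
  S <- c(0, cumsum(wt$den * m - wt$num))   # exact integers
  mins <- which(S == cummin(S))
  mins <- mins[!duplicated(S[mins])]       # strict prefix minima
  M <- rev(cummax(rev(S)))                 # suffix maxima (non-increasing)
  aOut <- integer(); bOut <- integer()
  ptr <- 1L
  for (a in mins) {
    t <- S[a]
    while (ptr < n + 1L && M[ptr + 1L] >= t) ptr <- ptr + 1L
    if (ptr > a) { aOut <- c(aOut, a); bOut <- c(bOut, ptr - 1L) }
  }
  if (!length(aOut)) return(data.frame(a = integer(), b = integer()))
  keep <- !duplicated(bOut)                # equal right end => contained
  data.frame(a = aOut[keep], b = bOut[keep])
}

# Maximum-scoring subinterval of m[a..b] under integer weights
# den*m - num; score ties broken by shortest interval, then leftmost.
# Returns c(start, end) in m-indices, or NULL when no positive interval.
.kadaneCore <- function(m, a, b, wt) {
  w <- wt$den * m[a:b] - wt$num
  C <- c(0, cumsum(w))                     # C[i+1] = sum of w[1..i]
  bestScore <- -Inf; bestS <- NA_integer_; bestE <- NA_integer_
  bestLen <- Inf
  minC <- C[1L]; minIdx <- 0L              # latest argmin of C[1..j]
  for (j in seq_along(w)) {
    if (C[j] <= minC) { minC <- C[j]; minIdx <- j - 1L }
    score <- C[j + 1L] - minC
    len <- j - minIdx
    if (score > bestScore ||
        (score == bestScore &&
           (len < bestLen || (len == bestLen && minIdx + 1L < bestS)))) {
      bestScore <- score; bestS <- minIdx + 1L; bestE <- j; bestLen <- len
    }
  }
  if (bestScore <= 0) return(NULL)
  c(a + bestS - 1L, a + bestE - 1L)
}

.consensusOf <- function(chars, p) {
  L <- length(chars)
  cons <- character(p)
  for (col in seq_len(p)) {
    idx <- seq(col, L, by = p)
    tab <- table(factor(chars[idx], levels = c("A", "C", "G", "T", "N")))
    cons[col] <- names(tab)[which.max(tab)]  # ties: alphabetical
  }
  paste(cons, collapse = "")
}

#' Detect tandem-repeat arrays
#'
#' Seed-free period scan: for each period in \code{[minPeriod, maxPeriod]}
#' the sequence is compared against itself shifted by the period, maximal
#' intervals with self-match identity at least \code{minIdentity} are
#' extracted, trimmed to matching boundaries, and filtered by minimum array
#' length and copy number. The per-column majority consensus (ties broken
#' alphabetically) is reported, and overlapping hits across periods are
#' pruned keeping the longest array (then highest identity, smallest period,
#' smallest start).
#'
#' @param seq DNA sequence (character, \code{DNAString}, or
#'   \linkS4class{ControlRegion}).
#' @param minPeriod,maxPeriod period bounds in nt (defaults 1 and 200;
#'   capped at half the sequence length).
#' @param minCopies minimum copy number (array length / period); default 2.
#' @param minArrayLength minimum array length in nt; default 20.
#' @param minIdentity minimum identity fraction; default 0.8.
#' @return data.frame with columns start, end (0-based half-open), period,
#'   copy_number, consensus, mean_identity (fraction of array positions
#'   matching the consensus); zero rows when nothing qualifies.
#' @export
findTandemRepeats <- function(seq, minPeriod = 1L, maxPeriod = 200L,
                              minCopies = 2, minArrayLength = 20L,
                              minIdentity = 0.8) {
  if (methods::is(seq, "ControlRegion")) seq <- crSeq(seq)
  s <- .seqChars(seq)
  n <- length(s)
  maxPeriod <- min(maxPeriod, n %/% 2L)
  if (maxPeriod < minPeriod || minPeriod < 1L)
    return(.emptyTrHits())
  wt <- .identityWeights(minIdentity)
  cands <- list()
  for (p in minPeriod:maxPeriod) {
    m <- as.integer(s[seq_len(n - p)] == s[(p + 1L):n])
    runs <- .maximalIdentityRuns(m, wt)
    for (k in seq_len(nrow(runs))) {
      a <- runs$a[k]; b <- runs$b[k]
      # cheap prefilter before extracting the core
      if (b - a + 1L + p < minArrayLength) next
      if ((b - a + 1L + p) / p < minCopies) next
      core <- .kadaneCore(m, a, b, wt)
      if (is.null(core)) next
      st <- core[1L]; en <- core[2L] + p   # 1-based inclusive seq interval
      L <- en - st + 1L
      if (L < minArrayLength || L / p < minCopies) next
      chars <- s[st:en]
      cons <- .consensusOf(chars, p)
      consCh <- strsplit(cons, "")[[1L]]
      nMatch <- sum(chars == consCh[((seq_len(L) - 1L) %% p) + 1L])
      ident <- nMatch / L
      if (nMatch * wt$den < wt$num * L) next
      cands[[length(cands) + 1L]] <- data.frame(
        start = st - 1L, end = en, period = p, copy_number = L / p,
        consensus = cons, mean_identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) return(.emptyTrHits())
  hits <- do.call(rbind, cands)
  hits <- hits[!duplicated(hits[c("start", "end", "period")]), , drop = FALSE]
  # cross-period/locus pruning
  ord <- order(-(hits$end - hits$start), -hits$mean_identity, hits$period,
               hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- keep & hits$start < hits$end[i] & hits$end > hits$start[i]
    keep[i] <- !any(ov)
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.emptyTrHits <- function() {
  data.frame(start = integer(), end = integer(), period = integer(),
             copy_number = numeric(), consensus = character(),
             mean_identity = numeric(), stringsAsFactors = FALSE)
}

#' Positional classes of a tandem repeat relative to the conserved elements
#'
#' @return character vector of the recognised classes, in CR order.
#' @export
trPositionClasses <- function() {
  c("before_TAS1", "between_TAS1_TAS2", "between_TAS2_CSB1",
    "between_CSB1_CSB2", "between_CSB2_CSB3", "after_CSB3", "unplaced")
}

#' Classify a tandem repeat's position relative to annotated elements
#'
#' A repeat strictly upstream of the first annotated element is
#' \code{before_TAS1}; strictly downstream of the last it is
#' \code{after_CSB3}; strictly between two canonically adjacent annotated
#' elements it takes the corresponding \code{between_*} class ("anormal"
#' placement); anything else (no elements annotated, overlap with an
#' element, or flanks that are not canonically adjacent) is
#' \code{unplaced}. Repeats before TAS1 or after CSB3 are "normal".
#'
#' @param trStart,trEnd 0-based half-open repeat interval, or a one-row hit
#'   data.frame from \code{\link{findTandemRepeats}} as \code{trStart}.
#' @param elements element hits (best per element) as returned by
#'   \code{\link{annotateElements}}.
#' @return one-row data.frame: position_class, normality
#'   ("normal"/"anormal"/"unplaced").
#' @export
classifyTrPosition <- function(trStart, trEnd = NULL, elements) {
  if (is.data.frame(trStart)) {
    stopifnot(nrow(trStart) == 1L)
    trEnd <- trStart$end; trStart <- trStart$start
  }
  res <- function(cls) {
    normality <- if (cls %in% c("before_TAS1", "after_CSB3")) "normal"
                 else if (grepl("^between_", cls)) "anormal" else "unplaced"
    data.frame(position_class = cls, normality = normality,
               stringsAsFactors = FALSE)
  }
  if (is.null(elements) || !nrow(elements)) return(res("unplaced"))
  el <- elements[order(elements$start), , drop = FALSE]
  canon <- names(referenceMotifs())
  if (trEnd <= min(el$start)) {
    first <- el$element[which.min(el$start)]
    return(res(if (first == "TAS1" || !"TAS1" %in% el$element)
      "before_TAS1" else "unplaced"))
  }
  if (trStart >= max(el$end)) {
    last <- el$element[which.max(el$end)]
    return(res(if (last == "CSB3" || !"CSB3" %in% el$element)
      "after_CSB3" else "unplaced"))
  }
  for (i in seq_len(nrow(el) - 1L)) {
    if (trStart >= el$end[i] && trEnd <= el$start[i + 1L]) {
      a <- el$element[i]; b <- el$element[i + 1L]
      if (match(b, canon) == match(a, canon) + 1L)
        return(res(paste0("between_", a, "_", b)))
      return(res("unplaced"))
    }
  }
  res("unplaced")
}

#' Test control-region repeats for the genus-diagnostic motifs
#'
#' Each diagnostic motif is tested against every detected repeat array: as a
#' substring of the raw array sequence and of any rotation of the consensus
#' (a repeat array's phase is arbitrary, so the printed motifs are matched
#' phase-free).
#'
#' @param hits data.frame from \code{\link{findTandemRepeats}}.
#' @param crSeq the control-region sequence the hits refer to.
#' @param motifs motifs to test (default \code{\link{diagnosticTrMotifs}}).
#' @return data.frame with columns motif, present.
#' @export
genusMotifReport <- function(hits, crSeq,
                             motifs = diagnosticTrMotifs()) {
  if (methods::is(crSeq, "ControlRegion")) crSeq <- crSeq(crSeq)
  s <- .asChar(crSeq)
  present <- vapply(motifs, function(motif) {
    if (!nrow(hits)) return(FALSE)
    any(vapply(seq_len(nrow(hits)), function(i) {
      arr <- substr(s, hits$start[i] + 1L, hits$end[i])
      if (grepl(motif, arr, fixed = TRUE)) return(TRUE)
      doubled <- strrep(hits$consensus[i],
                        max(2L, ceiling(nchar(motif) /
                                          nchar(hits$consensus[i])) + 1L))
      grepl(motif, doubled, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  data.frame(motif = motifs, present = unname(present),
             stringsAsFactors = FALSE)
}
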