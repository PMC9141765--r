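# Nei-Gojobori (1986) pairwise dN/dS under the vertebrate mitochondrial
# code, with optional Jukes-Cantor correction (the MEGA-style default).

.ngCache <- new.env(parent = emptyenv())

# Per-codon synonymous site count: at each position, the fraction of the
# three possible substitutions that are synonymous. Substitutions creating a
# stop codon count as nonsynonymous.
.synSites <- function() {
  if (!is.null(.ngCache$synSites)) return(.ngCache$synSites)
  code <- .mitoCode()
  bases <- c("A", "C", "G", "T")
  codons <- names(code)[code != "*"]
  s <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    ch <- strsplit(cd, "")[[1L]]
    syn <- 0
    for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
      alt <- ch; alt[pos] <- b
      altc <- paste(alt, collapse = "")
      if (code[[altc]] != "*" && code[[altc]] == code[[cd]])
        syn <- syn + 1 / 3
    }
    s[[cd]] <- syn
  }
  .ngCache$synSites <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons. All substitution orders are enumerated; orders passing through a
# stop codon are excluded (all orders are used if every one is blocked).
.codonDiffs <- function(codA, codB) {
  key <- paste(codA, codB)
  if (!is.null(.ngCache[[key]])) return(.ngCache[[key]])
  code <- .mitoCode()
  a <- strsplit(codA, "")[[1L]]
  b <- strsplit(codB, "")[[1L]]
  diff <- which(a != b)
  d <- length(diff)
  if (d == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- switch(d, list(1L), list(1:2, 2:1),
                    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
    paths <- list()
    for (perm in perms) {
      cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
      for (step in perm) {
        pos <- diff[step]
        nxt <- cur; nxt[pos] <- b[pos]
        curC <- paste(cur, collapse = ""); nxtC <- paste(nxt, collapse = "")
        if (code[[nxtC]] == "*") blocked <- TRUE
        if (code[[nxtC]] == code[[curC]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      paths[[length(paths) + 1L]] <- c(sd, nd, blocked)
    }
    pm <- do.call(rbind, paths)
    use <- pm[pm[, 3L] == 0, , drop = FALSE]
    if (!nrow(use)) use <- pm
    res <- c(sd = mean(use[, 1L]), nd = mean(use[, 2L]))
  }
  .ngCache[[key]] <- res
  res
}

.jcCorrect <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)   # correction undefined
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori pairwise dN/dS
#'
#' NG86 on a pair of aligned in-frame coding sequences under the vertebrate
#' mitochondrial code: expected synonymous/nonsynonymous site counts
#' averaged over the two sequences, pathway-averaged difference counting for
#' multi-substitution codons (substitution orders through stop codons
#' excluded), and Jukes-Cantor correction d = -3/4 ln(1 - 4p/3). Codons
#' containing gaps or ambiguity in either sequence, and codons that are
#' stops in either sequence, are skipped pairwise.
#'
#' @param seqA,seqB aligned DNA strings of equal length divisible by 3.
#' @param correction "jc" (default) or "none" (proportions used directly).
#' @return one-row data.frame: n_codons (compared), S_sites, N_sites, Sd,
#'   Nd, pS, pN, dS, dN, ratio, undefined (TRUE when dS is 0 or a
#'   correction failed).
#' @export
ng86Pair <- function(seqA, seqB, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  a <- .asChar(seqA); b <- .asChar(seqB)
  if (nchar(a) != nchar(b))
    stop("aligned sequences differ in length (", nchar(a), " vs ",
         nchar(b), ")")
  n <- nchar(a) - nchar(a) %% 3L
  if (n < 3L) stop("alignment shorter than one codon")
  codA <- substring(a, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  codB <- substring(b, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  okA <- grepl("^[ACGT]{3}$", codA); okB <- grepl("^[ACGT]{3}$", codB)
  keep <- okA & okB
  code <- .mitoCode()
  keep[keep] <- code[codA[keep]] != "*" & code[codB[keep]] != "*"
  codA <- codA[keep]; codB <- codB[keep]
  nc <- length(codA)
  if (!nc) stop("no comparable codons after filtering")
  syn <- .synSites()
  S <- (sum(syn[codA]) + sum(syn[codB])) / 2
  N <- 3 * nc - S
  diffs <- vapply(seq_len(nc),
                  function(i) .codonDiffs(codA[i], codB[i]), numeric(2))
  Sd <- sum(diffs[1L, ]); Nd <- sum(diffs[2L, ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  if (correction == "jc") {
    dS <- .jcCorrect(pS); dN <- .jcCorrect(pN)
  } else {
    dS <- pS; dN <- pN
  }
  undefined <- is.na(dS) || is.na(dN) || dS == 0
  ratio <- if (undefined) NA_real_ else dN / dS
  data.frame(n_codons = nc, S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, dS = dS, dN = dN, ratio = ratio,
             undefined = undefined, stringsAsFactors = FALSE)
}

#' Gene-level average dN/dS over all sequence pairs
#'
#' Computes NG86 for every unordered pair in a per-gene alignment and
#' averages the defined pairwise ratios (mean of ratios, not ratio of
#' means); pairs with undefined ratio (dS = 0 or failed correction) are
#' excluded and counted.
#'
#' @param alignment \code{DNAStringSet} or character vector of aligned
#'   in-frame CDSs (>= 2 sequences).
#' @param correction passed to \code{\link{ng86Pair}}.
#' @return list with \code{pairs} (per-pair data.frame with seq_a/seq_b
#'   indices) and \code{summary} (one-row data.frame: n_pairs, mean_dN,
#'   mean_dS, mean_ratio, n_undefined; mean_ratio is NA when every pair is
#'   undefined).
#' @export
geneAverageRatio <- function(alignment, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  if (methods::is(alignment, "DNAStringSet"))
    alignment <- as.character(alignment)
  k <- length(alignment)
  if (k < 2L) stop("need at least 2 sequences")
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- ng86Pair(alignment[[i]], alignment[[j]], correction)
    r <- cbind(data.frame(seq_a = i, seq_b = j), r)
    rows[[length(rows) + 1L]] <- r
  }
  pairs <- do.call(rbind, rows)
  def <- !pairs$undefined
  summary <- data.frame(
    n_pairs = nrow(pairs),
    mean_dN = mean(pairs$dN[!is.na(pairs$dN)]),
    mean_dS = mean(pairs$dS[!is.na(pairs$dS)]),
    mean_ratio = if (any(def)) mean(pairs$ratio[def]) else NA_real_,
    n_undefined = sum(!def), stringsAsFactors = FALSE)
  list(pairs = pairs, summary = summary)
}
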