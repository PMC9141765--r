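# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive re-derivations kept separate from the package
# implementations they check.

# --- sliding-window fuzzy match -------------------------------------------
oracleWindowScan <- function(seq, motif, maxMismatch) {
  s <- strsplit(toupper(seq), "")[[1L]]
  m <- strsplit(motif, "")[[1L]]
  w <- length(m)
  out <- data.frame(start = integer(), mismatches = integer())
  if (length(s) < w) return(out)
  for (p in 0:(length(s) - w)) {
    mm <- sum(s[(p + 1):(p + w)] != m)
    if (mm <= maxMismatch)
      out <- rbind(out, data.frame(start = p, mismatches = mm))
  }
  out
}

# --- interval intersections ------------------------------------------------
oracleIntersections <- function(starts, ends) {
  out <- list()
  n <- length(starts)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- max(starts[i], starts[j]); e <- min(ends[i], ends[j])
    if (e > s) out[[length(out) + 1L]] <- c(i, j, e - s)
  }
  if (!length(out)) return(matrix(numeric(), ncol = 3))
  do.call(rbind, out)
}

# --- tandem repeats --------------------------------------------------------
# Exhaustive re-derivation of the declared hit semantics: per period,
# enumerate all intervals with self-match identity >= theta, keep the
# containment-maximal ones, take the max-scoring core of each by direct
# enumeration of subintervals, then apply the same declared filters and the
# cross-period pruning rule.
oracleTandemRepeats <- function(seq, minPeriod = 1L, maxPeriod = 200L,
                                minCopies = 2, minArrayLength = 20L,
                                minIdentity = 0.8) {
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  maxPeriod <- min(maxPeriod, n %/% 2L)
  den <- 10000; num <- round(minIdentity * den)
  cands <- list()
  for (p in seq(minPeriod, length.out = max(0L, maxPeriod - minPeriod + 1L))) {
    m <- as.integer(s[seq_len(n - p)] == s[(p + 1L):n])
    nm <- length(m)
    # all intervals with identity >= theta
    ok <- matrix(FALSE, nm, nm)
    for (a in seq_len(nm)) {
      run <- 0L
      for (b in a:nm) {
        run <- run + m[b]
        ok[a, b] <- (den * run - num * (b - a + 1L)) >= 0
      }
    }
    iv <- which(ok, arr.ind = TRUE)
    if (!nrow(iv)) next
    # containment-maximal
    keep <- vapply(seq_len(nrow(iv)), function(k) {
      a <- iv[k, 1L]; b <- iv[k, 2L]
      !any(iv[, 1L] <= a & iv[, 2L] >= b &
             (iv[, 1L] < a | iv[, 2L] > b))
    }, logical(1))
    iv <- iv[keep, , drop = FALSE]
    for (k in seq_len(nrow(iv))) {
      a <- iv[k, 1L]; b <- iv[k, 2L]
      # max-scoring core by enumeration; ties: shortest, then leftmost
      bestScore <- -Inf; bestA <- NA; bestB <- NA
      for (a2 in a:b) for (b2 in a2:b) {
        sc <- den * sum(m[a2:b2]) - num * (b2 - a2 + 1L)
        better <- sc > bestScore ||
          (sc == bestScore &&
             ((b2 - a2) < (bestB - bestA) ||
                ((b2 - a2) == (bestB - bestA) && a2 < bestA)))
        if (better) { bestScore <- sc; bestA <- a2; bestB <- b2 }
      }
      if (bestScore <= 0) next
      st <- bestA; en <- bestB + p
      L <- en - st + 1L
      if (L < minArrayLength || L / p < minCopies) next
      chars <- s[st:en]
      cons <- character(p)
      for (col in seq_len(p)) {
        idx <- seq(col, L, by = p)
        tab <- table(factor(chars[idx], levels = c("A", "C", "G", "T", "N")))
        cons[col] <- names(tab)[which.max(tab)]
      }
      nMatch <- sum(chars == cons[((seq_len(L) - 1L) %% p) + 1L])
      if (nMatch * den < num * L) next
      cands[[length(cands) + 1L]] <- data.frame(
        start = st - 1L, end = en, period = p, copy_number = L / p,
        consensus = paste(cons, collapse = ""), mean_identity = nMatch / L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cands))
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), copy_number = numeric(),
                      consensus = character(), mean_identity = numeric(),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, cands)
  hits <- hits[!duplicated(hits[c("start", "end", "period")]), , drop = FALSE]
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

# --- NG86 ------------------------------------------------------------------
# Pathway oracle: recursive depth-first enumeration of substitution orders
# between two codons under the vertebrate mitochondrial code, dropping
# orders that pass through a stop codon (all orders used if none survive).
oracleCodonPaths <- function(codA, codB) {
  code <- Biostrings::getGeneticCode("2")
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, blocked)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codB, pos, pos)
      syn <- code[[nxt]] == code[[cur]]
      recurse(nxt, setdiff(remaining, pos),
              sd + as.integer(syn), nd + as.integer(!syn),
              blocked || code[[nxt]] == "*")
    }
  }
  diffPos <- which(strsplit(codA, "")[[1L]] != strsplit(codB, "")[[1L]])
  if (!length(diffPos)) return(c(sd = 0, nd = 0))
  recurse(codA, diffPos, 0L, 0L, FALSE)
  pm <- do.call(rbind, paths)
  use <- pm[pm[, 3L] == 0, , drop = FALSE]
  if (!nrow(use)) use <- pm
  c(sd = mean(use[, 1L]), nd = mean(use[, 2L]))
}

oracleSynSitesOfCodon <- function(codon) {
  code <- Biostrings::getGeneticCode("2")
  ch <- strsplit(codon, "")[[1L]]
  syn <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
    alt <- ch; alt[pos] <- b
    altc <- paste(alt, collapse = "")
    if (code[[altc]] != "*" && code[[altc]] == code[[codon]])
      syn <- syn + 1 / 3
  }
  syn
}

# --- composition / codon usage --------------------------------------------
oracleSkews <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  a <- sum(ch == "A"); t <- sum(ch == "T")
  g <- sum(ch == "G"); c_ <- sum(ch == "C")
  c(at = (a - t) / (a + t), gc = (g - c_) / (g + c_))
}

oracleCodonTally <- function(cdsList) {
  tally <- integer()
  for (s in cdsList) {
    s <- toupper(s)
    n <- nchar(s) - nchar(s) %% 3L
    for (i in seq(1L, n - 2L, 3L)) {
      cod <- substr(s, i, i + 2L)
      if (grepl("^[ACGT]{3}$", cod))
        tally[cod] <- (if (is.na(tally[cod])) 0L else tally[cod]) + 1L
    }
  }
  tally
}

randomDNAString <- function(n, seed = NULL, at = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}
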