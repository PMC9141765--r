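# Seeded generators: control regions, whole mitogenomes, codon alignments.
# One integer seed drives a single pseudo-random stream per artifact; the
# stream is consumed in a fixed order (spacers 5'->3', then per-gene codons)
# so outputs are reproducible byte-for-byte for a given spec + seed.

#' Shipped control-region presets
#'
#' Parameterised CR layouts emulating the genus-typical architectures:
#' \describe{
#'   \item{eremias_typical}{all five elements, repeat before TAS1 and after
#'     CSB3 (unit TAGCGGCTTTTTTG), CSB2-CSB3 gap 35 nt.}
#'   \item{darevskia_typical}{all five elements, repeat between CSB1 and
#'     CSB2 (unit CAAAACTTTTAA), CSB2-CSB3 gap 35 nt.}
#'   \item{takydromus_typical}{all five elements, repeat before TAS1 (unit
#'     GCGGCTT) and one between TAS2 and CSB1 (unit TTTTCC).}
#'   \item{minimal_V}{only CSB2 and CSB3, no repeats (a degenerate short
#'     CR).}
#' }
#'
#' @param name preset name.
#' @return a CR spec list (fields: name, at_percent, elements,
#'   spacers, trs, flanks, tr_gap).
#' @export
crPreset <- function(name = c("eremias_typical", "darevskia_typical",
                              "takydromus_typical", "minimal_V")) {
  name <- match.arg(name)
  base <- list(name = name, at_percent = 65,
               spacers = c(TAS1_TAS2 = 70, TAS2_CSB1 = 120, CSB1_CSB2 = 90,
                           CSB2_CSB3 = 35),
               flanks = c(lead = 80, trail = 70), tr_gap = 40)
  allDots <- function(el) strrep(".", nchar(referenceMotifs()[[el]]))
  switch(name,
    eremias_typical = {
      base$elements <- list(
        TAS1 = ".................A......",   # Eremias-type TAS1 variant
        TAS2 = "A........T",                 # Eremias-type TAS2 variant
        CSB1 = "....T........C.TCA....................",
        CSB2 = allDots("CSB2"), CSB3 = allDots("CSB3"))
      base$trs <- list(
        list(class = "before_TAS1", unit = "TAGCGGCTTTTTTG", copies = 3L,
             error_rate = 0),
        list(class = "after_CSB3", unit = "TAGCGGCTTTTTTG", copies = 3L,
             error_rate = 0))
      base
    },
    darevskia_typical = {
      base$elements <- list(
        TAS1 = allDots("TAS1"),
        TAS2 = "T..G......",                 # Darevskia-type TAS2 variant
        CSB1 = "...............C.T....................",
        CSB2 = allDots("CSB2"), CSB3 = allDots("CSB3"))
      base$trs <- list(
        list(class = "between_CSB1_CSB2", unit = "CAAAACTTTTAA",
             copies = 4L, error_rate = 0))
      base
    },
    takydromus_typical = {
      base$elements <- list(
        TAS1 = allDots("TAS1"), TAS2 = "....T.....",
        CSB1 = allDots("CSB1"), CSB2 = allDots("CSB2"),
        CSB3 = allDots("CSB3"))
      base$trs <- list(
        list(class = "before_TAS1", unit = "GCGGCTT", copies = 4L,
             error_rate = 0),
        list(class = "between_TAS2_CSB1", unit = "TTTTCC", copies = 5L,
             error_rate = 0))
      base
    },
    minimal_V = {
      base$elements <- list(CSB2 = allDots("CSB2"), CSB3 = allDots("CSB3"))
      base$trs <- list()
      base$flanks <- c(lead = 40, trail = 30)
      base
    })
}

.trArraySeq <- function(unit, copies, errorRate) {
  arr <- strsplit(strrep(unit, copies), "")[[1L]]
  if (errorRate > 0) {
    for (i in seq_along(arr)) {
      if (stats::runif(1) < errorRate)
        arr[i] <- sample(setdiff(c("A", "C", "G", "T"), arr[i]), 1L)
    }
  }
  paste(arr, collapse = "")
}

# One assembly attempt; consumes the current RNG stream.
.assembleCR <- function(spec) {
  refs <- referenceMotifs()
  canon <- names(refs)
  els <- spec$elements
  order <- if (!is.null(spec$element_order)) spec$element_order
           else canon[canon %in% names(els)]
  segs <- character()
  truthEl <- list(); truthTr <- list()
  pos <- 0L
  add <- function(seqstr) {
    segs[[length(segs) + 1L]] <<- seqstr
    pos <<- pos + nchar(seqstr)
  }
  addTr <- function(tr) {
    arr <- .trArraySeq(tr$unit, tr$copies, tr$error_rate)
    truthTr[[length(truthTr) + 1L]] <<- data.frame(
      start = pos, end = pos + nchar(arr), period = nchar(tr$unit),
      copies = tr$copies, unit = tr$unit, position_class = tr$class,
      stringsAsFactors = FALSE)
    add(arr)
  }
  trsBy <- function(cls) Filter(function(t) t$class == cls, spec$trs)

  add(.randomDNA(spec$flanks[["lead"]], spec$at_percent))
  for (tr in trsBy("before_TAS1")) {
    addTr(tr)
    add(.randomDNA(spec$tr_gap, spec$at_percent))
  }
  for (i in seq_along(order)) {
    el <- order[i]
    motif <- expandDots(els[[el]], refs[[el]])
    truthEl[[length(truthEl) + 1L]] <- data.frame(
      element = el, start = pos, end = pos + nchar(motif),
      motif = motif, dot_pattern = chartr("·", ".", els[[el]]),
      stringsAsFactors = FALSE)
    add(motif)
    if (i < length(order)) {
      pair <- paste0(el, "_", order[i + 1L])
      gap <- if (pair %in% names(spec$spacers)) spec$spacers[[pair]] else 80
      between <- trsBy(paste0("between_", pair))
      if (length(between)) {
        left <- gap %/% 2L
        add(.randomDNA(left, spec$at_percent))
        for (tr in between) addTr(tr)
        add(.randomDNA(gap - left, spec$at_percent))
      } else {
        add(.randomDNA(gap, spec$at_percent))
      }
    }
  }
  for (tr in trsBy("after_CSB3")) {
    add(.randomDNA(spec$tr_gap, spec$at_percent))
    addTr(tr)
  }
  add(.randomDNA(spec$flanks[["trail"]], spec$at_percent))
  list(seq = paste(segs, collapse = ""),
       elements = if (length(truthEl)) do.call(rbind, truthEl)
                  else data.frame(),
       trs = if (length(truthTr)) do.call(rbind, truthTr)
             else .emptyTrHits()[0, c("start", "end", "period")])
}

# Does the annotation pipeline recover exactly the ground truth?
.crAnnotatesCleanly <- function(built) {
  found <- annotateElements(built$seq, restrictDownstream = FALSE)
  truth <- built$elements
  if (nrow(found) != nrow(truth)) return(FALSE)
  if (nrow(truth)) {
    truth <- truth[order(truth$start), ]
    found <- found[order(found$start), ]
    if (!identical(found$element, truth$element)) return(FALSE)
    if (!identical(found$start, truth$start)) return(FALSE)
    if (!identical(found$matched_sequence, truth$motif)) return(FALSE)
  }
  hits <- findTandemRepeats(built$seq)
  tt <- built$trs
  if (nrow(hits) != nrow(tt)) return(FALSE)
  if (nrow(tt)) {
    tt <- tt[order(tt$start), ]
    if (!identical(hits$start, tt$start)) return(FALSE)
    if (!identical(hits$end, tt$end)) return(FALSE)
    if (!identical(hits$period, tt$period)) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic control region with ground truth
#'
#' Assembles a CR from a preset or custom spec: background spacers at the
#' requested AT content, conserved elements expanded from their dot
#' patterns, and tandem-repeat arrays at the requested position classes.
#' Spacer randomness is redrawn (deterministically within the seeded
#' stream) until the annotation pipeline recovers exactly the embedded
#' elements and repeats, so the returned ground truth is guaranteed
#' machine-checkable.
#'
#' @param spec a CR spec list (\code{\link{crPreset}} output, possibly
#'   modified) or a preset name.
#' @param seed integer seed.
#' @param maxTries resampling attempts before giving up.
#' @return list with \code{seq} (character), \code{elements} and \code{trs}
#'   ground-truth data.frames (0-based half-open CR coordinates), and
#'   \code{spec}.
#' @export
generateCR <- function(spec = "eremias_typical", seed = 1L, maxTries = 40L) {
  if (is.character(spec)) spec <- crPreset(spec)
  .validateCRSpec(spec)
  .withSeed(seed, {
    for (i in seq_len(maxTries)) {
      built <- .assembleCR(spec)
      if (.crAnnotatesCleanly(built)) {
        built$spec <- spec
        return(built)
      }
    }
    stop("could not assemble a cleanly-annotating CR for spec '",
         spec$name, "' in ", maxTries, " attempts")
  })
}

#' Build a CR spec realising a typing rule
#'
#' For a row of the typing rule table, constructs a generator spec whose
#' output should annotate and classify back to that rule's subtype: required
#' elements are embedded as exact reference motifs (in canonical order, or
#' with the first two swapped when the rule requires an order violation),
#' and the rule's anormal/normal repeat classes are populated with
#' genus-typical units.
#'
#' @param rule one row of \code{\link{readTypeRules}} output, or a subtype
#'   label resolved against the default table.
#' @return a CR spec list for \code{\link{generateCR}}.
#' @export
crSpecForRule <- function(rule) {
  if (is.character(rule)) {
    rules <- defaultTypeRules()
    rule <- rules[rules$subtype == rule, , drop = FALSE]
    if (!nrow(rule)) stop("unknown subtype label")
  }
  stopifnot(nrow(rule) == 1L)
  refs <- referenceMotifs()
  canon <- names(refs)
  flags <- c(TAS1 = rule$tas1, TAS2 = rule$tas2, CSB1 = rule$csb1,
             CSB2 = rule$csb2, CSB3 = rule$csb3)
  present <- canon[flags[canon] %in% c("1", "*")]
  elements <- lapply(present, function(el) strrep(".", nchar(refs[[el]])))
  names(elements) <- present
  order <- present
  if (identical(rule$order_ok, "0") && length(present) >= 2L)
    order <- c(present[2L], present[1L], present[-(1:2)])
  parseSet <- function(x) {
    if (x %in% c("-", "*") || !nzchar(x)) character()
    else strsplit(x, ";", fixed = TRUE)[[1L]]
  }
  trs <- list()
  for (cls in parseSet(rule$anormal))
    trs[[length(trs) + 1L]] <- list(class = cls, unit = "CAAAACTTTTAA",
                                    copies = 4L, error_rate = 0)
  for (cls in parseSet(rule$normal))
    trs[[length(trs) + 1L]] <- list(class = cls, unit = "TAGCGGCTTTTTTG",
                                    copies = 3L, error_rate = 0)
  list(name = paste0("rule_", rule$subtype), at_percent = 65,
       elements = elements, element_order = order,
       spacers = c(TAS1_TAS2 = 70, TAS2_CSB1 = 120, CSB1_CSB2 = 90,
                   CSB2_CSB3 = 35),
       flanks = c(lead = 80, trail = 70), tr_gap = 40, trs = trs)
}

.validateCRSpec <- function(spec) {
  refs <- referenceMotifs()
  if (!length(spec$elements) && !length(spec$trs))
    stop("CR spec is empty")
  bad <- setdiff(names(spec$elements), names(refs))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  for (el in names(spec$elements)) {
    if (nchar(spec$elements[[el]]) != nchar(refs[[el]]))
      stop("dot pattern for ", el, " has wrong length")
  }
  for (tr in spec$trs) {
    if (!tr$class %in% setdiff(trPositionClasses(), "unplaced"))
      stop("invalid TR position class: ", tr$class)
    if (tr$copies < 2L) stop("TR copies must be >= 2")
  }
  if (any(unlist(spec$spacers) < 0) || any(spec$flanks < 0))
    stop("negative spacer in CR spec (unrealizable)")
  invisible(TRUE)
}

.defaultGeneLengths <- function() {
  trn <- stats::setNames(rep(70L, 22L),
                         grep("^trn", canonicalGeneOrder(), value = TRUE))
  trn[c("trnS1", "trnC")] <- c(66L, 67L)
  c(trn, rrnS = 951L, rrnL = 1542L,
    ND1 = 957L, ND2 = 1035L, COI = 1551L, COII = 684L, ATP8 = 168L,
    ATP6 = 681L, COIII = 786L, ND3 = 345L, ND4L = 294L, ND4 = 1380L,
    ND5 = 1821L, ND6 = 516L, CYTB = 1140L, OL = 30L)
}

#' Default synthetic mitogenome spec
#'
#' Canonical 37-gene order, the four conserved gene overlaps (ATP8/ATP6
#' 10 nt via the ATGGNNNTAA motif, ND4L/ND4 7 nt, ND5/ND6 5 nt, ATP6/COIII
#' 1 nt), an O_L segment carrying the 26-nt motif, and an Eremias-typical
#' control region.
#'
#' @return spec list consumed by \code{\link{generateMitogenome}}.
#' @export
defaultMitogenomeSpec <- function() {
  cr <- crPreset("eremias_typical")
  # whole-genome emulation carries the long repeat arrays that drive CR
  # (and hence genome) size variation in racerunners
  cr$trs[[1L]]$copies <- 30L
  cr$trs[[2L]]$copies <- 30L
  list(record_id = "SYNMT1", taxon = "Syntheticus exemplaris",
       at_percent = 60, intergenic = 10L, cr_spacer = 0L,
       gene_lengths = .defaultGeneLengths(),
       overlaps = list(
         list(a = "ATP8", b = "ATP6", len = 10L, motif = "ATGGNNNTAA"),
         list(a = "ND4L", b = "ND4", len = 7L, motif = "ATGNTAA"),
         list(a = "ND5", b = "ND6", len = 5L, motif = "TTAGG"),
         list(a = "ATP6", b = "COIII", len = 1L, motif = "A")),
       ol_motif = "ol26",
       cr = cr)
}

.instantiateN <- function(motif) {
  ch <- strsplit(motif, "")[[1L]]
  ch[ch == "N"] <- sample(c("A", "C", "G", "T"), sum(ch == "N"),
                          replace = TRUE)
  paste(ch, collapse = "")
}

# Build one CDS of the given length with constraints; retries middle codons
# (and N instantiation in the forced suffix) until start/stop/no-internal-
# stop hold. prefix is immutable (already on the genome).
.makeCDS <- function(len, prefix = "", suffix = "", startCodon = "ATG",
                     stopCodon = "TAA", maxTries = 100L) {
  stopifnot(len %% 3L == 0L, nchar(prefix) + nchar(suffix) <= len)
  code <- .mitoCode()
  pool <- names(code)[code != "*"]
  starts <- c("ATG", "GTG")
  stops <- c("TAA", "TAG", "AGG", "AGA")
  for (i in seq_len(maxTries)) {
    mids <- sample(pool, len %/% 3L - 2L, replace = TRUE)
    ch <- strsplit(paste0(startCodon, paste(mids, collapse = ""), stopCodon),
                   "")[[1L]]
    if (nzchar(suffix)) {
      sfx <- strsplit(.instantiateN(suffix), "")[[1L]]
      ch[(len - length(sfx) + 1L):len] <- sfx
    }
    if (nzchar(prefix)) {
      pfx <- strsplit(prefix, "")[[1L]]
      ch[seq_along(pfx)] <- pfx
    }
    cds <- paste(ch, collapse = "")
    cods <- substring(cds, seq(1L, len - 2L, 3L), seq(3L, len, 3L))
    if (!cods[1L] %in% starts) next
    if (!cods[length(cods)] %in% stops) next
    if (any(code[cods[-length(cods)]] == "*")) next
    return(cds)
  }
  stop("could not satisfy CDS constraints (length ", len, ")")
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Lays the canonical 37 genes plus O_L and control region on a circular
#' H-strand sequence, instantiating the configured gene overlaps (wildcard
#' positions drawn at random unless pinned), embedding the O_L motif, and
#' generating the CR from its spec. H-strand protein-coding genes carry
#' valid start codons (ATG; GTG for COI), canonical stops, and no internal
#' stops; ND6 is laid as the reverse complement of a valid CDS on the light
#' strand.
#'
#' @param spec spec list from \code{\link{defaultMitogenomeSpec}} (possibly
#'   modified).
#' @param seed integer seed.
#' @return list with \code{record} (a \linkS4class{Mitogenome}) and
#'   \code{truth} (features, instantiated overlaps, ol hit, and the CR
#'   ground truth with its genome offset).
#' @export
generateMitogenome <- function(spec = defaultMitogenomeSpec(), seed = 1L) {
  .withSeed(seed, {
    lens <- spec$gene_lengths
    order <- setdiff(canonicalGeneOrder(), "CR")
    ovByB <- stats::setNames(spec$overlaps,
                             vapply(spec$overlaps, `[[`, "", "b"))
    ovByA <- stats::setNames(spec$overlaps,
                             vapply(spec$overlaps, `[[`, "", "a"))
    genome <- character()
    pos <- 0L
    feats <- list()
    ovTruth <- list()
    olTruth <- NULL
    seqNow <- function() paste(genome, collapse = "")
    spacerLen <- if (is.null(spec$intergenic)) 0L else spec$intergenic
    for (g in order) {
      len <- lens[[g]]
      ov <- 0L
      prefix <- ""
      if (g %in% names(ovByB)) {
        ov <- ovByB[[g]]$len
        prefix <- substr(seqNow(), pos - ov + 1L, pos)
      } else if (pos > 0L && spacerLen > 0L) {
        genome[[length(genome) + 1L]] <- .randomDNA(spacerLen,
                                                    spec$at_percent)
        pos <- pos + spacerLen
      }
      suffix <- ""
      if (g %in% names(ovByA)) suffix <- ovByA[[g]]$motif
      type <- .featureType(g)
      if (type == "PCG" && g != "ND6") {
        startCodon <- if (g == "COI") "GTG" else "ATG"
        seg <- .makeCDS(len, prefix = prefix, suffix = suffix,
                        startCodon = startCodon)
      } else if (g == "ND6") {
        # light strand: CDS runs 3'->5' on the H-strand reference
        cdsSuffix <- .revcompChar(prefix)    # constrains the CDS tail
        cds <- .makeCDS(len, prefix = "", suffix = cdsSuffix)
        seg <- .revcompChar(cds)
        if (nzchar(prefix) &&
            substr(seg, 1L, nchar(prefix)) != prefix)
          stop("internal error: ND6 overlap inconsistency")
      } else if (g == "OL") {
        motif <- .instantiateN(olMotifs()[[spec$ol_motif]])
        flank <- len - nchar(motif)
        lf <- flank %/% 2L
        seg <- paste0(.randomDNA(lf, spec$at_percent), motif,
                      .randomDNA(flank - lf, spec$at_percent))
        olTruth <- data.frame(start = pos - ov + lf, motif = motif,
                              pattern = spec$ol_motif,
                              stringsAsFactors = FALSE)
      } else {
        seg <- .randomDNA(len, spec$at_percent)
        if (nzchar(prefix)) seg <- paste0(prefix, substr(seg, ov + 1L, len))
      }
      start <- pos - ov
      genome[[length(genome) + 1L]] <- substr(seg, ov + 1L, len)
      pos <- start + len
      feats[[length(feats) + 1L]] <- data.frame(
        name = g, strand = if (g %in% lightStrandGenes()) "L" else "H",
        start = start, end = start + len, wraps_origin = FALSE,
        stringsAsFactors = FALSE)
      if (g %in% names(ovByB))
        ovTruth[[length(ovTruth) + 1L]] <- data.frame(
          gene_a = ovByB[[g]]$a, gene_b = g, overlap_length = ov,
          overlap_sequence = prefix, motif = ovByB[[g]]$motif,
          stringsAsFactors = FALSE)
    }
    cr <- {
      for (i in seq_len(40L)) {
        built <- .assembleCR(spec$cr)
        if (.crAnnotatesCleanly(built)) break
        built <- NULL
      }
      if (is.null(built))
        stop("could not assemble a cleanly-annotating CR")
      built
    }
    crStart <- pos
    genome[[length(genome) + 1L]] <- cr$seq
    pos <- pos + nchar(cr$seq)
    feats[[length(feats) + 1L]] <- data.frame(
      name = "CR", strand = "H", start = crStart, end = pos,
      wraps_origin = FALSE, stringsAsFactors = FALSE)
    ft <- .completeFeatures(do.call(rbind, feats))
    rec <- Mitogenome(spec$record_id, seqNow(), ft, circular = TRUE,
                      taxon = spec$taxon)
    list(record = rec,
         truth = list(features = ft,
                      overlaps = do.call(rbind, ovTruth),
                      ol = olTruth,
                      cr = c(cr[c("seq", "elements", "trs")],
                             list(offset = crStart))))
  })
}

#' Simulate a star-tree codon alignment with known substitution classes
#'
#' Draws a random stop-free ancestral coding sequence under the vertebrate
#' mitochondrial code and, independently per taxon, proposes one random
#' single-base change per site, accepting synonymous proposals with
#' probability \code{synRate} and nonsynonymous ones with probability
#' \code{nonsynRate} (proposals creating stop codons are rejected). With
#' \code{nonsynRate = 0} every difference from the ancestor is synonymous,
#' and vice versa.
#'
#' @param nTaxa number of tip sequences (>= 2).
#' @param nCodons codons per sequence.
#' @param synRate,nonsynRate per-site acceptance probabilities in [0, 1].
#' @param seed integer seed.
#' @return list with \code{alignment} (\code{DNAStringSet}),
#'   \code{ancestral} (character), and \code{truth} (per-taxon counts of
#'   applied synonymous/nonsynonymous changes).
#' @export
simulateCodonAlignment <- function(nTaxa, nCodons, synRate, nonsynRate,
                                   seed = 1L) {
  stopifnot(nTaxa >= 2L, nCodons >= 1L, synRate >= 0, nonsynRate >= 0,
            synRate <= 1, nonsynRate <= 1)
  code <- .mitoCode()
  pool <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  .withSeed(seed, {
    anc <- sample(pool, nCodons, replace = TRUE)
    seqs <- character(nTaxa)
    truth <- list()
    for (t in seq_len(nTaxa)) {
      cods <- anc
      nSyn <- 0L; nNon <- 0L
      for (ci in seq_len(nCodons)) {
        ch <- strsplit(cods[ci], "")[[1L]]
        for (p in 1:3) {
          b <- sample(setdiff(bases, ch[p]), 1L)
          alt <- ch; alt[p] <- b
          altC <- paste(alt, collapse = "")
          if (code[[altC]] == "*") next
          syn <- code[[altC]] == code[[paste(ch, collapse = "")]]
          rate <- if (syn) synRate else nonsynRate
          if (stats::runif(1) < rate) {
            ch <- alt
            if (syn) nSyn <- nSyn + 1L else nNon <- nNon + 1L
          }
        }
        cods[ci] <- paste(ch, collapse = "")
      }
      seqs[t] <- paste(cods, collapse = "")
      truth[[t]] <- data.frame(taxon = paste0("taxon", t),
                               syn_changes = nSyn, nonsyn_changes = nNon,
                               stringsAsFactors = FALSE)
    }
    list(alignment = Biostrings::DNAStringSet(
           stats::setNames(seqs, paste0("taxon", seq_len(nTaxa)))),
         ancestral = paste(anc, collapse = ""),
         truth = do.call(rbind, truth))
  })
}
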