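# Conserved control-region elements: fuzzy search against the L. dugesii
# reference motifs, dot-notation rendering, variant tables, type assignment.

#' Reference motifs for the conserved control-region elements
#'
#' The L. dugesii reference strings for TAS1, TAS2, CSB1, CSB2 and CSB3
#' against which all variants are rendered and typed.
#'
#' @return named character vector of five motifs.
#' @export
referenceMotifs <- function() {
  c(TAS1 = "ACTATTATGTATATAGTGCATTAA",
    TAS2 = "CATACATTAA",
    CSB1 = "CTATATGGTATTATTGTCTTAATGCTTGGTAGACATAT",
    CSB2 = "CAAACCCCCCTACCCCCC",
    CSB3 = "TCGCCAAACCCCTAAAACGA")
}

#' Alternative TAS2 anchors
#'
#' The classic L. dugesii TAS2 plus the proposed updated anchors. The
#' family-level update is printed in two non-identical forms in the source
#' literature; both are shipped verbatim and neither is silently corrected.
#' \code{fuzzyFind} searches TAS2 with the classic and the
#' \code{tas2_updated} anchor; mismatches are always reported against the
#' classic string, matching the variant tables.
#'
#' @return named character vector of anchors.
#' @export
tas2Anchors <- function() {
  c(tas2_classic = "CATACATTAA",
    tas2_updated = "TATGCATTAA",
    tas2_updated_abstract = "TATACATTAT")
}

#' Default mismatch budgets per element
#'
#' Per-element maximum mismatch counts for \code{\link{fuzzyFind}}: a quarter
#' of the motif length, rounded down (TAS1 6, TAS2 2, CSB1 9, CSB2 4,
#' CSB3 5). These cover every tabulated variant except the most divergent
#' CSB3 row (8 mismatches), which needs an explicit override and is otherwise
#' reported as absent/novel.
#'
#' @return named integer vector.
#' @export
defaultMaxMismatches <- function() {
  c(TAS1 = 6L, TAS2 = 2L, CSB1 = 9L, CSB2 = 4L, CSB3 = 5L)
}

.mismatchInfo <- function(window, reference) {
  w <- strsplit(window, "")[[1L]]
  r <- strsplit(reference, "")[[1L]]
  pos <- which(w != r)  # 1-based within the motif
  list(count = length(pos), positions = pos, ref = r[pos], obs = w[pos])
}

.fmtMismatches <- function(info) {
  if (!info$count) return("")
  paste(sprintf("%d%s>%s", info$positions, info$ref, info$obs),
        collapse = ";")
}

#' Fuzzy search for a conserved element
#'
#' Finds all substitution-only alignments of an element's reference motif in
#' a control-region sequence with at most \code{maxMismatches} mismatches
#' (no indels: every tabulated variant is length-preserving). Hits are
#' sorted by (mismatch count, start); ties go to the 5'-most window. TAS2 is
#' additionally searched with the updated anchor, but mismatches are always
#' counted against the classic reference.
#'
#' @param crSeq control-region sequence (character, \code{DNAString}, or
#'   \linkS4class{ControlRegion}).
#' @param element one of TAS1, TAS2, CSB1, CSB2, CSB3.
#' @param maxMismatches non-negative integer; default per
#'   \code{\link{defaultMaxMismatches}}.
#' @param from 0-based position from which to search (used to restrict an
#'   element search downstream of the previous element).
#' @return data.frame with columns element, start, end (0-based half-open in
#'   the CR), matched_sequence, mismatch_count, mismatch_positions
#'   (";"-separated \code{POSref>obs}, 1-based in the motif), dot_pattern,
#'   best (logical; fewest mismatches, 5'-most). Zero rows if nothing
#'   qualifies.
#' @export
fuzzyFind <- function(crSeq, element, maxMismatches = NULL, from = 0L) {
  element <- match.arg(element, names(referenceMotifs()))
  if (methods::is(crSeq, "ControlRegion")) crSeq <- crSeq(crSeq)
  s <- .asChar(crSeq)
  ref <- referenceMotifs()[[element]]
  if (is.null(maxMismatches)) maxMismatches <- defaultMaxMismatches()[[element]]
  stopifnot(maxMismatches >= 0)
  anchors <- ref
  if (element == "TAS2") anchors <- unique(c(ref, tas2Anchors()[["tas2_updated"]]))
  w <- nchar(ref)
  starts <- integer()
  sub <- Biostrings::DNAString(s)
  for (anchor in anchors) {
    hits <- Biostrings::matchPattern(anchor, sub,
                                     max.mismatch = maxMismatches,
                                     with.indels = FALSE)
    starts <- union(starts, BiocGenerics::start(hits) - 1L)
  }
  # matchPattern with mismatches admits windows hanging off the subject
  # edges; only fully contained windows are substitution-only alignments
  starts <- sort(starts[starts >= max(0L, from) & starts <= nchar(s) - w])
  if (!length(starts))
    return(.emptyElementHits())
  rows <- lapply(starts, function(p) {
    win <- substr(s, p + 1L, p + w)
    info <- .mismatchInfo(win, ref)
    data.frame(element = element, start = p, end = p + w,
               matched_sequence = win, mismatch_count = info$count,
               mismatch_positions = .fmtMismatches(info),
               dot_pattern = renderDots(win, ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mismatch_count, out$start), , drop = FALSE]
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}

.emptyElementHits <- function() {
  data.frame(element = character(), start = integer(), end = integer(),
             matched_sequence = character(), mismatch_count = integer(),
             mismatch_positions = character(), dot_pattern = character(),
             best = logical(), stringsAsFactors = FALSE)
}

#' Annotate all five conserved elements in a control region
#'
#' Searches TAS1, TAS2, CSB1, CSB2, CSB3 in order. By default each search is
#' restricted downstream of the previous best hit, enforcing the canonical
#' layout; disable to detect displaced (out-of-order) elements.
#'
#' When the downstream restriction is off, candidate hits of the five
#' elements are pooled and accepted greedily by (mismatch count, canonical
#' element order, start), skipping candidates that overlap an accepted hit
#' of another element; this prevents one element's motif from being called
#' inside another's (the TAS2 anchors share a suffix with TAS1).
#'
#' @inheritParams fuzzyFind
#' @param maxMismatches named integer vector of per-element budgets
#'   (defaults from \code{\link{defaultMaxMismatches}}).
#' @param restrictDownstream logical.
#' @return data.frame of accepted hits (at most one row per element).
#' @export
annotateElements <- function(crSeq, maxMismatches = defaultMaxMismatches(),
                             restrictDownstream = TRUE) {
  if (methods::is(crSeq, "ControlRegion")) crSeq <- crSeq(crSeq)
  budgets <- defaultMaxMismatches()
  budgets[names(maxMismatches)] <- maxMismatches
  canon <- names(referenceMotifs())
  if (restrictDownstream) {
    out <- .emptyElementHits()
    from <- 0L
    for (el in canon) {
      hits <- fuzzyFind(crSeq, el, budgets[[el]], from = from)
      if (nrow(hits)) {
        best <- hits[hits$best, , drop = FALSE]
        out <- rbind(out, best)
        from <- best$end[1L]
      }
    }
    rownames(out) <- NULL
    return(out)
  }
  pool <- do.call(rbind, lapply(canon, function(el)
    fuzzyFind(crSeq, el, budgets[[el]])))
  if (is.null(pool) || !nrow(pool)) return(.emptyElementHits())
  pool <- pool[order(pool$mismatch_count, match(pool$element, canon),
                     pool$start), , drop = FALSE]
  accepted <- .emptyElementHits()
  for (i in seq_len(nrow(pool))) {
    h <- pool[i, , drop = FALSE]
    if (h$element %in% accepted$element) next
    if (nrow(accepted) &&
        any(accepted$start < h$end & accepted$end > h$start)) next
    h$best <- TRUE
    accepted <- rbind(accepted, h)
  }
  accepted <- accepted[order(accepted$start), , drop = FALSE]
  rownames(accepted) <- NULL
  accepted
}

#' Render a variant in dot notation
#'
#' Positions equal to the reference are shown as "." (the tables' middle
#' dot, rendered in ASCII); substituted positions show the observed base.
#'
#' @param observed,reference equal-length DNA strings.
#' @return dot-notation string.
#' @export
renderDots <- function(observed, reference) {
  o <- strsplit(.asChar(observed), "")[[1L]]
  r <- strsplit(.asChar(reference), "")[[1L]]
  if (length(o) != length(r))
    stop("observed and reference differ in length (", length(o), " vs ",
         length(r), ")")
  paste(ifelse(o == r, ".", o), collapse = "")
}

#' Expand dot notation back to a full motif
#'
#' Inverse of \code{\link{renderDots}}; accepts ASCII "." or the typographic
#' middle dot.
#'
#' @param dots dot-notation string.
#' @param reference reference motif of the same length.
#' @return expanded DNA string.
#' @export
expandDots <- function(dots, reference) {
  d <- strsplit(chartr("·", ".", dots), "")[[1L]]
  r <- strsplit(.asChar(reference), "")[[1L]]
  if (length(d) != length(r))
    stop("dot pattern and reference differ in length (", length(d), " vs ",
         length(r), ")")
  paste(ifelse(d == ".", r, d), collapse = "")
}

#' Parse a variant table fixture
#'
#' Reads a per-element variant table (TSV with header comments
#' \code{# element:} and \code{# reference:}; columns type_id, n_species,
#' dot_pattern, species). Dot patterns are expanded against the reference
#' and validated for width.
#'
#' @param path fixture path, or an element name (TAS1..CSB3) to load the
#'   shipped table.
#' @return list with fields \code{element}, \code{reference}, and
#'   \code{rows} (data.frame: type_id, n_species, dot_pattern, motif,
#'   species).
#' @export
parseVariantTable <- function(path) {
  if (toupper(path) %in% names(referenceMotifs()))
    path <- .extdata("variant_tables", paste0(tolower(path), ".tsv"))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  element <- trimws(sub("^#\\s*element:\\s*", "",
                        grep("element:", hdr, value = TRUE)[1L]))
  reference <- trimws(sub("^#\\s*reference:\\s*", "",
                          grep("reference:", hdr, value = TRUE)[1L]))
  if (!nzchar(element) || !nzchar(reference))
    stop("variant table ", path, " lacks '# element:'/'# reference:' headers")
  tab <- .tsvRead(path, colClasses = c("integer", "integer", "character",
                                       "character"))
  bad <- nchar(tab$dot_pattern) != nchar(reference)
  if (any(bad))
    stop("variant table ", path, ": row(s) ",
         paste(tab$type_id[bad], collapse = ", "),
         " have a dot pattern whose width differs from the reference")
  refCh <- strsplit(reference, "")[[1L]]
  degen <- vapply(tab$dot_pattern, function(d) {
    ch <- strsplit(chartr("·", ".", d), "")[[1L]]
    any(ch != "." & ch == refCh)
  }, logical(1))
  if (any(degen))
    warning("variant table ", path, ": type(s) ",
            paste(tab$type_id[degen], collapse = ", "),
            " print letters equal to the reference base (inconsistent dot ",
            "notation)", call. = FALSE)
  tab$motif <- vapply(tab$dot_pattern, expandDots, "", reference = reference,
                      USE.NAMES = FALSE)
  nList <- lengths(strsplit(tab$species, ";", fixed = TRUE))
  if (any(nList != tab$n_species))
    warning("variant table ", path, ": species-list length disagrees with ",
            "n_species for type(s) ",
            paste(tab$type_id[nList != tab$n_species], collapse = ", "),
            call. = FALSE)
  list(element = element, reference = reference,
       rows = tab[c("type_id", "n_species", "dot_pattern", "motif",
                    "species")])
}

#' Assign a variant type from a variant table
#'
#' Exact string match of an observed motif against the expanded table rows;
#' motifs matching no row are "novel".
#'
#' @param hit an element hit row from \code{\link{fuzzyFind}}, or a plain
#'   motif string.
#' @param table a parsed variant table from \code{\link{parseVariantTable}}.
#' @return type id (integer as character) or "novel".
#' @export
assignVariantType <- function(hit, table) {
  motif <- if (is.data.frame(hit)) {
    if (nrow(hit) != 1L) stop("pass a single hit row")
    if (!identical(hit$element, table$element))
      stop("hit element '", hit$element, "' does not match table element '",
           table$element, "'")
    hit$matched_sequence
  } else .asChar(hit)
  i <- match(motif, table$rows$motif)
  if (is.na(i)) "novel" else as.character(table$rows$type_id[i])
}

#' Count taxa in a variant table by motif predicate
#'
#' Sums the per-row species counts over rows whose expanded motif satisfies
#' a predicate (e.g. "equals the reference", "first base is T").
#'
#' @param table parsed variant table.
#' @param predicate function of the expanded motif returning logical.
#' @return integer count of taxa.
#' @export
tabulateVariantCounts <- function(table, predicate) {
  rows <- table$rows
  if (!nrow(rows)) return(0L)
  sel <- vapply(rows$motif, function(m) isTRUE(predicate(m)), logical(1))
  sum(rows$n_species[sel])
}
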