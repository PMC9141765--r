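# Control-region typing: profile construction and rule-table classification
# into the five general types and 21 subtypes.

#' Build a control-region profile from element and repeat annotations
#'
#' Summarises a CR into the fields the typing rules consume: per-element
#' presence flags, whether the found elements appear in canonical order,
#' and which anormal (between-element) and normal (before TAS1 / after CSB3)
#' tandem-repeat position classes are occupied. Duplicate hits for an
#' element keep the one with fewest mismatches (then 5'-most), with a
#' warning.
#'
#' @param elements element hits (\code{\link{annotateElements}} output, or
#'   any \code{\link{fuzzyFind}} rows).
#' @param trs tandem-repeat hits (\code{\link{findTandemRepeats}} output).
#' @param crLength CR length in nt.
#' @param recordId record identifier carried through to the profile.
#' @return one-row data.frame: record_id, tas1, tas2, csb1, csb2, csb3
#'   (logical presence), element_order_ok, anormal (";"-set), normal
#'   (";"-set), cr_length.
#' @export
buildProfile <- function(elements, trs = NULL, crLength = NA_integer_,
                         recordId = "") {
  canon <- names(referenceMotifs())
  el <- elements
  if (is.null(el)) el <- .emptyElementHits()
  if (nrow(el) && anyDuplicated(el$element)) {
    warning("duplicate element hits; keeping best (fewest mismatches) per ",
            "element", call. = FALSE)
    el <- el[order(el$mismatch_count, el$start), , drop = FALSE]
    el <- el[!duplicated(el$element), , drop = FALSE]
  }
  presence <- canon %in% el$element
  names(presence) <- canon
  ordered <- el[order(el$start), , drop = FALSE]
  orderOk <- !is.unsorted(match(ordered$element, canon), strictly = TRUE)
  anormal <- character(); normal <- character()
  if (!is.null(trs) && nrow(trs)) {
    for (i in seq_len(nrow(trs))) {
      cls <- classifyTrPosition(trs$start[i], trs$end[i], el)
      if (cls$normality == "anormal") anormal <- c(anormal, cls$position_class)
      if (cls$normality == "normal") normal <- c(normal, cls$position_class)
    }
  }
  fmtSet <- function(x) if (length(x)) paste(sort(unique(x)), collapse = ";")
                        else "-"
  data.frame(record_id = recordId,
             tas1 = presence[["TAS1"]], tas2 = presence[["TAS2"]],
             csb1 = presence[["CSB1"]], csb2 = presence[["CSB2"]],
             csb3 = presence[["CSB3"]],
             element_order_ok = orderOk,
             anormal = fmtSet(anormal), normal = fmtSet(normal),
             cr_length = as.integer(crLength),
             stringsAsFactors = FALSE)
}

#' Read a control-region typing rule table
#'
#' @param path rule-table TSV (see the shipped
#'   \code{extdata/cr_type_rules.tsv} for the format); default loads the
#'   shipped table.
#' @return data.frame of rules; validated for unique subtype labels and
#'   consistent general-type grouping.
#' @export
readTypeRules <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("cr_type_rules.tsv")
  rules <- .tsvRead(path, colClasses = "character")
  need <- c("subtype", "general_type", "tas1", "tas2", "csb1", "csb2",
            "csb3", "order_ok", "anormal", "normal", "priority")
  if (!all(need %in% names(rules)))
    stop("rule table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(rules$subtype))
    stop("duplicate subtype labels in rule table")
  if (anyDuplicated(unique(rules[c("subtype", "general_type")])$subtype))
    stop("a subtype maps to more than one general type")
  rules$priority <- as.integer(rules$priority)
  rules
}

#' @rdname readTypeRules
#' @export
defaultTypeRules <- function() readTypeRules()

.setEquals <- function(required, observed) {
  if (required == "*") return(TRUE)
  req <- if (required == "-") character()
         else sort(strsplit(required, ";", fixed = TRUE)[[1L]])
  obs <- if (observed == "-" || !nzchar(observed)) character()
         else sort(unique(strsplit(observed, ";", fixed = TRUE)[[1L]]))
  identical(req, obs)
}

.flagMatches <- function(required, observed) {
  required == "*" || (required == "1") == isTRUE(observed)
}

#' Classify a control-region profile
#'
#' Applies a typing rule table to a profile: among the rules whose presence
#' pattern, order flag and TR class sets all match, the highest priority
#' wins; no matching rule yields "unclassified" (never forced into a type).
#' Equal-priority multiple matches are an error naming the rules.
#'
#' @param profile one-row profile from \code{\link{buildProfile}}.
#' @param rules rule table from \code{\link{readTypeRules}}.
#' @return one-row data.frame: record_id, general_type, subtype,
#'   matched_rule.
#' @export
classifyCR <- function(profile, rules = defaultTypeRules()) {
  stopifnot(is.data.frame(profile), nrow(profile) == 1L)
  ok <- vapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    .flagMatches(r$tas1, profile$tas1) &&
      .flagMatches(r$tas2, profile$tas2) &&
      .flagMatches(r$csb1, profile$csb1) &&
      .flagMatches(r$csb2, profile$csb2) &&
      .flagMatches(r$csb3, profile$csb3) &&
      .flagMatches(r$order_ok, profile$element_order_ok) &&
      .setEquals(r$anormal, profile$anormal) &&
      .setEquals(r$normal, profile$normal)
  }, logical(1))
  if (!any(ok))
    return(data.frame(record_id = profile$record_id,
                      general_type = "unclassified",
                      subtype = "unclassified", matched_rule = NA_character_,
                      stringsAsFactors = FALSE))
  cand <- rules[ok, , drop = FALSE]
  best <- cand[cand$priority == max(cand$priority), , drop = FALSE]
  if (nrow(best) > 1L)
    stop("ambiguous classification: rules ",
         paste(best$subtype, collapse = ", "),
         " match at equal priority")
  data.frame(record_id = profile$record_id,
             general_type = best$general_type, subtype = best$subtype,
             matched_rule = best$subtype, stringsAsFactors = FALSE)
}

#' Load the 21-subtype layout profile fixture
#'
#' Twenty-one element/TR layout profiles, one per published subtype, each
#' tagged with a representative taxon and the size of the subtype's
#' published membership list. The layouts are the package's documented
#' reconstruction (see the typing vignette).
#'
#' @return data.frame with profile fields plus subtype, general_type, taxon,
#'   n_species.
#' @export
subtypeProfiles <- function() {
  tab <- .tsvRead(.extdata("cr_subtype_profiles.tsv"), colClasses = "character")
  for (f in c("tas1", "tas2", "csb1", "csb2", "csb3", "order_ok"))
    tab[[f]] <- tab[[f]] == "1"
  tab$n_species <- as.integer(tab$n_species)
  tab
}

.profileFromFixtureRow <- function(row) {
  data.frame(record_id = row$taxon, tas1 = row$tas1, tas2 = row$tas2,
             csb1 = row$csb1, csb2 = row$csb2, csb3 = row$csb3,
             element_order_ok = row$order_ok, anormal = row$anormal,
             normal = row$normal, cr_length = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Classify a set of fixture or user profiles
#'
#' @param profiles data.frame of profiles (either \code{\link{buildProfile}}
#'   rows or the \code{\link{subtypeProfiles}} fixture layout).
#' @param rules rule table.
#' @return data.frame of assignments, one row per profile.
#' @export
classifyProfiles <- function(profiles, rules = defaultTypeRules()) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, , drop = FALSE]
    prof <- if ("element_order_ok" %in% names(row)) row
            else .profileFromFixtureRow(row)
    classifyCR(prof, rules)
  })
  do.call(rbind, rows)
}

#' Per-taxon type map table
#'
#' Tabulates assignments per taxon; taxa whose control region is incomplete
#' (flagged via \code{complete = FALSE}) are reported as "N.A.".
#'
#' @param assignments data.frame from \code{\link{classifyCR}} /
#'   \code{\link{classifyProfiles}}; may carry a logical \code{complete}
#'   column (default TRUE).
#' @return data.frame: taxon, general_type, subtype.
#' @export
typeMapTable <- function(assignments) {
  if (!nrow(assignments))
    return(data.frame(taxon = character(), general_type = character(),
                      subtype = character(), stringsAsFactors = FALSE))
  complete <- if ("complete" %in% names(assignments)) assignments$complete
              else rep(TRUE, nrow(assignments))
  data.frame(taxon = assignments$record_id,
             general_type = ifelse(complete, assignments$general_type, "N.A."),
             subtype = ifelse(complete, assignments$subtype, "N.A."),
             stringsAsFactors = FALSE)
}
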