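# Pipeline wrappers and TSV report assembly: annotate / typify / stats.

#' Annotate one mitogenome record
#'
#' Runs the full per-record annotation: control-region extraction, conserved
#' elements, tandem repeats (with positional classes), gene overlaps and the
#' O_L motif scan.
#'
#' @param record a \linkS4class{Mitogenome}.
#' @param maxMismatches per-element mismatch budgets.
#' @param trParams named list of \code{\link{findTandemRepeats}} overrides.
#' @param restrictDownstream passed to \code{\link{annotateElements}}.
#' @return list: cr (\linkS4class{ControlRegion} or NULL), elements, trs
#'   (with position_class/normality), overlaps, ol.
#' @export
annotateRecord <- function(record, maxMismatches = defaultMaxMismatches(),
                           trParams = list(), restrictDownstream = FALSE) {
  cr <- tryCatch(extractControlRegion(record), error = function(e) NULL)
  elements <- .emptyElementHits()
  trs <- cbind(.emptyTrHits(),
               data.frame(position_class = character(),
                          normality = character()))
  if (!is.null(cr)) {
    elements <- annotateElements(crSeq(cr), maxMismatches,
                                 restrictDownstream = restrictDownstream)
    trs <- do.call(findTandemRepeats, c(list(crSeq(cr)), trParams))
    if (nrow(trs)) {
      cls <- do.call(rbind, lapply(seq_len(nrow(trs)), function(i)
        classifyTrPosition(trs$start[i], trs$end[i], elements)))
      trs <- cbind(trs, cls)
    } else {
      trs <- cbind(trs, data.frame(position_class = character(),
                                   normality = character()))
    }
  }
  list(record_id = recordId(record), cr = cr, elements = elements,
       trs = trs, overlaps = scanGeneOverlaps(record),
       ol = scanOLMotif(record))
}

.prefixRecordId <- function(df, id) {
  if (!nrow(df)) return(cbind(data.frame(record_id = character()), df))
  cbind(data.frame(record_id = id, stringsAsFactors = FALSE), df)
}

#' Annotate a set of mitogenomes and write TSV reports
#'
#' One TSV per report class (elements, tandem repeats, overlaps, O_L hits)
#' across all input records, mirroring the per-record tables of a
#' comparative mitogenome study.
#'
#' @param records list of \linkS4class{Mitogenome} objects (e.g. from
#'   \code{\link{readGenBank}}).
#' @param outDir output directory (created if needed).
#' @param ... passed to \code{\link{annotateRecord}}.
#' @return invisible list of per-record annotation results; writes
#'   elements.tsv, tandem_repeats.tsv, overlaps.tsv, ol_hits.tsv.
#' @export
annotateGenomes <- function(records, outDir, ...) {
  if (!length(records)) stop("no input records")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  anns <- lapply(records, annotateRecord, ...)
  bindOf <- function(field) {
    do.call(rbind, lapply(anns, function(a) {
      df <- a[[field]]
      if ("record_id" %in% names(df)) df
      else .prefixRecordId(df, a$record_id)
    }))
  }
  .tsvWrite(bindOf("elements"), file.path(outDir, "elements.tsv"))
  .tsvWrite(bindOf("trs"), file.path(outDir, "tandem_repeats.tsv"))
  .tsvWrite(bindOf("overlaps"), file.path(outDir, "overlaps.tsv"))
  .tsvWrite(bindOf("ol"), file.path(outDir, "ol_hits.tsv"))
  invisible(anns)
}

#' Type the control regions of a set of mitogenomes
#'
#' Annotates each record, builds its CR profile, classifies it against the
#' rule table, and writes the assignment table plus a per-type summary.
#'
#' @param records list of \linkS4class{Mitogenome} objects.
#' @param outDir output directory; assignments.tsv and type_summary.tsv are
#'   written there.
#' @param rules typing rule table.
#' @param ... passed to \code{\link{annotateRecord}}.
#' @return invisible data.frame of assignments.
#' @export
typifyCRs <- function(records, outDir, rules = defaultTypeRules(), ...) {
  if (!length(records)) stop("no input records")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(rec) {
    ann <- annotateRecord(rec, ...)
    if (is.null(ann$cr))
      return(data.frame(record_id = recordId(rec), general_type = "N.A.",
                        subtype = "N.A.", matched_rule = NA_character_,
                        stringsAsFactors = FALSE))
    prof <- buildProfile(ann$elements, ann$trs, crLength(ann$cr),
                         recordId(rec))
    classifyCR(prof, rules)
  })
  assignments <- do.call(rbind, rows)
  .tsvWrite(assignments, file.path(outDir, "assignments.tsv"))
  summ <- as.data.frame(table(general_type = assignments$general_type,
                              subtype = assignments$subtype))
  summ <- summ[summ$Freq > 0, , drop = FALSE]
  names(summ)[3] <- "n_records"
  .tsvWrite(summ[order(summ$general_type, summ$subtype), ],
            file.path(outDir, "type_summary.tsv"))
  invisible(assignments)
}

#' Composition, codon-usage and distance reports for a set of mitogenomes
#'
#' Writes per-record base-composition rows for the five region classes
#' (whole genome, concatenated PCGs, rRNAs, tRNAs, CR), the pooled RSCU
#' table per record, and the pairwise p-distance matrix of whole genomes
#' (aligned inputs only; skipped with a message when lengths differ).
#'
#' @param records list of \linkS4class{Mitogenome} objects.
#' @param outDir output directory.
#' @return invisible list with the composition and RSCU tables.
#' @export
statsReports <- function(records, outDir) {
  if (!length(records)) stop("no input records")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  compRows <- list(); rscuRows <- list()
  for (rec in records) {
    s <- .asChar(genomeSeq(rec))
    ft <- mtFeatures(rec)
    regionSeq <- function(types) {
      sel <- ft[ft$type %in% types, , drop = FALSE]
      paste(vapply(seq_len(nrow(sel)), function(i)
        .circularSubseq(s, sel$start[i],
                        if (sel$wraps_origin[i]) sel$end[i]
                        else sel$end[i] %% (nchar(s) + 1L)),
        ""), collapse = "")
    }
    addComp <- function(seqStr, cls) {
      if (nzchar(seqStr))
        compRows[[length(compRows) + 1L]] <<-
          .prefixRecordId(computeComposition(seqStr, cls), recordId(rec))
    }
    addComp(s, "whole")
    addComp(regionSeq("PCG"), "PCGs")
    addComp(regionSeq("rRNA"), "rRNAs")
    addComp(regionSeq("tRNA"), "tRNAs")
    cr <- tryCatch(extractControlRegion(rec), error = function(e) NULL)
    if (!is.null(cr)) addComp(.asChar(crSeq(cr)), "CR")
    pcg <- ft[ft$type == "PCG", , drop = FALSE]
    if (nrow(pcg)) {
      cds <- vapply(seq_len(nrow(pcg)), function(i) {
        x <- .circularSubseq(s, pcg$start[i],
                             if (pcg$wraps_origin[i]) pcg$end[i]
                             else pcg$end[i] %% (nchar(s) + 1L))
        if (pcg$strand[i] == "L") .revcompChar(x) else x
      }, "")
      rscu <- computeCodonUsage(cds)
      rscuRows[[length(rscuRows) + 1L]] <- .prefixRecordId(rscu,
                                                           recordId(rec))
    }
  }
  comp <- do.call(rbind, compRows)
  rscu <- do.call(rbind, rscuRows)
  .tsvWrite(comp, file.path(outDir, "composition.tsv"))
  if (!is.null(rscu)) .tsvWrite(rscu, file.path(outDir, "rscu.tsv"))
  lens <- vapply(records, function(r) length(genomeSeq(r)), integer(1))
  if (length(records) >= 2L && length(unique(lens)) == 1L) {
    n <- length(records)
    pd <- matrix(0, n, n,
                 dimnames = list(vapply(records, recordId, ""),
                                 vapply(records, recordId, "")))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      pd[i, j] <- pd[j, i] <- pDistance(.asChar(genomeSeq(records[[i]])),
                                        .asChar(genomeSeq(records[[j]])))
    }
    utils::write.table(pd, file.path(outDir, "p_distance.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  invisible(list(composition = comp, rscu = rscu))
}

#' Per-gene dN/dS report from aligned FASTA files
#'
#' @param alignments named list of alignments (\code{DNAStringSet} or
#'   character vectors), one per gene, or paths to aligned FASTA files.
#' @param outDir output directory; writes dnds.tsv.
#' @param correction passed to \code{\link{geneAverageRatio}}.
#' @return invisible data.frame (gene, n_pairs, mean_dN, mean_dS,
#'   mean_ratio, n_undefined).
#' @export
dndsReport <- function(alignments, outDir, correction = "jc") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(alignments), function(g) {
    aln <- alignments[[g]]
    if (is.character(aln) && length(aln) == 1L && file.exists(aln))
      aln <- readFastaSeqs(aln)
    res <- geneAverageRatio(aln, correction)$summary
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  .tsvWrite(out, file.path(outDir, "dnds.tsv"))
  invisible(out)
}
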