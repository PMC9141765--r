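# GenBank flat-file I/O. A deliberately small dialect: LOCUS / FEATURES /
# ORIGIN sections, feature locations "a..b", "complement(a..b)" and
# "join(a..L,1..b)" (origin wrap), qualifiers /gene /product /note.
# GenBank coordinates are 1-based inclusive; internal coordinates are 0-based
# half-open on the H-strand, converted at this boundary only.

#' Feature-name synonym table
#'
#' Reads the shipped synonym table mapping GenBank \code{/gene} and
#' \code{/product} dialects (e.g. "COX3", "D-loop") to the canonical
#' vocabulary of \code{\link{canonicalGeneOrder}}.
#'
#' @param path optional path to an alternative table (TSV with columns
#'   \code{alias}, \code{canonical}).
#' @return named character vector: uppercase alias -> canonical name.
#' @export
geneSynonyms <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("gene_synonyms.tsv")
  tab <- .tsvRead(path)
  stats::setNames(tab$canonical, toupper(tab$alias))
}

.mapFeatureName <- function(gene, product, syn, used) {
  for (key in c(gene, product)) {
    if (is.na(key) || !nzchar(key)) next
    hit <- syn[toupper(trimws(key))]
    if (!is.na(hit)) {
      nm <- unname(hit)
      # plain tRNA-Leu/Ser: promote second occurrence to the other isotype
      if (nm == "trnL2" && "trnL2" %in% used) nm <- "trnL1"
      if (nm == "trnS2" && "trnS2" %in% used) nm <- "trnS1"
      return(list(name = nm, mapped = TRUE))
    }
  }
  raw <- if (!is.na(gene) && nzchar(gene)) gene else product
  list(name = if (is.na(raw)) "unknown" else raw, mapped = FALSE)
}

.parseLocation <- function(loc, locus) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "H"
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("record '", locus, "': unsupported join location: ", loc)
    m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
    if (any(lengths(m) != 3L))
      stop("record '", locus, "': malformed location: ", loc)
    a <- as.integer(m[[1L]][2L]); b <- as.integer(m[[2L]][3L])
    wraps <- TRUE
    return(list(start = a - 1L, end = as.integer(m[[2L]][3L]),
                strand = strand, wraps = TRUE))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1L]]
  if (length(m) != 3L)
    stop("record '", locus, "': malformed location: ", loc)
  list(start = as.integer(m[2L]) - 1L, end = as.integer(m[3L]),
       strand = strand, wraps = FALSE)
}

.parseQualifier <- function(lines, what) {
  pat <- paste0("^/", what, "=")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub("\"", "", sub(pat, "", hit[1L]))
}

#' Read mitogenomes from a GenBank flat file
#'
#' Parses CDS, tRNA, rRNA, D-loop and rep_origin features, maps their names
#' to the canonical vocabulary through the synonym table, and converts
#' coordinates to 0-based half-open. Unknown feature names are retained and
#' flagged (\code{mapped = FALSE}) with a warning.
#'
#' @param path path to a GenBank flat file (one or more records).
#' @param synonyms synonym table as returned by \code{\link{geneSynonyms}}.
#' @return list of \linkS4class{Mitogenome} objects.
#' @export
readGenBank <- function(path, synonyms = geneSynonyms()) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) stop("no GenBank record terminator '//' found in ", path)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  lapply(recs, .parseGenBankRecord, synonyms = synonyms)
}

.parseGenBankRecord <- function(lines, synonyms) {
  locusLine <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locusLine)) stop("malformed GenBank record: no LOCUS line")
  toks <- strsplit(trimws(locusLine[1L]), "\\s+")[[1L]]
  locus <- if (length(toks) >= 2L) toks[2L] else stop("malformed LOCUS line")
  circular <- any(grepl("circular", locusLine[1L], ignore.case = TRUE))

  orgLine <- grep("^\\s+ORGANISM", lines, value = TRUE)
  taxon <- if (length(orgLine)) trimws(sub("^\\s+ORGANISM", "", orgLine[1L])) else ""

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("record '", locus, "': missing ORIGIN section")
  seqLines <- lines[(oi[1L] + 1L):length(lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nzchar(seq)) stop("record '", locus, "': empty sequence under ORIGIN")

  fi <- grep("^FEATURES", lines)
  features <- .emptyFeatures()
  if (length(fi)) {
    block <- lines[(fi[1L] + 1L):(oi[1L] - 1L)]
    newFeat <- grepl("^ {5}\\S", block)
    idx <- cumsum(newFeat)
    keep <- c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin", "misc_feature")
    used <- character()
    rows <- list()
    for (k in seq_len(max(idx, 0L))) {
      fl <- block[idx == k]
      key <- sub("^ {5}(\\S+).*$", "\\1", fl[1L])
      if (!key %in% keep) next
      # location may continue over lines until the first qualifier
      qstart <- grep("^\\s{10,}/", fl)
      locEnd <- if (length(qstart)) qstart[1L] - 1L else length(fl)
      loc <- paste(c(sub("^ {5}\\S+\\s+", "", fl[1L]),
                     trimws(fl[seq_len(locEnd)][-1L])), collapse = "")
      quals <- trimws(fl[grep("^\\s{10,}/", fl)])
      p <- .parseLocation(loc, locus)
      gene <- .parseQualifier(quals, "gene")
      product <- .parseQualifier(quals, "product")
      if (key == "D-loop") { gene <- "CR"; product <- "control region" }
      if (key == "rep_origin" && (is.na(gene) || !nzchar(gene))) gene <- "OL"
      nm <- .mapFeatureName(gene, product, synonyms, used)
      if (!nm$mapped)
        warning("record '", locus, "': unmapped feature name '", nm$name,
                "' retained", call. = FALSE)
      used <- c(used, nm$name)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm$name, strand = p$strand, start = p$start, end = p$end,
        wraps_origin = p$wraps, type = .featureType(nm$name),
        mapped = nm$mapped,
        raw_name = if (!is.na(gene) && nzchar(gene)) gene else
          if (!is.na(product)) product else nm$name,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) features <- .completeFeatures(do.call(rbind, rows))
  }
  Mitogenome(locus, seq, features, circular = circular, taxon = taxon)
}

.gbLocation <- function(start, end, wraps, strand, L) {
  loc <- if (wraps) sprintf("join(%d..%d,1..%d)", start + 1L, L, end)
         else sprintf("%d..%d", start + 1L, end)
  if (strand == "L") loc <- sprintf("complement(%s)", loc)
  loc
}

.gbFeatureKey <- function(type) {
  switch(type, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop",
         OL = "rep_origin", "misc_feature")
}

.trnProduct <- function(name) {
  aa <- c(trnF = "Phe", trnV = "Val", trnL2 = "Leu", trnI = "Ile",
          trnQ = "Gln", trnM = "Met", trnW = "Trp", trnA = "Ala",
          trnN = "Asn", trnC = "Cys", trnY = "Tyr", trnS2 = "Ser",
          trnD = "Asp", trnK = "Lys", trnG = "Gly", trnR = "Arg",
          trnH = "His", trnS1 = "Ser", trnL1 = "Leu", trnE = "Glu",
          trnT = "Thr", trnP = "Pro")
  codon <- c(trnL2 = "(UUR)", trnL1 = "(CUN)", trnS2 = "(UCN)",
             trnS1 = "(AGN)")
  paste0("tRNA-", aa[name],
         if (name %in% names(codon)) codon[name] else "")
}

#' Write mitogenomes to a GenBank flat file
#'
#' Inverse of \code{\link{readGenBank}} for the supported feature set;
#' write -> read preserves all feature intervals exactly.
#'
#' @param records a \linkS4class{Mitogenome} or list thereof.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(records, path) {
  if (methods::is(records, "Mitogenome")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    L <- length(genomeSeq(rec))
    cat(sprintf("LOCUS       %s%17d bp    DNA     %s     VRT\n",
                formatC(recordId(rec), width = -16), L,
                if (isCircularGenome(rec)) "circular" else "linear"),
        file = con)
    cat(sprintf("DEFINITION  %s mitochondrion.\n",
                if (nzchar(taxonName(rec))) taxonName(rec) else recordId(rec)),
        file = con)
    if (nzchar(taxonName(rec))) {
      cat("SOURCE      mitochondrion\n", file = con)
      cat(sprintf("  ORGANISM  %s\n", taxonName(rec)), file = con)
    }
    cat("FEATURES             Location/Qualifiers\n", file = con)
    cat(sprintf("     source          1..%d\n", L), file = con)
    ft <- mtFeatures(rec)
    for (i in seq_len(nrow(ft))) {
      key <- .gbFeatureKey(ft$type[i])
      loc <- .gbLocation(ft$start[i], ft$end[i], ft$wraps_origin[i],
                         ft$strand[i], L)
      cat(sprintf("     %s%s\n", formatC(key, width = -16), loc), file = con)
      nm <- ft$name[i]
      if (ft$type[i] %in% c("PCG", "rRNA")) {
        cat(sprintf("                     /gene=\"%s\"\n", nm), file = con)
      } else if (ft$type[i] == "tRNA") {
        cat(sprintf("                     /gene=\"%s\"\n", nm), file = con)
        cat(sprintf("                     /product=\"%s\"\n",
                    .trnProduct(nm)), file = con)
      } else if (ft$type[i] == "CR") {
        cat("                     /note=\"control region\"\n", file = con)
      } else if (ft$type[i] == "OL") {
        cat("                     /gene=\"OL\"\n", file = con)
        cat("                     /note=\"origin of L-strand replication\"\n",
            file = con)
      } else {
        cat(sprintf("                     /note=\"%s\"\n", ft$raw_name[i]),
            file = con)
      }
    }
    cat("ORIGIN\n", file = con)
    s <- tolower(.asChar(genomeSeq(rec)))
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      grps <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      cat(sprintf("%9d %s\n", p, paste(grps, collapse = " ")), file = con)
    }
    cat("//\n", file = con)
  }
  invisible(path)
}

#' Read control-region (or any) sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}, returning uppercase
#' sequences.
#'
#' @param path FASTA file path.
#' @return \code{DNAStringSet}.
#' @export
readFastaSeqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
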