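# Internal helpers shared across modules.

.seqChars <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet"))
    x <- as.character(x)
  strsplit(toupper(x), "", fixed = TRUE)[[1L]]
}

.asChar <- function(x) {
  if (methods::is(x, "DNAString")) as.character(x) else toupper(as.character(x))
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Extract a (possibly origin-wrapping) interval from a circular sequence.
# start/end are 0-based half-open; wrap when end <= start.
.circularSubseq <- function(seq, start, end) {
  s <- .asChar(seq)
  L <- nchar(s)
  if (end > start) {
    substr(s, start + 1L, end)
  } else {
    paste0(substr(s, start + 1L, L), substr(s, 1L, end))
  }
}

# Run code with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Random DNA with a target AT percentage (A=T, G=C frequencies).
.randomDNA <- function(n, atPercent = 60) {
  if (n <= 0L) return("")
  at <- atPercent / 100
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# Vertebrate mitochondrial genetic code as a named character vector
# codon -> single-letter amino acid ('*' for stop).
.mitoCode <- function() {
  if (is.null(.mitoCR_cache$code)) {
    code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
    .mitoCR_cache$code <- code
  }
  .mitoCR_cache$code
}

.mitoCR_cache <- new.env(parent = emptyenv())

.isStopCodon <- function(codon) unname(.mitoCode()[codon] == "*")

.stopCodons <- function() names(.mitoCode())[.mitoCode() == "*"]

.tsvWrite <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.tsvRead <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", ...)
}

.extdata <- function(...) {
  system.file("extdata", ..., package = "mitoCR", mustWork = TRUE)
}
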