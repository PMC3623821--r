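# Shared small helpers. Sequence collections throughout the package are named
# character vectors (names = ids, values = uppercase IUPAC DNA strings).

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_LETTERS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; handles the full IUPAC alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAG")  # "CTT"
revcomp <- function(x) {
  comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# percentage helper: 100 * k / n, NA-safe for n = 0
.pct <- function(k, n) {
  if (is.na(n) || n == 0) return(NA_real_)
  100 * k / n
}

.check_dna <- function(x, what = "sequence") {
  bad <- grepl(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), x)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC characters (first offender: %s)",
                 what, names(x)[bad][1L] %||% x[bad][1L]), call. = FALSE)
  }
  invisible(x)
}

.check_seqset <- function(seqs) {
  if (!is.character(seqs)) stop("sequences must be a named character vector")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("every sequence needs a non-empty id")
  }
  if (anyDuplicated(names(seqs))) {
    stop("sequence ids must be unique (duplicate: ",
         names(seqs)[duplicated(names(seqs))][1L], ")")
  }
  .check_dna(toupper(seqs), "sequence set")
  invisible(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty SSR locus table, the common currency between modules
.empty_loci <- function() {
  data.frame(seq_id = character(0), preset = character(0),
             motif = character(0), canonical_class = character(0),
             repeat_count = integer(0), start = integer(0), end = integer(0),
             length = integer(0), stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
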