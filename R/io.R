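# FASTA and tabular readers/writers. FASTA goes through Biostrings; the id of
# a record is the first whitespace-delimited token of its header line.

#' Read a FASTA file into a named character vector
#'
#' Accepts arbitrary line wrapping. Sequences are uppercased; ids are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  .check_seqset(seqs)
  seqs
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 60 columns.
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  .check_seqset(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a genotype table
#'
#' Expected layout: tab-separated, header row of locus ids, first column
#' `individual`, cells either `"a/b"` (two integer allele labels, unordered)
#' or `"NA"` for missing.
#'
#' @param path path to the TSV file.
#' @return a `genotype_table` object (see [genotype_table()]).
#' @export
read_genotypes <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (names(df)[1L] != "individual") {
    stop("genotype table must have 'individual' as its first column")
  }
  inds <- df[[1L]]
  loci <- names(df)[-1L]
  n <- length(inds); m <- length(loci)
  a1 <- matrix(NA_integer_, n, m, dimnames = list(inds, loci))
  a2 <- a1
  for (j in seq_len(m)) {
    cell <- df[[j + 1L]]
    ok <- !is.na(cell) & cell != "NA" & cell != ""
    parts <- strsplit(cell[ok], "/", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad)) {
      stop(sprintf("malformed genotype cell at locus %s: '%s'",
                   loci[j], cell[ok][bad][1L]))
    }
    a1[ok, j] <- as.integer(vapply(parts, `[`, character(1), 1L))
    a2[ok, j] <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  genotype_table(inds, loci, a1, a2)
}

#' Write a genotype table to TSV
#'
#' @param gt a `genotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  cells <- matrix("NA", nrow(gt$a1), ncol(gt$a1))
  ok <- !is.na(gt$a1)
  cells[ok] <- paste0(gt$a1[ok], "/", gt$a2[ok])
  df <- data.frame(individual = gt$individuals, cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("individual", gt$loci)
  .write_tsv(df, path)
}

#' Read a species-by-locus transferability matrix
#'
#' Rows are species, columns are loci, cells 1 (amplified), 0 (failed) or NA.
#'
#' @param path path to the TSV file (first column `species`).
#' @return integer matrix with species row names.
#' @export
read_transfer_matrix <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1L] != "species") {
    stop("transferability table must have 'species' as its first column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  bad <- !(m %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("transferability cells must be 1, 0 or NA")
  m
}

#' Write a transferability matrix to TSV
#'
#' @param mat integer matrix (species x loci) of 1/0/NA.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfer_matrix <- function(mat, path) {
  df <- data.frame(species = rownames(mat), mat,
                   stringsAsFactors = FALSE, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a sequence-to-GO annotation map
#'
#' One `seq_id <TAB> term` pair per line (header `seq_id`, `term`).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `seq_id`, `term`.
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("seq_id", "term") %in% names(df))) {
    stop("annotation map needs columns seq_id and term")
  }
  df[, c("seq_id", "term")]
}

#' Write a sequence-to-GO annotation map
#'
#' @param ann data.frame with columns `seq_id`, `term`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  .write_tsv(ann[, c("seq_id", "term")], path)
}

#' Write gene-model features as GFF3
#'
#' @param features data.frame with columns `chrom`, `source`, `type`,
#'   `start`, `end`, `strand`, `attributes` (feature types among
#'   CDS / five_prime_UTR / three_prime_UTR / gene).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$chrom, features$source %||% "estssr",
                   features$type, features$start, features$end,
                   features$strand, features$attributes)
  writeLines(lines, con)
  invisible(path)
}
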