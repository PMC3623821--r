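# Pairwise alignment helpers shared by contaminant screening, redundancy
# clustering and the optional placement refiner. Scoring is match +1,
# mismatch -1, linear gap -2; N and IUPAC ambiguity codes never score as
# matches, in the alignment or in identity counts.

.substitution_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      n <- length(IUPAC_LETTERS)
      mat <- matrix(-1, n, n, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
      diag(mat)[1:4] <- 1            # only exact A/C/G/T self-matches score
      m <<- mat
    }
    m
  }
})

# k-mer prefilter: do a and b share any exact k-mer of A/C/G/T?
.shares_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                         seq_len(nchar(a) - k + 1L) + k - 1L))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                         seq_len(nchar(b) - k + 1L) + k - 1L))
  keep <- !grepl("[^ACGT]", ka)
  any(ka[keep] %in% kb)
}

# best local alignment of a (pattern) against b (subject); returns match
# count (exact ACGT matches), number of aligned columns, and the aligned
# span on each input
.local_align <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = .substitution_matrix(),
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == pb & pa %in% DNA_BASES)
  list(matches = matches,
       columns = length(pa),
       pattern_span = c(aln@pattern@range@start,
                        aln@pattern@range@start + aln@pattern@range@width - 1L),
       subject_span = c(aln@subject@range@start,
                        aln@subject@range@start + aln@subject@range@width - 1L))
}

#' Local-alignment identity between two sequences
#'
#' Identity is the number of exactly matching A/C/G/T columns in the best
#' local alignment divided by the length of the shorter sequence -- the
#' convention used by greedy incremental clustering tools. Ambiguity codes
#' never count as matches.
#'
#' @param a,b DNA strings.
#' @return identity fraction in \[0, 1\].
#' @export
local_identity <- function(a, b) {
  aln <- .local_align(a, b)
  aln$matches / min(nchar(a), nchar(b))
}

# identity/coverage of record `a` against reference `b`, for contaminant
# screening: identity over aligned columns, coverage = aligned span of a
# over its full length
.screen_align <- function(a, b) {
  aln <- .local_align(a, b)
  list(identity = if (aln$columns > 0) aln$matches / aln$columns else 0,
       coverage = (aln$pattern_span[2] - aln$pattern_span[1] + 1) / nchar(a))
}

# global alignment of two segments; returns the per-position map from
# positions of a to positions of b (NA where a aligns to a gap)
.global_position_map <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .substitution_matrix(),
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(a))
  ia <- 0L; ib <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") map[ia] <- ib
  }
  map
}
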