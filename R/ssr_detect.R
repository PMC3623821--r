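# Perfect microsatellite detection with canonical motif classes, compound
# merging and summary statistics. Periods 2-6 only (mononucleotide runs are
# deliberately out of scope). Coordinates in all outputs are 1-based
# inclusive; a locus spans exactly repeat_count full motif copies and
# trailing partial copies are ignored.

#' Criteria preset for SSR detection
#'
#' A preset bundles the per-period minimum repeat counts, an optional strict
#' minimum total length, and the maximum interruption allowed between
#' members of a compound SSR.
#'
#' @param name preset name.
#' @param min_repeats named integer vector with entries for periods
#'   `"2"`..`"6"`; periods absent from the vector are not searched.
#' @param min_total_length optional strict lower bound (bp) on locus length
#'   (`length > min_total_length` is required when set).
#' @param max_interruption maximum gap (bp) between consecutive loci merged
#'   into a compound SSR.
#' @return an object of class `ssr_preset`.
#' @export
ssr_preset <- function(name, min_repeats, min_total_length = NULL,
                       max_interruption = 100L) {
  pers <- as.integer(names(min_repeats))
  if (anyNA(pers) || any(pers < 2L) || any(pers > 6L)) {
    stop("min_repeats must be named by periods 2..6")
  }
  if (any(min_repeats < 1L)) stop("min_repeats must be >= 1")
  if (max_interruption < 0L) stop("max_interruption must be >= 0")
  structure(list(name = name,
                 min_repeats = as.integer(min_repeats),
                 periods = pers,
                 min_total_length = min_total_length,
                 max_interruption = as.integer(max_interruption)),
            class = "ssr_preset")
}

#' Built-in SSR criteria presets
#'
#' Three presets:
#' \describe{
#'   \item{misa_default}{di >= 10, tri >= 6, tetra >= 5, penta >= 4,
#'     hexa >= 3 repeats.}
#'   \item{cardle}{di >= 7, tri >= 5, tetra >= 4, penta >= 3 repeats;
#'     hexanucleotides are not searched under this preset (only four
#'     thresholds are defined for it).}
#'   \item{len20}{any period 2-6 with >= 2 repeats and total length
#'     strictly greater than 20 bp.}
#' }
#'
#' @return named list of `ssr_preset` objects.
#' @export
builtin_presets <- function() {
  list(
    misa_default = ssr_preset("misa_default",
      c(`2` = 10L, `3` = 6L, `4` = 5L, `5` = 4L, `6` = 3L)),
    cardle = ssr_preset("cardle",
      c(`2` = 7L, `3` = 5L, `4` = 4L, `5` = 3L)),
    len20 = ssr_preset("len20",
      c(`2` = 2L, `3` = 2L, `4` = 2L, `5` = 2L, `6` = 2L),
      min_total_length = 20L)
  )
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number power of a shorter
#' word (`"ATAT"` = `("AT")^2` is not primitive). Only primitive motifs are
#' reported by the detector, so a dinucleotide run is never double-reported
#' as its tetranucleotide square.
#'
#' @param motif DNA word of length 1-6.
#' @return logical.
#' @export
is_primitive <- function(motif) {
  n <- nchar(motif)
  if (n < 1L || n > 6L) stop("motif length must be 1..6")
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        strrep(substr(motif, 1L, d), n %/% d) == motif) return(FALSE)
  }
  TRUE
}

.rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(motif, k + 1L, n), substr(motif, 1L, k))
  }, character(1))
}

#' Canonical motif class
#'
#' Motifs are grouped into classes invariant to phase (cyclic rotation) and
#' strand (reverse complement). The class label is `"M/M'"` where `M` is the
#' lexicographic minimum over all rotations of the motif and of its reverse
#' complement, and `M'` is the reverse complement of `M` (e.g. `"GA"` and
#' `"TC"` both map to `"AG/CT"`).
#'
#' @param motif primitive DNA word of length 2-6 over A/C/G/T.
#' @return class label string.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (nchar(motif) < 2L || nchar(motif) > 6L) {
    stop("motif length must be 2..6")
  }
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A/C/G/T")
  if (!is_primitive(motif)) stop("motif is not primitive: ", motif)
  m <- min(c(.rotations(motif), .rotations(revcomp(motif))))
  paste0(m, "/", revcomp(m))
}

#' Detect perfect SSRs in one sequence
#'
#' Finds every maximal perfect tandem run of a primitive motif of period
#' 2-6 whose repeat count meets the preset's per-period minimum (and whose
#' total length strictly exceeds `min_total_length`, when the preset sets
#' one). The reported interval covers whole motif copies only; the motif is
#' given in the phase of the leftmost start. `N`/ambiguity bases never
#' extend a run. If runs of different periods occupy the identical
#' interval, only the shorter-period description is reported.
#'
#' @param seq uppercase DNA string.
#' @param preset an [ssr_preset()].
#' @param seq_id id used in the output table.
#' @return data.frame with columns `seq_id`, `preset`, `motif`,
#'   `canonical_class`, `repeat_count`, `start`, `end`, `length`
#'   (1-based inclusive coordinates).
#' @export
find_perfect_ssrs <- function(seq, preset, seq_id = "seq") {
  stopifnot(inherits(preset, "ssr_preset"))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  valid <- chars %in% DNA_BASES
  out <- list()
  for (k in seq_along(preset$periods)) {
    p <- preset$periods[k]
    min_rep <- preset$min_repeats[k]
    if (L < 2L * p) next
    idx <- seq_len(L - p)
    eq <- (chars[idx] == chars[idx + p]) & valid[idx] & valid[idx + p]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    need <- p * (min_rep - 1L)        # TRUE-run length implied by min_rep
    sel <- which(r$values & r$lengths >= max(need, p))
    for (s in sel) {
      i <- run_start[s]
      m <- r$lengths[s]
      count <- (m + p) %/% p
      if (count < min_rep) next
      motif <- substr(seq, i, i + p - 1L)
      if (!is_primitive(motif)) next  # fundamental period is shorter
      len <- count * p
      if (!is.null(preset$min_total_length) &&
          len <= preset$min_total_length) next
      out[[length(out) + 1L]] <- c(i, i + len - 1L, p, count)
    }
  }
  if (!length(out)) {
    res <- .empty_loci()
    return(res)
  }
  m <- do.call(rbind, out)
  # identical-interval conflicts: keep the shorter period
  ord <- order(m[, 1], m[, 2], m[, 3])
  m <- m[ord, , drop = FALSE]
  key <- paste(m[, 1], m[, 2])
  m <- m[!duplicated(key), , drop = FALSE]
  motifs <- substring(seq, m[, 1], m[, 1] + m[, 3] - 1L)
  data.frame(seq_id = seq_id, preset = preset$name, motif = motifs,
             canonical_class = vapply(motifs, canonical_motif, character(1),
                                      USE.NAMES = FALSE),
             repeat_count = as.integer(m[, 4]),
             start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             length = as.integer(m[, 2] - m[, 1] + 1L),
             stringsAsFactors = FALSE)
}

#' Detect perfect SSRs across a sequence set
#'
#' @param seqs named character vector of DNA sequences.
#' @param preset an [ssr_preset()] (default: the MISA-style default preset).
#' @return combined locus table (see [find_perfect_ssrs()]), ordered by
#'   sequence id then start.
#' @export
detect_ssrs <- function(seqs, preset = builtin_presets()$misa_default) {
  .check_seqset(seqs)
  res <- lapply(names(seqs), function(id) {
    find_perfect_ssrs(seqs[[id]], preset, seq_id = id)
  })
  out <- do.call(rbind, c(res, list(.empty_loci())))
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Merge nearby loci into compound SSRs
#'
#' Consecutive loci on the same sequence whose gap (bases strictly between
#' them) is at most `max_interruption` are chained into one compound SSR;
#' chains may have more than two members. Every input locus ends up either
#' in exactly one compound or as a singleton.
#'
#' @param loci locus table from [detect_ssrs()].
#' @param preset the `ssr_preset` supplying `max_interruption`.
#' @return list with elements `compounds` (one row per compound:
#'   `compound_id`, `seq_id`, `start`, `end`, `n_members`, `motifs`,
#'   `gaps`), `compound_members` (locus rows plus `compound_id`), and
#'   `singletons` (locus rows).
#' @export
merge_compound <- function(loci, preset) {
  stopifnot(inherits(preset, "ssr_preset"))
  loci <- loci[order(loci$seq_id, loci$start), , drop = FALSE]
  n <- nrow(loci)
  if (n == 0L) {
    return(list(compounds = data.frame(), compound_members = data.frame(),
                singletons = loci))
  }
  same <- loci$seq_id[-1L] == loci$seq_id[-n]
  gap <- loci$start[-1L] - loci$end[-n] - 1L
  if (any(same & gap < 0L)) {
    bad <- which(same & gap < 0L)[1L]
    stop(sprintf("overlapping loci on %s at %d-%d / %d-%d",
                 loci$seq_id[bad], loci$start[bad], loci$end[bad],
                 loci$start[bad + 1L], loci$end[bad + 1L]))
  }
  chain <- c(FALSE, same & gap <= preset$max_interruption)
  group <- cumsum(!chain)
  sizes <- tabulate(group)
  is_cmp <- sizes[group] > 1L
  singles <- loci[!is_cmp, , drop = FALSE]
  members <- loci[is_cmp, , drop = FALSE]
  if (nrow(members)) {
    g <- group[is_cmp]
    cid <- paste0("cmp", match(g, unique(g)))
    members$compound_id <- cid
    comp <- do.call(rbind, lapply(split(seq_len(nrow(members)), cid)[unique(cid)],
      function(ix) {
        mm <- members[ix, , drop = FALSE]
        data.frame(compound_id = mm$compound_id[1L], seq_id = mm$seq_id[1L],
                   start = min(mm$start), end = max(mm$end),
                   n_members = nrow(mm),
                   motifs = paste(mm$motif, collapse = ","),
                   gaps = paste(mm$start[-1L] - mm$end[-nrow(mm)] - 1L,
                                collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    rownames(comp) <- NULL
  } else {
    comp <- data.frame()
    members <- cbind(members, compound_id = character(0))
  }
  list(compounds = comp, compound_members = members, singletons = singles)
}

#' SSR density in kb of sequence per locus
#'
#' @param total_bases total searched bases.
#' @param n_loci number of detected loci.
#' @return kb per SSR (`NA` when `n_loci` is zero -- flagged, not an error).
#' @export
ssr_density_kb <- function(total_bases, n_loci) {
  if (n_loci == 0L) return(NA_real_)
  total_bases / n_loci / 1000
}

#' Summarise a detection run
#'
#' @param loci locus table.
#' @param compounds result of [merge_compound()] (or NULL).
#' @param total_bases total bases searched.
#' @param n_sequences number of sequences searched.
#' @return list with counts by period and canonical class, percentage per
#'   class, mean repeat count, single- vs multi-SSR sequence counts,
#'   density (kb per SSR; `density_defined = FALSE` when no loci), the
#'   SSR-containing-sequence frequency and the per-sequence locus frequency
#'   (both percentages).
#' @export
summarize_ssrs <- function(loci, compounds = NULL, total_bases, n_sequences) {
  n_loci <- nrow(loci)
  per_seq <- table(loci$seq_id)
  by_period <- table(factor(nchar(loci$motif), levels = 2:6))
  by_class <- sort(table(loci$canonical_class), decreasing = TRUE)
  n_compounds <- if (!is.null(compounds) && nrow(compounds$compounds)) {
    nrow(compounds$compounds)
  } else 0L
  list(
    n_loci = n_loci,
    n_sequences = n_sequences,
    total_bases = total_bases,
    by_period = as.list(stats::setNames(as.integer(by_period),
                                        paste0("p", 2:6))),
    by_period_pct = as.list(stats::setNames(
      vapply(as.integer(by_period), .pct, numeric(1), n = n_loci),
      paste0("p", 2:6))),
    by_class = as.list(stats::setNames(as.integer(by_class),
                                       names(by_class))),
    by_class_pct = as.list(stats::setNames(
      vapply(as.integer(by_class), .pct, numeric(1), n = n_loci),
      names(by_class))),
    mean_repeat_count = if (n_loci) mean(loci$repeat_count) else NA_real_,
    n_ssr_sequences = length(per_seq),
    n_single_ssr_sequences = sum(per_seq == 1L),
    n_multi_ssr_sequences = sum(per_seq > 1L),
    n_compounds = n_compounds,
    compound_share_pct = .pct(n_compounds, n_loci),
    density_kb_per_ssr = ssr_density_kb(total_bases, n_loci),
    density_defined = n_loci > 0L,
    frequency_pct = .pct(length(per_seq), n_sequences),
    loci_per_sequence_pct = .pct(n_loci, n_sequences)
  )
}
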