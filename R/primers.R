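# Exhaustive flanking-primer enumeration with a transparent penalty
# function, Wallace and nearest-neighbor melting temperatures, and M13(-21)
# forward tailing.

#' The standard M13(-21) forward tail (18 bases)
#' @export
M13_TAIL <- "TGTAAAACGACGGCCAGT"

#' Primer design constraints
#'
#' Defaults follow common microsatellite-genotyping practice: primers of
#' 18-27 bases (optimum 20), melting temperature 57-63 degrees C (optimum
#' 60), GC content 30-70\% (optimum 50), products of 100-300 bp, and at
#' least 50 bp of flank on each side of the locus.
#'
#' @param size_range,size_opt primer length range and optimum (bases).
#' @param tm_range,tm_opt melting temperature range and optimum (deg C).
#' @param gc_range,gc_opt GC percentage range and optimum.
#' @param product_range amplicon size range (bp), inclusive.
#' @param min_flank minimum flank on each side of the locus (bp).
#' @param weights penalty weights: per base of length deviation, per degree
#'   of Tm deviation, per GC percentage point, per degree of pair Tm
#'   difference.
#' @param self_comp_k reject primers containing a self-complementary word
#'   of this length or longer.
#' @param tm_method `"nn"` (nearest-neighbor, default) or `"wallace"`.
#' @return object of class `primer_constraints`.
#' @export
primer_constraints <- function(size_range = c(18L, 27L), size_opt = 20L,
                               tm_range = c(57, 63), tm_opt = 60,
                               gc_range = c(30, 70), gc_opt = 50,
                               product_range = c(100L, 300L),
                               min_flank = 50L,
                               weights = c(size = 1, tm = 1, gc = 0.2,
                                           tm_diff = 1),
                               self_comp_k = 8L,
                               tm_method = "nn") {
  stopifnot(size_range[1] <= size_range[2], tm_range[1] <= tm_range[2],
            gc_range[1] <= gc_range[2],
            product_range[1] <= product_range[2],
            min_flank >= size_range[1])
  structure(list(size_range = as.integer(size_range),
                 size_opt = as.integer(size_opt),
                 tm_range = tm_range, tm_opt = tm_opt,
                 gc_range = gc_range, gc_opt = gc_opt,
                 product_range = as.integer(product_range),
                 min_flank = as.integer(min_flank),
                 weights = weights, self_comp_k = as.integer(self_comp_k),
                 tm_method = tm_method),
            class = "primer_constraints")
}

#' Check that a locus has designable flanks
#'
#' @param seq the sequence containing the locus.
#' @param locus one locus row (needs `start`, `end`).
#' @param constraints a [primer_constraints()].
#' @return list with `ok` (logical) and `reason` (`""`,
#'   `"flank_too_short_5p"` or `"flank_too_short_3p"`).
#' @export
check_flanks <- function(seq, locus, constraints = primer_constraints()) {
  L <- nchar(seq)
  if (locus$start < 1L || locus$end > L) stop("locus outside record bounds")
  if (locus$start - 1L < constraints$min_flank) {
    return(list(ok = FALSE, reason = "flank_too_short_5p"))
  }
  if (L - locus$end < constraints$min_flank) {
    return(list(ok = FALSE, reason = "flank_too_short_3p"))
  }
  list(ok = TRUE, reason = "")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' dinucleotides.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# initiation terms, by terminal base pair
.NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
.NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Oligo melting temperature
#'
#' `"wallace"`: Tm = 2(A+T) + 4(G+C). `"nn"` (default): nearest-neighbor
#' enthalpy/entropy sums with the SantaLucia (1998) unified parameter
#' table, entropic salt correction 0.368 (N-1) ln\[Na+\], and
#' Tm = 1000 dH / (dS + R ln(C/4)) - 273.15 with R = 1.987.
#'
#' @param oligo primer sequence (A/C/G/T only, length >= 8).
#' @param method `"nn"` or `"wallace"`.
#' @param conc_nM total oligo concentration (nM; default 50).
#' @param na_mM monovalent cation concentration (mM; default 50).
#' @return melting temperature in degrees C.
#' @export
melting_temperature <- function(oligo, method = c("nn", "wallace"),
                                conc_nM = 50, na_mM = 50) {
  method <- match.arg(method)
  oligo <- toupper(oligo)
  n <- nchar(oligo)
  if (n < 8L) stop("oligo must be at least 8 bases")
  if (grepl("[^ACGT]", oligo)) {
    stop("ambiguity bases are not allowed in melting temperature input")
  }
  chars <- strsplit(oligo, "", fixed = TRUE)[[1]]
  if (method == "wallace") {
    gc <- sum(chars %in% c("G", "C"))
    return(2 * (n - gc) + 4 * gc)
  }
  dinucs <- paste0(chars[-n], chars[-1L])
  dH <- sum(.NN_DH[dinucs])
  dS <- sum(.NN_DS[dinucs])
  ends <- ifelse(chars[c(1L, n)] %in% c("G", "C"), "GC", "AT")
  dH <- dH + sum(.NN_INIT_DH[ends])
  dS <- dS + sum(.NN_INIT_DS[ends])
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * dH / (dS + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

#' GC content of an oligo, in percent
#' @param oligo DNA string.
#' @return percentage of G+C bases.
#' @export
gc_percent <- function(oligo) {
  chars <- strsplit(toupper(oligo), "", fixed = TRUE)[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

# hairpin/self-dimer guard: TRUE when some k-mer of the oligo has its
# reverse complement also present in the oligo
.self_complementary <- function(oligo, k) {
  n <- nchar(oligo)
  if (n < k) return(FALSE)
  kmers <- substring(oligo, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  any(revcomp(kmers) %in% kmers)
}

# enumerate one flank's primer candidates as a data.frame
.enumerate_windows <- function(seq, lo, hi, constraints) {
  if (hi < lo) return(NULL)
  sizes <- constraints$size_range[1]:constraints$size_range[2]
  grid <- expand.grid(start = lo:hi, size = sizes)
  grid <- grid[grid$start + grid$size - 1L <= hi, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid$end <- grid$start + grid$size - 1L
  grid$oligo <- substring(seq, grid$start, grid$end)
  grid <- grid[!grepl("[^ACGT]", grid$oligo), , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid$gc <- vapply(grid$oligo, gc_percent, numeric(1), USE.NAMES = FALSE)
  keep <- grid$gc >= constraints$gc_range[1] & grid$gc <= constraints$gc_range[2]
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid$tm <- vapply(grid$oligo, melting_temperature, numeric(1),
                    method = constraints$tm_method, USE.NAMES = FALSE)
  keep <- grid$tm >= constraints$tm_range[1] & grid$tm <= constraints$tm_range[2]
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  keep <- !vapply(grid$oligo, .self_complementary, logical(1),
                  k = constraints$self_comp_k, USE.NAMES = FALSE)
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid
}

# per-primer penalty component
.primer_penalty <- function(grid, constraints) {
  w <- constraints$weights
  w[["size"]] * abs(grid$size - constraints$size_opt) +
    w[["tm"]] * abs(grid$tm - constraints$tm_opt) +
    w[["gc"]] * abs(grid$gc - constraints$gc_opt)
}

#' Design primer pairs flanking an SSR locus
#'
#' Enumerates every forward window entirely 5' of the locus and every
#' reverse window entirely 3' of it that satisfies the length, Tm, GC and
#' self-complementarity constraints, forms all pairs whose product size is
#' within range (the product always spans the full locus), scores each pair
#' by the summed weighted deviations from the per-primer optima plus a
#' pair-Tm-difference term, and returns the `n_best` pairs with the
#' smallest penalty. Ties are broken deterministically: smaller product
#' size, then leftmost forward start.
#'
#' @param seq sequence containing the locus.
#' @param locus one locus row (needs `seq_id`, `start`, `end`; a locus id
#'   is derived as `seq_id:start-end`).
#' @param constraints a [primer_constraints()].
#' @param n_best maximum number of pairs returned (default 3).
#' @return data.frame with one row per returned pair: `locus_id`,
#'   `forward`, `reverse`, `tm_forward`, `tm_reverse`, `gc_forward`,
#'   `gc_reverse`, `forward_start`, `reverse_end` (template coordinates of
#'   the amplicon), `product_size`, `penalty`, `rank`, `m13_tailed`.
#'   Zero rows (with a `reason` attribute) when no feasible pair exists.
#' @export
design_primers <- function(seq, locus, constraints = primer_constraints(),
                           n_best = 3L) {
  fl <- check_flanks(seq, locus, constraints)
  if (!fl$ok) stop("flank check failed: ", fl$reason)
  L <- nchar(seq)
  prod_max <- constraints$product_range[2]
  size_min <- constraints$size_range[1]
  # forward primers end before the locus and must reach a reverse window
  f_lo <- max(1L, locus$end + size_min - prod_max + 1L)
  fwd <- .enumerate_windows(seq, f_lo, locus$start - 1L, constraints)
  # reverse primers start after the locus (windows on the plus strand;
  # the reverse primer itself is the reverse complement)
  r_hi <- min(L, locus$start - size_min + prod_max - 1L)
  rev_ <- .enumerate_windows(seq, locus$end + 1L, r_hi, constraints)
  empty <- function(reason) {
    out <- data.frame(locus_id = character(0), forward = character(0),
                      reverse = character(0), tm_forward = numeric(0),
                      tm_reverse = numeric(0), gc_forward = numeric(0),
                      gc_reverse = numeric(0), forward_start = integer(0),
                      reverse_end = integer(0), product_size = integer(0),
                      penalty = numeric(0), rank = integer(0),
                      m13_tailed = logical(0), stringsAsFactors = FALSE)
    attr(out, "reason") <- reason
    out
  }
  if (is.null(fwd) || is.null(rev_)) return(empty("no_feasible_primer"))
  pairs <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev_)))
  product <- rev_$end[pairs$r] - fwd$start[pairs$f] + 1L
  keep <- product >= constraints$product_range[1] &
          product <= constraints$product_range[2]
  pairs <- pairs[keep, , drop = FALSE]
  product <- product[keep]
  if (!nrow(pairs)) return(empty("no_feasible_pair"))
  pf <- .primer_penalty(fwd, constraints)
  pr <- .primer_penalty(rev_, constraints)
  penalty <- pf[pairs$f] + pr[pairs$r] +
    constraints$weights[["tm_diff"]] * abs(fwd$tm[pairs$f] - rev_$tm[pairs$r])
  ord <- order(penalty, product, fwd$start[pairs$f])
  take <- ord[seq_len(min(n_best, length(ord)))]
  locus_id <- sprintf("%s:%d-%d", locus$seq_id, locus$start, locus$end)
  data.frame(
    locus_id = locus_id,
    forward = fwd$oligo[pairs$f[take]],
    reverse = revcomp(rev_$oligo[pairs$r[take]]),
    tm_forward = fwd$tm[pairs$f[take]],
    tm_reverse = rev_$tm[pairs$r[take]],
    gc_forward = fwd$gc[pairs$f[take]],
    gc_reverse = rev_$gc[pairs$r[take]],
    forward_start = fwd$start[pairs$f[take]],
    reverse_end = rev_$end[pairs$r[take]],
    product_size = product[take],
    penalty = penalty[take],
    rank = seq_along(take),
    m13_tailed = FALSE,
    stringsAsFactors = FALSE)
}

#' Add the M13(-21) tail to the forward primer of a pair
#'
#' Prefixes the forward primer with the 18-base universal tail; the reverse
#' primer is unchanged and the expected product grows by the tail length.
#'
#' @param pair one or more rows from [design_primers()].
#' @param tail tail sequence (default [M13_TAIL]).
#' @return the rows with `forward` tailed, `product_size` increased and
#'   `m13_tailed` set.
#' @export
add_m13_tail <- function(pair, tail = M13_TAIL) {
  if (any(pair$m13_tailed)) stop("primer pair is already M13-tailed")
  pair$forward <- paste0(tail, pair$forward)
  pair$product_size <- pair$product_size + nchar(tail)
  pair$m13_tailed <- TRUE
  pair
}

#' Design primers for every locus in a table
#'
#' @param seqs named character vector of sequences.
#' @param loci locus table from [detect_ssrs()].
#' @param constraints a [primer_constraints()].
#' @param n_best pairs kept per locus.
#' @return list with `primers` (combined table, `rank` 1..n per locus) and
#'   `failed` (data.frame of locus ids with failure reasons).
#' @export
design_primers_all <- function(seqs, loci,
                               constraints = primer_constraints(),
                               n_best = 3L) {
  out <- list(); fail <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    lid <- sprintf("%s:%d-%d", locus$seq_id, locus$start, locus$end)
    fl <- check_flanks(seqs[[locus$seq_id]], locus, constraints)
    if (!fl$ok) {
      fail[[length(fail) + 1L]] <- data.frame(locus_id = lid,
                                              reason = fl$reason)
      next
    }
    pp <- design_primers(seqs[[locus$seq_id]], locus, constraints, n_best)
    if (nrow(pp) == 0L) {
      fail[[length(fail) + 1L]] <- data.frame(locus_id = lid,
                                              reason = attr(pp, "reason"))
    } else {
      out[[length(out) + 1L]] <- pp
    }
  }
  list(primers = if (length(out)) do.call(rbind, out) else data.frame(),
       failed = if (length(fail)) do.call(rbind, fail) else data.frame())
}
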