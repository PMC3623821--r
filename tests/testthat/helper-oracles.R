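# Independent oracles used to verify the implementation. These are written
# as plain, slow, obviously-correct routines and deliberately share no code
# path with the package internals they check.

# ---- brute-force SSR enumeration ------------------------------------------
# Tests every (start, period) pair by direct substring comparison: a locus
# is reported at start i, period p, when the p-word at i is primitive, at
# least min_repeats full copies follow, and i is the leftmost position of
# its repeat run.
oracle_primitive <- function(motif) {
  n <- nchar(motif)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L && paste(rep(substr(motif, 1, d), n / d),
                              collapse = "") == motif) return(FALSE)
  }
  TRUE
}

oracle_find_ssrs <- function(seq, preset) {
  L <- nchar(seq)
  found <- list()
  for (k in seq_along(preset$periods)) {
    p <- preset$periods[k]
    min_rep <- preset$min_repeats[k]
    if (L < 2L * p) next
    starts <- seq_len(L - 2L * p + 1L)
    w1 <- substring(seq, starts, starts + p - 1L)
    w2 <- substring(seq, starts + p, starts + 2L * p - 1L)
    cand <- starts[w1 == w2 & !grepl("[^ACGT]", w1)]
    for (i in cand) {
      motif <- substr(seq, i, i + p - 1L)
      # leftmost run position: the character p before the run's end of the
      # previous position must not continue the periodicity
      if (i > 1L) {
        prev <- substr(seq, i - 1L, i - 1L)
        ahead <- substr(seq, i - 1L + p, i - 1L + p)
        if (prev == ahead && prev %in% c("A", "C", "G", "T")) next
      }
      cnt <- 1L
      while (i + (cnt + 1L) * p - 1L <= L &&
             substr(seq, i + cnt * p, i + (cnt + 1L) * p - 1L) == motif) {
        cnt <- cnt + 1L
      }
      if (cnt < min_rep) next
      if (!oracle_primitive(motif)) next
      len <- cnt * p
      if (!is.null(preset$min_total_length) &&
          len <= preset$min_total_length) next
      found[[length(found) + 1L]] <-
        data.frame(motif = motif, repeat_count = cnt, start = i,
                   end = i + len - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) {
    return(data.frame(motif = character(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0)))
  }
  df <- do.call(rbind, found)
  df <- df[order(df$start, df$end, nchar(df$motif)), , drop = FALSE]
  df <- df[!duplicated(paste(df$start, df$end)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- exhaustive Smith-Waterman with traceback -----------------------------
# match +1, mismatch -1, linear gap -2; N/ambiguity never matches. Returns
# the match count on the best-scoring local alignment.
oracle_local_matches <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  M <- matrix(0L, n + 1L, m + 1L)   # matches on the best path to each cell
  best <- 0; bestM <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      is_match <- A[i] == B[j] && A[i] %in% c("A", "C", "G", "T")
      diag <- H[i, j] + if (is_match) 1 else -1
      up <- H[i, j + 1L] - 2
      lf <- H[i + 1L, j] - 2
      sc <- max(0, diag, up, lf)
      H[i + 1L, j + 1L] <- sc
      M[i + 1L, j + 1L] <- if (sc == 0) 0L
        else if (sc == diag) M[i, j] + as.integer(is_match)
        else if (sc == up) M[i, j + 1L]
        else M[i + 1L, j]
      if (sc > best || (sc == best && M[i + 1L, j + 1L] > bestM)) {
        best <- sc; bestM <- M[i + 1L, j + 1L]
      }
    }
  }
  bestM
}

# ---- Fisher enumeration ----------------------------------------------------
oracle_fisher_greater <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; N <- m1 + m2
  ks <- max(0, n1 - m2):min(m1, n1)
  probs <- choose(m1, ks) * choose(m2, n1 - ks) / choose(N, n1)
  sum(probs[ks >= a])
}

# ---- direct BH step-up formula --------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[o][i:m] / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# ---- independently coded nearest-neighbor Tm ------------------------------
# Same published unified parameter set, written out separately and summed
# in a different style.
oracle_nn_tm <- function(oligo, conc_nM = 50, na_mM = 50) {
  tab <- list(
    AA = c(-7.9, -22.2), TT = c(-7.9, -22.2), AT = c(-7.2, -20.4),
    TA = c(-7.2, -21.3), CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
    GT = c(-8.4, -22.4), AC = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    AG = c(-7.8, -21.0), GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
    CG = c(-10.6, -27.2), GC = c(-9.8, -24.4), GG = c(-8.0, -19.9),
    CC = c(-8.0, -19.9))
  n <- nchar(oligo)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    v <- tab[[substr(oligo, i, i + 1)]]
    dH <- dH + v[1]; dS <- dS + v[2]
  }
  for (end in c(substr(oligo, 1, 1), substr(oligo, n, n))) {
    if (end %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * dH / (dS + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

# ---- independent primer-pair re-enumeration -------------------------------
# Loops over every window pair with plain for-loops and the documented
# penalty; returns the minimum penalty found (Inf when infeasible).
oracle_best_pair_penalty <- function(seq, locus, constraints) {
  L <- nchar(seq)
  w <- constraints$weights
  cand <- function(lo, hi) {
    out <- list()
    for (start in seq(lo, hi)) {
      for (size in constraints$size_range[1]:constraints$size_range[2]) {
        end <- start + size - 1L
        if (end > hi) next
        o <- substr(seq, start, end)
        if (grepl("[^ACGT]", o)) next
        gc <- estssr::gc_percent(o)
        if (gc < constraints$gc_range[1] || gc > constraints$gc_range[2]) next
        tm <- estssr::melting_temperature(o, constraints$tm_method)
        if (tm < constraints$tm_range[1] || tm > constraints$tm_range[2]) next
        kk <- constraints$self_comp_k
        n <- nchar(o)
        selfc <- FALSE
        if (n >= kk) {
          km <- substring(o, 1:(n - kk + 1), kk:n)
          selfc <- any(estssr::revcomp(km) %in% km)
        }
        if (selfc) next
        out[[length(out) + 1L]] <- list(start = start, end = end,
                                        size = size, gc = gc, tm = tm)
      }
    }
    out
  }
  fwd <- cand(max(1L, locus$end + constraints$size_range[1] -
                    constraints$product_range[2] + 1L), locus$start - 1L)
  rv <- cand(locus$end + 1L,
             min(L, locus$start - constraints$size_range[1] +
                   constraints$product_range[2] - 1L))
  best <- Inf
  for (f in fwd) for (r in rv) {
    prod <- r$end - f$start + 1L
    if (prod < constraints$product_range[1] ||
        prod > constraints$product_range[2]) next
    pen <- w[["size"]] * (abs(f$size - constraints$size_opt) +
                          abs(r$size - constraints$size_opt)) +
      w[["tm"]] * (abs(f$tm - constraints$tm_opt) +
                   abs(r$tm - constraints$tm_opt)) +
      w[["gc"]] * (abs(f$gc - constraints$gc_opt) +
                   abs(r$gc - constraints$gc_opt)) +
      w[["tm_diff"]] * abs(f$tm - r$tm)
    if (pen < best) best <- pen
  }
  best
}

# ---- misc -----------------------------------------------------------------
# enumerate canonical class count for one period by direct grouping
oracle_class_count <- function(period) {
  words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")),
                                           period)))
  words <- words[vapply(words, oracle_primitive, logical(1))]
  classes <- vapply(words, function(wd) {
    rots <- function(x) {
      n <- nchar(x)
      vapply(seq_len(n) - 1L, function(k)
        paste0(substr(x, k + 1, n), substr(x, 1, k)), character(1))
    }
    min(c(rots(wd), rots(estssr::revcomp(wd))))
  }, character(1))
  length(unique(classes))
}

# random sequence with an optional planted repeat, for oracle-vs-detector
# comparisons (does not reject SSRs in the background: both routes see the
# same input whatever it contains)
random_test_seq <- function(L, plant_prob = 0.3) {
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  if (runif(1) < plant_prob) {
    p <- sample(2:6, 1)
    cnt <- sample(3:12, 1)
    motif <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
                   collapse = "")
    run <- strrep(motif, cnt)
    if (nchar(run) + 2 < L) {
      at <- sample.int(L - nchar(run) - 1L, 1)
      s <- paste0(substr(s, 1, at), run, substr(s, at + nchar(run) + 1L, L))
    }
  }
  s
}

# compare detector and oracle locus tables on the shared columns
expect_same_loci <- function(det, orc) {
  det2 <- det[order(det$start, det$end), c("motif", "repeat_count",
                                           "start", "end")]
  rownames(det2) <- NULL
  orc2 <- orc[order(orc$start, orc$end), c("motif", "repeat_count",
                                           "start", "end")]
  rownames(orc2) <- NULL
  expect_equal(det2, orc2)
}
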