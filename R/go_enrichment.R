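# GO-term overrepresentation among SSR-containing sequences: Fisher's exact
# test on 2x2 tables (log-space hypergeometric tail, overflow-safe for
# margins up to 1e6) with Benjamini-Hochberg FDR control. The annotation
# map is taken as given; no GO-graph ancestor propagation is performed.

#' Fisher's exact test on a 2x2 table
#'
#' Table layout: `a` = subset with the term, `b` = background-only with the
#' term, `c` = subset without it, `d` = neither. One-sided (`"greater"`,
#' the default) sums hypergeometric probabilities of tables at least as
#' extreme in `a`; two-sided sums all tables with probability not exceeding
#' the observed one (with a 1e-7 relative tolerance). Computation is in
#' log space via `lchoose`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param sided `"greater"` or `"two.sided"`.
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + b          # total with the term
  m2 <- c + d          # total without
  n1 <- a + c          # subset size
  N <- m1 + m2
  lo <- max(0L, n1 - m2)
  hi <- min(m1, n1)
  k <- lo:hi
  logp <- lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(N, n1)
  if (sided == "greater") {
    sel <- k >= a
  } else {
    obs <- logp[match(a, k)]
    sel <- logp <= obs + 1e-7
  }
  # log-sum-exp over the selected tail
  lp <- logp[sel]
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up construction `q_(i) = min_{j >= i} m p_(j) / j`, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' GO-term overrepresentation in a subset of sequences
#'
#' One Fisher test per term present in the background map; the fold change
#' is the term's relative frequency in the subset over its relative
#' frequency in the whole background. Results are sorted by q-value, then
#' decreasing fold.
#'
#' @param subset_ids sequence ids forming the subset (must all occur in the
#'   background map's universe).
#' @param annotations data.frame with columns `seq_id`, `term`
#'   ([read_annotations()]); its distinct `seq_id`s define the background.
#' @param universe optional explicit background id vector (sequences with
#'   no annotation included); defaults to the distinct annotated ids.
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param sided test sidedness, see [fisher_exact_2x2()].
#' @return data.frame with columns `term`, `a`, `b`, `c`, `d`, `fold`,
#'   `p`, `q`, `significant`.
#' @export
enrich <- function(subset_ids, annotations, universe = NULL,
                   fdr_alpha = 0.05, sided = "greater") {
  universe <- unique(universe %||% annotations$seq_id)
  subset_ids <- unique(subset_ids)
  if (!length(subset_ids)) stop("subset is empty")
  missing_ids <- setdiff(subset_ids, universe)
  if (length(missing_ids)) {
    stop("subset ids absent from background: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  ann <- annotations[annotations$seq_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("seq_id", "term")])
  N <- length(universe)
  S <- length(subset_ids)
  terms <- unique(ann$term)
  in_subset <- ann$seq_id %in% subset_ids
  a_vec <- tapply(in_subset, ann$term, sum)[terms]
  tot_vec <- tapply(rep(1L, nrow(ann)), ann$term, sum)[terms]
  rows <- lapply(seq_along(terms), function(k) {
    a <- as.integer(a_vec[k])
    tot <- as.integer(tot_vec[k])
    b <- tot - a
    c_ <- S - a
    d <- N - a - b - c_
    data.frame(term = terms[k], a = a, b = b, c = c_, d = d,
               fold = (a / S) / (tot / N),
               p = fisher_exact_2x2(a, b, c_, d, sided = sided),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_alpha
  out[order(out$q, -out$fold, out$term), , drop = FALSE]
}
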