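# Per-locus diversity statistics from co-dominant genotype tables: allele
# counts and frequencies, expected heterozygosity, polymorphism information
# content, polymorphism calls, and the polymorphism-versus-repeat-count
# logistic regression. Missing calls are dropped per locus (pairwise
# deletion); alleles are opaque integer labels.

#' Construct a genotype table
#'
#' @param individuals character vector of individual ids.
#' @param loci character vector of locus ids.
#' @param a1,a2 integer matrices (individual x locus) of the two allele
#'   labels per call; both NA where the call is missing.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, loci, a1, a2) {
  stopifnot(nrow(a1) == length(individuals), ncol(a1) == length(loci),
            identical(dim(a1), dim(a2)),
            identical(is.na(a1), is.na(a2)))
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% missing)\n",
              length(x$individuals), length(x$loci),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Allele frequencies at one locus
#'
#' `P_i` is the count of allele `i` over twice the number of typed
#' individuals; missing calls are excluded entirely.
#'
#' @param gt a [genotype_table()].
#' @param locus locus id.
#' @return named numeric vector of allele frequencies (names are allele
#'   labels), summing to 1.
#' @export
allele_frequencies <- function(gt, locus) {
  j <- match(locus, gt$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  alleles <- c(gt$a1[, j], gt$a2[, j])
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles)) stop("locus has no typed individuals: ", locus)
  tab <- table(alleles)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

.check_freqs <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-9 || any(freqs < 0)) {
    stop("allele frequencies must be non-negative and sum to 1")
  }
  invisible(freqs)
}

#' Polymorphism information content
#'
#' Two formulas are available. `"printed"` (the default) is
#' `1 - sum(P_i^2)` -- numerically identical to expected heterozygosity.
#' `"botstein"` subtracts the additional pairwise term:
#' `1 - sum(P_i^2) - sum_{i<j} 2 P_i^2 P_j^2`.
#'
#' @param freqs normalised allele frequencies.
#' @param formula `"printed"` or `"botstein"`.
#' @return PIC value in \[0, 1).
#' @export
pic <- function(freqs, formula = c("printed", "botstein")) {
  formula <- match.arg(formula)
  .check_freqs(freqs)
  p2 <- freqs^2
  base <- 1 - sum(p2)
  if (formula == "printed") return(base)
  base - (sum(p2)^2 - sum(p2^2))  # subtracts sum_{i != j} p_i^2 p_j^2
}

#' Expected heterozygosity
#'
#' `"He"` is `1 - sum(P_i^2)`; `"uHe"` applies the small-sample correction
#' `2n / (2n - 1)` with `n` the number of typed individuals.
#'
#' @param freqs normalised allele frequencies.
#' @param variant `"He"` or `"uHe"`.
#' @param n_typed number of typed individuals (required for `"uHe"`).
#' @return heterozygosity value.
#' @export
expected_heterozygosity <- function(freqs, variant = c("He", "uHe"),
                                    n_typed = NULL) {
  variant <- match.arg(variant)
  .check_freqs(freqs)
  he <- 1 - sum(freqs^2)
  if (variant == "He") return(he)
  if (is.null(n_typed) || n_typed < 2L) {
    stop("uHe needs n_typed >= 2")
  }
  (2 * n_typed) / (2 * n_typed - 1) * he
}

#' Per-locus diversity table
#'
#' @param gt a [genotype_table()].
#' @return data.frame with one row per locus: `locus`, `n` (typed
#'   individuals), `n_alleles`, `He`, `uHe`, `PIC_printed`,
#'   `PIC_botstein`, `polymorphic`.
#' @export
locus_diversity <- function(gt) {
  rows <- lapply(gt$loci, function(loc) {
    j <- match(loc, gt$loci)
    typed <- !is.na(gt$a1[, j])
    n <- sum(typed)
    if (n == 0L) stop("locus has no typed individuals: ", loc)
    f <- allele_frequencies(gt, loc)
    data.frame(locus = loc, n = n, n_alleles = length(f),
               He = expected_heterozygosity(f, "He"),
               uHe = if (n >= 2L) expected_heterozygosity(f, "uHe", n)
                     else NA_real_,
               PIC_printed = pic(f, "printed"),
               PIC_botstein = pic(f, "botstein"),
               polymorphic = length(f) >= 2L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Polymorphism calls and rate
#'
#' A locus is polymorphic when at least two distinct alleles are observed
#' among its typed individuals.
#'
#' @param gt a [genotype_table()].
#' @return list with `polymorphic` (named logical per locus), `n_polymorphic`,
#'   `n_loci`, and `rate_pct` (percentage, one decimal).
#' @export
call_polymorphic <- function(gt) {
  poly <- vapply(gt$loci, function(loc) {
    length(allele_frequencies(gt, loc)) >= 2L
  }, logical(1))
  list(polymorphic = poly,
       n_polymorphic = sum(poly),
       n_loci = length(poly),
       rate_pct = round(.pct(sum(poly), length(poly)), 1))
}

#' Logistic regression of polymorphism on repeat count
#'
#' Fits polymorphic (0/1) on repeat count by maximum likelihood
#' (iteratively reweighted least squares, at most 25 iterations, tolerance
#' 1e-8) and reports Wald tests per coefficient together with the Pearson
#' (point-biserial) correlation between repeat count and the 0/1 outcome.
#' Complete separation is flagged and no finite slope is reported.
#'
#' @param repeat_counts numeric vector of repeat counts.
#' @param polymorphic logical (or 0/1) outcome vector of the same length.
#' @return object of class `polymorphism_regression` with fields `slope`,
#'   `intercept`, `z`, `p` (named vectors), `pearson_r`, `n`, `converged`,
#'   `separated`.
#' @export
polymorphism_regression <- function(repeat_counts, polymorphic) {
  y <- as.integer(polymorphic)
  x <- as.numeric(repeat_counts)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 10L) stop("need at least 10 observations")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25L)))
  co <- summary(fit)$coefficients
  # separation diagnostics: a perfectly separating predictor drives the
  # residual deviance to zero (fitted probabilities to 0/1) or the IRLS
  # estimates off to infinity
  eta <- abs(stats::predict(fit, type = "link"))
  separated <- !fit$converged || max(eta) > 30 || abs(co["x", 1]) > 50 ||
    fit$deviance < 1e-6
  r <- stats::cor(x, y)
  structure(list(
    slope = if (separated) NA_real_ else unname(co["x", 1]),
    intercept = if (separated) NA_real_ else unname(co["(Intercept)", 1]),
    z = stats::setNames(co[, 3], c("intercept", "slope")),
    p = stats::setNames(co[, 4], c("intercept", "slope")),
    pearson_r = r,
    n = length(y),
    converged = fit$converged,
    separated = separated,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    fit = fit), class = "polymorphism_regression")
}

#' @export
print.polymorphism_regression <- function(x, ...) {
  cat("Logistic regression of polymorphism on repeat count\n")
  if (x$separated) {
    cat("  complete separation detected; no finite slope reported\n")
  } else {
    cat(sprintf("  slope     : %.4f (z = %.2f, p = %.3g)\n",
                x$slope, x$z[["slope"]], x$p[["slope"]]))
    cat(sprintf("  intercept : %.4f\n", x$intercept))
  }
  cat(sprintf("  point-biserial r : %.3f  (n = %d)\n", x$pearson_r, x$n))
  invisible(x)
}
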