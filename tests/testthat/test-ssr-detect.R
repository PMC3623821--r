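# Detection of perfect microsatellites, canonical classes, compounds and
# summaries.

test_that("canonical motif classes are rotation- and strand-invariant", {
  expect_equal(canonical_motif("GA"), "AG/CT")
  expect_equal(canonical_motif("CTT"), "AAG/CTT")
  expect_equal(canonical_motif("TC"), "AG/CT")   # reverse strand phase
  expect_equal(canonical_motif("AT"), "AT/AT")   # self-complementary class
  # invariance over every rotation and the reverse complement, several motifs
  for (motif in c("AG", "AAG", "ACGT", "AACGT", "AACGTC")) {
    ref <- canonical_motif(motif)
    n <- nchar(motif)
    rots <- vapply(seq_len(n) - 1L, function(k)
      paste0(substr(motif, k + 1, n), substr(motif, 1, k)), character(1))
    for (r in c(rots, revcomp(rots))) {
      expect_equal(canonical_motif(r), ref)
    }
  }
  expect_error(canonical_motif("ATAT"), "primitive")
  expect_error(canonical_motif("A"), "length")
})

test_that("class counts per period match exhaustive enumeration", {
  # group every primitive word by the package classifier and compare the
  # number of groups with an independent enumeration
  for (p in 2:6) {
    words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), p)))
    words <- words[vapply(words, is_primitive, logical(1))]
    n_impl <- length(unique(vapply(words, canonical_motif, character(1))))
    expect_equal(n_impl, oracle_class_count(p))
  }
  counts <- vapply(2:6, oracle_class_count, integer(1))
  expect_equal(counts, c(4L, 10L, 33L, 102L, 350L))
})

test_that("primitivity detects motif powers", {
  expect_false(is_primitive("ATAT"))
  expect_true(is_primitive("AAG"))
  expect_false(is_primitive("AAA"))
  expect_false(is_primitive("ACACAC"))
  words4 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4)))
  expect_equal(sum(vapply(words4, is_primitive, logical(1))), 4^4 - 4^2)
})

test_that("perfect-SSR detection honours preset thresholds and coordinates", {
  p <- builtin_presets()
  loci <- find_perfect_ssrs(paste0("C", strrep("AG", 10), "C"), p$misa_default)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motif, "AG")
  expect_equal(loci$canonical_class, "AG/CT")
  expect_equal(loci$repeat_count, 10L)
  expect_equal(c(loci$start, loci$end), c(2L, 21L))
  # nine AT repeats: below the default di threshold, above Cardle's
  expect_equal(nrow(find_perfect_ssrs(strrep("AT", 9), p$misa_default)), 0L)
  cr <- find_perfect_ssrs(strrep("AT", 9), p$cardle)
  expect_equal(cr$repeat_count, 9L)
  # trailing partial copies do not count and do not extend the locus
  tr <- find_perfect_ssrs(paste0(strrep("AAG", 7), "AA"), p$misa_default)
  expect_equal(tr$repeat_count, 7L)
  expect_equal(tr$end, 21L)
  # N breaks a run
  expect_equal(nrow(find_perfect_ssrs(
    paste0(strrep("AG", 6), "N", strrep("AG", 6)), p$misa_default)), 0L)
  # len20 preset requires length strictly > 20 bp
  expect_equal(nrow(find_perfect_ssrs(strrep("AG", 10), p$len20)), 0L)
  expect_equal(find_perfect_ssrs(strrep("AG", 11), p$len20)$length, 22L)
})

test_that("built-in presets carry the documented thresholds", {
  p <- builtin_presets()
  expect_equal(p$misa_default$min_repeats[p$misa_default$periods == 2], 10L)
  expect_equal(p$misa_default$min_repeats[p$misa_default$periods == 6], 3L)
  expect_equal(p$cardle$min_repeats[p$cardle$periods == 5], 3L)
  expect_false(6L %in% p$cardle$periods)
  expect_equal(p$len20$min_total_length, 20L)
  expect_equal(p$misa_default$max_interruption, 100L)
})

test_that("detector agrees with brute-force enumeration on random input", {
  set.seed(101)
  presets <- builtin_presets()
  for (i in 1:150) {
    s <- random_test_seq(sample(100:600, 1))
    for (pr in presets) {
      expect_same_loci(find_perfect_ssrs(s, pr), oracle_find_ssrs(s, pr))
    }
  }
})

test_that("detection is strand-symmetric", {
  set.seed(77)
  pr <- builtin_presets()$misa_default
  for (i in 1:40) {
    s <- random_test_seq(400)
    fwd <- find_perfect_ssrs(s, pr)
    rev_ <- find_perfect_ssrs(revcomp(s), pr)
    expect_equal(nrow(fwd), nrow(rev_))
    if (nrow(fwd)) {
      L <- nchar(s)
      # mirror the forward loci into reverse coordinates and pair them up
      mir <- fwd[order(L - fwd$end + 1L), , drop = FALSE]
      expect_equal(rev_$canonical_class, mir$canonical_class)
      expect_equal(rev_$repeat_count, mir$repeat_count)
      # intervals agree up to a sub-period phase shift: whole-copy
      # trimming anchors at the leftmost base, which is strand-dependent
      # when partial copies flank the run
      p <- nchar(mir$motif)
      expect_true(all(abs(rev_$start - (L - mir$end + 1L)) < p))
      expect_true(all(abs(rev_$end - (L - mir$start + 1L)) < p))
    }
  }
})

test_that("extracting a locus interval re-detects the same motif and count", {
  set.seed(55)
  pr <- builtin_presets()$misa_default
  hits <- 0L
  for (i in 1:60) {
    s <- random_test_seq(400, plant_prob = 0.8)
    loci <- find_perfect_ssrs(s, pr)
    for (j in seq_len(nrow(loci))) {
      sub <- substr(s, loci$start[j], loci$end[j])
      re <- find_perfect_ssrs(sub, pr)
      expect_equal(re$motif, loci$motif[j])
      expect_equal(re$repeat_count, loci$repeat_count[j])
      expect_equal(c(re$start, re$end), c(1L, nchar(sub)))
      hits <- hits + 1L
    }
  }
  expect_gt(hits, 10L)  # the property must actually have been exercised
})

test_that("compound merging chains loci within the interruption limit", {
  pr <- builtin_presets()$misa_default
  mk <- function(gaps) {
    # synthetic locus table: (AG)10 runs separated by the given gaps
    start <- 1L
    rows <- list()
    for (k in seq_along(c(0, gaps))) {
      rows[[k]] <- data.frame(seq_id = "s", preset = "misa_default",
                              motif = "AG", canonical_class = "AG/CT",
                              repeat_count = 10L, start = start,
                              end = start + 19L, length = 20L)
      if (k <= length(gaps)) start <- start + 20L + gaps[k]
    }
    do.call(rbind, rows)
  }
  r1 <- merge_compound(mk(50L), pr)
  expect_equal(nrow(r1$compounds), 1L)
  expect_equal(r1$compounds$n_members, 2L)
  expect_equal(r1$compounds$gaps, "50")
  r2 <- merge_compound(mk(101L), pr)   # boundary: strictly greater gap
  expect_equal(nrow(r2$compounds), 0L)
  expect_equal(nrow(r2$singletons), 2L)
  r3 <- merge_compound(mk(100L), pr)   # boundary: equal gap chains
  expect_equal(r3$compounds$n_members, 2L)
  r4 <- merge_compound(mk(c(10L, 10L)), pr)
  expect_equal(r4$compounds$n_members, 3L)
  # conservation: members + singletons = input loci
  loci <- mk(c(10L, 150L, 5L))
  r5 <- merge_compound(loci, pr)
  expect_equal(nrow(r5$compound_members) + nrow(r5$singletons), nrow(loci))
  # overlap is an upstream error
  bad <- mk(50L); bad$start[2] <- 10L; bad$end[2] <- 29L
  expect_error(merge_compound(bad, pr), "overlap")
})

test_that("summaries report density, frequency and class shares", {
  expect_equal(ssr_density_kb(62650653, 4202), 62650653 / 4202 / 1000)
  expect_true(is.na(ssr_density_kb(1000, 0)))
  loci <- rbind(
    data.frame(seq_id = "a", preset = "x", motif = "AG",
               canonical_class = "AG/CT", repeat_count = 10L, start = 1L,
               end = 20L, length = 20L),
    data.frame(seq_id = "a", preset = "x", motif = "AAG",
               canonical_class = "AAG/CTT", repeat_count = 6L, start = 100L,
               end = 117L, length = 18L),
    data.frame(seq_id = "b", preset = "x", motif = "GA",
               canonical_class = "AG/CT", repeat_count = 11L, start = 1L,
               end = 22L, length = 22L))
  s <- summarize_ssrs(loci, NULL, total_bases = 30000, n_sequences = 10)
  expect_equal(s$n_loci, 3L)
  expect_equal(s$by_period$p2, 2L)
  expect_equal(s$by_class_pct[["AG/CT"]], 100 * 2 / 3)
  expect_equal(s$n_single_ssr_sequences, 1L)
  expect_equal(s$n_multi_ssr_sequences, 1L)
  expect_equal(s$density_kb_per_ssr, 10)
  expect_equal(s$frequency_pct, 20)
  s0 <- summarize_ssrs(.empty_loci <- loci[0, ], NULL, 1000, 5)
  expect_false(s0$density_defined)
  expect_true(is.na(s0$density_kb_per_ssr))
})
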