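# EST cleanup: trimming, length filter, contaminant screen, clustering,
# accounting.

test_that("terminal poly-A/T trimming removes qualifying runs only", {
  cfg <- preprocess_config(trim_run_min = 10L)
  expect_equal(unname(trim_poly_at(paste0(strrep("T", 10), "ACGTACGT"), cfg)),
               "ACGTACGT")
  expect_equal(unname(trim_poly_at("ACGTACGT", cfg)), "ACGTACGT")
  expect_equal(unname(trim_poly_at(paste0("ACGT", strrep("A", 9)), cfg)),
               paste0("ACGT", strrep("A", 9)))   # run below threshold
  # both ends, both bases, applied iteratively
  s <- paste0(strrep("A", 12), strrep("T", 11), "GGCC", strrep("A", 15))
  expect_equal(unname(trim_poly_at(s, cfg)), "GGCC")
  # interior runs untouched
  s2 <- paste0("GG", strrep("A", 20), "CC")
  expect_equal(unname(trim_poly_at(s2, cfg)), s2)
})

test_that("trimming is idempotent on random poly-tailed sequences", {
  set.seed(9)
  cfg <- preprocess_config()
  for (i in 1:50) {
    s <- paste0(strrep(sample(c("A", "T", ""), 1), sample(5:20, 1)),
                paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
                strrep(sample(c("A", "T", ""), 1), sample(5:20, 1)))
    once <- trim_poly_at(s, cfg)
    expect_identical(trim_poly_at(once, cfg), once)
  }
})

test_that("length filter is strict below the minimum", {
  cfg <- preprocess_config(min_length = 100L)
  seqs <- c(short = strrep("A", 99), exact = strrep("C", 100),
            long = strrep("G", 150))
  fs <- filter_short(seqs, cfg)
  expect_equal(fs$removed_ids, "short")
  expect_setequal(names(fs$kept), c("exact", "long"))
  empty <- filter_short(character(0), cfg)
  expect_length(empty$removed_ids, 0L)
})

test_that("contaminant screening removes by identity and coverage", {
  set.seed(31)
  ref <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  cfg <- preprocess_config()
  contaminants <- list(vector = c(vec1 = ref))
  # verbatim substring: full coverage, identity 1 -> removed as vector
  seqs <- c(sub = substr(ref, 101, 300))
  sc <- screen_contaminants(seqs, contaminants, cfg)
  expect_equal(sc$removed_ids$vector, "sub")
  # unrelated random sequence: kept (no shared 12-mer is near-certain at
  # this size, and identity is far below threshold regardless)
  rnd <- c(r1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  expect_equal(names(screen_contaminants(rnd, contaminants, cfg)$kept), "r1")
  # ~50% identical to the reference: kept; verified against the exhaustive
  # dynamic-programming alignment oracle
  half <- strsplit(substr(ref, 1, 200), "")[[1]]
  flip <- seq(1, 200, by = 2)
  half[flip] <- vapply(half[flip], function(ch)
    setdiff(c("A", "C", "G", "T"), ch)[1], character(1))
  halfseq <- c(h1 = paste(half, collapse = ""))
  oracle_ident <- oracle_local_matches(halfseq[[1]], ref) / 200
  expect_lt(oracle_ident, 0.9)
  expect_equal(names(screen_contaminants(halfseq, contaminants, cfg)$kept),
               "h1")
  # unknown class label is a configuration error
  expect_error(screen_contaminants(seqs, list(bacteria = c(x = ref)), cfg),
               "unknown contaminant class")
  # first matching class in fixed order is charged
  both <- list(vector = c(v = ref), chloroplast = c(c = ref))
  sc2 <- screen_contaminants(seqs, both, cfg)
  expect_equal(sc2$removed_ids$vector, "sub")
  expect_length(sc2$removed_ids$chloroplast, 0L)
})

test_that("greedy clustering groups by identity over the shorter sequence", {
  set.seed(12)
  cfg <- preprocess_config(cluster_identity = 0.90)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  # identical pair: one cluster, representative is the first id at equal length
  cl <- cluster_redundant(c(b = base, a = base), cfg)
  expect_equal(names(cl$representatives), "a")
  expect_setequal(cl$clusters$a, c("a", "b"))
  # a 0.89-identity pair (22 isolated interior mismatches over 200 bp) at
  # threshold 0.90 founds two clusters; identity confirmed by the DP oracle
  mut <- strsplit(base, "")[[1]]
  pos <- seq(9, 198, by = 9)
  mut[pos] <- vapply(mut[pos], function(ch)
    setdiff(c("A", "C", "G", "T"), ch)[1], character(1))
  mutseq <- paste(mut, collapse = "")
  ident <- local_identity(base, mutseq)
  expect_lt(ident, 0.90)
  expect_equal(oracle_local_matches(base, mutseq) / 200,
               ident, tolerance = 1e-12)
  cl2 <- cluster_redundant(c(x = base, y = mutseq), cfg)
  expect_length(cl2$representatives, 2L)
  # planted fixture: 10 originals + 5 exact duplicates -> 10 representatives
  fx <- make_est_set(n_sequences = 10, duplicate_rate = 0.5, seed = 99)
  cl3 <- cluster_redundant(fx$sequences, cfg)
  expect_length(cl3$representatives, 10L)
  # every member reaches the threshold with its representative, and the
  # clustering is deterministic under input permutation of equal data
  for (r in names(cl3$clusters)) {
    for (m in setdiff(cl3$clusters[[r]], r)) {
      expect_gte(local_identity(fx$sequences[[m]], fx$sequences[[r]]), 0.90)
    }
  }
  perm <- sample(length(fx$sequences))
  cl4 <- cluster_redundant(fx$sequences[perm], cfg)
  expect_identical(names(cl3$representatives), names(cl4$representatives))
})

test_that("accounting report conserves counts and rejects impossible ones", {
  rep_ <- build_report(108175, 109,
                       list(vector = 6, chloroplast = 148, mitochondrial = 3),
                       n_clusters = 94090)
  expect_equal(rep_$n_valid, 107909L)
  expect_equal(rep_$n_clusters, 94090L)
  r2 <- build_report(10, 0, list(vector = 0), n_clusters = 10)
  expect_equal(r2$n_valid, 10L)
  expect_error(build_report(5, 4, list(vector = 3), n_clusters = 1),
               "accounting")
  expect_error(build_report(10, 1, list(vector = 1), n_clusters = 9),
               "accounting")
})

test_that("the full preprocessing stage accounts for every input", {
  fx <- make_est_set(n_sequences = 8, duplicate_rate = 0.25,
                     n_contaminants = 3, seed = 17)
  res <- preprocess_ests(fx$sequences, fx$contaminant_refs)
  r <- res$report
  expect_equal(r$n_input,
               r$n_valid + r$n_removed_short +
                 Reduce(`+`, r$n_removed_by_contaminant_class))
  expect_setequal(unlist(r$id_lists$removed_contaminants),
                  fx$truth$contaminant_ids)
  # duplicates collapse: representatives = base sequences
  expect_equal(r$n_clusters, 8L)
  expect_lte(r$n_clusters, r$n_valid)
})

test_that("FASTA round-trips with 60-column wrapping and token ids", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(s1 = strrep("ACGT", 40), s2 = "ACGTACGTAC")
  write_fasta(seqs, tmp)
  lines <- readLines(tmp)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(tmp)
  expect_identical(back, seqs)
  # header id = first whitespace-delimited token
  writeLines(c(">idA description here", "ACGT", "ACGT"), tmp)
  expect_identical(names(read_fasta(tmp)), "idA")
})
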