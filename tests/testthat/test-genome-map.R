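# Hit parsing, best-hit selection, coordinate projection and CDS/UTR
# classification.

write_hits <- function(df, path) {
  write.table(data.frame(df$query_id, df$subject_id,
                         sprintf("%.2f", df$identity * 100), df$aln_length,
                         df$mismatches, df$gap_opens, df$query_start,
                         df$query_end, df$subject_start, df$subject_end,
                         df$evalue, df$bitscore),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

one_hit <- function(qid = "q1", sid = "chr1", ident = 0.95, qs = 1L,
                    qe = 100L, ss = 1001L, se = 1100L, bits = 200,
                    len = 100L) {
  data.frame(query_id = qid, subject_id = sid, identity = ident,
             aln_length = len, mismatches = 0L, gap_opens = 0L,
             query_start = qs, query_end = qe, subject_start = ss,
             subject_end = se, evalue = 0, bitscore = bits,
             strand = if (ss > se) "-" else "+",
             stringsAsFactors = FALSE)
}

loc <- function(seq_id, start, end, motif = "AG") {
  data.frame(seq_id = seq_id, preset = "p", motif = motif,
             canonical_class = "AG/CT", repeat_count = 10L,
             start = start, end = end, length = end - start + 1L,
             stringsAsFactors = FALSE)
}

test_that("tabular hits parse with strand convention and line diagnostics", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_hits(rbind(one_hit(ident = 0.801),
                   one_hit(qid = "q2", ss = 500L, se = 401L)), tmp)
  hits <- read_blast_hits(tmp)
  expect_equal(hits$identity[1], 0.801)
  expect_equal(hits$strand, c("+", "-"))
  writeLines(c(paste(rep("x", 12), collapse = "\t"),
               paste(rep("x", 11), collapse = "\t")), tmp)
  expect_error(read_blast_hits(tmp), "line 2")
})

test_that("best-hit selection applies the strict identity cut and tie-breaks", {
  cfg <- mapping_config()
  h <- one_hit(ident = 0.799)
  expect_equal(nrow(select_best_hit(h, cfg)), 0L)
  expect_equal(nrow(select_best_hit(one_hit(ident = 0.8), cfg)), 0L)  # strict
  h2 <- rbind(one_hit(bits = 100), one_hit(bits = 90, ss = 2001L, se = 2100L))
  expect_equal(select_best_hit(h2, cfg)$bitscore, 100)
  h3 <- rbind(one_hit(bits = 100, len = 400L),
              one_hit(bits = 100, len = 500L, ss = 3001L, se = 3500L))
  expect_equal(select_best_hit(h3, cfg)$aln_length, 500L)
  h4 <- rbind(one_hit(sid = "chr2"), one_hit(sid = "chr1", ss = 9001L,
                                             se = 9100L))
  expect_equal(select_best_hit(h4, cfg)$subject_id, "chr1")
})

test_that("affine projection maps plus and minus strands exactly", {
  hit <- one_hit(qs = 11L, qe = 110L, ss = 1001L, se = 1100L)
  pl <- project_locus(loc("q1", 18, 37), hit)
  expect_equal(pl$genomic_start, 1001L + 7L)
  expect_equal(pl$genomic_end, 1001L + 26L)
  expect_equal(pl$strand, "+")
  # locus sticking out of the hit is unplaced
  out <- project_locus(loc("q1", 100, 113), hit)
  expect_equal(out$region_class, "unplaced")
  expect_error(project_locus(loc("q2", 18, 37), hit), "different queries")
  # minus strand: verify against the exhaustive position correspondence
  mhit <- one_hit(qs = 1L, qe = 60L, ss = 560L, se = 501L, len = 60L)
  ml <- loc("q1", 21, 30)
  pl2 <- project_locus(ml, mhit)
  expect_equal(pl2$strand, "-")
  # brute-force map: query position q pairs with subject 560 - (q - 1)
  positions <- vapply(21:30, function(q) 560L - (q - 1L), integer(1))
  expect_equal(pl2$genomic_start, min(positions))
  expect_equal(pl2$genomic_end, max(positions))
  # round trip: inverse affine map recovers the query coordinates
  q_back <- mhit$subject_start - c(pl2$genomic_end, pl2$genomic_start) +
    mhit$query_start
  expect_equal(sort(q_back), c(ml$start, ml$end))
})

test_that("refined projection absorbs indels between query and subject", {
  set.seed(19)
  subj <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  # query = subject segment with a 2 bp deletion at position 31..32
  qry <- paste0(substr(subj, 1, 30), substr(subj, 33, 120))
  hit <- one_hit(qs = 1L, qe = nchar(qry), ss = 2001L,
                 se = 2001L + nchar(subj) - 1L, len = nchar(subj))
  locus <- loc("q1", 61, 80)
  naive <- project_locus(locus, hit)
  refined <- project_locus(locus, hit, mapping_config(refine = TRUE),
                           query_seq = qry, subject_seq = subj)
  # after the deletion, true genomic coordinates shift by +2
  expect_equal(refined$genomic_start, naive$genomic_start + 2L)
  expect_equal(refined$genomic_end, naive$genomic_end + 2L)
  expect_identical(substr(subj, refined$genomic_start - 2000L,
                          refined$genomic_end - 2000L),
                   substr(qry, 61, 80))
})

test_that("region classification picks the largest overlap with fixed ties", {
  models <- data.frame(
    chrom = "chr1",
    type = c("five_prime_UTR", "CDS", "three_prime_UTR"),
    start = c(101L, 201L, 501L), end = c(200L, 500L, 600L),
    strand = "+", gene = "g1", stringsAsFactors = FALSE)
  mkpl <- function(gs, ge) {
    data.frame(locus_id = "x", seq_id = "q", locus_start = 1L,
               locus_end = 20L, chromosome = "chr1", genomic_start = gs,
               genomic_end = ge, strand = "+", region_class = "unplaced",
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_region(mkpl(250, 300), models), "CDS")
  expect_equal(classify_region(mkpl(1, 50), models), "intergenic")
  # overlap UTR5 by 14 bp (187..200) and CDS by 10 bp (201..210):
  # confirmed by a per-base labelling oracle
  pl <- mkpl(187, 210)
  labels <- character(0)
  for (g in 187:210) {
    hit <- models$type[models$start <= g & models$end >= g]
    labels <- c(labels, if (length(hit)) hit else "intergenic")
  }
  expect_equal(sum(labels == "five_prime_UTR"), 14L)
  expect_equal(sum(labels == "CDS"), 10L)
  expect_equal(classify_region(pl, models), "UTR5")
  # exact tie goes to CDS
  expect_equal(classify_region(mkpl(191, 210), models), "CDS")
  expect_warning(
    cls <- classify_region(mkpl(1, 10) |>
                             transform(chromosome = "chrZ"), models),
    "chrZ")
  expect_equal(cls, "unplaced")
})

test_that("the synthetic genome fixture round-trips through the full mapper", {
  fx <- make_genome_fixture(n_ests = 25, seed = 4)
  tmp_gff <- withr::local_tempfile(fileext = ".gff3")
  tmp_hits <- withr::local_tempfile(fileext = ".tsv")
  write_gff3(fx$features, tmp_gff)
  write_hits(fx$hits, tmp_hits)
  placements <- map_ssr_loci(fx$loci, read_blast_hits(tmp_hits),
                             read_gene_models(tmp_gff))
  expect_equal(placements$region_class, fx$truth$region_class)
  expect_equal(placements$genomic_start, fx$truth$genomic_start)
  dt <- distribution_table(placements, fx$loci)
  expect_equal(dt$n_placed, 25L)
  expect_equal(dt$placed_pct, 100)
  # the planted 72/18/10 mix is recovered (18 CDS, 4 UTR5, 2 UTR3 + CDS
  # remainder at n = 25)
  expect_equal(dt$by_region$CDS, 19L)
  expect_equal(dt$by_region$UTR5, 4L)
  expect_equal(dt$by_region$UTR3, 2L)
  # classification is total
  expect_true(all(placements$region_class %in%
                    c("CDS", "UTR5", "UTR3", "intergenic", "unplaced")))
  # minus-strand fixture places identically
  fxm <- make_genome_fixture(n_ests = 10, minus_strand_rate = 1, seed = 5)
  write_gff3(fxm$features, tmp_gff)
  write_hits(fxm$hits, tmp_hits)
  pm <- map_ssr_loci(fxm$loci, read_blast_hits(tmp_hits),
                     read_gene_models(tmp_gff))
  expect_equal(pm$region_class, fxm$truth$region_class)
  expect_equal(pm$genomic_start, fxm$truth$genomic_start)
  expect_true(all(pm$strand == "-"))
})
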