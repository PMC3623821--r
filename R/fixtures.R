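# Seeded synthetic-fixture generators. Every generator is a pure function
# of its arguments and seed: the same call gives byte-identical output.
# Ground truth is returned alongside each artifact so detector recall,
# clustering, diversity estimation, tree recovery and enrichment can be
# checked exactly, without any external data.

#' Random DNA string(s)
#'
#' Uniform over A/C/G/T using the current RNG state (callers seed).
#'
#' @param lengths integer vector of sequence lengths.
#' @return character vector of DNA strings.
#' @export
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

# a random primitive motif of the given period
.random_primitive_motif <- function(period) {
  repeat {
    m <- paste(sample(DNA_BASES, period, replace = TRUE), collapse = "")
    if (is_primitive(m)) return(m)
  }
}

# background sequence with no SSR under `preset`, by rejection
.ssr_free_dna <- function(L, preset, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    s <- random_dna(L)
    if (nrow(find_perfect_ssrs(s, preset)) == 0L) return(s)
  }
  stop("could not generate an SSR-free background of length ", L)
}

# insert `run` into `s` at a position leaving >= margin bases each side;
# returns list(seq, start, end)
.insert_run <- function(s, run, margin) {
  L <- nchar(s)
  lo <- margin + 1L
  hi <- L - margin - nchar(run) + 1L
  if (hi < lo) stop("sequence too short for planted SSR")
  at <- sample(lo:hi, 1L)
  list(seq = paste0(substr(s, 1L, at - 1L), run,
                    substr(s, at + nchar(run), L)),
       start = at, end = at + nchar(run) - 1L)
}

#' Synthetic EST set with planted SSRs, duplicates and contaminants
#'
#' Backgrounds are rejection-sampled to contain no SSR under `preset`, so
#' recall and precision of the detector on the planted loci are exact by
#' construction. Each planted sequence is re-screened after insertion and
#' redrawn unless detection returns exactly the planted locus set.
#'
#' @param n_sequences number of base (non-duplicate, non-contaminant)
#'   sequences.
#' @param length_range min/max background length (bp).
#' @param planted data.frame with columns `period` and `count`: one row per
#'   planted SSR, assigned to distinct sequences in order (rows beyond
#'   `n_sequences` are an error). NULL plants nothing.
#' @param compound_gaps integer vector: for each entry, one extra sequence
#'   carrying two planted di-SSRs separated by exactly that many bases.
#' @param duplicate_rate fraction of base sequences duplicated verbatim
#'   under a new id.
#' @param n_contaminants number of contaminant-derived sequences appended
#'   (one third each vector/chloroplast/mitochondrial, rounded up in that
#'   order).
#' @param preset detection preset the fixture is calibrated against.
#' @param seed RNG seed (mandatory).
#' @return list with `sequences` (named character vector),
#'   `contaminant_refs` (named list of reference sets), and `truth`
#'   (planted locus table, duplicate map, contaminant ids, clean ids).
#' @export
make_est_set <- function(n_sequences = 30L, length_range = c(300L, 800L),
                         planted = data.frame(period = c(2L, 3L, 4L, 5L, 6L),
                                              count = c(12L, 8L, 6L, 5L, 4L)),
                         compound_gaps = integer(0),
                         duplicate_rate = 0, n_contaminants = 0L,
                         preset = builtin_presets()$misa_default, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  if (!is.null(planted) && nrow(planted) > n_sequences) {
    stop("more planted SSRs than sequences")
  }
  seqs <- character(0)
  truth_rows <- list()
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  for (i in seq_len(n_sequences)) {
    id <- sprintf("est%03d", i)
    L <- sample(length_range[1]:length_range[2], 1L)
    repeat {
      bg <- .ssr_free_dna(L, preset)
      if (i > n_planted) {
        seqs[[id]] <- bg
        break
      }
      motif <- .random_primitive_motif(planted$period[i])
      run <- strrep(motif, planted$count[i])
      ins <- .insert_run(bg, run, margin = 60L)
      det <- find_perfect_ssrs(ins$seq, preset, seq_id = id)
      if (nrow(det) == 1L && det$start == ins$start &&
          det$end == ins$end && det$motif == motif &&
          det$repeat_count == planted$count[i]) {
        seqs[[id]] <- ins$seq
        truth_rows[[length(truth_rows) + 1L]] <- det
        break
      }
    }
  }
  # compound carriers: two di-SSR runs at a controlled gap
  for (k in seq_along(compound_gaps)) {
    id <- sprintf("cmp_est%02d", k)
    gap <- compound_gaps[k]
    repeat {
      L <- max(2L * 150L + gap + 2L * 10L * 2L, length_range[2])
      bg <- .ssr_free_dna(L, preset)
      m1 <- .random_primitive_motif(2L); m2 <- .random_primitive_motif(2L)
      run <- paste0(strrep(m1, 10L),
                    substr(bg, 1L, gap),   # reuse screened background as gap
                    strrep(m2, 10L))
      ins <- .insert_run(bg, run, margin = 60L)
      det <- find_perfect_ssrs(ins$seq, preset, seq_id = id)
      e1 <- ins$start + 20L - 1L
      s2 <- ins$start + 20L + gap
      ok <- nrow(det) == 2L &&
        det$start[1] == ins$start && det$end[1] == e1 &&
        det$start[2] == s2 && det$end[2] == s2 + 20L - 1L
      if (ok) {
        seqs[[id]] <- ins$seq
        truth_rows[[length(truth_rows) + 1L]] <- det
        break
      }
    }
  }
  # duplicates
  dup_map <- list()
  n_dup <- round(duplicate_rate * n_sequences)
  if (n_dup > 0L) {
    src <- sample(names(seqs)[seq_len(n_sequences)], n_dup)
    for (s in src) {
      did <- paste0(s, "_dup")
      seqs[[did]] <- seqs[[s]]
      dup_map[[s]] <- c(dup_map[[s]], did)
    }
  }
  # contaminant references and spiked records
  refs <- list(vector = stats::setNames(random_dna(700L), "vec_ref"),
               chloroplast = stats::setNames(random_dna(700L), "cp_ref"),
               mitochondrial = stats::setNames(random_dna(700L), "mt_ref"))
  cont_ids <- character(0)
  if (n_contaminants > 0L) {
    classes <- rep(names(refs), length.out = n_contaminants)
    for (k in seq_len(n_contaminants)) {
      ref <- refs[[classes[k]]][[1]]
      at <- sample.int(nchar(ref) - 200L, 1L)
      id <- sprintf("ctm_%s%02d", substr(classes[k], 1, 2), k)
      seqs[[id]] <- substr(ref, at, at + 199L)
      cont_ids <- c(cont_ids, id)
    }
  }
  truth_loci <- if (length(truth_rows)) do.call(rbind, truth_rows)
                else .empty_loci()
  list(sequences = seqs,
       contaminant_refs = refs,
       truth = list(loci = truth_loci,
                    duplicates = dup_map,
                    contaminant_ids = cont_ids,
                    clean_ids = setdiff(names(seqs), cont_ids)))
}

#' Synthetic diploid genotype table
#'
#' Calls are drawn from the per-locus allele frequencies under random
#' mating (the two alleles of an individual are independent draws); a
#' `missing_rate` fraction of calls is masked.
#'
#' @param n_individuals number of individuals.
#' @param freqs named list: locus id -> named numeric vector of allele
#'   frequencies (names are integer allele labels, e.g. fragment sizes).
#' @param missing_rate fraction of calls set to missing.
#' @param seed RNG seed (mandatory).
#' @return list with `gt` (a [genotype_table()]) and `truth` (the input
#'   frequencies).
#' @export
make_genotypes <- function(n_individuals = 24L, freqs, missing_rate = 0,
                           seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  loci <- names(freqs)
  inds <- sprintf("ind%03d", seq_len(n_individuals))
  a1 <- matrix(NA_integer_, n_individuals, length(loci))
  a2 <- a1
  for (j in seq_along(loci)) {
    f <- freqs[[j]]
    labels <- as.integer(names(f))
    a1[, j] <- labels[sample.int(length(f), n_individuals, replace = TRUE,
                                 prob = f)]
    a2[, j] <- labels[sample.int(length(f), n_individuals, replace = TRUE,
                                 prob = f)]
    if (missing_rate > 0) {
      drop <- stats::runif(n_individuals) < missing_rate
      a1[drop, j] <- NA_integer_
      a2[drop, j] <- NA_integer_
    }
  }
  list(gt = genotype_table(inds, loci, a1, a2), truth = freqs)
}

#' Synthetic transferability matrix evolved on a known tree
#'
#' Each edge of the generating tree receives a dedicated block of
#' `loci_per_edge` binary characters that flip across exactly that edge, so
#' with `noise = 0` the pairwise mismatch distances are exactly additive on
#' the tree (edge length = `loci_per_edge / n_loci`) and neighbor joining
#' recovers the generating topology. `noise` adds independent per-cell
#' flips at the given rate.
#'
#' @param n_species number of species (>= 4).
#' @param loci_per_edge characters dedicated to each edge.
#' @param noise per-cell flip probability added on top.
#' @param missing_rate fraction of cells masked to NA.
#' @param seed RNG seed (mandatory).
#' @param tree optional generating topology (`phylo`); a random unrooted
#'   topology is drawn when NULL.
#' @return list with `matrix` (species x loci of 0/1, possibly NA) and
#'   `truth` (the generating `phylo` with edge lengths in mismatch units).
#' @export
make_transfer_matrix <- function(n_species = 8L, loci_per_edge = 20L,
                                 noise = 0, missing_rate = 0, seed,
                                 tree = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_species >= 4L)
  set.seed(seed)
  if (is.null(tree)) {
    tree <- ape::unroot(ape::rtree(n_species, br = NULL))
    tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  }
  n_edges <- nrow(tree$edge)
  n_loci <- n_edges * loci_per_edge
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  mat <- matrix(0L, ntip, n_loci,
                dimnames = list(tree$tip.label,
                                sprintf("loc%04d", seq_len(n_loci))))
  for (e in seq_len(n_edges)) {
    below <- desc_tips(tree$edge[e, 2])
    cols <- ((e - 1L) * loci_per_edge + 1L):(e * loci_per_edge)
    mat[below, cols] <- 1L
  }
  if (noise > 0) {
    flip <- matrix(stats::runif(length(mat)) < noise, nrow(mat))
    mat[flip] <- 1L - mat[flip]
  }
  if (missing_rate > 0) {
    mat[matrix(stats::runif(length(mat)) < missing_rate, nrow(mat))] <-
      NA_integer_
  }
  truth <- tree
  truth$edge.length <- rep(loci_per_edge / n_loci, n_edges)
  list(matrix = mat, truth = truth)
}

#' Synthetic GO annotation map with planted enrichment
#'
#' Every background sequence receives each term independently at
#' `base_rate`; for the designated subset, the planted terms' rate is
#' raised so that the *expected* enrichment fold, measured as in
#' [enrich()] (subset frequency over whole-background frequency), equals
#' `fold`.
#'
#' @param n_background total number of sequences (the universe).
#' @param n_subset size of the designated subset (first `n_subset` ids).
#' @param n_terms number of GO terms.
#' @param n_enriched number of planted enriched terms (the first terms).
#' @param fold target measured enrichment fold of the planted terms.
#' @param base_rate background per-term annotation probability.
#' @param seed RNG seed (mandatory).
#' @return list with `annotations` (`seq_id`/`term` data.frame),
#'   `universe`, `subset_ids`, `enriched_terms`.
#' @export
make_annotations <- function(n_background = 2000L, n_subset = 100L,
                             n_terms = 40L, n_enriched = 2L, fold = 5,
                             base_rate = 0.05, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  ids <- sprintf("seq%05d", seq_len(n_background))
  subset_ids <- ids[seq_len(n_subset)]
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  enriched <- terms[seq_len(n_enriched)]
  # solve the subset rate so the measured fold (subset freq over
  # whole-background freq) has expectation `fold`
  S <- n_subset; N <- n_background
  denom <- N - fold * S
  if (denom <= 0) stop("fold/subset size combination is infeasible")
  subset_rate <- base_rate * fold * (N - S) / denom
  if (subset_rate > 1) stop("planted subset rate exceeds 1; lower the fold")
  rows <- list()
  for (tm in terms) {
    p <- rep(base_rate, N)
    if (tm %in% enriched) p[seq_len(S)] <- subset_rate
    has <- stats::runif(N) < p
    if (any(has)) {
      rows[[tm]] <- data.frame(seq_id = ids[has], term = tm,
                               stringsAsFactors = FALSE)
    }
  }
  list(annotations = do.call(rbind, c(rows, make.row.names = FALSE)),
       universe = ids, subset_ids = subset_ids, enriched_terms = enriched)
}

#' Synthetic genome-mapping fixture
#'
#' Builds a toy chromosome with annotated genes (5'UTR / CDS / 3'UTR),
#' extracts ESTs as exact substrings, plants an SSR-sized interval of each
#' EST inside a feature of a prescribed region class, and emits the
#' corresponding 12-column alignment hits. Because ESTs match the genome
#' exactly, the true placement and region class of every locus are known.
#'
#' @param n_ests number of EST/locus pairs.
#' @param region_mix named numeric vector of target shares for classes
#'   `CDS`, `UTR5`, `UTR3` (normalised internally; counts are rounded,
#'   remainder to CDS).
#' @param minus_strand_rate fraction of hits encoded on the minus strand.
#' @param seed RNG seed (mandatory).
#' @return list with `sequences` (ESTs), `loci` (locus table), `hits`
#'   (data.frame in [read_blast_hits()] layout), `features` (GFF3-style
#'   feature data.frame for [write_gff3()]), `genome` (named chromosome
#'   sequences), and `truth` (data.frame of locus id and true region
#'   class/coordinates).
#' @export
make_genome_fixture <- function(n_ests = 20L,
                                region_mix = c(CDS = 0.72, UTR5 = 0.18,
                                               UTR3 = 0.10),
                                minus_strand_rate = 0, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  region_mix <- region_mix / sum(region_mix)
  counts <- floor(region_mix * n_ests)
  counts["CDS"] <- counts["CDS"] + (n_ests - sum(counts))
  classes <- rep(names(counts), counts)
  # one gene per EST, tiled on one chromosome with intergenic spacers
  u5 <- 120L; cds <- 400L; u3 <- 120L; spacer <- 150L
  gene_len <- u5 + cds + u3
  chrom_len <- n_ests * (gene_len + spacer) + spacer
  genome <- stats::setNames(random_dna(chrom_len), "chr1")
  feats <- list(); hits <- list(); loci <- list(); ests <- character(0)
  truth <- list()
  for (i in seq_len(n_ests)) {
    g0 <- spacer + (i - 1L) * (gene_len + spacer) + 1L   # gene start
    gene <- sprintf("gene%03d", i)
    feats[[i]] <- data.frame(
      chrom = "chr1", source = "estssr",
      type = c("five_prime_UTR", "CDS", "three_prime_UTR"),
      start = c(g0, g0 + u5, g0 + u5 + cds),
      end = c(g0 + u5 - 1L, g0 + u5 + cds - 1L, g0 + gene_len - 1L),
      strand = "+",
      attributes = paste0("ID=", gene, ".", c("utr5", "cds", "utr3"),
                          ";Parent=", gene),
      stringsAsFactors = FALSE)
    # locus interval of 20 bp centred in the target feature
    cls <- classes[i]
    f_start <- switch(cls, UTR5 = g0, CDS = g0 + u5, UTR3 = g0 + u5 + cds)
    f_len <- switch(cls, UTR5 = u5, CDS = cds, UTR3 = u3)
    l_g1 <- f_start + f_len %/% 2L - 10L
    l_g2 <- l_g1 + 19L
    # plant a real (AG)10 run at the locus interval on the chromosome
    genome[[1]] <- paste0(substr(genome[[1]], 1L, l_g1 - 1L),
                          strrep("AG", 10L),
                          substr(genome[[1]], l_g2 + 1L, chrom_len))
    # EST covers the locus with 80 bp flanks
    e_g1 <- l_g1 - 80L; e_g2 <- l_g2 + 80L
    est_id <- sprintf("gest%03d", i)
    est <- substr(genome[[1]], e_g1, e_g2)
    minus <- stats::runif(1) < minus_strand_rate
    if (minus) est <- revcomp(est)
    ests[[est_id]] <- est
    qlen <- nchar(est)
    q1 <- if (minus) qlen - (l_g2 - e_g1) else l_g1 - e_g1 + 1L
    q2 <- if (minus) qlen - (l_g1 - e_g1) else l_g2 - e_g1 + 1L
    loci[[i]] <- data.frame(seq_id = est_id, preset = "fixture",
                            motif = "AG", canonical_class = "AG/CT",
                            repeat_count = 10L, start = q1, end = q2,
                            length = 20L, stringsAsFactors = FALSE)
    hits[[i]] <- data.frame(
      query_id = est_id, subject_id = "chr1", identity = 1.0,
      aln_length = qlen, mismatches = 0L, gap_opens = 0L,
      query_start = 1L, query_end = qlen,
      subject_start = if (minus) e_g2 else e_g1,
      subject_end = if (minus) e_g1 else e_g2,
      evalue = 0, bitscore = 2 * qlen,
      strand = if (minus) "-" else "+",
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      locus_id = sprintf("%s:%d-%d", est_id, q1, q2),
      region_class = cls, genomic_start = l_g1, genomic_end = l_g2,
      stringsAsFactors = FALSE)
  }
  list(sequences = ests,
       loci = do.call(rbind, loci),
       hits = do.call(rbind, hits),
       features = do.call(rbind, feats),
       genome = genome,
       truth = do.call(rbind, truth))
}
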