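# Placement of SSR loci on a reference genome from precomputed tabular
# alignment hits, and CDS/UTR region classification against GFF3 gene
# models. GFF3 and hit coordinates are 1-based inclusive; a subject
# interval with start > end encodes the minus strand.

#' Mapping configuration
#'
#' @param min_identity minimum hit identity (fraction); the comparison is
#'   strict (`identity > min_identity`).
#' @param refine when TRUE, [project_locus()] replaces the affine offset
#'   with a global pairwise realignment of the aligned segments.
#' @return object of class `mapping_config`.
#' @export
mapping_config <- function(min_identity = 0.80, refine = FALSE) {
  stopifnot(min_identity >= 0, min_identity <= 1)
  structure(list(min_identity = min_identity, refine = refine),
            class = "mapping_config")
}

#' Read 12-column tabular alignment hits
#'
#' Standard BLAST tabular layout (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Percent identity is
#' converted to a fraction; malformed rows raise an error naming the line.
#'
#' @param path path to the tab-separated hit file.
#' @return data.frame of hits with `identity` on the 0-1 scale and a
#'   derived `strand` column (`"-"` when `subject_start > subject_end`).
#' @export
read_blast_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop(sprintf("hit file %s line %d: expected 12 columns, found %d",
                 path, bad, nf[bad]))
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity = as.numeric(m[, 3]) / 100,
    aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (anyNA(df$identity) || anyNA(df$query_start)) {
    stop("hit file ", path, ": non-numeric fields in a numeric column")
  }
  df$strand <- ifelse(df$subject_start > df$subject_end, "-", "+")
  df
}

#' Select the best qualifying hit per query
#'
#' Hits with identity not strictly above `min_identity` are discarded;
#' among the survivors of each query the winner has the highest bitscore,
#' ties broken by longer alignment, then lexicographically smaller
#' subject id, then smaller subject start.
#'
#' @param hits data.frame from [read_blast_hits()].
#' @param config a [mapping_config()].
#' @return data.frame with at most one row per query id.
#' @export
select_best_hit <- function(hits, config = mapping_config()) {
  hits <- hits[hits$identity > config$min_identity, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, -hits$aln_length,
               hits$subject_id, pmin(hits$subject_start, hits$subject_end))
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

.unplaced <- function(locus) {
  data.frame(locus_id = sprintf("%s:%d-%d", locus$seq_id, locus$start,
                                locus$end),
             seq_id = locus$seq_id, locus_start = locus$start,
             locus_end = locus$end, chromosome = NA_character_,
             genomic_start = NA_integer_, genomic_end = NA_integer_,
             strand = NA_character_, region_class = "unplaced",
             stringsAsFactors = FALSE)
}

#' Project a locus through an alignment hit onto the genome
#'
#' The locus must lie fully inside the hit's query interval, otherwise it
#' is reported unplaced. By default the projection is the affine offset
#' map: plus strand `g = subject_start + (q - query_start)`, minus strand
#' `g = subject_start - (q - query_start)`. With `config$refine = TRUE`
#' and both segment sequences supplied, a global pairwise alignment
#' (match +1, mismatch -1, gap -2) of the aligned query segment to the
#' subject segment supplies the position map instead, absorbing indels.
#'
#' @param locus one locus row.
#' @param hit one hit row with the same `query_id` as the locus `seq_id`.
#' @param config a [mapping_config()].
#' @param query_seq,subject_seq full query sequence and subject (genomic)
#'   segment covering `subject_start..subject_end`; required only when
#'   refining.
#' @return one-row placement data.frame (`region_class` is `"unplaced"`
#'   until classified).
#' @export
project_locus <- function(locus, hit, config = mapping_config(),
                          query_seq = NULL, subject_seq = NULL) {
  if (locus$seq_id != hit$query_id) {
    stop("locus and hit belong to different queries")
  }
  if (locus$start < hit$query_start || locus$end > hit$query_end) {
    return(.unplaced(locus))
  }
  q1 <- locus$start; q2 <- locus$end
  if (isTRUE(config$refine) && !is.null(query_seq) && !is.null(subject_seq)) {
    qseg <- substr(query_seq, hit$query_start, hit$query_end)
    sseg <- if (hit$strand == "+") subject_seq else revcomp(subject_seq)
    map <- .global_position_map(qseg, sseg)
    o1 <- map[q1 - hit$query_start + 1L]
    o2 <- map[q2 - hit$query_start + 1L]
    if (is.na(o1) || is.na(o2)) return(.unplaced(locus))
    if (hit$strand == "+") {
      g1 <- hit$subject_start + o1 - 1L
      g2 <- hit$subject_start + o2 - 1L
    } else {
      g1 <- hit$subject_start - o1 + 1L
      g2 <- hit$subject_start - o2 + 1L
    }
  } else if (hit$strand == "+") {
    g1 <- hit$subject_start + (q1 - hit$query_start)
    g2 <- hit$subject_start + (q2 - hit$query_start)
  } else {
    g1 <- hit$subject_start - (q1 - hit$query_start)
    g2 <- hit$subject_start - (q2 - hit$query_start)
  }
  data.frame(locus_id = sprintf("%s:%d-%d", locus$seq_id, q1, q2),
             seq_id = locus$seq_id, locus_start = q1, locus_end = q2,
             chromosome = hit$subject_id,
             genomic_start = min(g1, g2), genomic_end = max(g1, g2),
             strand = hit$strand, region_class = "unplaced",
             stringsAsFactors = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Keeps CDS, five_prime_UTR and three_prime_UTR features. Each feature is
#' assigned to a gene by its `Parent` (or, failing that, `ID`) attribute.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `chrom`, `type`, `start`, `end`,
#'   `strand`, `gene`.
#' @export
read_gene_models <- function(path) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  keep <- gff$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR")
  gff <- gff[keep, , drop = FALSE]
  att <- as.character(gff$attributes)
  gene <- sub(".*Parent=([^;]+).*", "\\1", att)
  noparent <- !grepl("Parent=", att)
  gene[noparent] <- sub(".*ID=([^;]+).*", "\\1", att[noparent])
  data.frame(chrom = as.character(gff$seqid), type = as.character(gff$type),
             start = gff$start, end = gff$end,
             strand = as.character(gff$strand), gene = gene,
             stringsAsFactors = FALSE)
}

#' Classify a placement into CDS / UTR5 / UTR3 / intergenic
#'
#' The placement is first attributed to the gene with the largest total
#' feature overlap; within that gene the class is the feature type with
#' the largest base overlap, ties broken CDS > UTR5 > UTR3. Zero overlap
#' with any feature gives `"intergenic"`. A chromosome absent from the
#' annotation gives `"unplaced"` with a warning.
#'
#' @param placement one placement row from [project_locus()].
#' @param models gene models from [read_gene_models()].
#' @return region class string.
#' @export
classify_region <- function(placement, models) {
  if (is.na(placement$chromosome)) return("unplaced")
  if (!placement$chromosome %in% models$chrom) {
    warning("chromosome not in annotation: ", placement$chromosome)
    return("unplaced")
  }
  feats <- models[models$chrom == placement$chromosome, , drop = FALSE]
  ov <- pmin(feats$end, placement$genomic_end) -
        pmax(feats$start, placement$genomic_start) + 1L
  ov[ov < 0L] <- 0L
  if (all(ov == 0L)) return("intergenic")
  by_gene <- tapply(ov, feats$gene, sum)
  best_gene <- names(by_gene)[order(-by_gene, names(by_gene))][1L]
  ing <- feats$gene == best_gene
  cls_ov <- tapply(ov[ing], factor(feats$type[ing],
                                   levels = c("CDS", "five_prime_UTR",
                                              "three_prime_UTR")), sum)
  cls_ov[is.na(cls_ov)] <- 0
  winner <- names(cls_ov)[which.max(cls_ov)]  # ties: CDS > UTR5 > UTR3
  c(CDS = "CDS", five_prime_UTR = "UTR5", three_prime_UTR = "UTR3")[[winner]]
}

#' Place and classify every locus in a table
#'
#' @param loci locus table.
#' @param hits alignment hits ([read_blast_hits()]).
#' @param models gene models ([read_gene_models()]), or NULL to skip
#'   classification.
#' @param config a [mapping_config()].
#' @param query_seqs named sequences (needed only when refining).
#' @param subject_seqs named genomic segment list keyed by
#'   `"subject_id:start-end"` (needed only when refining).
#' @return placement data.frame, one row per locus.
#' @export
map_ssr_loci <- function(loci, hits, models = NULL,
                         config = mapping_config(),
                         query_seqs = NULL, subject_seqs = NULL) {
  best <- select_best_hit(hits, config)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    hi <- best[best$query_id == locus$seq_id, , drop = FALSE]
    if (!nrow(hi)) return(.unplaced(locus))
    hit <- hi[1L, ]
    sseg <- if (!is.null(subject_seqs)) {
      subject_seqs[[sprintf("%s:%d-%d", hit$subject_id, hit$subject_start,
                            hit$subject_end)]]
    } else NULL
    project_locus(locus, hit, config,
                  query_seq = if (!is.null(query_seqs))
                    query_seqs[[locus$seq_id]] else NULL,
                  subject_seq = sseg)
  })
  placements <- do.call(rbind, rows)
  if (!is.null(models)) {
    for (i in which(!is.na(placements$chromosome))) {
      placements$region_class[i] <- classify_region(placements[i, ], models)
    }
  }
  placements
}

#' Per-chromosome and per-region distribution of placements
#'
#' @param placements placement table.
#' @param loci optional locus table (joined by `locus_id`) to add the
#'   region-class by motif-period cross table.
#' @return list with `by_chromosome`, `by_region` (counts), `by_region_pct`
#'   (percentages of placed loci), `n_placed`, `placed_pct`, and, when
#'   `loci` is given, `region_by_period` (class x period counts).
#' @export
distribution_table <- function(placements, loci = NULL) {
  placed <- placements[placements$region_class != "unplaced", , drop = FALSE]
  by_chrom <- table(placed$chromosome)
  region_levels <- c("CDS", "UTR5", "UTR3", "intergenic")
  by_region <- table(factor(placed$region_class, levels = region_levels))
  out <- list(
    by_chromosome = as.list(stats::setNames(as.integer(by_chrom),
                                            names(by_chrom))),
    by_region = as.list(stats::setNames(as.integer(by_region),
                                        region_levels)),
    by_region_pct = as.list(stats::setNames(
      vapply(as.integer(by_region), .pct, numeric(1), n = nrow(placed)),
      region_levels)),
    n_placed = nrow(placed),
    n_total = nrow(placements),
    placed_pct = .pct(nrow(placed), nrow(placements)))
  if (!is.null(loci)) {
    lid <- sprintf("%s:%d-%d", loci$seq_id, loci$start, loci$end)
    period <- nchar(loci$motif)[match(placed$locus_id, lid)]
    out$region_by_period <- table(
      region = factor(placed$region_class, levels = region_levels),
      period = factor(period, levels = 2:6))
  }
  out
}
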