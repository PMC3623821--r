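# End-to-end orchestration: preprocess -> detect -> primers -> optional
# mapping / diversity / enrichment / transferability stages, a joined
# per-locus marker table, headline summary reporting, and a flat-file
# marker database export. All randomness flows from the single config seed;
# identical configs give byte-identical outputs.

#' Pipeline configuration
#'
#' File-path fields may be NULL to skip the corresponding optional stage.
#'
#' @param est_fasta path to the raw EST/transcript FASTA (required).
#' @param out_dir output directory (created if absent).
#' @param preset name of a built-in criteria preset
#'   (`misa_default`/`cardle`/`len20`) or an [ssr_preset()] object.
#' @param contaminant_fastas named list of FASTA paths (classes among
#'   vector/chloroplast/mitochondrial), or NULL.
#' @param genotype_tsv,hits_tsv,gff3,annotation_tsv,transfer_tsv optional
#'   stage inputs (see the corresponding readers).
#' @param preprocess a [preprocess_config()].
#' @param constraints a [primer_constraints()].
#' @param mapping a [mapping_config()].
#' @param fdr_alpha FDR level for enrichment.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param seed RNG seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(est_fasta, out_dir,
                            preset = "misa_default",
                            contaminant_fastas = NULL,
                            genotype_tsv = NULL, hits_tsv = NULL,
                            gff3 = NULL, annotation_tsv = NULL,
                            transfer_tsv = NULL,
                            preprocess = preprocess_config(),
                            constraints = primer_constraints(),
                            mapping = mapping_config(),
                            fdr_alpha = 0.05,
                            bootstrap_replicates = 1000L,
                            seed = 1L) {
  if (is.character(preset)) {
    presets <- builtin_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset: ", preset, " (built-ins: ",
           paste(names(presets), collapse = ", "), ")")
    }
    preset <- presets[[preset]]
  }
  stopifnot(inherits(preset, "ssr_preset"))
  structure(list(est_fasta = est_fasta, out_dir = out_dir, preset = preset,
                 contaminant_fastas = contaminant_fastas,
                 genotype_tsv = genotype_tsv, hits_tsv = hits_tsv,
                 gff3 = gff3, annotation_tsv = annotation_tsv,
                 transfer_tsv = transfer_tsv, preprocess = preprocess,
                 constraints = constraints, mapping = mapping,
                 fdr_alpha = fdr_alpha,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full marker-development pipeline
#'
#' Required stages: preprocessing and SSR detection (with compound merging)
#' and primer design. Optional stages run when their input is configured:
#' genome mapping (hits, optionally GFF3 models), diversity statistics
#' (genotypes), GO enrichment (annotation map; the subset is the
#' SSR-containing sequences), and transferability (matrix; bootstrap NJ
#' tree). Per-stage outputs, a combined per-locus marker table and a run
#' log (parameter echo, seed) are written under `config$out_dir`. Any stage
#' failure aborts with a stage-named error.
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory stage results (`preprocess`, `loci`,
#'   `compounds`, `primers`, `placements`, `diversity`, `enrichment`,
#'   `transfer`, `summary`, `markers`) and `paths` of written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("estssr pipeline  (package %s)",
                         as.character(utils::packageVersion("estssr"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("preset: %s", config$preset$name),
                 sprintf("preset min_repeats: %s",
                         paste(sprintf("%d:%d", config$preset$periods,
                                       config$preset$min_repeats),
                               collapse = " ")),
                 sprintf("max_interruption: %d",
                         config$preset$max_interruption),
                 sprintf("min_length: %d", config$preprocess$min_length),
                 sprintf("cluster_identity: %g",
                         config$preprocess$cluster_identity),
                 sprintf("mapping min_identity: %g",
                         config$mapping$min_identity),
                 sprintf("fdr_alpha: %g", config$fdr_alpha),
                 sprintf("bootstrap_replicates: %d",
                         config$bootstrap_replicates))
  set.seed(config$seed)

  # ---- preprocess -----------------------------------------------------
  pre <- .stage("preprocess", {
    raw <- read_fasta(config$est_fasta)
    cont <- NULL
    if (!is.null(config$contaminant_fastas)) {
      cont <- lapply(config$contaminant_fastas, read_fasta)
    }
    preprocess_ests(raw, cont, config$preprocess)
  })
  paths$clean_fasta <- write_fasta(pre$sequences, out("clean.fasta"))
  write_report(pre$report, out("preprocess_report.json"),
               out("preprocess_report.txt"))
  paths$report_json <- out("preprocess_report.json")

  # ---- detect ---------------------------------------------------------
  det <- .stage("detect", {
    loci <- detect_ssrs(pre$sequences, config$preset)
    cmp <- merge_compound(loci, config$preset)
    list(loci = loci, compounds = cmp)
  })
  paths$loci_tsv <- .write_tsv(det$loci, out("ssr_loci.tsv"))
  if (nrow(det$compounds$compounds)) {
    paths$compounds_tsv <- .write_tsv(det$compounds$compounds,
                                      out("ssr_compounds.tsv"))
  }

  # ---- primers --------------------------------------------------------
  primers <- .stage("primers", {
    design_primers_all(pre$sequences, det$loci, config$constraints)
  })
  if (nrow(primers$primers)) {
    paths$primers_tsv <- .write_tsv(primers$primers, out("primers.tsv"))
  }

  # ---- optional: genome mapping --------------------------------------
  placements <- NULL
  if (!is.null(config$hits_tsv)) {
    placements <- .stage("map", {
      hits <- read_blast_hits(config$hits_tsv)
      models <- if (!is.null(config$gff3)) read_gene_models(config$gff3)
                else NULL
      map_ssr_loci(det$loci, hits, models, config$mapping)
    })
    paths$placements_tsv <- .write_tsv(placements, out("placements.tsv"))
  } else if (!is.null(config$gff3)) {
    stop("[stage map] gff3 supplied without hits_tsv")
  }

  # ---- optional: diversity -------------------------------------------
  diversity <- NULL
  if (!is.null(config$genotype_tsv)) {
    diversity <- .stage("stats", {
      if (!file.exists(config$genotype_tsv)) {
        stop("genotype file not found: ", config$genotype_tsv)
      }
      locus_diversity(read_genotypes(config$genotype_tsv))
    })
    paths$diversity_tsv <- .write_tsv(diversity, out("diversity.tsv"))
  }

  # ---- optional: enrichment ------------------------------------------
  enrichment <- NULL
  if (!is.null(config$annotation_tsv)) {
    enrichment <- .stage("enrich", {
      ann <- read_annotations(config$annotation_tsv)
      subset_ids <- intersect(unique(det$loci$seq_id), unique(ann$seq_id))
      if (!length(subset_ids)) {
        stop("no SSR-containing sequence has an annotation")
      }
      enrich(subset_ids, ann, fdr_alpha = config$fdr_alpha)
    })
    paths$enrichment_tsv <- .write_tsv(enrichment, out("enrichment.tsv"))
  }

  # ---- optional: transferability -------------------------------------
  transfer <- NULL
  if (!is.null(config$transfer_tsv)) {
    transfer <- .stage("transfer", {
      mat <- read_transfer_matrix(config$transfer_tsv)
      bs <- bootstrap_support(mat, config$bootstrap_replicates,
                              seed = config$seed)
      dist <- binary_distance(mat)
      list(matrix = mat, distances = dist, tree = bs$tree,
           supports = bs$supports, n_replicates = bs$n_replicates)
    })
    paths$newick <- write_newick(transfer$tree, out("transfer_tree.nwk"))
    dd <- data.frame(species = rownames(transfer$distances),
                     transfer$distances, check.names = FALSE)
    paths$distances_tsv <- .write_tsv(dd, out("transfer_distances.tsv"))
  }

  # ---- join + summary -------------------------------------------------
  markers <- .stage("join", {
    marker_table(det$loci, primers$primers, placements, diversity)
  })
  paths$markers_tsv <- .write_tsv(markers, out("markers.tsv"))
  summary <- summary_report(
    loci = det$loci, compounds = det$compounds,
    total_bases = sum(nchar(pre$sequences)),
    n_sequences = length(pre$sequences),
    placements = placements, diversity = diversity)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$summary_json <- out("summary.json")
  writeLines(log_lines, out("run_log.txt"))
  paths$log <- out("run_log.txt")

  list(preprocess = pre, loci = det$loci, compounds = det$compounds,
       primers = primers, placements = placements, diversity = diversity,
       enrichment = enrichment, transfer = transfer, summary = summary,
       markers = markers, paths = paths)
}

#' Joined per-locus marker table
#'
#' One row per detected locus; the locus id (`seq_id:start-end`) is the
#' join key. Adds the rank-1 primer pair, the placement/region class and
#' the diversity statistics where available (diversity rows are joined by
#' locus id).
#'
#' @param loci locus table.
#' @param primers primer table (may be empty).
#' @param placements placement table or NULL.
#' @param diversity diversity table or NULL (its `locus` column must hold
#'   locus ids to join).
#' @return data.frame.
#' @export
marker_table <- function(loci, primers = NULL, placements = NULL,
                         diversity = NULL) {
  if (!nrow(loci)) return(loci)
  lid <- sprintf("%s:%d-%d", loci$seq_id, loci$start, loci$end)
  if (anyDuplicated(lid)) {
    stop("duplicate locus ids in the marker table: ", lid[duplicated(lid)][1])
  }
  out <- cbind(locus_id = lid, loci, stringsAsFactors = FALSE)
  if (!is.null(primers) && nrow(primers)) {
    p1 <- primers[primers$rank == 1L, , drop = FALSE]
    m <- match(lid, p1$locus_id)
    out$forward <- p1$forward[m]
    out$reverse <- p1$reverse[m]
    out$tm_forward <- p1$tm_forward[m]
    out$tm_reverse <- p1$tm_reverse[m]
    out$product_size <- p1$product_size[m]
  }
  if (!is.null(placements) && nrow(placements)) {
    m <- match(lid, placements$locus_id)
    out$chromosome <- placements$chromosome[m]
    out$genomic_start <- placements$genomic_start[m]
    out$genomic_end <- placements$genomic_end[m]
    out$region_class <- placements$region_class[m]
  }
  if (!is.null(diversity) && nrow(diversity)) {
    m <- match(lid, diversity$locus)
    out$n_alleles <- diversity$n_alleles[m]
    out$He <- diversity$He[m]
    out$PIC <- diversity$PIC_printed[m]
    out$polymorphic <- diversity$polymorphic[m]
  }
  rownames(out) <- NULL
  out
}

#' Headline summary of a marker-development run
#'
#' Emits the customary reporting shapes: loci per motif period with
#' percentages, top canonical classes, single- versus multi-SSR sequence
#' counts, compound count and share, SSR density and frequency, placement
#' and region-class shares when mapping ran, polymorphism rate when
#' diversity ran, and the amplification rate when validation counts are
#' supplied. All fields are present (zero or NA) on an empty locus set.
#'
#' @param loci locus table.
#' @param compounds [merge_compound()] result or NULL.
#' @param total_bases,n_sequences searched bases and sequence count.
#' @param placements placement table or NULL.
#' @param diversity diversity table or NULL.
#' @param n_primers_tested,n_amplified optional validation counts.
#' @return list of summary fields.
#' @export
summary_report <- function(loci, compounds = NULL, total_bases = NA,
                           n_sequences = NA, placements = NULL,
                           diversity = NULL, n_primers_tested = NULL,
                           n_amplified = NULL) {
  s <- summarize_ssrs(loci, compounds, total_bases, n_sequences)
  if (!is.null(placements)) {
    dt <- distribution_table(placements, loci)
    s$n_placed <- dt$n_placed
    s$placed_pct <- dt$placed_pct
    s$by_region <- dt$by_region
    s$by_region_pct <- dt$by_region_pct
  }
  if (!is.null(diversity)) {
    s$n_loci_genotyped <- nrow(diversity)
    s$n_polymorphic <- sum(diversity$polymorphic)
    s$polymorphic_rate_pct <- round(
      .pct(sum(diversity$polymorphic), nrow(diversity)), 1)
  }
  if (!is.null(n_primers_tested) && !is.null(n_amplified)) {
    s$n_primers_tested <- n_primers_tested
    s$n_amplified <- n_amplified
    s$amplification_rate_pct <- .pct(n_amplified, n_primers_tested)
  }
  s
}

#' Export the normalised flat-file marker database
#'
#' Writes one TSV per entity (sequences, loci, primers, placements,
#' diversity, transferability) plus a JSON column dictionary, replacing a
#' relational marker database with queryable flat files.
#'
#' @param result a [run_pipeline()] result (or a list with the same
#'   fields).
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
export_marker_db <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  seq_df <- data.frame(seq_id = names(result$preprocess$sequences),
                       length = nchar(result$preprocess$sequences),
                       sequence = unname(result$preprocess$sequences),
                       stringsAsFactors = FALSE)
  paths["sequences"] <- .write_tsv(seq_df, file.path(dir, "sequences.tsv"))
  lid <- sprintf("%s:%d-%d", result$loci$seq_id, result$loci$start,
                 result$loci$end)
  if (anyDuplicated(lid)) stop("duplicate locus ids; cannot export")
  paths["loci"] <- .write_tsv(cbind(locus_id = lid, result$loci),
                              file.path(dir, "loci.tsv"))
  if (!is.null(result$primers) && nrow(result$primers$primers)) {
    paths["primers"] <- .write_tsv(result$primers$primers,
                                   file.path(dir, "primers.tsv"))
  }
  if (!is.null(result$placements)) {
    paths["placements"] <- .write_tsv(result$placements,
                                      file.path(dir, "placements.tsv"))
  }
  if (!is.null(result$diversity)) {
    paths["diversity"] <- .write_tsv(result$diversity,
                                     file.path(dir, "diversity.tsv"))
  }
  if (!is.null(result$transfer)) {
    tm <- result$transfer$matrix
    paths["transferability"] <- write_transfer_matrix(
      tm, file.path(dir, "transferability.tsv"))
  }
  dict <- list(
    sequences = "seq_id, length, sequence: the non-redundant working set",
    loci = "locus_id (seq_id:start-end, join key), motif, canonical_class, repeat_count, 1-based coordinates",
    primers = "per locus up to 3 ranked pairs: forward/reverse, Tm (C), GC (%), product size (bp), penalty",
    placements = "locus_id, chromosome, genomic 1-based interval, strand, region_class (CDS/UTR5/UTR3/intergenic/unplaced)",
    diversity = "locus, n typed, n_alleles, He, uHe, PIC (printed and Botstein), polymorphic",
    transferability = "species x locus amplification success (1/0/NA)")
  jsonlite::write_json(dict, file.path(dir, "columns.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths["columns"] <- file.path(dir, "columns.json")
  invisible(paths)
}

#' Load an exported marker database
#'
#' @param dir directory written by [export_marker_db()].
#' @return list of data.frames (absent tables are NULL), plus a `query`
#'   function: `query(class = , region = )` filters the joined loci.
#' @export
load_marker_db <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) .read_tsv(p) else NULL
  }
  db <- list(sequences = rd("sequences.tsv"), loci = rd("loci.tsv"),
             primers = rd("primers.tsv"), placements = rd("placements.tsv"),
             diversity = rd("diversity.tsv"),
             transferability = if (file.exists(file.path(dir, "transferability.tsv")))
               read_transfer_matrix(file.path(dir, "transferability.tsv"))
             else NULL)
  db$query <- function(class = NULL, region = NULL) {
    out <- db$loci
    if (!is.null(class)) {
      out <- out[out$canonical_class == class, , drop = FALSE]
    }
    if (!is.null(region)) {
      if (is.null(db$placements)) stop("no placements table in this export")
      keep <- db$placements$locus_id[db$placements$region_class == region]
      out <- out[out$locus_id %in% keep, , drop = FALSE]
    }
    out
  }
  db
}
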