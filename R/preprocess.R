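# Raw EST cleanup: terminal poly-A/T trimming, length filtering, contaminant
# screening and greedy redundancy clustering, with conserved accounting.

#' Preprocessing configuration
#'
#' @param min_length minimum sequence length kept after trimming (bp);
#'   "below" is strict, so a sequence of exactly `min_length` is kept.
#' @param cluster_identity identity threshold for redundancy clustering
#'   (fraction of the shorter sequence).
#' @param trim_run_min minimum terminal A/T run length (bp) removed by
#'   trimming; runs are exact-base only.
#' @param contaminant_min_identity minimum local-alignment identity for a
#'   contaminant call.
#' @param contaminant_min_coverage minimum fraction of the record covered by
#'   the contaminant alignment.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(min_length = 100L, cluster_identity = 0.90,
                              trim_run_min = 10L,
                              contaminant_min_identity = 0.90,
                              contaminant_min_coverage = 0.50) {
  stopifnot(min_length >= 1L,
            cluster_identity > 0, cluster_identity <= 1,
            trim_run_min >= 1L,
            contaminant_min_identity > 0, contaminant_min_identity <= 1,
            contaminant_min_coverage > 0, contaminant_min_coverage <= 1)
  structure(list(min_length = as.integer(min_length),
                 cluster_identity = cluster_identity,
                 trim_run_min = as.integer(trim_run_min),
                 contaminant_min_identity = contaminant_min_identity,
                 contaminant_min_coverage = contaminant_min_coverage),
            class = "preprocess_config")
}

# documented fixed charge order for contaminant classes
CONTAMINANT_CLASSES <- c("vector", "chloroplast", "mitochondrial")

#' Trim terminal poly-A/T runs
#'
#' Removes maximal terminal runs of A or of T (either base at either end,
#' since EST orientation is unknown) of length at least `trim_run_min`,
#' iterating until no terminal run qualifies. Interior runs are never
#' touched. The operation is idempotent; an empty result is allowed and is
#' caught downstream by the length filter.
#'
#' @param seqs named character vector of sequences (a single unnamed string
#'   is also accepted).
#' @param config a [preprocess_config()].
#' @return trimmed sequences, same names.
#' @export
trim_poly_at <- function(seqs, config = preprocess_config()) {
  k <- config$trim_run_min
  lead <- sprintf("^(A{%d,}|T{%d,})", k, k)
  trail <- sprintf("(A{%d,}|T{%d,})$", k, k)
  vapply(seqs, function(s) {
    repeat {
      s2 <- sub(lead, "", s)
      s2 <- sub(trail, "", s2)
      if (s2 == s) return(s)
      s <- s2
    }
  }, character(1))
}

#' Drop sequences shorter than the minimum length
#'
#' @param seqs named character vector.
#' @param config a [preprocess_config()].
#' @return list with `kept` (sequences) and `removed_ids`.
#' @export
filter_short <- function(seqs, config = preprocess_config()) {
  short <- nchar(seqs) < config$min_length
  list(kept = seqs[!short], removed_ids = names(seqs)[short])
}

#' Screen sequences against contaminant reference sets
#'
#' A record is removed when its best local alignment to any contaminant
#' reference reaches `contaminant_min_identity` (matches over aligned
#' columns) while covering at least `contaminant_min_coverage` of the
#' record. Classes are checked in the fixed order vector, chloroplast,
#' mitochondrial, and a removed record is charged to the first matching
#' class only. A shared exact 12-mer is required before any alignment is
#' attempted, so records sharing no 12-mer with a reference are always kept.
#'
#' @param seqs named character vector.
#' @param contaminant_sets named list of contaminant reference sequence
#'   vectors; names must be among `vector`, `chloroplast`, `mitochondrial`.
#' @param config a [preprocess_config()].
#' @return list with `kept` and `removed_ids` (a named list, one id vector
#'   per contaminant class).
#' @export
screen_contaminants <- function(seqs, contaminant_sets,
                                config = preprocess_config()) {
  unknown <- setdiff(names(contaminant_sets), CONTAMINANT_CLASSES)
  if (length(unknown)) {
    stop("unknown contaminant class: ", paste(unknown, collapse = ", "))
  }
  classes <- intersect(CONTAMINANT_CLASSES, names(contaminant_sets))
  removed <- stats::setNames(
    rep(list(character(0)), length(CONTAMINANT_CLASSES)),
    CONTAMINANT_CLASSES)
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    for (cls in classes) {
      hit <- FALSE
      for (ref in contaminant_sets[[cls]]) {
        if (!.shares_kmer(seqs[[i]], ref, 12L)) next
        sa <- .screen_align(seqs[[i]], ref)
        if (sa$identity >= config$contaminant_min_identity &&
            sa$coverage >= config$contaminant_min_coverage) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        removed[[cls]] <- c(removed[[cls]], names(seqs)[i])
        keep[i] <- FALSE
        break  # first matching class is charged
      }
    }
  }
  list(kept = seqs[keep], removed_ids = removed)
}

#' Greedy redundancy clustering
#'
#' CD-HIT-style greedy incremental clustering: sequences are visited in
#' order of decreasing length (ties broken by id); each joins the first
#' existing representative with identity at least `cluster_identity`
#' (matches in the best local alignment over the length of the shorter
#' sequence), otherwise it founds a new cluster. An exact shared 8-mer is
#' required before alignment. Representatives are returned in founding
#' order, which makes the procedure deterministic.
#'
#' @param seqs named character vector.
#' @param config a [preprocess_config()].
#' @return list with `representatives` (named character vector) and
#'   `clusters` (named list: representative id -> member ids, the
#'   representative included first).
#' @export
cluster_redundant <- function(seqs, config = preprocess_config()) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  rep_ids <- character(0)
  clusters <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (r in rep_ids) {
      if (!.shares_kmer(seqs[[i]], seqs[[r]], 8L)) next
      if (local_identity(seqs[[i]], seqs[[r]]) >= config$cluster_identity) {
        clusters[[r]] <- c(clusters[[r]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, id)
      clusters[[id]] <- id
    }
  }
  list(representatives = seqs[rep_ids], clusters = clusters)
}

#' Assemble the preprocessing accounting report
#'
#' Enforces conservation: `n_input` must equal `n_valid` plus all removals,
#' and the number of cluster representatives cannot exceed `n_valid`.
#'
#' @param n_input number of raw input sequences.
#' @param removed_short ids (or a count) of sequences removed as too short.
#' @param removed_contaminants named list (or named counts) of removals per
#'   contaminant class.
#' @param n_clusters number of non-redundant representatives.
#' @param id_lists optional list of per-stage id vectors kept verbatim.
#' @return object of class `preprocess_report`.
#' @export
build_report <- function(n_input, removed_short, removed_contaminants,
                         n_clusters, id_lists = NULL) {
  n_short <- if (is.numeric(removed_short)) as.integer(removed_short)
             else length(removed_short)
  n_cont <- vapply(removed_contaminants, function(x) {
    if (is.numeric(x)) as.integer(x) else length(x)
  }, integer(1))
  n_valid <- n_input - n_short - sum(n_cont)
  if (n_valid < 0L) {
    stop("accounting violation: removals exceed the number of inputs")
  }
  if (n_clusters > n_valid) {
    stop("accounting violation: more clusters than valid sequences")
  }
  structure(list(n_input = as.integer(n_input),
                 n_removed_short = n_short,
                 n_removed_by_contaminant_class = as.list(n_cont),
                 n_valid = as.integer(n_valid),
                 n_clusters = as.integer(n_clusters),
                 id_lists = id_lists),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("EST preprocessing report\n")
  cat(sprintf("  input sequences      : %d\n", x$n_input))
  cat(sprintf("  removed (< min len)  : %d\n", x$n_removed_short))
  for (cls in names(x$n_removed_by_contaminant_class)) {
    cat(sprintf("  removed (%-12s): %d\n", cls,
                x$n_removed_by_contaminant_class[[cls]]))
  }
  cat(sprintf("  valid sequences      : %d\n", x$n_valid))
  cat(sprintf("  non-redundant        : %d\n", x$n_clusters))
  invisible(x)
}

#' Full preprocessing stage
#'
#' Runs trimming, length filtering, contaminant screening and redundancy
#' clustering in order and returns the non-redundant working set together
#' with the accounting report.
#'
#' @param seqs named character vector of raw sequences.
#' @param contaminant_sets optional named list of contaminant references
#'   (see [screen_contaminants()]).
#' @param config a [preprocess_config()].
#' @return list with `sequences` (representatives), `clusters`, and
#'   `report`.
#' @export
preprocess_ests <- function(seqs, contaminant_sets = NULL,
                            config = preprocess_config()) {
  .check_seqset(seqs)
  n_input <- length(seqs)
  trimmed <- trim_poly_at(seqs, config)
  fs <- filter_short(trimmed, config)
  if (!is.null(contaminant_sets) && length(contaminant_sets)) {
    sc <- screen_contaminants(fs$kept, contaminant_sets, config)
  } else {
    sc <- list(kept = fs$kept,
               removed_ids = stats::setNames(
                 rep(list(character(0)), length(CONTAMINANT_CLASSES)),
                 CONTAMINANT_CLASSES))
  }
  cl <- cluster_redundant(sc$kept, config)
  report <- build_report(
    n_input, fs$removed_ids, sc$removed_ids,
    length(cl$representatives),
    id_lists = list(removed_short = fs$removed_ids,
                    removed_contaminants = sc$removed_ids,
                    representatives = names(cl$representatives)))
  list(sequences = cl$representatives, clusters = cl$clusters,
       report = report)
}

#' Write a preprocessing report as JSON and text
#'
#' @param report a `preprocess_report`.
#' @param json_path,text_path output paths (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report)[c(
      "n_input", "n_removed_short", "n_removed_by_contaminant_class",
      "n_valid", "n_clusters")], json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(report)
}
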