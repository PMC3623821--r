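# Cross-species transferability analysis: binary p-distances with pairwise
# deletion, Saitou-Nei neighbor joining with deterministic tie-breaks and
# clamp-and-transfer handling of negative branch lengths, and bootstrap
# bipartition support. Trees are ape "phylo" objects throughout.

#' Mismatch-proportion distance from a binary transferability matrix
#'
#' `d(i, j)` is the number of loci scored differently in species i and j
#' divided by the number of loci scored (non-missing) in both. A pair with
#' no jointly scored locus is an error.
#'
#' @param mat integer matrix (species x loci) of 1/0/NA.
#' @return symmetric distance matrix with species labels and zero diagonal.
#' @export
binary_distance <- function(mat) {
  if (is.null(rownames(mat))) stop("matrix needs species row names")
  if (any(apply(mat, 1, function(r) all(is.na(r))))) {
    stop("matrix has an all-missing species row")
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (!any(both)) {
        stop(sprintf("species %s and %s share no scored locus",
                     rownames(mat)[i], rownames(mat)[j]))
      }
      d[i, j] <- d[j, i] <- mean(mat[i, both] != mat[j, both])
    }
  }
  d
}

.check_dist <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    stop("distance matrix is not symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Tie-breaks are
#' deterministic: among pairs minimising Q, the pair whose (sorted) label
#' keys are lexicographically smallest is joined, where an internal node's
#' key is the smallest leaf label beneath it. A negative branch length is
#' clamped to zero and the deficit transferred to its sibling branch so the
#' pair distance is preserved. For exactly additive distances the
#' generating topology and branch lengths are recovered.
#'
#' @param d symmetric distance matrix (or `dist`) with at least 3 labels.
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- .check_dist(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 labels")
  labels <- rownames(d)
  # newick fragment and tie-break key per active node
  nwk <- labels
  key <- labels
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }        # clamp and transfer
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    new_key <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    rownames(d) <- colnames(d) <- key
    n <- n - 1L
  }
  # closed-form three-point star
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1], fmt(v1), nwk[2], fmt(v2), nwk[3], fmt(v3))
  ape::read.tree(text = text)
}

# canonical bipartition keys of the internal edges of an unrooted phylo:
# the side of each internal edge not containing the reference leaf,
# labels sorted and joined by "|"; returns a named character vector keyed
# by the phylo node number of the edge's child node
.bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  n <- length(tree$tip.label)
  root <- n + 1L
  internal <- setdiff(unique(tree$edge[, 2L][tree$edge[, 2L] > n]), root)
  if (!length(internal)) return(character(0))
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, function(k) if (k <= n) tree$tip.label[k] else desc(k)))
  }
  out <- vapply(internal, function(node) {
    side <- desc(node)
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  names(out) <- internal
  out
}

#' Bootstrap support for a transferability NJ tree
#'
#' Builds the full-data NJ tree, then resamples loci (columns) with
#' replacement `replicates` times, rebuilding the distance matrix and tree
#' each time. The support of each internal edge of the full tree is the
#' percentage of replicate trees containing the same bipartition.
#' Replicates whose resampled matrix leaves some species pair with no
#' jointly scored locus are skipped; more than `max_failures` such
#' replicates is an error. Supports are attached as internal node labels.
#'
#' @param mat species x locus 1/0/NA matrix.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed mandatory RNG seed.
#' @param max_failures maximum tolerated failed replicates (default 10% of
#'   `replicates`).
#' @return list with `tree` (phylo, node labels = integer percent support,
#'   root label empty), `supports` (named by bipartition), `n_replicates`
#'   (successful count).
#' @export
bootstrap_support <- function(mat, replicates = 1000L, seed,
                              max_failures = ceiling(replicates / 10)) {
  if (missing(seed)) stop("seed is required for bootstrap_support")
  stopifnot(replicates >= 1L)
  full <- neighbor_joining(binary_distance(mat))
  bip <- .bipartitions(full)
  counts <- stats::setNames(rep(0L, length(bip)), bip)
  set.seed(seed)
  failures <- 0L
  done <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    t <- tryCatch(neighbor_joining(binary_distance(mat[, cols, drop = FALSE])),
                  error = function(e) NULL)
    if (is.null(t)) {
      failures <- failures + 1L
      if (failures > max_failures) {
        stop("too many bootstrap replicates failed (", failures, ")")
      }
      next
    }
    done <- done + 1L
    hit <- bip %in% .bipartitions(t)
    counts[hit] <- counts[hit] + 1L
  }
  supports <- round(100 * counts / done)
  # attach as node labels (root and any label-less nodes get "")
  n <- length(full$tip.label)
  node_lab <- rep("", full$Nnode)
  for (k in seq_along(bip)) {
    node <- as.integer(names(bip)[k])
    node_lab[node - n] <- as.character(supports[[k]])
  }
  full$node.label <- node_lab
  list(tree = full, supports = supports, n_replicates = done,
       n_failures = failures)
}

#' Write a tree to a Newick file
#'
#' Branch lengths are kept; integer bootstrap supports, when present, are
#' serialised as internal node labels.
#'
#' @param tree a `phylo` object.
#' @param path output path (NULL returns the Newick string).
#' @return the path (or the Newick text when `path` is NULL), invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) {
    return(ape::write.tree(tree))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
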