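# Distance-based trees (NJ, UPGMA) with column-resampling bootstrap support,
# emitted as ape "phylo" objects and therefore Newick-serialisable with
# ape::write.tree().

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]).  For additive matrices the
#' generating topology and branch lengths are reproduced exactly.  Negative
#' branch lengths are clamped to zero; the pre-clamp values are kept in the
#' `"clamped"` attribute.
#'
#' @param dm Symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  .check_dist_matrix(dm, min_taxa = 3L)
  tr <- ape::nj(as.matrix(dm))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    attr(tr, "clamped") <- tr$edge.length[neg]
    tr$edge.length[neg] <- 0
  }
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration (via [phangorn::upgma()]); the result is
#' rooted and ultrametric, with leaf-to-root depths equal to half the fusion
#' heights.
#'
#' @param dm Symmetric distance matrix with ids as dimnames (>= 2 taxa).
#' @return Rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  .check_dist_matrix(dm, min_taxa = 2L)
  phangorn::upgma(stats::as.dist(as.matrix(dm)))
}

.check_dist_matrix <- function(dm, min_taxa) {
  dm <- as.matrix(dm)
  if (nrow(dm) < min_taxa) stop("need at least ", min_taxa, " taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("distance matrix is not symmetric")
  invisible(dm)
}

#' Distance tree with bootstrap support from an alignment
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, recomputes the
#' distance matrix and the tree for each replicate, and reports for every
#' internal bipartition of the point tree the percentage of replicates that
#' contain it (stored in `node.label`).  Replicates in which some pair has
#' no comparable sites are skipped and counted.
#'
#' @param seqs Aligned sequences (named equal-length character vector or
#'   site matrix).
#' @param builder `"nj"` (default; n_reps defaults to 1000) or `"upgma"`
#'   (n_reps defaults to 100).
#' @param metric `"p"` or `"tn93_mcl"`.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Seed for the resampling RNG.
#' @return List with `tree` (point tree, supports in `node.label`),
#'   `supports` (numeric, per internal node), `n_used` (replicates that
#'   produced a tree) and `n_skipped`.
#' @export
bootstrap_support <- function(seqs, builder = c("nj", "upgma"),
                              metric = c("p", "tn93_mcl"),
                              n_reps = NULL, seed = 1L) {
  builder <- match.arg(builder)
  metric <- match.arg(metric)
  if (is.null(n_reps)) n_reps <- if (builder == "nj") 1000L else 100L
  stopifnot(n_reps >= 1L)
  mat <- .seq_matrix(seqs)
  if (ncol(mat) < 1L) stop("alignment has no columns")
  dist_fun <- function(m) suppressWarnings(
    if (metric == "p") p_distance_matrix(m) else mcl_distance_matrix(m))
  build_fun <- if (builder == "nj") nj_tree else upgma_tree
  point <- build_fun(dist_fun(mat))
  set.seed(seed)
  boots <- vector("list", n_reps)
  n_skipped <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    tr <- tryCatch(build_fun(dist_fun(mat[, cols, drop = FALSE])),
                   error = function(e) NULL)
    if (is.null(tr)) n_skipped <- n_skipped + 1L else boots[[b]] <- tr
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  counts <- ape::prop.clades(point, boots, rooted = (builder == "upgma"))
  counts[is.na(counts)] <- 0
  supports <- 100 * counts / length(boots)
  point$node.label <- sprintf("%g", round(supports, 1))
  list(tree = point, supports = supports, n_used = length(boots),
       n_skipped = n_skipped)
}
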