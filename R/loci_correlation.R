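# Independence of variation among the four loci: if repeat variants arise
# independently in ITS1, 5.8S, ITS2 and LSU, the per-clone distances to the
# reference should be uncorrelated across loci.

#' Pearson correlation with a t-based p-value
#'
#' Thin, validating wrapper around [stats::cor.test()]: product-moment
#' correlation with the two-sided p-value from the t transform on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `>= 3` with non-zero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate vector: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Per-clone, per-locus distances to the reference
#'
#' @param reference Reference sequence anchored to the clones.
#' @param clones Clone set (with `consensus` present when
#'   `source = "consensus"`) or a site matrix.
#' @param ann A [locus_annotation()].
#' @param source `"consensus"` or `"original"` sequences.
#' @param metric Distance metric.
#' @param original_strand Strand used as the original sequence.
#' @return Numeric matrix (clones x loci) of distances; clones with a
#'   non-finite distance in any locus are dropped listwise with a message.
#' @export
locus_distance_profiles <- function(reference, clones, ann,
                                    source = c("consensus", "original"),
                                    metric = c("p", "tn93_mcl"),
                                    original_strand = c("fwd", "rev")) {
  source <- match.arg(source)
  metric <- match.arg(metric)
  original_strand <- match.arg(original_strand)
  mat <- if (is.matrix(clones)) clones
  else if (source == "consensus") {
    if (is.null(clones$consensus))
      stop("clones carry no consensus; run consensus_clone_set() first")
    clones$consensus
  } else clones[[original_strand]]
  ref <- .residues(reference)
  prof <- vapply(ann$locus,
                 function(locus) .dist_vs_ref(ref, mat,
                                              locus_sites(ann, locus),
                                              metric),
                 numeric(nrow(mat)))
  colnames(prof) <- ann$locus
  prof <- prof[, .LOCI, drop = FALSE]
  bad <- !stats::complete.cases(prof) | rowSums(!is.finite(prof)) > 0
  if (any(bad)) {
    message(sum(bad), " clone(s) dropped (no comparable sites in a locus)")
    prof <- prof[!bad, , drop = FALSE]
  }
  prof
}

#' Correlation table among the four loci
#'
#' Builds the 4 x 4 locus correlation table: Pearson correlations in the
#' lower triangle and their two-sided p-values in the upper triangle,
#' computed over clones from the per-locus distances to the reference.
#' p-values are reported raw (a Bonferroni-adjusted copy for the six pairs
#' is returned alongside, clearly separated).
#'
#' @param profiles Clone x locus distance matrix from
#'   [locus_distance_profiles()].
#' @param strict If `TRUE` (default), a zero-variance locus raises the
#'   [pearson_r()] error; if `FALSE`, affected pairs become `NA`.
#' @return Object of class `locus_correlation`: list with `r`, `p`,
#'   `p_bonferroni` (4 x 4 matrices), `table` (lower triangle r, upper
#'   triangle p) and `n`.
#' @export
correlation_table <- function(profiles, strict = TRUE) {
  if (nrow(profiles) < 3L) stop("need at least 3 complete clone profiles")
  loci <- colnames(profiles)
  k <- length(loci)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      res <- if (strict) pearson_r(profiles[, i], profiles[, j]) else
        tryCatch(pearson_r(profiles[, i], profiles[, j]),
                 error = function(e) list(r = NA_real_,
                                          p_value = NA_real_))
      r[j, i] <- r[i, j] <- res$r
      p[j, i] <- p[i, j] <- res$p_value
    }
  }
  tab <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  tab[lower.tri(tab)] <- r[lower.tri(r)]
  tab[upper.tri(tab)] <- p[upper.tri(p)]
  structure(list(r = r, p = p,
                 p_bonferroni = pmin(p * choose(k, 2), 1),
                 table = tab, n = nrow(profiles)),
            class = "locus_correlation")
}

#' @export
print.locus_correlation <- function(x, digits = 4, ...) {
  cat("Locus correlation table (lower triangle r, upper triangle p), n =",
      x$n, "clones\n")
  print(round(x$table, digits), na.print = "")
  invisible(x)
}
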