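# Metagenomics-scenario analysis: what happens when single reads drawn from a
# heterogeneous repeat array are identified against species-level distance
# thresholds, and how many spurious OTUs the intragenomic variants create.

#' Species-identification distance thresholds
#'
#' Default per-locus distance thresholds (as fractions of sites): 1% for the
#' LSU D1/D2 domain and 1.59% for the ITS regions, the values commonly used
#' for yeast species delimitation; 5.8S has no published threshold of its own
#' and inherits the ITS value.  A stricter whole-ITS barcode limit of 0.69%
#' is carried alongside.
#'
#' @param LSU,ITS1,ITS2,`5.8S` Per-locus thresholds.
#' @param whole_its Whole-ITS barcode limit.
#' @return Named numeric vector of class `threshold_set`.
#' @export
threshold_set <- function(LSU = 0.01, ITS1 = 0.0159, ITS2 = 0.0159,
                          `5.8S` = 0.0159, whole_its = 0.0069) {
  out <- c(ITS1 = ITS1, "5.8S" = `5.8S`, ITS2 = ITS2, LSU = LSU,
           whole_its = whole_its)
  if (any(out <= 0 | out >= 1)) stop("thresholds must lie in (0, 1)")
  class(out) <- "threshold_set"
  out
}

#' Attribute a read to a species from its distances to two type strains
#'
#' @param d_A,d_B Distances of the read to type strains A and B (vectorised).
#' @param t Distance threshold.
#' @return Character vector: `"A"`, `"B"`, `"ambiguous_both"` (within the
#'   threshold of both) or `"novel_neither"` (outside both).
#' @export
attribute_read <- function(d_A, d_B, t) {
  stopifnot(all(d_A >= 0), all(d_B >= 0), length(t) == 1L)
  ifelse(d_A <= t & d_B > t, "A",
         ifelse(d_B <= t & d_A > t, "B",
                ifelse(d_A <= t & d_B <= t, "ambiguous_both",
                       "novel_neither")))
}

#' Fraction of pairwise distances exceeding a threshold
#'
#' @param dm Symmetric distance matrix.
#' @param t Threshold; strictly greater distances count (boundary values are
#'   "within the threshold range").
#' @return Fraction of upper-triangle distances `> t`.
#' @export
threshold_exceedance <- function(dm, t) {
  v <- dm[upper.tri(dm)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty distance matrix")
  mean(v > t)
}

#' Per-locus species attribution and alpha-diversity overestimate
#'
#' Treats each clone sequence as a single metagenomic read: per locus, each
#' read is attributed to type strain A, type strain B, both, or neither by
#' comparing its distances to the two strains with the locus threshold
#' (`mode = "nearest"` instead assigns each read to the closer strain, with
#' `novel_neither` when both exceed the threshold).  Reads are also clustered
#' by single linkage at the threshold; since every read derives from one
#' genome, each cluster beyond the first is a spurious OTU.
#'
#' @param reads Reads anchored to refA (named equal-length character vector
#'   or site matrix, or a clone set plus `use`).
#' @param refA,refB Type-strain sequences anchored to the same coordinates.
#' @param ann A [locus_annotation()].
#' @param thresholds A [threshold_set()].
#' @param metric Distance metric for read-vs-strain and read-vs-read
#'   distances (`"p"` default).
#' @param mode `"threshold"` (default) or `"nearest"`.
#' @param use For clone-set input: which matrix holds the reads
#'   (default `"fwd"`, the original strand).
#' @return List with `per_locus` (data.frame: locus, threshold, pct_A, pct_B,
#'   pct_ambiguous, pct_novel, exceedance, spurious_otus, n_reads) and
#'   `attributions` (per read and locus: distances and call).
#' @export
diversity_overestimate <- function(reads, refA, refB, ann,
                                   thresholds = threshold_set(),
                                   metric = c("p", "tn93_mcl"),
                                   mode = c("threshold", "nearest"),
                                   use = "fwd") {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (is.list(reads) && !is.null(reads[[use]])) reads <- reads[[use]]
  mat <- .seq_matrix(reads)
  if (nrow(mat) == 0L) stop("empty read set")
  ra <- .residues(refA); rb <- .residues(refB)
  per_locus <- list(); attr_rows <- list()
  for (locus in ann$locus) {
    sites <- locus_sites(ann, locus)
    t <- unname(thresholds[[locus]])
    dA <- .dist_vs_ref(ra, mat, sites, metric)
    dB <- .dist_vs_ref(rb, mat, sites, metric)
    call <- if (mode == "threshold") attribute_read(dA, dB, t) else
      ifelse(pmin(dA, dB) > t, "novel_neither",
             ifelse(dA < dB, "A", ifelse(dB < dA, "B", "ambiguous_both")))
    sub <- mat[, sites, drop = FALSE]
    if (nrow(sub) > 1L) {
      dm <- suppressWarnings(
        if (metric == "p") p_distance_matrix(sub) else
          mcl_distance_matrix(sub))
      exceed <- threshold_exceedance(dm, t)
      hc <- stats::hclust(stats::as.dist(dm), method = "single")
      n_otu <- length(unique(stats::cutree(hc, h = t)))
    } else {
      exceed <- 0; n_otu <- 1L
    }
    per_locus[[locus]] <- data.frame(
      locus = locus, threshold = t,
      pct_A = 100 * mean(call == "A"),
      pct_B = 100 * mean(call == "B"),
      pct_ambiguous = 100 * mean(call == "ambiguous_both"),
      pct_novel = 100 * mean(call == "novel_neither"),
      exceedance = exceed, spurious_otus = n_otu - 1L,
      n_reads = nrow(mat), stringsAsFactors = FALSE)
    attr_rows[[locus]] <- data.frame(
      read_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
      locus = locus, distance_to_A = unname(dA), distance_to_B = unname(dB),
      call = call, stringsAsFactors = FALSE)
  }
  list(per_locus = do.call(rbind, c(per_locus, make.row.names = FALSE)),
       attributions = do.call(rbind, c(attr_rows, make.row.names = FALSE)))
}

#' Histogram and accumulation curve of pairwise distances
#'
#' @param dm Symmetric distance matrix.
#' @param bins Number of equal-width bins over `[0, max(distance)]`.
#' @return `data.frame` with `bin_left`, `bin_right`, `count`, `cumulative`
#'   (fraction of distances at or below `bin_right`).
#' @export
distance_histogram <- function(dm, bins = 30L) {
  v <- dm[upper.tri(dm)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty distance matrix")
  top <- max(v)
  if (top == 0) top <- 1e-6
  breaks <- seq(0, top, length.out = bins + 1L)
  cnt <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                       bins), nbins = bins)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1L],
             count = cnt, cumulative = cumsum(cnt) / length(v))
}
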