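# Per-locus substitution distances: p-distance, Tamura-Nei (1993), and a
# pooled-parameter TN93 variant in which base frequencies are estimated once
# from all compared pairs and each pair's distance is then computed from its
# own substitution counts (a composite-likelihood style estimator).

#' Substitution counts for one pair of anchored sequences
#'
#' Counts compared sites and substitution classes between two sequences on a
#' common coordinate system.  Under pairwise deletion (the default and only
#' mode for a single pair), sites where either member carries a gap, `N` or
#' any IUPAC ambiguity code are excluded.
#'
#' @param a,b Sequences (character strings or residue vectors) of equal
#'   length.
#' @return List with `L` (compared sites), `P1` (A<->G transitions), `P2`
#'   (C<->T transitions), `Q` (transversions), and `base_freqs` (named
#'   numeric, A/C/G/T frequencies over both members at compared sites).
#' @examples
#' pair_counts("ACGT", "GCGT")  # L = 4, P1 = 1
#' @export
pair_counts <- function(a, b) {
  av <- .residues(a); bv <- .residues(b)
  if (length(av) != length(bv))
    stop("sequences must be anchored to common coordinates (equal length)")
  ok <- av %in% .DNA_BASES & bv %in% .DNA_BASES
  av <- av[ok]; bv <- bv[ok]
  L <- length(av)
  P1 <- sum((av == "A" & bv == "G") | (av == "G" & bv == "A"))
  P2 <- sum((av == "C" & bv == "T") | (av == "T" & bv == "C"))
  diff <- sum(av != bv)
  cnt <- table(factor(c(av, bv), levels = .DNA_BASES))
  bf <- if (L > 0) as.numeric(cnt) / (2 * L) else rep(NA_real_, 4L)
  names(bf) <- .DNA_BASES
  list(L = L, P1 = P1, P2 = P2, Q = diff - P1 - P2, base_freqs = bf)
}

#' Proportion of differing sites (p-distance)
#'
#' @param counts A [pair_counts()] result.
#' @return Numeric distance `(P1 + P2 + Q) / L`.
#' @export
p_distance <- function(counts) {
  if (counts$L == 0) stop("no comparable sites")
  (counts$P1 + counts$P2 + counts$Q) / counts$L
}

# TN93 distance from substitution proportions and base frequencies;
# vectorised over p1/p2/q (matrices or scalars).  Saturated entries -> NA.
.tn93_formula <- function(p1, p2, q, pi) {
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  gR <- piA + piG; gY <- piC + piT
  if (gR <= 0 || gY <= 0)
    stop("degenerate base composition: a purine/pyrimidine class is absent")
  k1 <- 2 * piA * piG / gR
  k2 <- 2 * piC * piT / gY
  k3 <- 2 * (gR * gY - piA * piG * gY / gR - piC * piT * gR / gY)
  w1 <- if (k1 > 0) 1 - p1 / k1 - q / (2 * gR) else 1 + 0 * p1
  w2 <- if (k2 > 0) 1 - p2 / k2 - q / (2 * gY) else 1 + 0 * p2
  w3 <- 1 - q / (2 * gR * gY)
  sat <- w1 <= 0 | w2 <= 0 | w3 <= 0
  w1[sat] <- w2[sat] <- w3[sat] <- 1  # placeholder, overwritten with NA
  d <- -(if (k1 > 0) k1 * log(w1) else 0 * w1) -
    (if (k2 > 0) k2 * log(w2) else 0 * w2) - k3 * log(w3)
  d[sat] <- NA_real_
  d
}

#' Tamura-Nei (1993) distance for one pair
#'
#' Closed-form TN93 distance (two transition classes plus transversions,
#' unequal base frequencies) computed from a pair's substitution counts.
#' Pairs whose counts put a logarithm argument at or below zero are
#' saturated: the distance is `NA` with attribute `saturated = TRUE` and a
#' warning.
#'
#' @param counts A [pair_counts()] result (or any list with `L`, `P1`, `P2`,
#'   `Q` and `base_freqs`).
#' @return Numeric distance in substitutions per site.
#' @export
tn93_distance <- function(counts) {
  if (counts$L == 0) stop("no comparable sites")
  d <- .tn93_formula(counts$P1 / counts$L, counts$P2 / counts$L,
                     counts$Q / counts$L, counts$base_freqs)
  if (is.na(d)) {
    warning("saturated pair: TN93 logarithm argument <= 0")
    attr(d, "saturated") <- TRUE
  }
  d
}

# Indicator matrices and all-pairs substitution counts for a site matrix.
# Returns n x n count matrices via cross products: for rows i, j,
#   L[i,j]  = sites where both are unambiguous A/C/G/T,
#   P1, P2  = transition counts, Q = transversions, and per-base counts
#   Cb[i,j] = copies of base b in row i at sites compared with row j.
.pairwise_counts <- function(mat) {
  I <- lapply(.DNA_BASES, function(b) (mat == b) * 1)
  names(I) <- .DNA_BASES
  M <- I$A + I$C + I$G + I$T
  L <- tcrossprod(M)
  match <- tcrossprod(I$A) + tcrossprod(I$C) + tcrossprod(I$G) +
    tcrossprod(I$T)
  P1 <- tcrossprod(I$A, I$G) + tcrossprod(I$G, I$A)
  P2 <- tcrossprod(I$C, I$T) + tcrossprod(I$T, I$C)
  Q <- L - match - P1 - P2
  Cb <- lapply(I, function(Ib) tcrossprod(Ib, M))
  list(L = L, P1 = P1, P2 = P2, Q = Q, Cb = Cb)
}

# pooled A/C/G/T frequencies over a set of ordered pairs (logical mask on the
# n x n pair matrix; the mask is symmetrised internally)
.pooled_freqs <- function(cnt, mask) {
  mask <- mask | t(mask)
  tot <- vapply(cnt$Cb, function(Cb) sum(Cb[mask]), numeric(1))
  if (sum(tot) == 0) stop("no comparable sites in any pair")
  tot / sum(tot)
}

#' Pairwise distance matrix under the pooled-parameter TN93 model
#'
#' Computes all pairwise distances for a set of reference-anchored sequences.
#' Base frequencies are estimated once, pooled over the compared sites of all
#' pairs; each pair's distance is then the TN93 closed form evaluated with the
#' pooled frequencies and that pair's own transition/transversion counts.
#' With exactly two sequences this reduces to [tn93_distance()].
#'
#' Sites carrying a gap, `N` or an ambiguity code in a member of a pair are
#' excluded for that pair (pairwise deletion); `gap_mode = "complete"` instead
#' drops every site that is ambiguous in any sequence of the set.  Saturated
#' pairs are `NA` with a warning and are reported in the `"saturated"`
#' attribute.
#'
#' @param seqs Named character vector of equal-length sequences, or a
#'   character site matrix (rows = sequences).
#' @param gap_mode `"pairwise"` (default) or `"complete"` deletion.
#' @return Symmetric numeric matrix of distances (substitutions per site)
#'   with sequence ids as dimnames and attributes `metric = "tn93_mcl"` and
#'   `saturated` (two-column matrix of saturated pair indices, if any).
#' @export
mcl_distance_matrix <- function(seqs, gap_mode = c("pairwise", "complete")) {
  gap_mode <- match.arg(gap_mode)
  mat <- .seq_matrix(seqs)
  if (nrow(mat) < 2L) stop("need at least 2 sequences")
  if (gap_mode == "complete") {
    keep <- apply(matrix(mat %in% .DNA_BASES, nrow(mat)), 2L, all)
    mat <- mat[, keep, drop = FALSE]
  }
  cnt <- .pairwise_counts(mat)
  off <- upper.tri(cnt$L)
  if (any(cnt$L[off] == 0)) stop("no comparable sites for at least one pair")
  pi <- .pooled_freqs(cnt, off)
  d <- .tn93_formula(cnt$P1 / cnt$L, cnt$P2 / cnt$L, cnt$Q / cnt$L, pi)
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  sat <- which(is.na(d) & (off | t(off)), arr.ind = TRUE)
  if (nrow(sat)) {
    warning(nrow(sat) / 2, " saturated pair(s) set to NA")
    attr(d, "saturated") <- sat[sat[, 1] < sat[, 2], , drop = FALSE]
  }
  attr(d, "metric") <- "tn93_mcl"
  d
}

#' Pairwise p-distance matrix
#'
#' @inheritParams mcl_distance_matrix
#' @return Symmetric matrix of uncorrected distances with
#'   `metric = "p"` attribute.
#' @export
p_distance_matrix <- function(seqs) {
  mat <- .seq_matrix(seqs)
  if (nrow(mat) < 2L) stop("need at least 2 sequences")
  cnt <- .pairwise_counts(mat)
  if (any(cnt$L[upper.tri(cnt$L)] == 0))
    stop("no comparable sites for at least one pair")
  d <- (cnt$P1 + cnt$P2 + cnt$Q) / cnt$L
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  attr(d, "metric") <- "p"
  d
}

# Distances of every row of `mat` to a reference residue vector, restricted
# to columns `sites`.  For metric "tn93_mcl" base frequencies are pooled over
# all reference-vs-row pairs.
.dist_vs_ref <- function(ref, mat, sites, metric = c("p", "tn93_mcl")) {
  metric <- match.arg(metric)
  rv <- ref[sites]
  sub <- mat[, sites, drop = FALSE]
  refmat <- matrix(rv, nrow(sub), ncol(sub), byrow = TRUE)
  ok <- matrix(rv %in% .DNA_BASES, nrow(sub), ncol(sub), byrow = TRUE) &
    (sub == "A" | sub == "C" | sub == "G" | sub == "T")
  L <- rowSums(ok)
  if (metric == "p") {
    nd <- rowSums(ok & sub != refmat)
    d <- ifelse(L > 0, nd / L, NA_real_)
  } else {
    isA <- sub == "A" & ok; isC <- sub == "C" & ok
    isG <- sub == "G" & ok; isT <- sub == "T" & ok
    rA <- refmat == "A"; rC <- refmat == "C"
    rG <- refmat == "G"; rT <- refmat == "T"
    P1 <- rowSums((isA & rG) | (isG & rA))
    P2 <- rowSums((isC & rT) | (isT & rC))
    nd <- rowSums(ok & sub != refmat)
    Q <- nd - P1 - P2
    tot <- c(A = sum(isA) + sum(ok & rA), C = sum(isC) + sum(ok & rC),
             G = sum(isG) + sum(ok & rG), T = sum(isT) + sum(ok & rT))
    pi <- tot / sum(tot)
    d <- .tn93_formula(P1 / L, P2 / L, Q / L, pi)
    d[L == 0] <- NA_real_
  }
  names(d) <- rownames(mat)
  d
}

#' Per-locus distance summaries for the four analytical settings
#'
#' Summarises, per locus, the mean and maximum substitution distance under
#' four settings: clone consensus sequences vs the reference Sanger sequence,
#' clone original (single-strand) sequences vs the reference, all pairwise
#' distances among consensus sequences, and all pairwise distances among
#' original sequences.  The contrast between the vs-reference and pairwise
#' settings, and between consensus and original sequences, measures how much
#' intragenomic heterogeneity the consensus-building step hides.
#'
#' @param reference Reference sequence (string or residue vector), anchored
#'   to the same coordinates as the clones.
#' @param clones A clone set (see [simulate_clone_reads()]) that has passed
#'   through [consensus_clone_set()], or a list with `fwd`, `rev` and
#'   `consensus` character matrices.
#' @param ann A [locus_annotation()].
#' @param metric `"p"` or `"tn93_mcl"`.
#' @param original_strand Which single-strand read plays the "original
#'   (non-consensus)" role: `"fwd"` (default) or `"rev"`.
#' @return `data.frame` with columns `locus`, `setting`, `metric`, `mean`,
#'   `max`, `n`, `n_saturated`.
#' @export
four_setting_summary <- function(reference, clones, ann,
                                 metric = c("p", "tn93_mcl"),
                                 original_strand = c("fwd", "rev")) {
  metric <- match.arg(metric)
  original_strand <- match.arg(original_strand)
  if (is.null(clones$consensus))
    stop("clones carry no consensus; run consensus_clone_set() first")
  ref <- .residues(reference)
  orig <- clones[[original_strand]]
  cons <- clones$consensus
  if (nrow(orig) < 2L)
    warning("fewer than 2 clones: pairwise settings are empty")
  settings <- c("ref_vs_consensus", "ref_vs_original",
                "pairwise_consensus", "pairwise_original")
  res <- list()
  for (locus in ann$locus) {
    sites <- locus_sites(ann, locus)
    for (setting in settings) {
      ds <- switch(setting,
        ref_vs_consensus = .dist_vs_ref(ref, cons, sites, metric),
        ref_vs_original = .dist_vs_ref(ref, orig, sites, metric),
        pairwise_consensus = ,
        pairwise_original = {
          m <- (if (setting == "pairwise_consensus") cons else
                  orig)[, sites, drop = FALSE]
          if (nrow(m) < 2L) numeric(0) else {
            dm <- suppressWarnings(
              if (metric == "p") p_distance_matrix(m)
              else mcl_distance_matrix(m))
            dm[upper.tri(dm)]
          }
        })
      nsat <- sum(is.na(ds))
      ds <- ds[!is.na(ds)]
      res[[length(res) + 1L]] <- data.frame(
        locus = locus, setting = setting, metric = metric,
        mean = if (length(ds)) mean(ds) else NA_real_,
        max = if (length(ds)) max(ds) else NA_real_,
        n = length(ds), n_saturated = nsat,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Per-clone distance to the reference for one locus
#'
#' @param reference Reference sequence (string or residue vector).
#' @param seqs Clone sequences (named equal-length character vector or site
#'   matrix) anchored to the reference.
#' @param ann A [locus_annotation()], or `NULL` to use the whole sequence.
#' @param locus Locus name (ignored when `ann` is `NULL`).
#' @param metric `"p"` or `"tn93_mcl"`.
#' @return Named numeric vector of distances.
#' @export
distance_to_reference <- function(reference, seqs, ann = NULL, locus = NULL,
                                  metric = c("p", "tn93_mcl")) {
  metric <- match.arg(metric)
  ref <- .residues(reference)
  mat <- .seq_matrix(seqs)
  sites <- if (is.null(ann)) seq_along(ref) else locus_sites(ann, locus)
  .dist_vs_ref(ref, mat, sites, metric)
}
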