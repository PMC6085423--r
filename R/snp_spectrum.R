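# SNP frequency spectrum among cloned repeat copies, classified against two
# type-strain sequences.  Every variable reference-anchored site is a SNP with
# respect to (1) type strain A only, (2) type strain B only, (3) both, or
# (4) none, and carries a frequency among the clones that — in the repeat
# arrays this package models — is expected to be bimodal: fixed differences
# near 100% and rare repeat variants at a few percent, with no intermediate
# class.

#' Allele counts of the clones at one reference site
#'
#' @param seqs Clone sequences anchored to the reference (named equal-length
#'   character vector or site matrix).
#' @param pos 1-based reference position.
#' @return Named integer vector of A/C/G/T counts (only bases present);
#'   attribute `uncalled` counts clones with a gap, `N` or ambiguity code at
#'   the site.
#' @export
call_site_alleles <- function(seqs, pos) {
  col <- .seq_matrix(seqs)[, pos]
  called <- col[col %in% .DNA_BASES]
  out <- table(called)
  out <- structure(as.integer(out), names = names(out))
  attr(out, "uncalled") <- length(col) - length(called)
  out
}

#' Classify one variable site against the two type strains
#'
#' The site's variant allele is the most frequent clone allele differing from
#' either type-strain allele.  The frequency rule makes the spectrum read the
#' way a clone library is read: when the clone-majority allele matches both
#' type strains, `freq` is the fraction of called clones carrying the variant
#' (a rare repeat variant); when the majority allele itself differs from a
#' type allele (a fixed difference), `freq` is the fraction carrying the
#' majority allele, i.e. about 1 for a species-diagnostic site.
#'
#' @param counts Named integer vector of clone allele counts (as from
#'   [call_site_alleles()]).
#' @param allele_A,allele_B Type-strain bases at the site.
#' @return List with `category` (one of `vs_A_only`, `vs_B_only`, `vs_both`,
#'   `none`), `freq`, and `variant_allele` (`NA` for category `none`).
#' @examples
#' classify_site(c(A = 83, G = 2), "A", "A")   # vs_both, freq 2/85
#' classify_site(c(G = 85), "A", "G")          # vs_A_only, freq 1
#' @export
classify_site <- function(counts, allele_A, allele_B) {
  stopifnot(length(counts) > 0)
  total <- sum(counts)
  ord <- order(-counts, names(counts))  # ties broken alphabetically
  majority <- names(counts)[ord[1L]]
  if (majority == allele_A && majority == allele_B) {
    minor <- counts[names(counts) != majority]
    if (!length(minor)) return(list(category = "none", freq = 0,
                                    variant_allele = NA_character_))
    variant <- names(minor)[order(-minor, names(minor))][1L]
    freq <- sum(minor) / total
  } else {
    variant <- majority
    freq <- counts[[majority]] / total
  }
  category <- if (variant != allele_A && variant != allele_B) "vs_both"
  else if (variant != allele_A) "vs_A_only"
  else "vs_B_only"
  list(category = category, freq = unname(freq), variant_allele = variant)
}

#' Frequency class of a SNP
#'
#' @param freq Variant frequency in `[0, 1]` (vectorised).
#' @param high_cut Frequencies at or above this are `high` (default 0.5).
#' @param low_cut Frequencies at or below this are `low` (default 0.1).
#' @return Character vector in `high`, `low`, `intermediate`.  The
#'   intermediate class is reported, never suppressed: its absence from real
#'   repeat arrays is an empirical finding, not a rule.
#' @export
frequency_class <- function(freq, high_cut = 0.5, low_cut = 0.1) {
  stopifnot(all(freq >= 0 & freq <= 1))
  ifelse(freq >= high_cut, "high",
         ifelse(freq <= low_cut, "low", "intermediate"))
}

#' Build the SNP spectrum of a clone set against two type strains
#'
#' Scans every reference position and emits one record per clone allele that
#' differs from at least one type-strain allele (multi-allelic sites
#' decompose into one record per such allele, each with its own frequency),
#' consistent with [classify_site()].  Positions where the two type strains
#' differ are tallied separately (the "stripes" under a spectrum plot),
#' independently of the clones.
#'
#' @param clones Clone sequences anchored to type strain A's coordinates
#'   (named equal-length character vector, site matrix, or a clone set whose
#'   matrix is selected with `use`).
#' @param refA,refB Type-strain sequences; `refA` is the coordinate anchor
#'   and `refB` must be anchored to it (equal length, or it is aligned and
#'   lifted over).
#' @param ann A [locus_annotation()].
#' @param use For clone-set input: `"consensus"`, `"fwd"` or `"rev"`.
#' @param high_cut,low_cut Passed to [frequency_class()].
#' @return Object of class `spectrum_report`: list with `snps` (data.frame:
#'   locus, pos, allele_A, allele_B, variant_allele, n_called, count, freq,
#'   category, freq_class), `typestrain_diffs` (data.frame: locus, pos),
#'   `per_locus` (count table by locus, category and frequency class) and
#'   `n_clones`.
#' @export
build_spectrum <- function(clones, refA, refB, ann, use = "consensus",
                           high_cut = 0.5, low_cut = 0.1) {
  if (is.list(clones) && !is.null(clones[[use]])) clones <- clones[[use]]
  mat <- .seq_matrix(clones)
  ra <- .residues(refA)
  rb <- .residues(refB)
  if (length(rb) != length(ra)) {
    aln <- align_to_reference(.collapse(ra), .collapse(rb))
    lifted <- rep("-", length(ra))
    qc <- .chars(aln$aligned_qry)
    keep <- !is.na(aln$ref_coords)
    lifted[aln$ref_coords[keep]] <- qc[keep]
    rb <- lifted
  }
  if (ncol(mat) != length(ra))
    stop("clones are not anchored to refA (length mismatch)")
  if (!setequal(ann$locus, .LOCI))
    stop("annotation must cover all four loci")
  locus_of <- rep(NA_character_, length(ra))
  for (locus in ann$locus) locus_of[locus_sites(ann, locus)] <- locus

  # candidate sites: any called clone allele differs from a type allele, or
  # the type strains differ between themselves
  counts4 <- vapply(.DNA_BASES, function(b) colSums(mat == b),
                    numeric(ncol(mat)))            # L x 4
  called <- rowSums(counts4)
  ts_diff <- ra != rb & ra %in% .DNA_BASES & rb %in% .DNA_BASES
  non_refA <- called - ifelse(ra %in% .DNA_BASES,
                              counts4[cbind(seq_along(ra),
                                            match(ra, .DNA_BASES))], 0)
  non_refB <- called - ifelse(rb %in% .DNA_BASES,
                              counts4[cbind(seq_along(rb),
                                            match(rb, .DNA_BASES))], 0)
  candidates <- which((non_refA > 0 | non_refB > 0 | ts_diff) &
                        !is.na(locus_of))
  rows <- list()
  for (pos in candidates) {
    cnts <- counts4[pos, counts4[pos, ] > 0]
    if (!length(cnts)) next
    if (!(ra[pos] %in% .DNA_BASES) || !(rb[pos] %in% .DNA_BASES)) next
    total <- sum(cnts)
    ord <- order(-cnts, names(cnts))
    majority <- names(cnts)[ord[1L]]
    for (allele in names(cnts)) {
      if (allele == ra[pos] && allele == rb[pos]) next
      # frequency rule of classify_site, per allele
      freq <- cnts[[allele]] / total
      category <- if (allele != ra[pos] && allele != rb[pos]) "vs_both"
      else if (allele != ra[pos]) "vs_A_only"
      else "vs_B_only"
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus_of[pos], pos = pos,
        allele_A = ra[pos], allele_B = rb[pos],
        variant_allele = allele, n_called = total,
        count = cnts[[allele]], freq = freq, category = category,
        stringsAsFactors = FALSE)
    }
  }
  snps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), pos = integer(0),
               allele_A = character(0), allele_B = character(0),
               variant_allele = character(0), n_called = integer(0),
               count = integer(0), freq = numeric(0),
               category = character(0), stringsAsFactors = FALSE)
  snps$freq_class <- if (nrow(snps))
    frequency_class(snps$freq, high_cut, low_cut) else character(0)
  ts <- data.frame(locus = locus_of[which(ts_diff)],
                   pos = which(ts_diff), stringsAsFactors = FALSE)
  ts <- ts[!is.na(ts$locus), , drop = FALSE]
  per_locus <- if (nrow(snps))
    as.data.frame(table(locus = factor(snps$locus, levels = .LOCI),
                        category = snps$category,
                        freq_class = snps$freq_class),
                  responseName = "n") else NULL
  structure(list(snps = snps, typestrain_diffs = ts, per_locus = per_locus,
                 n_clones = nrow(mat)),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat("SNP spectrum:", nrow(x$snps), "records from", x$n_clones, "clones;",
      nrow(x$typestrain_diffs), "type-strain differences\n")
  if (nrow(x$snps)) {
    tab <- table(x$snps$locus, x$snps$freq_class)
    print(tab)
  }
  invisible(x)
}
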