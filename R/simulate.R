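# Synthetic tandem-repeat arrays with the variant structure observed in
# intragenomically heterogeneous rDNA operons: two sister species separated
# by a handful of fixed (high-frequency) differences per locus, plus rare
# repeat variants each carried by a small, exact fraction of the copies, with
# nothing in between.  The generator is the ground truth against which every
# analysis stage of the package is validated.

#' Simulation configuration
#'
#' Defaults emulate a yeast rDNA clone-library study: an amplicon of four
#' loci (ITS1 180 bp, 5.8S 160 bp, ITS2 230 bp, LSU D1/D2 570 bp, ~1140 bp
#' total), 120 tandem copies per genome, 85 clones sequenced in both
#' directions, per-locus fixed interspecies differences (ITS1 5, 5.8S 0,
#' ITS2 3, LSU 5), per-locus rare-variant site counts (ITS1 8, 5.8S 6,
#' ITS2 5, LSU 22), each rare variant carried by an exact 2% of the copies,
#' and error-free reads.
#'
#' @param seed Integer seed; all randomness of a run flows from it.
#' @param locus_lengths Named integer vector of locus lengths in genomic
#'   order.
#' @param C Tandem copies per genome.
#' @param n_clones Clones sampled (with replacement) from the array.
#' @param interspecies_diffs Named integer vector: fixed differences between
#'   the two species canonicals, per locus.
#' @param low_freq_sites Named integer vector: rare-variant sites per locus.
#' @param low_freq Carrier fraction per rare variant, in (0, 0.5).
#' @param read_error_rate Per-base substitution error rate of each read.
#' @param carrier_mode `"exact"` (default): each rare variant is planted in
#'   exactly `round(low_freq * C)` copies, making the planted frequency a
#'   sharp ground truth; `"bernoulli"`: each copy carries it independently
#'   with probability `low_freq`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       locus_lengths = c(ITS1 = 180L, "5.8S" = 160L,
                                         ITS2 = 230L, LSU = 570L),
                       C = 120L, n_clones = 85L,
                       interspecies_diffs = c(ITS1 = 5L, "5.8S" = 0L,
                                              ITS2 = 3L, LSU = 5L),
                       low_freq_sites = c(ITS1 = 8L, "5.8S" = 6L,
                                          ITS2 = 5L, LSU = 22L),
                       low_freq = 0.02, read_error_rate = 0,
                       carrier_mode = c("exact", "bernoulli")) {
  carrier_mode <- match.arg(carrier_mode)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(setequal(names(locus_lengths), .LOCI),
            setequal(names(interspecies_diffs), .LOCI),
            setequal(names(low_freq_sites), .LOCI),
            C >= 1, n_clones >= 1,
            low_freq > 0, low_freq < 0.5,
            read_error_rate >= 0, read_error_rate < 1,
            all(interspecies_diffs >= 0), all(low_freq_sites >= 0))
  if (any(locus_lengths[.LOCI] <
            interspecies_diffs[.LOCI] + low_freq_sites[.LOCI]))
    stop("locus shorter than the variant sites it must host")
  structure(list(seed = as.integer(seed),
                 locus_lengths = locus_lengths[names(locus_lengths)],
                 C = as.integer(C), n_clones = as.integer(n_clones),
                 interspecies_diffs = interspecies_diffs,
                 low_freq_sites = low_freq_sites,
                 low_freq = low_freq, read_error_rate = read_error_rate,
                 carrier_mode = carrier_mode),
            class = "sim_config")
}

#' Simulate a tandem-repeat array for two sister species
#'
#' Draws a random canonical amplicon for species A (uniform base
#' composition), derives species B by substituting `interspecies_diffs`
#' random positions per locus, and plants each rare variant at a distinct
#' position (disjoint from the fixed differences) into a random carrier
#' subset of the `C` species-A copies.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `repeat_array_sim`: list with `config`,
#'   `annotation` (a [locus_annotation()] on `"reference"`), `canonical_A`
#'   and `species_B` (residue vectors), `copies` (C x L character matrix,
#'   rownames `copy_###`) and `truth` (data.frame: locus, pos, class,
#'   allele_A, allele_B, variant_allele, n_carriers, carriers list-column).
#' @export
simulate_repeat_array <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  .simulate_repeat_array_impl(cfg)
}

.simulate_repeat_array_impl <- function(cfg) {
  ann <- annotation_from_lengths("reference", cfg$locus_lengths)
  L <- sum(cfg$locus_lengths)
  canonical <- sample(.DNA_BASES, L, replace = TRUE)
  speciesB <- canonical
  copies <- matrix(canonical, cfg$C, L, byrow = TRUE)
  rownames(copies) <- sprintf("copy_%03d", seq_len(cfg$C))
  rows <- list()
  n_carry <- if (cfg$carrier_mode == "exact")
    max(1L, round(cfg$low_freq * cfg$C)) else NA_integer_
  for (locus in ann$locus) {
    sites <- locus_sites(ann, locus)
    n_fix <- cfg$interspecies_diffs[[locus]]
    n_low <- cfg$low_freq_sites[[locus]]
    pos <- if (n_fix + n_low > 0) sample(sites, n_fix + n_low) else integer(0)
    fix_pos <- pos[seq_len(n_fix)]
    low_pos <- pos[setdiff(seq_along(pos), seq_len(n_fix))]
    for (p in fix_pos) {
      alt <- sample(setdiff(.DNA_BASES, canonical[p]), 1L)
      speciesB[p] <- alt
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, pos = p, class = "interspecies_fixed",
        allele_A = canonical[p], allele_B = alt,
        variant_allele = canonical[p], n_carriers = cfg$C,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$carriers <- list(seq_len(cfg$C))
    }
    for (p in low_pos) {
      alt <- sample(setdiff(.DNA_BASES, canonical[p]), 1L)
      carriers <- if (cfg$carrier_mode == "exact")
        sort(sample.int(cfg$C, n_carry)) else
          which(stats::runif(cfg$C) < cfg$low_freq)
      copies[carriers, p] <- alt
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, pos = p, class = "low_freq",
        allele_A = canonical[p], allele_B = canonical[p],
        variant_allele = alt, n_carriers = length(carriers),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$carriers <- list(carriers)
    }
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(config = cfg, annotation = ann, canonical_A = canonical,
                 species_B = speciesB, copies = copies, truth = truth),
            class = "repeat_array_sim")
}

#' Majority-call Sanger-style reference of a repeat array
#'
#' Emulates what direct Sanger sequencing of the pooled amplicon reports:
#' the per-site majority base over all copies, with sites whose minority
#' fraction reaches `secondary_peak_floor` recorded as secondary-peak sites
#' (the visible trace of internal heterogeneity).  At the default rare
#' variant frequency of 2% and a 10% floor, no rare variant surfaces and the
#' reference equals the species canonical.
#'
#' @param sim A [simulate_repeat_array()] result.
#' @param secondary_peak_floor Minority fraction at which a secondary peak is
#'   visible.
#' @return List with `reference` (residue vector), `secondary_peak_sites`
#'   (1-based positions) and `minority_fraction` (per site).
#' @export
simulate_sanger_reference <- function(sim, secondary_peak_floor = 0.1) {
  counts <- vapply(.DNA_BASES, function(b) colSums(sim$copies == b),
                   numeric(ncol(sim$copies)))
  top <- max.col(counts, ties.method = "first")
  reference <- .DNA_BASES[top]
  minority <- 1 - counts[cbind(seq_len(nrow(counts)), top)] /
    nrow(sim$copies)
  list(reference = reference,
       secondary_peak_sites = which(minority >= secondary_peak_floor),
       minority_fraction = minority)
}

#' Sample clone reads from a repeat array
#'
#' Samples `n_clones` copies uniformly with replacement (each clone is one
#' plasmid-borne repeat) and produces a forward and a reverse read per clone,
#' each the copy's sequence with independent per-base substitution errors at
#' `read_error_rate`.  Reads are stored in forward orientation; the
#' ground-truth copy index is retained.
#'
#' @param sim A [simulate_repeat_array()] result.
#' @param cfg Configuration; defaults to `sim$config`.
#' @param seed Optional seed; `NULL` (default) continues the current RNG
#'   stream (as in [simulate_study()]).
#' @return Object of class `clone_set`: list with `clone_id`, `copy_id`
#'   (integer indices into the array), `fwd` and `rev` (n_clones x L
#'   character matrices).
#' @export
simulate_clone_reads <- function(sim, cfg = sim$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_clones
  idx <- sample.int(nrow(sim$copies), n, replace = TRUE)
  base <- sim$copies[idx, , drop = FALSE]
  add_errors <- function(m) {
    if (cfg$read_error_rate <= 0) return(m)
    hit <- which(stats::runif(length(m)) < cfg$read_error_rate)
    if (length(hit)) {
      m[hit] <- vapply(m[hit],
                       function(b) sample(setdiff(.DNA_BASES, b), 1L), "")
    }
    m
  }
  ids <- sprintf("clone_%03d", seq_len(n))
  fwd <- add_errors(base); rownames(fwd) <- ids
  rev <- add_errors(base); rownames(rev) <- ids
  structure(list(clone_id = ids, copy_id = idx, fwd = fwd, rev = rev),
            class = "clone_set")
}

#' Run a complete simulation under one RNG stream
#'
#' Seeds the RNG once from `cfg$seed`, then draws the repeat array, the
#' Sanger-style reference and the clone reads, so a config reproduces the
#' whole study byte-for-byte.
#'
#' @param cfg A [sim_config()].
#' @param secondary_peak_floor Passed to [simulate_sanger_reference()].
#' @return List with `sim`, `sanger` and `clones`.
#' @export
simulate_study <- function(cfg, secondary_peak_floor = 0.1) {
  set.seed(cfg$seed)
  sim <- .simulate_repeat_array_impl(cfg)
  sanger <- simulate_sanger_reference(sim, secondary_peak_floor)
  clones <- simulate_clone_reads(sim, cfg, seed = NULL)
  list(sim = sim, sanger = sanger, clones = clones)
}

#' Compare a recovered SNP spectrum with the simulation ground truth
#'
#' For every planted variant, reports whether the spectrum recovered it (same
#' position and variant allele), whether its category and frequency class are
#' the expected ones (`vs_both`/low for rare variants, `vs_B_only`/high for
#' fixed interspecies differences, with clones drawn from species A and type
#' strain A as anchor), and the estimated frequency.  Variants whose carrier
#' copies were never sampled into a clone are counted `unsampled` and
#' excluded from the recall denominator.
#'
#' @param sim A [simulate_repeat_array()] result.
#' @param clones The [simulate_clone_reads()] clone set analysed.
#' @param spectrum The [build_spectrum()] result to audit.
#' @return List with `per_variant` (data.frame), `recall`, `precision`,
#'   `category_accuracy` (fraction of sampled variants recovered in the
#'   expected category) and `n_unsampled`.
#' @export
end_to_end_truth_check <- function(sim, clones, spectrum) {
  truth <- sim$truth
  snps <- spectrum$snps
  n <- length(clones$copy_id)
  per <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    carriers <- tr$carriers[[1L]]
    k <- sum(clones$copy_id %in% carriers)
    expected_cat <- if (tr$class == "interspecies_fixed") "vs_B_only"
    else "vs_both"
    expected_class <- if (tr$class == "interspecies_fixed") "high" else "low"
    hit <- snps[snps$pos == tr$pos &
                  snps$variant_allele == tr$variant_allele, , drop = FALSE]
    data.frame(locus = tr$locus, pos = tr$pos, class = tr$class,
               n_sampled = k, sampled = k > 0 |
                 tr$class == "interspecies_fixed",
               recovered = nrow(hit) > 0,
               category_ok = nrow(hit) > 0 &&
                 hit$category[1L] == expected_cat,
               class_ok = nrow(hit) > 0 &&
                 hit$freq_class[1L] == expected_class,
               freq_est = if (nrow(hit)) hit$freq[1L] else NA_real_,
               freq_true = k / n, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  sampled <- per[per$sampled, , drop = FALSE]
  key_truth <- paste(truth$pos, truth$variant_allele)
  spurious <- if (nrow(snps))
    sum(!(paste(snps$pos, snps$variant_allele) %in% key_truth)) else 0L
  list(per_variant = per,
       recall = if (nrow(sampled)) mean(sampled$recovered) else NA_real_,
       precision = if (nrow(snps))
         1 - spurious / nrow(snps) else NA_real_,
       category_accuracy = if (nrow(sampled))
         mean(sampled$recovered & sampled$category_ok) else NA_real_,
       n_unsampled = sum(!per$sampled))
}
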