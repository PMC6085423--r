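# Replicated simulation studies: the package's own evaluation harnesses.
# Each runs many seeded simulations under the default study conditions and
# summarises the property the corresponding analysis stage is supposed to
# exhibit on such data (consensus masking, spectrum recovery and bimodality,
# locus independence).  Per-replicate seeds are base_seed + replicate index.

#' Consensus-masking study
#'
#' Replicates the consensus-vs-original contrast: reads carry independent
#' sequencing errors, the consensus is built with the reference-biased
#' policy, and per locus the mean distance of the original (single-strand)
#' sequences to the Sanger reference is compared with the mean distance of
#' the consensus sequences.  Reference-biased consensus building corrects
#' read errors toward the reference, so the original means should be at
#' least as large in (nearly) every replicate — the masking effect.
#'
#' @param n_reps Number of replicates.
#' @param base_seed Base seed; replicate r uses `base_seed + r`.
#' @param read_error_rate Per-base read error rate used for this study
#'   (reads must carry errors for consensus building to have anything to
#'   mask; 0.003 is a typical raw Sanger read error rate).
#' @param metric Distance metric.
#' @param cfg_args Further arguments passed to [sim_config()].
#' @return List with `per_rep` (data.frame: rep, locus, mean_original,
#'   mean_consensus), `n_ok` (replicates with mean_original >=
#'   mean_consensus in every locus) and `n_reps`.
#' @export
masking_study <- function(n_reps = 100L, base_seed = 1L,
                          read_error_rate = 0.003,
                          metric = c("p", "tn93_mcl"), cfg_args = list()) {
  metric <- match.arg(metric)
  rows <- vector("list", n_reps)
  n_ok <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- do.call(sim_config,
                   c(list(seed = base_seed + r,
                          read_error_rate = read_error_rate), cfg_args))
    st <- simulate_study(cfg)
    ref <- st$sanger$reference
    clones <- consensus_clone_set(st$clones, policy = "reference_biased",
                                  reference = ref)
    ann <- st$sim$annotation
    mo <- mc <- numeric(length(.LOCI)); names(mo) <- names(mc) <- .LOCI
    for (locus in .LOCI) {
      sites <- locus_sites(ann, locus)
      mo[locus] <- mean(.dist_vs_ref(ref, clones$fwd, sites, metric),
                        na.rm = TRUE)
      mc[locus] <- mean(.dist_vs_ref(ref, clones$consensus, sites, metric),
                        na.rm = TRUE)
    }
    ok <- all(mo >= mc - 1e-12)
    n_ok <- n_ok + ok
    rows[[r]] <- data.frame(rep = r, locus = .LOCI, mean_original = mo,
                            mean_consensus = mc, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  list(per_rep = do.call(rbind, rows), n_ok = n_ok, n_reps = n_reps)
}

#' Spectrum-recovery study
#'
#' Replicates default simulations, rebuilds the SNP spectrum from the clone
#' reads, and audits it against the planted ground truth with
#' [end_to_end_truth_check()]: every sampled planted variant should be
#' recovered in the expected category, estimated rare-variant frequencies
#' should sit within 3 binomial standard errors of the planted carrier
#' fraction, and the recovered spectrum should be bimodal (no
#' intermediate-frequency records).
#'
#' @inheritParams masking_study
#' @return List with `per_variant` (pooled over replicates),
#'   `category_accuracy`, `freq_within_3se` (fraction of sampled rare
#'   variants within the binomial band), `n_intermediate` (intermediate
#'   frequency-class records over all replicates), `freq_range_low` (range
#'   of recovered rare-variant frequencies) and `n_reps`.
#' @export
spectrum_recovery_study <- function(n_reps = 500L, base_seed = 1L,
                                    cfg_args = list()) {
  per <- vector("list", n_reps)
  n_intermediate <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- do.call(sim_config, c(list(seed = base_seed + r), cfg_args))
    st <- simulate_study(cfg)
    spec <- build_spectrum(st$clones$fwd, st$sim$canonical_A,
                           st$sim$species_B, st$sim$annotation)
    chk <- end_to_end_truth_check(st$sim, st$clones, spec)
    n_intermediate <- n_intermediate +
      sum(spec$snps$freq_class == "intermediate")
    pv <- chk$per_variant
    pv$rep <- r
    per[[r]] <- pv
  }
  per <- do.call(rbind, per)
  sampled <- per[per$sampled, , drop = FALSE]
  low <- sampled[sampled$class == "low_freq" & sampled$recovered, ,
                 drop = FALSE]
  cfg1 <- do.call(sim_config, c(list(seed = base_seed + 1L), cfg_args))
  f <- cfg1$low_freq
  band <- 3 * sqrt(f * (1 - f) / cfg1$n_clones)
  within <- abs(low$freq_est - f) <= band
  list(per_variant = per,
       category_accuracy = mean(sampled$recovered & sampled$category_ok),
       freq_within_3se = mean(within),
       n_intermediate = n_intermediate,
       freq_range_low = range(low$freq_est),
       n_reps = n_reps)
}

#' Locus-independence study
#'
#' Replicates default simulations (variants planted independently per
#' locus), computes per-clone per-locus distances to the reference, and the
#' Pearson correlation of every locus pair.  Under the independent-loci
#' generator the correlations should hover near zero and their p-values
#' should be uniform.  Pairs involving a zero-variance locus (no variant
#' sampled) are skipped and counted.
#'
#' @inheritParams masking_study
#' @return List with `per_pair` (data.frame: rep, pair, r, p), `abs_r_p95`
#'   (95th percentile of |r|), `ks_p` (Kolmogorov-Smirnov p-value of the
#'   pooled p-values against the uniform), `n_degenerate` and `n_reps`.
#' @export
locus_independence_study <- function(n_reps = 500L, base_seed = 1L,
                                     metric = c("p", "tn93_mcl"),
                                     cfg_args = list()) {
  metric <- match.arg(metric)
  pairs <- utils::combn(.LOCI, 2L)
  rows <- vector("list", n_reps)
  n_degenerate <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- do.call(sim_config, c(list(seed = base_seed + r), cfg_args))
    st <- simulate_study(cfg)
    ref <- st$sanger$reference
    ann <- st$sim$annotation
    prof <- vapply(.LOCI,
                   function(locus) .dist_vs_ref(ref, st$clones$fwd,
                                                locus_sites(ann, locus),
                                                metric),
                   numeric(cfg$n_clones))
    res <- apply(pairs, 2L, function(pr) {
      x <- prof[, pr[1L]]; y <- prof[, pr[2L]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(c(NA_real_, NA_real_))
      ct <- stats::cor.test(x, y, method = "pearson")
      c(unname(ct$estimate), ct$p.value)
    })
    n_degenerate <- n_degenerate + sum(is.na(res[1L, ]))
    rows[[r]] <- data.frame(rep = r,
                            pair = paste(pairs[1L, ], pairs[2L, ],
                                         sep = ":"),
                            r = res[1L, ], p = res[2L, ],
                            stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, rows)
  ok <- !is.na(per_pair$r)
  ks <- suppressWarnings(stats::ks.test(per_pair$p[ok], "punif"))
  list(per_pair = per_pair,
       abs_r_p95 = unname(stats::quantile(abs(per_pair$r[ok]), 0.95)),
       ks_p = ks$p.value,
       n_degenerate = n_degenerate, n_reps = n_reps)
}
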