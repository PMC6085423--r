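test_that("configuration validates the study conditions", {
  expect_error(sim_config(), "seed is mandatory")
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$C, 120L)
  expect_equal(cfg$n_clones, 85L)
  expect_equal(cfg$low_freq, 0.02)
  expect_equal(sum(cfg$locus_lengths), 1140L)
  expect_error(sim_config(seed = 1, low_freq = 0.7), "low_freq")
  expect_error(sim_config(seed = 1,
                          locus_lengths = c(ITS1 = 10L, "5.8S" = 160L,
                                            ITS2 = 230L, LSU = 570L)),
               "shorter")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(simulate_study(cfg), simulate_study(cfg))
  expect_false(identical(simulate_study(sim_config(seed = 100))$sim$truth,
                         simulate_study(cfg)$sim$truth))
})

test_that("the truth table carries the planted variant structure", {
  cfg <- sim_config(seed = 71)
  sim <- simulate_repeat_array(cfg)
  truth <- sim$truth
  tab <- table(truth$locus, truth$class)
  expect_equal(as.integer(tab[c("ITS1", "5.8S", "ITS2", "LSU"),
                              "interspecies_fixed"]), c(5L, 0L, 3L, 5L))
  expect_equal(as.integer(tab[c("ITS1", "5.8S", "ITS2", "LSU"),
                              "low_freq"]), c(8L, 6L, 5L, 22L))
  expect_false(anyDuplicated(truth$pos) > 0)
  # exact carrier counts: round(0.02 * 120) = 2 copies per rare variant
  expect_true(all(truth$n_carriers[truth$class == "low_freq"] == 2L))
  # each copy differs from the canonical exactly at the variants it carries
  low <- truth[truth$class == "low_freq", ]
  for (i in seq_len(nrow(sim$copies))) {
    planted <- low$pos[vapply(low$carriers, function(cc) i %in% cc,
                              logical(1))]
    observed <- which(sim$copies[i, ] != sim$canonical_A)
    expect_identical(sort(observed), sort(as.integer(planted)))
  }
  # species B differs from A exactly at the fixed positions
  expect_identical(which(sim$species_B != sim$canonical_A),
                   sort(truth$pos[truth$class == "interspecies_fixed"]))
})

test_that("majority-call reference hides 2% variants but shows 40% ones", {
  cfg <- sim_config(seed = 72)
  sim <- simulate_repeat_array(cfg)
  sg <- simulate_sanger_reference(sim)
  expect_identical(sg$reference, sim$canonical_A)
  expect_length(sg$secondary_peak_sites, 0L)
  # plant a 40% minority allele: site is flagged, majority still called
  sim2 <- sim
  minority <- 1:48                     # 48 / 120 copies
  pos <- sim$truth$pos[1]
  alt <- setdiff(c("A", "C", "G", "T"), sim$canonical_A[pos])[1]
  sim2$copies[minority, pos] <- alt
  sg2 <- simulate_sanger_reference(sim2)
  expect_true(pos %in% sg2$secondary_peak_sites)
  expect_identical(sg2$reference[pos], sim$canonical_A[pos])
})

test_that("clone reads sample copies faithfully", {
  cfg <- sim_config(seed = 73)
  st <- simulate_study(cfg)
  clones <- st$clones
  expect_equal(nrow(clones$fwd), 85L)
  # error-free: both reads equal the sampled copy
  expect_identical(clones$fwd, clones$rev)
  expect_identical(unname(clones$fwd),
                   unname(st$sim$copies[clones$copy_id, ]))
  # with errors, reads differ from the copy at about the error rate
  cfg2 <- sim_config(seed = 73, read_error_rate = 0.01)
  st2 <- simulate_study(cfg2)
  truth <- st2$sim$copies[st2$clones$copy_id, ]
  rate <- mean(st2$clones$fwd != truth)
  expect_gt(rate, 0.005); expect_lt(rate, 0.02)
  expect_false(identical(st2$clones$fwd, st2$clones$rev))
})

test_that("bernoulli carrier mode draws carriers per copy", {
  cfg <- sim_config(seed = 74, carrier_mode = "bernoulli", low_freq = 0.1)
  sim <- simulate_repeat_array(cfg)
  ncar <- sim$truth$n_carriers[sim$truth$class == "low_freq"]
  expect_gt(length(unique(ncar)), 1L)   # counts vary, unlike exact mode
  expect_lt(mean(ncar) / cfg$C, 0.2)
})

test_that("the truth check audits recovery, category and sampling", {
  cfg <- sim_config(seed = 75)
  st <- simulate_study(cfg)
  spec <- build_spectrum(st$clones$fwd, st$sim$canonical_A,
                         st$sim$species_B, st$sim$annotation)
  chk <- end_to_end_truth_check(st$sim, st$clones, spec)
  expect_equal(chk$recall, 1)
  expect_equal(chk$precision, 1)
  expect_equal(chk$category_accuracy, 1)
  pv <- chk$per_variant
  expect_equal(chk$n_unsampled, sum(!pv$sampled))
  expect_true(all(pv$sampled[pv$class == "interspecies_fixed"]))
  # unsampled variants are not recovered and sit outside the denominator
  expect_true(all(!pv$recovered[!pv$sampled]))
  # read errors may create spurious singleton records: precision can drop
  cfg2 <- sim_config(seed = 76, read_error_rate = 0.005)
  st2 <- simulate_study(cfg2)
  spec2 <- build_spectrum(st2$clones$fwd, st2$sim$canonical_A,
                          st2$sim$species_B, st2$sim$annotation)
  chk2 <- end_to_end_truth_check(st2$sim, st2$clones, spec2)
  expect_lte(chk2$precision, 1)
  expect_gt(nrow(spec2$snps), nrow(spec$snps))
})
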