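test_that("site allele calling excludes gaps, N and ambiguity codes", {
  mat <- rbind(matrix("A", 9, 1), "G")
  expect_equal(call_site_alleles(mat, 1), c(A = 9L, G = 1L),
               ignore_attr = TRUE)
  mat[10, 1] <- "-"
  counts <- call_site_alleles(mat, 1)
  expect_equal(counts, c(A = 9L), ignore_attr = TRUE)
  expect_equal(attr(counts, "uncalled"), 1L)
  mat[10, 1] <- "R"
  expect_equal(attr(call_site_alleles(mat, 1), "uncalled"), 1L)
})

test_that("site classification reproduces the category and frequency rules", {
  expect_equal(classify_site(c(A = 85), "A", "A"),
               list(category = "none", freq = 0,
                    variant_allele = NA_character_))
  # rare repeat variant: majority matches both type strains
  res <- classify_site(c(A = 83, G = 2), "A", "A")
  expect_equal(res$category, "vs_both")
  expect_equal(res$freq, 2 / 85)
  expect_equal(res$variant_allele, "G")
  # fixed difference: clones match type B, differ from type A
  res <- classify_site(c(G = 85), "A", "G")
  expect_equal(res, list(category = "vs_A_only", freq = 1,
                         variant_allele = "G"))
  # majority differing from both type strains
  res <- classify_site(c(T = 80, A = 5), "A", "G")
  expect_equal(res$category, "vs_both")
  expect_equal(res$freq, 80 / 85)
})

test_that("frequency classes split at the configured cuts", {
  expect_identical(frequency_class(1.0), "high")
  expect_identical(frequency_class(0.02), "low")
  expect_identical(frequency_class(0.04), "low")
  expect_identical(frequency_class(0.3), "intermediate")
  expect_identical(frequency_class(c(0.5, 0.1)), c("high", "low"))
  expect_identical(frequency_class(0.3, low_cut = 0.35), "low")
})

test_that("spectrum recovers planted variant structure from the whole array", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_repeat_array(cfg)
  # use all 120 copies as the clone set: every planted variant is present
  spec <- build_spectrum(sim$copies, sim$canonical_A, sim$species_B,
                         sim$annotation)
  ts <- table(factor(spec$typestrain_diffs$locus, levels = c("ITS1", "5.8S",
                                                             "ITS2", "LSU")))
  expect_equal(as.integer(ts), c(5L, 0L, 3L, 5L))
  snps <- spec$snps
  low <- snps[snps$freq_class == "low", ]
  expect_equal(as.integer(table(factor(low$locus,
                                       levels = c("ITS1", "5.8S", "ITS2",
                                                  "LSU")))),
               c(8L, 6L, 5L, 22L))
  expect_true(all(low$category == "vs_both"))
  expect_equal(unique(low$freq), 2 / 120)
  high <- snps[snps$freq_class == "high", ]
  expect_true(all(high$category == "vs_B_only"))
  expect_equal(nrow(high), 13L)     # 5 + 0 + 3 + 5 fixed differences
  expect_true(all(high$freq == 1))
  # partition: exactly one category per record, no intermediate class
  expect_true(all(snps$category %in% c("vs_A_only", "vs_B_only", "vs_both")))
  expect_equal(sum(snps$freq_class == "intermediate"), 0L)
})

test_that("spectrum is empty when clones match identical type strains", {
  ann <- annotation_from_lengths("r", c(ITS1 = 10L, "5.8S" = 10L,
                                        ITS2 = 10L, LSU = 10L))
  set.seed(32)
  ref <- strsplit(random_seq(40), "")[[1]]
  clones <- matrix(ref, 5, 40, byrow = TRUE)
  spec <- build_spectrum(clones, ref, ref, ann)
  expect_equal(nrow(spec$snps), 0L)
  expect_equal(nrow(spec$typestrain_diffs), 0L)
})

test_that("swapping the type strains swaps the A/B categories exactly", {
  cfg <- sim_config(seed = 33)
  st <- simulate_study(cfg)
  specAB <- build_spectrum(st$clones$fwd, st$sim$canonical_A,
                           st$sim$species_B, st$sim$annotation)
  specBA <- build_spectrum(st$clones$fwd, st$sim$species_B,
                           st$sim$canonical_A, st$sim$annotation)
  tab <- function(s) table(factor(s$snps$category,
                                  levels = c("vs_A_only", "vs_B_only",
                                             "vs_both")))
  ab <- tab(specAB); ba <- tab(specBA)
  expect_equal(as.integer(ab[c("vs_A_only", "vs_B_only")]),
               as.integer(ba[c("vs_B_only", "vs_A_only")]))
  expect_equal(as.integer(ab["vs_both"]), as.integer(ba["vs_both"]))
})

test_that("planted frequencies are recovered within the binomial band", {
  n_hit <- 0L; n_tot <- 0L
  for (r in 1:50) {
    cfg <- sim_config(seed = 300 + r)
    st <- simulate_study(cfg)
    spec <- build_spectrum(st$clones$fwd, st$sim$canonical_A,
                           st$sim$species_B, st$sim$annotation)
    chk <- end_to_end_truth_check(st$sim, st$clones, spec)
    pv <- chk$per_variant
    low <- pv[pv$class == "low_freq" & pv$sampled, ]
    band <- 3 * sqrt(cfg$low_freq * (1 - cfg$low_freq) / cfg$n_clones)
    n_hit <- n_hit + sum(abs(low$freq_est - cfg$low_freq) <= band)
    n_tot <- n_tot + nrow(low)
    expect_equal(chk$recall, 1)
    expect_equal(chk$precision, 1)
  }
  expect_gte(n_hit / n_tot, 0.99)
})
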