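test_that("pair counts classify substitutions and apply pairwise deletion", {
  c0 <- pair_counts("ACGT", "ACGT")
  expect_equal(c0[c("L", "P1", "P2", "Q")], list(L = 4, P1 = 0, P2 = 0,
                                                 Q = 0))
  c1 <- pair_counts("ACGT", "GCGT")
  expect_equal(c1[c("L", "P1", "P2", "Q")], list(L = 4, P1 = 1, P2 = 0,
                                                 Q = 0))
  expect_equal(pair_counts("AC-T", "ACGT")$L, 3)
  expect_equal(pair_counts("ACNT", "ACGT")$L, 3)   # N excluded
  expect_equal(pair_counts("ACRT", "ACGT")$L, 3)   # ambiguity excluded
  expect_equal(sum(pair_counts("ACGT", "TGCA")$base_freqs), 1)
  expect_error(p_distance(pair_counts("----", "ACGT")), "no comparable")
})

test_that("p-distance equals the direct mismatch count", {
  expect_equal(p_distance(pair_counts("ACGT", "ACGA")), 0.25)
  expect_equal(p_distance(pair_counts("ACGT", "ACGT")), 0)
  set.seed(5)
  a <- strsplit(random_seq(1000), "")[[1]]
  b <- a
  idx <- sample(1000, 10)
  b[idx] <- vapply(a[idx], function(x) sample(setdiff(BASES, x), 1L), "")
  expect_equal(p_distance(pair_counts(paste(a, collapse = ""),
                                      paste(b, collapse = ""))), 0.01)
})

test_that("TN93 reduces to the Jukes-Cantor closed form in the equal case", {
  # equal base frequencies and JC-consistent substitution-class counts
  for (p in c(0.01, 0.05, 0.2)) {
    L <- 60000
    cnt <- list(L = L, P1 = L * p / 6, P2 = L * p / 6, Q = L * 4 * p / 6,
                base_freqs = c(A = .25, C = .25, G = .25, T = .25))
    expect_equal(tn93_distance(cnt), -3 / 4 * log(1 - 4 * p / 3),
                 tolerance = 1e-9)
  }
  expect_equal(tn93_distance(pair_counts("ACGT", "ACGT")), 0)
})

test_that("TN93 agrees with an independent implementation", {
  set.seed(8)
  for (i in 1:5) {
    a <- sample(BASES, 1500, TRUE, prob = c(.35, .15, .3, .2))
    b <- a
    idx <- sample(1500, 90)
    b[idx] <- vapply(a[idx], function(x) sample(setdiff(BASES, x), 1L), "")
    ours <- tn93_distance(pair_counts(paste(a, collapse = ""),
                                      paste(b, collapse = "")))
    bin <- ape::as.DNAbin(matrix(tolower(c(a, b)), nrow = 2, byrow = TRUE))
    expect_equal(ours, as.numeric(ape::dist.dna(bin, model = "TN93")),
                 tolerance = 1e-12)
  }
})

test_that("TN93 correction is expansive and flags saturation", {
  set.seed(9)
  anc <- sample(BASES, 800, TRUE)
  der <- jc_evolve(anc, 0.4)
  cnt <- pair_counts(paste(anc, collapse = ""), paste(der, collapse = ""))
  expect_gt(tn93_distance(cnt), p_distance(cnt))
  # a saturated pair: ~all sites differ
  sat <- list(L = 100, P1 = 30, P2 = 30, Q = 39,
              base_freqs = c(A = .25, C = .25, G = .25, T = .25))
  expect_warning(d <- tn93_distance(sat), "saturated")
  expect_true(is.na(d))
})

test_that("pooled-parameter matrix reduces to per-pair TN93 for two taxa", {
  set.seed(10)
  a <- random_seq(1200)
  bv <- strsplit(a, "")[[1]]
  idx <- sample(1200, 60)
  bv[idx] <- vapply(bv[idx], function(x) sample(setdiff(BASES, x), 1L), "")
  seqs <- c(x = a, y = paste(bv, collapse = ""))
  dm <- mcl_distance_matrix(seqs)
  expect_equal(dm["x", "y"],
               tn93_distance(pair_counts(seqs["x"], seqs["y"])))
  expect_equal(dm["x", "y"], dm["y", "x"])
  expect_equal(diag(dm), c(x = 0, y = 0))
})

test_that("distance matrices respect duplicates, symmetry and zero diagonal", {
  set.seed(12)
  a <- sample(BASES, 300, TRUE)
  seqs <- c(a = paste(a, collapse = ""),
            b = paste(jc_evolve(a, 0.15), collapse = ""))
  seqs <- c(seqs, c = unname(seqs["a"]))      # duplicated row
  for (fn in list(p_distance_matrix, mcl_distance_matrix)) {
    dm <- fn(seqs)
    expect_equal(dm["a", "c"], 0)
    expect_equal(dm, t(dm))
    expect_equal(unname(diag(dm)), rep(0, 3))
  }
  # identical input: all-zero matrix
  same <- c(u = "ACGTACGT", v = "ACGTACGT", w = "ACGTACGT")
  expect_true(all(mcl_distance_matrix(same) == 0))
})

test_that("distance estimates converge to the generating branch length", {
  set.seed(13)
  d_true <- 0.1
  med_err <- vapply(c(1e3, 1e4, 1e5), function(L) {
    errs <- replicate(20, {
      anc <- sample(BASES, L, TRUE)
      der <- jc_evolve(anc, d_true)
      est <- tn93_distance(pair_counts(paste(anc, collapse = ""),
                                       paste(der, collapse = "")))
      abs(est - d_true)
    })
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("four-setting summary matches direct enumeration on a toy set", {
  ann <- annotation_from_lengths("reference",
                                 c(ITS1 = 8L, "5.8S" = 8L, ITS2 = 8L,
                                   LSU = 8L))
  ref <- strsplit("ACGTACGTACGTACGTACGTACGTACGTACGT", "")[[1]]
  # three clones: 1 identical; 2 with one ITS1 change; 3 with two LSU changes
  f <- rbind(ref, ref, ref)
  rownames(f) <- paste0("c", 1:3)
  f[2, 2] <- "T"
  f[3, 27] <- "A"; f[3, 29] <- "C"
  clones <- structure(list(clone_id = rownames(f), fwd = f, rev = f),
                      class = "clone_set")
  clones <- consensus_clone_set(clones, policy = "iupac")
  fss <- four_setting_summary(ref, clones, ann, metric = "p")
  pick <- function(locus, setting, what)
    fss[fss$locus == locus & fss$setting == setting, what]
  # vs-reference ITS1: distances 0, 1/8, 0
  expect_equal(pick("ITS1", "ref_vs_original", "mean"), (1 / 8) / 3)
  expect_equal(pick("ITS1", "ref_vs_original", "max"), 1 / 8)
  # pairwise LSU: c1-c2 = 0, c1-c3 = 2/8, c2-c3 = 2/8
  expect_equal(pick("LSU", "pairwise_original", "mean"), (4 / 8) / 3)
  expect_equal(pick("LSU", "pairwise_original", "n"), 3L)
  expect_equal(pick("5.8S", "ref_vs_consensus", "mean"), 0)
  expect_equal(pick("5.8S", "ref_vs_consensus", "n"), 3L)
  # all-identical clones give an all-zero summary
  same <- structure(list(clone_id = "z", fwd = rbind(z = ref),
                         rev = rbind(z = ref)), class = "clone_set")
  same <- consensus_clone_set(same, policy = "iupac")
  expect_warning(fss0 <- four_setting_summary(ref, same, ann, metric = "p"),
                 "fewer than 2")
  expect_true(all(fss0$mean[fss0$n > 0] == 0))
})

test_that("ambiguity codes from iupac consensus are excluded pairwise", {
  # consensus with an R at a disagreement site: the site drops out of L
  res <- build_consensus("ACGTACGT", "ACGTACAT", policy = "iupac")
  cnt <- pair_counts(res$consensus, "ACGTACGT")
  expect_equal(cnt$L, 7)
  expect_equal(p_distance(cnt), 0)
})
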