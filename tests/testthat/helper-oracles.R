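# Independent oracles used across tests.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# Brute-force global affine alignment score by exhaustive enumeration of all
# alignments (strings <= ~8 bp).  A gap of length k costs open + (k-1)*ext,
# the same convention as align_to_reference().
bf_align_score <- function(a, b, match = 1, mis = -1, open = 4, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, (if (A[i] == B[j]) match else mis) +
                    rec(i + 1L, j + 1L, "m"))
    if (i <= length(A))
      best <- max(best, -(if (last == "d") ext else open) +
                    rec(i + 1L, j, "d"))
    if (j <= length(B))
      best <- max(best, -(if (last == "i") ext else open) +
                    rec(i, j + 1L, "i"))
    best
  }
  rec(1L, 1L, "m")
}

# Direct mismatch count between equal-length strings over unambiguous sites
bf_mismatches <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av %in% BASES & bv %in% BASES
  c(diff = sum(av[ok] != bv[ok]), L = sum(ok))
}

# Evolve a sequence by Jukes-Cantor for branch length d (substitutions/site)
jc_evolve <- function(seq_chars, d) {
  p <- 3 / 4 * (1 - exp(-4 * d / 3))
  hit <- runif(length(seq_chars)) < p
  seq_chars[hit] <- vapply(seq_chars[hit],
                           function(b) sample(setdiff(BASES, b), 1L), "")
  seq_chars
}

# small simulation config for fast pipeline-level tests
small_cfg <- function(seed, ...) {
  sim_config(seed = seed,
             locus_lengths = c(ITS1 = 60L, "5.8S" = 50L, ITS2 = 70L,
                               LSU = 120L),
             C = 30L, n_clones = 12L,
             interspecies_diffs = c(ITS1 = 2L, "5.8S" = 0L, ITS2 = 1L,
                                    LSU = 2L),
             low_freq_sites = c(ITS1 = 2L, "5.8S" = 2L, ITS2 = 2L,
                                LSU = 4L),
             low_freq = 0.1, ...)
}
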