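# Internal constants and small helpers shared across modules.

.LOCI <- c("ITS1", "5.8S", "ITS2", "LSU")
.DNA_BASES <- c("A", "C", "G", "T")
.IUPAC_LETTERS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                    "V", "H", "D", "B", "N")
.ALLOWED_CHARS <- c(.IUPAC_LETTERS, "-")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                 M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
                 V = "B", H = "D", D = "H", B = "V", N = "N", "-" = "-")

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

# lookup: "XY" -> IUPAC code of union(set(X), set(Y)); 15 x 15 entries
.IUPAC_PAIR <- local({
  codes <- names(.IUPAC_SETS)
  key_of <- function(s) paste(sort(unique(s)), collapse = "")
  code_by_key <- structure(codes, names = vapply(.IUPAC_SETS, key_of, ""))
  out <- character(0)
  for (x in codes) {
    for (y in codes) {
      out[paste0(x, y)] <- code_by_key[[key_of(c(.IUPAC_SETS[[x]],
                                                 .IUPAC_SETS[[y]]))]]
    }
  }
  out
})

# IUPAC code of the union of two codes; vectorised
.iupac_merge <- function(x, y) unname(.IUPAC_PAIR[paste0(x, y)])

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.collapse <- function(x) paste(x, collapse = "")

# named character vector of equal-length sequences -> character matrix
# (one row per sequence); matrices pass through unchanged
.seq_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences must have equal length to form a site matrix; ",
         "align them to a common reference first")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

# character matrix -> named character vector of sequences
.matrix_seqs <- function(m) {
  out <- apply(m, 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

# a sequence argument may be a plain string or a character vector of residues
.residues <- function(s) {
  if (length(s) == 1L && nchar(s[1L]) > 1L) .chars(s) else as.character(s)
}
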