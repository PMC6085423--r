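#' Reverse complement of a sequence
#'
#' Watson-Crick complement, reversed; IUPAC ambiguity codes are complemented
#' correctly (R to Y, M to K, etc.) and gaps are preserved.
#'
#' @param s Sequence (character string).
#' @return Reverse-complemented character string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(s) {
  .collapse(rev(unname(.COMPLEMENT[.chars(toupper(s))])))
}

#' Build a clone consensus from forward and reverse reads
#'
#' Merges a forward read and a reverse read (already in forward orientation)
#' into the clone consensus, the way Sanger clone libraries are cleaned before
#' analysis.  Where the two reads agree, the agreed base is called; where they
#' disagree, the `policy` decides:
#'
#' * `"iupac"` — the IUPAC ambiguity code of the two bases (e.g. A/G -> R);
#' * `"fwd_wins"` — the forward base;
#' * `"reference_biased"` — whichever of the two bases equals the reference
#'   base at that position; if neither does, the IUPAC code.  This models the
#'   common practice of resolving trace conflicts by eye against the type
#'   strain, which drags the consensus toward the reference.
#'
#' If the reads differ in length they are first aligned to each other
#' (Needleman-Wunsch); at columns where one read has a gap the other read's
#' base is taken (an indel disagreement is not an ambiguity).
#'
#' @param fwd,rev Reads as character strings, both in forward orientation.
#' @param policy One of `"iupac"`, `"fwd_wins"`, `"reference_biased"`.
#' @param ref Reference sequence, required for `policy = "reference_biased"`;
#'   must be reference-anchored, i.e. equal in length to the reads.
#' @return List with `consensus` (character string), `discordant_sites`
#'   (1-based positions in consensus coordinates where the reads both had a
#'   base but disagreed) and `detail` (data.frame of position, fwd base, rev
#'   base and call at those sites).
#' @examples
#' build_consensus("ACGT", "ACAT", policy = "iupac")$consensus  # "ACRT"
#' @export
build_consensus <- function(fwd, rev,
                            policy = c("iupac", "fwd_wins",
                                       "reference_biased"),
                            ref = NULL) {
  policy <- match.arg(policy)
  if (policy == "reference_biased" && is.null(ref))
    stop("policy 'reference_biased' requires a reference sequence")
  fwd <- toupper(unname(fwd)); rev <- toupper(unname(rev))
  if (nchar(fwd) == nchar(rev)) {
    f <- .chars(fwd); r <- .chars(rev)
  } else {
    aln <- align_to_reference(fwd, rev, ref_id = "fwd", qry_id = "rev")
    f <- .chars(aln$aligned_ref); r <- .chars(aln$aligned_qry)
  }
  if (policy == "reference_biased") {
    rf <- .chars(toupper(unname(ref)))
    if (length(rf) != length(f))
      stop("policy 'reference_biased' requires reference-anchored reads ",
           "(reference and reads of equal length)")
  }
  cons <- f
  cons[f == "-"] <- r[f == "-"]
  cons[r == "-" & f != "-"] <- f[r == "-" & f != "-"]
  disagree <- which(f != r & f != "-" & r != "-")
  if (length(disagree)) {
    call <- switch(policy,
      iupac = .iupac_merge(f[disagree], r[disagree]),
      fwd_wins = f[disagree],
      reference_biased = {
        rb <- rf[disagree]
        ifelse(f[disagree] == rb, rb,
               ifelse(r[disagree] == rb, rb,
                      .iupac_merge(f[disagree], r[disagree])))
      })
    cons[disagree] <- call
  } else {
    call <- character(0)
  }
  # positions reported in consensus coordinates (no gap columns survive)
  keep <- cons != "-"
  pos_map <- cumsum(keep)
  disc <- pos_map[disagree]
  list(consensus = .collapse(cons[keep]),
       discordant_sites = as.integer(disc),
       detail = data.frame(position = as.integer(disc),
                           fwd = f[disagree], rev = r[disagree],
                           call = call, stringsAsFactors = FALSE))
}

#' Apply consensus building to a whole clone set
#'
#' Vectorised consensus construction for a [simulate_clone_reads()] clone set
#' (or any list carrying equal-width `fwd` and `rev` character matrices in
#' forward orientation).
#'
#' @param clones A `clone_set`.
#' @param policy,reference As in [build_consensus()]; `reference` is the
#'   reference residue vector (or string) for `"reference_biased"`.
#' @return The clone set with a `consensus` character matrix and a
#'   `discordant` list (1-based site positions per clone) added.
#' @export
consensus_clone_set <- function(clones,
                                policy = c("iupac", "fwd_wins",
                                           "reference_biased"),
                                reference = NULL) {
  policy <- match.arg(policy)
  f <- clones$fwd; r <- clones$rev
  stopifnot(is.matrix(f), is.matrix(r), all(dim(f) == dim(r)))
  cons <- f
  mask <- f != r
  if (any(mask)) {
    if (policy == "iupac") {
      cons[mask] <- .iupac_merge(f[mask], r[mask])
    } else if (policy == "reference_biased") {
      if (is.null(reference))
        stop("policy 'reference_biased' requires a reference")
      rf <- .residues(reference)
      if (length(rf) != ncol(f))
        stop("reference length does not match read length")
      refmat <- matrix(rf, nrow(f), ncol(f), byrow = TRUE)
      fe <- f[mask]; re <- r[mask]; be <- refmat[mask]
      cons[mask] <- ifelse(fe == be, be,
                           ifelse(re == be, be, .iupac_merge(fe, re)))
    }
  }
  clones$consensus <- cons
  clones$consensus_policy <- policy
  clones$discordant <- apply(mask, 1L, which, simplify = FALSE)
  clones
}
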