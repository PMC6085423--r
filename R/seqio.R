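#' Read DNA sequences from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file and returns the
#' sequences as a named character vector, uppercased, in file order.  Residues
#' are validated against the DNA alphabet extended with IUPAC ambiguity codes
#' and the gap character `-` (so pre-aligned FASTA files are also readable).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the FASTA ids
#'   (text up to the first whitespace).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences found in FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  for (i in seq_along(seqs)) {
    bad <- which(!(.chars(seqs[[i]]) %in% .ALLOWED_CHARS))
    if (length(bad))
      stop("illegal residue '", .chars(seqs[[i]])[bad[1L]],
           "' in record '", names(seqs)[i], "' at position ", bad[1L])
    if (nchar(seqs[[i]]) == 0L)
      stop("empty sequence in record '", names(seqs)[i], "'")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Locus annotation of a reference amplicon
#'
#' Describes where the four rDNA loci (ITS1, 5.8S, ITS2, LSU D1/D2) fall on a
#' reference coordinate system.  Intervals are stored 0-based half-open, the
#' convention also used by the on-disk TSV format; use [locus_sites()] to get
#' 1-based column indices for use on R matrices.
#'
#' @param reference_id Id of the reference sequence the coordinates refer to.
#' @param start,end Integer vectors (0-based half-open) parallel to `locus`.
#' @param locus Locus names; all four of ITS1, 5.8S, ITS2, LSU must appear
#'   exactly once.
#' @return A `data.frame` of class `locus_annotation` with columns
#'   `reference_id`, `locus`, `start`, `end`.
#' @export
locus_annotation <- function(reference_id, locus, start, end) {
  ann <- data.frame(reference_id = reference_id, locus = as.character(locus),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  if (!setequal(ann$locus, .LOCI) || anyDuplicated(ann$locus))
    stop("annotation must contain each of ", paste(.LOCI, collapse = ", "),
         " exactly once")
  if (any(ann$end <= ann$start)) stop("empty or reversed locus interval")
  if (any(utils::head(ann$end, -1L) > utils::tail(ann$start, -1L)))
    stop("locus intervals overlap")
  class(ann) <- c("locus_annotation", "data.frame")
  ann
}

#' Build an annotation from consecutive locus lengths
#'
#' @param reference_id Reference sequence id.
#' @param lengths Named integer vector of locus lengths in genomic order,
#'   e.g. `c(ITS1 = 180, "5.8S" = 160, ITS2 = 230, LSU = 570)`.
#' @return A [locus_annotation()].
#' @export
annotation_from_lengths <- function(reference_id, lengths) {
  ends <- cumsum(as.integer(lengths))
  locus_annotation(reference_id, names(lengths),
                   start = ends - as.integer(lengths), end = ends)
}

#' @rdname locus_annotation
#' @param path TSV file with columns reference_id, locus, start, end
#'   (0-based half-open coordinates).
#' @export
read_locus_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  locus_annotation(tab$reference_id[1L], tab$locus, tab$start, tab$end)
}

#' @rdname locus_annotation
#' @param ann A `locus_annotation`.
#' @export
write_locus_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' 1-based site indices of a locus
#'
#' @param ann A [locus_annotation()].
#' @param locus Locus name.
#' @return Integer vector of 1-based positions on the reference.
#' @export
locus_sites <- function(ann, locus) {
  row <- ann[ann$locus == locus, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown locus: ", locus)
  (row$start + 1L):row$end
}

#' Global pairwise alignment of a query to a reference
#'
#' Needleman-Wunsch global alignment with affine gap costs, used to anchor
#' clone sequences on the reference coordinate system.  A gap of length k
#' costs `|gap_open| + (k - 1) * |gap_extend|`.
#'
#' @param ref,qry Sequences (character strings); may be named, or ids given
#'   via `ref_id`/`qry_id`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults:
#'   +1/-1/-4/-1).
#' @param ref_id,qry_id Optional ids.
#' @return An object of class `pairwise_alignment`: a list with elements
#'   `ref_id`, `qry_id`, `aligned_ref`, `aligned_qry` (equal-length gapped
#'   strings), `score`, and `ref_coords` (per alignment column, the 1-based
#'   reference position, or `NA` for insertion columns).
#' @export
align_to_reference <- function(ref, qry, match = 1, mismatch = -1,
                               gap_open = -4, gap_extend = -1,
                               ref_id = NULL, qry_id = NULL) {
  ref_id <- ref_id %||% names(ref) %||% "ref"
  qry_id <- qry_id %||% names(qry) %||% "qry"
  ref <- unname(ref); qry <- unname(qry)
  if (!nzchar(ref) || !nzchar(qry)) stop("sequences must be non-empty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qry),
    subject = Biostrings::DNAString(ref),
    substitutionMatrix = sm,
    gapOpening = abs(gap_open) - abs(gap_extend),
    gapExtension = abs(gap_extend),
    type = "global")
  a_qry <- as.character(Biostrings::alignedPattern(pa))
  a_ref <- as.character(Biostrings::alignedSubject(pa))
  rc <- .chars(a_ref)
  ref_coords <- ifelse(rc == "-", NA_integer_, cumsum(rc != "-"))
  structure(list(ref_id = ref_id, qry_id = qry_id,
                 aligned_ref = a_ref, aligned_qry = a_qry,
                 score = Biostrings::score(pa),
                 ref_coords = as.integer(ref_coords)),
            class = "pairwise_alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition an aligned query into the four rDNA loci
#'
#' Extracts, for each annotated locus, the query residues aligned to reference
#' positions inside the locus interval (gaps removed).  Query insertions
#' between two reference positions are assigned to the locus of the left
#' flanking reference position.
#'
#' @param aln A [align_to_reference()] result.
#' @param ann A [locus_annotation()]; its `reference_id` must match the
#'   alignment's.
#' @return Named character vector with one (possibly empty) sequence per
#'   locus; loci whose interval is fully deleted in the query carry a
#'   `warned_empty` attribute listing them, and a warning is raised.
#' @export
partition_loci <- function(aln, ann) {
  if (!identical(ann$reference_id[1L], aln$ref_id))
    stop("annotation reference_id (", ann$reference_id[1L],
         ") does not match alignment ref_id (", aln$ref_id, ")")
  qc <- .chars(aln$aligned_qry)
  # left-fill insertion columns with the flanking reference position
  pos <- aln$ref_coords
  ii <- cumsum(!is.na(pos))
  filled <- c(NA_integer_, pos[!is.na(pos)])[ii + 1L]
  out <- character(length(.LOCI)); names(out) <- .LOCI
  empty <- character(0)
  for (k in seq_len(nrow(ann))) {
    locus <- ann$locus[k]
    keep <- !is.na(filled) & filled > ann$start[k] & filled <= ann$end[k] &
      qc != "-"
    out[locus] <- .collapse(qc[keep])
    if (!nzchar(out[locus])) empty <- c(empty, locus)
  }
  if (length(empty)) {
    warning("locus interval fully deleted in query: ",
            paste(empty, collapse = ", "))
    attr(out, "warned_empty") <- empty
  }
  out
}
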