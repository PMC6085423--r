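# Workflow entry points: write a simulated study to disk as standard FASTA /
# TSV, run the full analysis over it, and render a plain-text report.  These
# are the same functions the command-line wrapper (inst/scripts/rdnahet)
# drives.

.stop_if_nonempty <- function(dir, force) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory ", dir, " is non-empty; use force = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
}

#' Write a simulated clone-library study to disk
#'
#' Runs [simulate_study()] and writes standard formats: `copies.fasta` (the
#' repeat array), `clones_F.fasta` / `clones_R.fasta` (reads; reverse reads
#' are written reverse-complemented, as a sequencer would deliver them),
#' `reference.fasta` (majority-call Sanger reference), `typeA.fasta` /
#' `typeB.fasta` (the two species canonicals in the type-strain role),
#' `annotation.tsv`, `truth.tsv` and a `manifest.json` recording the exact
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the [simulate_study()] result.
#' @export
run_simulation <- function(cfg, out_dir, force = FALSE) {
  .stop_if_nonempty(out_dir, force)
  st <- simulate_study(cfg)
  p <- function(f) file.path(out_dir, f)
  write_fasta(.matrix_seqs(st$sim$copies), p("copies.fasta"))
  fwd <- .matrix_seqs(st$clones$fwd)
  names(fwd) <- paste0(st$clones$clone_id, "_F")
  write_fasta(fwd, p("clones_F.fasta"))
  rv <- vapply(.matrix_seqs(st$clones$rev), reverse_complement, "")
  names(rv) <- paste0(st$clones$clone_id, "_R")
  write_fasta(rv, p("clones_R.fasta"))
  write_fasta(c(reference = .collapse(st$sanger$reference)),
              p("reference.fasta"))
  write_fasta(c(typeA = .collapse(st$sim$canonical_A)), p("typeA.fasta"))
  write_fasta(c(typeB = .collapse(st$sim$species_B)), p("typeB.fasta"))
  write_locus_annotation(st$sim$annotation, p("annotation.tsv"))
  truth <- st$sim$truth
  truth$carriers <- vapply(truth$carriers, paste, "", collapse = ",")
  truth$ref_pos0 <- truth$pos - 1L
  utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(package = "rdnaHet",
                   version = as.character(utils::packageVersion("rdnaHet")),
                   config = unclass(cfg))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(st)
}

# read a run_simulation() directory back into the in-memory layout
.load_study_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("clones_F.fasta", "clones_R.fasta", "reference.fasta",
              "typeA.fasta", "typeB.fasta", "annotation.tsv"))
    if (!file.exists(p(f))) stop("missing input file: ", f)
  fwd <- read_fasta(p("clones_F.fasta"))
  rev <- vapply(read_fasta(p("clones_R.fasta")), reverse_complement, "")
  names(fwd) <- sub("_F$", "", names(fwd))
  names(rev) <- sub("_R$", "", names(rev))
  rev <- rev[names(fwd)]
  clones <- structure(list(clone_id = names(fwd), copy_id = NULL,
                           fwd = .seq_matrix(fwd), rev = .seq_matrix(rev)),
                      class = "clone_set")
  list(clones = clones,
       reference = .chars(read_fasta(p("reference.fasta"))[[1L]]),
       typeA = .chars(read_fasta(p("typeA.fasta"))[[1L]]),
       typeB = .chars(read_fasta(p("typeB.fasta"))[[1L]]),
       annotation = read_locus_annotation(p("annotation.tsv")))
}

#' Run the full heterogeneity analysis
#'
#' Chains every stage over a simulated study (directory from
#' [run_simulation()] or the in-memory [simulate_study()] result): consensus
#' building, the four-setting distance summary, the locus correlation
#' tables, per-locus distance histograms and threshold attribution, the SNP
#' spectrum, and NJ + UPGMA trees (concatenated and per-locus alignments of
#' clones plus both type strains) with bootstrap support.
#'
#' @param input Directory path or [simulate_study()] result.
#' @param out_dir Output directory.
#' @param consensus_policy Passed to [consensus_clone_set()].
#' @param metric Distance metric for the distance summary and trees.
#' @param thresholds A [threshold_set()].
#' @param original_strand Which strand is the "original" sequence.
#' @param boot_nj,boot_upgma Bootstrap replicates for NJ / UPGMA trees.
#' @param seed Seed for bootstrap resampling.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_analysis <- function(input, out_dir,
                         consensus_policy = c("iupac", "fwd_wins",
                                              "reference_biased"),
                         metric = c("p", "tn93_mcl"),
                         thresholds = threshold_set(),
                         original_strand = c("fwd", "rev"),
                         boot_nj = 1000L, boot_upgma = 100L, seed = 1L,
                         force = FALSE) {
  consensus_policy <- match.arg(consensus_policy)
  metric <- match.arg(metric)
  original_strand <- match.arg(original_strand)
  .stop_if_nonempty(out_dir, force)
  st <- if (is.character(input)) .load_study_dir(input) else
    list(clones = input$clones, reference = input$sanger$reference,
         typeA = input$sim$canonical_A, typeB = input$sim$species_B,
         annotation = input$sim$annotation)
  p <- function(f) file.path(out_dir, f)
  tsv <- function(x, f) utils::write.table(x, p(f), sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE)
  ann <- st$annotation
  clones <- consensus_clone_set(st$clones, policy = consensus_policy,
                                reference = st$reference)

  fss <- four_setting_summary(st$reference, clones, ann, metric = metric,
                              original_strand = original_strand)
  tsv(fss, "distance_summary.tsv")

  cors <- list()
  for (src in c("consensus", "original")) {
    prof <- locus_distance_profiles(st$reference, clones, ann,
                                    source = src, metric = metric,
                                    original_strand = original_strand)
    ct <- correlation_table(prof, strict = FALSE)
    tab <- as.data.frame(round(ct$table, 4))
    tab <- cbind(source = src, locus = rownames(tab), tab)
    cors[[src]] <- tab
  }
  tsv(do.call(rbind, c(cors, make.row.names = FALSE)),
      "locus_correlations.tsv")

  spec <- build_spectrum(clones, st$typeA, st$typeB, ann,
                         use = "consensus")
  out_snps <- spec$snps
  if (nrow(out_snps)) out_snps$ref_pos0 <- out_snps$pos - 1L
  tsv(out_snps, "snp_spectrum.tsv")
  jsonlite::write_json(
    list(n_clones = spec$n_clones,
         n_records = nrow(spec$snps),
         typestrain_diffs = as.list(table(
           factor(spec$typestrain_diffs$locus, levels = .LOCI))),
         by_class = as.list(table(spec$snps$freq_class))),
    p("snp_summary.json"), auto_unbox = TRUE, pretty = TRUE)

  ident <- list(); hists <- list()
  for (src in c("consensus", "original")) {
    mat <- if (src == "consensus") clones$consensus else
      clones[[original_strand]]
    d <- diversity_overestimate(mat, st$typeA, st$typeB, ann,
                                thresholds = thresholds, metric = "p")
    d$per_locus <- cbind(source = src, d$per_locus)
    d$attributions <- cbind(source = src, d$attributions)
    ident[[src]] <- d
    for (locus in ann$locus) {
      dm <- p_distance_matrix(mat[, locus_sites(ann, locus), drop = FALSE])
      h <- distance_histogram(dm)
      hists[[paste(src, locus)]] <- cbind(source = src, locus = locus, h)
    }
  }
  tsv(do.call(rbind, c(lapply(ident, `[[`, "attributions"),
                       make.row.names = FALSE)), "attribution.tsv")
  tsv(do.call(rbind, c(lapply(ident, `[[`, "per_locus"),
                       make.row.names = FALSE)),
      "identification_summary.tsv")
  tsv(do.call(rbind, c(hists, make.row.names = FALSE)),
      "distance_histograms.tsv")

  dir.create(p("trees"), showWarnings = FALSE)
  strands <- rbind(clones$consensus, typeA = st$typeA, typeB = st$typeB)
  trees <- list()
  panels <- c(list(concat = seq_len(ncol(strands))),
              stats::setNames(lapply(ann$locus, locus_sites, ann = ann),
                              ann$locus))
  for (panel in names(panels)) {
    sub <- strands[, panels[[panel]], drop = FALSE]
    for (builder in c("nj", "upgma")) {
      bs <- bootstrap_support(sub, builder = builder, metric = metric,
                              n_reps = if (builder == "nj") boot_nj else
                                boot_upgma,
                              seed = seed)
      fn <- sprintf("trees/%s_%s.nwk", builder, gsub("[^A-Za-z0-9]", "",
                                                     panel))
      ape::write.tree(bs$tree, p(fn))
      trees[[paste(builder, panel)]] <- bs
    }
  }

  jsonlite::write_json(
    list(consensus_policy = consensus_policy, metric = metric,
         thresholds = unclass(thresholds),
         original_strand = original_strand,
         boot_nj = boot_nj, boot_upgma = boot_upgma, seed = seed),
    p("config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(clones = clones, distance_summary = fss,
                 correlations = cors, spectrum = spec,
                 identification = ident, trees = trees))
}

#' Render a plain-text summary of an analysis directory
#'
#' @param analysis_dir Directory written by [run_analysis()].
#' @param out_file Output file (default `report.md` inside the directory).
#' @return Invisibly, the report lines.
#' @export
render_report <- function(analysis_dir,
                          out_file = file.path(analysis_dir, "report.md")) {
  p <- function(f) file.path(analysis_dir, f)
  need <- c("distance_summary.tsv", "identification_summary.tsv",
            "snp_spectrum.tsv", "locus_correlations.tsv")
  missing <- need[!file.exists(p(need))]
  if (length(missing))
    stop("analysis directory incomplete; missing: ",
         paste(missing, collapse = ", "))
  fss <- utils::read.delim(p("distance_summary.tsv"), check.names = FALSE)
  ident <- utils::read.delim(p("identification_summary.tsv"),
                             check.names = FALSE)
  snps <- utils::read.delim(p("snp_spectrum.tsv"), check.names = FALSE)
  lines <- c("# rDNA repeat heterogeneity report", "")
  orig <- ident[ident$source == "original", ]
  for (locus in .LOCI) {
    row <- orig[orig$locus == locus, ]
    mx <- fss[fss$locus == locus & fss$setting == "ref_vs_original",
              "max"]
    lines <- c(lines, sprintf(
      "- %s: max original-vs-reference distance %.4f; %.1f%% of pairwise distances exceed the %.2f%% species threshold; %d spurious OTU(s).",
      locus, mx, 100 * row$exceedance, 100 * row$threshold,
      row$spurious_otus))
  }
  lines <- c(lines, "")
  if (nrow(snps) == 0) {
    lines <- c(lines, "No heterogeneity detected: the SNP spectrum is empty.")
  } else {
    cls <- table(snps$freq_class)
    lines <- c(lines, sprintf(
      "SNP spectrum: %d records (%s); %s.",
      nrow(snps),
      paste(sprintf("%s: %d", names(cls), as.integer(cls)),
            collapse = ", "),
      if (is.na(cls["intermediate"]) || cls["intermediate"] == 0)
        "bimodal (no intermediate-frequency class)" else
          "intermediate-frequency records present"))
  }
  writeLines(lines, out_file)
  invisible(lines)
}
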