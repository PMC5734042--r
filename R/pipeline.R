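#' Configuration for a family survey run
#'
#' Collects inputs, thresholds and output location for [run_survey()].
#' Inputs may be given as file paths (FASTA / TSV) or as live objects; file
#' inputs are validated at construction.
#'
#' @param reference_protein [aa_sequence], character, or FASTA path (first
#'   record used, translated if it looks like DNA).
#' @param loci Named list of [gene_locus], or FASTA path (with
#'   `annotations`).
#' @param annotations Annotation TSV path or data.frame (see
#'   [read_locus_annotations()]); required when `loci` is a FASTA path.
#' @param reference_cds Optional [nt_sequence]/character/FASTA path for the
#'   nucleotide consensus criterion.
#' @param sites Optional sites TSV path, data.frame, or integer positions.
#' @param thresholds See [repair_thresholds()].
#' @param k k-mer length for the family tree.
#' @param seed Integer seed recorded in the report (the survey itself is
#'   deterministic; the seed is for any downstream simulation).
#' @param out_dir Optional output directory; when given, [run_survey()]
#'   writes `summary.tsv`, `similarity_matrix.tsv`, `repaired.fasta`,
#'   `tree.nwk` and `report.json` there.
#' @return Object of class `survey_config`.
#' @export
survey_config <- function(reference_protein, loci, annotations = NULL,
                          reference_cds = NULL, sites = NULL,
                          thresholds = repair_thresholds(), k = 15L,
                          seed = 1L, out_dir = NULL) {
  if (is.character(reference_protein) && length(reference_protein) == 1L &&
      file.exists(reference_protein)) {
    rec <- read_fasta(reference_protein)[[1L]]
    res <- if (grepl("^[ACGTN]+$", rec$residues)) {
      sub("\\*$", "", translate(rec$residues))   # CDS record: translate
    } else rec$residues
    reference_protein <- aa_sequence(rec$id, res, mature = TRUE)
  }
  if (is.character(loci) && length(loci) == 1L && file.exists(loci)) {
    if (is.null(annotations)) {
      stop("loci given as FASTA path require an annotation table",
           call. = FALSE)
    }
    if (is.character(annotations)) annotations <- read_locus_annotations(annotations)
    loci <- make_loci(read_fasta(loci), annotations)
  }
  if (is.character(reference_cds) && length(reference_cds) == 1L &&
      file.exists(reference_cds)) {
    reference_cds <- read_fasta(reference_cds)[[1L]]
  }
  if (is.character(sites) && length(sites) == 1L && file.exists(sites)) {
    sites <- read_sites_tsv(sites)
  }
  ref <- family_reference(reference_protein, cds = reference_cds,
                          sites = sites)
  structure(list(reference = ref, loci = loci, thresholds = thresholds,
                 k = as.integer(k), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "survey_config")
}

#' Run the full family survey
#'
#' Orchestrates the whole analysis over every locus: repair scan and
#' four-criterion audit, catalytic-site mapping, classification, the
#' similarity table (nucleotide / amino-acid percent similarity against the
#' reference), and the alignment-free k-mer neighbor-joining tree over the
#' intact and repaired CDSs (built only when at least three are available).
#' A failure on one locus is recorded in that locus's row and does not abort
#' the others. Reruns with identical inputs and configuration are
#' bit-identical.
#'
#' @param config A [survey_config].
#' @return Object of class `survey_report`: `reports` (per-locus
#'   [classify_locus()] results or error records), `summary` (data.frame),
#'   `similarity` (data.frame), `repaired` (list of [nt_sequence]), `tree`
#'   (`phylo` or `NULL`), `n_failed`, and `metadata`.
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  ref <- config$reference
  loci <- config$loci
  th <- config$thresholds

  reports <- list()
  repaired <- list()
  rows <- list()
  sim_rows <- list()
  n_failed <- 0L

  for (lab in names(loci)) {
    locus <- loci[[lab]]
    rep_i <- tryCatch(
      classify_locus(locus, ref, thresholds = th),
      error = function(e) structure(list(label = lab, status = "error",
                                         message = conditionMessage(e)),
                                    class = "survey_error"))
    reports[[lab]] <- rep_i
    if (inherits(rep_i, "survey_error")) {
      n_failed <- n_failed + 1L
      rows[[lab]] <- data.frame(
        label = lab, status = "error", best_edit = NA_character_,
        c1_consensus = NA, c2_single_edit = NA, c3_length = NA,
        c4_similarity = NA, nt_similarity = NA_real_,
        aa_similarity = NA_real_, stringsAsFactors = FALSE)
      sim_rows[[lab]] <- data.frame(label = lab, cell = "*",
                                    stringsAsFactors = FALSE)
      next
    }
    fix <- tryCatch(apply_repair(locus, rep_i$best_proposal),
                    error = function(e) NULL)
    nt_sim <- if (!is.null(ref$cds) && !is.null(fix)) {
      consensus_fraction(fix$cds, ref$cds)
    } else NA_real_
    aa_sim <- if (!is.null(fix) && nzchar(fix$protein$residues)) {
      percent_similarity(global_align(fix$protein, ref$protein,
                                      scoring_scheme("protein")))
    } else NA_real_
    if (!is.null(fix) && rep_i$status %in%
        c("intact", "missense_catalytic", "frameshift_split",
          "nonsense_truncated")) {
      repaired[[lab]] <- fix$cds
    }
    best_edit <- if (!is.null(rep_i$best_proposal)) {
      p <- rep_i$best_proposal
      sprintf("%s@%d:%s>%s", p$edit_kind, p$position, p$ref_base, p$alt_base)
    } else NA_character_
    cr <- rep_i$criteria
    rows[[lab]] <- data.frame(
      label = lab, status = rep_i$status, best_edit = best_edit,
      c1_consensus = cr$c1_consensus_ok, c2_single_edit = cr$c2_single_edit_ok,
      c3_length = cr$c3_length_ok, c4_similarity = cr$c4_protein_similarity_ok,
      nt_similarity = nt_sim, aa_similarity = aa_sim,
      stringsAsFactors = FALSE)
    cell <- if (rep_i$status == "absent") "NR" else if (is.na(nt_sim)) "*"
    else sprintf("%.1f/%.1f", nt_sim, aa_sim)
    sim_rows[[lab]] <- data.frame(label = lab, cell = cell,
                                  stringsAsFactors = FALSE)
  }

  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  sim_df <- do.call(rbind, sim_rows)
  rownames(sim_df) <- NULL
  names(sim_df)[2] <- "nt_similarity/aa_similarity"

  tree <- NULL
  if (length(repaired) >= 3L) {
    d <- kmer_distance_matrix(unname(repaired), k = config$k)
    rownames(d) <- colnames(d) <- names(repaired)
    tree <- neighbor_joining(d)
  } else {
    message("fewer than 3 intact/repaired CDSs; no tree built")
  }

  meta <- list(package_version = as.character(utils::packageVersion("orfrescue")),
               k = config$k, seed = config$seed,
               thresholds = th,
               similarity_convention = paste(
                 "global end-to-end alignment, gaps counted in denominator;",
                 "aa similarity = % columns with positive BLOSUM62 score"))
  out <- structure(list(reports = reports, summary = summary_df,
                        similarity = sim_df, repaired = repaired,
                        tree = tree, n_failed = n_failed, metadata = meta),
                   class = "survey_report")
  if (!is.null(config$out_dir)) write_survey_report(out, config$out_dir)
  out
}

#' Write the survey report artifacts
#'
#' Writes `summary.tsv`, `similarity_matrix.tsv` (with a header comment
#' recording the similarity convention), `repaired.fasta`, `tree.nwk` (when
#' a tree was built) and `report.json`.
#'
#' @param report A `survey_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_report <- function(report, dir) {
  stopifnot(inherits(report, "survey_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$summary, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "similarity_matrix.tsv"), "w")
  writeLines(paste0("# ", report$metadata$similarity_convention), con)
  write.table(report$similarity, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  if (length(report$repaired) > 0L) {
    write_fasta(report$repaired, file.path(dir, "repaired.fasta"))
  }
  if (!is.null(report$tree)) {
    write_newick(report$tree, file.path(dir, "tree.nwk"))
  }
  payload <- list(metadata = report$metadata, summary = report$summary,
                  similarity = report$similarity)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.survey_report <- function(x, ...) {
  cat(sprintf("<survey_report> %d loci (%d failed), %d repaired/intact CDSs%s\n",
              nrow(x$summary), x$n_failed, length(x$repaired),
              if (is.null(x$tree)) "" else ", NJ tree built"))
  print(x$summary[, c("label", "status", "best_edit")])
  invisible(x)
}
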