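#' Bundle the reference gene for a family survey
#'
#' The pseudogene audit needs the reference protein; the nucleotide consensus
#' criterion additionally needs the reference CDS, and the catalytic audit a
#' site table. This container carries whichever are available.
#'
#' @param protein Reference protein ([aa_sequence] or character).
#' @param cds Optional reference CDS ([nt_sequence] or character).
#' @param sites Optional catalytic-site data.frame (see [read_sites_tsv()])
#'   or integer positions.
#' @return Object of class `family_reference`.
#' @export
family_reference <- function(protein, cds = NULL, sites = NULL) {
  if (is.character(protein)) protein <- aa_sequence("reference", protein,
                                                    mature = TRUE)
  stopifnot(inherits(protein, "aa_sequence"))
  if (is.character(cds)) cds <- nt_sequence("reference_cds", cds)
  if (!is.null(sites) && !is.data.frame(sites)) {
    sites <- data.frame(reference_position = as.integer(sites),
                        expected_residue = vapply(as.integer(sites), function(p)
                          substr(protein$residues, p, p), ""))
  }
  structure(list(protein = protein, cds = cds, sites = sites),
            class = "family_reference")
}

#' Fraction of the reference protein alignable to a locus context
#'
#' For each forward reading frame of the context, the reference protein is
#' locally aligned (Smith-Waterman) to the frame translation; a reference
#' position counts as alignable if, in any frame, its alignment column has
#' a strictly positive substitution score. Local alignment keeps the
#' measure frame-robust: a frameshifted copy is covered piecewise by two
#' frames, while a 5'-deleted copy leaves the missing positions uncovered
#' in every frame; counting only positive columns keeps chance extensions
#' of the aligned segment from inflating coverage. Alignments scoring below
#' `min_local_score` are ignored entirely: chance local alignments of
#' unrelated translated sequence rarely reach the mid-40s under BLOSUM62
#' with 11/1 gaps, while any genuinely homologous fragment of a few dozen
#' residues scores in the hundreds.
#'
#' @param locus A [gene_locus].
#' @param reference Reference protein or [family_reference].
#' @param scheme Protein [scoring_scheme].
#' @param min_local_score Ignore local alignments below this score.
#' @return Fraction in `[0, 1]`.
#' @export
alignable_fraction <- function(locus, reference,
                               scheme = scoring_scheme("protein"),
                               min_local_score = 60) {
  ref <- .ref_protein(reference)
  rlen <- nchar(ref$residues)
  covered <- logical(rlen)
  ctx <- locus$context$residues
  for (off in 0:2) {
    aa <- translate(ctx, off)
    if (!nzchar(aa)) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref$residues), Biostrings::AAString(aa),
      substitutionMatrix = scheme$submat,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      type = "local")
    if (Biostrings::score(pa) < min_local_score) next
    a <- .seq_chars(as.character(Biostrings::alignedPattern(pa)))
    b <- .seq_chars(as.character(Biostrings::alignedSubject(pa)))
    rng <- pa@pattern@range
    ref_pos <- rng@start - 1L + cumsum(a != "-")
    m <- scheme$submat
    ok <- a != "-" & b != "-" & a %in% rownames(m) & b %in% colnames(m)
    pos_col <- ok
    pos_col[ok] <- m[cbind(a[ok], b[ok])] > 0
    covered[ref_pos[pos_col]] <- TRUE
  }
  mean(covered)
}

#' Evaluate the four ancestral-ORF criteria
#'
#' The published decision rule for calling a degraded locus an ancestrally
#' intact gene: (i) the out-of-frame nucleotide sequence shares at least the
#' consensus threshold with the reference CDS, (ii) a single simulated
#' base-pair edit restores the frame, (iii) the restored ORF is similar in
#' length to the reference CDS, and (iv) the restored protein shares at
#' least the similarity threshold with the reference protein.
#'
#' @param locus A [gene_locus].
#' @param proposal One repair-proposal row (see [scan_single_edit_repairs()]).
#' @param reference A [family_reference] (criterion i needs its `cds`; when
#'   absent the consensus value is `NA` and the boolean is `NA`).
#' @param thresholds See [repair_thresholds()].
#' @return List of class `criterion_report`: booleans `c1_consensus_ok`,
#'   `c2_single_edit_ok`, `c3_length_ok`, `c4_protein_similarity_ok` plus the
#'   supporting values (`consensus`, `n_edits`, `length_ratio`,
#'   `aa_similarity`).
#' @export
check_ancestral_criteria <- function(locus, proposal, reference,
                                     thresholds = repair_thresholds()) {
  stopifnot(inherits(locus, "gene_locus"))
  if (!inherits(reference, "family_reference")) {
    reference <- family_reference(reference)
  }
  p <- if (is.data.frame(proposal) && nrow(proposal) >= 1L) {
    as.data.frame(proposal)[1L, ]
  } else NULL

  consensus <- NA_real_
  if (!is.null(reference$cds)) {
    # footprint of the (repaired) ORF on the unedited context
    if (is.null(p)) {
      region <- locus_cds(locus)$residues
    } else {
      oe <- p$orf_end
      if (p$edit_kind == "insertion") oe <- oe - 1L
      if (p$edit_kind == "deletion") oe <- oe + 1L
      oe <- min(oe, nchar(locus$context$residues))
      region <- substr(locus$context$residues, p$orf_start, oe)
    }
    consensus <- consensus_fraction(region, reference$cds)
  }
  n_edits <- if (is.null(p)) 0L else 1L
  if (is.null(p)) {
    ann <- .annotated_translation(locus)
    ratio <- nchar(ann$protein) / nchar(reference$protein$residues)
    sim <- if (nzchar(ann$protein)) {
      percent_similarity(global_align(ann$protein, reference$protein$residues,
                                      scoring_scheme("protein")))
    } else 0
  } else {
    ratio <- p$length_ratio
    sim <- p$aa_similarity
  }
  band <- thresholds$length_ratio
  out <- list(
    c1_consensus_ok = if (is.na(consensus)) NA else consensus >= thresholds$consensus,
    c2_single_edit_ok = n_edits <= 1L,
    c3_length_ok = ratio >= band[1] && ratio <= band[2],
    c4_protein_similarity_ok = sim >= thresholds$aa_similarity,
    consensus = consensus, n_edits = n_edits,
    length_ratio = ratio, aa_similarity = sim)
  class(out) <- "criterion_report"
  out
}

#' @export
print.criterion_report <- function(x, ...) {
  cat(sprintf(
    "<criterion_report> consensus %s (%.1f) | edits %s (%d) | length %s (%.2f) | similarity %s (%.1f)\n",
    x$c1_consensus_ok, x$consensus, x$c2_single_edit_ok, x$n_edits,
    x$c3_length_ok, x$length_ratio, x$c4_protein_similarity_ok,
    x$aa_similarity))
  invisible(x)
}

#' Classify a locus on the pseudogenization ladder
#'
#' Decision ladder:
#' \itemize{
#'   \item `intact` -- the annotated ORF passes the length and similarity
#'     criteria and every catalytic site is conserved;
#'   \item `missense_catalytic` -- full length, but a catalytic site is not
#'     conserved;
#'   \item `frameshift_split` -- the best single-base repair is an indel
#'     (one ancestral ORF split across a frameshift);
#'   \item `nonsense_truncated` -- the best repair is a stop-removing
#'     substitution;
#'   \item `partial_deletion` -- less than `partial_fraction` of the
#'     reference aligns to the context (also the fallback when no single
#'     edit repairs a degraded locus);
#'   \item `absent` -- less than `absent_floor` of the reference aligns.
#' }
#'
#' Following the ambiguity of active genes that nevertheless carry an
#' upstream lesion, the report always carries both the annotated-ORF verdict
#' and any upstream stop-repair proposals rather than forcing one
#' interpretation.
#'
#' @param locus A [gene_locus].
#' @param reference A [family_reference] (or protein; catalytic audit then
#'   uses `site_positions`).
#' @param site_positions Optional catalytic positions (overrides
#'   `reference$sites`).
#' @param thresholds See [repair_thresholds()].
#' @param scheme Protein [scoring_scheme].
#' @return Object of class `pseudogene_report`.
#' @export
classify_locus <- function(locus, reference, site_positions = NULL,
                           thresholds = repair_thresholds(),
                           scheme = scoring_scheme("protein")) {
  stopifnot(inherits(locus, "gene_locus"))
  if (!inherits(reference, "family_reference")) {
    reference <- family_reference(reference)
  }
  if (is.null(site_positions) && !is.null(reference$sites)) {
    site_positions <- reference$sites$reference_position
  }
  ref <- reference$protein
  ref_len <- nchar(ref$residues)
  band <- thresholds$length_ratio

  ann <- .annotated_translation(locus)
  ann_ratio <- nchar(ann$protein) / ref_len
  ann_sim <- if (nzchar(ann$protein)) {
    .protein_align_stats(ann$protein, ref$residues, scheme)$aa_similarity
  } else 0
  ann_full <- ann$has_terminal_stop && startsWith(ann$protein, "M") &&
    ann_ratio >= band[1] && ann_ratio <= band[2] &&
    ann_sim >= thresholds$aa_similarity

  site_map <- NULL
  status <- NULL
  best <- NULL
  proposals <- .empty_proposals()

  if (ann_full) {
    if (!is.null(site_positions) && length(site_positions) > 0L) {
      site_map <- map_catalytic_sites(ref, site_positions, ann$protein,
                                      scheme = scheme)
      status <- if (all(site_map$conserved)) "intact" else "missense_catalytic"
    } else {
      status <- "intact"
    }
  } else {
    frac <- alignable_fraction(locus, ref, scheme)
    if (frac < thresholds$absent_floor) {
      status <- "absent"
    } else {
      proposals <- scan_single_edit_repairs(locus, reference,
                                            thresholds = thresholds,
                                            scheme = scheme)
      if (nrow(proposals) > 0L) {
        best <- proposals[1L, ]
        status <- if (best$edit_kind %in% c("insertion", "deletion")) {
          "frameshift_split"
        } else {
          "nonsense_truncated"
        }
        if (!is.null(site_positions) && length(site_positions) > 0L) {
          site_map <- map_catalytic_sites(ref, site_positions, best$protein,
                                          scheme = scheme)
        }
      } else if (frac < thresholds$partial_fraction) {
        status <- "partial_deletion"
      } else {
        # degraded beyond a single edit but still largely alignable
        status <- "partial_deletion"
      }
    }
  }
  if (is.null(site_map) && ann_full &&
      !is.null(site_positions) && length(site_positions) > 0L) {
    site_map <- map_catalytic_sites(ref, site_positions, ann$protein,
                                    scheme = scheme)
  }

  upstream <- tryCatch(
    scan_upstream_stop_repairs(locus, ref, scheme = scheme),
    error = function(e) NULL)

  criteria <- check_ancestral_criteria(locus, best, reference, thresholds)
  out <- list(
    label = locus$label,
    status = status,
    annotated_protein = ann$protein,
    annotated_length_ratio = ann_ratio,
    annotated_similarity = ann_sim,
    best_proposal = best,
    proposals = proposals,
    upstream_proposals = upstream,
    criteria = criteria,
    site_map = site_map,
    thresholds = thresholds)
  class(out) <- "pseudogene_report"
  out
}

#' @export
print.pseudogene_report <- function(x, ...) {
  cat(sprintf("<pseudogene_report> %s: %s\n", x$label, x$status))
  cat(sprintf("  annotated ORF: %d aa (ratio %.2f, similarity %.1f%%)\n",
              nchar(x$annotated_protein), x$annotated_length_ratio,
              x$annotated_similarity))
  if (!is.null(x$best_proposal)) {
    p <- x$best_proposal
    cat(sprintf("  best repair: %s at %d (%s>%s), %d aa, similarity %.1f%%\n",
                p$edit_kind, p$position, p$ref_base, p$alt_base,
                nchar(p$protein), p$aa_similarity))
  }
  if (!is.null(x$site_map)) {
    cat(sprintf("  catalytic sites conserved: %d/%d\n",
                sum(x$site_map$conserved), nrow(x$site_map)))
  }
  invisible(x)
}
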