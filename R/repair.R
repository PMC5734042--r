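.encode_dna <- function(s) {
  x <- match(.seq_chars(s), DNA_ALPHABET) - 1L
  if (anyNA(x)) stop("cannot encode non-IUPAC base", call. = FALSE)
  x
}

# apply a single-base edit to a character scalar (context coordinates)
.apply_edit_string <- function(s, kind, pos, alt) {
  n <- nchar(s)
  switch(kind,
    substitution = paste0(substr(s, 1L, pos - 1L), alt, substr(s, pos + 1L, n)),
    insertion = paste0(substr(s, 1L, pos), alt, substr(s, pos + 1L, n)),
    deletion = paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, n)),
    stop("unknown edit kind: ", kind))
}

#' Default thresholds for the ancestral-ORF criteria
#'
#' Defaults mirror the published decision rule: >= 80% nucleotide consensus,
#' exactly one simulated base-pair edit, a repaired ORF within 10% of the
#' reference length, and >= 80% amino-acid similarity. The partial-deletion
#' cutoff (less than half of the reference alignable to the locus) and the
#' absent floor are operational additions, both configurable.
#'
#' @param consensus Minimum nucleotide consensus percent (criterion i).
#' @param aa_similarity Minimum amino-acid similarity percent (criterion iv).
#' @param length_ratio Two-sided band for repaired-ORF / reference length
#'   (criterion iii).
#' @param partial_fraction Below this alignable fraction of the reference the
#'   locus is called `partial_deletion`.
#' @param absent_floor Below this alignable fraction the locus is called
#'   `absent`.
#' @return Named list of thresholds.
#' @export
repair_thresholds <- function(consensus = 80, aa_similarity = 80,
                              length_ratio = c(0.9, 1.1),
                              partial_fraction = 0.5, absent_floor = 0.3) {
  stopifnot(length(length_ratio) == 2L, length_ratio[1] < length_ratio[2])
  list(consensus = consensus, aa_similarity = aa_similarity,
       length_ratio = length_ratio, partial_fraction = partial_fraction,
       absent_floor = absent_floor)
}

.ref_protein <- function(reference) {
  if (inherits(reference, "family_reference")) reference$protein
  else if (inherits(reference, "aa_sequence")) reference
  else if (is.character(reference)) aa_sequence("reference", reference, mature = TRUE)
  else stop("reference must be a protein sequence or family_reference",
            call. = FALSE)
}

# Batch alignment of candidate proteins against the reference; returns a
# data.frame with score, identity, similarity per candidate.
.protein_align_stats <- function(proteins, ref, scheme) {
  if (length(proteins) == 0L) {
    return(data.frame(aa_identity = numeric(), aa_similarity = numeric()))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(proteins), Biostrings::AAString(ref),
    substitutionMatrix = scheme$submat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global")
  aas <- as.character(Biostrings::alignedPattern(pa))
  bbs <- as.character(Biostrings::alignedSubject(pa))
  m <- scheme$submat
  stats <- t(vapply(seq_along(aas), function(i) {
    a <- strsplit(aas[i], "", fixed = TRUE)[[1]]
    b <- strsplit(bbs[i], "", fixed = TRUE)[[1]]
    ident <- a == b & a != "-"
    ok <- a != "-" & b != "-" & a %in% rownames(m) & b %in% colnames(m)
    sim <- logical(length(a))
    sim[ok] <- m[cbind(a[ok], b[ok])] > 0
    c(100 * sum(ident) / length(a), 100 * sum(sim) / length(a))
  }, numeric(2)))
  data.frame(aa_identity = stats[, 1], aa_similarity = stats[, 2])
}

.empty_proposals <- function() {
  structure(data.frame(
    edit_kind = character(), position = integer(), context_pos = integer(),
    ref_base = character(), alt_base = character(),
    orf_start = integer(), orf_end = integer(), orf_nt = integer(),
    protein = character(), aa_similarity = numeric(), aa_identity = numeric(),
    nt_identity = numeric(), length_ratio = numeric(),
    stringsAsFactors = FALSE),
    class = c("repair_proposals", "data.frame"))
}

# Ranking is a parsimony ladder: amino-acid identity to the reference first
# (a repair restoring the locus's own residues beats one leaving a
# frame-scrambled or merely conservative stretch), then nucleotide identity
# of the reconstructed CDS to the reference CDS (DNA has three times the
# resolution and scrambled windows always lose there), then positive-matrix
# similarity, ORF length, and proximity to the annotated start.
.rank_proposals <- function(df) {
  if (nrow(df) == 0L) return(df)
  nt <- if ("nt_identity" %in% names(df)) {
    ifelse(is.na(df$nt_identity), -1, df$nt_identity)
  } else rep(-1, nrow(df))
  df <- df[order(-df$aa_identity, -nt, -df$aa_similarity, -df$orf_nt,
                 abs(df$position)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# batch nucleotide identity of candidate CDSs against a reference CDS
.nt_identity_stats <- function(cds_vec, ref_cds) {
  scheme <- scoring_scheme("nucleotide")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(cds_vec), Biostrings::DNAString(ref_cds),
    substitutionMatrix = scheme$submat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global")
  aas <- as.character(Biostrings::alignedPattern(pa))
  bbs <- as.character(Biostrings::alignedSubject(pa))
  vapply(seq_along(aas), function(i) {
    a <- strsplit(aas[i], "", fixed = TRUE)[[1]]
    b <- strsplit(bbs[i], "", fixed = TRUE)[[1]]
    100 * sum(a == b & a != "-") / length(a)
  }, numeric(1))
}

#' Scan all single-base repairs of a locus
#'
#' Evaluates every single-base substitution (3 per position), insertion
#' (4 per junction) and deletion (1 per position) within the window, and
#' returns those edits for which the edited context contains an open reading
#' frame that overlaps the annotated CDS, starts with ATG, ends at a stop,
#' and whose translation satisfies the amino-acid-similarity and length
#' thresholds against the reference protein. If the annotated ORF already
#' meets the thresholds, nothing needs repair and the result is empty.
#'
#' Indels inside homopolymer runs are left-aligned to a canonical coordinate
#' (the 5'-most equivalent edit), and equivalent proposals are deduplicated.
#' Proposals are ranked by parsimony against the reference: amino-acid
#' identity, then (when a reference CDS is supplied) nucleotide identity of
#' the reconstructed CDS, then positive-matrix amino-acid similarity, then
#' ORF length, then proximity to the annotated start. The top-ranked
#' proposal is the most conservative ancestral-state reconstruction.
#'
#' @param locus A [gene_locus].
#' @param reference Reference protein ([aa_sequence] or [family_reference]).
#' @param window Integer length-2 vector of context positions to scan
#'   (default: annotated CDS plus 1 kb on each side, clamped to the context).
#' @param thresholds See [repair_thresholds()].
#' @param scheme Protein [scoring_scheme] for similarity evaluation.
#' @return A `repair_proposals` data.frame; `position` is in locus
#'   coordinates (negative = upstream of the annotated start; for insertions
#'   it is the junction "after this position").
#' @export
scan_single_edit_repairs <- function(locus, reference, window = NULL,
                                     thresholds = repair_thresholds(),
                                     scheme = scoring_scheme("protein")) {
  stopifnot(inherits(locus, "gene_locus"))
  ref <- .ref_protein(reference)
  ref_len <- nchar(ref$residues)
  if (ref_len < 50L) stop("reference protein implausibly short", call. = FALSE)
  ctx <- locus$context$residues
  n <- nchar(ctx)
  if (is.null(window)) {
    window <- c(max(1L, locus$cds_start - 1000L),
                min(n, locus$cds_end + 1000L))
  }
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2]) {
    stop("empty or invalid edit window", call. = FALSE)
  }

  band <- thresholds$length_ratio
  # annotated ORF already acceptable -> nothing to repair
  ann <- .annotated_translation(locus)
  if (ann$has_terminal_stop && startsWith(ann$protein, "M")) {
    ratio <- nchar(ann$protein) / ref_len
    if (ratio >= band[1] && ratio <= band[2]) {
      sim <- .protein_align_stats(ann$protein, ref$residues, scheme)$aa_similarity
      if (sim >= thresholds$aa_similarity) return(.empty_proposals())
    }
  }

  min_orf_nt <- 3L * (ceiling(band[1] * ref_len) + 1L)
  target_orf_nt <- 3L * (ref_len + 1L)
  hits <- .scan_edits_cpp(.encode_dna(ctx), locus$cds_start, locus$cds_end,
                          window[1], window[2], min_orf_nt, target_orf_nt,
                          TRUE)
  if (nrow(hits) == 0L) return(.empty_proposals())

  kind <- c("substitution", "insertion", "deletion")[hits$kind]
  alt <- ifelse(hits$alt >= 0L, DNA_ALPHABET[hits$alt + 1L], "")
  pos <- hits$pos

  # left-align indels within homopolymer runs (canonical VCF-style coordinate)
  ctx_chr <- .seq_chars(ctx)
  for (i in which(kind == "insertion")) {
    while (pos[i] >= 1L && ctx_chr[pos[i]] == alt[i]) pos[i] <- pos[i] - 1L
  }
  for (i in which(kind == "deletion")) {
    while (pos[i] > 1L && ctx_chr[pos[i] - 1L] == ctx_chr[pos[i]]) {
      pos[i] <- pos[i] - 1L
    }
  }
  keep <- !duplicated(data.frame(kind, pos, alt))
  hits <- hits[keep, , drop = FALSE]
  kind <- kind[keep]; alt <- alt[keep]; pos <- pos[keep]

  # evaluate survivors: reconstruct protein, align to reference
  proteins <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    edited <- .apply_edit_string(ctx, kind[i], pos[i], alt[i])
    orf <- substr(edited, hits$orf_start[i], hits$orf_end[i])
    proteins[i] <- sub("\\*$", "", translate(orf))
  }
  st <- .protein_align_stats(proteins, ref$residues, scheme)
  ratio <- nchar(proteins) / ref_len
  ok <- st$aa_similarity >= thresholds$aa_similarity &
    ratio >= band[1] & ratio <= band[2]
  if (!any(ok)) return(.empty_proposals())

  hits <- hits[ok, , drop = FALSE]
  nt_identity <- rep(NA_real_, sum(ok))
  if (inherits(reference, "family_reference") && !is.null(reference$cds)) {
    cds_vec <- character(nrow(hits))
    idx <- which(ok)
    for (j in seq_along(idx)) {
      i <- idx[j]
      edited <- .apply_edit_string(ctx, kind[i], pos[i], alt[i])
      cds_vec[j] <- substr(edited, hits$orf_start[j], hits$orf_end[j])
    }
    nt_identity <- .nt_identity_stats(cds_vec, reference$cds$residues)
  }
  df <- data.frame(
    edit_kind = kind[ok],
    position = to_locus_coord(pmax(pos[ok], 1L), locus$cds_start),
    context_pos = pos[ok],
    ref_base = ifelse(kind[ok] == "insertion", "", ctx_chr[pmax(pos[ok], 1L)]),
    alt_base = alt[ok],
    orf_start = hits$orf_start, orf_end = hits$orf_end,
    orf_nt = hits$orf_end - hits$orf_start + 1L,
    protein = proteins[ok],
    aa_similarity = st$aa_similarity[ok],
    aa_identity = st$aa_identity[ok],
    nt_identity = nt_identity,
    length_ratio = ratio[ok],
    stringsAsFactors = FALSE)
  # junction 0 (insertion before the first base) keeps its context coordinate
  df$position[df$edit_kind == "insertion" & df$context_pos == 0L] <-
    to_locus_coord(1L, locus$cds_start) - 1L
  df <- .rank_proposals(df)
  class(df) <- c("repair_proposals", "data.frame")
  df
}

#' Scan the 5' flank for stop-removing substitutions
#'
#' Looks for the nearest upstream in-frame stop codon (in frame with the
#' annotated start codon) and enumerates the single-base substitutions that
#' abolish it. For each, the open reading frame is extended to the upstream
#' in-frame ATG whose translation best matches the reference; the extension
#' is reported in nucleotides and residues, with positions in the negative
#' upstream coordinate convention (-1 is the base immediately 5' of the A of
#' the annotated ATG).
#'
#' @param locus A [gene_locus] with 5' flank available.
#' @param reference Reference protein.
#' @param max_extension_nt Search depth into the 5' flank (>= 3); defaults to
#'   the whole available flank.
#' @param scheme Protein [scoring_scheme].
#' @return A `repair_proposals` data.frame with additional columns
#'   `extension_nt` and `extension_aa`; empty if no upstream in-frame stop
#'   exists within reach.
#' @export
scan_upstream_stop_repairs <- function(locus, reference,
                                       max_extension_nt = NULL,
                                       scheme = scoring_scheme("protein")) {
  stopifnot(inherits(locus, "gene_locus"))
  ref <- .ref_protein(reference)
  flank <- locus$cds_start - 1L
  if (flank < 3L) stop("no usable 5' flank on locus ", locus$label, call. = FALSE)
  if (is.null(max_extension_nt)) max_extension_nt <- flank
  stopifnot(max_extension_nt >= 3L)
  max_extension_nt <- min(max_extension_nt, flank)

  ctx <- locus$context$residues
  ctx_chr <- .seq_chars(ctx)
  cds_start <- locus$cds_start
  k_max <- max_extension_nt %/% 3L
  starts <- cds_start - 3L * seq_len(k_max)          # in-frame codon starts
  codons <- substring(ctx, starts, starts + 2L)
  stop_k <- which(codons %in% c("TAA", "TAG", "TGA"))
  out <- .empty_proposals()
  out$extension_nt <- integer(); out$extension_aa <- integer()
  if (length(stop_k) == 0L) return(out)

  k1 <- stop_k[1L]                                   # nearest upstream stop
  q <- starts[k1]
  # candidate new starts: in-frame ATGs strictly upstream of the abolished
  # stop, not beyond the next upstream stop or the search depth
  upper_k <- if (length(stop_k) > 1L) stop_k[2L] - 1L else k_max
  cand_k <- seq(k1 + 1L, upper_k)
  cand_starts <- starts[cand_k]
  cand_starts <- cand_starts[codons[cand_k] == "ATG"]
  if (length(cand_starts) == 0L) return(out)

  rows <- list()
  for (off in 1:3) {
    p <- q + off - 1L
    for (b in setdiff(c("A", "C", "G", "T"), ctx_chr[p])) {
      new_codon <- paste0(
        ifelse(off == 1, b, ctx_chr[q]),
        ifelse(off == 2, b, ctx_chr[q + 1L]),
        ifelse(off == 3, b, ctx_chr[q + 2L]))
      if (new_codon %in% c("TAA", "TAG", "TGA")) next
      edited <- .apply_edit_string(ctx, "substitution", p, b)
      # pick the upstream start whose protein best matches the reference
      cand <- lapply(cand_starts, function(r) {
        aa <- translate(substr(edited, r, nchar(edited)))
        stop_at <- regexpr("*", aa, fixed = TRUE)
        if (stop_at < 0L) return(NULL)
        list(r = r, protein = substr(aa, 1L, stop_at - 1L),
             orf_end = r + 3L * stop_at - 1L)
      })
      cand <- Filter(Negate(is.null), cand)
      if (length(cand) == 0L) next
      st <- .protein_align_stats(vapply(cand, `[[`, "", "protein"),
                                 ref$residues, scheme)
      best <- order(-st$aa_similarity, -st$aa_identity)[1L]
      cb <- cand[[best]]
      rows[[length(rows) + 1L]] <- data.frame(
        edit_kind = "substitution",
        position = to_locus_coord(p, cds_start),
        context_pos = p,
        ref_base = ctx_chr[p], alt_base = b,
        orf_start = cb$r, orf_end = cb$orf_end,
        orf_nt = cb$orf_end - cb$r + 1L,
        protein = cb$protein,
        aa_similarity = st$aa_similarity[best],
        aa_identity = st$aa_identity[best],
        nt_identity = NA_real_,
        length_ratio = nchar(cb$protein) / nchar(ref$residues),
        extension_nt = cds_start - cb$r,
        extension_aa = (cds_start - cb$r) %/% 3L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(out)
  df <- .rank_proposals(do.call(rbind, rows))
  class(df) <- c("repair_proposals", "data.frame")
  df
}

#' Apply a repair proposal to a locus
#'
#' Applies the single-base edit of `proposal` to the locus context and
#' extracts the reconstructed CDS and its translation. With `proposal =
#' NULL` (an intact locus) the annotated CDS is returned unchanged.
#'
#' @param locus A [gene_locus].
#' @param proposal One row of a `repair_proposals` data.frame (the first row
#'   is used if several are supplied), or `NULL`.
#' @return List with `cds` ([nt_sequence], description carries the edit
#'   trail) and `protein` ([aa_sequence], no internal stop).
#' @export
apply_repair <- function(locus, proposal = NULL) {
  stopifnot(inherits(locus, "gene_locus"))
  if (is.null(proposal) || (is.data.frame(proposal) && nrow(proposal) == 0L)) {
    cds <- locus_cds(locus)
    cds$description <- "unedited annotated CDS"
    prot <- sub("\\*$", "", translate(cds$residues))
    return(list(cds = cds,
                protein = aa_sequence(paste0(locus$label, "_protein"), prot,
                                      mature = TRUE)))
  }
  p <- as.data.frame(proposal)[1L, ]
  ctx <- locus$context$residues
  if (p$edit_kind != "insertion") {
    have <- substr(ctx, p$context_pos, p$context_pos)
    if (!identical(have, p$ref_base)) {
      stop("proposal/locus mismatch: context has '", have, "' at position ",
           p$context_pos, ", proposal expects '", p$ref_base, "'",
           call. = FALSE)
    }
  }
  edited <- .apply_edit_string(ctx, p$edit_kind, p$context_pos, p$alt_base)
  cds_str <- substr(edited, p$orf_start, p$orf_end)
  trail <- sprintf("repair=%s@%d%s edited_orf=%d..%d", p$edit_kind,
                   p$position,
                   if (p$edit_kind == "deletion") paste0(":del", p$ref_base)
                   else paste0(":", p$ref_base, ">", p$alt_base),
                   p$orf_start, p$orf_end)
  cds <- nt_sequence(paste0(locus$label, "_repaired"), cds_str, trail)
  prot <- sub("\\*$", "", translate(cds_str))
  if (!identical(prot, p$protein)) {
    stop("proposal/locus mismatch: reconstructed protein differs",
         call. = FALSE)
  }
  list(cds = cds,
       protein = aa_sequence(paste0(locus$label, "_repaired_protein"), prot,
                             mature = TRUE))
}
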