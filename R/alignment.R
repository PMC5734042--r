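#' Alignment scoring scheme
#'
#' Affine-gap scoring for global pairwise alignment. The gap cost of a
#' length-k gap is `gap_open + k * gap_extend`, and end gaps are penalized
#' (end-to-end global alignment), since the family survey compares annotated
#' full-length ORFs. Defaults: nucleotide match +2 / mismatch -3, gap open 5,
#' extend 2; protein BLOSUM62, gap open 11, extend 1.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide scores (ignored for protein mode).
#' @param matrix Protein substitution matrix name (`"BLOSUM62"`,
#'   `"BLOSUM45"`, `"BLOSUM80"`, `"PAM70"`, `"PAM30"`, `"PAM250"`).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 2, mismatch = -3,
                           matrix = "BLOSUM62",
                           gap_open = if (mode == "protein") 11 else 5,
                           gap_extend = if (mode == "protein") 1 else 2) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= 0, gap_extend >= 0)
  sub <- if (mode == "nucleotide") {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
    # extend with an N row/column scoring 0 against everything
    m <- rbind(cbind(m, N = 0), N = 0)
    m
  } else {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  }
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 matrix_name = if (mode == "protein") matrix else NA_character_,
                 gap_open = gap_open, gap_extend = gap_extend,
                 submat = sub),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  if (x$mode == "nucleotide") {
    cat(sprintf("<scoring_scheme> nucleotide match %+g mismatch %+g, gap %g/%g\n",
                x$match, x$mismatch, x$gap_open, x$gap_extend))
  } else {
    cat(sprintf("<scoring_scheme> protein %s, gap %g/%g\n",
                x$matrix_name, x$gap_open, x$gap_extend))
  }
  invisible(x)
}

.default_scheme <- function(x) {
  if (inherits(x, "aa_sequence")) scoring_scheme("protein")
  else scoring_scheme("nucleotide")
}

.as_xstring <- function(x, mode) {
  r <- .residues(x)
  if (mode == "nucleotide") Biostrings::DNAString(r) else Biostrings::AAString(r)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (end gaps penalized),
#' computed by `Biostrings::pairwiseAlignment()`. The traceback is
#' deterministic, so repeated runs are bit-for-bit reproducible.
#'
#' @param a,b Sequences ([nt_sequence], [aa_sequence], or character) of the
#'   scheme's alphabet. Both non-empty.
#' @param scheme A [scoring_scheme]; defaults to the mode matching `a`.
#' @param type Alignment type passed through (`"global"` default;
#'   `"global-local"` aligns all of `a` within `b`).
#' @return Object of class `pairwise_alignment`: fields `a_aligned`,
#'   `b_aligned` (equal-length gapped strings), `score`, `scheme`, `type`.
#' @export
global_align <- function(a, b, scheme = NULL, type = "global") {
  if (is.null(scheme)) scheme <- .default_scheme(a)
  ra <- .residues(a); rb <- .residues(b)
  if (!nzchar(ra) || !nzchar(rb)) stop("cannot align empty sequence", call. = FALSE)
  if (scheme$mode == "protein" &&
      (grepl("[^ACGTN]", ra) + grepl("[^ACGTN]", rb)) == 1L) {
    # heuristically flag obvious alphabet mixture
    warning("aligning sequences of apparently different alphabets")
  }
  pa <- Biostrings::pairwiseAlignment(
    .as_xstring(a, scheme$mode), .as_xstring(b, scheme$mode),
    substitutionMatrix = scheme$submat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = type)
  structure(list(
    a_aligned = as.character(Biostrings::alignedPattern(pa)),
    b_aligned = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    scheme = scheme, type = type),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %g (%s)\n",
              nchar(x$a_aligned), x$score, x$scheme$mode))
  invisible(x)
}

.alignment_columns <- function(al) {
  a <- .seq_chars(al$a_aligned); b <- .seq_chars(al$b_aligned)
  if (length(a) != length(b)) stop("ragged alignment", call. = FALSE)
  if (length(a) == 0L) stop("zero-length alignment", call. = FALSE)
  if (any(a == "-" & b == "-")) stop("gap/gap column in alignment", call. = FALSE)
  list(a = a, b = b)
}

#' Percent identity of an alignment
#'
#' `100 * identical columns / aligned columns`; gap columns count in the
#' denominator (end-to-end convention).
#'
#' @param al A [pairwise_alignment].
#' @return Percent in `[0, 100]`.
#' @export
percent_identity <- function(al) {
  cols <- .alignment_columns(al)
  ident <- cols$a == cols$b & cols$a != "-"
  100 * sum(ident) / length(cols$a)
}

#' Percent similarity of a protein alignment
#'
#' `100 * columns with positive substitution score / aligned columns`.
#' Identical residues score positively on the matrix diagonal and therefore
#' count; gap columns never count (but remain in the denominator). For
#' nucleotide alignments "similarity" is not defined and an error is raised
#' (use [percent_identity()]).
#'
#' @param al A [pairwise_alignment] produced with a protein scheme.
#' @return Percent in `[0, 100]`.
#' @export
percent_similarity <- function(al) {
  if (al$scheme$mode != "protein") {
    stop("percent_similarity is defined for protein alignments only",
         call. = FALSE)
  }
  cols <- .alignment_columns(al)
  m <- al$scheme$submat
  ok <- cols$a != "-" & cols$b != "-" &
    cols$a %in% rownames(m) & cols$b %in% colnames(m)
  sim <- logical(length(cols$a))
  sim[ok] <- m[cbind(cols$a[ok], cols$b[ok])] > 0
  100 * sum(sim) / length(cols$a)
}

#' Nucleotide consensus fraction of two sequences
#'
#' The percent of consensus (identical) positions in the global nucleotide
#' alignment of `a` and `b` -- the statistic behind the ">= 80% consensus
#' positions" criterion for out-of-frame candidate loci.
#'
#' @param a,b Nucleotide sequences.
#' @param scheme Optional nucleotide [scoring_scheme].
#' @return Percent in `[0, 100]`.
#' @export
consensus_fraction <- function(a, b, scheme = NULL) {
  if (is.null(scheme)) scheme <- scoring_scheme("nucleotide")
  stopifnot(scheme$mode == "nucleotide")
  percent_identity(global_align(a, b, scheme))
}
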