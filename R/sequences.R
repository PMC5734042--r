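#' @useDynLib orfrescue, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median setNames
#' @importFrom utils read.delim write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "*", "X")

# codon -> amino acid lookup, standard genetic code (table 1)
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Nucleotide sequence
#'
#' A labelled DNA sequence over the alphabet `{A, C, G, T, N}`. Residues are
#' normalized to uppercase; any other character is an error. This is the
#' container used for coding sequences, gene loci with their flanks, and
#' generated ancestors.
#'
#' @param id Label string.
#' @param residues Character scalar of residues (case-insensitive on input).
#' @param description Optional free-text description.
#' @return An object of class `nt_sequence` with fields `id`, `residues`,
#'   `description`.
#' @export
nt_sequence <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop("non-IUPAC nucleotide character(s) in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, residues = residues, description = description),
            class = "nt_sequence")
}

#' Protein sequence
#'
#' A labelled amino-acid sequence over the 20 standard residues plus `*`
#' (stop) and `X` (unknown). When `mature = TRUE` the sequence is asserted to
#' contain no internal stop (a single terminal `*` is tolerated and removed).
#'
#' @param id Label string.
#' @param residues Character scalar of residues.
#' @param mature If `TRUE`, reject internal stops.
#' @return An object of class `aa_sequence`.
#' @export
aa_sequence <- function(id, residues, mature = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid amino-acid character(s) in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (mature) {
    residues <- sub("\\*$", "", residues)
    if (grepl("*", residues, fixed = TRUE)) {
      stop("mature protein '", id, "' contains an internal stop", call. = FALSE)
    }
  }
  structure(list(id = id, residues = residues), class = "aa_sequence")
}

#' @export
print.nt_sequence <- function(x, ...) {
  cat(sprintf("<nt_sequence> %s (%d nt)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' @export
print.aa_sequence <- function(x, ...) {
  cat(sprintf("<aa_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

.seq_chars <- function(x) {
  if (inherits(x, c("nt_sequence", "aa_sequence"))) x <- x$residues
  strsplit(x, "", fixed = TRUE)[[1]]
}

.residues <- function(x) {
  if (inherits(x, c("nt_sequence", "aa_sequence"))) x$residues else x
}

#' Reverse complement
#'
#' @param seq An [nt_sequence] (or plain character scalar).
#' @return Object of the same type; the complement of `N` is `N`.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  plain <- !inherits(seq, "nt_sequence")
  s <- if (plain) nt_sequence("seq", seq) else seq
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s$residues)))
  if (plain) rc else nt_sequence(s$id, rc, s$description)
}

#' Translate a nucleotide sequence
#'
#' Translates from `offset` (0, 1 or 2) using the standard genetic code.
#' Trailing partial codons are dropped; stops render as `*`; codons
#' containing `N` render as `X`.
#'
#' @param dna An [nt_sequence] or character scalar.
#' @param offset Frame offset, 0-2.
#' @return An [aa_sequence] (or character scalar if the input was plain).
#' @examples
#' translate("ATGTAA")  # "M*"
#' @export
translate <- function(dna, offset = 0L) {
  stopifnot(offset %in% 0:2)
  plain <- !inherits(dna, "nt_sequence")
  s <- .residues(dna)
  n <- nchar(s)
  n_codons <- (n - offset) %/% 3L
  if (n_codons <= 0L) {
    out <- ""
  } else {
    starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, starts, starts + 2L)
    aa <- .codon_table[codons]
    aa[is.na(aa)] <- "X"  # any codon containing N (or other ambiguity)
    out <- paste(aa, collapse = "")
  }
  if (plain) out else aa_sequence(paste0(dna$id, "_translation"), out)
}

#' Convert a context position to the locus coordinate convention
#'
#' User-facing locus coordinates are 1-based within the annotated CDS and
#' negative upstream of it, with -1 the base immediately 5' of the A of the
#' start codon (there is no position 0).
#'
#' @param pos Position within the context (1-based).
#' @param cds_start CDS start within the context (1-based).
#' @return Integer locus coordinate.
#' @export
to_locus_coord <- function(pos, cds_start) {
  ifelse(pos >= cds_start, pos - cds_start + 1L, pos - cds_start)
}

#' Inverse of [to_locus_coord()]
#'
#' @param coord Locus coordinate (negative allowed, never 0).
#' @param cds_start CDS start within the context (1-based).
#' @return Integer context position.
#' @export
from_locus_coord <- function(coord, cds_start) {
  if (any(coord == 0L)) stop("locus coordinate 0 does not exist", call. = FALSE)
  ifelse(coord > 0L, coord + cds_start - 1L, coord + cds_start)
}

#' Gene locus
#'
#' A candidate gene region: an annotated CDS interval inside a larger
#' nucleotide context (typically the CDS plus up to 1 kb of flank on each
#' side). Minus-strand loci are normalized to CDS-forward orientation on
#' ingest, so that all downstream coordinates are reported 5'->3' relative
#' to the annotated ORF. The annotated interval is not required to be a
#' multiple of 3 (annotations of broken genes may be broken themselves).
#'
#' @param label Locus label.
#' @param context An [nt_sequence].
#' @param cds_start,cds_end 1-based inclusive CDS bounds within `context`.
#' @param strand `"+"` or `"-"` (orientation of the annotation in `context`
#'   as supplied; stored after normalization as the original strand).
#' @return An object of class `gene_locus`.
#' @export
gene_locus <- function(label, context, cds_start, cds_end, strand = "+") {
  stopifnot(inherits(context, "nt_sequence"), strand %in% c("+", "-"))
  n <- nchar(context$residues)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (!(cds_start >= 1L && cds_start <= cds_end && cds_end <= n)) {
    stop("CDS bounds [", cds_start, ", ", cds_end,
         "] outside context of length ", n, call. = FALSE)
  }
  if (strand == "-") {
    context <- reverse_complement(context)
    new_start <- n - cds_end + 1L
    new_end <- n - cds_start + 1L
    cds_start <- new_start; cds_end <- new_end
  }
  structure(list(label = label, context = context,
                 cds_start = cds_start, cds_end = cds_end,
                 strand = strand),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s: CDS %d..%d (%s) in %d nt context\n",
              x$label, x$cds_start, x$cds_end, x$strand,
              nchar(x$context$residues)))
  invisible(x)
}

#' Annotated CDS of a locus
#'
#' @param locus A [gene_locus].
#' @return [nt_sequence] of the annotated interval (CDS-forward).
#' @export
locus_cds <- function(locus) {
  stopifnot(inherits(locus, "gene_locus"))
  nt_sequence(paste0(locus$label, "_cds"),
              substr(locus$context$residues, locus$cds_start, locus$cds_end))
}

# Translation of the annotated interval up to and including the first stop.
# Returns list(protein = chr, has_terminal_stop = lgl, orf_nt = int).
.annotated_translation <- function(locus) {
  aa <- translate(locus_cds(locus)$residues)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(protein = substr(aa, 1L, stop_at - 1L),
         has_terminal_stop = TRUE,
         orf_nt = 3L * stop_at)
  } else {
    list(protein = aa, has_terminal_stop = FALSE, orf_nt = 3L * nchar(aa))
  }
}
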