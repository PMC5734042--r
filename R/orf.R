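#' Scan a sequence for open reading frames
#'
#' Enumerates ORFs (start codon through stop codon, inclusive) in all three
#' frames of both strands. An ORF begins at an `ATG` (unless
#' `require_atg = FALSE`, in which case it begins at the first codon after
#' the previous stop or at the frame origin), ends at the first in-frame
#' stop codon, contains no internal stop, and must encode at least `min_aa`
#' residues (stop excluded).
#'
#' @param dna [nt_sequence] or character scalar.
#' @param min_aa Minimum number of encoded residues (>= 1).
#' @param require_atg Require an ATG start codon (default `TRUE`).
#' @return A data.frame with columns `start`, `end` (1-based inclusive on the
#'   forward strand), `strand` (`"+"`/`"-"`), `frame` (0-2, offset within the
#'   scanned strand), `aa_length`. Sorted by `start`, then `end`, then strand.
#'   For minus-strand ORFs, `start`/`end` are forward-strand positions of the
#'   interval; the ORF reads from `end` to `start` on the reverse complement.
#' @examples
#' scan_orfs("ATGAAATAA", min_aa = 1)
#' @export
scan_orfs <- function(dna, min_aa = 1L, require_atg = TRUE) {
  stopifnot(min_aa >= 1L)
  s <- .residues(dna)
  n <- nchar(s)
  res <- list()
  for (str in c("+", "-")) {
    seq_str <- if (str == "+") s else reverse_complement(s)
    hits <- .scan_orfs_one_strand(seq_str, min_aa, require_atg)
    if (nrow(hits) > 0L) {
      if (str == "-") {
        # map back to forward-strand coordinates
        new_start <- n - hits$end + 1L
        new_end <- n - hits$start + 1L
        hits$start <- new_start; hits$end <- new_end
      }
      hits$strand <- str
      res[[str]] <- hits
    }
  }
  out <- if (length(res) == 0L) {
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), aa_length = integer())
  } else {
    do.call(rbind, unname(res))
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "strand", "frame", "aa_length")]
}

# single-strand ORF scan; coordinates on the given string
.scan_orfs_one_strand <- function(s, min_aa, require_atg) {
  n <- nchar(s)
  out <- list()
  for (off in 0:2) {
    n_codons <- (n - off) %/% 3L
    if (n_codons < 2L) next
    starts <- off + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    # segment id: index of stops partitions codon run
    stop_idx <- which(is_stop)
    if (length(stop_idx) == 0L) next
    prev_stop <- 0L
    for (si in stop_idx) {
      seg <- (prev_stop + 1L):(si - 1L)
      seg <- seg[seg >= 1L]
      if (length(seg) >= 1L) {
        first <- if (require_atg) {
          w <- which(is_atg[seg]); if (length(w)) seg[w[1L]] else NA_integer_
        } else seg[1L]
        if (!is.na(first)) {
          aa_len <- si - first
          if (aa_len >= min_aa) {
            out[[length(out) + 1L]] <- data.frame(
              start = starts[first], end = starts[si] + 2L,
              frame = off, aa_length = aa_len)
          }
        }
      }
      prev_stop <- si
    }
  }
  if (length(out) == 0L) {
    data.frame(start = integer(), end = integer(), frame = integer(),
               aa_length = integer())
  } else {
    do.call(rbind, out)
  }
}
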