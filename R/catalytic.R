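#' Read a catalytic-site table
#'
#' Two-column TSV: `reference_position` and `expected_residue` (one-letter
#' code), e.g. the aldo-keto reductase tetrad `71 D / 76 Y / 103 K / 152 H`.
#' A header line is optional.
#'
#' @param path TSV path.
#' @return data.frame with columns `reference_position`, `expected_residue`.
#' @export
read_sites_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*\\d", first)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("sites TSV needs two columns", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("reference_position", "expected_residue")
  df$reference_position <- as.integer(df$reference_position)
  df$expected_residue <- toupper(trimws(df$expected_residue))
  df[order(df$reference_position), , drop = FALSE]
}

#' Map catalytic residues from a reference onto a target protein
#'
#' Transfers reference positions through the global protein alignment of
#' reference and target. A reference site aligned to a gap maps to `MISSING`
#' (`NA` target position). A site is conserved when the target residue is
#' identical to the reference residue (or, with
#' `conserved = "similar"`, scores positively against it).
#'
#' @param reference Reference protein ([aa_sequence] or character).
#' @param site_positions Integer positions in the reference (1-based), or a
#'   data.frame from [read_sites_tsv()].
#' @param target Target protein (non-empty).
#' @param conserved `"identical"` (default) or `"similar"`.
#' @param scheme Protein [scoring_scheme].
#' @return data.frame (class `catalytic_site_map`): `reference_position`,
#'   `reference_residue`, `target_position` (NA = MISSING),
#'   `target_residue`, `conserved`.
#' @export
map_catalytic_sites <- function(reference, site_positions, target,
                                conserved = c("identical", "similar"),
                                scheme = scoring_scheme("protein")) {
  conserved <- match.arg(conserved)
  ref <- .ref_protein(reference)
  if (is.data.frame(site_positions)) {
    site_positions <- site_positions$reference_position
  }
  site_positions <- as.integer(site_positions)
  rlen <- nchar(ref$residues)
  if (any(site_positions < 1L | site_positions > rlen)) {
    stop("site position outside reference", call. = FALSE)
  }
  if (is.unsorted(site_positions, strictly = TRUE)) {
    site_positions <- sort(unique(site_positions))
  }
  tgt <- .residues(target)
  if (!nzchar(tgt)) stop("empty target protein", call. = FALSE)

  al <- global_align(ref, target, scheme)
  a <- .seq_chars(al$a_aligned); b <- .seq_chars(al$b_aligned)
  ref_pos <- cumsum(a != "-")
  tgt_pos <- cumsum(b != "-")
  m <- scheme$submat
  rows <- lapply(site_positions, function(p) {
    col <- which(a != "-" & ref_pos == p)[1L]
    rr <- substr(ref$residues, p, p)
    if (b[col] == "-") {
      data.frame(reference_position = p, reference_residue = rr,
                 target_position = NA_integer_, target_residue = NA_character_,
                 conserved = FALSE, stringsAsFactors = FALSE)
    } else {
      tr <- b[col]
      cons <- if (conserved == "identical") identical(rr, tr) else {
        rr %in% rownames(m) && tr %in% colnames(m) && m[rr, tr] > 0
      }
      data.frame(reference_position = p, reference_residue = rr,
                 target_position = tgt_pos[col], target_residue = tr,
                 conserved = cons, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("catalytic_site_map", "data.frame")
  out
}
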