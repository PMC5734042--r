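#' Read a FASTA file of nucleotide sequences
#'
#' Residues are normalized to uppercase. Duplicated ids trigger a warning but
#' all records are kept, in file order. An empty file or a file that does not
#' start with a header line is a format error.
#'
#' @param path Path to a FASTA file.
#' @return List of [nt_sequence] objects.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(lines[[1]], ">")) {
    stop("malformed FASTA (no header on first line): ", path, call. = FALSE)
  }
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  headers <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("malformed FASTA header in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA id(s) in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            "; all records kept", call. = FALSE)
  }
  bodies <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  # records with no sequence lines
  seqs <- character(length(ids))
  seqs[as.integer(names(bodies))] <- bodies
  mapply(function(i, s, d) nt_sequence(i, s, d), ids, seqs, desc,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A list of [nt_sequence]/[aa_sequence] objects (a single
#'   object is accepted).
#' @param path Output path.
#' @param wrap Line width for sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  if (inherits(seqs, c("nt_sequence", "aa_sequence"))) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    hdr <- if (!is.null(s$description) && nzchar(s$description)) {
      paste0(">", s$id, " ", s$description)
    } else paste0(">", s$id)
    writeLines(hdr, con)
    r <- s$residues
    n <- nchar(r)
    if (n == 0L) next
    starts <- seq(1L, n, by = wrap)
    writeLines(substring(r, starts, pmin(starts + wrap - 1L, n)), con)
  }
  invisible(path)
}

#' Read a locus annotation sidecar (TSV)
#'
#' Columns: `label`, `fasta_id`, `cds_start`, `cds_end`, `strand`. Combined
#' with the FASTA of contexts this yields the [gene_locus] objects of a
#' survey.
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_locus_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "fasta_id", "cds_start", "cds_end", "strand")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Assemble gene loci from a FASTA and its annotation table
#'
#' @param seqs List of [nt_sequence] (as from [read_fasta()]).
#' @param annotations data.frame (as from [read_locus_annotations()]).
#' @return Named list of [gene_locus].
#' @export
make_loci <- function(seqs, annotations) {
  ids <- vapply(seqs, function(s) s$id, "")
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    j <- match(a$fasta_id, ids)
    if (is.na(j)) stop("annotation '", a$label, "' refers to missing FASTA id '",
                       a$fasta_id, "'", call. = FALSE)
    gene_locus(a$label, seqs[[j]], a$cds_start, a$cds_end, a$strand)
  })
  names(out) <- annotations$label
  out
}

#' Write the annotation sidecar for a list of loci
#'
#' @param loci Named list of [gene_locus].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_annotations <- function(loci, path) {
  df <- data.frame(
    label = vapply(loci, function(l) l$label, ""),
    fasta_id = vapply(loci, function(l) l$context$id, ""),
    cds_start = vapply(loci, function(l) l$cds_start, 0L),
    cds_end = vapply(loci, function(l) l$cds_end, 0L),
    strand = "+",  # contexts are stored CDS-forward
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
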