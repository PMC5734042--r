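#' Distinct k-mer profile of a sequence
#'
#' The set of distinct forward-strand k-mers; k-mers containing `N` are
#' dropped. The alignment-free tree construction uses k = 15.
#'
#' @param seq [nt_sequence] or character scalar.
#' @param k Word length (>= 1).
#' @param label Profile label (defaults to the sequence id).
#' @return Object of class `kmer_profile`: `label`, `k`, `kmers` (sorted
#'   character vector).
#' @export
kmer_profile <- function(seq, k = 15L, label = NULL) {
  stopifnot(k >= 1L)
  s <- .residues(seq)
  if (is.null(label)) {
    label <- if (inherits(seq, "nt_sequence")) seq$id else "seq"
  }
  n <- nchar(s)
  kmers <- if (n < k) character(0) else {
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    sort(unique(km[!grepl("N", km, fixed = TRUE)]))
  }
  structure(list(label = label, k = as.integer(k), kmers = kmers),
            class = "kmer_profile")
}

#' Fractional-common-k-mer distance between two profiles
#'
#' `d = 1 - |A intersect B| / min(|A|, |B|)` on distinct-k-mer sets -- a
#' standard parameter-free alignment-free dissimilarity. With
#' `method = "jaccard"`, `d = 1 - |A intersect B| / |A union B|`. Both are
#' symmetric with `d(a, a) = 0`; the triangle inequality is not guaranteed.
#'
#' @param a,b [kmer_profile] objects with equal `k`.
#' @param method `"min"` (default) or `"jaccard"`.
#' @return Distance in `[0, 1]`.
#' @export
kmer_distance <- function(a, b, method = c("min", "jaccard")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "kmer_profile"), inherits(b, "kmer_profile"))
  if (a$k != b$k) stop("profiles have different k", call. = FALSE)
  na <- length(a$kmers); nb <- length(b$kmers)
  if (na == 0L && nb == 0L) {
    stop("k-mer distance undefined for two empty profiles", call. = FALSE)
  }
  if (na == 0L || nb == 0L) return(1)
  inter <- length(intersect(a$kmers, b$kmers))
  denom <- if (method == "min") min(na, nb) else (na + nb - inter)
  1 - inter / denom
}

#' Pairwise k-mer distance matrix for a set of sequences
#'
#' @param seqs List of [nt_sequence] (or named character vector).
#' @param k Word length.
#' @param method Distance formula, see [kmer_distance()].
#' @return Labelled symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   with attribute `method`.
#' @export
kmer_distance_matrix <- function(seqs, k = 15L, method = c("min", "jaccard")) {
  method <- match.arg(method)
  if (is.character(seqs)) {
    labs <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
    seqs <- mapply(nt_sequence, labs, seqs, SIMPLIFY = FALSE)
  }
  profs <- lapply(seqs, kmer_profile, k = k)
  labels <- vapply(profs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate sequence labels", call. = FALSE)
  n <- length(profs)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kmer_distance(profs[[i]], profs[[j]], method)
    }
  }
  attr(d, "method") <- method
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via \code{ape::nj}). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with a warning. A 2 x 2 matrix returns the trivial two-leaf tree.
#'
#' @param d Labelled symmetric distance matrix (or `dist`).
#' @return An unrooted `phylo` tree (ape) whose tips are the matrix labels.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (any(d < 0)) stop("negative entries in distance matrix", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write / read Newick
#'
#' Thin wrappers over \code{ape::write.tree} / \code{ape::read.tree};
#' round-trips preserve topology and branch lengths to at least 6 decimals.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly if written to file);
#'   `read_newick`: a `phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' @rdname write_newick
#' @param text Newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- suppressWarnings(
    if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text))
  if (is.null(tr)) stop("malformed Newick input", call. = FALSE)
  tr
}

#' Filter an ortholog hit table
#'
#' Keeps, per species, the top-ranked hit passing both thresholds (the
#' published rule: score >= 60 and length strictly > 150 bp, one
#' representative per species). Species with no passing hit are dropped.
#'
#' @param hits data.frame with columns `species`, `score`, `length`, `rank`.
#' @param min_score Minimum score (inclusive).
#' @param min_length_nt Length threshold (strict: length must exceed it).
#' @param one_per_species Keep only the best-ranked passing hit per species.
#' @return Filtered data.frame in species order of first appearance.
#' @export
filter_hits <- function(hits, min_score = 60, min_length_nt = 150,
                        one_per_species = TRUE) {
  need <- c("species", "score", "length", "rank")
  miss <- setdiff(need, names(hits))
  if (length(miss)) {
    stop("hit table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pass <- hits[hits$score >= min_score & hits$length > min_length_nt, ,
               drop = FALSE]
  if (!one_per_species || nrow(pass) == 0L) {
    rownames(pass) <- NULL
    return(pass)
  }
  pass <- pass[order(match(pass$species, unique(hits$species)), pass$rank), ,
               drop = FALSE]
  pass <- pass[!duplicated(pass$species), , drop = FALSE]
  rownames(pass) <- NULL
  pass
}
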