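# Independent oracles used to check the production code paths. These are
# deliberately naive implementations (quadratic scans, explicit DP) kept
# separate from the package internals.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(setdiff(orfrescue:::AA_ALPHABET, c("*", "X")), n,
               replace = TRUE), collapse = "")
}

.oracle_stops <- c("TAA", "TAG", "TGA")

# every (ATG-start, next in-frame stop) pair on one strand, by walking
# codons from each ATG occurrence independently
oracle_orfs_one_strand <- function(s, min_aa, require_atg) {
  n <- nchar(s)
  out <- list()
  emit <- function(st, stop_pos) {
    aa_len <- (stop_pos - st) %/% 3L
    if (aa_len >= min_aa) {
      out[[length(out) + 1L]] <<- data.frame(
        start = st, end = stop_pos + 2L, frame = (st - 1L) %% 3L,
        aa_length = aa_len)
    }
  }
  if (require_atg) {
    starts <- as.integer(gregexpr("ATG", s, fixed = TRUE)[[1]])
    for (st in starts[starts > 0L]) {
      p <- st
      repeat {
        if (p + 2L > n) break
        if (substr(s, p, p + 2L) %in% .oracle_stops) {
          emit(st, p)
          break
        }
        p <- p + 3L
      }
    }
  } else {
    for (f in 0:2) {
      seg_start <- f + 1L
      p <- f + 1L
      while (p + 2L <= n) {
        if (substr(s, p, p + 2L) %in% .oracle_stops) {
          if (p > seg_start) emit(seg_start, p)
          seg_start <- p + 3L
        }
        p <- p + 3L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      aa_length = integer()))
  }
  do.call(rbind, out)
}

# first-ATG-per-stop-segment convention (the scan_orfs contract): among ORFs
# sharing a stop, keep the 5'-most start
oracle_scan_orfs <- function(s, min_aa = 1L, require_atg = TRUE) {
  n <- nchar(s)
  res <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    hits <- oracle_orfs_one_strand(ss, 1L, require_atg)
    if (nrow(hits) > 0L) {
      hits <- hits[order(hits$end, hits$start), , drop = FALSE]
      hits <- hits[!duplicated(hits[, c("end", "frame")]), , drop = FALSE]
      hits <- hits[hits$aa_length >= min_aa, , drop = FALSE]
      if (strand == "-" && nrow(hits) > 0L) {
        new_start <- n - hits$end + 1L
        new_end <- n - hits$start + 1L
        hits$start <- new_start; hits$end <- new_end
      }
      if (nrow(hits) > 0L) {
        hits$strand <- strand
        res[[strand]] <- hits
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), aa_length = integer()))
  }
  out <- do.call(rbind, unname(res))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "strand", "frame", "aa_length")]
}

# explicit affine-gap Needleman-Wunsch score (end gaps penalized; a
# length-k gap costs open + k * extend), three-matrix DP
oracle_nw_score <- function(a, b, submat, open, extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # last move: match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (A aligned to '-')
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[A[i], B[j]]
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend,
                               X[i, j + 1L] - extend,
                               Y[i, j + 1L] - open - extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend,
                               Y[i + 1L, j] - extend,
                               X[i + 1L, j] - open - extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# brute-force single-edit repair scan over a small locus, independent of the
# compiled kernel: enumerate every edit with string operations, find the
# canonical ORF by explicit enumeration, and apply the same thresholds
oracle_edit_scan <- function(locus, reference, thresholds = repair_thresholds(),
                             window = NULL) {
  ref <- if (inherits(reference, "family_reference")) reference$protein else reference
  ref_len <- nchar(ref$residues)
  band <- thresholds$length_ratio
  min_nt <- 3L * (ceiling(band[1] * ref_len) + 1L)
  target_nt <- 3L * (ref_len + 1L)
  ctx <- locus$context$residues
  n <- nchar(ctx)
  if (is.null(window)) {
    window <- c(max(1L, locus$cds_start - 1000L), min(n, locus$cds_end + 1000L))
  }
  scheme <- scoring_scheme("protein")

  # nothing to repair when the annotated ORF already meets the thresholds
  ann_aa <- orfrescue::translate(substr(ctx, locus$cds_start, locus$cds_end))
  stop_at <- regexpr("*", ann_aa, fixed = TRUE)
  if (stop_at > 0L) {
    ann_prot <- substr(ann_aa, 1L, stop_at - 1L)
    ratio0 <- nchar(ann_prot) / ref_len
    if (startsWith(ann_prot, "M") && ratio0 >= band[1] && ratio0 <= band[2]) {
      sim0 <- orfrescue:::.protein_align_stats(ann_prot, ref$residues,
                                               scheme)$aa_similarity
      if (sim0 >= thresholds$aa_similarity) return(NULL)
    }
  }

  canonical_orf <- function(s, lo, hi) {
    orfs <- oracle_orfs_one_strand(s, 1L, TRUE)
    if (nrow(orfs) == 0L) return(NULL)
    len <- orfs$end - orfs$start + 1L
    ok <- len >= min_nt & orfs$start <= hi & orfs$end >= lo
    if (!any(ok)) return(NULL)
    orfs <- orfs[ok, , drop = FALSE]
    len <- len[ok]
    dev <- abs(len - target_nt)
    orfs[order(dev, -len, orfs$start), , drop = FALSE][1L, ]
  }

  rows <- list()
  add <- function(kind, pos, alt, edited, lo, hi) {
    orf <- canonical_orf(edited, lo, hi)
    if (is.null(orf)) return()
    prot <- sub("\\*$", "", orfrescue::translate(
      substr(edited, orf$start, orf$end)))
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, pos = pos, alt = alt,
      orf_start = orf$start, orf_end = orf$end, protein = prot,
      stringsAsFactors = FALSE)
  }
  cs <- locus$cds_start; ce <- locus$cds_end
  for (p in window[1]:window[2]) {
    refb <- substr(ctx, p, p)
    for (b in setdiff(c("A", "C", "G", "T"), refb)) {
      add("substitution", p, b,
          paste0(substr(ctx, 1, p - 1L), b, substr(ctx, p + 1L, n)), cs, ce)
    }
  }
  for (j in (window[1] - 1L):window[2]) {
    lo <- cs + (j < cs); hi <- ce + (j < ce)
    for (b in c("A", "C", "G", "T")) {
      add("insertion", j, b,
          paste0(substr(ctx, 1, j), b, substr(ctx, j + 1L, n)), lo, hi)
    }
  }
  for (p in window[1]:window[2]) {
    lo <- cs - (p < cs); hi <- max(ce - (p <= ce), cs - (p < cs))
    add("deletion", p, "",
        paste0(substr(ctx, 1, p - 1L), substr(ctx, p + 1L, n)), lo, hi)
  }
  if (length(rows) == 0L) return(NULL)
  df <- do.call(rbind, rows)

  # left-align indels, dedupe, apply thresholds
  chars <- strsplit(ctx, "")[[1]]
  for (i in which(df$kind == "insertion")) {
    while (df$pos[i] >= 1L && chars[df$pos[i]] == df$alt[i]) {
      df$pos[i] <- df$pos[i] - 1L
    }
  }
  for (i in which(df$kind == "deletion")) {
    while (df$pos[i] > 1L && chars[df$pos[i] - 1L] == chars[df$pos[i]]) {
      df$pos[i] <- df$pos[i] - 1L
    }
  }
  df <- df[!duplicated(df[, c("kind", "pos", "alt")]), , drop = FALSE]
  st <- orfrescue:::.protein_align_stats(df$protein, ref$residues, scheme)
  ratio <- nchar(df$protein) / ref_len
  keep <- st$aa_similarity >= thresholds$aa_similarity &
    ratio >= band[1] & ratio <= band[2]
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# a small test family: short ancestor, narrow flanks -- cheap enough for the
# brute-force oracle
small_family_locus <- function(seed, lesion = c("del", "sub", "none"),
                               n_codons = 70L, flank = 10L) {
  lesion <- match.arg(lesion)
  set.seed(seed)
  anc <- generate_ancestor(n_codons = n_codons, gc_target = 0.45,
                           seed = seed)
  s <- anc$residues
  if (lesion == "del") {
    pos <- 3L * (n_codons %/% 2L)   # mid-CDS base
    body <- paste0(substr(s, 1, pos - 1L), substr(s, pos + 1L, nchar(s)))
  } else if (lesion == "sub") {
    # plant a premature stop at a codon that is one substitution from TAG
    body <- s
    planted <- FALSE
    for (cod in 10:(n_codons - 10L)) {
      i <- 3L * (cod - 1L) + 1L
      codon <- substr(s, i, i + 2L)
      if (substr(codon, 1, 1) == "T" && substr(codon, 3, 3) == "G" &&
          !(codon %in% c("TAG", "TAA", "TGA"))) {
        body <- paste0(substr(s, 1, i), "A", substr(s, i + 2L, nchar(s)))
        planted <- TRUE
        break
      }
    }
    if (!planted) return(NULL)
  } else {
    body <- s
  }
  ctx <- paste0(rand_dna(flank), body, rand_dna(flank))
  ref <- aa_sequence("ref", sub("\\*$", "", orfrescue::translate(s)),
                     mature = TRUE)
  # annotate ATG through first stop
  aa <- orfrescue::translate(substr(ctx, flank + 1L, nchar(ctx)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  cds_end <- if (stop_at > 0L) flank + 3L * stop_at else flank + nchar(body)
  locus <- gene_locus("small", nt_sequence("small", ctx), flank + 1L,
                      min(cds_end, nchar(ctx)), "+")
  list(locus = locus, reference = ref, ancestor = anc)
}
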