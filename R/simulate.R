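# RNG isolation: generators are deterministic per seed and leave the global
# RNG stream untouched.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

.STOPS <- c("TAA", "TAG", "TGA")

.random_bases <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Default scaffold codons for the synthetic family ancestor
#'
#' Fixed codons that give the synthetic ancestor the anatomy the lesion
#' catalog needs: an aldo-keto-reductase-style catalytic tetrad
#' (Asp71, Tyr76, Lys103, His152), a Trp codon at 77 (the plantable
#' nonsense site: TGG is one substitution from TAG), an internal in-frame
#' Met at codon 89 (the re-annotatable downstream start, 264 nt into the
#' gene) and an AGC at codon 173 (nt 517-519, the plantable frameshift
#' site with its G at CDS position 518).
#'
#' @return Named character vector: names are codon indices.
#' @export
family_scaffold_codons <- function() {
  c("71" = "GAC", "76" = "TAC", "103" = "AAG", "152" = "CAC",
    "77" = "TGG", "89" = "ATG", "173" = "AGC")
}

#' Generate a random ancestral coding sequence
#'
#' A valid CDS: starts with ATG, ends with a stop codon, contains no
#' internal stop, with realized GC content within 5 percentage points of the
#' target. Deterministic per seed.
#'
#' @param n_codons Number of codons including start and stop (>= 50).
#' @param gc_target Target GC fraction.
#' @param seed Integer seed (`NULL` = use current RNG state).
#' @param forced_codons Optional named codon map (names = codon indices) to
#'   stamp onto the sequence, e.g. [family_scaffold_codons()].
#' @return [nt_sequence] of length `3 * n_codons`.
#' @export
generate_ancestor <- function(n_codons = 330L, gc_target = 0.40, seed = NULL,
                              forced_codons = NULL) {
  stopifnot(n_codons >= 50L)
  .with_seed(seed, {
    for (try in 1:50) {
      body <- .random_bases(3L * (n_codons - 2L), gc_target)
      # scrub internal stops
      repeat {
        starts <- 3L * (seq_len(n_codons - 2L) - 1L) + 1L
        codons <- substring(body, starts, starts + 2L)
        bad <- which(codons %in% .STOPS)
        if (length(bad) == 0L) break
        for (b in bad) {
          codons[b] <- .random_nonstop_codon(gc_target)
        }
        body <- paste(codons, collapse = "")
      }
      s <- paste0("ATG", body, sample(.STOPS, 1L))
      if (!is.null(forced_codons)) {
        ch <- .seq_chars(s)
        for (idx in names(forced_codons)) {
          i <- as.integer(idx)
          if (i < 1L || i > n_codons) stop("forced codon outside CDS")
          ch[(3L * (i - 1L) + 1L):(3L * i)] <-
            .seq_chars(forced_codons[[idx]])
        }
        s <- paste(ch, collapse = "")
      }
      gc <- mean(.seq_chars(s) %in% c("G", "C"))
      if (abs(gc - gc_target) <= 0.05) {
        return(nt_sequence("ancestor", s,
                           sprintf("synthetic ancestor, %d codons, GC %.3f",
                                   n_codons, gc)))
      }
    }
    stop("could not achieve target GC ", gc_target, call. = FALSE)
  })
}

.random_nonstop_codon <- function(gc = 0.5) {
  repeat {
    c3 <- .random_bases(3L, gc)
    if (!(c3 %in% .STOPS) && c3 != "ATG") return(c3)
  }
}

#' Describe a lesion to plant in one family copy
#'
#' Lesion kinds mirror the pseudogenization catalog of the yeast AAD family:
#' \describe{
#'   \item{none}{intact copy.}
#'   \item{frameshift_del / frameshift_ins}{single-base indel inside the CDS
#'     (default: the G at CDS position 518, splitting the ORF).}
#'   \item{nonsense_sub}{premature stop inside the CDS (default: Trp codon
#'     77, TGG -> TAG).}
#'   \item{catalytic_missense}{missense at a catalytic-tetrad site (default:
#'     Tyr76 -> Cys via A -> G at the codon's middle base; combined with a
#'     3-codon N-terminal trim so the site sits at target position 73 and
#'     CDS position 218, as in the real paralog).}
#'   \item{upstream_nonsense}{the nonsense lesion falls 5' of the annotated
#'     start: with `reannotate = TRUE` the locus is re-annotated to the
#'     internal Met at codon 89 so the stop sits at upstream position -35
#'     and repair regains a 264-nt / 88-aa N-terminal extension; with
#'     `reannotate = FALSE` the annotated ORF stays full length and a short
#'     synthetic upstream extension carries the lesion (an active gene with
#'     an upstream scar).}
#'   \item{five_prime_deletion}{the 5' `fraction` of the CDS is removed from
#'     the genome.}
#' }
#'
#' @param kind Lesion kind.
#' @param position CDS coordinate for indel/nonsense lesions; `NULL` =
#'   scaffold default; `"random"` = uniform within the CDS interior.
#' @param fraction Fraction of the CDS removed by `five_prime_deletion`.
#' @param offset_codons N-terminal trim for `catalytic_missense`.
#' @param ext_codons,stop_codon_upstream,reannotate `upstream_nonsense`
#'   geometry: extension length (codons), upstream codon index of the
#'   planted stop, and whether the locus is re-annotated to the downstream
#'   start.
#' @return Object of class `lesion_spec`.
#' @export
lesion_spec <- function(kind = c("none", "frameshift_del", "frameshift_ins",
                                 "nonsense_sub", "catalytic_missense",
                                 "upstream_nonsense", "five_prime_deletion"),
                        position = NULL, fraction = 0.6, offset_codons = 3L,
                        ext_codons = 88L, stop_codon_upstream = 12L,
                        reannotate = TRUE) {
  kind <- match.arg(kind)
  stopifnot(fraction > 0, fraction < 1)
  structure(list(kind = kind, position = position, fraction = fraction,
                 offset_codons = as.integer(offset_codons),
                 ext_codons = as.integer(ext_codons),
                 stop_codon_upstream = as.integer(stop_codon_upstream),
                 reannotate = isTRUE(reannotate)),
            class = "lesion_spec")
}

#' The seven-copy lesion catalog of the motivating family
#'
#' Two intact copies, a catalytic missense, a frameshift deletion splitting
#' the ORF, an upstream nonsense with re-annotated start, a 5' deletion, and
#' an intact copy carrying an upstream scar.
#'
#' @return Named list of [lesion_spec].
#' @export
paper_family_lesions <- function() {
  list(
    copy1_intact = lesion_spec("none"),
    copy2_intact = lesion_spec("none"),
    copy3_catalytic = lesion_spec("catalytic_missense"),
    copy4_frameshift = lesion_spec("frameshift_del"),
    copy5_upstream_stop = lesion_spec("upstream_nonsense", reannotate = TRUE),
    copy6_deleted5p = lesion_spec("five_prime_deletion"),
    copy7_upstream_scar = lesion_spec("upstream_nonsense", reannotate = FALSE,
                                      ext_codons = 15L,
                                      stop_codon_upstream = 4L))
}

# neutral divergence with protected positions and internal-stop rejection
.diverge_cds <- function(cds, rate, protect_codons) {
  ch <- .seq_chars(cds)
  n <- length(ch)
  protect <- rep(FALSE, n)
  for (i in protect_codons) protect[(3L * (i - 1L) + 1L):(3L * i)] <- TRUE
  protect[1:3] <- TRUE
  protect[(n - 2L):n] <- TRUE
  if (rate > 0) {
    hit <- which(stats::runif(n) < rate & !protect)
    for (p in hit) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    # reject substitutions that created internal in-frame stops
    repeat {
      s <- paste(ch, collapse = "")
      aa <- translate(s)
      stops <- which(.seq_chars(aa) == "*")
      stops <- stops[stops < nchar(aa)]
      if (length(stops) == 0L) break
      orig <- .seq_chars(cds)
      for (cs in stops) {
        idx <- (3L * (cs - 1L) + 1L):(3L * cs)
        ch[idx] <- orig[idx]
      }
    }
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic gene family with planted lesions
#'
#' Each copy is the ancestor after neutral substitutions at
#' `divergence_sub_rate` (uniform random, never creating an internal stop;
#' scaffold and catalytic codons protected so planted lesions stay
#' unambiguous), with at most one planted lesion, embedded in i.i.d. random
#' flanks. The returned truth table records, for every copy, the planted
#' lesion and the classification and repair the pipeline is expected to
#' recover; indel coordinates are left-aligned (5'-most equivalent edit).
#'
#' @param ancestor [nt_sequence] CDS, or `NULL` to generate one with
#'   [family_scaffold_codons()] (330 codons, GC 0.40).
#' @param lesions Named list of [lesion_spec] (one per copy); default
#'   [paper_family_lesions()].
#' @param divergence_sub_rate Per-base neutral substitution rate in
#'   `[0, 0.2]`.
#' @param flank_nt Flank length on each side.
#' @param seed Integer seed.
#' @param catalytic_sites Reference positions of the catalytic tetrad.
#' @return List: `loci` (named [gene_locus] list), `truth` (data.frame),
#'   `ancestor` ([nt_sequence]), `reference` ([family_reference] built from
#'   the ancestor).
#' @export
generate_family <- function(ancestor = NULL,
                            lesions = paper_family_lesions(),
                            divergence_sub_rate = 0.05,
                            flank_nt = 1000L, seed = NULL,
                            catalytic_sites = c(71L, 76L, 103L, 152L)) {
  stopifnot(divergence_sub_rate >= 0, divergence_sub_rate <= 0.2)
  .with_seed(seed, {
    if (is.null(ancestor)) {
      ancestor <- generate_ancestor(forced_codons = family_scaffold_codons())
    }
    stopifnot(inherits(ancestor, "nt_sequence"))
    anc <- ancestor$residues
    n_codons <- nchar(anc) %/% 3L
    if (nchar(anc) %% 3L != 0L) stop("ancestor is not a whole-codon CDS")
    if (is.null(names(lesions))) {
      names(lesions) <- paste0("copy", seq_along(lesions))
    }
    protect <- sort(unique(c(catalytic_sites,
                             as.integer(names(family_scaffold_codons())))))

    loci <- list()
    truth <- list()
    for (lab in names(lesions)) {
      sp <- lesions[[lab]]
      div <- .diverge_cds(anc, divergence_sub_rate, protect)
      made <- .plant_lesion(div, sp, n_codons, flank_nt, lab)
      loci[[lab]] <- made$locus
      truth[[lab]] <- made$truth
    }
    ref_prot <- aa_sequence("ancestor_protein",
                            sub("\\*$", "", translate(anc)), mature = TRUE)
    sites_df <- data.frame(
      reference_position = catalytic_sites,
      expected_residue = vapply(catalytic_sites, function(p)
        substr(ref_prot$residues, p, p), ""),
      stringsAsFactors = FALSE)
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(loci = loci, truth = truth, ancestor = ancestor,
         reference = family_reference(ref_prot, cds = ancestor,
                                      sites = sites_df))
  })
}

# build one lesioned locus + its truth row; div = diverged CDS string
.plant_lesion <- function(div, sp, n_codons, flank_nt, lab) {
  flank5 <- .random_bases(flank_nt)
  flank3 <- .random_bases(flank_nt)
  L <- nchar(div)
  tr <- list(label = lab, lesion_kind = sp$kind,
             lesion_position = NA_integer_, lesion_ref = NA_character_,
             lesion_alt = NA_character_, expected_status = NA_character_,
             expected_repair_kind = NA_character_,
             expected_repair_position = NA_integer_,
             expected_repair_alt = NA_character_,
             has_upstream_repair = FALSE)
  body <- div
  upstream_extra <- ""   # in-frame sequence placed between flank5 and CDS
  cds_len <- L

  pick_pos <- function(default) {
    if (is.null(sp$position)) default
    else if (identical(sp$position, "random")) {
      3L * sample(20:(n_codons - 20L), 1L)  # a codon-2 position, interior
    } else as.integer(sp$position)
  }

  if (sp$kind == "none") {
    tr$expected_status <- "intact"

  } else if (sp$kind == "frameshift_del") {
    pos <- pick_pos(518L)
    base <- substr(div, pos, pos)
    body <- .apply_edit_string(div, "deletion", pos, "")
    tr$lesion_position <- pos; tr$lesion_ref <- base
    tr$expected_status <- "frameshift_split"
    tr$expected_repair_kind <- "insertion"
    # left-aligned junction of the restoring insertion
    j <- pos - 1L
    while (j >= 1L && substr(body, j, j) == base) j <- j - 1L
    tr$expected_repair_position <- j
    tr$expected_repair_alt <- base
    cds_len <- nchar(body)

  } else if (sp$kind == "frameshift_ins") {
    pos <- pick_pos(517L)
    ins <- setdiff(c("A", "C", "G", "T"),
                   c(substr(div, pos, pos), substr(div, pos + 1L, pos + 1L)))[1L]
    body <- .apply_edit_string(div, "insertion", pos, ins)
    tr$lesion_position <- pos; tr$lesion_alt <- ins
    tr$expected_status <- "frameshift_split"
    tr$expected_repair_kind <- "deletion"
    p <- pos + 1L   # the inserted base, left-aligned
    while (p > 1L && substr(body, p - 1L, p - 1L) == ins) p <- p - 1L
    tr$expected_repair_position <- p
    tr$expected_repair_alt <- ""
    cds_len <- nchar(body)

  } else if (sp$kind == "nonsense_sub" ||
             (sp$kind == "upstream_nonsense" && sp$reannotate)) {
    # plant TGG -> TAG at the scaffold Trp codon (or a random stoppable site)
    pos <- if (sp$kind == "nonsense_sub") pick_pos(230L) else 230L
    ref_b <- substr(div, pos, pos)
    body <- .apply_edit_string(div, "substitution", pos, "A")
    cod <- (pos - 1L) %/% 3L + 1L
    codon <- substr(body, 3L * (cod - 1L) + 1L, 3L * cod)
    if (!(codon %in% .STOPS)) {
      stop("nonsense lesion at ", pos, " did not create a stop (codon ",
           codon, "); use a scaffold position", call. = FALSE)
    }
    tr$lesion_position <- pos; tr$lesion_ref <- ref_b; tr$lesion_alt <- "A"
    tr$expected_status <- "nonsense_truncated"
    tr$expected_repair_kind <- "substitution"
    tr$expected_repair_alt <- ref_b

  } else if (sp$kind == "upstream_nonsense" && !sp$reannotate) {
    # intact annotated ORF plus a short upstream in-frame extension carrying
    # a premature stop: ATG, then random non-stop codons, stop planted at
    # upstream codon index stop_codon_upstream
    ext <- c("ATG", replicate(sp$ext_codons - 1L, .random_nonstop_codon()))
    je <- sp$ext_codons - sp$stop_codon_upstream + 1L
    stopifnot(je > 1L, je <= sp$ext_codons)
    ext[je] <- "TAG"
    upstream_extra <- paste(ext, collapse = "")
    tr$lesion_position <- -3L * sp$stop_codon_upstream
    tr$lesion_alt <- "A"   # the stop's middle base relative to a TGG ancestor
    tr$expected_status <- "intact"
    tr$has_upstream_repair <- TRUE

  } else if (sp$kind == "catalytic_missense") {
    off <- sp$offset_codons
    body <- paste0(substr(div, 1L, 3L),
                   substr(div, 3L * (1L + off) + 1L, L))
    pos <- 3L * (76L - off - 1L) + 2L    # middle base of the shifted Tyr codon
    ref_b <- substr(body, pos, pos)
    body <- .apply_edit_string(body, "substitution", pos, "G")
    tr$lesion_position <- pos; tr$lesion_ref <- ref_b; tr$lesion_alt <- "G"
    tr$expected_status <- "missense_catalytic"
    cds_len <- nchar(body)

  } else if (sp$kind == "five_prime_deletion") {
    k <- ceiling(sp$fraction * n_codons)
    body <- substr(div, 3L * k + 1L, L)
    tr$lesion_position <- 1L
    tr$expected_status <- "partial_deletion"
    cds_len <- nchar(body)
  }

  # assemble context and annotation
  if (sp$kind == "upstream_nonsense" && sp$reannotate) {
    # re-annotated start: internal Met at codon 89, 264 nt into the gene
    new_start_nt <- 3L * sp$ext_codons + 1L       # 265 with the default 88
    ctx <- paste0(flank5, body, flank3)
    cds_start <- flank_nt + new_start_nt
    cds_end <- flank_nt + nchar(body)
    tr$lesion_position <- tr$lesion_position - (new_start_nt)  # 230-265 = -35
    tr$expected_repair_position <- tr$lesion_position
  } else {
    ctx <- paste0(flank5, upstream_extra, body, flank3)
    cds_start <- flank_nt + nchar(upstream_extra) + 1L
    if (sp$kind %in% c("frameshift_del", "frameshift_ins", "nonsense_sub")) {
      # annotation reflects the broken gene: ATG through the first stop
      tail_seq <- paste0(body, flank3)
      aa <- translate(tail_seq)
      stop_at <- regexpr("*", aa, fixed = TRUE)
      cds_end <- if (stop_at > 0L) cds_start + 3L * stop_at - 1L
    else cds_start + cds_len - 1L
      if (sp$kind == "nonsense_sub") {
        tr$expected_repair_position <- tr$lesion_position
      }
    } else {
      cds_end <- cds_start + cds_len - 1L
    }
  }
  locus <- gene_locus(lab, nt_sequence(lab, ctx,
                                       paste0("synthetic locus, lesion=",
                                              sp$kind)),
                      cds_start, cds_end, "+")
  list(locus = locus, truth = as.data.frame(tr, stringsAsFactors = FALSE))
}

#' Design of a synthetic saturation-kinetics experiment
#'
#' Default design: 8 log-spaced substrate concentrations from 0.1 x Km to
#' 10 x Km, triplicate measurements, 5% multiplicative Gaussian noise.
#'
#' @param km,vmax True parameters (uM; umol min^-1 mg^-1).
#' @param concentrations Optional explicit concentration grid (uM).
#' @param replicates Replicates per concentration.
#' @param noise `"multiplicative"` (`rate = truth * (1 + eps)`,
#'   `eps ~ N(0, cv)`) or `"additive"` (`rate = truth + N(0, sd)`).
#' @param cv,sd Noise magnitudes.
#' @param seed Integer seed.
#' @return Object of class `mm_design`.
#' @export
mm_design <- function(km, vmax, concentrations = NULL, replicates = 3L,
                      noise = c("multiplicative", "additive"),
                      cv = 0.05, sd = 0, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(km > 0, vmax > 0, cv >= 0, sd >= 0)
  if (is.null(concentrations)) {
    concentrations <- exp(seq(log(0.1 * km), log(10 * km), length.out = 8L))
  }
  stopifnot(all(concentrations > 0))
  structure(list(km = km, vmax = vmax, concentrations = concentrations,
                 replicates = as.integer(replicates), noise = noise,
                 cv = cv, sd = sd, seed = seed),
            class = "mm_design")
}

#' Generate a noisy Michaelis-Menten dataset
#'
#' Rates are drawn around `v = Vmax * S / (Km + S)` under the design's noise
#' model; negative draws (possible under additive noise) are resampled.
#' Deterministic per seed.
#'
#' @param design An [mm_design].
#' @param substrate Substrate label.
#' @return A [rate_dataset].
#' @export
generate_mm_dataset <- function(design, substrate = "substrate") {
  stopifnot(inherits(design, "mm_design"))
  .with_seed(design$seed, {
    S <- rep(design$concentrations, each = design$replicates)
    truth <- design$vmax * S / (design$km + S)
    noisy <- function(mu) {
      if (design$noise == "multiplicative") {
        mu * (1 + stats::rnorm(length(mu), 0, design$cv))
      } else {
        mu + stats::rnorm(length(mu), 0, design$sd)
      }
    }
    v <- noisy(truth)
    bad <- which(v < 0)
    tries <- 0L
    while (length(bad) > 0L && tries < 100L) {
      v[bad] <- noisy(truth[bad])
      bad <- which(v < 0)
      tries <- tries + 1L
    }
    if (length(bad) > 0L) v[bad] <- 0
    rate_dataset(substrate, S, v)
  })
}
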