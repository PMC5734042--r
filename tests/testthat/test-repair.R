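test_that("an intact locus yields no repair proposals", {
  fx <- small_family_locus(seed = 101, lesion = "none")
  pr <- scan_single_edit_repairs(fx$locus, fx$reference)
  expect_equal(nrow(pr), 0L)
})

test_that("single-edit scan equals the brute-force oracle on small contexts", {
  for (cfg in list(list(seed = 102, lesion = "del"),
                   list(seed = 103, lesion = "sub"),
                   list(seed = 104, lesion = "del"),
                   list(seed = 105, lesion = "none"))) {
    fx <- small_family_locus(seed = cfg$seed, lesion = cfg$lesion)
    if (is.null(fx)) next
    expect_lte(nchar(fx$locus$context$residues), 230)
    got <- scan_single_edit_repairs(fx$locus, fx$reference)
    want <- oracle_edit_scan(fx$locus, fx$reference)
    got_keys <- if (nrow(got)) {
      as.data.frame(got)[order(got$edit_kind, got$context_pos, got$alt_base),
                         c("edit_kind", "context_pos", "alt_base",
                           "orf_start", "orf_end", "protein")]
    } else NULL
    want_keys <- if (!is.null(want) && nrow(want)) {
      names(want)[names(want) == "kind"] <- "edit_kind"
      names(want)[names(want) == "pos"] <- "context_pos"
      names(want)[names(want) == "alt"] <- "alt_base"
      want[order(want$edit_kind, want$context_pos, want$alt_base), ]
    } else NULL
    if (is.null(want_keys)) {
      expect_null(got_keys, info = paste("cfg", cfg$seed))
    } else {
      rownames(got_keys) <- rownames(want_keys) <- NULL
      expect_equal(got_keys, want_keys[, names(got_keys)],
                   info = paste("cfg", cfg$seed))
    }
  }
})

test_that("deleting one base from an ancestor is repaired by the exact insertion", {
  fx <- small_family_locus(seed = 106, lesion = "del")
  pr <- scan_single_edit_repairs(fx$locus, fx$reference)
  expect_gt(nrow(pr), 0L)
  top <- pr[1L, ]
  expect_equal(top$edit_kind, "insertion")
  expect_equal(top$protein, fx$reference$residues)
  expect_equal(top$aa_identity, 100)
  fix <- apply_repair(fx$locus, top)
  expect_equal(fix$protein$residues, fx$reference$residues)
})

test_that("the split-ORF fixture is fused by a G insertion at junction 517/518", {
  fam <- generate_family(seed = 9)
  loc <- fam$loci$copy4_frameshift
  # the annotated (broken) ORF stops well short of the reference
  ann <- orfrescue:::.annotated_translation(loc)
  expect_lt(nchar(ann$protein) / nchar(fam$reference$protein$residues), 0.9)
  pr <- scan_single_edit_repairs(loc, fam$reference)
  top <- pr[1L, ]
  expect_equal(top$edit_kind, "insertion")
  expect_equal(top$position, 517L)       # between CDS positions 517 and 518
  expect_equal(top$alt_base, "G")
  # the fused ORF is reference-length and family-similar (>80%)
  expect_equal(top$length_ratio, 1, tolerance = 1e-9)
  expect_gt(top$aa_similarity, 80)
})

test_that("upstream stop-repair recovers the -35 substitution and 264-nt extension", {
  fam <- generate_family(seed = 10)
  loc <- fam$loci$copy5_upstream_stop
  up <- scan_upstream_stop_repairs(loc, fam$reference)
  expect_gt(nrow(up), 0L)
  top <- up[1L, ]
  expect_equal(top$position, -35L)
  expect_equal(top$extension_nt, 264L)
  expect_equal(top$extension_aa, 88L)
  # repairing extends the annotated translation by the 88 lost residues
  ann <- orfrescue:::.annotated_translation(loc)
  fix <- apply_repair(loc, top)
  expect_equal(nchar(fix$protein$residues) - nchar(ann$protein), 88L)
  # a locus with no upstream in-frame stop reports nothing
  clean <- small_family_locus(seed = 107, lesion = "none", flank = 30L)
  ctxc <- clean$locus$context$residues
  # force a stop-free upstream frame by rewriting the flank
  ctx2 <- paste0(strrep("CAC", 10), substr(ctxc, 31, nchar(ctxc)))
  loc2 <- gene_locus("clean", nt_sequence("clean", ctx2),
                     clean$locus$cds_start, clean$locus$cds_end, "+")
  expect_equal(nrow(scan_upstream_stop_repairs(loc2, clean$reference)), 0L)
})

test_that("planted nonsense lesions are recovered exactly across seeds", {
  hits <- 0L; total <- 0L
  for (seed in 201:215) {
    fx <- small_family_locus(seed = seed, lesion = "sub")
    if (is.null(fx)) next
    total <- total + 1L
    pr <- scan_single_edit_repairs(fx$locus, fx$reference)
    if (nrow(pr) > 0L && pr$edit_kind[1] == "substitution" &&
        pr$protein[1] == fx$reference$residues) {
      hits <- hits + 1L
    }
  }
  expect_gte(total, 10L)
  expect_equal(hits, total)   # every planted stop is reversed exactly
})

test_that("raising the similarity threshold never adds proposals", {
  fx <- small_family_locus(seed = 108, lesion = "del")
  lo <- scan_single_edit_repairs(fx$locus, fx$reference,
                                 thresholds = repair_thresholds(aa_similarity = 60))
  hi <- scan_single_edit_repairs(fx$locus, fx$reference,
                                 thresholds = repair_thresholds(aa_similarity = 95))
  key <- function(df) paste(df$edit_kind, df$context_pos, df$alt_base)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("reconstructed proteins are mature ORFs and repair is idempotent", {
  for (seed in c(301, 302, 303)) {
    fx <- small_family_locus(seed = seed, lesion = "del")
    pr <- scan_single_edit_repairs(fx$locus, fx$reference)
    expect_gt(nrow(pr), 0L)
    for (i in seq_len(min(nrow(pr), 5L))) {
      expect_false(grepl("*", pr$protein[i], fixed = TRUE))
      expect_true(startsWith(pr$protein[i], "M"))
    }
    fix <- apply_repair(fx$locus, pr[1L, ])
    # re-scan after applying the repair: nothing left to fix
    n2 <- nchar(fix$cds$residues)
    loc2 <- gene_locus("fixed", fix$cds, 1L, n2, "+")
    expect_equal(nrow(scan_single_edit_repairs(loc2, fx$reference)), 0L)
  }
})

test_that("apply_repair validates the proposal against the locus", {
  fx <- small_family_locus(seed = 109, lesion = "del")
  pr <- scan_single_edit_repairs(fx$locus, fx$reference)
  bad <- pr[1L, ]
  bad$ref_base <- "N"; bad$edit_kind <- "substitution"
  expect_error(apply_repair(fx$locus, bad), "mismatch")
  same <- apply_repair(fx$locus, NULL)
  expect_equal(same$cds$residues, locus_cds(fx$locus)$residues)
})
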