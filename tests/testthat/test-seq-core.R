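test_that("reverse complement is correct and involutive", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement(""), "")
  # the two strands of a mutagenesis primer pair are exact reverse complements
  f2c <- "AGTTTACACATTCTAGTGCAGCAGGGCAAGGTCCTCTATTTGGGTGTGTCT"
  r1b <- "AGACACACCCAAATAGAGGACCTTGCCCTGCTGCACTAGAATGTGTAAACT"
  expect_equal(reverse_complement(f2c), r1b)
  expect_equal(reverse_complement("NACGT"), "ACGTN")
  set.seed(11)
  for (i in 1:40) {
    s <- rand_dna(sample(0:120, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  s <- nt_sequence("x", "acgt")
  expect_equal(s$residues, "ACGT")        # uppercase normalization
  expect_error(nt_sequence("x", "ACGU"), "non-IUPAC")
})

test_that("translation follows the standard genetic code", {
  expect_equal(translate("ATGTAA"), "M*")
  # the codon pair behind the catalytic-site missense: TAC = Tyr, TGC = Cys
  expect_equal(translate("TAC"), "Y")
  expect_equal(translate("TGC"), "C")
  expect_equal(translate("ATGAAA", 0), "MK")
  expect_equal(translate("CATGAAA", 1), "MK")   # offset frames
  expect_equal(translate("ATGAA"), "M")          # trailing partial dropped
  expect_equal(translate("ATGANA"), "MX")        # N codon -> X
  # a 264-nt in-frame segment encodes 88 residues
  set.seed(3)
  seg <- paste(replicate(88, orfrescue:::.random_nonstop_codon()),
               collapse = "")
  expect_equal(nchar(seg), 264)
  expect_equal(nchar(translate(seg)), 88)
  expect_false(grepl("*", translate(seg), fixed = TRUE))
  # translation never errors on a sequence plus its reverse complement and
  # stays inside the protein alphabet
  for (i in 1:10) {
    s <- rand_dna(sample(3:90, 1))
    out <- translate(paste0(s, reverse_complement(s)))
    expect_true(all(strsplit(out, "")[[1]] %in% orfrescue:::AA_ALPHABET))
  }
})

test_that("ORF scanning matches a brute-force six-frame enumeration", {
  one <- scan_orfs("ATGAAATAA", min_aa = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 1L)
  expect_equal(one$end, 9L)
  expect_equal(one$aa_length, 2L)   # encodes "MK" before the stop
  expect_equal(translate(substr("ATGAAATAA", one$start, one$end)), "MK*")

  # an internal TAG splits one ATG...TAA run into two ORFs
  split_seq <- "ATGAAACCCTAGATGAAATAA"
  hits <- scan_orfs(split_seq, min_aa = 1)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 2L)

  expect_equal(nrow(scan_orfs(strrep("C", 120))), 0L)

  set.seed(7)
  for (i in 1:25) {
    s <- rand_dna(sample(30:300, 1), gc = runif(1, 0.3, 0.6))
    for (atg in c(TRUE, FALSE)) {
      got <- scan_orfs(s, min_aa = 2, require_atg = atg)
      want <- oracle_scan_orfs(s, min_aa = 2, require_atg = atg)
      expect_equal(got, want, info = paste("seq", i, "atg", atg))
    }
  }
})

test_that("locus coordinates skip zero and invert cleanly", {
  cs <- 265L
  expect_equal(to_locus_coord(265L, cs), 1L)
  expect_equal(to_locus_coord(264L, cs), -1L)   # immediately 5' of the ATG
  expect_equal(to_locus_coord(230L, cs), -35L)
  expect_error(from_locus_coord(0L, cs), "0")
  for (p in c(1L, 100L, 264L, 265L, 266L, 900L)) {
    expect_equal(from_locus_coord(to_locus_coord(p, cs), cs), p)
  }
})

test_that("minus-strand loci are normalized to CDS-forward orientation", {
  cds <- "ATGAAACCCTAA"
  ctx_fwd <- paste0("GGGGG", cds, "TTTTT")
  ctx_rev <- reverse_complement(ctx_fwd)
  loc <- gene_locus("rev", nt_sequence("rev", ctx_rev),
                    cds_start = 6L, cds_end = 17L, strand = "-")
  expect_equal(locus_cds(loc)$residues, cds)
  expect_equal(loc$strand, "-")
  expect_error(gene_locus("bad", nt_sequence("bad", "ACGT"), 2, 10),
               "outside context")
})

test_that("FASTA I/O round-trips, normalizes case, and flags duplicates", {
  tmp <- tempfile(fileext = ".fasta")
  seqs <- list(nt_sequence("a", "ACGTACGTACGT", "first"),
               nt_sequence("b", strrep("ACGTN", 30)),
               nt_sequence("c", ""))
  write_fasta(seqs, tmp, wrap = 20)
  back <- read_fasta(tmp)
  expect_equal(vapply(back, `[[`, "", "id"), c("a", "b", "c"))
  expect_equal(vapply(back, `[[`, "", "residues"),
               vapply(seqs, `[[`, "", "residues"))
  expect_equal(back[[1]]$description, "first")

  writeLines(c(">low", "acgtacgt"), tmp)
  expect_equal(read_fasta(tmp)[[1]]$residues, "ACGTACGT")

  writeLines(c(">dup", "AAAA", ">dup", "CCCC"), tmp)
  expect_warning(recs <- read_fasta(tmp), "duplicate")
  expect_length(recs, 2L)

  writeLines(character(0), tmp)
  expect_error(read_fasta(tmp), "empty")
  writeLines(c("ACGT", ">x"), tmp)
  expect_error(read_fasta(tmp), "malformed")
})

test_that("locus annotation sidecar round-trips through make_loci", {
  fam <- generate_family(seed = 5, flank_nt = 50,
                         lesions = list(a = lesion_spec("none"),
                                        b = lesion_spec("frameshift_del")))
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_fasta(lapply(fam$loci, function(l) l$context), fa)
  write_locus_annotations(fam$loci, tsv)
  loci2 <- make_loci(read_fasta(fa), read_locus_annotations(tsv))
  expect_equal(names(loci2), names(fam$loci))
  for (lab in names(loci2)) {
    expect_equal(locus_cds(loci2[[lab]])$residues,
                 locus_cds(fam$loci[[lab]])$residues)
  }
})
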