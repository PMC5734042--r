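test_that("generated ancestors are valid CDSs at the target GC", {
  anc <- generate_ancestor(n_codons = 100, gc_target = 0.40, seed = 70)
  expect_equal(nchar(anc$residues), 300L)
  aa <- translate(anc)
  expect_true(startsWith(aa$residues, "M"))
  expect_true(endsWith(aa$residues, "*"))
  expect_false(grepl("*", substr(aa$residues, 1, 98), fixed = TRUE))
  expect_identical(generate_ancestor(100, 0.40, seed = 70)$residues,
                   anc$residues)   # deterministic per seed
  for (seed in 71:90) {
    gc <- mean(strsplit(generate_ancestor(100, 0.40, seed = seed)$residues,
                        "")[[1]] %in% c("G", "C"))
    expect_gte(gc, 0.35); expect_lte(gc, 0.45)
  }
  # scaffold codons are stamped in place
  anc2 <- generate_ancestor(seed = 70, forced_codons = family_scaffold_codons())
  expect_equal(substr(anc2$residues, 226, 228), "TAC")
  expect_equal(substr(translate(anc2)$residues, 71, 76), paste0(
    "D", substr(translate(anc2)$residues, 72, 75), "Y"))
})

test_that("zero-divergence intact families are identical to the ancestor", {
  fam <- generate_family(seed = 71, divergence_sub_rate = 0, flank_nt = 100,
                         lesions = list(a = lesion_spec("none"),
                                        b = lesion_spec("none"),
                                        c = lesion_spec("none")))
  for (lab in c("a", "b", "c")) {
    expect_equal(locus_cds(fam$loci[[lab]])$residues, fam$ancestor$residues)
    expect_equal(classify_locus(fam$loci[[lab]], fam$reference)$status,
                 "intact")
  }
})

test_that("divergence 0.05 yields about 95% nucleotide identity", {
  ids <- c()
  for (seed in 72:76) {
    fam <- generate_family(seed = seed, flank_nt = 50,
                           lesions = list(a = lesion_spec("none")))
    a <- strsplit(locus_cds(fam$loci$a)$residues, "")[[1]]
    b <- strsplit(fam$ancestor$residues, "")[[1]]
    ids <- c(ids, 100 * mean(a == b))
  }
  expect_equal(mean(ids), 95, tolerance = 0.015)
  # neutral substitutions never create internal stops in unlesioned copies
  for (seed in 72:76) {
    fam <- generate_family(seed = seed, flank_nt = 50,
                           lesions = list(a = lesion_spec("none")))
    aa <- translate(locus_cds(fam$loci$a))$residues
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("family generation is bit-reproducible per seed", {
  f1 <- generate_family(seed = 77, flank_nt = 200)
  f2 <- generate_family(seed = 77, flank_nt = 200)
  for (lab in names(f1$loci)) {
    expect_identical(f1$loci[[lab]]$context$residues,
                     f2$loci[[lab]]$context$residues)
  }
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_family(seed = 78, flank_nt = 200)
  expect_false(identical(f1$loci[[1]]$context$residues,
                         f3$loci[[1]]$context$residues))
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(99); before <- runif(5)
  set.seed(99); invisible(generate_family(seed = 1, flank_nt = 50,
                                          lesions = list(a = lesion_spec("none"))))
  after <- runif(5)
  expect_identical(before, after)
})

test_that("synthetic kinetics datasets follow the design", {
  d0 <- generate_mm_dataset(mm_design(km = 296, vmax = 0.49, cv = 0, seed = 1))
  expect_equal(d0$rates, 0.49 * d0$concentrations / (296 + d0$concentrations))
  # a point at S = Km sits exactly at Vmax/2 when noiseless
  dk <- generate_mm_dataset(mm_design(km = 100, vmax = 2,
                                      concentrations = c(10, 50, 100, 1000),
                                      cv = 0, seed = 1))
  expect_equal(dk$rates[dk$concentrations == 100], rep(1.0, 3))
  # empirical residual cv matches the design cv
  dn <- generate_mm_dataset(mm_design(km = 296, vmax = 0.49, cv = 0.05,
                                      replicates = 125, seed = 2))
  mu <- 0.49 * dn$concentrations / (296 + dn$concentrations)
  expect_lt(abs(sd(dn$rates / mu - 1) - 0.05), 0.005)
  expect_equal(length(dn$rates), 1000L)
  # deterministic per seed
  expect_identical(
    generate_mm_dataset(mm_design(km = 10, vmax = 1, cv = 0.05, seed = 3))$rates,
    generate_mm_dataset(mm_design(km = 10, vmax = 1, cv = 0.05, seed = 3))$rates)
})
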