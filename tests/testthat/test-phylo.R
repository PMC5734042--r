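test_that("k-mer profiles enumerate distinct words and drop N", {
  expect_length(kmer_profile("ACGTACGT", k = 15)$kmers, 0L)
  expect_length(kmer_profile(strrep("A", 15), k = 15)$kmers, 1L)
  # a non-repetitive 100-mer has exactly L - k + 1 = 86 distinct 15-mers
  set.seed(60)
  repeat {
    s <- rand_dna(100)
    p <- kmer_profile(s, k = 15)
    if (length(p$kmers) == 86L) break
  }
  expect_length(p$kmers, 86L)
  withN <- kmer_profile(paste0(strrep("A", 14), "N", strrep("C", 14)), k = 15)
  expect_length(withN$kmers, 0L)
})

test_that("fractional-common-k-mer distance matches hand-enumerated sets", {
  a <- kmer_profile("ACGTACGTAC", k = 3)
  expect_equal(kmer_distance(a, a), 0)
  b <- kmer_profile(strrep("A", 10), k = 3)
  c3 <- kmer_profile(strrep("C", 10), k = 3)
  expect_equal(kmer_distance(b, c3), 1)
  # |A| = 10, |B| = 20, |A intersect B| = 5 -> d = 1 - 5/10 = 0.5
  mk <- function(words) structure(list(label = "x", k = 3L,
                                       kmers = sort(words)),
                                  class = "kmer_profile")
  A <- mk(sprintf("A%02d", 1:10))
  B <- mk(c(sprintf("A%02d", 1:5), sprintf("B%02d", 1:15)))
  expect_equal(length(A$kmers), 10L)
  expect_equal(length(B$kmers), 20L)
  expect_equal(kmer_distance(A, B), 0.5)
  expect_equal(kmer_distance(B, A), 0.5)       # symmetry
  empty <- mk(character(0))
  expect_error(kmer_distance(empty, empty), "empty")
  expect_equal(kmer_distance(A, empty), 1)
  # jaccard variant: 1 - 5/25
  expect_equal(kmer_distance(A, B, method = "jaccard"), 1 - 5 / 25)
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(61)
  seqs <- replicate(5, rand_dna(300))
  names(seqs) <- paste0("s", 1:5)
  d <- kmer_distance_matrix(seqs, k = 8)
  expect_equal(diag(d), setNames(rep(0, 5), names(seqs)))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 3, 8,
                3, 0, 9,
                8, 9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3L)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(d), colnames(d)], d, tolerance = 1e-10)
  # v_a = (d(a,b) + d(a,c) - d(b,c)) / 2 = 1
  tip_edge <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(tip_edge, (3 + 8 - 9) / 2)
})

test_that("NJ recovers additive matrices exactly (random-tree oracle)", {
  set.seed(62)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.1, 2)
    d <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr0), tr), 0)
    cd <- ape::cophenetic.phylo(tr)
    expect_equal(cd[rownames(d), colnames(d)], d, tolerance = 1e-8)
  }
})

test_that("degenerate and invalid matrices are handled", {
  # two identical rows join first with zero-length pendants
  d <- matrix(c(0, 0, 5, 5,
                0, 0, 5, 5,
                5, 5, 0, 2,
                5, 5, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- suppressWarnings(neighbor_joining(d))
  ab <- ape::cophenetic.phylo(tr)["a", "b"]
  expect_equal(ab, 0)
  bad <- d; bad[1, 2] <- 1
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_joining(neg), "negative")
  two <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- neighbor_joining(two)
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(sum(t2$edge.length), 3)
})

test_that("Newick output round-trips topology and branch lengths", {
  two <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  s <- write_newick(neighbor_joining(two))
  expect_match(s, "^\\(A:[0-9.]+,B:[0-9.]+\\);$")
  set.seed(63)
  for (i in 1:20) {
    tr0 <- ape::rtree(sample(4:12, 1), rooted = FALSE)
    tmp <- tempfile(fileext = ".nwk")
    write_newick(tr0, tmp)
    tr1 <- read_newick(tmp)
    expect_equal(phangorn::RF.dist(tr0, tr1), 0)
    m0 <- ape::cophenetic.phylo(tr0); m1 <- ape::cophenetic.phylo(tr1)
    expect_equal(m1[rownames(m0), colnames(m0)], m0, tolerance = 1e-6)
  }
  # unlabeled internal nodes tolerated
  tr <- read_newick(text = "((A:1,B:2):0.5,C:3);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_error(read_newick(text = "not a tree"))
})

test_that("ortholog hit filtering applies the score/length/uniqueness rule", {
  hits <- data.frame(
    species = c("sp1", "sp1", "sp2", "sp2", "sp3", "sp3"),
    score = c(120, 80, 59, 70, 200, 150),
    length = c(900, 400, 800, 150, 100, 300),
    rank = c(1, 2, 1, 2, 1, 2))
  out <- filter_hits(hits)
  # sp1: rank-1 passes; sp2: rank-1 fails score, rank-2 fails length (150 is
  # not > 150); sp3: rank-1 fails length, rank-2 passes
  expect_equal(out$species, c("sp1", "sp3"))
  expect_equal(out$score, c(120, 150))
  expect_equal(nrow(filter_hits(data.frame(species = "s", score = 59,
                                           length = 500, rank = 1))), 0L)
  expect_equal(nrow(filter_hits(data.frame(species = "s", score = 60,
                                           length = 151, rank = 1))), 1L)
  expect_error(filter_hits(data.frame(species = "s", score = 60)), "missing")
})
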