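test_that("codonSites matches hand-enumerated neighbor fractions", {
  expect_equal(codonSites("TTT")$sSites, 1 / 3)
  s <- codonSites("GGG")
  expect_equal(s$sSites, 1)
  expect_equal(s$nSites, 2)
  expect_error(codonSites("TAA"), "stop codon")
  expect_error(codonSites("T-A"), "invalid codon")
  expect_error(codonSites("TNA"), "invalid codon")
})

test_that("site counts sum to 3 and agree with the naive oracle for all sense codons", {
  for (cod in setdiff(names(standardGeneticCode()),
                      c("TAA", "TAG", "TGA"))) {
    s <- codonSites(cod)
    expect_equal(s$sSites + s$nSites, 3, tolerance = 1e-9)
    expect_equal(s$sSites, oracleCodonSites(cod), tolerance = 1e-12,
                 label = cod)
  }
})

test_that("pathwayCounts averages over minimal pathways with stop exclusion", {
  expect_equal(pathwayCounts("TTT", "TTT"), c(Sd = 0, Nd = 0))
  expect_equal(pathwayCounts("GGG", "GGA"), c(Sd = 1, Nd = 0))
  expect_equal(pathwayCounts("TTT", "GTA"), c(Sd = 0.5, Nd = 1.5))
  expect_error(pathwayCounts("TAA", "TTT"), "stop")
  expect_error(pathwayCounts("T-T", "TTT"), "invalid")
})

test_that("pathwayCounts is symmetric and conserves the number of differences", {
  sense <- setdiff(names(standardGeneticCode()), c("TAA", "TAG", "TGA"))
  set.seed(11)
  for (k in 1:200) {
    pair <- sample(sense, 2)
    pc <- pathwayCounts(pair[1], pair[2])
    expect_equal(pc, pathwayCounts(pair[2], pair[1]))
    d <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    expect_equal(unname(pc["Sd"] + pc["Nd"]), d, tolerance = 1e-12)
  }
})

test_that("jukesCantor evaluates the closed form, guards saturation, and dominates p", {
  expect_equal(jukesCantor(0), 0)
  expect_equal(jukesCantor(0.5), 0.8239592, tolerance = 1e-6)
  expect_true(is.na(jukesCantor(0.75)))
  expect_true(is.na(jukesCantor(0.9)))
  expect_error(jukesCantor(-0.1), "negative")
  p <- seq(0, 0.74, by = 0.01)
  d <- jukesCantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("pairwiseDsDn reproduces the hand-enumerated worked example", {
  aln <- makeCodonAln(c(rep("TTT", 9), "GGG"), c(rep("TTT", 8), "TTA", "GGA"))
  r <- pairwiseDsDn(aln, 1, 2)
  expect_equal(r$codons_compared, 10L)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 1)
  expect_equal(r$S, 25 / 6, tolerance = 1e-9)
  expect_equal(r$S + r$N, 3 * 10, tolerance = 1e-9)
  expect_equal(r$pS, 0.24, tolerance = 1e-9)
  expect_equal(r$dS, 0.2892469, tolerance = 1e-6)
  expect_equal(r$dN, 0.0397444, tolerance = 1e-6)
  expect_equal(r$ratio, 7.277676, tolerance = 1e-5)
  expect_false(r$saturated)
  expect_true(r$computable)
})

test_that("identical rows yield zero distances with a dN_zero reason", {
  aln <- makeCodonAln(rep("ATG", 5), rep("ATG", 5))
  r <- pairwiseDsDn(aln, 1, 2)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$dS, 0)
  expect_equal(r$dN, 0)
  expect_true(is.na(r$ratio))
  expect_identical(r$reason, "dN_zero")
})

test_that("pS >= 0.75 triggers the saturation flag and suppresses the ratio", {
  # CTA vs TTG: both leucine, two synonymous differences over one mean
  # synonymous site -> pS = 2
  aln <- makeCodonAln("CTA", "TTG")
  r <- pairwiseDsDn(aln, 1, 2)
  expect_true(r$pS >= 0.75)
  expect_true(r$saturated)
  expect_true(is.na(r$dS))
  expect_true(is.na(r$ratio))
  expect_false(r$computable)
  expect_identical(r$reason, "saturated")
})

test_that("pairwiseDsDn is symmetric up to the id columns and skips gap codons pairwise", {
  aln <- makeCodonAln(c("TTT", "---", "GGG", "ATG"),
                      c("TTC", "AAA", "GGA", "---"),
                      c("TTA", "AAA", "GGG", "ATG"))
  ab <- pairwiseDsDn(aln, 1, 2)
  ba <- pairwiseDsDn(aln, 2, 1)
  expect_equal(ab[, setdiff(names(ab), c("id_a", "id_b"))],
               ba[, setdiff(names(ba), c("id_a", "id_b"))])
  expect_equal(ab$codons_compared, 2L)  # gaps in either row skipped
  ac <- pairwiseDsDn(aln, 1, 3)
  expect_equal(ac$codons_compared, 3L)  # each pair uses its own maximal set
})

test_that("Sd + Nd equals the summed per-codon nucleotide difference count", {
  set.seed(7)
  sense <- setdiff(names(standardGeneticCode()), c("TAA", "TAG", "TGA"))
  for (rep in 1:20) {
    a <- sample(sense, 30, replace = TRUE)
    b <- sample(sense, 30, replace = TRUE)
    r <- pairwiseDsDn(makeCodonAln(a, b), 1, 2)
    nd <- sum(mapply(function(x, y) {
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, a, b))
    expect_equal(r$Sd + r$Nd, nd, tolerance = 1e-9)
  }
})

test_that("per-sequence means average the computable pairwise ratios", {
  aln <- makeCodonAln(
    c(rep("TTT", 9), "GGG"),
    c(rep("TTT", 8), "TTA", "GGA"),
    c(rep("TTC", 9), "GGT")
  )
  pairs <- allPairsDsDn(aln)
  expect_equal(nrow(pairs), 3L)
  m <- perSequenceMeanDsDn(aln)
  for (id in seqIds(aln)) {
    mine <- pairs[pairs$id_a == id | pairs$id_b == id, ]
    expected <- mean(mine$ratio[mine$computable])
    got <- m$perSequence$mean_ratio[m$perSequence$id == id]
    if (is.nan(expected)) expect_true(is.na(got)) else expect_equal(got, expected)
  }
  expect_equal(m$computableFraction, mean(pairs$computable))
})

test_that("all-identical alignments have no computable pairs", {
  aln <- makeCodonAln(rep("ATG", 4), rep("ATG", 4), rep("ATG", 4))
  m <- perSequenceMeanDsDn(aln)
  expect_true(all(is.na(m$perSequence$mean_ratio)))
  expect_equal(m$computableFraction, 0)
  expect_equal(unique(m$perSequence$pairs_total), 2L)
})

test_that("perCodonSd averages pathway Sd per column over comparable pairs", {
  base <- rep("AAA", 6)
  changed <- base
  changed[3] <- "AAG"  # synonymous Lys change at codon 3
  aln <- makeCodonAln(base, base, changed)
  prof <- perCodonSd(aln)
  expect_equal(nrow(prof), 6L)
  expect_equal(prof$mean_Sd[3], 2 / 3, tolerance = 1e-12)
  expect_equal(prof$mean_Sd[-3], rep(0, 5))
  expect_equal(unique(prof$pairs_used), 3L)

  gapped <- base
  gapped[3] <- "---"
  aln2 <- makeCodonAln(base, changed, gapped)
  prof2 <- perCodonSd(aln2)
  expect_equal(prof2$pairs_used[3], 1L)
  expect_equal(prof2$pairs_used[1], 3L)
  expect_equal(prof2$mean_Sd[3], 1)
})
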