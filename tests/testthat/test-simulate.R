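test_that("zero branch lengths leave every leaf identical to the root", {
  sim <- simulateCodonAlignment(starTree(4, 0), nCodons = 50, omega = 1,
                                seed = 9)
  seqs <- as.character(alignedSequences(sim$alignment))
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(sum(sim$eventLog$syn_events + sim$eventLog$nonsyn_events), 0L)
})

test_that("the codon simulator is deterministic under a fixed seed", {
  s1 <- simulateCodonAlignment(starTree(5, 0.2), nCodons = 80, omega = 1.5,
                               seed = 123)
  s2 <- simulateCodonAlignment(starTree(5, 0.2), nCodons = 80, omega = 1.5,
                               seed = 123)
  expect_identical(as.character(alignedSequences(s1$alignment)),
                   as.character(alignedSequences(s2$alignment)))
  expect_identical(s1$eventLog, s2$eventLog)
  s3 <- simulateCodonAlignment(starTree(5, 0.2), nCodons = 80, omega = 1.5,
                               seed = 124)
  expect_false(identical(as.character(alignedSequences(s1$alignment)),
                         as.character(alignedSequences(s3$alignment))))
})

test_that("simulated alignments contain no stop codons and respect the tree tips", {
  tree <- ape::read.tree(text = "((t1:0.1,t2:0.1):0.05,t3:0.2);")
  sim <- simulateCodonAlignment(tree, nCodons = 60, omega = 1, seed = 4)
  expect_setequal(seqIds(sim$alignment), c("t1", "t2", "t3"))
  for (s in as.character(alignedSequences(sim$alignment))) {
    expect_false(any(standardGeneticCode()[
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))] == "*"))
  }
  expect_error(simulateCodonAlignment(starTree(3, 0.1), omega = 0), "omega")
  expect_error(simulateCodonAlignment(ape::read.tree(text = "(t1,t2);"),
                                      seed = 1), "branch lengths")
})

test_that("at low omega almost all accepted events are synonymous", {
  sim <- simulateCodonAlignment(starTree(6, 0.4), nCodons = 200, omega = 0.05,
                                seed = 17)
  tot <- colSums(sim$eventLog[, c("syn_events", "nonsyn_events")])
  expect_gt(tot["syn_events"], 10)
  expect_lt(tot["nonsyn_events"] / sum(tot), 0.25)
})

test_that("event-log totals match observed differences at low divergence", {
  sim <- simulateCodonAlignment(starTree(2, 0.02), nCodons = 300, omega = 1,
                                seed = 31)
  seqs <- as.character(alignedSequences(sim$alignment))
  ndiff <- sum(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]])
  nev <- sum(sim$eventLog$syn_events + sim$eventLog$nonsyn_events)
  # multiple hits at one site are rare at this divergence
  expect_lte(ndiff, nev)
  expect_gte(ndiff, 0.8 * nev)
})

test_that("operon simulation plants genes at the configured extremes", {
  simNone <- simulateOperonTables(10, c(gx = 0), window = 5, seed = 2)
  expect_false("gx" %in% simNone$features$gene_name)
  simAll <- simulateOperonTables(10, c(gx = 1), window = 5, seed = 2)
  nbs <- lapply(simAll$focalLoci, function(l) {
    extractNeighborhood(simAll$features, l, window = 5)
  })
  ft <- geneAssociationFrequency(nbs)
  expect_equal(ft$freq[ft$gene_name == "gx"], 1)
  expect_error(simulateOperonTables(5, c(a = 0.5, b = 0.5), window = 0),
               "window too small")
  s1 <- simulateOperonTables(5, c(gx = 0.5), seed = 7)
  s2 <- simulateOperonTables(5, c(gx = 0.5), seed = 7)
  expect_identical(s1$features, s2$features)
})

test_that("simulated feature tables round-trip through the TSV reader", {
  sim <- simulateOperonTables(3, c(gx = 0.5), window = 4, seed = 5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTsv(sim$features, tsv)
  back <- readFeatures(tsv, "tsv")
  expect_equal(nrow(back), nrow(sim$features))
  expect_setequal(back$locus_tag, sim$features$locus_tag)
  nb <- extractNeighborhood(back, sim$focalLoci[1], window = 4)
  expect_equal(nrow(nb$neighbors), 8L)
})

test_that("simulated TM proteins carry their planted architecture", {
  sim <- simulateTmProtein(nTm = 6, tmLength = 21, seed = 13)
  iv <- tmIntervals(sim$truth)
  expect_equal(length(iv), 6L)
  expect_true(all(IRanges::width(iv) == 21L))
  expect_equal(nchar(sim$protein), sim$truth@seqLength)
  none <- simulateTmProtein(nTm = 0, seed = 13)
  expect_equal(length(tmIntervals(none$truth)), 0L)
  expect_equal(length(tmIntervals(hydropathyPredict(none$protein))), 0L)
  a <- simulateTmProtein(seed = 99, nPredictors = 2)
  b <- simulateTmProtein(seed = 99, nPredictors = 2)
  expect_identical(a$protein, b$protein)
  expect_identical(as.data.frame(tmIntervals(a$predictions[[2]])),
                   as.data.frame(tmIntervals(b$predictions[[2]])))
})

test_that("generator streams are independent across the master seed", {
  # consuming the alignment stream must not change the operon stream
  op1 <- simulateOperonTables(4, c(gx = 0.5), seed = 55)
  invisible(simulateCodonAlignment(starTree(3, 0.2), nCodons = 30, seed = 55))
  op2 <- simulateOperonTables(4, c(gx = 0.5), seed = 55)
  expect_identical(op1$features, op2$features)
})
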