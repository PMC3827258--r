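test_that("readFeatures parses and sorts the TSV dialect with name normalization", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    genome_id = "g1", contig = "c1",
    locus_tag = c("L3", "L1", "L2"),
    gene = c("TatA.1", "", "ywbN"),
    start = c(5000L, 1000L, 3000L), end = c(5900L, 1900L, 3900L),
    strand = c("+", "-", "+"),
    product = c("sec-independent translocase", "Hypothetical Protein", "peroxidase")
  )
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  feats <- readFeatures(tsv, "tsv")
  expect_equal(feats$locus_tag, c("L1", "L2", "L3"))  # sorted by start
  expect_equal(feats$gene_name[feats$locus_tag == "L3"], "tata")
  expect_equal(feats$gene_name[feats$locus_tag == "L2"], "ywbn")
  # unnamed gene falls back to a product token
  expect_equal(feats$gene_name[feats$locus_tag == "L1"], "hypothetical_protein")
})

test_that("readFeatures rejects malformed coordinates and strands", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(genome_id = "g", contig = "c", locus_tag = "L1",
                    gene = "x", start = 900L, end = 100L, strand = "+",
                    product = "p")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFeatures(tsv, "tsv"), "end < start")
  tab$end <- 1900L
  tab$strand <- "."
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFeatures(tsv, "tsv"), "strand")
})

test_that("readFeatures imports GFF3 annotations", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tgene\t3000\t3900\t.\t+\t.\tID=g3;locus_tag=LT3;gene=tatC;product=translocase subunit",
    "c1\ttest\tgene\t1000\t1900\t.\t-\t.\tID=g1;locus_tag=LT1;gene=yqcE;product=transporter",
    "c1\ttest\tgene\t2000\t2900\t.\t+\t.\tID=g2;locus_tag=LT2;product=amidase"
  ), gff)
  feats <- readFeatures(gff, "gff3", genomeId = "gX")
  expect_equal(nrow(feats), 3L)
  expect_equal(feats$locus_tag, c("LT1", "LT2", "LT3"))
  expect_equal(feats$gene_name, c("yqce", "amidase", "tatc"))
  expect_equal(feats$strand, c("-", "+", "+"))
  expect_equal(unique(feats$genome_id), "gX")
})

test_that("extractNeighborhood windows truncate at contig ends and record strand relation", {
  feats <- makeContigFeatures(25)
  mid <- extractNeighborhood(feats, "g1_013", window = 10)
  expect_equal(sum(mid$neighbors$relative_position < 0), 10L)
  expect_equal(sum(mid$neighbors$relative_position > 0), 10L)
  edge <- extractNeighborhood(feats, "g1_003", window = 10)
  expect_equal(sum(edge$neighbors$relative_position < 0), 2L)
  expect_equal(sum(edge$neighbors$relative_position > 0), 10L)
  expect_error(extractNeighborhood(feats, "nope"), "not found")
  # alternating strands: immediate neighbors are opposite to the focal gene
  expect_false(mid$neighbors$same_strand[mid$neighbors$relative_position == 1])
  # neighbors never cross contigs
  feats2 <- rbind(feats, makeContigFeatures(25, genome = "g1", contig = "c2"))
  feats2$locus_tag[26:50] <- sprintf("g1_c2_%03d", 1:25)
  nb <- extractNeighborhood(feats2, "g1_025", window = 10)
  expect_true(all(nb$neighbors$relative_position <= 0))
})

test_that("gene association frequency counts presence once per neighborhood", {
  feats <- makeContigFeatures(25)
  nbs <- lapply(sprintf("g1_%03d", 11:15), function(l) {
    extractNeighborhood(feats, l, window = 3)
  })
  ft <- geneAssociationFrequency(nbs)
  # gene012 sits within 3 genes of loci 11..15 except locus 15 (|15-12| > 3)
  row <- ft[ft$gene_name == "gene012", ]
  expect_equal(row$n_gene, 4L)
  expect_equal(row$O, 5L)
  expect_equal(row$freq, 0.8)
  expect_equal(row$n_locus, 6L)
  expect_false("gene024" %in% ft$gene_name)  # absent genes do not appear
  # naive recount invariant
  for (g in ft$gene_name[ft$group == "all"]) {
    n <- sum(vapply(nbs, function(nb) g %in% nb$neighbors$gene_name, logical(1)))
    expect_equal(ft$n_gene[ft$gene_name == g & ft$group == "all"], n)
  }
})

test_that("duplicate copies in one window count once and synonyms merge names", {
  feats <- makeContigFeatures(9)
  feats$gene_name[c(3, 5)] <- "duplic"
  feats$gene_name[7] <- "efeb"
  nb <- extractNeighborhood(feats, "g1_004", window = 4)
  ft <- geneAssociationFrequency(list(nb), synonyms = c(efeb = "ywbn"))
  expect_equal(ft$n_gene[ft$gene_name == "duplic"], 1L)
  expect_true("ywbn" %in% ft$gene_name)
  expect_false("efeb" %in% ft$gene_name)
  expect_true(all(ft$freq <= 1))
})

test_that("adding a neighborhood containing a gene never lowers its frequency", {
  feats <- makeContigFeatures(25)
  nbs <- lapply(sprintf("g1_%03d", 11:14), extractNeighborhood,
                features = feats, window = 3)
  f1 <- geneAssociationFrequency(nbs)
  f2 <- geneAssociationFrequency(c(nbs, nbs[2]))
  for (g in f1$gene_name) {
    if (g %in% nbs[[2]]$neighbors$gene_name) {
      expect_gte(f2$freq[f2$gene_name == g], f1$freq[f1$gene_name == g])
    }
  }
})

test_that("paper-style formula column and group tallies are available", {
  feats <- makeContigFeatures(25)
  nbs <- list(
    extractNeighborhood(feats, "g1_011", window = 3, group = "isoformA"),
    extractNeighborhood(feats, "g1_012", window = 3, group = "isoformB")
  )
  ft <- geneAssociationFrequency(nbs, paperFormula = TRUE)
  expect_true("paper_formula" %in% names(ft))
  all <- ft[ft$group == "all", ]
  expect_equal(all$paper_formula, (all$n_gene / all$n_locus) * all$O)
  expect_setequal(unique(ft$group), c("all", "isoformA", "isoformB"))
})

test_that("conservation classes follow the 50-80 / >=80 percent conventions", {
  tab <- data.frame(group = "all", gene_name = c("a", "b", "c"),
                    n_gene = c(17, 12, 6), O = 20, n_locus = 20,
                    freq = c(0.85, 0.60, 0.30),
                    modal_relative_position = 1L,
                    modal_strand_relation = "same")
  cls <- classifyGeneConservation(tab)
  expect_equal(cls$conservation_class[cls$gene_name == "a"], "high")
  expect_equal(cls$conservation_class[cls$gene_name == "b"], "moderate")
  expect_equal(cls$conservation_class[cls$gene_name == "c"], "below")
  # boundary: exactly 0.80 is high, exactly 0.50 moderate
  tab$freq <- c(0.80, 0.50, 0.4999)
  cls <- classifyGeneConservation(tab)
  expect_equal(cls$conservation_class,
               c("high", "moderate", "below")[order(-tab$freq)])
  expect_error(classifyGeneConservation(tab, moderate = 0.9, high = 0.8),
               "thresholds")
})

test_that("operonDiagram lays out the most frequent gene per relative position", {
  feats <- makeContigFeatures(25)
  nbs <- lapply(sprintf("g1_%03d", 11:15), extractNeighborhood,
                features = feats, window = 2)
  cls <- classifyGeneConservation(geneAssociationFrequency(nbs))
  diag <- operonDiagram(nbs, cls)
  expect_true(length(diag) > 0)
  expect_true(all(vapply(diag, function(d)
    all(c("relative_position", "gene_name", "freq",
          "conservation_class") %in% names(d)), logical(1))))
})
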