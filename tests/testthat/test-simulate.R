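test_that("the whole simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(backgroundGenes = 40)
  s1 <- simulateExperiment(cfg, seed = 9)
  s2 <- simulateExperiment(cfg, seed = 9)
  expect_identical(SummarizedExperiment::assay(s1$se, "counts"),
                   SummarizedExperiment::assay(s2$se, "counts"))
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(s1, d1); writeSimulation(s2, d2)
  for (f in c("genome.fasta", "genome.gff3", "boxes.tsv", "counts.tsv",
              "truth_genes.tsv", "truth_boxes.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  s3 <- simulateExperiment(cfg, seed = 10)
  expect_false(identical(SummarizedExperiment::assay(s1$se, "counts"),
                         SummarizedExperiment::assay(s3$se, "counts")))
})

test_that("the default plan plants the documented box inventory", {
  sim <- simulateGenome(simulationConfig(backgroundGenes = 20), seed = 13)
  tb <- sim$truth$boxes
  expect_equal(sum(tb$box_type == "NB"), 15L)
  expect_equal(sum(tb$box_type == "TB"), 18L)
  expect_equal(sum(tb$box_type == "NB" & tb$planted == "active"), 11L)
  expect_equal(sum(tb$box_type == "NB" & tb$planted == "weakly-active"), 1L)
  expect_equal(sum(tb$box_type == "NB" & tb$planted == "no-downstream-gene"),
               2L)
  expect_equal(sum(tb$box_type == "TB" & tb$planted == "active"), 11L)
  expect_equal(sum(tb$box_type == "TB" & tb$planted == "non-functional"), 7L)
  # unlinked boxes really have no gene within 1 kb
  ann <- linkBoxToGene(sim$annotation, 1000)
  mc <- S4Vectors::mcols(promoterBoxes(ann))
  noDown <- tb$box_id[tb$planted == "no-downstream-gene"]
  expect_true(all(is.na(mc$downstream_gene[mc$box_id %in% noDown])))
})

test_that("planted exact boxes pass the scanner and broken cores fail it", {
  set.seed(401)
  sim <- simulateGenome(simulationConfig(backgroundGenes = 10), seed = 17)
  ann <- sim$annotation
  b <- promoterBoxes(ann)
  mc <- S4Vectors::mcols(b)
  pats <- list(NB = nbConsensusPattern(), TB = tbConsensusPattern(),
               SyrM = syrmBoxPattern())
  for (k in seq_along(b)) {
    repl <- as.character(GenomeInfoDb::seqnames(b)[k])
    s <- as.character(Biostrings::subseq(genomeSequences(ann)[[repl]],
                                         GenomicRanges::start(b)[k],
                                         GenomicRanges::end(b)[k]))
    if (as.character(GenomicRanges::strand(b)[k]) == "-") s <- oracleRevComp(s)
    hits <- scanMotif(s, pats[[mc$box_type[k]]], 0, strands = "+")
    broken <- sim$truth$boxes$reason[
      match(mc$box_id[k], sim$truth$boxes$box_id)] == "broken_core"
    expect_equal(nrow(hits), if (broken) 0L else 1L, label = mc$box_id[k])
  }
})

test_that("with no effects and dispersion 0 the counts are Poisson around mu", {
  libs <- librarySpecs(depthRange = c(1, 1), seed = 19)
  cfg <- simulationConfig(
    units = defaultUnitPlan()[0, ], backgroundGenes = 300,
    replicons = data.frame(id = "chr", length = 400000L, kind = "chromosome",
                           stringsAsFactors = FALSE))
  sim <- simulateGenome(cfg, 23)
  se <- simulateCounts(sim$annotation, sim$truth, libs, 24, dispersion = 0)
  cts <- SummarizedExperiment::assay(se, "counts")
  g <- genes(sim$annotation)
  tg <- sim$truth$genes[match(rownames(cts), sim$truth$genes$gene_id), ]
  mu <- tg$baseline_mean * GenomicRanges::width(g)[
    match(rownames(cts), S4Vectors::mcols(g)$gene_id)] / 1000
  z <- (rowMeans(cts) - mu) / sqrt(mu / ncol(cts))
  expect_lt(abs(mean(z)), 0.2)          # standardized residuals center on 0
  expect_lt(abs(stats::sd(z) - 1), 0.15) # ...with unit spread
})

test_that("negative-binomial moments match the mean-dispersion parameterization", {
  libs <- librarySpecs(nReplicates = 1700, depthRange = c(1, 1), seed = 29)
  cfg <- simulationConfig(
    units = defaultUnitPlan()[0, ], backgroundGenes = 1,
    replicons = data.frame(id = "chr", length = 5000L, kind = "chromosome",
                           stringsAsFactors = FALSE))
  sim <- simulateGenome(cfg, 31)
  disp <- 0.1
  se <- simulateCounts(sim$annotation, sim$truth, libs, 32, dispersion = disp)
  x <- as.numeric(SummarizedExperiment::assay(se, "counts"))
  g <- genes(sim$annotation)
  mu <- sim$truth$genes$baseline_mean * GenomicRanges::width(g) / 1000
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(stats::var(x), mu + disp * mu^2, tolerance = 0.1)
})

test_that("NB-class genes realize their planted fold-change distribution", {
  set.seed(402)
  libs <- librarySpecs(seed = 37)
  units <- unitPlanOfClass("NB", 1000, induction = 8)
  cfg <- simulationConfig(
    units = units, backgroundGenes = 0, baselineRange = c(200, 600),
    geneLengthRange = c(1000L, 1000L),
    replicons = data.frame(id = "chr", length = 1600000L, kind = "chromosome",
                           stringsAsFactors = FALSE), boxReplicon = "chr")
  sim <- simulateGenome(cfg, 41)
  se <- simulateCounts(sim$annotation, sim$truth, libs, 42, dispersion = 0.05)
  # every gene is induced here, so normalize by the true depth factors
  # (median-of-ratios needs a majority of unchanged genes to anchor on)
  sf <- setNames(libs$depth_factor / geomeanHelper(libs$depth_factor),
                 libs$library_id)
  res <- contrastDE(se, "WT", sizeFactors = sf)
  fcs <- res$FC
  expect_gt(mean(fcs), 5); expect_lt(mean(fcs), 13)
  expect_gt(mean(fcs >= 5 & fcs <= 13), 0.90)
  # the same genes show no induction in the nodD1 knockout
  resN <- contrastDE(se, "nodD1", sizeFactors = sf)
  expect_lt(abs(mean(resN$log2FC)),
            3 * stats::sd(resN$log2FC) / sqrt(nrow(resN)) + 0.02)
})

test_that("TB-class genes are silent in the ttsI knockout cell", {
  set.seed(403)
  libs <- librarySpecs(seed = 43)
  cfg <- simulationConfig(
    units = unitPlanOfClass("TB", 500, induction = 9), backgroundGenes = 0,
    baselineRange = c(200, 600), geneLengthRange = c(1000L, 1000L),
    replicons = data.frame(id = "chr", length = 800000L, kind = "chromosome",
                           stringsAsFactors = FALSE), boxReplicon = "chr")
  sim <- simulateGenome(cfg, 47)
  se <- simulateCounts(sim$annotation, sim$truth, libs, 48, dispersion = 0.05)
  sf <- setNames(libs$depth_factor / geomeanHelper(libs$depth_factor),
                 libs$library_id)
  res <- contrastDE(se, "ttsI", sizeFactors = sf)
  ci <- mean(res$log2FC) +
    c(-3, 3) * stats::sd(res$log2FC) / sqrt(nrow(res))
  expect_true(ci[1] < 0 && ci[2] > 0 + 0.05)
  expect_gt(mean(contrastDE(se, "WT", sizeFactors = sf)$FC), 5)
})

test_that("the effect model routes induction to the right design cells", {
  expect_equal(effectFactor("NB", 8, "ttsI", TRUE), 8)
  expect_equal(effectFactor("NB", 8, "nodD1", TRUE), 1)
  expect_equal(effectFactor("TB", 8, "ttsI", TRUE), 1)
  expect_equal(effectFactor("TB", 8, "WT", TRUE), 8)
  expect_equal(effectFactor("SyrM", 8, "ttsI", TRUE), 8)
  expect_equal(effectFactor("SyrM", 8, "ttsI", TRUE, syrmInTtsI = FALSE), 1)
  expect_equal(effectFactor("independent-up", 6, "nodD1", TRUE), 6)
  expect_equal(effectFactor("mutant-background", 0.2, "nodD1", FALSE), 0.2)
  expect_equal(effectFactor("mutant-background", 0.2, "WT", TRUE), 1)
  expect_equal(effectFactor("background", 1, "WT", TRUE), 1)
  expect_error(effectFactor("nope", 1, "WT", TRUE), "unknown regulon class")
})

test_that("overfull replicons abort with an infeasible-packing error", {
  cfg <- simulationConfig(
    replicons = data.frame(id = "tiny", length = 3000L, kind = "chromosome",
                           stringsAsFactors = FALSE),
    backgroundGenes = 40, boxReplicon = "tiny",
    units = defaultUnitPlan()[0, ])
  expect_error(simulateGenome(cfg, 1), "infeasible packing")
})
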