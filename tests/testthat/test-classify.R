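# A small hand-built genome: two NB operons, two TB operons, one SyrM box,
# one box with no downstream gene, plus loose genes used by the set-assembly
# and discard tests.
classifyFixture <- function() {
  genesDf <- data.frame(
    gene_id = c("nbLead", "nbSecond",     # NB9-like active operon
                "weakGene",               # NB3-like weak target
                "tbLead", "tbSecond",     # active TB operon
                "decoyLead",              # TB operon induced in ttsI too
                "lowGene",                # below the coverage floor
                "loneGene",               # isolated, modest induction
                "boxedGene",              # conserved-box rescue case
                "antiGene"),              # antisense to an NB
    replicon = "chr",
    start = c(2001L, 3001L, 6001L, 9001L, 10001L, 13001L, 16001L, 19001L,
              22001L, 25046L),
    end = c(2900L, 3900L, 6900L, 9900L, 10900L, 13900L, 16900L, 19900L,
            22900L, 25945L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "-"),
    operon_id = c("opNB", "opNB", NA, "opTB", "opTB", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  boxes <- makeBoxGRanges(data.frame(
    box_id = c("NB9", "NB3", "TB10", "TB7", "SB1", "NB5", "TB2"),
    box_type = c("NB", "NB", "TB", "TB", "SyrM", "NB", "TB"),
    replicon = "chr",
    start = c(1855L, 5855L, 8873L, 12873L, 15855L, 28000L, 21873L),
    end = c(1900L, 5900L, 8900L, 12900L, 15900L, 28045L, 21900L),
    strand = "+", mismatches = 0L, stringsAsFactors = FALSE))
  ann <- makeAnnotation(genesDf, repliconLength = 30000L, boxes = boxes)
  linkBoxToGene(ann, 1000)
}

classifyDeg <- function() {
  ids <- c("nbLead", "nbSecond", "weakGene", "tbLead", "tbSecond",
           "decoyLead", "lowGene", "loneGene", "boxedGene", "antiGene")
  mk <- function(fc, p, meanBase = 500) makeDegTable(ids, fc, p, meanBase)
  list(
    WT = mk(fc = c(8.2, 7.0, 2.5, 10, 9, 12, 9, 2.5, 2.1, 6),
            p = c(rep(1e-8, 10)),
            meanBase = c(500, 500, 500, 500, 500, 500, 4, 500, 500, 500)),
    nodD1 = mk(fc = c(1, 1.1, 1, 1, 1, 1, 1, 1, 1, 1), p = rep(0.9, 10)),
    ttsI = mk(fc = c(7.9, 6.5, 2.4, 1, 1.2, 11, 1, 2.4, 1, 5.5),
              p = c(1e-8, 1e-8, 1e-4, 0.9, 0.8, 1e-8, 0.9, 1e-3, 0.9, 1e-6))
  )
}

test_that("epistasis rules call box functionality as the induction pattern dictates", {
  ann <- classifyFixture()
  deg <- classifyDeg()
  calls <- boxActivity(ann, deg)
  call <- setNames(calls$call, calls$box_id)
  expect_equal(call[["NB9"]], "active")          # WT + ttsI up, nodD1 silent
  expect_equal(call[["NB3"]], "weakly_active")   # 2.5-fold with the NB pattern
  expect_equal(call[["TB10"]], "active")         # WT only
  expect_equal(call[["TB7"]], "non_functional")  # persists in the ttsI mutant
  expect_equal(calls$reason[calls$box_id == "TB7"],
               "ttsI_independent_induction")
  expect_equal(call[["SB1"]], "not_testable")    # SyrM boxes are not assessed
  expect_equal(call[["NB5"]], "not_testable")    # no downstream gene
  expect_equal(calls$reason[calls$box_id == "NB5"], "no_downstream_gene")
  # regulon members come from the operon of the downstream gene
  expect_equal(calls$regulon_genes[calls$box_id == "NB9"], "nbLead,nbSecond")
})

test_that("boxes above poorly covered genes are not testable", {
  ann <- classifyFixture()
  deg <- classifyDeg()
  # point TB2 at the low-coverage gene instead
  b <- promoterBoxes(ann)
  mc <- S4Vectors::mcols(b)
  mc$downstream_gene[mc$box_id == "TB2"] <- "lowGene"
  S4Vectors::mcols(b) <- mc
  promoterBoxes(ann) <- b
  calls <- boxActivity(ann, deg, coverageFloor = 10)
  expect_equal(calls$call[calls$box_id == "TB2"], "not_testable")
  expect_equal(calls$reason[calls$box_id == "TB2"], "low_reads")
})

test_that("a design without the ttsI contrast fails loudly", {
  ann <- classifyFixture()
  deg <- classifyDeg()
  expect_error(boxActivity(ann, deg[c("WT", "nodD1")]), "ttsI")
})

test_that("the majority rule lets operon members speak for a weak lead", {
  ann <- classifyFixture()
  deg <- classifyDeg()
  # lead below threshold, second member strongly induced (in WT only)
  for (s in c("WT")) {
    deg[[s]]$FC[deg[[s]]$gene_id == "tbLead"] <- 2.2
    deg[[s]] <- callDegs(deg[[s]][, 1:7])
  }
  calls <- boxActivity(ann, deg)
  expect_equal(calls$call[calls$box_id == "TB10"], "active")
})

test_that("affected-set assembly uses all three inclusion routes", {
  ann <- classifyFixture()
  deg <- classifyDeg()
  # make the second NB operon member sub-threshold (noeI/nolK pattern)
  deg$WT$FC[deg$WT$gene_id == "nbSecond"] <- 1.8
  deg$WT <- callDegs(deg$WT[, 1:7])
  aff <- assembleAffectedSet(ann, deg, rescueFc = 2)
  route <- setNames(aff$route, aff$gene_id)
  expect_equal(route[["nbLead"]], "direct_DEG")
  expect_equal(route[["nbSecond"]], "operon_rescue")
  expect_equal(route[["boxedGene"]], "conserved_box_rescue")  # FC 2.1, exact TB
  expect_false("loneGene" %in% aff$gene_id)  # FC 2.5 but no box, no operon
  expect_false("weakGene" %in% aff$gene_id == FALSE &&
                 route[["weakGene"]] != "conserved_box_rescue")
})

test_that("discard rules drop antisense and duplicated genes with reasons", {
  set.seed(501)
  genesDf <- data.frame(
    gene_id = c("orig", "copy", "plain", "anti"),
    replicon = "chr",
    start = c(2001L, 6001L, 9001L, 12101L),
    end = c(2600L, 6600L, 9600L, 12700L),
    strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  seq <- randomDnaChars(15000)
  # make 'copy' sequence-identical to the box-controlled 'orig'
  substr(seq, 6001, 6600) <- substr(seq, 2001, 2600)
  boxes <- makeBoxGRanges(data.frame(
    box_id = c("NB1", "NB2"), box_type = "NB", replicon = "chr",
    start = c(1855L, 12001L), end = c(1900L, 12046L), strand = "+",
    mismatches = 0L, stringsAsFactors = FALSE))
  ann <- makeAnnotation(genesDf, repliconLength = 15000L,
                        seqs = c(chr = seq), boxes = boxes)
  ann <- linkBoxToGene(ann, 1000)
  aff <- data.frame(gene_id = c("orig", "copy", "plain", "anti"),
                    route = "direct_DEG", stringsAsFactors = FALSE)
  res <- applyDiscardRules(ann, aff)
  reason <- setNames(res$discards$reason, res$discards$gene_id)
  expect_equal(reason[["anti"]], "opposed_to_NB")
  expect_equal(reason[["copy"]], "identical_copy")
  expect_setequal(res$retained$gene_id, c("orig", "plain"))
  # every affected gene ends with exactly one of group / discard reason
  expect_equal(sort(c(res$retained$gene_id, res$discards$gene_id)),
               sort(aff$gene_id))
})

test_that("group assignment and dependence flags follow the DEG patterns", {
  ann <- classifyFixture()
  deg <- classifyDeg()
  calls <- boxActivity(ann, deg)
  aff <- assembleAffectedSet(ann, deg)
  filt <- applyDiscardRules(ann, aff)
  grp <- assignGroups(ann, filt$retained, calls, deg)
  g <- setNames(grp$group, grp$gene_id)
  expect_equal(g[["nbLead"]], "NB")
  expect_equal(g[["nbSecond"]], "NB")
  expect_equal(g[["weakGene"]], "NB")      # weakly active NB still claims it
  expect_equal(g[["tbLead"]], "TB")
  expect_equal(g[["decoyLead"]], "other")  # its TB is non-functional
  # decoyLead: DEG in WT and ttsI but not nodD1 -> NodD1-dependent only
  expect_true(grp$nodD1_dependent[grp$gene_id == "decoyLead"])
  expect_false(grp$ttsI_dependent[grp$gene_id == "decoyLead"])
  # a gene DEG in all three strains is independent of both regulators
  deg2 <- deg
  deg2$nodD1$FC[deg2$nodD1$gene_id == "decoyLead"] <- 9
  deg2$nodD1$pvalue[deg2$nodD1$gene_id == "decoyLead"] <- 1e-9
  deg2$nodD1 <- callDegs(deg2$nodD1[, 1:7])
  grp2 <- assignGroups(ann, filt$retained, calls, deg2)
  expect_false(grp2$nodD1_dependent[grp2$gene_id == "decoyLead"])
  expect_false(grp2$ttsI_dependent[grp2$gene_id == "decoyLead"])
})

test_that("competing NB and TB claims resolve to the nearer box with a warning", {
  ann <- classifyFixture()
  deg <- classifyDeg()
  calls <- boxActivity(ann, deg)
  # forge a second claim: pretend TB10's regulon includes nbLead
  calls$regulon_genes[calls$box_id == "TB10"] <- "tbLead,tbSecond,nbLead"
  retained <- data.frame(gene_id = "nbLead", route = "direct_DEG",
                         stringsAsFactors = FALSE)
  expect_warning(grp <- assignGroups(ann, retained, calls, deg),
                 "claimed by both")
  # NB9 sits 100 bp upstream of nbLead, nearer than the forged TB claim
  expect_equal(grp$group, "NB")
})

test_that("Venn partitions match brute-force set algebra", {
  set.seed(502)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:50) {
    sets <- list(WT = sample(pool, sample(0:40, 1)),
                 nodD1 = sample(pool, sample(0:40, 1)),
                 ttsI = sample(pool, sample(0:40, 1)))
    expect_equal(vennPartition(sets), oracleVenn(sets))
  }
  ident <- list(WT = pool[1:10], nodD1 = pool[1:10], ttsI = pool[1:10])
  v <- vennPartition(ident)
  expect_equal(unname(v[["all"]]), 10L)
  expect_equal(sum(v), 10L)
  disj <- list(WT = pool[1:5], nodD1 = pool[6:12], ttsI = pool[13:15])
  vd <- vennPartition(disj)
  expect_equal(unname(vd[c("WT_only", "nodD1_only", "ttsI_only")]),
               c(5L, 7L, 3L))
  expect_equal(sum(vd), 15L)
})

test_that("planted box calls and gene partition are recovered end to end", {
  res <- lapply(c(61, 62), function(seed) {
    sim <- simulateExperiment(simulationConfig(backgroundGenes = 60), seed)
    deg <- genisteinContrasts(sim$se)
    calls <- boxActivity(sim$annotation, deg)
    truth <- sim$truth$boxes
    strong <- truth$reason %in% c("active", "decoy", "silent", "broken_core",
                                  "no_downstream")
    want <- c(active = "active", decoy = "non_functional",
              silent = "non_functional", broken_core = "non_functional",
              no_downstream = "not_testable")
    got <- setNames(calls$call, calls$box_id)
    expect_equal(unname(got[truth$box_id[strong &
                                           truth$box_type != "SyrM"]]),
                 unname(want[truth$reason[strong & truth$box_type != "SyrM"]]))
    # full partition property: affected genes -> one group xor one discard
    aff <- assembleAffectedSet(sim$annotation, deg)
    filt <- applyDiscardRules(sim$annotation, aff)
    grp <- assignGroups(sim$annotation, filt$retained, calls, deg)
    expect_setequal(c(grp$gene_id, filt$discards$gene_id), aff$gene_id)
    expect_equal(anyDuplicated(c(grp$gene_id, filt$discards$gene_id)), 0L)
    # report consistency
    rep <- stimulonSummary(deg, sim$annotation, assignments = grp,
                           boxCalls = calls, discards = filt$discards)
    v <- rep@venn
    expect_equal(sum(v[c("WT_only", "WT_nodD1", "WT_ttsI", "all")]),
                 length(degSet(deg$WT)))
    TRUE
  })
  expect_true(all(unlist(res)))
})

test_that("mutant-background shifts are reported apart from the groups", {
  set.seed(503)
  libs <- librarySpecs(seed = 67)
  cfg <- simulationConfig(
    units = unitPlanOfClass("mutant-background", 2, induction = 0.15),
    backgroundGenes = 80, baselineRange = c(300, 800),
    replicons = data.frame(id = "chr", length = 200000L, kind = "chromosome",
                           stringsAsFactors = FALSE), boxReplicon = "chr")
  sim <- simulateGenome(cfg, 71)
  se <- simulateCounts(sim$annotation, sim$truth, libs, 72, dispersion = 0.05)
  mut <- mutantBaselineEffects(se)
  planted <- sim$truth$genes$gene_id[
    sim$truth$genes$class == "mutant-background"]
  expect_setequal(mut$gene_id, planted)
  expect_equal(unique(mut$direction), "down")
})
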