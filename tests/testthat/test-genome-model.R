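test_that("GFF3/FASTA round-trip preserves every feature field", {
  set.seed(101)
  ann <- makeAnnotation(data.frame(
    gene_id = c("gA", "gB", "gC"), replicon = "chr",
    start = c(1001L, 2501L, 4001L), end = c(2000L, 3600L, 4900L),
    strand = c("+", "+", "-"),
    operon_id = c("op1", "op1", NA),
    product = c("widget synthase", "widget exporter", NA),
    stringsAsFactors = FALSE))
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeAnnotation(ann, gff, fa)
  back <- readAnnotation(gff, fa)
  expect_equal(repliconTable(back), repliconTable(ann))
  for (col in c("gene_id", "operon_id", "product")) {
    expect_equal(S4Vectors::mcols(genes(back))[[col]],
                 S4Vectors::mcols(genes(ann))[[col]])
  }
  expect_equal(GenomicRanges::start(genes(back)),
               GenomicRanges::start(genes(ann)))
  expect_equal(GenomicRanges::end(genes(back)), GenomicRanges::end(genes(ann)))
  expect_equal(as.character(GenomicRanges::strand(genes(back))),
               as.character(GenomicRanges::strand(genes(ann))))
  expect_equal(as.character(genomeSequences(back)),
               as.character(genomeSequences(ann)))
  expect_equal(operons(back), operons(ann))
  # a second write is byte-identical (writer determinism)
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeAnnotation(back, gff2, fa2)
  writeAnnotation(ann, gff, fa)
  expect_identical(readLines(gff), readLines(gff2))
  expect_identical(readLines(fa), readLines(fa2))
})

test_that("a gene beyond its replicon bound is rejected by name", {
  set.seed(102)
  expect_error(
    makeAnnotation(data.frame(
      gene_id = "runaway", replicon = "chr", start = 9500L, end = 10500L,
      strand = "+", stringsAsFactors = FALSE), repliconLength = 10000L),
    "runaway")
})

test_that("GFF3 seqids missing from the FASTA are a hard error", {
  set.seed(103)
  ann <- makeAnnotation(data.frame(
    gene_id = c("g1", "g2"), replicon = c("chr", "plas"),
    start = c(100L, 100L), end = c(700L, 700L), strand = "+",
    stringsAsFactors = FALSE), repliconLength = c(5000L, 3000L))
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeAnnotation(ann, gff, fa)
  Biostrings::writeXStringSet(genomeSequences(ann)["chr"], fa)
  expect_error(readAnnotation(gff, fa), "plas")
})

test_that("upstream windows follow the offset convention on both strands", {
  set.seed(104)
  ann <- makeAnnotation(data.frame(
    gene_id = c("plus", "minus", "edge"), replicon = "chr",
    start = c(1001L, 3001L, 30L), end = c(1600L, 3600L, 500L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE))
  s <- as.character(genomeSequences(ann)[["chr"]])
  w <- upstreamWindow(ann, "plus", 100)
  expect_equal(w$positions, 901:1000)
  expect_equal(w$offsets, -100:-1)
  expect_equal(w$sequence, substr(s, 901, 1000))
  # minus strand: upstream = reverse complement of the 3'-flanking segment
  w2 <- upstreamWindow(ann, "minus", 80)
  expect_equal(w2$sequence, oracleRevComp(substr(s, 3601, 3680)))
  expect_equal(w2$positions, 3680:3601)
  # truncation at the replicon edge keeps the -1 anchor
  w3 <- upstreamWindow(ann, "edge", 100)
  expect_equal(w3$offsets, -29:-1)
  expect_equal(w3$positions, 1:29)
  expect_error(upstreamWindow(ann, "nope", 50), "unknown gene")
})

test_that("box linking records offsets, no-gene cases and opposed genes", {
  set.seed(105)
  genesDf <- data.frame(
    gene_id = c("target", "anti"), replicon = "chr",
    start = c(2001L, 5101L), end = c(2600L, 5700L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  boxes <- makeBoxGRanges(data.frame(
    box_id = c("NB1", "NB2", "NB3"), box_type = "NB", replicon = "chr",
    start = c(1755L, 8000L, 5001L), end = c(1800L, 8045L, 5046L),
    strand = "+", stringsAsFactors = FALSE))
  ann <- makeAnnotation(genesDf, boxes = boxes)
  ann <- linkBoxToGene(ann, maxDistance = 1000)
  mc <- S4Vectors::mcols(promoterBoxes(ann))
  # NB1 sits 200 bp upstream of 'target'
  expect_equal(mc$downstream_gene[1], "target")
  expect_equal(mc$offset_end[1], -201L)
  expect_equal(mc$offset_start[1], -246L)
  expect_false(mc$opposed[1])
  # NB2 has no gene within 1 kb 3' of it
  expect_true(is.na(mc$downstream_gene[2]))
  # NB3's nearest 3' gene is antisense
  expect_true(mc$opposed[3])
  expect_equal(mc$opposed_gene[3], "anti")
})

test_that("operon inference obeys the gap threshold and keeps input tags", {
  set.seed(106)
  two <- makeAnnotation(data.frame(
    gene_id = c("a", "b"), replicon = "chr",
    start = c(1000L, 1751L), end = c(1700L, 2400L), strand = "+",
    stringsAsFactors = FALSE))
  joined <- inferOperons(two, maxGap = 200)
  expect_equal(length(unique(operons(joined)$operon_id)), 1L)
  split2 <- inferOperons(two, maxGap = 20)
  expect_equal(length(unique(operons(split2)$operon_id)), 2L)
  # pre-existing tags win and break chains for the neighbours
  tagged <- makeAnnotation(data.frame(
    gene_id = c("a", "b", "c"), replicon = "chr",
    start = c(1000L, 1751L, 2501L), end = c(1700L, 2400L, 3100L),
    strand = "+", operon_id = c(NA, "keepme", NA),
    stringsAsFactors = FALSE))
  res <- inferOperons(tagged, maxGap = 500)
  mc <- S4Vectors::mcols(genes(res))
  expect_equal(mc$operon_id[mc$gene_id == "b"], "keepme")
  expect_false(mc$operon_id[mc$gene_id == "a"] ==
                 mc$operon_id[mc$gene_id == "c"])
})

test_that("operon inference matches the brute-force gap scan on random layouts", {
  set.seed(107)
  for (rep in 1:100) {
    nGenes <- sample(4:14, 1)
    maxGap <- sample(c(50, 200, 400), 1)
    starts <- cumsum(sample(100:600, nGenes, TRUE))
    lens <- sample(80:300, nGenes, TRUE)
    df <- data.frame(
      gene_id = sprintf("g%02d", seq_len(nGenes)),
      replicon = sample(c("r1", "r2"), nGenes, TRUE),
      start = starts, end = starts + lens,
      strand = sample(c("+", "-"), nGenes, TRUE),
      stringsAsFactors = FALSE)
    ann <- makeAnnotation(df, repliconLength = max(df$end) + 100L,
                          repliconIds = c("r1", "r2"))
    res <- inferOperons(ann, maxGap)
    got <- S4Vectors::mcols(genes(res))$operon_id
    ids <- S4Vectors::mcols(genes(res))$gene_id
    want <- oracleOperonGroups(df, maxGap)[match(ids, df$gene_id)]
    # same partition (labels may differ)
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
  }
})

test_that("operon helpers report transcription order and gene sequences", {
  set.seed(108)
  ann <- makeAnnotation(data.frame(
    gene_id = c("x1", "x2"), replicon = "chr",
    start = c(1000L, 1801L), end = c(1700L, 2500L), strand = "-",
    operon_id = "opX", stringsAsFactors = FALSE))
  # minus strand: transcription runs right to left
  expect_equal(operonMembers(ann, "opX"), c("x2", "x1"))
  expect_equal(operonLead(ann, "opX"), "x2")
  expect_equal(operonOf(ann, "x1"), "opX")
  s <- as.character(genomeSequences(ann)[["chr"]])
  expect_equal(geneSequence(ann, "x1"), oracleRevComp(substr(s, 1000, 1700)))
})
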