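#' Library design for the three-strain knockout experiment
#'
#' Builds the full strain x inducer design: 3 strains (WT, nodD1, ttsI)
#' x 2 conditions (with / without genistein) x `nReplicates` biological
#' replicates.  Sequencing-depth factors are drawn log-uniformly from
#' `depthRange` so that the normalization stage has real work to do.
#'
#' @param nReplicates Biological replicates per cell (default 2, giving
#'   the canonical 12-library design).
#' @param depthRange Range for log-uniform depth factors (default
#'   `c(0.7, 1.4)`).
#' @param seed RNG seed for the depth draws.
#' @return `data.frame`: `library_id`, `strain`, `genistein`, `replicate`,
#'   `depth_factor`.
#' @export
librarySpecs <- function(nReplicates = 2, depthRange = c(0.7, 1.4), seed = 1) {
  stopifnot(nReplicates >= 1, all(depthRange > 0))
  d <- expand.grid(replicate = seq_len(nReplicates),
                   genistein = c(FALSE, TRUE),
                   strain = c("WT", "nodD1", "ttsI"),
                   stringsAsFactors = FALSE)
  d <- d[, c("strain", "genistein", "replicate")]
  d$library_id <- sprintf("%s_%s_r%d", d$strain,
                          ifelse(d$genistein, "gen", "ctl"), d$replicate)
  set.seed(seed)
  d$depth_factor <- exp(stats::runif(nrow(d), log(depthRange[1]),
                                     log(depthRange[2])))
  d[, c("library_id", "strain", "genistein", "replicate", "depth_factor")]
}

# Regulon classes understood by the effect model.
REGULON_CLASSES <- c("NB", "TB", "SyrM", "independent-up", "independent-down",
                     "background", "mutant-background")

#' Expected expression effect of a gene in one design cell
#'
#' Encodes where each regulon class is induced, relative to the wild-type
#' no-genistein baseline: NB-class genes respond to genistein in the wild
#' type and the ttsI knockout but not the nodD1 knockout; TB-class genes
#' respond in the wild type only; SyrM-class genes behave like NB-class
#' ones (NodD1-dependent, TtsI-independent) unless `syrmInTtsI = FALSE`;
#' independent classes respond to genistein in every strain; the
#' mutant-background class is altered in both knockouts regardless of
#' genistein; background genes never move.
#'
#' @param class Regulon class (one of `r toString(REGULON_CLASSES)`).
#' @param induction Multiplicative effect size (>= 1 for up classes,
#'   in (0, 1\] for down classes).
#' @param strain,genistein Design cell.
#' @param syrmInTtsI Whether SyrM-class induction persists in the ttsI
#'   knockout (default `TRUE`).
#' @return Positive multiplicative factor.
#' @export
effectFactor <- function(class, induction, strain, genistein,
                         syrmInTtsI = TRUE) {
  switch(class,
    "background" = 1,
    "NB" = if (genistein && strain %in% c("WT", "ttsI")) induction else 1,
    "TB" = if (genistein && strain == "WT") induction else 1,
    "SyrM" = if (genistein &&
                 (strain == "WT" || (syrmInTtsI && strain == "ttsI")))
               induction else 1,
    "independent-up" = if (genistein) induction else 1,
    "independent-down" = if (genistein) induction else 1,
    "mutant-background" = if (strain != "WT") induction else 1,
    stop(sprintf("unknown regulon class '%s'", class))
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic genome + counts generator.  The
#' defaults emulate the study system at desk scale: a 7-replicon genome of
#' about 200 kb and 350 genes whose symbiotic-plasmid analogue (`pD`)
#' carries nod boxes (11 active, 1 weakly active, 1 silent, 2 without a
#' downstream gene), tts boxes (11 active, 1 TtsI-independent decoy, 6
#' with a broken `CGN2AG` core) and a SyrM box, alongside
#' genistein-independent and mutant-background special cases.
#'
#' @param replicons Replicon table (`id`, `length`, `kind`).
#' @param units Transcription-unit plan: `data.frame` with `class`
#'   (regulon class), `n_genes`, `box_type` (`NA`, `"NB"`, `"TB"`,
#'   `"SyrM"`), `box_status` (`"active"`, `"weak"`, `"decoy"`, `"silent"`,
#'   `"broken_core"`, `"no_downstream"`, `NA`), `induction` (`NA` = draw
#'   from `inductionRange`), `replicon` (`NA` = spread by free space).
#' @param backgroundGenes Number of unregulated singleton genes added to
#'   the plan.
#' @param baselineRange Log-uniform range of per-kilobase baseline
#'   expression means.
#' @param dispersion Negative-binomial dispersion (0 recovers Poisson).
#' @param inductionRange Log-uniform range for drawn induction factors of
#'   up classes; the default `c(8, 30)` mirrors the strong inductions seen
#'   for functional boxes (printed log2 fold-changes of ~3-4.7).
#' @param downRange Log-uniform range for drawn repression factors of down
#'   classes.
#' @param geneLengthRange,intraGapRange,interGapRange Uniform ranges (bp)
#'   for gene lengths, within-operon gaps and between-unit gaps.
#' @param boxOffsetRange Range of the distance (bp) between a planted
#'   box's 3' end and the downstream translation start.
#' @param boxMismatches Mismatches inserted into planted (non-broken)
#'   boxes; 0 means exact consensus copies.
#' @param nReplicates,depthRange Passed to [librarySpecs()].
#' @param boxReplicon Preferred replicon for box-bearing units.
#' @param patterns Named list of [MotifPattern-class] objects for `NB`,
#'   `TB`, `SyrM`.
#' @return A `stimulon_sim_config` list.
#' @seealso [simulateGenome()], [simulateCounts()]
#' @export
simulationConfig <- function(
    replicons = data.frame(
      id = c("chr", "pA1", "pA2", "pB", "pC", "pD", "pE"),
      length = c(70000L, 6000L, 7000L, 9000L, 22000L, 70000L, 30000L),
      kind = c("chromosome", rep("plasmid", 6)),
      stringsAsFactors = FALSE),
    units = defaultUnitPlan(),
    backgroundGenes = 180,
    baselineRange = c(150, 600),
    dispersion = 0.05,
    inductionRange = c(8, 30),
    downRange = c(0.15, 0.35),
    geneLengthRange = c(300L, 900L),
    intraGapRange = c(20L, 80L),
    interGapRange = c(250L, 450L),
    boxOffsetRange = c(30L, 150L),
    boxMismatches = 0,
    nReplicates = 2,
    depthRange = c(0.7, 1.4),
    boxReplicon = "pD",
    patterns = list(NB = nbConsensusPattern(), TB = tbConsensusPattern(),
                    SyrM = syrmBoxPattern())) {
  cfg <- list(replicons = replicons, units = units,
              backgroundGenes = backgroundGenes,
              baselineRange = baselineRange, dispersion = dispersion,
              inductionRange = inductionRange, downRange = downRange,
              geneLengthRange = geneLengthRange,
              intraGapRange = intraGapRange, interGapRange = interGapRange,
              boxOffsetRange = boxOffsetRange, boxMismatches = boxMismatches,
              nReplicates = nReplicates, depthRange = depthRange,
              boxReplicon = boxReplicon, patterns = patterns)
  class(cfg) <- "stimulon_sim_config"
  cfg
}

unitRow <- function(class, n_genes, box_type = NA_character_,
                    box_status = NA_character_, induction = NA_real_,
                    replicon = NA_character_, n = 1) {
  data.frame(class = rep(class, n), n_genes = rep(as.integer(n_genes), n),
             box_type = rep(box_type, n), box_status = rep(box_status, n),
             induction = rep(induction, n), replicon = rep(replicon, n),
             stringsAsFactors = FALSE)
}

#' Default transcription-unit plan
#'
#' Mirrors the study's promoter-box inventory: 15 nod boxes (11 active,
#' one weakly active at 2.5-fold, one silent above an uninduced gene, two
#' without any downstream gene), 18 tts boxes (11 active, one decoy whose
#' operon stays induced in the ttsI knockout because a SyrM-type effect
#' drives it, six with a corrupted core above unresponsive genes), one
#' SyrM-box operon, one gene induced and one three-gene operon repressed
#' independently of both regulators, and one mutant-background gene.
#'
#' @return Unit-plan `data.frame` (see [simulationConfig()]).
#' @export
defaultUnitPlan <- function() {
  rbind(
    unitRow("NB", 2, "NB", "active", n = 6),
    unitRow("NB", 3, "NB", "active", n = 5),
    unitRow("NB", 1, "NB", "weak", induction = 2.5),
    unitRow("background", 1, "NB", "silent"),
    unitRow("background", 0, "NB", "no_downstream", n = 2),
    unitRow("TB", 2, "TB", "active", n = 6),
    unitRow("TB", 3, "TB", "active", n = 3),
    unitRow("TB", 2, "TB", "active", replicon = "pC", n = 2),
    unitRow("SyrM", 2, "TB", "decoy"),
    unitRow("background", 2, "TB", "broken_core", n = 6),
    unitRow("SyrM", 3, "SyrM", "active"),
    unitRow("independent-up", 1, induction = 6),
    unitRow("independent-down", 3),
    unitRow("mutant-background", 1)
  )
}

#' Simulate a genome with planted regulatory structure
#'
#' Lays out the configured transcription units along the replicons (box
#' units preferentially on the symbiotic-plasmid analogue, background
#' genes spread by free space), plants promoter boxes as exact or
#' k-mismatch instantiations of their consensus patterns upstream of their
#' operon leads, corrupts the mandatory core of `broken_core` tts boxes,
#' leaves `no_downstream` boxes with no gene within 1 kb 3' of them, and
#' returns the machine-readable truth table next to the annotation.
#' Deterministic given `seed`.
#'
#' @param config A [simulationConfig()] list.
#' @param seed Integer RNG seed.
#' @return List with `annotation` ([GenomeAnnotation-class]), `truth`
#'   (list of `genes` and `boxes` data.frames), `config`, `seed`.
#' @export
simulateGenome <- function(config, seed) {
  stopifnot(inherits(config, "stimulon_sim_config"))
  set.seed(seed)
  rep <- config$replicons
  units <- config$units
  # append background singletons
  if (config$backgroundGenes > 0) {
    units <- rbind(units, unitRow("background", 1, n = config$backgroundGenes))
  }
  n <- nrow(units)
  units$unit_id <- sprintf("u%03d", seq_len(n))
  # draw induction factors where unset
  up <- is.na(units$induction) &
    units$class %in% c("NB", "TB", "SyrM", "independent-up")
  units$induction[up] <- exp(stats::runif(sum(up), log(config$inductionRange[1]),
                                          log(config$inductionRange[2])))
  down <- is.na(units$induction) &
    units$class %in% c("independent-down", "mutant-background")
  units$induction[down] <- exp(stats::runif(sum(down), log(config$downRange[1]),
                                            log(config$downRange[2])))
  units$induction[is.na(units$induction)] <- 1
  units$strand <- sample(c("+", "-"), n, replace = TRUE)
  units$strand[!is.na(units$box_status) &
               units$box_status == "no_downstream"] <- "+"

  cursor <- stats::setNames(rep(1L, nrow(rep)), rep$id)
  geneRows <- list(); boxRows <- list(); opRows <- list()
  geneCounter <- stats::setNames(rep(0L, nrow(rep)), rep$id)
  boxCounter <- c(NB = 0L, TB = 0L, SyrM = 0L)
  patch <- list()  # planted box sequences to splice into the replicons

  # place box units first so the preferred replicon can host them
  ord <- order(is.na(units$box_type), sample.int(n))
  for (i in ord) {
    u <- units[i, ]
    hasBox <- !is.na(u$box_type)
    pat <- if (hasBox) config$patterns[[u$box_type]] else NULL
    plen <- if (hasBox) patternLength(pat) else 0L
    glen <- if (u$n_genes > 0)
      sample(seq(config$geneLengthRange[1], config$geneLengthRange[2]),
             u$n_genes, replace = TRUE) else integer(0)
    gaps <- if (u$n_genes > 1)
      sample(seq(config$intraGapRange[1], config$intraGapRange[2]),
             u$n_genes - 1L, replace = TRUE) else integer(0)
    off <- if (hasBox)
      sample(seq(config$boxOffsetRange[1], config$boxOffsetRange[2]), 1L)
      else 0L
    preGap <- sample(seq(config$interGapRange[1], config$interGapRange[2]), 1L)
    boxRoom <- if (hasBox) off + plen + 20L else 0L
    if (hasBox && u$strand == "+") preGap <- max(preGap, boxRoom)
    postReserve <- 0L
    if (hasBox && u$strand == "-") postReserve <- boxRoom
    if (hasBox && !is.na(u$box_status) && u$box_status == "no_downstream") {
      postReserve <- 1000L + 100L   # keep the 3' side gene-free beyond 1 kb
    }
    need <- preGap + sum(glen) + sum(gaps) + postReserve
    # choose a replicon: stated preference, then box replicon, then most free
    free <- rep$length - cursor[rep$id] + 1L
    prefs <- c(if (!is.na(u$replicon)) u$replicon,
               if (hasBox) config$boxReplicon,
               rep$id[order(free, decreasing = TRUE)])
    prefs <- unique(prefs)
    target <- NA_character_
    for (r in prefs) {
      if (cursor[r] + need + 50L <= rep$length[rep$id == r]) { target <- r; break }
    }
    if (is.na(target)) {
      stop(sprintf("infeasible packing: unit %s (%d bp) does not fit on any replicon",
                   u$unit_id, need))
    }
    pos <- cursor[target] + preGap
    starts <- integer(u$n_genes); ends <- integer(u$n_genes)
    p <- pos
    for (k in seq_len(u$n_genes)) {
      starts[k] <- p; ends[k] <- p + glen[k] - 1L
      p <- ends[k] + (if (k < u$n_genes) gaps[k] + 1L else 1L)
    }
    cursor[target] <- (if (u$n_genes > 0) ends[u$n_genes] else pos) +
      postReserve + 1L
    # gene records; transcription order: left-to-right for +, reversed for -
    ids <- character(u$n_genes)
    if (u$n_genes > 0) {
      idxTx <- if (u$strand == "-") rev(seq_len(u$n_genes)) else seq_len(u$n_genes)
      opId <- if (u$n_genes >= 1) sprintf("op_%s", u$unit_id) else NA_character_
      for (k in seq_len(u$n_genes)) {
        geneCounter[target] <- geneCounter[target] + 1L
        ids[k] <- sprintf("%s_%04d", target, geneCounter[target])
      }
      for (k in seq_len(u$n_genes)) {
        geneRows[[length(geneRows) + 1L]] <- data.frame(
          gene_id = ids[k], replicon = target, start = starts[k],
          end = ends[k], strand = u$strand, operon_id = opId,
          unit_id = u$unit_id, class = u$class, induction = units$induction[i],
          stringsAsFactors = FALSE)
      }
      for (j in seq_along(idxTx)) {
        opRows[[length(opRows) + 1L]] <- data.frame(
          operon_id = opId, gene_id = ids[idxTx[j]], idx = j,
          stringsAsFactors = FALSE)
      }
    }
    # box record + planted sequence
    if (hasBox) {
      boxCounter[u$box_type] <- boxCounter[u$box_type] + 1L
      bid <- sprintf("%s%d", if (u$box_type == "SyrM") "SB" else u$box_type,
                     boxCounter[u$box_type])
      status <- u$box_status
      broken <- !is.na(status) && status == "broken_core"
      boxSeq <- instantiatePattern(pat, mismatches = config$boxMismatches,
                                   corruptCore = broken)
      if (u$n_genes > 0) {
        leadStart <- if (u$strand == "-") ends[u$n_genes] else starts[1]
        lead <- if (u$strand == "-") ids[u$n_genes] else ids[1]
        if (u$strand == "-") {
          bstart <- leadStart + off; bend <- bstart + plen - 1L
        } else {
          bend <- leadStart - off; bstart <- bend - plen + 1L
        }
        downGene <- lead
        offEnd <- -off; offStart <- -(off + plen - 1L)
      } else {
        bstart <- pos; bend <- pos + plen - 1L
        downGene <- NA_character_; offEnd <- NA_integer_; offStart <- NA_integer_
      }
      boxRows[[length(boxRows) + 1L]] <- data.frame(
        box_id = bid, box_type = u$box_type, replicon = target,
        start = bstart, end = bend, strand = u$strand,
        downstream_gene = downGene, offset_start = offStart,
        offset_end = offEnd, unit_id = u$unit_id, status = status,
        stringsAsFactors = FALSE)
      patch[[length(patch) + 1L]] <- list(replicon = target, start = bstart,
                                          seq = if (u$strand == "-")
                                            revComp(boxSeq) else boxSeq)
    }
  }

  gdf <- do.call(rbind, geneRows)
  gdf <- gdf[order(gdf$replicon, gdf$start), , drop = FALSE]
  bdf <- if (length(boxRows)) do.call(rbind, boxRows) else NULL
  opdf <- if (length(opRows)) do.call(rbind, opRows) else
    data.frame(operon_id = character(), gene_id = character(), idx = integer())

  # replicon sequences with planted boxes spliced in
  seqs <- Biostrings::DNAStringSet(vapply(rep$length, randomDna, character(1)))
  names(seqs) <- rep$id
  for (pt in patch) {
    s <- as.character(seqs[[pt$replicon]])
    substr(s, pt$start, pt$start + nchar(pt$seq) - 1L) <- pt$seq
    seqs[[pt$replicon]] <- Biostrings::DNAString(s)
  }

  g <- GenomicRanges::GRanges(gdf$replicon,
                              IRanges::IRanges(gdf$start, gdf$end),
                              strand = gdf$strand)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    gene_id = gdf$gene_id, operon_id = gdf$operon_id,
    product = sprintf("%s-class synthetic gene", gdf$class))
  bx <- NULL
  if (!is.null(bdf)) {
    bx <- GenomicRanges::GRanges(bdf$replicon,
                                 IRanges::IRanges(bdf$start, bdf$end),
                                 strand = bdf$strand)
    S4Vectors::mcols(bx) <- S4Vectors::DataFrame(
      box_id = bdf$box_id, box_type = bdf$box_type,
      downstream_gene = bdf$downstream_gene,
      offset_start = bdf$offset_start, offset_end = bdf$offset_end,
      opposed = FALSE, opposed_gene = NA_character_,
      mismatches = ifelse(bdf$status == "broken_core", NA_integer_,
                          as.integer(config$boxMismatches)))
  }
  ann <- GenomeAnnotation(rep, g, operons = opdf, boxes = bx, sequences = seqs)

  # truth tables
  gdf$baseline_mean <- exp(stats::runif(nrow(gdf), log(config$baselineRange[1]),
                                        log(config$baselineRange[2])))
  cells <- expand.grid(strain = c("WT", "nodD1", "ttsI"),
                       genistein = c(FALSE, TRUE), stringsAsFactors = FALSE)
  fcCols <- matrix(NA_real_, nrow(gdf), nrow(cells))
  for (j in seq_len(nrow(cells))) {
    fcCols[, j] <- mapply(effectFactor, gdf$class, gdf$induction,
                          MoreArgs = list(strain = cells$strain[j],
                                          genistein = cells$genistein[j]))
  }
  colnames(fcCols) <- sprintf("fc_%s_%s", cells$strain,
                              ifelse(cells$genistein, "gen", "ctl"))
  truthGenes <- cbind(
    gdf[, c("gene_id", "replicon", "unit_id", "operon_id", "class",
            "induction", "baseline_mean")],
    as.data.frame(fcCols))
  rownames(truthGenes) <- NULL
  truthBoxes <- NULL
  if (!is.null(bdf)) {
    truthBoxes <- data.frame(
      box_id = bdf$box_id, box_type = bdf$box_type, unit_id = bdf$unit_id,
      lead_gene = bdf$downstream_gene,
      planted = vapply(seq_len(nrow(bdf)), function(k) {
        switch(bdf$status[k],
               active = "active", weak = "weakly-active",
               decoy = , silent = , broken_core = "non-functional",
               no_downstream = "no-downstream-gene", "non-functional")
      }, character(1)),
      reason = bdf$status, stringsAsFactors = FALSE)
  } else {
    truthBoxes <- data.frame(box_id = character(), box_type = character(),
                             unit_id = character(), lead_gene = character(),
                             planted = character(), reason = character())
  }
  truth <- list(genes = truthGenes, boxes = truthBoxes)
  attr(truth, "dispersion") <- config$dispersion
  list(annotation = ann, truth = truth, config = config, seed = seed)
}

#' Simulate a count matrix over a library design
#'
#' Per gene and library, the count is negative-binomial with mean
#' `baseline * effect(class, strain, genistein) * length/1kb * depth` and
#' the configured dispersion; dispersion 0 recovers Poisson sampling.
#' Deterministic given `seed`.
#'
#' @param annotation A [GenomeAnnotation-class] from [simulateGenome()].
#' @param truth The matching truth list (`$genes` must cover every gene).
#' @param libraries Library table from [librarySpecs()].
#' @param seed Integer RNG seed.
#' @param dispersion NB dispersion; defaults to the generating config's.
#' @return A [StimulonExperiment-class] with the truth stored in
#'   `metadata()`.
#' @export
simulateCounts <- function(annotation, truth, libraries, seed,
                           dispersion = NULL) {
  tg <- truth$genes
  g <- genes(annotation)
  ids <- S4Vectors::mcols(g)$gene_id
  if (!all(ids %in% tg$gene_id)) {
    stop("truth table does not cover every annotated gene")
  }
  tg <- tg[match(ids, tg$gene_id), , drop = FALSE]
  if (is.null(dispersion)) dispersion <- attr(truth, "dispersion") %||% 0
  set.seed(seed)
  lens <- GenomicRanges::width(g) / 1000
  nG <- length(ids); nL <- nrow(libraries)
  mu <- matrix(0, nG, nL)
  for (j in seq_len(nL)) {
    eff <- tg[[sprintf("fc_%s_%s", libraries$strain[j],
                       ifelse(libraries$genistein[j], "gen", "ctl"))]]
    mu[, j] <- tg$baseline_mean * eff * lens * libraries$depth_factor[j]
  }
  cts <- if (dispersion > 0) {
    matrix(stats::rnbinom(nG * nL, mu = mu, size = 1 / dispersion), nG, nL)
  } else {
    matrix(stats::rpois(nG * nL, lambda = mu), nG, nL)
  }
  rownames(cts) <- ids
  colnames(cts) <- libraries$library_id
  se <- StimulonExperiment(cts, libraries)
  S4Vectors::metadata(se)$truth <- truth
  S4Vectors::metadata(se)$seed <- seed
  se
}

#' Simulate a full experiment in one call
#'
#' Convenience wrapper: [simulateGenome()] with `seed`, [librarySpecs()]
#' with `seed + 1`, [simulateCounts()] with `seed + 2`.
#'
#' @param config A [simulationConfig()].
#' @param seed Integer seed (derived seeds stay below 2^31).
#' @return List with `annotation`, `truth`, `libraries`, `se`.
#' @export
simulateExperiment <- function(config, seed) {
  sim <- simulateGenome(config, seed)
  libs <- librarySpecs(config$nReplicates, config$depthRange, seed = seed + 1L)
  se <- simulateCounts(sim$annotation, sim$truth, libs, seed = seed + 2L,
                       dispersion = config$dispersion)
  list(annotation = sim$annotation, truth = sim$truth, libraries = libs,
       se = se, config = config, seed = seed)
}

#' Benchmark design: tts-box recovery under knockout epistasis
#'
#' A two-replicon genome planting 18 tts-box-preceded operons: 11 induced
#' only in the wild type (the TtsI-dependent pattern), one decoy whose
#' operon stays induced in the ttsI knockout (SyrM-type drive), and six
#' silent boxes with corrupted cores above unresponsive operons, plus
#' unregulated background genes.  Baseline per-kb means of at least 400
#' over 0.6-1.2 kb genes keep every expected count above ~240, and
#' induction factors of 8-30x sit far above the 3-fold calling threshold,
#' so the epistasis classifier should recover exactly the planted calls.
#'
#' @return A [simulationConfig()].
#' @export
ttsBoxRecoveryConfig <- function() {
  units <- rbind(
    unitRow("TB", 2, "TB", "active", n = 6),
    unitRow("TB", 3, "TB", "active", n = 5),
    unitRow("SyrM", 2, "TB", "decoy"),
    unitRow("background", 2, "TB", "broken_core", n = 6)
  )
  simulationConfig(
    replicons = data.frame(
      id = c("chr", "pSym"), length = c(80000L, 90000L),
      kind = c("chromosome", "plasmid"), stringsAsFactors = FALSE),
    units = units, backgroundGenes = 60,
    baselineRange = c(400, 800), geneLengthRange = c(600L, 1200L),
    dispersion = 0.05, boxReplicon = "pSym")
}

#' Benchmark design: regulator dependence of boxless responsive genes
#'
#' Plants 30 genistein-responsive genes with no promoter box: 17 that
#' lose induction in the nodD1 knockout only (NodD1-dependent,
#' TtsI-independent), 7 induced in the wild type only (dependent on both
#' regulators) and 6 induced in every strain, plus background genes.  A
#' correct dependence caller flags 24 of the 30 as NodD1-dependent and 7
#' as TtsI-dependent.
#'
#' @return A [simulationConfig()].
#' @export
boxlessDependenceConfig <- function() {
  units <- rbind(
    unitRow("SyrM", 1, n = 17),          # induced in WT and ttsI-, not nodD1-
    unitRow("TB", 1, n = 7),             # induced in WT only
    unitRow("independent-up", 1, n = 6)  # induced in all three strains
  )
  simulationConfig(
    replicons = data.frame(id = "chr", length = 150000L,
                           kind = "chromosome", stringsAsFactors = FALSE),
    units = units, backgroundGenes = 70,
    baselineRange = c(400, 800), geneLengthRange = c(600L, 1200L),
    dispersion = 0.05, boxReplicon = "chr")
}

#' Write simulator outputs to disk
#'
#' Emits FASTA + GFF3 (via [writeAnnotation()]), a boxes TSV, a counts
#' TSV, a library-spec TSV and the truth tables, all plain text.
#'
#' @param sim Result of [simulateExperiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeAnnotation(sim$annotation, file.path(dir, "genome.gff3"),
                  file.path(dir, "genome.fasta"))
  writeBoxTable(promoterBoxes(sim$annotation), file.path(dir, "boxes.tsv"))
  writeCountsTsv(sim$se, file.path(dir, "counts.tsv"))
  writeTsv(sim$libraries, file.path(dir, "libraries.tsv"))
  writeTsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  writeTsv(sim$truth$boxes, file.path(dir, "truth_boxes.tsv"))
  invisible(dir)
}
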