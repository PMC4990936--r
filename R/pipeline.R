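#' Pipeline configuration
#'
#' Assembles and validates the single configuration object driving
#' [runPipeline()].  Either a `simulate` block (a [simulationConfig()]) or
#' the paths to an annotation (GFF3 + FASTA), a boxes TSV, a counts TSV
#' and a library TSV must be supplied.
#'
#' @param simulate Optional [simulationConfig()]; when present the
#'   pipeline generates its own inputs.
#' @param gff3,fasta,boxes,counts,libraries Input paths (ignored when
#'   `simulate` is given).
#' @param qpcr Optional Ct-table path; when present the qPCR stage runs
#'   with `qpcrTreated` / `qpcrControl` condition labels.
#' @param qpcrTreated,qpcrControl Condition labels for the qPCR stage.
#' @param fc,alpha DEG thresholds (defaults 3 and 0.05).
#' @param weakFc Weak-activity fold-change bound (must satisfy
#'   `fc > weakFc > 1`).
#' @param rescueFc Conserved-box rescue threshold.
#' @param operonGap Operon-inference gap (bp), used when the annotation
#'   carries no operon tags.
#' @param coverageFloor Box testability floor (mean baseline count).
#' @param scanWindow,scanBudget Upstream SyrM-box scan parameters.
#' @param linkDistance Box-to-gene linking distance (bp).
#' @param seed Integer seed for the simulate stage.
#' @return A validated `stimulon_config` list.
#' @export
pipelineConfig <- function(simulate = NULL, gff3 = NULL, fasta = NULL,
                           boxes = NULL, counts = NULL, libraries = NULL,
                           qpcr = NULL, qpcrTreated = "gen",
                           qpcrControl = "ctl", fc = 3, alpha = 0.05,
                           weakFc = 2, rescueFc = 2, operonGap = 200,
                           coverageFloor = 10, scanWindow = 900,
                           scanBudget = 2, linkDistance = 1000, seed = 1) {
  cfg <- list(simulate = simulate, gff3 = gff3, fasta = fasta, boxes = boxes,
              counts = counts, libraries = libraries, qpcr = qpcr,
              qpcrTreated = qpcrTreated, qpcrControl = qpcrControl,
              fc = fc, alpha = alpha, weakFc = weakFc, rescueFc = rescueFc,
              operonGap = operonGap, coverageFloor = coverageFloor,
              scanWindow = scanWindow, scanBudget = scanBudget,
              linkDistance = linkDistance, seed = as.integer(seed))
  class(cfg) <- "stimulon_config"
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("config invalid: alpha must lie in (0, 1)")
  }
  for (f in c("fc", "weakFc", "rescueFc", "operonGap", "coverageFloor",
              "scanWindow", "linkDistance")) {
    if (!(is.numeric(cfg[[f]]) && cfg[[f]] > 0)) {
      stop(sprintf("config invalid: %s must be positive", f))
    }
  }
  if (!(cfg$fc > cfg$weakFc && cfg$weakFc > 1)) {
    stop("config invalid: need fc > weakFc > 1")
  }
  if (cfg$scanBudget < 0) stop("config invalid: scanBudget must be >= 0")
  if (is.null(cfg$simulate)) {
    need <- c("gff3", "fasta", "counts", "libraries")
    miss <- need[vapply(cfg[need], is.null, logical(1))]
    if (length(miss)) {
      stop(sprintf("config invalid: without a simulate block, %s must be set",
                   paste(miss, collapse = ", ")))
    }
  } else if (!inherits(cfg$simulate, "stimulon_sim_config")) {
    stop("config invalid: simulate must be a simulationConfig()")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar keys mirror the [pipelineConfig()] arguments; a `simulate: true`
#' key requests the default [simulationConfig()] (a mapping under
#' `simulate` overrides scalar fields of it).
#'
#' @param path YAML path.
#' @return A validated `stimulon_config`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim <- simulationConfig()
    if (is.list(y$simulate)) {
      for (nm in intersect(names(y$simulate),
                           c("backgroundGenes", "dispersion", "nReplicates",
                             "boxMismatches"))) {
        sim[[nm]] <- y$simulate[[nm]]
      }
    }
  }
  args <- y[setdiff(names(y), "simulate")]
  do.call(pipelineConfig, c(list(simulate = sim), args))
}

#' Run the full stimulon pipeline
#'
#' Orchestrates simulate (or load) -> normalize/DE -> SyrM-box scan ->
#' classify -> report.  Every output file carries the configuration hash
#' and seed in its header so that reruns are traceable; a rerun with the
#' same configuration is byte-identical.  Any stage failure aborts with
#' the stage name.
#'
#' @param config A `stimulon_config` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @param outputDir Directory for stage outputs (created if needed).
#' @return The [StimulonReport-class], invisibly.
#' @export
runPipeline <- function(config, outputDir) {
  validatePipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config)
  stamp <- c(sprintf("config_hash: %s", hash),
             sprintf("seed: %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      s <- simulateExperiment(config$simulate, config$seed)
      writeSimulation(s, file.path(outputDir, "simulated"))
      s
    })
    ann <- sim$annotation
    se <- sim$se
  } else {
    ann <- stage("load_annotation",
                 readAnnotation(config$gff3, config$fasta,
                                boxes = config$boxes))
    se <- stage("load_counts", {
      libs <- readTsv(config$libraries)
      readCountsTsv(config$counts, libs)
    })
  }
  ann <- stage("operons", {
    if (!nrow(operons(ann)) ||
        anyNA(S4Vectors::mcols(genes(ann))$operon_id)) {
      inferOperons(ann, config$operonGap)
    } else ann
  })
  ann <- stage("link_boxes", linkBoxToGene(ann, config$linkDistance))
  # --- differential expression ----------------------------------------------
  deg <- stage("de", {
    sf <- medianRatioSizeFactors(SummarizedExperiment::assay(se, "counts"))
    res <- genisteinContrasts(se, sizeFactors = sf, fc = config$fc,
                              alpha = config$alpha)
    for (s in names(res)) {
      writeContrastTsv(res[[s]],
                       file.path(outputDir, sprintf("de_%s.tsv", s)), stamp)
    }
    attr(res, "sizeFactors") <- sf
    res
  })
  # --- SyrM-box candidates upstream of responsive genes ---------------------
  stage("scan", {
    cand <- scanUpstream(ann, syrmBoxPattern(), config$scanWindow,
                         config$scanBudget, geneIds = degSet(deg$WT))
    writeTsv(cand, file.path(outputDir, "syrm_candidates.tsv"), stamp)
  })
  # --- classification -------------------------------------------------------
  out <- stage("classify", {
    calls <- boxActivity(ann, deg, fc = config$fc, alpha = config$alpha,
                         weakFc = config$weakFc,
                         coverageFloor = config$coverageFloor)
    affected <- assembleAffectedSet(ann, deg, rescueFc = config$rescueFc)
    filt <- applyDiscardRules(ann, affected)
    groups <- assignGroups(ann, filt$retained, calls, deg)
    writeTsv(calls, file.path(outputDir, "box_calls.tsv"), stamp)
    writeTsv(groups, file.path(outputDir, "gene_groups.tsv"), stamp)
    writeTsv(filt$discards, file.path(outputDir, "discards.tsv"), stamp)
    list(calls = calls, groups = groups, discards = filt$discards)
  })
  mut <- stage("mutant_background",
               mutantBaselineEffects(se, attr(deg, "sizeFactors"),
                                     config$fc, config$alpha))
  writeTsv(mut, file.path(outputDir, "mutant_background.tsv"), stamp)
  # --- qPCR (optional) ------------------------------------------------------
  if (!is.null(config$qpcr)) {
    stage("qpcr", {
      ct <- readCtTable(config$qpcr)
      q <- ddctFoldChange(ct, config$qpcrTreated, config$qpcrControl)
      writeTsv(q, file.path(outputDir, "qpcr_foldchange.tsv"), stamp)
      conc <- qpcrConcordance(q, deg$WT)
      writeTsv(conc$table, file.path(outputDir, "qpcr_concordance.tsv"),
               c(stamp, sprintf("pearson_r_log2: %.6f", conc$r)))
    })
  }
  # --- report ---------------------------------------------------------------
  report <- stage("report", {
    rep <- stimulonSummary(deg, ann, assignments = out$groups,
                           boxCalls = out$calls, discards = out$discards)
    writeReportJson(rep, file.path(outputDir, "report.json"),
                    meta = list(config_hash = hash, seed = config$seed))
    rep
  })
  invisible(report)
}
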