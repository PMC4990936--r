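#' Call promoter-box functionality from knockout epistasis
#'
#' Applies the three-strain induction rules to every annotated box.  With
#' `I(s)` = "the box's operon is up-regulated by genistein in strain `s`"
#' (judged on the operon lead gene, or on a majority of members when the
#' lead alone falls short):
#'
#' * nod box (NB): **active** iff `I(WT) & I(ttsI) & !I(nodD1)` —
#'   induction requires NodD1 but not TtsI.
#' * tts box (TB): **active** iff `I(WT) & !I(nodD1) & !I(ttsI)` —
#'   induction requires both regulators (TtsI is itself NB-driven).
#' * **weakly_active**: the same epistasis sign pattern, but the wild-type
#'   fold-change sits in `[weakFc, fc)` (significant yet under the DEG
#'   threshold).
#' * **non_functional**: any other induction pattern — including the
#'   decoy case of a tts box whose operon stays induced after ttsI
#'   inactivation.
#' * **not_testable**: no downstream gene, or mean baseline coverage of
#'   the lead below `coverageFloor` ("low reads").  SyrM boxes are never
#'   assessed (their functionality is outside the epistasis design) and
#'   return `not_testable`.
#'
#' All three genistein contrasts must be present; a design without the
#' ttsI libraries stops with an error rather than guessing.
#'
#' @param annotation A [GenomeAnnotation-class] with linked boxes.
#' @param degResults Named list (`WT`, `nodD1`, `ttsI`) of [callDegs()]
#'   tables for the genistein contrasts.
#' @param fc DEG fold-change threshold (default 3).
#' @param alpha p-value threshold (default 0.05).
#' @param weakFc Lower fold-change bound for weak activity (default 2).
#' @param coverageFloor Minimum mean normalized baseline count of the lead
#'   gene for a box to be testable (default 10).
#' @return `data.frame`: `box_id`, `box_type`, `call`, `reason`,
#'   `lead_gene`, `n_regulon`, `regulon_genes` (comma-separated),
#'   `induced_WT`, `induced_nodD1`, `induced_ttsI`, `fc_WT`, `fc_nodD1`,
#'   `fc_ttsI`.
#' @export
boxActivity <- function(annotation, degResults, fc = 3, alpha = 0.05,
                        weakFc = 2, coverageFloor = 10) {
  need <- c("WT", "nodD1", "ttsI")
  miss <- setdiff(need, names(degResults))
  if (length(miss)) {
    stop(sprintf("box functionality needs all three genistein contrasts; missing: %s",
                 paste(miss, collapse = ", ")))
  }
  b <- promoterBoxes(annotation)
  mc <- S4Vectors::mcols(b)
  rows <- lapply(seq_along(b), function(k) {
    out <- data.frame(
      box_id = mc$box_id[k], box_type = mc$box_type[k],
      call = NA_character_, reason = NA_character_,
      lead_gene = NA_character_, n_regulon = 0L, regulon_genes = "",
      induced_WT = NA, induced_nodD1 = NA, induced_ttsI = NA,
      fc_WT = NA_real_, fc_nodD1 = NA_real_, fc_ttsI = NA_real_,
      stringsAsFactors = FALSE)
    dg <- mc$downstream_gene[k]
    if (is.na(dg)) {
      out$call <- "not_testable"; out$reason <- "no_downstream_gene"
      return(out)
    }
    opId <- operonOf(annotation, dg)
    members <- if (is.na(opId)) dg else operonMembers(annotation, opId)
    lead <- members[1]
    out$lead_gene <- lead
    out$n_regulon <- length(members)
    out$regulon_genes <- paste(members, collapse = ",")
    if (mc$box_type[k] == "SyrM") {
      out$call <- "not_testable"; out$reason <- "syrm_not_assessed"
      return(out)
    }
    wtRow <- degResults$WT[match(lead, degResults$WT$gene_id), ]
    if (is.na(wtRow$meanBase) || wtRow$meanBase < coverageFloor) {
      out$call <- "not_testable"; out$reason <- "low_reads"
      return(out)
    }
    induced <- vapply(need, function(s) {
      tab <- degResults[[s]]
      rowsM <- tab[match(members, tab$gene_id), , drop = FALSE]
      leadUp <- isTRUE(rowsM$call[1]) && identical(rowsM$direction[1], "up")
      if (leadUp) return(TRUE)
      up <- rowsM$call & rowsM$direction == "up"
      mean(up, na.rm = TRUE) >= 0.5 && length(members) > 1
    }, logical(1))
    fcs <- vapply(need, function(s) {
      tab <- degResults[[s]]
      tab$FC[match(lead, tab$gene_id)]
    }, numeric(1))
    ps <- vapply(need, function(s) {
      tab <- degResults[[s]]
      tab$pvalue[match(lead, tab$gene_id)]
    }, numeric(1))
    out$induced_WT <- induced["WT"]; out$induced_nodD1 <- induced["nodD1"]
    out$induced_ttsI <- induced["ttsI"]
    out$fc_WT <- fcs["WT"]; out$fc_nodD1 <- fcs["nodD1"]
    out$fc_ttsI <- fcs["ttsI"]
    mutantsOk <- if (mc$box_type[k] == "NB") {
      induced["ttsI"] && !induced["nodD1"]
    } else {
      !induced["ttsI"] && !induced["nodD1"]
    }
    weakMutantsOk <- if (mc$box_type[k] == "NB") {
      !induced["nodD1"] &&
        (induced["ttsI"] ||
           (!is.na(fcs["ttsI"]) && fcs["ttsI"] >= weakFc && ps["ttsI"] < alpha))
    } else {
      !induced["ttsI"] && !induced["nodD1"]
    }
    if (induced["WT"] && mutantsOk) {
      out$call <- "active"
    } else if (!induced["WT"] && weakMutantsOk &&
               !is.na(fcs["WT"]) && fcs["WT"] >= weakFc && fcs["WT"] < fc &&
               ps["WT"] < alpha) {
      out$call <- "weakly_active"
      out$reason <- "low_efficiency"
    } else {
      out$call <- "non_functional"
      out$reason <- if (induced["WT"] && mc$box_type[k] == "TB" && induced["ttsI"]) {
        "ttsI_independent_induction"
      } else if (induced["WT"] && induced["nodD1"]) {
        "nodD1_independent_induction"
      } else if (!induced["WT"]) {
        "not_induced"
      } else {
        "inconsistent_pattern"
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the inducer-affected gene set
#'
#' The union of three inclusion routes:
#'
#' 1. `direct_DEG` — wild-type genistein DEGs (either direction);
#' 2. `operon_rescue` — sub-threshold members of operons containing at
#'    least one direct DEG;
#' 3. `conserved_box_rescue` — genes directly preceded by a 0-mismatch
#'    promoter box whose wild-type fold-change reaches `rescueFc`
#'    (default 2), even outside a rescued operon.
#'
#' @param annotation A [GenomeAnnotation-class] with linked boxes.
#' @param degResults Named contrast list as in [boxActivity()].
#' @param rescueFc Conserved-box rescue fold-change threshold.
#' @return `data.frame`: `gene_id`, `route`.
#' @export
assembleAffectedSet <- function(annotation, degResults, rescueFc = 2) {
  wt <- degResults$WT
  direct <- degSet(wt)
  route <- stats::setNames(rep("direct_DEG", length(direct)), direct)
  op <- operons(annotation)
  rescuedOps <- unique(op$operon_id[op$gene_id %in% direct])
  opGenes <- op$gene_id[op$operon_id %in% rescuedOps]
  for (gn in setdiff(opGenes, names(route))) route[gn] <- "operon_rescue"
  b <- promoterBoxes(annotation)
  if (length(b)) {
    mc <- S4Vectors::mcols(b)
    conserved <- !is.na(mc$downstream_gene) &
      (is.na(mc$mismatches) | mc$mismatches == 0)
    for (gn in mc$downstream_gene[conserved]) {
      if (gn %in% names(route)) next
      fcv <- wt$FC[match(gn, wt$gene_id)]
      if (!is.na(fcv) && fcv >= rescueFc) route[gn] <- "conserved_box_rescue"
    }
  }
  data.frame(gene_id = names(route), route = unname(route),
             stringsAsFactors = FALSE)
}

#' Discard artefactual members of the affected set
#'
#' Two removal rules, each logged with its reason:
#'
#' * `opposed_to_NB` — genes antisense to a nod box that sits immediately
#'   3' of it (the box's `opposed` flag): apparent signal opposite to the
#'   box orientation;
#' * `identical_copy` — genes whose nucleotide sequence is identical to a
#'   retained box-controlled gene; the box-linked copy is kept.
#'
#' @param annotation A [GenomeAnnotation-class] with sequences and linked
#'   boxes.
#' @param affected Output of [assembleAffectedSet()].
#' @return List with `retained` (filtered `affected`) and `discards`
#'   (`gene_id`, `reason`).
#' @export
applyDiscardRules <- function(annotation, affected) {
  b <- promoterBoxes(annotation)
  mc <- if (length(b)) S4Vectors::mcols(b) else NULL
  reasons <- character(0)
  # rule (a): antisense to a nod box
  if (!is.null(mc)) {
    oppGenes <- mc$opposed_gene[mc$box_type == "NB" & mc$opposed %in% TRUE]
    oppGenes <- oppGenes[!is.na(oppGenes)]
    for (gn in intersect(oppGenes, affected$gene_id)) {
      reasons[gn] <- "opposed_to_NB"
    }
  }
  # rule (b): identical copies of a box-controlled gene
  boxControlled <- character(0)
  if (!is.null(mc)) {
    for (dg in mc$downstream_gene[!is.na(mc$downstream_gene)]) {
      opId <- operonOf(annotation, dg)
      boxControlled <- c(boxControlled,
                         if (is.na(opId)) dg else operonMembers(annotation, opId))
    }
  }
  remaining <- setdiff(affected$gene_id, names(reasons))
  if (length(genomeSequences(annotation)) && length(remaining) > 1) {
    seqs <- vapply(remaining, function(g) geneSequence(annotation, g),
                   character(1))
    ctrl <- remaining %in% boxControlled
    for (i in which(!ctrl)) {
      twin <- which(ctrl & seqs == seqs[i])
      if (length(twin)) reasons[remaining[i]] <- "identical_copy"
    }
  }
  discards <- data.frame(gene_id = names(reasons), reason = unname(reasons),
                         stringsAsFactors = FALSE)
  retained <- affected[!(affected$gene_id %in% discards$gene_id), ,
                       drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, discards = discards)
}

#' Assign retained genes to regulon groups
#'
#' Genes in the regulon (downstream operon) of an active or weakly active
#' nod box form group `NB`; genes under an active tts box form group
#' `TB`; everything else is group `other`.  A gene claimed by both an
#' active NB and an active TB is assigned to the nearer box and a warning
#' is logged.  For group-`other` genes that are direct wild-type DEGs,
#' regulator dependence is flagged: `nodD1_dependent` when the gene is a
#' DEG in the wild type but not in the nodD1 knockout (+genistein),
#' `ttsI_dependent` likewise for the ttsI knockout; genes that are DEGs
#' in all three strains carry both flags `FALSE`.  Flags are `NA` for
#' rescue-route genes (not themselves DEGs).
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param retained `retained` table from [applyDiscardRules()].
#' @param boxCalls Output of [boxActivity()].
#' @param degResults Named contrast list as in [boxActivity()].
#' @return `data.frame`: `gene_id`, `group`, `route`, `nodD1_dependent`,
#'   `ttsI_dependent`.
#' @export
assignGroups <- function(annotation, retained, boxCalls, degResults) {
  b <- promoterBoxes(annotation)
  mc <- if (length(b)) S4Vectors::mcols(b) else NULL
  claim <- list()  # gene -> data.frame(group, box_id, dist)
  if (!is.null(mc) && nrow(boxCalls)) {
    for (k in seq_len(nrow(boxCalls))) {
      bc <- boxCalls[k, ]
      grp <- if (bc$box_type == "NB" &&
                 bc$call %in% c("active", "weakly_active")) "NB"
             else if (bc$box_type == "TB" && bc$call == "active") "TB"
             else NA_character_
      if (is.na(grp)) next
      memb <- strsplit(bc$regulon_genes, ",", fixed = TRUE)[[1]]
      i <- match(bc$box_id, mc$box_id)
      base <- abs(mc$offset_end[i])
      for (m in seq_along(memb)) {
        gn <- memb[m]
        d <- base + (m - 1L) * 1000L   # later operon members are farther
        claim[[gn]] <- rbind(claim[[gn]],
                             data.frame(group = grp, box_id = bc$box_id,
                                        dist = d, stringsAsFactors = FALSE))
      }
    }
  }
  wt <- degResults$WT
  res <- lapply(seq_len(nrow(retained)), function(i) {
    gn <- retained$gene_id[i]
    cl <- claim[[gn]]
    grp <- "other"
    if (!is.null(cl)) {
      if (length(unique(cl$group)) > 1) {
        pick <- cl[which.min(cl$dist), ]
        warning(sprintf(
          "gene %s claimed by both an active NB and an active TB; assigned to nearer box %s",
          gn, pick$box_id))
        grp <- pick$group
      } else {
        grp <- cl$group[1]
      }
    }
    nd <- NA; td <- NA
    if (grp == "other" && retained$route[i] == "direct_DEG") {
      inWT <- gn %in% degSet(degResults$WT)
      inNod <- gn %in% degSet(degResults$nodD1)
      inTts <- gn %in% degSet(degResults$ttsI)
      if (inWT) {
        nd <- !inNod
        td <- !inTts
      }
    }
    data.frame(gene_id = gn, group = grp, route = retained$route[i],
               nodD1_dependent = nd, ttsI_dependent = td,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res) %||%
    data.frame(gene_id = character(), group = character(), route = character(),
               nodD1_dependent = logical(), ttsI_dependent = logical())
  rownames(out) <- NULL
  out
}

#' Mutant-background expression shifts
#'
#' Finds genes whose expression differs from the wild-type baseline in
#' the knockout strains even without genistein (tested with the same
#' exact-test machinery on the mutant no-genistein contrasts).  These are
#' reported apart from the three regulon groups.
#'
#' @param se A [StimulonExperiment-class].
#' @param sizeFactors Optional size factors.
#' @param fc,alpha Calling thresholds.
#' @return `data.frame` of genes called in both knockouts' no-genistein
#'   contrasts, with per-mutant fold-changes.
#' @export
mutantBaselineEffects <- function(se, sizeFactors = NULL, fc = 3, alpha = 0.05) {
  if (is.null(sizeFactors)) {
    sizeFactors <- medianRatioSizeFactors(
      SummarizedExperiment::assay(se, "counts"))
  }
  nod <- callDegs(contrastDE(se, "nodD1", FALSE, sizeFactors), fc, alpha)
  tts <- callDegs(contrastDE(se, "ttsI", FALSE, sizeFactors), fc, alpha)
  both <- intersect(degSet(nod), degSet(tts))
  data.frame(gene_id = both,
             fc_nodD1_ctl = nod$FC[match(both, nod$gene_id)],
             fc_ttsI_ctl = tts$FC[match(both, tts$gene_id)],
             direction = nod$direction[match(both, nod$gene_id)],
             stringsAsFactors = FALSE)
}

#' Venn partition of three gene sets
#'
#' @param sets Named list of three character vectors (`WT`, `nodD1`,
#'   `ttsI`).
#' @return Named integer vector over the 7 disjoint cells.
#' @export
vennPartition <- function(sets) {
  stopifnot(identical(sort(names(sets)), sort(c("WT", "nodD1", "ttsI"))))
  w <- unique(sets$WT); n <- unique(sets$nodD1); t <- unique(sets$ttsI)
  all3 <- intersect(intersect(w, n), t)
  c(WT_only = length(setdiff(w, union(n, t))),
    nodD1_only = length(setdiff(n, union(w, t))),
    ttsI_only = length(setdiff(t, union(w, n))),
    WT_nodD1 = length(setdiff(intersect(w, n), t)),
    WT_ttsI = length(setdiff(intersect(w, t), n)),
    nodD1_ttsI = length(setdiff(intersect(n, t), w)),
    all = length(all3))
}

#' Summarize a stimulon analysis
#'
#' Builds the [StimulonReport-class]: Venn partition of the three DEG
#' sets, per-replicon up/down counts per strain, totals (including the
#' percentage of annotated coding sequences affected in each strain), the
#' box calls, group table and discard log.  Internal consistency (cells
#' disjoint, WT-containing cells summing to the WT total) is asserted by
#' the class validity.
#'
#' @param degResults Named contrast list (`WT`, `nodD1`, `ttsI`) of
#'   [callDegs()] tables.
#' @param annotation A [GenomeAnnotation-class] (for replicon lookup).
#' @param assignments Optional [assignGroups()] table.
#' @param boxCalls Optional [boxActivity()] table.
#' @param discards Optional discard log.
#' @param genomeCds Number of coding sequences used for the percentage
#'   denominators (default: annotated gene count).
#' @return A [StimulonReport-class].
#' @export
stimulonSummary <- function(degResults, annotation, assignments = NULL,
                            boxCalls = NULL, discards = NULL,
                            genomeCds = NULL) {
  g <- genes(annotation)
  gmc <- S4Vectors::mcols(g)
  if (is.null(genomeCds)) genomeCds <- length(g)
  sets <- lapply(degResults, degSet)
  venn <- vennPartition(sets)
  rc <- list()
  for (s in names(degResults)) {
    tab <- degResults[[s]]
    for (dir in c("up", "down")) {
      ids <- degSet(tab, dir)
      repl <- as.character(GenomeInfoDb::seqnames(g))[match(ids, gmc$gene_id)]
      cnt <- table(factor(repl, levels = repliconTable(annotation)$id))
      for (r in names(cnt)) {
        key <- paste(s, r, sep = ".")
        if (is.null(rc[[key]])) {
          rc[[key]] <- data.frame(strain = s, replicon = r, up = 0L,
                                  down = 0L, stringsAsFactors = FALSE)
        }
        rc[[key]][[dir]] <- as.integer(cnt[[r]])
      }
    }
  }
  repliconCounts <- do.call(rbind, unname(rc)) %||%
    data.frame(strain = character(), replicon = character(), up = integer(),
               down = integer())
  degTotals <- vapply(sets, length, integer(1))
  upTotals <- vapply(degResults, function(tab) length(degSet(tab, "up")),
                     integer(1))
  totals <- list(
    genome_cds = genomeCds,
    deg_per_strain = degTotals,
    up_per_strain = upTotals,
    down_per_strain = degTotals - upTotals,
    deg_percent = round(100 * degTotals / genomeCds, 2))
  if (!is.null(assignments) && nrow(assignments)) {
    tab <- table(factor(assignments$group, levels = c("NB", "TB", "other")))
    totals$group_sizes <- stats::setNames(as.integer(tab), names(tab))
    totals$considered <- nrow(assignments) +
      (if (!is.null(discards)) nrow(discards) else 0L)
    totals$retained <- nrow(assignments)
    nd <- assignments$nodD1_dependent
    td <- assignments$ttsI_dependent
    totals$other_nodD1_dependent <-
      sum(assignments$group == "other" & nd %in% TRUE)
    totals$other_ttsI_dependent <-
      sum(assignments$group == "other" & td %in% TRUE)
  }
  methods::new("StimulonReport",
               venn = venn,
               repliconCounts = repliconCounts,
               boxCalls = boxCalls %||% data.frame(),
               groups = assignments %||% data.frame(),
               discards = discards %||%
                 data.frame(gene_id = character(), reason = character()),
               totals = totals)
}

#' Export a report as JSON
#'
#' @param report A [StimulonReport-class].
#' @param path Output path.
#' @param meta Optional named list merged into the JSON (e.g. config hash
#'   and seed).
#' @return Invisibly, the path.
#' @export
writeReportJson <- function(report, path, meta = list()) {
  obj <- c(meta, list(
    venn = as.list(report@venn),
    totals = report@totals,
    replicon_counts = report@repliconCounts,
    box_calls = if (nrow(report@boxCalls)) report@boxCalls else NULL,
    groups = if (nrow(report@groups)) report@groups else NULL,
    discards = if (nrow(report@discards)) report@discards else NULL))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
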