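#' Delta-delta-Ct relative quantification
#'
#' Classic two-step normalization against a reference gene (here the 16S
#' rRNA), with amplification efficiency fixed at 2: technical replicates
#' are averaged within each biological replicate, `dCt = Ct_target -
#' Ct_reference` per biological replicate, condition `dCt` is the mean
#' over biological replicates, `ddCt = dCt_treated - dCt_control` and the
#' fold-change is `2^-ddCt`.  The reported spread is the range of
#' per-biological-replicate fold-changes on the treated side (each against
#' the control mean).
#'
#' @param records `data.frame` of Ct measurements with columns `gene`,
#'   `condition`, `bio_rep`, `tech_rep`, `ct_target`, `ct_ref`.
#' @param treated,control Condition labels to compare.
#' @param genes Genes to quantify (default: all genes present in both
#'   conditions).
#' @return `data.frame`: `gene`, `fold_change`, `log2_fc`, `spread`,
#'   `n_bio_treated`, `n_bio_control`.
#' @export
ddctFoldChange <- function(records, treated, control, genes = NULL) {
  need <- c("gene", "condition", "bio_rep", "ct_target", "ct_ref")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(sprintf("Ct table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyNA(records$ct_ref)) stop("missing reference Ct value(s)")
  if (anyNA(records$ct_target)) stop("missing target Ct value(s)")
  if (is.null(genes)) {
    genes <- intersect(unique(records$gene[records$condition == treated]),
                       unique(records$gene[records$condition == control]))
  }
  condDct <- function(d) {
    # technical replicates averaged within biological replicates first
    perBio <- vapply(split(d, d$bio_rep),
                     function(x) mean(x$ct_target) - mean(x$ct_ref),
                     numeric(1))
    perBio
  }
  out <- lapply(genes, function(gn) {
    dt <- records[records$gene == gn & records$condition == treated, ]
    dc <- records[records$gene == gn & records$condition == control, ]
    if (!nrow(dt) || !nrow(dc)) {
      stop(sprintf("gene '%s' lacks records in one condition", gn))
    }
    dctT <- condDct(dt); dctC <- condDct(dc)
    ddct <- mean(dctT) - mean(dctC)
    fcBio <- 2^-(dctT - mean(dctC))
    data.frame(gene = gn, fold_change = 2^-ddct, log2_fc = -ddct,
               spread = if (length(fcBio) > 1) diff(range(fcBio)) else 0,
               n_bio_treated = length(dctT), n_bio_control = length(dctC),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concordance between qPCR and RNA-seq fold-changes
#'
#' Pearson correlation on the log2 scale over genes shared between the
#' two tables; genes whose log2 fold-changes disagree in sign are flagged
#' discordant.
#'
#' @param qpcr Output of [ddctFoldChange()] (needs `gene`,
#'   `fold_change`).
#' @param rnaseq A contrast table with `gene_id` and `log2FC`.
#' @return List with `r` (Pearson correlation of log2 values), `n`, and
#'   `table` (`gene`, `log2_qpcr`, `log2_rnaseq`, `discordant`).
#' @export
qpcrConcordance <- function(qpcr, rnaseq) {
  shared <- intersect(qpcr$gene, rnaseq$gene_id)
  if (length(shared) < 3) {
    stop("need at least 3 shared genes for a correlation")
  }
  lq <- log2(qpcr$fold_change[match(shared, qpcr$gene)])
  lr <- rnaseq$log2FC[match(shared, rnaseq$gene_id)]
  tab <- data.frame(gene = shared, log2_qpcr = lq, log2_rnaseq = lr,
                    discordant = sign(lq) != sign(lr) & lq != 0 & lr != 0,
                    stringsAsFactors = FALSE)
  list(r = stats::cor(lq, lr), n = length(shared), table = tab)
}

#' Read a Ct table
#'
#' TSV with columns `gene`, `condition`, `bio_rep`, `tech_rep`,
#' `ct_target`, `ct_ref`.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
readCtTable <- function(path) readTsv(path)
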