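#' Median-of-ratios library size factors
#'
#' For each library, the factor is the median over genes (restricted to
#' rows positive in every library) of the ratio between that library's
#' count and the gene's geometric mean across libraries; factors are then
#' rescaled to geometric mean 1.  When no gene is positive in all
#' libraries the estimator falls back to total-count scaling with a
#' warning.
#'
#' @param counts Integer matrix, genes x libraries, or a
#'   [StimulonExperiment-class].
#' @return Named numeric vector of positive size factors (geometric mean 1).
#' @export
medianRatioSizeFactors <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  stopifnot(all(colSums(counts) > 0))
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos)) {
    warning("no gene is positive in all libraries; falling back to total-count scaling")
    f <- colSums(counts)
  } else {
    m <- counts[allPos, , drop = FALSE]
    gm <- exp(rowMeans(log(m)))
    f <- apply(m / gm, 2, stats::median)
  }
  f <- f / geomean(f)
  stats::setNames(f, colnames(counts))
}

#' Normalized counts
#'
#' @param counts Count matrix or [StimulonExperiment-class].
#' @param sizeFactors Per-library size factors (defaults to
#'   [medianRatioSizeFactors()]).
#' @return Numeric matrix of counts divided by their library's factor.
#' @export
normalizedCounts <- function(counts, sizeFactors = NULL) {
  if (methods::is(counts, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
  sweep(counts, 2, sizeFactors, "/")
}

#' Two-sided exact conditioned-binomial test for a count contrast
#'
#' Conditions on the total count `N` across both sides of the contrast:
#' under the null of equal (normalized) expression, the treatment total is
#' Binomial(N, q) with `q` the treatment share of the summed size factors.
#' The p-value is the exact two-sided tail: the sum of the probabilities
#' of all outcomes no more probable than the observed one (with the
#' conventional `1 + 1e-7` relative tolerance on ties).  Raw counts enter
#' the test directly; normalization acts only through `q`.  `N = 0` gives
#' p = 1.
#'
#' For large `N` the opposite-tail boundary is located by binary search on
#' the monotone flanks of the binomial mass function, which is exact and
#' avoids enumerating all `N + 1` outcomes.
#'
#' @param x Observed treatment-side total (integer, `0 <= x <= n`).
#' @param n Total count across both sides.
#' @param q Null treatment probability in (0, 1).
#' @return p-value in \[0, 1\].
#' @export
exactCountTest <- function(x, n, q) {
  stopifnot(length(x) == 1, length(n) == 1, x >= 0, x <= n, q > 0, q < 1)
  if (n == 0) return(1)
  d <- stats::dbinom(x, n, q)
  rel <- d * (1 + 1e-7)
  mode <- floor((n + 1) * q)
  if (x == mode || stats::dbinom(mode, n, q) <= rel) return(1)
  if (x < mode) {
    # observed in the left tail; find first y >= mode with dbinom(y) <= rel
    lo <- mode; hi <- n + 1L   # invariant: dbinom(lo) > rel, hi satisfies or past end
    while (hi - lo > 1L) {
      mid <- lo + ((hi - lo) %/% 2L)
      if (stats::dbinom(mid, n, q) <= rel) hi <- mid else lo <- mid
    }
    p <- stats::pbinom(x, n, q) +
      (if (hi <= n) stats::pbinom(hi - 1L, n, q, lower.tail = FALSE) else 0)
  } else {
    # observed in the right tail; find last y <= mode with dbinom(y) <= rel
    lo <- -1L; hi <- mode      # invariant: lo satisfies or before start, dbinom(hi) > rel
    while (hi - lo > 1L) {
      mid <- lo + ((hi - lo) %/% 2L)
      if (stats::dbinom(mid, n, q) <= rel) lo <- mid else hi <- mid
    }
    p <- stats::pbinom(x - 1L, n, q, lower.tail = FALSE) +
      (if (lo >= 0L) stats::pbinom(lo, n, q) else 0)
  }
  min(1, p)
}

#' Fold-change between two sides of a contrast
#'
#' Fold-change is the ratio of mean normalized counts (replicate means),
#' guarded by a pseudocount added to both sides' means.  The pseudocount
#' protects the ratio from zeros only; it never enters the exact test.
#'
#' @param counts Count matrix or [StimulonExperiment-class].
#' @param treatCols,baseCols Column names or indices of the two sides.
#' @param sizeFactors Per-library size factors.
#' @param pseudocount Added to each side's mean normalized count
#'   (default 0.5).
#' @return `data.frame` with `gene_id`, `meanTreat`, `meanBase`, `FC`,
#'   `log2FC`.
#' @export
contrastFoldChange <- function(counts, treatCols, baseCols,
                               sizeFactors = NULL, pseudocount = 0.5) {
  if (methods::is(counts, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
  norm <- sweep(counts, 2, sizeFactors, "/")
  mt <- rowMeans(norm[, treatCols, drop = FALSE])
  mb <- rowMeans(norm[, baseCols, drop = FALSE])
  fc <- (mt + pseudocount) / (mb + pseudocount)
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             meanTreat = mt, meanBase = mb, FC = fc, log2FC = log2(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression for one strain + genistein contrast
#'
#' Compares the libraries of `strain` grown with genistein against the
#' wild-type no-genistein baseline.  Replicates are pooled within sides
#' for the exact test (with the size-factor share as the null
#' probability); fold-changes use replicate means of normalized counts.
#'
#' @param se A [StimulonExperiment-class].
#' @param strain `"WT"`, `"nodD1"` or `"ttsI"`.
#' @param genistein Treatment-side inducer status (default `TRUE`; set
#'   `FALSE` to test a mutant's uninduced baseline against the wild type).
#' @param sizeFactors Per-library size factors (defaults to
#'   [medianRatioSizeFactors()] of the whole matrix).
#' @param pseudocount Fold-change pseudocount.
#' @return `data.frame` with `gene_id`, `contrast`, `meanTreat`,
#'   `meanBase`, `FC`, `log2FC`, `pvalue`.
#' @export
contrastDE <- function(se, strain, genistein = TRUE, sizeFactors = NULL,
                       pseudocount = 0.5) {
  cd <- SummarizedExperiment::colData(se)
  treat <- which(cd$strain == strain & cd$genistein == genistein)
  base <- which(cd$strain == "WT" & !cd$genistein)
  if (!length(treat)) stop(sprintf("no libraries for strain '%s' (genistein=%s)",
                                   strain, genistein))
  if (!length(base)) stop("no wild-type no-genistein baseline libraries")
  cts <- SummarizedExperiment::assay(se, "counts")
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(cts)
  fc <- contrastFoldChange(cts, treat, base, sizeFactors, pseudocount)
  xt <- rowSums(cts[, treat, drop = FALSE])
  xb <- rowSums(cts[, base, drop = FALSE])
  q <- sum(sizeFactors[treat]) / (sum(sizeFactors[treat]) + sum(sizeFactors[base]))
  p <- vapply(seq_len(nrow(cts)),
              function(i) exactCountTest(xt[i], xt[i] + xb[i], q),
              numeric(1))
  lab <- sprintf("%s%s_vs_WT", strain, if (genistein) "+gen" else "-gen")
  data.frame(gene_id = fc$gene_id, contrast = lab,
             meanTreat = fc$meanTreat, meanBase = fc$meanBase,
             FC = fc$FC, log2FC = fc$log2FC, pvalue = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' A gene passes when its fold-change is at least `fc` (up) or at most
#' `1/fc` (down) *and* its p-value is below `alpha`.  The threshold is on
#' the fold-change, not on the p-value alone: a tiny p-value with
#' FC < `fc` is not a DEG.  Down-regulation is reported with the
#' conventional negative sign (FC <= -3 in printed tables means a ratio
#' <= 1/3).
#'
#' @param res A contrast result from [contrastDE()].
#' @param fc Fold-change threshold (default 3; the log2 cutoff is
#'   `log2(fc)`).
#' @param alpha p-value threshold (default 0.05, unadjusted).
#' @param adjust If `TRUE`, apply Benjamini-Hochberg and threshold the
#'   adjusted p-values instead (off by default to match raw-p calling).
#' @return The input with added `call` (logical) and `direction`
#'   (`"up"`/`"down"`/`NA`) columns (plus `padj` when `adjust`).
#' @export
callDegs <- function(res, fc = 3, alpha = 0.05, adjust = FALSE) {
  stopifnot(fc > 1, alpha > 0, alpha < 1)
  p <- res$pvalue
  if (adjust) {
    res$padj <- stats::p.adjust(p, method = "BH")
    p <- res$padj
  }
  passFc <- res$FC >= fc | res$FC <= 1 / fc
  res$call <- passFc & p < alpha
  res$direction <- ifelse(res$call, ifelse(res$FC >= fc, "up", "down"),
                          NA_character_)
  res
}

#' DEG gene-id set from a called contrast
#'
#' @param res Output of [callDegs()].
#' @param direction Optionally restrict to `"up"` or `"down"` calls.
#' @return Character vector of gene ids.
#' @export
degSet <- function(res, direction = NULL) {
  keep <- res$call
  if (!is.null(direction)) keep <- keep & res$direction == direction
  res$gene_id[which(keep)]
}

#' Run the three genistein contrasts of the knockout design
#'
#' Convenience wrapper: computes size factors once and returns called
#' contrast tables for WT+genistein, nodD1+genistein and ttsI+genistein,
#' each against the wild-type no-genistein baseline.
#'
#' @inheritParams contrastDE
#' @inheritParams callDegs
#' @return Named list (`WT`, `nodD1`, `ttsI`) of [callDegs()] tables.
#' @export
genisteinContrasts <- function(se, sizeFactors = NULL, fc = 3, alpha = 0.05,
                               pseudocount = 0.5, adjust = FALSE) {
  if (is.null(sizeFactors)) {
    sizeFactors <- medianRatioSizeFactors(
      SummarizedExperiment::assay(se, "counts"))
  }
  strains <- c("WT", "nodD1", "ttsI")
  res <- lapply(strains, function(s) {
    callDegs(contrastDE(se, s, TRUE, sizeFactors, pseudocount),
             fc = fc, alpha = alpha, adjust = adjust)
  })
  stats::setNames(res, strains)
}

#' Write a called contrast table as TSV
#'
#' @param res Output of [callDegs()].
#' @param path Output path.
#' @param comments Optional comment header lines.
#' @export
writeContrastTsv <- function(res, path, comments = character()) {
  out <- res
  out$direction[is.na(out$direction)] <- ""
  writeTsv(out, path, comments)
}
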