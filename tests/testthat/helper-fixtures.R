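# Fixture builders and independent oracles used across the suite.
# Oracles deliberately re-derive results with naive algorithms so that the
# package implementation is checked against an independent code path.

geomeanHelper <- function(x) exp(mean(log(x)))

# n boxless single-gene units of one regulon class.
unitPlanOfClass <- function(class, n, induction = NA_real_) {
  data.frame(class = rep(class, n), n_genes = 1L, box_type = NA_character_,
             box_status = NA_character_, induction = induction,
             replicon = NA_character_, stringsAsFactors = FALSE)
}

randomDnaChars <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a GenomeAnnotation from plain data.frames.
makeAnnotation <- function(genesDf, repliconLength = 10000L,
                           repliconIds = NULL, seqs = NULL, boxes = NULL,
                           operons = NULL) {
  if (is.null(repliconIds)) repliconIds <- unique(genesDf$replicon)
  if (length(repliconLength) == 1) {
    repliconLength <- rep(repliconLength, length(repliconIds))
  }
  replicons <- data.frame(id = repliconIds, length = repliconLength,
                          kind = c("chromosome",
                                   rep("plasmid", length(repliconIds) - 1)),
                          stringsAsFactors = FALSE)
  if (is.null(seqs)) {
    seqs <- Biostrings::DNAStringSet(vapply(
      repliconLength,
      function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
      character(1)))
    names(seqs) <- repliconIds
  } else if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  g <- GenomicRanges::GRanges(genesDf$replicon,
                              IRanges::IRanges(genesDf$start, genesDf$end),
                              strand = genesDf$strand)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    gene_id = genesDf$gene_id,
    operon_id = if ("operon_id" %in% names(genesDf)) genesDf$operon_id
                else NA_character_,
    product = if ("product" %in% names(genesDf)) genesDf$product
              else NA_character_)
  GenomeAnnotation(replicons, g, operons = operons, boxes = boxes,
                   sequences = seqs)
}

makeBoxGRanges <- function(df) {
  gr <- GenomicRanges::GRanges(df$replicon,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    box_id = df$box_id, box_type = df$box_type,
    downstream_gene = if ("downstream_gene" %in% names(df)) df$downstream_gene
                      else NA_character_,
    offset_start = NA_integer_, offset_end = NA_integer_,
    opposed = FALSE, opposed_gene = NA_character_,
    mismatches = if ("mismatches" %in% names(df)) df$mismatches
                 else NA_integer_)
  gr
}

# Hand-built called contrast table (runs the real caller on synthetic stats).
makeDegTable <- function(geneIds, fc, p, meanBase = 500, fcThreshold = 3,
                         alpha = 0.05) {
  res <- data.frame(gene_id = geneIds, contrast = "synthetic",
                    meanTreat = meanBase * fc, meanBase = meanBase,
                    FC = fc, log2FC = log2(fc), pvalue = p,
                    stringsAsFactors = FALSE)
  callDegs(res, fc = fcThreshold, alpha = alpha)
}

# --- independent oracles ----------------------------------------------------

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"))

oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "")[[1]]), collapse = "")
}

# Expand "ATCN9GAT" into a per-position character vector.
oracleExpandPattern <- function(text) {
  out <- character(0)
  for (tok in regmatches(text, gregexpr("N[0-9]*|[^N]", text))[[1]]) {
    if (startsWith(tok, "N")) {
      k <- if (nchar(tok) > 1) as.integer(substring(tok, 2)) else 1L
      out <- c(out, rep("N", k))
    } else {
      out <- c(out, toupper(tok))
    }
  }
  out
}

# Naive per-window scan honoring an optional mandatory core (positions given
# in pattern coordinates).  Returns start/strand/mismatch rows sorted like
# the implementation contract says.
oracleScan <- function(seq, patternText, budget, strands = c("+", "-"),
                       corePositions = integer(0)) {
  pat <- oracleExpandPattern(patternText)
  plen <- length(pat)
  L <- nchar(seq)
  rows <- list()
  scanStrand <- function(s, strandLabel) {
    v <- strsplit(toupper(s), "")[[1]]
    for (st in seq_len(max(0, L - plen + 1))) {
      mm <- 0L; coreBad <- FALSE
      for (j in seq_len(plen)) {
        pc <- pat[j]
        if (pc == "N") next
        if (!(v[st + j - 1] %in% ORACLE_IUPAC[[pc]])) {
          mm <- mm + 1L
          if (j %in% corePositions) coreBad <- TRUE
        }
      }
      if (mm <= budget && !coreBad) {
        fwStart <- if (strandLabel == "+") st else L - (st + plen - 1) + 1
        rows[[length(rows) + 1]] <<- data.frame(
          start = fwStart, end = fwStart + plen - 1, strand = strandLabel,
          mismatches = mm)
      }
    }
  }
  if ("+" %in% strands) scanStrand(seq, "+")
  if ("-" %in% strands) scanStrand(oracleRevComp(seq), "-")
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive operon grouping: walk the sorted gene list and cut chains at strand
# changes, large gaps, or tagged genes.
oracleOperonGroups <- function(genesDf, maxGap) {
  out <- rep(NA_integer_, nrow(genesDf))
  grp <- 0L
  for (repl in unique(genesDf$replicon)) {
    idx <- which(genesDf$replicon == repl)
    idx <- idx[order(genesDf$start[idx])]
    prev <- NA_integer_
    for (i in idx) {
      tagged <- "operon_id" %in% names(genesDf) &&
        !is.na(genesDf$operon_id[i])
      if (tagged) { prev <- NA_integer_; next }
      newChain <- is.na(prev) ||
        genesDf$strand[prev] != genesDf$strand[i] ||
        (genesDf$start[i] - genesDf$end[prev] - 1) > maxGap
      if (newChain) grp <- grp + 1L
      out[i] <- grp
      prev <- i
    }
  }
  out
}

# Exhaustive two-sided exact binomial p-value.
oracleExactP <- function(x, n, q) {
  if (n == 0) return(1)
  d <- dbinom(0:n, n, q)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

# Venn cells by direct membership tabulation.
oracleVenn <- function(sets) {
  u <- unique(unlist(sets))
  key <- vapply(u, function(g) paste0(as.integer(g %in% sets$WT),
                                      as.integer(g %in% sets$nodD1),
                                      as.integer(g %in% sets$ttsI)),
                character(1))
  cnt <- function(k) sum(key == k)
  c(WT_only = cnt("100"), nodD1_only = cnt("010"), ttsI_only = cnt("001"),
    WT_nodD1 = cnt("110"), WT_ttsI = cnt("101"), nodD1_ttsI = cnt("011"),
    all = cnt("111"))
}
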