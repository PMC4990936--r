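#' MotifPattern: a degenerate promoter-box consensus
#'
#' Represents a fuzznuc-style degenerate pattern made of literal IUPAC
#' blocks separated by fixed-length N spacers, e.g.
#' `"ATCN9GATN7ATCN6ATCGATN6AAT"` (the classic nod-box consensus).
#' N positions are pure spacers: they match any base and never count as
#' mismatches.  An optional mandatory core marks positions where any
#' mismatch disqualifies a hit regardless of the mismatch budget (used for
#' the `CGN2AG` core of the tts-box consensus).
#'
#' @slot id Pattern identifier.
#' @slot text The pattern string as parsed.
#' @slot chars Per-position characters (`"N"` at spacer positions).
#' @slot informative Integer positions carrying literal bases.
#' @slot corePositions Integer positions belonging to the mandatory core
#'   (empty when no core is set).
#' @seealso [parseMotifPattern()], [scanMotif()]
#' @export
setClass("MotifPattern",
  slots = c(id = "character", text = "character", chars = "character",
            informative = "integer", corePositions = "integer"))

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern '%s': %s\n  length %d, %d informative positions%s\n",
              object@id, object@text, length(object@chars),
              length(object@informative),
              if (length(object@corePositions))
                sprintf(", mandatory core at %d-%d",
                        min(object@corePositions), max(object@corePositions))
              else ""))
  invisible(object)
})

#' Pattern length and informative-position count
#' @param pattern A [MotifPattern-class].
#' @return Integer scalar.
#' @export
patternLength <- function(pattern) length(pattern@chars)

#' @rdname patternLength
#' @export
informativePositions <- function(pattern) length(pattern@informative)

# Tokenize a pattern string into per-position characters.
# Grammar: LITERAL (Ncount LITERAL)*, alphabet = IUPAC codes; N introduces
# a spacer run whose length is the following integer (1 when omitted).
parsePatternChars <- function(text) {
  up <- toupper(text)
  n <- nchar(up)
  out <- character(0)
  i <- 1L
  sawLiteral <- FALSE
  while (i <= n) {
    ch <- substr(up, i, i)
    if (ch == "N") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9]$", substr(up, j, j))) j <- j + 1L
      count <- if (j > i + 1L) as.integer(substr(up, i + 1L, j - 1L)) else 1L
      out <- c(out, rep("N", count))
      i <- j
    } else if (ch %in% setdiff(names(IUPAC_SETS), "N")) {
      out <- c(out, ch)
      sawLiteral <- TRUE
      i <- i + 1L
    } else {
      stop(sprintf("malformed pattern '%s': unexpected character '%s' at position %d",
                   text, ch, i))
    }
  }
  if (!sawLiteral) {
    stop(sprintf("malformed pattern '%s': no literal block", text))
  }
  out
}

#' Parse a degenerate consensus pattern
#'
#' @param text Pattern string, e.g. `"GTCAGN5CGN2AGN10TA"`.
#' @param id Pattern identifier (defaults to the text itself).
#' @param core Optional mandatory-core sub-pattern (e.g. `"CGN2AG"`); it
#'   must occur at exactly one offset within the pattern unless
#'   `coreOffset` pins it down (1-based position of the core's first base).
#' @return A [MotifPattern-class].
#' @export
parseMotifPattern <- function(text, id = text, core = NULL, coreOffset = NULL) {
  ch <- parsePatternChars(text)
  corePos <- integer(0)
  if (!is.null(core) && !is.na(core) && nzchar(core)) {
    cch <- parsePatternChars(core)
    lit <- which(cch != "N")
    if (is.null(coreOffset)) {
      hits <- integer(0)
      for (o in seq_len(length(ch) - length(cch) + 1L)) {
        seg <- ch[o + seq_along(cch) - 1L]
        ok <- all(seg[lit] != "N") && all(seg[lit] == cch[lit])
        if (ok) hits <- c(hits, o)
      }
      if (length(hits) != 1L) {
        stop(sprintf("core '%s' matches pattern '%s' at %d offsets; supply coreOffset",
                     core, text, length(hits)))
      }
      coreOffset <- hits
    }
    corePos <- as.integer(coreOffset + lit - 1L)
    if (any(ch[corePos] == "N")) {
      stop("mandatory core covers spacer positions of the pattern")
    }
  }
  methods::new("MotifPattern", id = id, text = toupper(text), chars = ch,
               informative = which(ch != "N"), corePositions = corePos)
}

#' Built-in consensus patterns
#'
#' `nbConsensusPattern()` is the classic nod-box consensus
#' `ATCN9GATN7ATCN6ATCGATN6AAT` (46 bp, 18 informative positions).
#' `tbConsensusPattern()` is the tts-box consensus `GTCAGN5CGN2AGN10TA`
#' (28 bp, 11 informative positions) with the internal `CGN2AG` motif
#' marked as a mandatory core: boxes that fail to maintain it are rejected
#' regardless of the mismatch budget.  `syrmBoxPattern()` is a synthetic
#' 66-bp stand-in defined by this package for SyrM-box searches — the
#' published SyrM consensus is external and only the 66-bp span implied by
#' printed upstream coordinates is used as a length constraint; the actual
#' degenerate string to scan with can always be supplied via a pattern
#' table instead.
#'
#' @return A [MotifPattern-class].
#' @export
nbConsensusPattern <- function() {
  parseMotifPattern("ATCN9GATN7ATCN6ATCGATN6AAT", id = "NB")
}

#' @rdname nbConsensusPattern
#' @export
tbConsensusPattern <- function() {
  parseMotifPattern("GTCAGN5CGN2AGN10TA", id = "TB", core = "CGN2AG")
}

#' @rdname nbConsensusPattern
#' @export
syrmBoxPattern <- function() {
  parseMotifPattern("GTTAACN8CATN10GGAATN9TTGN7ACGTAN7TGA", id = "SyrM")
}

#' Scan a sequence for degenerate pattern hits
#'
#' Reports every window whose informative positions differ from the
#' pattern in at most `maxMismatches` places; N positions match anything.
#' The reverse strand is scanned against the reverse complement and hits
#' are reported in forward-strand coordinates.  Hits are sorted by start
#' position, ties broken plus strand first.  Windows with any mismatch
#' inside a mandatory core are rejected regardless of the budget.
#'
#' @param sequence Character scalar (or `DNAString`) of A/C/G/T.
#' @param pattern A [MotifPattern-class].
#' @param maxMismatches Mismatch budget over informative positions (>= 0).
#' @param strands Strands to scan, subset of `c("+", "-")`.
#' @param seqId Sequence identifier for the output.
#' @return `data.frame` with `seq_id`, `pattern_id`, `start`, `end`,
#'   `strand`, `mismatches`.  Empty when the sequence is shorter than the
#'   pattern.
#' @export
scanMotif <- function(sequence, pattern, maxMismatches = 0,
                      strands = c("+", "-"), seqId = "seq") {
  stopifnot(maxMismatches >= 0)
  sequence <- toupper(as.character(sequence))
  plen <- patternLength(pattern)
  L <- nchar(sequence)
  empty <- data.frame(seq_id = character(), pattern_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (L < plen) return(empty)
  scanOne <- function(s) {
    v <- chars(s)
    nstart <- L - plen + 1L
    starts <- seq_len(nstart)
    mism <- integer(nstart)
    coreBad <- logical(nstart)
    for (j in pattern@informative) {
      allowed <- IUPAC_SETS[[pattern@chars[j]]]
      bad <- !(v[starts + j - 1L] %in% allowed)
      mism <- mism + bad
      if (j %in% pattern@corePositions) coreBad <- coreBad | bad
    }
    keep <- which(mism <= maxMismatches & !coreBad)
    data.frame(start = keep, mismatches = mism[keep])
  }
  res <- empty
  if ("+" %in% strands) {
    h <- scanOne(sequence)
    if (nrow(h)) {
      res <- rbind(res, data.frame(
        seq_id = seqId, pattern_id = pattern@id, start = h$start,
        end = h$start + plen - 1L, strand = "+", mismatches = h$mismatches,
        stringsAsFactors = FALSE))
    }
  }
  if ("-" %in% strands) {
    h <- scanOne(revComp(sequence))
    if (nrow(h)) {
      res <- rbind(res, data.frame(
        seq_id = seqId, pattern_id = pattern@id,
        start = L - (h$start + plen - 1L) + 1L,
        end = L - h$start + 1L, strand = "-", mismatches = h$mismatches,
        stringsAsFactors = FALSE))
    }
  }
  res[order(res$start, res$strand != "+"), , drop = FALSE]
}

#' Scan gene upstream windows for promoter-box candidates
#'
#' Runs [scanMotif()] on the upstream window of every gene (promoter
#' orientation: the forward strand of the oriented window) and converts
#' hit coordinates to offsets relative to the translation start as well as
#' genomic coordinates.
#'
#' @param annotation A [GenomeAnnotation-class] with sequences loaded.
#' @param pattern A [MotifPattern-class].
#' @param window Upstream window width in bp (>= pattern length).
#' @param maxMismatches Mismatch budget.
#' @param geneIds Genes to scan (default: all).
#' @return `data.frame` of candidates: `candidate_id`, `box_type`,
#'   `gene_id`, `replicon`, `start`, `end`, `strand`, `offset_start`,
#'   `offset_end`, `mismatches`.
#' @export
scanUpstream <- function(annotation, pattern, window, maxMismatches = 0,
                         geneIds = NULL) {
  stopifnot(window >= patternLength(pattern))
  g <- genes(annotation)
  ids <- geneIds %||% S4Vectors::mcols(g)$gene_id
  out <- list()
  n <- 0L
  for (id in ids) {
    uw <- upstreamWindow(annotation, id, window)
    w <- length(uw$offsets)
    if (w < patternLength(pattern)) next
    hits <- scanMotif(uw$sequence, pattern, maxMismatches, strands = "+",
                      seqId = id)
    if (!nrow(hits)) next
    for (r in seq_len(nrow(hits))) {
      n <- n + 1L
      gpos <- uw$positions[c(hits$start[r], hits$end[r])]
      out[[n]] <- data.frame(
        candidate_id = sprintf("%s_%s_%d", pattern@id, id, r),
        box_type = pattern@id, gene_id = id, replicon = uw$replicon,
        start = min(gpos), end = max(gpos), strand = uw$strand,
        offset_start = uw$offsets[hits$start[r]],
        offset_end = uw$offsets[hits$end[r]],
        mismatches = hits$mismatches[r], stringsAsFactors = FALSE)
    }
  }
  if (!n) {
    return(data.frame(candidate_id = character(), box_type = character(),
                      gene_id = character(), replicon = character(),
                      start = integer(), end = integer(), strand = character(),
                      offset_start = integer(), offset_end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read a pattern table
#'
#' TSV with columns `id`, `pattern`, optional `core` and `budget`.
#'
#' @param path TSV path.
#' @return Named list of [MotifPattern-class] objects; default budgets are
#'   attached as the `"budget"` attribute of each pattern.
#' @export
readPatternTable <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("id", "pattern") %in% names(df)))
  pats <- lapply(seq_len(nrow(df)), function(i) {
    core <- if ("core" %in% names(df)) df$core[i] else NULL
    if (!is.null(core) && (is.na(core) || !nzchar(core))) core <- NULL
    p <- parseMotifPattern(df$pattern[i], id = df$id[i], core = core)
    attr(p, "budget") <- if ("budget" %in% names(df)) as.integer(df$budget[i])
                         else 0L
    p
  })
  stats::setNames(pats, df$id)
}

#' Instantiate a pattern as a concrete sequence
#'
#' Fills spacer (N) positions with random bases and optionally corrupts
#' `mismatches` informative positions outside the mandatory core (used by
#' the simulator to plant imperfect boxes).
#'
#' @param pattern A [MotifPattern-class].
#' @param mismatches Number of informative positions to corrupt.
#' @param corruptCore If `TRUE`, corrupt positions inside the mandatory
#'   core instead (produces a box the scanner must reject).
#' @return Character scalar of the pattern's length.
#' @export
instantiatePattern <- function(pattern, mismatches = 0, corruptCore = FALSE) {
  v <- pattern@chars
  for (j in seq_along(v)) {
    v[j] <- sample(IUPAC_SETS[[v[j]]], 1L)
  }
  pool <- if (corruptCore) {
    if (!length(pattern@corePositions)) {
      stop("pattern has no mandatory core to corrupt")
    }
    pattern@corePositions
  } else {
    setdiff(pattern@informative, pattern@corePositions)
  }
  k <- if (corruptCore) max(mismatches, 1L) else mismatches
  if (k > 0) {
    hit <- sample(pool, min(k, length(pool)))
    for (j in hit) {
      allowed <- IUPAC_SETS[[pattern@chars[j]]]
      v[j] <- sample(setdiff(c("A", "C", "G", "T"), allowed), 1L)
    }
  }
  paste(v, collapse = "")
}
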