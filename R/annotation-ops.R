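#' Group genes into operons by intergenic distance
#'
#' Consecutive genes on the same strand of the same replicon whose
#' intergenic gap is at most `maxGap` base pairs are grouped into one
#' transcription unit.  Genes carrying a pre-existing `operon_id` tag keep
#' it untouched: tagged genes are never regrouped and act as chain breaks
#' for their untagged neighbours.  Every untagged gene ends up in an operon
#' (possibly a singleton).
#'
#' @param annotation A [GenomeAnnotation-class] (genes need not be sorted).
#' @param maxGap Maximum intergenic gap in bp (default 200).
#' @return The annotation with the operon table and per-gene `operon_id`
#'   tags filled in.
#' @export
inferOperons <- function(annotation, maxGap = 200) {
  g <- genes(annotation)
  mc <- S4Vectors::mcols(g)
  ord <- order(as.character(GenomeInfoDb::seqnames(g)), GenomicRanges::start(g))
  newId <- mc$operon_id
  counter <- 0L
  openChain <- NULL  # indices of the chain being grown
  flush <- function(chain) {
    if (!length(chain)) return()
    counter <<- counter + 1L
    newId[chain] <<- sprintf("opn_%04d", counter)
  }
  prev <- NULL
  for (i in ord) {
    if (!is.na(mc$operon_id[i])) {    # pre-tagged: break any open chain
      flush(openChain); openChain <- NULL; prev <- i
      next
    }
    chainable <- !is.null(prev) &&
      is.na(mc$operon_id[prev]) &&
      as.character(GenomeInfoDb::seqnames(g)[prev]) ==
        as.character(GenomeInfoDb::seqnames(g)[i]) &&
      as.character(GenomicRanges::strand(g)[prev]) ==
        as.character(GenomicRanges::strand(g)[i]) &&
      (GenomicRanges::start(g)[i] - GenomicRanges::end(g)[prev] - 1L) <= maxGap
    if (chainable && length(openChain)) {
      openChain <- c(openChain, i)
    } else {
      flush(openChain)
      openChain <- i
    }
    prev <- i
  }
  flush(openChain)
  mc$operon_id <- newId
  S4Vectors::mcols(g) <- mc
  annotation@genes <- g
  annotation@operons <- operonsFromTags(g)
  methods::validObject(annotation)
  annotation
}

#' Extract the upstream window of a gene
#'
#' Returns the `window` bases 5' of the translation start on the gene's
#' own strand (reverse-complemented for minus-strand genes), truncated at
#' the replicon edge.  Position `i` of the returned sequence corresponds
#' to offset `-w + i - 1` where `w` is the realized window width, so the
#' final base always has offset -1 (immediately 5' of the start codon).
#'
#' @param annotation A [GenomeAnnotation-class] with sequences loaded.
#' @param geneId Gene identifier.
#' @param window Requested window width in bp (>= 1).
#' @return A list with `sequence` (character), `offsets` (integer vector,
#'   one per base), `positions` (matching genomic coordinates), `strand`
#'   and `replicon`.
#' @export
upstreamWindow <- function(annotation, geneId, window) {
  stopifnot(window >= 1)
  g <- genes(annotation)
  i <- match(geneId, S4Vectors::mcols(g)$gene_id)
  if (is.na(i)) stop(sprintf("unknown gene id '%s'", geneId))
  repl <- as.character(GenomeInfoDb::seqnames(g)[i])
  seq <- genomeSequences(annotation)[[repl]]
  L <- length(seq)
  str <- as.character(GenomicRanges::strand(g)[i])
  if (str == "-") {
    from <- GenomicRanges::end(g)[i] + 1L
    to <- min(L, GenomicRanges::end(g)[i] + window)
    if (from > to) {
      return(list(sequence = "", offsets = integer(), positions = integer(),
                  strand = str, replicon = repl))
    }
    s <- revComp(as.character(Biostrings::subseq(seq, from, to)))
    w <- to - from + 1L
    positions <- seq.int(to, from)          # 5'->3' on the gene strand
  } else {
    to <- GenomicRanges::start(g)[i] - 1L
    from <- max(1L, GenomicRanges::start(g)[i] - window)
    if (from > to) {
      return(list(sequence = "", offsets = integer(), positions = integer(),
                  strand = str, replicon = repl))
    }
    s <- as.character(Biostrings::subseq(seq, from, to))
    w <- to - from + 1L
    positions <- seq.int(from, to)
  }
  list(sequence = s, offsets = seq.int(-w, -1L), positions = positions,
       strand = str, replicon = repl)
}

#' Link promoter boxes to their downstream genes
#'
#' For each box, the downstream gene is the nearest gene on the box strand
#' whose translation start lies 3' of the box within `maxDistance` bp; its
#' offsets (relative to the translation start, -1 = immediately 5') are
#' recorded.  When the nearest 3' gene is antisense to the box and closer
#' than any same-strand candidate, the box is flagged `opposed` and the
#' antisense gene id recorded; a box with no gene in range keeps
#' `downstream_gene = NA`.
#'
#' @param annotation A [GenomeAnnotation-class] with boxes attached.
#' @param maxDistance Search distance 3' of the box in bp (default 1000).
#' @return The annotation with box linkage columns filled.
#' @export
linkBoxToGene <- function(annotation, maxDistance = 1000) {
  b <- promoterBoxes(annotation)
  if (!length(b)) return(annotation)
  g <- genes(annotation)
  mc <- S4Vectors::mcols(b)
  gmc <- S4Vectors::mcols(g)
  grep_ <- as.character(GenomeInfoDb::seqnames(g))
  gstr <- as.character(GenomicRanges::strand(g))
  gstart <- GenomicRanges::start(g)
  gend <- GenomicRanges::end(g)
  for (k in seq_along(b)) {
    repl <- as.character(GenomeInfoDb::seqnames(b)[k])
    bstr <- as.character(GenomicRanges::strand(b)[k])
    onRepl <- grep_ == repl
    if (bstr == "-") {
      # 3' of the box = decreasing coordinates; translation start = gene end
      dist <- GenomicRanges::start(b)[k] - gend   # bp from box 3' end to start
      cand <- onRepl & dist > 0 & dist <= maxDistance
    } else {
      dist <- gstart - GenomicRanges::end(b)[k]
      cand <- onRepl & dist > 0 & dist <= maxDistance
    }
    same <- which(cand & gstr == bstr)
    anti <- which(cand & gstr != bstr)
    dSame <- if (length(same)) min(dist[same]) else Inf
    dAnti <- if (length(anti)) min(dist[anti]) else Inf
    if (is.finite(dSame)) {
      j <- same[which.min(dist[same])]
      mc$downstream_gene[k] <- gmc$gene_id[j]
      if (bstr == "-") {
        mc$offset_end[k] <- as.integer(gend[j] - GenomicRanges::start(b)[k])
        mc$offset_start[k] <- as.integer(gend[j] - GenomicRanges::end(b)[k])
      } else {
        mc$offset_start[k] <- as.integer(GenomicRanges::start(b)[k] - gstart[j])
        mc$offset_end[k] <- as.integer(GenomicRanges::end(b)[k] - gstart[j])
      }
    } else {
      mc$downstream_gene[k] <- NA_character_
      mc$offset_start[k] <- NA_integer_
      mc$offset_end[k] <- NA_integer_
    }
    if (is.finite(dAnti) && dAnti < dSame) {
      mc$opposed[k] <- TRUE
      mc$opposed_gene[k] <- gmc$gene_id[anti[which.min(dist[anti])]]
    } else {
      mc$opposed[k] <- FALSE
      mc$opposed_gene[k] <- NA_character_
    }
  }
  S4Vectors::mcols(b) <- mc
  annotation@boxes <- b
  methods::validObject(annotation)
  annotation
}

#' Nucleotide sequence of a gene
#'
#' @param annotation A [GenomeAnnotation-class] with sequences loaded.
#' @param geneId Gene identifier.
#' @return Character scalar, 5'->3' on the gene's strand.
#' @export
geneSequence <- function(annotation, geneId) {
  g <- genes(annotation)
  i <- match(geneId, S4Vectors::mcols(g)$gene_id)
  if (is.na(i)) stop(sprintf("unknown gene id '%s'", geneId))
  repl <- as.character(GenomeInfoDb::seqnames(g)[i])
  s <- as.character(Biostrings::subseq(genomeSequences(annotation)[[repl]],
                                       GenomicRanges::start(g)[i],
                                       GenomicRanges::end(g)[i]))
  if (as.character(GenomicRanges::strand(g)[i]) == "-") revComp(s) else s
}

# --- operon helpers ---------------------------------------------------------

#' Operon membership helpers
#'
#' `operonOf()` returns the operon id containing a gene (or `NA`),
#' `operonMembers()` the member gene ids in transcription order, and
#' `operonLead()` the first gene in transcription order.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param geneId,operonId Identifiers.
#' @return Character scalar(s).
#' @export
operonOf <- function(annotation, geneId) {
  op <- operons(annotation)
  i <- match(geneId, op$gene_id)
  if (is.na(i)) NA_character_ else op$operon_id[i]
}

#' @rdname operonOf
#' @export
operonMembers <- function(annotation, operonId) {
  op <- operons(annotation)
  d <- op[op$operon_id == operonId, , drop = FALSE]
  d$gene_id[order(d$idx)]
}

#' @rdname operonOf
#' @export
operonLead <- function(annotation, operonId) {
  operonMembers(annotation, operonId)[1]
}
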