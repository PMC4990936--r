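#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' GenomeAnnotation: a multi-replicon bacterial genome model
#'
#' Holds the replicon table, gene features, operon membership, promoter-box
#' annotations and the nucleotide sequence of every replicon.  All
#' coordinates are 1-based inclusive (GFF3 convention); promoter-box offsets
#' are measured relative to the first base of the start codon of the
#' downstream gene, with -1 denoting the base immediately 5' of it.
#'
#' @slot replicons `data.frame` with columns `id`, `length`, `kind`
#'   (`"chromosome"` or `"plasmid"`).
#' @slot genes `GRanges` keyed on replicon ids with metadata columns
#'   `gene_id`, `operon_id` (may be `NA`), `product`.
#' @slot operons `data.frame` with columns `operon_id`, `gene_id`, `idx`
#'   (1 = lead gene in transcription order).
#' @slot boxes `GRanges` of promoter boxes with metadata columns `box_id`,
#'   `box_type` (`"NB"`, `"TB"`, `"SyrM"`), `downstream_gene`,
#'   `offset_start`, `offset_end`, `opposed`, `opposed_gene`, `mismatches`.
#' @slot sequences `DNAStringSet`, one entry per replicon.
#'
#' @seealso [readAnnotation()], [inferOperons()], [upstreamWindow()],
#'   [linkBoxToGene()]
#' @export
setClass("GenomeAnnotation",
  slots = c(
    replicons = "data.frame",
    genes     = "GRanges",
    operons   = "data.frame",
    boxes     = "GRanges",
    sequences = "DNAStringSet"
  )
)

emptyBoxGRanges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    box_id = character(), box_type = character(),
    downstream_gene = character(), offset_start = integer(),
    offset_end = integer(), opposed = logical(),
    opposed_gene = character(), mismatches = integer()
  )
  gr
}

validGenomeAnnotation <- function(object) {
  msg <- character()
  rep <- object@replicons
  need <- c("id", "length", "kind")
  if (!all(need %in% names(rep))) {
    return(sprintf("replicon table must have columns %s",
                   paste(need, collapse = ", ")))
  }
  if (anyDuplicated(rep$id)) msg <- c(msg, "replicon ids must be unique")
  if (any(rep$length < 1)) msg <- c(msg, "replicon lengths must be >= 1")
  if (!all(rep$kind %in% c("chromosome", "plasmid"))) {
    msg <- c(msg, "replicon kind must be 'chromosome' or 'plasmid'")
  }
  g <- object@genes
  if (length(g)) {
    gid <- S4Vectors::mcols(g)$gene_id
    if (is.null(gid)) return("genes must carry a gene_id metadata column")
    if (anyDuplicated(gid)) {
      msg <- c(msg, sprintf("duplicated gene ids: %s",
                            paste(unique(gid[duplicated(gid)]), collapse = ", ")))
    }
    bad <- !(as.character(GenomeInfoDb::seqnames(g)) %in% rep$id)
    if (any(bad)) {
      msg <- c(msg, sprintf("gene '%s' references unknown replicon '%s'",
                            gid[which(bad)[1]],
                            as.character(GenomeInfoDb::seqnames(g))[which(bad)[1]]))
    }
    lens <- rep$length[match(as.character(GenomeInfoDb::seqnames(g)), rep$id)]
    oob <- which(GenomicRanges::start(g) < 1 | GenomicRanges::end(g) > lens)
    if (length(oob)) {
      msg <- c(msg, sprintf(
        "gene '%s' lies outside its replicon (coordinates %d-%d, replicon length %d)",
        gid[oob[1]], GenomicRanges::start(g)[oob[1]],
        GenomicRanges::end(g)[oob[1]], lens[oob[1]]))
    }
  }
  op <- object@operons
  if (nrow(op)) {
    gid <- S4Vectors::mcols(object@genes)$gene_id
    unknown <- setdiff(op$gene_id, gid)
    if (length(unknown)) {
      msg <- c(msg, sprintf("operon member '%s' is not an annotated gene",
                            unknown[1]))
    }
  }
  b <- object@boxes
  if (length(b)) {
    bad <- !(as.character(GenomeInfoDb::seqnames(b)) %in% rep$id)
    if (any(bad)) msg <- c(msg, "promoter box references unknown replicon")
    dg <- S4Vectors::mcols(b)$downstream_gene
    gid <- S4Vectors::mcols(object@genes)$gene_id
    unknown <- setdiff(dg[!is.na(dg)], gid)
    if (length(unknown)) {
      msg <- c(msg, sprintf("box downstream gene '%s' is not annotated",
                            unknown[1]))
    }
  }
  sq <- object@sequences
  if (length(sq)) {
    if (!all(rep$id %in% names(sq))) {
      msg <- c(msg, "every replicon needs a sequence entry")
    } else {
      w <- Biostrings::width(sq)[match(rep$id, names(sq))]
      if (any(w != rep$length)) {
        msg <- c(msg, "sequence widths disagree with replicon lengths")
      }
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("GenomeAnnotation", validGenomeAnnotation)

#' Construct a GenomeAnnotation
#'
#' @param replicons `data.frame` with `id`, `length`, `kind`.
#' @param genes `GRanges` with `gene_id`, optional `operon_id`, `product`.
#' @param operons optional operon membership `data.frame`
#'   (`operon_id`, `gene_id`, `idx`); derived from the `operon_id` gene
#'   column when omitted.
#' @param boxes optional promoter-box `GRanges` (see class docs).
#' @param sequences `DNAStringSet` named by replicon id.
#' @return A validated [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(replicons, genes, operons = NULL, boxes = NULL,
                             sequences = Biostrings::DNAStringSet()) {
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  replicons$length <- as.integer(replicons$length)
  mc <- S4Vectors::mcols(genes)
  if (is.null(mc$operon_id)) mc$operon_id <- NA_character_
  if (is.null(mc$product)) mc$product <- NA_character_
  S4Vectors::mcols(genes) <- mc
  sl <- stats::setNames(replicons$length, replicons$id)
  GenomeInfoDb::seqlevels(genes) <- replicons$id
  # out-of-bounds features raise a named error in the validity method, so
  # the GRanges-level warning would be redundant noise
  suppressWarnings(GenomeInfoDb::seqlengths(genes) <- sl)
  if (is.null(operons)) operons <- operonsFromTags(genes)
  if (is.null(boxes)) boxes <- emptyBoxGRanges()
  if (length(boxes)) {
    GenomeInfoDb::seqlevels(boxes) <- replicons$id
    GenomeInfoDb::seqlengths(boxes) <- sl
  }
  methods::new("GenomeAnnotation", replicons = replicons, genes = genes,
               operons = operons, boxes = boxes, sequences = sequences)
}

# Build the operon table from per-gene operon_id tags (transcription order).
operonsFromTags <- function(genes) {
  mc <- S4Vectors::mcols(genes)
  tagged <- which(!is.na(mc$operon_id))
  if (!length(tagged)) {
    return(data.frame(operon_id = character(), gene_id = character(),
                      idx = integer(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    operon_id = mc$operon_id[tagged],
    gene_id   = mc$gene_id[tagged],
    start     = GenomicRanges::start(genes)[tagged],
    strand    = as.character(GenomicRanges::strand(genes)[tagged]),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(split(df, df$operon_id), function(d) {
    ord <- order(d$start, decreasing = d$strand[1] == "-")
    data.frame(operon_id = d$operon_id[ord], gene_id = d$gene_id[ord],
               idx = seq_len(nrow(d)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf(
    "GenomeAnnotation: %d replicon(s), %s bp; %d genes, %d operons, %d promoter boxes\n",
    nrow(object@replicons), format(sum(object@replicons$length), big.mark = ","),
    length(object@genes), length(unique(object@operons$operon_id)),
    length(object@boxes)))
  if (nrow(object@replicons)) {
    for (i in seq_len(nrow(object@replicons))) {
      cat(sprintf("  %-12s %9d bp  (%s)\n", object@replicons$id[i],
                  object@replicons$length[i], object@replicons$kind[i]))
    }
  }
  invisible(object)
})

#' StimulonExperiment: counts plus library design
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass whose
#' `counts` assay holds non-negative integer read counts and whose
#' `colData` records, per library, the genetic background (`strain`:
#' `"WT"`, `"nodD1"` or `"ttsI"`), inducer exposure (`genistein`, logical)
#' and biological `replicate` index.
#'
#' @export
setClass("StimulonExperiment", contains = "SummarizedExperiment")

setValidity("StimulonExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("a 'counts' assay is required")
  }
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("strain", "genistein", "replicate")
  miss <- setdiff(need, names(cd))
  if (length(miss)) {
    msg <- c(msg, sprintf("colData must contain %s", paste(miss, collapse = ", ")))
  } else {
    if (!all(cd$strain %in% c("WT", "nodD1", "ttsI"))) {
      msg <- c(msg, "strain must be one of WT, nodD1, ttsI")
    }
    if (!is.logical(cd$genistein)) msg <- c(msg, "genistein must be logical")
  }
  if (anyDuplicated(colnames(object))) msg <- c(msg, "library ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulonExperiment
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   libraries in columns (colnames = library ids).
#' @param libraries `data.frame` with one row per library: `library_id`,
#'   `strain`, `genistein`, `replicate` and optionally `depth_factor`.
#' @return A [StimulonExperiment-class].
#' @export
StimulonExperiment <- function(counts, libraries) {
  libraries <- as.data.frame(libraries, stringsAsFactors = FALSE)
  stopifnot("library_id" %in% names(libraries))
  if (is.null(colnames(counts))) colnames(counts) <- libraries$library_id
  libraries <- libraries[match(colnames(counts), libraries$library_id), ,
                         drop = FALSE]
  if (anyNA(libraries$library_id)) {
    stop("count matrix columns and library table disagree")
  }
  cd <- S4Vectors::DataFrame(libraries, row.names = libraries$library_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  methods::new("StimulonExperiment", se)
}

#' StimulonReport: summary of a stimulon analysis
#'
#' Aggregates the outcome of the classification stage: the Venn partition
#' of the three strains' DEG sets, per-replicon up/down counts for every
#' strain, the box functionality calls, the gene group table, the discard
#' log, and summary totals.
#'
#' @slot venn named integer vector over the 7 disjoint Venn cells
#'   (`WT_only`, `nodD1_only`, `ttsI_only`, `WT_nodD1`, `WT_ttsI`,
#'   `nodD1_ttsI`, `all`).
#' @slot repliconCounts `data.frame`: `strain`, `replicon`, `up`, `down`.
#' @slot boxCalls `data.frame` of per-box functionality calls.
#' @slot groups `data.frame` of gene group assignments.
#' @slot discards `data.frame`: `gene_id`, `reason`.
#' @slot totals list of summary counts and genome percentages.
#' @export
setClass("StimulonReport",
  slots = c(
    venn = "integer",
    repliconCounts = "data.frame",
    boxCalls = "data.frame",
    groups = "data.frame",
    discards = "data.frame",
    totals = "list"
  )
)

setValidity("StimulonReport", function(object) {
  v <- object@venn
  cells <- c("WT_only", "nodD1_only", "ttsI_only", "WT_nodD1", "WT_ttsI",
             "nodD1_ttsI", "all")
  if (!identical(sort(names(v)), sort(cells))) {
    return("venn must have the 7 canonical cell names")
  }
  t <- object@totals
  wt_cells <- sum(v[c("WT_only", "WT_nodD1", "WT_ttsI", "all")])
  if (!is.null(t$deg_per_strain) && !is.na(t$deg_per_strain["WT"]) &&
      wt_cells != t$deg_per_strain["WT"]) {
    return("WT-containing Venn cells must sum to the WT DEG total")
  }
  TRUE
})

setMethod("show", "StimulonReport", function(object) {
  cat("StimulonReport\n")
  t <- object@totals
  if (!is.null(t$deg_per_strain)) {
    cat("  DEGs per strain: ",
        paste(sprintf("%s=%d", names(t$deg_per_strain), t$deg_per_strain),
              collapse = ", "), "\n", sep = "")
  }
  cat("  Venn cells: ",
      paste(sprintf("%s=%d", names(object@venn), object@venn), collapse = ", "),
      "\n", sep = "")
  if (nrow(object@groups)) {
    tab <- table(object@groups$group)
    cat("  Groups: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  if (nrow(object@discards)) {
    cat(sprintf("  Discarded genes: %d\n", nrow(object@discards)))
  }
  invisible(object)
})
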