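#' Read a genome annotation from GFF3 + FASTA
#'
#' Builds a [GenomeAnnotation-class] from standard files.  Gene features are
#' taken from GFF3 records of type `gene` (falling back to `CDS` when no
#' `gene` features exist); replicon sequences come from the FASTA file and
#' define the replicon table.  Replicon kind is recovered from `region`
#' features written by [writeAnnotation()] when present, otherwise the
#' longest replicon is labelled `chromosome` and the rest `plasmid`.
#'
#' @param gff3 Path to a GFF3 file whose seqids match the FASTA names.
#' @param fasta Path to a FASTA file of replicon sequences.
#' @param operonAttribute GFF3 attribute holding operon membership tags
#'   (default `"operon_id"`); absent tags leave `operon_id` as `NA`.
#' @param boxes Optional path to a promoter-box TSV (see [readBoxTable()]).
#' @return A [GenomeAnnotation-class].
#' @export
readAnnotation <- function(gff3, fasta, operonAttribute = "operon_id",
                           boxes = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff3)
  mc <- S4Vectors::mcols(gff)
  regions <- gff[mc$type == "region"]
  feats <- gff[mc$type == "gene"]
  if (!length(feats)) feats <- gff[mc$type == "CDS"]
  fseq <- as.character(GenomeInfoDb::seqnames(feats))
  missing <- setdiff(unique(fseq), names(seqs))
  if (length(missing)) {
    stop(sprintf("GFF3 seqid(s) absent from FASTA: %s",
                 paste(missing, collapse = ", ")))
  }
  kind <- rep(NA_character_, length(seqs))
  if (length(regions) && !is.null(S4Vectors::mcols(regions)$kind)) {
    kind <- S4Vectors::mcols(regions)$kind[
      match(names(seqs), as.character(GenomeInfoDb::seqnames(regions)))]
  }
  if (anyNA(kind)) {
    kind[is.na(kind)] <- "plasmid"
    kind[which.max(Biostrings::width(seqs))] <- "chromosome"
  }
  replicons <- data.frame(id = names(seqs),
                          length = Biostrings::width(seqs),
                          kind = kind, stringsAsFactors = FALSE)
  fmc <- S4Vectors::mcols(feats)
  gene_id <- fmc$ID
  if (is.null(gene_id)) stop("GFF3 gene features must carry an ID attribute")
  operon_id <- if (operonAttribute %in% names(fmc)) {
    as.character(fmc[[operonAttribute]])
  } else NA_character_
  product <- if ("product" %in% names(fmc)) as.character(fmc$product)
             else NA_character_
  g <- GenomicRanges::GRanges(
    seqnames = fseq,
    ranges = IRanges::IRanges(GenomicRanges::start(feats),
                              GenomicRanges::end(feats)),
    strand = GenomicRanges::strand(feats))
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    gene_id = as.character(gene_id),
    operon_id = operon_id, product = product)
  bx <- if (!is.null(boxes)) readBoxTable(boxes) else NULL
  GenomeAnnotation(replicons, g, boxes = bx, sequences = seqs)
}

#' Write a genome annotation to GFF3 + FASTA
#'
#' Inverse of [readAnnotation()]: `read -> write -> read` reproduces the
#' feature set exactly.  Replicon kinds are preserved through `region`
#' features.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param gff3,fasta Output paths.
#' @return Invisibly, the GFF3 path.
#' @export
writeAnnotation <- function(annotation, gff3, fasta) {
  rep <- repliconTable(annotation)
  regions <- GenomicRanges::GRanges(
    seqnames = rep$id,
    ranges = IRanges::IRanges(1L, rep$length),
    strand = "*")
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    type = "region", ID = paste0("region:", rep$id), kind = rep$kind)
  g <- genes(annotation)
  out <- g
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = "gene",
    ID = S4Vectors::mcols(g)$gene_id,
    operon_id = S4Vectors::mcols(g)$operon_id,
    product = S4Vectors::mcols(g)$product)
  GenomeInfoDb::seqlevels(regions) <- GenomeInfoDb::seqlevels(out)
  full <- suppressWarnings(c(regions, out))
  rtracklayer::export(full, gff3, format = "gff3")
  Biostrings::writeXStringSet(genomeSequences(annotation), fasta)
  invisible(gff3)
}

#' Read or write a promoter-box table
#'
#' Boxes travel as a 7-column TSV: `id`, `type`, `replicon`, `start`,
#' `end`, `strand`, `downstream_gene` (optional, empty/NA when unlinked).
#'
#' @param path TSV path.
#' @return `readBoxTable()` returns a `GRanges` suitable for
#'   [promoterBoxes<-()]; `writeBoxTable()` invisibly returns `path`.
#' @export
readBoxTable <- function(path) {
  df <- readTsv(path)
  need <- c("id", "type", "replicon", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("box table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  dg <- if ("downstream_gene" %in% names(df)) as.character(df$downstream_gene)
        else rep(NA_character_, nrow(df))
  dg[!is.na(dg) & dg == ""] <- NA_character_
  gr <- GenomicRanges::GRanges(
    seqnames = df$replicon,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    box_id = as.character(df$id), box_type = as.character(df$type),
    downstream_gene = dg,
    offset_start = NA_integer_, offset_end = NA_integer_,
    opposed = FALSE, opposed_gene = NA_character_,
    mismatches = if ("mismatches" %in% names(df)) as.integer(df$mismatches)
                 else NA_integer_)
  gr
}

#' @rdname readBoxTable
#' @param boxes Promoter-box `GRanges` (e.g. from [promoterBoxes()]).
#' @param comments Optional comment lines for the file header.
#' @export
writeBoxTable <- function(boxes, path, comments = character()) {
  mc <- S4Vectors::mcols(boxes)
  df <- data.frame(
    id = mc$box_id, type = mc$box_type,
    replicon = as.character(GenomeInfoDb::seqnames(boxes)),
    start = GenomicRanges::start(boxes), end = GenomicRanges::end(boxes),
    strand = as.character(GenomicRanges::strand(boxes)),
    downstream_gene = ifelse(is.na(mc$downstream_gene), "", mc$downstream_gene),
    stringsAsFactors = FALSE)
  writeTsv(df, path, comments)
}

#' Read or write a count matrix as TSV
#'
#' Genes in rows, libraries in columns; the first column (`gene_id`) holds
#' gene identifiers and the header row holds library ids.
#'
#' @param path TSV path.
#' @param libraries Library table (as in [StimulonExperiment()]); required
#'   by `readCountsTsv()` to rebuild the experiment object.
#' @return `readCountsTsv()` returns a [StimulonExperiment-class].
#' @export
readCountsTsv <- function(path, libraries) {
  df <- readTsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  StimulonExperiment(m, libraries)
}

#' @rdname readCountsTsv
#' @param se A [StimulonExperiment-class].
#' @param comments Optional comment lines for the file header.
#' @export
writeCountsTsv <- function(se, path, comments = character()) {
  m <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path, comments)
}
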