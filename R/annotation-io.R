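#' Read gene models from GFF3 or BED12
#'
#' Produces one record per gene with 1-based inclusive coordinates and an
#' ordered exon list. In GFF3, \code{gene} features are paired with their
#' \code{exon} children via \code{Parent}; a gene without exon children gets a
#' single exon spanning its body. In BED12 each line is one gene and its
#' blocks are the exons (converted from 0-based half-open at the boundary).
#'
#' The transcription start site (TSS) is \code{start} on the plus strand and
#' \code{end} on the minus strand; the TES is the opposite terminus.
#'
#' @param path GFF3 (\code{.gff}, \code{.gff3}) or BED12 (\code{.bed}) file.
#' @param format \code{"auto"} (by extension), \code{"gff3"} or \code{"bed12"}.
#' @return A \code{data.table} with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end}, \code{tss}, \code{tes} and a
#'   list-column \code{exons} (each a two-column matrix of start, end).
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed12" else "gff3"
  }
  genes <- if (format == "gff3") .genes_from_gff3(path) else .genes_from_bed12(path)
  .validate_gene_models(genes, path)
  genes[, tss := ifelse(strand == "+", start, end)]
  genes[, tes := ifelse(strand == "+", end, start)]
  data.table::setkey(genes, chrom, start)
  genes[]
}

.genes_from_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- as.character(gr$type) == "gene"
  g <- gr[is_gene]
  if (length(g) == 0L) stop("No gene features in GFF3: ", path)
  ids <- g$ID
  if (is.null(ids) || anyNA(ids)) ids <- g$Name
  ex <- gr[as.character(gr$type) == "exon"]
  if (length(ex) > 0L) {
    parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
    exon_by_gene <- split(
      data.table::data.table(start = BiocGenerics::start(ex),
                             end = BiocGenerics::end(ex), parent = parent),
      parent
    )
  } else {
    exon_by_gene <- list()
  }
  genes <- data.table::data.table(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(BiocGenerics::strand(g)),
    start = BiocGenerics::start(g),
    end = BiocGenerics::end(g)
  )
  genes[, exons := lapply(seq_len(.N), function(i) {
    e <- exon_by_gene[[gene_id[i]]]
    if (is.null(e) || nrow(e) == 0L) {
      cbind(start = start[i], end = end[i])
    } else {
      e <- e[order(e$start), ]
      cbind(start = e$start, end = e$end)
    }
  })]
  genes
}

.genes_from_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) {
    # BED6: whole span is the single exon
    blocks <- IRanges::IRangesList(lapply(IRanges::width(gr), function(w)
      IRanges::IRanges(1L, w)))
  } else {
    blocks <- gr$blocks
  }
  genes <- data.table::data.table(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr)
  )
  off <- genes$start - 1L
  genes[, exons := lapply(seq_len(.N), function(i) {
    b <- blocks[[i]]   # block ranges are relative to the gene start
    cbind(start = BiocGenerics::start(b) + off[i],
          end = BiocGenerics::end(b) + off[i])
  })]
  genes
}

.validate_gene_models <- function(genes, path) {
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("Gene(s) without strand in ", path, ": ",
         paste(utils::head(genes$gene_id[!genes$strand %in% c("+", "-")], 3),
               collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("Gene with start > end in ", path)
  for (i in seq_len(nrow(genes))) {
    e <- genes$exons[[i]]
    if (any(e[, "start"] < genes$start[i]) || any(e[, "end"] > genes$end[i])) {
      stop("Exon outside gene span for gene ", genes$gene_id[i], " in ", path)
    }
    if (nrow(e) > 1L && any(e[-1L, "start"] <= e[-nrow(e), "end"])) {
      stop("Overlapping exons for gene ", genes$gene_id[i], " in ", path)
    }
  }
  invisible()
}

#' Read repeat-element annotations
#'
#' Accepts a BED file whose name column carries the repeat family, or a
#' RepeatMasker-style \code{.out} table. Analysis is restricted to the four
#' families LINE, SINE, LTR and Simple: in BED input any other family is an
#' error; in RepeatMasker input other families are dropped (the class before
#' the \code{/} is used, \code{Simple_repeat} mapping to \code{Simple}).
#'
#' @param path Annotation file.
#' @param format \code{"auto"}, \code{"bed"} or \code{"rmsk"}.
#' @return \code{data.table} with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive), \code{family}.
#' @export
read_repeats <- function(path, format = c("auto", "bed", "rmsk")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.out$", path)) "rmsk" else "bed"
  families <- c("LINE", "SINE", "LTR", "Simple")
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    reps <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      family = as.character(gr$name)
    )
    bad <- setdiff(unique(reps$family), families)
    if (length(bad)) {
      stop("Repeat family outside {LINE, SINE, LTR, Simple}: ",
           paste(bad, collapse = ", "))
    }
  } else {
    lines <- readLines(path)
    lines <- lines[-seq_len(min(3L, length(lines)))]  # header block
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "\\s+")
    reps <- data.table::data.table(
      chrom = vapply(fields, `[`, "", 5L),
      start = as.integer(vapply(fields, `[`, "", 6L)),
      end = as.integer(vapply(fields, `[`, "", 7L)),
      family = sub("/.*$", "", vapply(fields, `[`, "", 11L))
    )
    reps[family == "Simple_repeat", family := "Simple"]
    reps <- reps[family %in% families]
  }
  data.table::setkey(reps, chrom, start)
  reps[]
}
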