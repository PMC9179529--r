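#' Metagene methylation profile over gene bodies and flanks
#'
#' Averages site methylation along a strand-oriented metagene axis: a fixed
#' upstream flank (default 15 kb in 200 bp bins, 75 bins), the gene body
#' rescaled into a fixed number of proportional bins (default 100) so genes
#' of different lengths align, and a matching downstream flank. Minus-strand
#' genes are mirrored so "upstream" is always 5' of the TSS. Per-gene per-bin
#' means are computed first, then averaged across genes with data; bins
#' without data stay missing. Flanks running off a chromosome end are simply
#' truncated (their bins get no sites).
#'
#' A site exactly on a proportional-bin boundary is assigned to the lower
#' bin. Overlapping genes each receive the site independently.
#'
#' @param sites Coverage-filtered call table.
#' @param genes Gene models from [read_gene_models()].
#' @param flank_bp Flank width (default 15000).
#' @param flank_bin_bp Flank bin width (default 200; 15000/200 = 75 bins).
#' @param body_bins Number of proportional body bins (default 100).
#' @param context Cytosine context (default \code{"CG"}).
#' @return \code{data.table} with \code{region} (upstream/body/downstream),
#'   \code{bin} (1-based within region), \code{mean_level}, \code{n_genes},
#'   \code{n_sites}; ordered along the metagene axis.
#' @export
metagene_profile <- function(sites, genes, flank_bp = 15000L,
                             flank_bin_bp = 200L, body_bins = 100L,
                             context = "CG") {
  stopifnot(flank_bp %% flank_bin_bp == 0)
  n_flank <- flank_bp %/% flank_bin_bp
  ctx_keep <- sites$context == context
  s <- sites[ctx_keep, ]
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    .gene_bin_means(s, genes$chrom[i], genes$start[i], genes$end[i],
                    genes$strand[i], flank_bp, flank_bin_bp, body_bins)
  })
  binned <- data.table::rbindlist(per_gene)
  skeleton <- data.table::data.table(
    region = rep(c("upstream", "body", "downstream"),
                 c(n_flank, body_bins, n_flank)),
    bin = c(seq_len(n_flank), seq_len(body_bins), seq_len(n_flank))
  )
  if (nrow(binned) == 0L) {
    skeleton[, `:=`(mean_level = NA_real_, n_genes = 0L, n_sites = 0L)]
    return(skeleton[])
  }
  agg <- binned[, .(mean_level = mean(gene_mean), n_genes = .N,
                    n_sites = sum(n_sites)), by = .(region, bin)]
  out <- merge(skeleton, agg, by = c("region", "bin"), all.x = TRUE,
               sort = FALSE)
  out[is.na(n_genes), `:=`(n_genes = 0L, n_sites = 0L)]
  out[]
}

# Per-gene mean level in every metagene bin, on the oriented axis.
.gene_bin_means <- function(s, chrom, start, end, strand,
                            flank_bp, flank_bin_bp, body_bins) {
  keep <- s$chrom == chrom & s$pos >= start - flank_bp &
    s$pos <= end + flank_bp
  sel <- s[keep, ]
  if (nrow(sel) == 0L) return(NULL)
  # Mirror minus-strand genes: work in oriented coordinates where the
  # gene always runs left to right from its TSS.
  if (strand == "+") {
    p <- sel$pos; g1 <- start; g2 <- end
  } else {
    p <- -sel$pos; g1 <- -end; g2 <- -start
  }
  len <- g2 - g1 + 1L
  region <- character(length(p)); bin <- integer(length(p))
  up <- p < g1; dn <- p > g2; body <- !up & !dn
  region[up] <- "upstream"
  bin[up] <- ((p[up] - (g1 - flank_bp)) %/% flank_bin_bp) + 1L
  region[dn] <- "downstream"
  bin[dn] <- ((p[dn] - g2 - 1L) %/% flank_bin_bp) + 1L
  region[body] <- "body"
  rel <- p[body] - g1
  bin[body] <- pmax(1L, as.integer(ceiling(rel * body_bins / len)))
  data.table::data.table(region = region, bin = bin, level = sel$level)[
    , .(gene_mean = mean(level), n_sites = .N), by = .(region, bin)]
}

#' Methylation levels of repeat families and genic partitions
#'
#' Computes the mean CG methylation of eight feature classes: the four repeat
#' families (LINE, SINE, LTR, Simple), the intragenic region (gene bodies),
#' the intergenic region (the complement of gene bodies within the union of
#' the +/-15 kb gene neighbourhoods), exons, and introns (gene bodies minus
#' exons). By default all site levels falling in any interval of a class are
#' pooled into one unweighted mean; \code{per_element = TRUE} instead
#' averages per-interval means. A site inside overlapping classes counts in
#' each of them.
#'
#' @param sites Coverage-filtered call table.
#' @param genes Gene models.
#' @param repeats Repeat table from [read_repeats()].
#' @param context Cytosine context (default \code{"CG"}).
#' @param flank_bp Width of the flank defining the intergenic universe
#'   (default 15000).
#' @param per_element Average per element before averaging classes
#'   (default \code{FALSE}: pool all sites of a class).
#' @return \code{data.table}: \code{feature}, \code{mean_level},
#'   \code{n_sites} (total sites pooled, whichever mode).
#' @export
feature_levels <- function(sites, genes, repeats, context = "CG",
                           flank_bp = 15000L, per_element = FALSE) {
  ctx_keep <- sites$context == context
  s <- sites[ctx_keep, ]
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  universe <- GenomicRanges::reduce(GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(1L, genes$start - flank_bp),
                                  genes$end + flank_bp)))
  intragenic <- GenomicRanges::reduce(gene_gr)
  intergenic <- GenomicRanges::setdiff(universe, intragenic)
  exon_dt <- data.table::rbindlist(lapply(seq_len(nrow(genes)), function(i) {
    e <- genes$exons[[i]]
    data.table::data.table(chrom = genes$chrom[i],
                           start = e[, "start"], end = e[, "end"])
  }))
  exon_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exon_dt$chrom, IRanges::IRanges(exon_dt$start, exon_dt$end)))
  intron_gr <- GenomicRanges::setdiff(intragenic, exon_gr)
  rep_grs <- lapply(c("LINE", "SINE", "LTR", "Simple"), function(f) {
    r <- repeats[repeats$family == f]
    GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
  })
  names(rep_grs) <- c("LINE", "SINE", "LTR", "Simple")
  classes <- c(rep_grs, list(intergenic = intergenic, intragenic = intragenic,
                             exon = exon_gr, intron = intron_gr))
  sgr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
  rows <- lapply(names(classes), function(f) {
    hits <- GenomicRanges::findOverlaps(sgr, classes[[f]])
    qh <- S4Vectors::queryHits(hits)
    if (length(qh) == 0L) {
      return(data.table::data.table(feature = f, mean_level = NA_real_,
                                    n_sites = 0L))
    }
    if (per_element) {
      el_means <- data.table::data.table(
        el = S4Vectors::subjectHits(hits), level = s$level[qh]
      )[, .(m = mean(level)), by = el]$m
      data.table::data.table(feature = f, mean_level = mean(el_means),
                             n_sites = length(unique(qh)))
    } else {
      lv <- s$level[unique(qh)]
      data.table::data.table(feature = f, mean_level = mean(lv),
                             n_sites = length(lv))
    }
  })
  data.table::rbindlist(rows)
}
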