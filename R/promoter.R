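#' Load a genome FASTA for CG counting
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that trims FASTA
#' description lines to the first word so sequence names match annotation
#' chromosome names.
#'
#' @param path FASTA path.
#' @return A \code{DNAStringSet} keyed by chromosome name.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

# Strand-oriented tiling of TSS +/- (nb/2 * wb) bp into nb bins of wb bp.
# Bin indices are signed and skip zero (... -1 upstream, 1 downstream ...);
# rows are ordered along the direction of transcription. On the plus strand
# bin 1 starts at the TSS; on the minus strand bin 1 ends at the TSS.
.tss_bins <- function(tss, strand, nb, wb) {
  half <- nb %/% 2L
  j <- c(seq.int(-half, -1L), seq.int(1L, half))
  if (strand == "+") {
    start <- ifelse(j > 0, tss + (j - 1L) * wb, tss + j * wb)
    end <- start + wb - 1L
  } else {
    end <- ifelse(j > 0, tss - (j - 1L) * wb, tss - j * wb)
    start <- end - wb + 1L
  }
  data.table::data.table(bin = j, start = start, end = end)
}

# CG dinucleotides whose C lies in [start, end]; the search window extends
# one base past the bin end so a CG straddling the boundary is counted here.
.count_cg <- function(seq, start, end) {
  len <- length(seq)
  s <- max(1L, start); e <- min(len, end + 1L)
  if (s > e - 1L) return(0L)
  Biostrings::countPattern("CG", Biostrings::subseq(seq, s, e))
}

#' CG-count scan of the TSS +/- 10 kb neighbourhood
#'
#' Tiles each gene's TSS +/- \code{half_bp} region into \code{n_subregions}
#' strand-oriented 200 bp subregions and counts the CG dinucleotides in each
#' (a CG is counted in the subregion containing its C). Used to locate the
#' candidate promoter region as the CG-enriched band around the TSS.
#'
#' @param genes Gene models from [read_gene_models()].
#' @param genome \code{DNAStringSet} from [read_genome()].
#' @param half_bp Half-width of the scanned neighbourhood (default 10000).
#' @param n_subregions Number of subregions (default 100; 200 bp each).
#' @return \code{data.table}: \code{gene_id}, \code{subregion} (1 = most
#'   upstream .. n = most downstream), \code{bin} (signed index skipping 0),
#'   \code{start}, \code{end}, \code{cg_count}, \code{truncated}.
#' @export
tss_scan <- function(genes, genome, half_bp = 10000L, n_subregions = 100L) {
  stopifnot((2L * half_bp) %% n_subregions == 0L)
  wb <- (2L * half_bp) %/% n_subregions
  missing_chr <- setdiff(unique(genes$chrom), names(genome))
  if (length(missing_chr)) {
    stop("Chromosome(s) missing from FASTA: ",
         paste(missing_chr, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    seq <- genome[[genes$chrom[i]]]
    b <- .tss_bins(genes$tss[i], genes$strand[i], n_subregions, wb)
    b[, `:=`(
      gene_id = genes$gene_id[i],
      subregion = seq_len(n_subregions),
      cg_count = vapply(seq_len(.N), function(k)
        .count_cg(seq, start[k], end[k]), integer(1)),
      truncated = start < 1L | end > length(seq)
    )]
    b
  })
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("gene_id", "subregion", "bin", "start",
                                 "end", "cg_count", "truncated"))
  res[]
}

#' Aggregate a TSS scan across genes
#' @param scan Output of [tss_scan()].
#' @return Per-subregion mean CG count over genes.
#' @export
aggregate_tss_scan <- function(scan) {
  scan[, .(bin = bin[1L], mean_cg = mean(cg_count), n_genes = .N),
       by = subregion][]
}

#' Promoter bin grids: CG counts and methylation per 200 bp bin
#'
#' Defines each gene's promoter as TSS +/- \code{half_bp} (default 2 kb),
#' tiled into \code{n_bins} strand-oriented 200 bp bins named by signed index
#' (bin -10 .. bin -1 upstream, bin 1 .. bin 10 downstream; bin 1 is the
#' first bin in the direction of transcription). Each bin gets its CG
#' dinucleotide count from the genome sequence and its mean methylation from
#' the qualifying CG site calls (missing when no covered site falls in the
#' bin; the CG count is computed regardless).
#'
#' @param genes Gene models.
#' @param genome \code{DNAStringSet}.
#' @param sites Coverage-filtered call table (may be \code{NULL} to skip
#'   methylation).
#' @param half_bp Promoter half-width (default 2000).
#' @param n_bins Number of bins (default 20).
#' @return \code{data.table}: \code{gene_id}, \code{bin} (signed),
#'   \code{start}, \code{end}, \code{cg_count}, \code{level},
#'   \code{truncated}.
#' @export
promoter_grids <- function(genes, genome, sites = NULL, half_bp = 2000L,
                           n_bins = 20L) {
  grid <- tss_scan(genes, genome, half_bp = half_bp, n_subregions = n_bins)
  data.table::setnames(grid, "subregion", "bin_rank")
  if (is.null(sites)) {
    grid[, level := NA_real_]
  } else {
    cg <- sites[sites$context == "CG"]
    gene_chrom <- stats::setNames(genes$chrom, genes$gene_id)
    grid[, chrom := gene_chrom[gene_id]]
    sgr <- GenomicRanges::GRanges(cg$chrom, IRanges::IRanges(cg$pos, cg$pos))
    valid <- which(grid$end >= 1L)
    ggr <- GenomicRanges::GRanges(grid$chrom[valid],
                                  IRanges::IRanges(pmax(1L, grid$start[valid]),
                                                   grid$end[valid]))
    hits <- GenomicRanges::findOverlaps(sgr, ggr)
    agg <- data.table::data.table(
      row = valid[S4Vectors::subjectHits(hits)],
      level = cg$level[S4Vectors::queryHits(hits)]
    )[, .(m = mean(level)), by = row]
    grid[, level := NA_real_]
    grid[agg$row, level := agg$m]
    grid[, chrom := NULL]
  }
  grid[]
}

#' Classify promoters by CG density
#'
#' The classification statistic is the mean CG dinucleotide count per 200 bp
#' bin over the promoter grid (total CG count / number of bins). Classes:
#' HCG (high CG density) strictly above 8 CGs per bin, LCG (low) strictly
#' below 4, ICG (intermediate) the inclusive 4--8 band. The three classes
#' are disjoint and exhaustive. Grids truncated at a chromosome edge are
#' classified on their available (non-truncated) bins and flagged.
#'
#' @param grids Output of [promoter_grids()].
#' @param hcg_min Exclusive lower bound for HCG (default 8).
#' @param lcg_max Exclusive upper bound for LCG (default 4).
#' @return \code{data.table}: \code{gene_id}, \code{mean_cg},
#'   \code{class} (\code{HCG}/\code{ICG}/\code{LCG}), \code{truncated}.
#' @export
classify_promoters <- function(grids, hcg_min = 8, lcg_max = 4) {
  cls <- grids[, .(
    mean_cg = if (any(!truncated)) mean(cg_count[!truncated]) else mean(cg_count),
    truncated = any(truncated)
  ), by = gene_id]
  cls[, class := data.table::fifelse(mean_cg > hcg_min, "HCG",
                                     data.table::fifelse(mean_cg < lcg_max,
                                                         "LCG", "ICG"))]
  cls[]
}

#' Per-class promoter methylation profiles
#'
#' For every promoter class and bin, the mean methylation level over genes
#' with data in that bin, plus each class's overall mean (all gene-bin levels
#' pooled). Empty classes are omitted with a warning.
#'
#' @param grids Output of [promoter_grids()] (with methylation levels).
#' @param classes Output of [classify_promoters()].
#' @return List with \code{profile} (class x bin table) and \code{overall}
#'   (per-class mean level and gene count).
#' @export
class_profiles <- function(grids, classes) {
  g <- merge(grids, classes[, .(gene_id, class)], by = "gene_id")
  present <- sort(unique(g$class))
  absent <- setdiff(c("HCG", "ICG", "LCG"), present)
  if (length(absent)) {
    warning("Empty promoter class(es): ", paste(absent, collapse = ", "))
  }
  profile <- g[!is.na(level),
               .(mean_level = mean(level), n_genes = .N),
               by = .(class, bin)]
  data.table::setorder(profile, class, bin)
  overall <- g[!is.na(level),
               .(mean_level = mean(level),
                 n_genes = data.table::uniqueN(gene_id)),
               by = class]
  list(profile = profile[], overall = overall[])
}
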