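#' Coverage-filter methylation calls
#'
#' Retains calls with read coverage at or above the minimum (default 3x, the
#' usual threshold below which a per-site level estimate is too noisy to use).
#' Counts of dropped sites are reported per context as a message.
#'
#' @param calls Call table from [read_cgmap()].
#' @param min_coverage Minimum total read count (default 3).
#' @param verbose Report per-context drop counts (default FALSE).
#' @return The filtered call table; a warning is raised when nothing survives.
#' @export
filter_sites <- function(calls, min_coverage = 3L, verbose = FALSE) {
  stopifnot(min_coverage >= 0)
  keep <- calls$total_reads >= min_coverage
  if (verbose && any(!keep)) {
    dropped <- table(calls$context[!keep])
    message("Dropped below ", min_coverage, "x coverage: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  }
  out <- calls[keep]
  if (nrow(out) == 0L) warning("No sites at >= ", min_coverage, "x coverage")
  out
}

#' Merge symmetric CpG strand calls
#'
#' Sums methylated and total read counts of the plus-strand C and the
#' minus-strand C of the same CpG dinucleotide (positions p and p + 1) into a
#' single call anchored at the plus-strand C. Apply before coverage filtering
#' when strand-combined CpG levels are wanted; by default the pipeline treats
#' each strand call as an independent site.
#'
#' @param calls Call table; only CG-context rows are merged, other contexts
#'   pass through unchanged.
#' @return Call table with merged CG dinucleotide calls.
#' @export
merge_cpg_calls <- function(calls) {
  cg <- calls[context == "CG"]
  other <- calls[context != "CG"]
  cg[, anchor := ifelse(strand == "+", pos, pos - 1L)]
  merged <- cg[, .(
    pos = anchor[1L], strand = "+", context = "CG", dinuc = "CG",
    meth_reads = sum(meth_reads), total_reads = sum(total_reads)
  ), by = .(chrom, anchor)]
  merged[, level := ifelse(total_reads > 0, meth_reads / total_reads, 0)]
  merged[, anchor := NULL]
  out <- data.table::rbindlist(list(merged, other), use.names = TRUE)
  data.table::setcolorder(out, c("chrom", "pos", "strand", "context", "dinuc",
                                 "level", "meth_reads", "total_reads"))
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Mean methylation level of a genomic interval
#'
#' The unweighted arithmetic mean of the levels of all sites of the requested
#' context falling in the interval (1-based inclusive on both ends). A site
#' with coverage 30 counts the same as one with coverage 3; a read-weighted
#' mean is available via \code{weighted = TRUE}. When no qualifying site
#' exists the level is undefined and \code{NA} is returned -- never 0, which
#' is a valid methylation level.
#'
#' @param sites Coverage-filtered call table.
#' @param chrom,start,end Interval in internal (1-based inclusive) coordinates.
#' @param context Cytosine context, default \code{"CG"}.
#' @param weighted If \code{TRUE}, weight site levels by total read count.
#' @return Mean level in \[0,1\], or \code{NA_real_}.
#' @export
region_level <- function(sites, chrom, start, end, context = "CG",
                         weighted = FALSE) {
  if (start > end) stop("Invalid interval: start ", start, " > end ", end)
  keep <- sites$chrom == chrom & sites$context == context &
    sites$pos >= start & sites$pos <= end
  sel <- sites[keep, ]
  if (nrow(sel) == 0L) return(NA_real_)
  if (weighted) {
    sum(sel$level * sel$total_reads) / sum(sel$total_reads)
  } else {
    mean(sel$level)
  }
}

#' Per-sample methylation level over gene bodies and flanks
#'
#' Each gene contributes the mean site level over its body extended by
#' \code{flank_bp} on both sides (one joint superinterval); the sample level
#' is the arithmetic mean over genes with a defined level. Genes with no
#' qualifying site are excluded, not zero-filled.
#'
#' @param sites Coverage-filtered call table.
#' @param genes Gene models from [read_gene_models()].
#' @param context Cytosine context, default \code{"CG"}.
#' @param flank_bp Flank width in bp (default 15000).
#' @return A list with \code{level} (the sample mean), \code{gene_levels}
#'   (per-gene table) and \code{n_genes_used}.
#' @export
sample_level <- function(sites, genes, context = "CG", flank_bp = 15000L) {
  ctx_keep <- sites$context == context
  s <- sites[ctx_keep, ]
  gl <- vapply(seq_len(nrow(genes)), function(i) {
    region_level(s, genes$chrom[i], max(1L, genes$start[i] - flank_bp),
                 genes$end[i] + flank_bp, context = context)
  }, numeric(1))
  ok <- !is.na(gl)
  if (!any(ok)) stop("No gene has a defined ", context, " level")
  list(level = mean(gl[ok]),
       gene_levels = data.table::data.table(gene_id = genes$gene_id, level = gl),
       n_genes_used = sum(ok))
}

#' Group methylation level
#'
#' The unweighted arithmetic mean of member sample levels -- the level of a
#' biological group (breed/age/tissue) is the average over its replicates.
#'
#' @param sample_levels Numeric vector of per-sample levels.
#' @param group Group label.
#' @param tissue Optional tissue label.
#' @param context Cytosine context the levels refer to.
#' @return One-row \code{data.table}: group, tissue, context, level, n_samples.
#' @export
group_level <- function(sample_levels, group, tissue = NA_character_,
                        context = "CG") {
  if (length(sample_levels) == 0L) stop("Empty group: ", group)
  data.table::data.table(group = group, tissue = tissue, context = context,
                         level = mean(sample_levels),
                         n_samples = length(sample_levels))
}

#' Distribution of per-site methylation levels
#'
#' Bins site levels into the given edges. Bins are left-closed, right-open,
#' with the last bin closed on both sides, so a split at 0.1 reproduces the
#' "< 0.1 vs >= 0.1" summary used for non-CG contexts exactly.
#'
#' @param sites Coverage-filtered call table.
#' @param context Cytosine context.
#' @param edges Strictly increasing bin edges spanning \[0,1\]
#'   (default 20 equal bins).
#' @return A list: \code{context}, \code{edges}, \code{fractions} (summing to
#'   1), \code{counts}, \code{n_sites}.
#' @export
level_distribution <- function(sites, context = "CG",
                               edges = seq(0, 1, by = 0.05)) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("Bin edges must be strictly increasing")
  }
  lv <- sites$level[sites$context == context]
  if (length(lv) == 0L) stop("No ", context, " sites to bin")
  nb <- length(edges) - 1L
  idx <- findInterval(lv, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1L] <- 1L; idx[idx > nb] <- nb
  counts <- tabulate(idx, nbins = nb)
  list(context = context, edges = edges, counts = counts,
       fractions = counts / length(lv), n_sites = length(lv))
}

#' Pool replicate calls of a biological group
#'
#' Sums methylated and total read counts per site across replicate call
#' tables, then recomputes levels and applies the coverage filter to the
#' pooled coverage. This yields a single level per site per group, matching a
#' pairwise "two samples" comparison between groups.
#'
#' @param call_list List of call tables (one per replicate).
#' @param min_coverage Coverage filter applied to pooled counts (default 3).
#' @return Pooled, filtered call table.
#' @export
pool_group_calls <- function(call_list, min_coverage = 3L) {
  all <- data.table::rbindlist(call_list, use.names = TRUE)
  pooled <- all[, .(
    dinuc = dinuc[1L],
    meth_reads = sum(meth_reads), total_reads = sum(total_reads)
  ), by = .(chrom, pos, strand, context)]
  pooled[, level := ifelse(total_reads > 0, meth_reads / total_reads, 0)]
  pooled <- pooled[total_reads >= min_coverage]
  data.table::setcolorder(pooled, c("chrom", "pos", "strand", "context",
                                    "dinuc", "level", "meth_reads",
                                    "total_reads"))
  data.table::setkey(pooled, chrom, pos)
  pooled[]
}
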