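#' Tile chromosomes with sliding scan windows
#'
#' Generates the fixed 600 bp / 300 bp step window grid used for DMR
#' screening. Windows start at \code{phase} (default 1) and advance by
#' \code{step}; a window whose end would run past the chromosome is dropped,
#' so every emitted window has exactly \code{window_bp} width.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window_bp Window width (default 600).
#' @param step_bp Step between starts (default 300).
#' @param phase Start of the first window on every chromosome (default 1).
#' @return \code{data.table} with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive) in genomic order.
#' @export
scan_windows <- function(chrom_lengths, window_bp = 600L, step_bp = 300L,
                         phase = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  if (any(chrom_lengths <= 0)) stop("Non-positive chromosome length")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    last_start <- len - window_bp + 1L
    if (last_start < phase) return(NULL)
    starts <- seq.int(phase, last_start, by = step_bp)
    data.table::data.table(chrom = ch, start = starts,
                           end = starts + window_bp - 1L)
  })
  data.table::rbindlist(out)
}

#' Per-window methylation levels for one group
#'
#' For every scan window, the number of qualifying CG sites it contains and
#' the unweighted arithmetic mean of their levels. A window with fewer than
#' \code{min_cg} qualifying sites has an undefined level (\code{NA}).
#'
#' @param windows Window grid from [scan_windows()].
#' @param sites Pooled, coverage-filtered group calls
#'   (see [pool_group_calls()]); only CG-context sites are used.
#' @param min_cg Minimum qualifying CGs per window (default 3).
#' @return The window table with added \code{n_cg} and \code{level} columns.
#' @export
window_levels <- function(windows, sites, min_cg = 3L) {
  cg <- sites[sites$context == "CG"]
  w <- data.table::copy(windows)
  w[, win_id := .I]
  sgr <- GenomicRanges::GRanges(cg$chrom, IRanges::IRanges(cg$pos, cg$pos))
  wgr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, w$end))
  hits <- GenomicRanges::findOverlaps(sgr, wgr)
  agg <- data.table::data.table(
    win_id = S4Vectors::subjectHits(hits),
    level = cg$level[S4Vectors::queryHits(hits)]
  )[, .(n_cg = .N, level = mean(level)), by = win_id]
  w <- merge(w, agg, by = "win_id", all.x = TRUE, sort = FALSE)
  w[is.na(n_cg), n_cg := 0L]
  w[n_cg < min_cg, level := NA_real_]
  data.table::setorder(w, win_id)
  w[, win_id := NULL]
  w[]
}

#' Call differentially methylated regions between two groups
#'
#' Slides the 600/300 window grid over the genome, computes each group's
#' window level (mean of at least \code{min_cg} CG levels at qualifying
#' coverage), and reports every window where both groups are defined and the
#' absolute level difference reaches \code{delta_min}. Overlapping flagged
#' windows are reported separately, never merged.
#'
#' @param sites_a,sites_b Pooled, coverage-filtered calls of the two groups.
#' @param chrom_lengths Named chromosome lengths.
#' @param group_a,group_b Group labels (must differ).
#' @param delta_min Minimum absolute level difference, in (0, 1\] (default
#'   0.15).
#' @param min_cg Minimum qualifying CGs per window per group (default 3).
#' @param window_bp,step_bp,phase Window scheme, see [scan_windows()].
#' @return \code{data.table} of DMRs in genomic order: \code{chrom},
#'   \code{start}, \code{end}, \code{group_a}, \code{group_b},
#'   \code{level_a}, \code{level_b}, \code{delta} (= level_a - level_b),
#'   \code{n_cg_a}, \code{n_cg_b}. The full compared window set is attached
#'   as attribute \code{"windows"}.
#' @export
call_dmrs <- function(sites_a, sites_b, chrom_lengths,
                      group_a = "A", group_b = "B",
                      delta_min = 0.15, min_cg = 3L,
                      window_bp = 600L, step_bp = 300L, phase = 1L) {
  if (identical(group_a, group_b)) stop("Group labels must differ")
  stopifnot(delta_min > 0, delta_min <= 1)
  grid <- scan_windows(chrom_lengths, window_bp, step_bp, phase)
  wa <- window_levels(grid, sites_a, min_cg)
  wb <- window_levels(grid, sites_b, min_cg)
  cmp <- data.table::data.table(
    chrom = grid$chrom, start = grid$start, end = grid$end,
    level_a = wa$level, level_b = wb$level,
    n_cg_a = wa$n_cg, n_cg_b = wb$n_cg
  )
  cmp <- cmp[!is.na(level_a) & !is.na(level_b)]
  cmp[, delta := level_a - level_b]
  dmrs <- cmp[abs(delta) >= delta_min]
  dmrs[, `:=`(group_a = group_a, group_b = group_b)]
  data.table::setcolorder(dmrs, c("chrom", "start", "end", "group_a",
                                  "group_b", "level_a", "level_b", "delta",
                                  "n_cg_a", "n_cg_b"))
  data.table::setorder(dmrs, chrom, start)
  data.table::setattr(dmrs, "windows", cmp)
  dmrs[]
}

#' Annotate DMRs to overlapping genes
#'
#' Every (DMR, gene) pair with any positional intersection is reported, with
#' the most specific of three interval relations recorded: the gene contained
#' in the DMR (\code{gene_in_dmr}), the DMR contained in the gene
#' (\code{dmr_in_gene}), or partial \code{overlap}. When the two intervals are
#' identical, \code{dmr_in_gene} is recorded. A DMR touching no gene is kept
#' with an empty gene field.
#'
#' @param dmrs DMR table from [call_dmrs()] (or [read_dmr_table()]).
#' @param genes Gene models from [read_gene_models()].
#' @return \code{data.table}: DMR coordinates plus \code{gene_id} and
#'   \code{criterion} (\code{NA} for unannotated DMRs).
#' @export
annotate_dmrs <- function(dmrs, genes) {
  if (nrow(dmrs) == 0L) {
    return(data.table::data.table(dmrs, gene_id = character(0),
                                  criterion = character(0)))
  }
  dgr <- GenomicRanges::GRanges(dmrs$chrom,
                                IRanges::IRanges(dmrs$start, dmrs$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(dgr, ggr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  crit <- character(length(qh))
  d_in_g <- dmrs$start[qh] >= genes$start[sh] & dmrs$end[qh] <= genes$end[sh]
  g_in_d <- genes$start[sh] >= dmrs$start[qh] & genes$end[sh] <= dmrs$end[qh]
  crit[] <- "overlap"
  crit[g_in_d] <- "gene_in_dmr"
  crit[d_in_g] <- "dmr_in_gene"   # containment beats overlap; ties -> dmr_in_gene
  ann <- data.table::data.table(dmrs[qh],
                                gene_id = genes$gene_id[sh],
                                criterion = crit)
  orphan_idx <- setdiff(seq_len(nrow(dmrs)), unique(qh))
  if (length(orphan_idx)) {
    orphans <- data.table::data.table(dmrs[orphan_idx],
                                      gene_id = NA_character_,
                                      criterion = NA_character_)
    ann <- data.table::rbindlist(list(ann, orphans), use.names = TRUE)
  }
  data.table::setorder(ann, chrom, start)
  ann[]
}

#' Write a DMR table to TSV
#'
#' Tab-separated with header; coordinates stay 1-based inclusive. If the
#' input carries gene annotations (from [annotate_dmrs()]), they are
#' collapsed per DMR into comma-joined \code{annotated_genes} /
#' \code{criteria} columns; otherwise those columns are empty. Levels are
#' written with 6 decimals.
#'
#' @param dmrs DMR table, annotated or not.
#' @param path Output path.
#' @export
write_dmr_table <- function(dmrs, path) {
  cols <- c("chrom", "start", "end", "group_a", "group_b",
            "level_a", "level_b", "delta", "n_cg_a", "n_cg_b")
  if (nrow(dmrs) == 0L) {
    hdr <- c(cols, "annotated_genes", "criteria")
    writeLines(paste(hdr, collapse = "\t"), path)
    return(invisible(path))
  }
  d <- data.table::as.data.table(dmrs)
  if ("gene_id" %in% names(d)) {
    out <- d[, c(.SD[1L, cols, with = FALSE],
                 .(annotated_genes = paste(stats::na.omit(gene_id), collapse = ","),
                   criteria = paste(stats::na.omit(criterion), collapse = ","))),
             by = .(.row = paste(chrom, start, group_a, group_b))][, .row := NULL]
  } else {
    out <- d[, cols, with = FALSE]
    out[, `:=`(annotated_genes = "", criteria = "")]
  }
  for (cc in c("level_a", "level_b", "delta")) {
    data.table::set(out, j = cc, value = sprintf("%.6f", out[[cc]]))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a DMR table written by [write_dmr_table()]
#' @param path TSV path.
#' @return DMR \code{data.table}.
#' @export
read_dmr_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  for (cc in c("level_a", "level_b", "delta")) {
    if (cc %in% names(dt)) data.table::set(dt, j = cc, value = as.numeric(dt[[cc]]))
  }
  dt[]
}

#' Export DMRs as BED6
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based
#' half-open at the boundary; the score is \code{round(1000 * |delta|)}.
#'
#' @param dmrs DMR table.
#' @param path Output BED path.
#' @export
dmrs_to_bed <- function(dmrs, path) {
  bed <- data.table::data.table(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L,
    end = dmrs$end,
    name = paste0(dmrs$group_a, "_vs_", dmrs$group_b),
    score = round(1000 * abs(dmrs$delta)),
    strand = "."
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
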