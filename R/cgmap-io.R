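#' Read a CGmap-dialect methylation call file
#'
#' Reads per-cytosine methylation calls in the tab-separated CGmap dialect
#' emitted by BS-Seeker-family callers. The canonical layout has 8 columns:
#' chromosome, nucleotide (C or G), 1-based position, context
#' (CG/CHG/CHH), raw dinucleotide context string, methylation level,
#' methylated read count, total read count. A 7-column variant lacking the
#' level column is tolerated; the level is then recomputed as
#' \code{meth_reads / total_reads}.
#'
#' Strand follows standard CGmap semantics: a \code{C} in the nucleotide
#' column is a cytosine on the plus strand, a \code{G} a cytosine on the
#' minus strand.
#'
#' @param path Path to a plain or gzip-compressed CGmap file.
#' @param min_coverage Non-negative integer; calls with
#'   \code{total_reads < min_coverage} are dropped when positive.
#' @param normalize_chr If \code{TRUE}, strip a leading \code{"chr"} prefix
#'   from chromosome names. Off by default: silent renaming hides
#'   annotation/genome mismatches.
#' @return A \code{data.table} with columns \code{chrom}, \code{pos},
#'   \code{strand}, \code{context}, \code{dinuc}, \code{level},
#'   \code{meth_reads}, \code{total_reads}, in file order.
#' @export
read_cgmap <- function(path, min_coverage = 0L, normalize_chr = FALSE) {
  stopifnot(length(path) == 1L, is.numeric(min_coverage), min_coverage >= 0)
  if (!file.exists(path)) stop("CGmap file not found: ", path)
  dt <- .fread_maybe_gz(path)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      chrom = character(0), pos = integer(0), strand = character(0),
      context = character(0), dinuc = character(0), level = numeric(0),
      meth_reads = integer(0), total_reads = integer(0)))
  }
  nc <- ncol(dt)
  if (nc == 8L) {
    data.table::setnames(dt, c("chrom", "nuc", "pos", "context", "dinuc",
                               "level", "meth_reads", "total_reads"))
  } else if (nc == 7L) {
    data.table::setnames(dt, c("chrom", "nuc", "pos", "context", "dinuc",
                               "meth_reads", "total_reads"))
  } else {
    stop("CGmap file must have 7 or 8 tab-separated columns, found ", nc,
         ": ", path)
  }
  for (col in c("pos", "meth_reads", "total_reads")) {
    data.table::set(dt, j = col,
                    value = suppressWarnings(as.integer(dt[[col]])))
  }
  if (nc == 7L) {
    dt[, level := ifelse(total_reads > 0, meth_reads / total_reads, 0)]
  } else {
    data.table::set(dt, j = "level",
                    value = suppressWarnings(as.numeric(dt$level)))
  }
  .validate_cgmap(dt, path)
  dt[, strand := ifelse(nuc == "C", "+", "-")]
  dt[, nuc := NULL]
  if (normalize_chr) dt[, chrom := sub("^chr", "", chrom)]
  if (min_coverage > 0) dt <- dt[total_reads >= min_coverage]
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "context", "dinuc",
                                "level", "meth_reads", "total_reads"))
  dt[]
}

.fread_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    txt <- readLines(con)
    if (length(txt) == 0L) return(data.table::data.table())
    data.table::fread(text = txt, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1))
  } else {
    if (file.size(path) == 0) return(data.table::data.table())
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1))
  }
}

.validate_cgmap <- function(dt, path) {
  bad_line <- function(i, what) {
    stop("Malformed CGmap line ", i, " in ", path, ": ", what, call. = FALSE)
  }
  if (nrow(dt) == 0L) return(invisible())
  if (!is.numeric(dt$pos) || anyNA(dt$pos)) {
    bad_line(which(is.na(dt$pos))[1], "non-numeric position")
  }
  bad_nuc <- which(!dt$nuc %in% c("C", "G"))
  if (length(bad_nuc)) bad_line(bad_nuc[1], paste0("nucleotide '", dt$nuc[bad_nuc[1]], "'"))
  bad_ctx <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad_ctx)) bad_line(bad_ctx[1], paste0("unknown context '", dt$context[bad_ctx[1]], "'"))
  if (!is.numeric(dt$level) || anyNA(dt$level)) {
    bad_line(which(is.na(dt$level))[1], "non-numeric level")
  }
  bad_lvl <- which(dt$level < 0 | dt$level > 1)
  if (length(bad_lvl)) bad_line(bad_lvl[1], paste0("level ", dt$level[bad_lvl[1]], " outside [0,1]"))
  bad_cnt <- which(is.na(dt$meth_reads) | is.na(dt$total_reads) |
                     dt$meth_reads < 0 | dt$meth_reads > dt$total_reads)
  if (length(bad_cnt)) bad_line(bad_cnt[1], "read counts violate 0 <= meth <= total")
  cov <- which(dt$total_reads > 0 &
                 abs(dt$level - dt$meth_reads / dt$total_reads) > 1e-6)
  if (length(cov)) bad_line(cov[1], "level inconsistent with read counts")
  invisible()
}

#' Write methylation calls as a CGmap-dialect file
#'
#' Inverse of [read_cgmap()]; emits the canonical 8-column layout.
#' Levels are written with 6 decimals so repeated runs are byte-identical.
#'
#' @param calls A call table as returned by [read_cgmap()].
#' @param path Output path (plain text).
#' @export
write_cgmap <- function(calls, path) {
  out <- data.table::data.table(
    chrom = calls$chrom,
    nuc = ifelse(calls$strand == "+", "C", "G"),
    pos = calls$pos,
    context = calls$context,
    dinuc = calls$dinuc,
    level = sprintf("%.6f", calls$level),
    meth_reads = calls$meth_reads,
    total_reads = calls$total_reads
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
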