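#' Configuration for a synthetic WGBS study
#'
#' Bundles every parameter of the toy-study generator: genome geometry, gene
#' and repeat placement, the replicate group design, read coverage, the
#' bimodal CG methylation mixture, the TSS-proximal methylation dip, repeat
#' family level shifts, and planted between-group DMRs. Defaults describe a
#' desk-scale sheep-like study: ~20.8x coverage, 68% of CG sites in a
#' high-methylation mode, near-zero CHG/CHH methylation, a methylation dip
#' around the TSS whose depth grows with promoter CG density, and the
#' tail-fat group design (DM, MG, F1TF with 3/4/3 replicates).
#'
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param n_chroms,chrom_length_bp Genome geometry (default 2 x 2 Mb).
#' @param n_genes Total genes (default 40), split evenly over chromosomes.
#' @param gene_length_bp Min/max gene length (default 2--20 kb).
#' @param exons_per_gene Min/max exon count per gene.
#' @param n_repeats Named counts per repeat family (default 50 each).
#' @param repeat_length_bp Min/max repeat length.
#' @param groups \code{data.frame(label, tissue, n_replicates)}.
#' @param mean_coverage Poisson mean read coverage per site (default 20.78).
#' @param p_high Fraction of CG sites in the high-methylation mode
#'   (default 0.68).
#' @param cg_high_mode,cg_low_mode Modes of the two Beta components of the
#'   CG mixture. The defaults place the high mode near saturation and the
#'   low mode around a third, which reproduces a ~0.68 fraction of CG sites
#'   above 0.5 together with gene-centric sample levels around 0.70 once the
#'   TSS dip is applied.
#' @param mixture_conc Beta concentration of the mixture components.
#' @param chg_chh_level Mean latent non-CG methylation (default 0.05).
#' @param chg_chh_p_high Fraction of non-CG sites in an appreciably
#'   methylated subpopulation; most non-CG cytosines are essentially
#'   unmethylated.
#' @param chg_chh_high_level Mean latent level of that subpopulation.
#' @param chg_chh_conc Beta concentration of the non-CG components.
#' @param tss_dip_halfwidth_bp Half-width of the TSS dip (default 2000).
#' @param tss_dip_depth Named depth per promoter class (multiplier removed at
#'   the TSS, tapering linearly to 0 at the half-width); deeper for
#'   CG-dense promoters so promoter methylation is negatively related to CG
#'   density.
#' @param promoter_class_fracs Fractions of genes designated HCG/ICG/LCG.
#' @param promoter_cg_per_bin Planted CG dinucleotides per 200 bp promoter
#'   bin for each designated class.
#' @param repeat_level_shift Named additive latent-level shift per family
#'   (SINE highest, Simple lowest, as in mammalian genomes).
#' @param cg_deplete_prob Probability a background CpG is disrupted, giving
#'   the CG-poor background typical of mammalian DNA.
#' @param planted_dmrs \code{data.frame(chrom, start, end, group_a, group_b,
#'   delta)}; within each interval the second group's latent CG level is
#'   shifted by \code{delta} (clipped to \[0,1\]).
#' @param contexts Cytosine contexts to emit (default all three).
#' @param non_cg_keep Fraction of CHG/CHH cytosines emitted (thinning the
#'   vastly more numerous non-CG sites; 1 = all).
#' @param replicate_jitter_conc If non-\code{NULL}, per-replicate latent
#'   levels are drawn from a Beta centred on the group latent with this
#'   concentration; by default replicates share the group latent exactly and
#'   differ only by read sampling.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length_bp = 2e6,
                       n_genes = 40L, gene_length_bp = c(2000L, 20000L),
                       exons_per_gene = c(2L, 8L),
                       n_repeats = c(LINE = 50L, SINE = 50L, LTR = 50L,
                                     Simple = 50L),
                       repeat_length_bp = c(150L, 600L),
                       groups = data.frame(
                         label = c("DM", "MG", "F1TF"),
                         tissue = "tail_fat",
                         n_replicates = c(3L, 4L, 3L)),
                       mean_coverage = 20.78,
                       p_high = 0.68,
                       cg_high_mode = 0.99, cg_low_mode = 0.33,
                       mixture_conc = 20,
                       chg_chh_level = 0.05,
                       chg_chh_p_high = 0.08,
                       chg_chh_high_level = 0.45,
                       chg_chh_conc = 40,
                       tss_dip_halfwidth_bp = 2000L,
                       tss_dip_depth = c(HCG = 0.9, ICG = 0.65, LCG = 0.3),
                       promoter_class_fracs = c(HCG = 1/3, ICG = 1/3,
                                                LCG = 1/3),
                       promoter_cg_per_bin = c(HCG = 12L, ICG = 6L,
                                               LCG = 3L),
                       repeat_level_shift = c(LINE = -0.04, SINE = 0,
                                              LTR = -0.05, Simple = -0.18),
                       cg_deplete_prob = 0.7,
                       planted_dmrs = NULL,
                       contexts = c("CG", "CHG", "CHH"),
                       non_cg_keep = 1,
                       replicate_jitter_conc = NULL) {
  cfg <- as.list(environment())
  stopifnot(p_high >= 0, p_high <= 1,
            cg_high_mode > 0, cg_high_mode < 1,
            cg_low_mode > 0, cg_low_mode < 1,
            chg_chh_level > 0, chg_chh_level < 1,
            cg_deplete_prob >= 0, cg_deplete_prob <= 1,
            non_cg_keep > 0, non_cg_keep <= 1,
            mean_coverage > 0,
            all(contexts %in% c("CG", "CHG", "CHH")),
            all(c("label", "tissue", "n_replicates") %in% names(groups)),
            all(groups$n_replicates >= 1))
  if (!is.null(planted_dmrs)) {
    stopifnot(all(c("chrom", "start", "end", "group_a", "group_b",
                    "delta") %in% names(planted_dmrs)))
    if (!all(planted_dmrs$group_a %in% groups$label) ||
        !all(planted_dmrs$group_b %in% groups$label)) {
      stop("Planted DMR names an unknown group")
    }
    if (any(planted_dmrs$start < 1) ||
        any(planted_dmrs$end > chrom_length_bp)) {
      stop("Planted DMR outside chromosome bounds")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a toy genome with gene and repeat annotations
#'
#' Generates random CG-depleted chromosome sequences, places non-overlapping
#' genes on both strands with exon/intron structure, rewrites each gene's
#' TSS +/- 2 kb promoter so every 200 bp bin carries exactly the CG count of
#' its designated density class (HCG/ICG/LCG), and scatters repeats of the
#' four analysed families in intergenic space. Planted promoter CGs are real
#' CG dinucleotides in the emitted FASTA, so sequence-based CG counting and
#' call positions agree by construction.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return List: file paths (\code{fasta}, \code{genes_gff3},
#'   \code{repeats_bed}), in-memory \code{genome} (DNAStringSet),
#'   \code{genes} (with designated \code{promoter_class}), \code{repeats},
#'   \code{chrom_lengths}.
#' @export
simulate_genome <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  L <- as.integer(config$chrom_length_bp)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- stats::setNames(rep(L, config$n_chroms), chroms)

  genes_list <- list(); reps_list <- list(); seqs <- list()
  n_per_chrom <- .split_count(config$n_genes, config$n_chroms)
  rep_per_chrom <- lapply(config$n_repeats,
                          function(n) .split_count(n, config$n_chroms))
  class_pool <- rep(names(config$promoter_class_fracs),
                    .split_count(config$n_genes,
                                 length(config$promoter_class_fracs),
                                 weights = config$promoter_class_fracs))
  gi <- 0L
  for (ci in seq_along(chroms)) {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
    # CG depletion: disrupt most background CpGs, as in mammalian genomes
    is_cg <- which(chars[-L] == "C" & chars[-1L] == "G")
    kill <- is_cg[stats::runif(length(is_cg)) < config$cg_deplete_prob]
    chars[kill + 1L] <- "A"

    placed <- .place_intervals(
      n = n_per_chrom[ci],
      len_range = config$gene_length_bp,
      chrom_len = L, margin = 12000L, min_gap = 6000L,
      what = "genes")
    if (nrow(placed)) {
      placed[, `:=`(
        chrom = chroms[ci],
        gene_id = paste0("g", gi + seq_len(.N)),
        strand = sample(c("+", "-"), .N, replace = TRUE),
        promoter_class = class_pool[gi + seq_len(.N)]
      )]
      gi <- gi + nrow(placed)
      placed[, exons := lapply(seq_len(.N), function(k)
        .random_exons(start[k], end[k], config$exons_per_gene))]
      placed[, tss := ifelse(strand == "+", start, end)]
      # rewrite promoter bins to the class's exact CG density
      for (k in seq_len(nrow(placed))) {
        n_cg <- config$promoter_cg_per_bin[[placed$promoter_class[k]]]
        chars <- .plant_promoter_cg(chars, placed$tss[k], placed$strand[k],
                                    n_cg)
      }
      genes_list[[ci]] <- placed
    }
    occupied <- placed[, .(start, end)]
    rp <- data.table::rbindlist(lapply(names(config$n_repeats), function(f) {
      n <- rep_per_chrom[[f]][ci]
      if (n == 0L) return(NULL)
      # keep repeats out of promoters and TSS-dip zones, not just gene bodies
      avoid <- occupied[, .(start = start - 2000L, end = end + 2000L)]
      r <- .place_intervals(n, config$repeat_length_bp, L, margin = 1000L,
                            min_gap = 10L, what = "repeats",
                            avoid = avoid)
      r[, family := f]
      r
    }))
    if (nrow(rp) == 0L) {
      rp <- data.table::data.table(start = integer(0), end = integer(0),
                                   family = character(0))
    }
    rp[, chrom := chroms[ci]]
    reps_list[[ci]] <- rp
    seqs[[ci]] <- paste(chars, collapse = "")
  }
  genes <- data.table::rbindlist(genes_list)
  if (nrow(genes) == 0L) {
    genes <- data.table::data.table(
      gene_id = character(0), chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0), tss = integer(0),
      promoter_class = character(0), exons = list())
  }
  genes[, tes := ifelse(strand == "+", end, start)]
  data.table::setcolorder(genes, c("gene_id", "chrom", "strand", "start",
                                   "end", "tss", "tes", "promoter_class",
                                   "exons"))
  repeats <- data.table::rbindlist(reps_list)
  genome <- Biostrings::DNAStringSet(stats::setNames(unlist(seqs), chroms))

  fasta <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta, width = 80L)
  gff3 <- file.path(outdir, "genes.gff3")
  .write_gff3(genes, gff3)
  bed <- file.path(outdir, "repeats.bed")
  data.table::fwrite(
    data.table::data.table(repeats$chrom, repeats$start - 1L, repeats$end,
                           repeats$family),
    bed, sep = "\t", col.names = FALSE, quote = FALSE)
  list(fasta = fasta, genes_gff3 = gff3, repeats_bed = bed,
       genome = genome, genes = genes, repeats = repeats,
       chrom_lengths = chrom_lengths)
}

.split_count <- function(n, k, weights = rep(1, k)) {
  raw <- floor(n * weights / sum(weights))
  left <- n - sum(raw)
  if (left > 0) raw[seq_len(left)] <- raw[seq_len(left)] + 1
  as.integer(raw)
}

.place_intervals <- function(n, len_range, chrom_len, margin, min_gap,
                             what, avoid = NULL) {
  out <- data.table::data.table(start = integer(0), end = integer(0))
  taken <- if (is.null(avoid) || nrow(avoid) == 0L) {
    data.table::data.table(start = integer(0), end = integer(0))
  } else data.table::copy(avoid)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > n * 200L) {
      stop("Could not place ", n, " non-overlapping ", what,
           " on a ", chrom_len, " bp chromosome; use a longer chromosome")
    }
    len <- sample(seq.int(len_range[1], len_range[2]), 1L)
    s <- sample.int(chrom_len - 2L * margin - len, 1L) + margin
    e <- s + len - 1L
    clash <- nrow(taken) > 0L &&
      any(s <= taken$end + min_gap & e >= taken$start - min_gap)
    if (!clash) {
      out <- rbind(out, data.table::data.table(start = s, end = e))
      taken <- rbind(taken, data.table::data.table(start = s, end = e))
    }
  }
  data.table::setorder(out, start)
  out
}

.random_exons <- function(start, end, exon_range) {
  k <- sample(seq.int(exon_range[1], exon_range[2]), 1L)
  len <- end - start + 1L
  if (2L * k - 1L >= len) k <- 1L
  if (k == 1L) return(cbind(start = start, end = end))
  cuts <- sort(sample(seq.int(start + 1L, end - 1L), 2L * k - 2L))
  bounds <- c(start, cuts, end)
  idx <- seq(1L, 2L * k - 1L, by = 2L)
  cbind(start = bounds[idx] + c(0L, rep(1L, k - 1L)),
        end = bounds[idx + 1L])
}

# Rewrite each 200 bp promoter bin of TSS +/- 2 kb: clear existing CGs,
# then plant exactly n_cg CGs on an even-offset lattice so plants never
# interfere with each other or with a neighbouring bin's straddling CG.
.plant_promoter_cg <- function(chars, tss, strand, n_cg,
                               half_bp = 2000L, bin_bp = 200L) {
  b <- .tss_bins(tss, strand, 2L * half_bp %/% bin_bp, bin_bp)
  L <- length(chars)
  for (k in seq_len(nrow(b))) {
    bs <- max(2L, b$start[k]); be <- min(L - 1L, b$end[k])
    if (bs >= be) next
    idx <- seq.int(bs, be)
    has_cg <- idx[chars[idx] == "C" & chars[idx + 1L] == "G"]
    chars[has_cg + 1L] <- "A"
    slots <- seq.int(bs + 1L, be - 2L, by = 2L)
    pick <- sort(sample(slots, min(n_cg, length(slots))))
    chars[pick] <- "C"
    chars[pick + 1L] <- "G"
  }
  chars
}

.write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    lines <- c(lines, paste(
      genes$chrom[i], "methylscan_sim", "gene", genes$start[i], genes$end[i],
      ".", genes$strand[i], ".",
      paste0("ID=", genes$gene_id[i], ";Name=", genes$gene_id[i]),
      sep = "\t"))
    e <- genes$exons[[i]]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, paste(
        genes$chrom[i], "methylscan_sim", "exon", e[j, "start"], e[j, "end"],
        ".", genes$strand[i], ".",
        paste0("ID=", genes$gene_id[i], ".e", j, ";Parent=",
               genes$gene_id[i]),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
}

#' Simulate replicate methylation-call files
#'
#' For every cytosine of the simulated genome (both strands, contexts from
#' sequence): a latent methylation probability is drawn from the bimodal CG
#' Beta mixture (non-CG sites from a low Beta with mean
#' \code{chg_chh_level}); the TSS dip multiplies CG latent levels near each
#' TSS by a factor that falls with distance to the TSS and is deepest for
#' CG-dense promoters; repeat families add their level shifts; planted DMRs
#' shift the second group's latent level by delta. Replicates of a group
#' share the latent level and differ only in read sampling: per replicate,
#' coverage ~ Poisson(\code{mean_coverage}), methylated reads ~
#' Binomial(coverage, latent); uncovered sites are not emitted.
#'
#' @param config A [sim_config()].
#' @param genome_sim Output of [simulate_genome()].
#' @param outdir Output directory for the per-replicate CGmap files.
#' @return List: \code{samples} (\code{data.table} with sample_id, tissue,
#'   group, path), \code{truth} (latent-parameter summary written alongside
#'   as \code{ground_truth.json}).
#' @export
simulate_calls <- function(config, genome_sim, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 1L)
  genes <- genome_sim$genes
  repeats <- genome_sim$repeats
  groups <- config$groups

  site_list <- lapply(names(genome_sim$genome), function(ch) {
    st <- .enumerate_cytosines(genome_sim$genome[[ch]], config)
    st[, chrom := ch]
    st
  })
  sites <- data.table::rbindlist(site_list)
  data.table::setcolorder(sites, c("chrom", "pos", "strand", "context",
                                   "dinuc"))
  n <- nrow(sites)

  # latent base level
  conc <- config$mixture_conc
  shp <- function(mode) c(mode * (conc - 2) + 1, (1 - mode) * (conc - 2) + 1)
  latent <- numeric(n)
  is_cg <- sites$context == "CG"
  n_cg <- sum(is_cg)
  hi <- stats::runif(n_cg) < config$p_high
  sh_hi <- shp(config$cg_high_mode); sh_lo <- shp(config$cg_low_mode)
  lat_cg <- numeric(n_cg)
  lat_cg[hi] <- stats::rbeta(sum(hi), sh_hi[1], sh_hi[2])
  lat_cg[!hi] <- stats::rbeta(sum(!hi), sh_lo[1], sh_lo[2])
  latent[is_cg] <- lat_cg
  base_frac_high <- mean(lat_cg > 0.5)   # mixture alone, before TSS/repeat shifts
  # non-CG: mostly near-zero with a small appreciably methylated subpopulation,
  # parameterized so the overall mean equals chg_chh_level
  n_ncg <- n - n_cg
  p_hi_ncg <- config$chg_chh_p_high
  hi_mean <- config$chg_chh_high_level
  lo_mean <- (config$chg_chh_level - p_hi_ncg * hi_mean) / (1 - p_hi_ncg)
  if (lo_mean <= 0) stop("chg_chh_level too low for the non-CG high mode")
  cc <- config$chg_chh_conc
  hi_ncg <- stats::runif(n_ncg) < p_hi_ncg
  lat_ncg <- numeric(n_ncg)
  lat_ncg[hi_ncg] <- stats::rbeta(sum(hi_ncg), hi_mean * cc,
                                  (1 - hi_mean) * cc)
  lat_ncg[!hi_ncg] <- stats::rbeta(sum(!hi_ncg), lo_mean * cc,
                                   (1 - lo_mean) * cc)
  latent[!is_cg] <- lat_ncg

  # TSS dip, class-dependent depth, linear taper (CG sites only)
  hw <- config$tss_dip_halfwidth_bp
  for (i in seq_len(nrow(genes))) {
    depth <- config$tss_dip_depth[[genes$promoter_class[i]]]
    idx <- which(sites$chrom == genes$chrom[i] & is_cg &
                   abs(sites$pos - genes$tss[i]) <= hw)
    if (length(idx)) {
      d <- abs(sites$pos[idx] - genes$tss[i])
      latent[idx] <- latent[idx] * (1 - depth * (1 - d / hw))
    }
  }
  # repeat family shifts (CG sites only)
  for (i in seq_len(nrow(repeats))) {
    shift <- config$repeat_level_shift[[repeats$family[i]]]
    if (shift == 0) next
    idx <- which(sites$chrom == repeats$chrom[i] & is_cg &
                   sites$pos >= repeats$start[i] &
                   sites$pos <= repeats$end[i])
    latent[idx] <- pmin(1, pmax(0, latent[idx] + shift))
  }

  # per-group latent levels (planted DMR shifts applied to group_b)
  group_latent <- lapply(groups$label, function(g) latent)
  names(group_latent) <- groups$label
  if (!is.null(config$planted_dmrs)) {
    pd <- config$planted_dmrs
    for (i in seq_len(nrow(pd))) {
      idx <- which(sites$chrom == pd$chrom[i] & is_cg &
                     sites$pos >= pd$start[i] & sites$pos <= pd$end[i])
      g <- pd$group_b[i]
      group_latent[[g]][idx] <-
        pmin(1, pmax(0, group_latent[[g]][idx] + pd$delta[i]))
    }
  }

  samples <- list()
  for (gi in seq_len(nrow(groups))) {
    glab <- groups$label[gi]
    lat_g <- group_latent[[glab]]
    for (r in seq_len(groups$n_replicates[gi])) {
      lat <- lat_g
      if (!is.null(config$replicate_jitter_conc)) {
        cc <- config$replicate_jitter_conc
        eps <- 1e-4
        p <- pmin(1 - eps, pmax(eps, lat))
        lat <- stats::rbeta(n, p * cc, (1 - p) * cc)
      }
      cov <- stats::rpois(n, config$mean_coverage)
      meth <- stats::rbinom(n, cov, lat)
      keep <- cov > 0L
      calls <- data.table::data.table(
        chrom = sites$chrom[keep], pos = sites$pos[keep],
        strand = sites$strand[keep], context = sites$context[keep],
        dinuc = sites$dinuc[keep],
        level = meth[keep] / cov[keep],
        meth_reads = meth[keep], total_reads = cov[keep])
      sid <- paste0(glab, "_rep", r)
      path <- file.path(outdir, paste0(sid, ".cgmap"))
      write_cgmap(calls, path)
      samples[[length(samples) + 1L]] <- data.table::data.table(
        sample_id = sid, tissue = groups$tissue[gi], group = glab,
        path = path)
    }
  }
  truth <- list(
    seed = config$seed,
    n_sites = n,
    n_cg_sites = n_cg,
    latent_cg_mean = mean(latent[is_cg]),
    latent_cg_frac_above_0.5 = mean(latent[is_cg] > 0.5),
    latent_cg_frac_above_0.5_base = base_frac_high,
    latent_noncg_mean = if (n > n_cg) mean(latent[!is_cg]) else NA,
    promoter_classes = stats::setNames(as.list(genes$promoter_class),
                                       genes$gene_id),
    planted_dmrs = config$planted_dmrs
  )
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(samples = data.table::rbindlist(samples), truth = truth)
}

# All cytosines of one chromosome, both strands, with sequence context.
.enumerate_cytosines <- function(seq, config) {
  chars <- strsplit(as.character(seq), "")[[1]]
  L <- length(chars)
  pad <- c(chars, "N", "N")      # so i+1 / i+2 lookups never overflow
  padl <- c("N", "N", chars)     # shifted for minus-strand lookbehind
  cpos <- which(chars == "C")
  ctx_p <- ifelse(pad[cpos + 1L] == "G", "CG",
                  ifelse(pad[cpos + 2L] == "G", "CHG", "CHH"))
  din_p <- ifelse(ctx_p == "CG", "CG",
                  paste0("C", pad[cpos + 1L]))
  gpos <- which(chars == "G")
  # minus-strand cytosine at a G: read the complement 5'->3' (leftwards)
  up1 <- padl[gpos + 1L]   # genomic pos - 1
  up2 <- padl[gpos]        # genomic pos - 2
  ctx_m <- ifelse(up1 == "C", "CG",
                  ifelse(up2 == "C", "CHG", "CHH"))
  din_m <- ifelse(ctx_m == "CG", "CG",
                  paste0("C", .revcomp_base(up1)))
  st <- data.table::data.table(
    pos = c(cpos, gpos),
    strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
    context = c(ctx_p, ctx_m),
    dinuc = c(din_p, din_m))
  st <- st[context %in% config$contexts]
  if (config$non_cg_keep < 1) {
    noncg <- st$context != "CG"
    drop <- noncg & stats::runif(nrow(st)) >= config$non_cg_keep
    st <- st[!drop]
  }
  data.table::setorder(st, pos)
  st
}

.revcomp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_genome()] and [simulate_calls()] into one directory.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @return List combining both stages: file paths, in-memory annotation
#'   objects, \code{chrom_lengths}, \code{samples} table and \code{truth}.
#' @export
simulate_study <- function(config, outdir) {
  g <- simulate_genome(config, outdir)
  cc <- simulate_calls(config, g, outdir)
  c(g, cc)
}
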