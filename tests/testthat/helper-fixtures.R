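# Fixtures are built in code at test time; the shared synthetic study is
# simulated once per session and reused across test files.

.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$st)) {
    cfg <- sim_config(
      seed = 42L, n_chroms = 1L, chrom_length_bp = 6e5, n_genes = 24L,
      gene_length_bp = c(2000L, 8000L),
      n_repeats = c(LINE = 10L, SINE = 10L, LTR = 10L, Simple = 10L),
      non_cg_keep = 0.15)
    dir <- file.path(tempdir(), "methylscan-shared-sim")
    .sim_cache$cfg <- cfg
    .sim_cache$st <- simulate_study(cfg, dir)
    st <- .sim_cache$st
    .sim_cache$genes <- read_gene_models(st$genes_gff3)
    .sim_cache$repeats <- read_repeats(st$repeats_bed)
    .sim_cache$genome <- read_genome(st$fasta)
    .sim_cache$calls1 <- read_cgmap(st$samples$path[1])
    .sim_cache$sites1 <- filter_sites(.sim_cache$calls1, 3)
  }
  .sim_cache
}

cg_line <- function(chrom = "chr1", nuc = "C", pos = 100, ctx = "CG",
                    dinuc = "CG", level = 1, meth = 3, total = 3) {
  paste(chrom, nuc, pos, ctx, dinuc, level, meth, total, sep = "\t")
}

write_mini_cgmap <- function(lines, path = tempfile(fileext = ".cgmap")) {
  writeLines(lines, path)
  path
}

# a deterministic in-memory site table (already coverage-filtered)
make_sites <- function(chrom, pos, level, context = "CG", coverage = 10L) {
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos), strand = "+", context = context,
    dinuc = ifelse(context == "CG", "CG", "CA"),
    level = level,
    meth_reads = as.integer(round(level * coverage)),
    total_reads = as.integer(coverage))
}

# brute-force oracle: unweighted mean level of context sites in [start, end],
# by an explicit single-pass loop over every site
brute_region_level <- function(sites, chrom, start, end, context = "CG") {
  total <- 0; n <- 0L
  s_chrom <- sites$chrom; s_ctx <- sites$context
  s_pos <- sites$pos; s_lvl <- sites$level
  for (i in seq_along(s_pos)) {
    if (s_chrom[i] == chrom && s_ctx[i] == context &&
        s_pos[i] >= start && s_pos[i] <= end) {
      total <- total + s_lvl[i]
      n <- n + 1L
    }
  }
  if (n == 0L) NA_real_ else total / n
}

# brute-force oracle: CG dinucleotide count with the C inside [start, end]
brute_cg_count <- function(seq_string, start, end) {
  n <- 0L
  L <- nchar(seq_string)
  for (p in max(1, start):min(L - 1, end)) {
    if (substr(seq_string, p, p + 1) == "CG") n <- n + 1L
  }
  n
}
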