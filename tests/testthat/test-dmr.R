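# two site tables whose single 600 bp window has exact, controlled levels
window_pair <- function(level_a, level_b, n_cg = 3L, coverage = 10000L) {
  pos <- seq(100L, by = 150L, length.out = n_cg)
  list(a = make_sites("chr1", pos, rep(level_a, n_cg), coverage = coverage),
       b = make_sites("chr1", pos, rep(level_b, n_cg), coverage = coverage))
}

test_that("scan windows tile chromosomes in 600/300 steps without partials", {
  w <- scan_windows(c(chr1 = 1500L))
  expect_equal(w$start, c(1L, 301L, 601L, 901L))
  expect_equal(w$end, c(600L, 900L, 1200L, 1500L))
  expect_equal(nrow(scan_windows(c(chr1 = 599L))), 0L)
  one <- scan_windows(c(chr1 = 600L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$end - one$start + 1L, 600L)
  expect_error(scan_windows(c(chr1 = 0L)), "Non-positive")
  # geometry invariant across random lengths
  set.seed(2)
  for (len in sample(600:50000, 10)) {
    w <- scan_windows(stats::setNames(len, "c"))
    expect_true(all(w$end - w$start + 1L == 600L))
    if (nrow(w) > 1) expect_true(all(diff(w$start) == 300L))
    expect_true(all(w$end <= len))
  }
})

test_that("window levels are means of at least three qualifying CGs", {
  s <- make_sites("chr1", c(100, 300, 500), c(0.1, 0.5, 0.9))
  w <- window_levels(scan_windows(c(chr1 = 600L)), s)
  expect_equal(w$n_cg, 3L)
  expect_equal(w$level, 0.5)
  s2 <- make_sites("chr1", c(100, 300), c(0.1, 0.9))
  w2 <- window_levels(scan_windows(c(chr1 = 600L)), s2)
  expect_equal(w2$n_cg, 2L)
  expect_true(is.na(w2$level))
})

test_that("window levels match a brute-force site loop on many random windows", {
  st <- shared_sim()
  sites <- st$sites1
  grid <- scan_windows(st$st$chrom_lengths)
  wl <- window_levels(grid, sites)
  set.seed(13)
  idx <- sample.int(nrow(grid), 100)
  for (i in idx) {
    want <- brute_region_level(sites, grid$chrom[i], grid$start[i],
                               grid$end[i])
    got <- wl$level[i]
    if (is.na(got)) {
      n <- sum(sites$context == "CG" & sites$chrom == grid$chrom[i] &
                 sites$pos >= grid$start[i] & sites$pos <= grid$end[i])
      expect_lt(n, 3)
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("the 0.15 difference threshold is inclusive", {
  exact <- window_pair(0.65, 0.50)
  d1 <- call_dmrs(exact$a, exact$b, c(chr1 = 600L), "A", "B")
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$delta, 0.15, tolerance = 1e-9)
  below <- window_pair(0.6499, 0.50)
  d2 <- call_dmrs(below$a, below$b, c(chr1 = 600L), "A", "B")
  expect_equal(nrow(d2), 0L)
})

test_that("a 0.01-grid sweep of constructed deltas flags exactly >= 0.15", {
  for (d100 in seq(0L, 40L, by = 1L)) {
    wp <- window_pair(0.50 + d100 / 100, 0.50)
    dm <- call_dmrs(wp$a, wp$b, c(chr1 = 600L), "A", "B")
    expect_equal(nrow(dm), as.integer(d100 >= 15L),
                 info = paste("delta =", d100 / 100))
  }
})

test_that("windows qualify only with >= 3 CGs at >= 3x coverage", {
  # third CG at 2x coverage is lost to the pooled filter -> window undefined
  a <- rbind(make_sites("chr1", c(100, 300), c(0.9, 0.9), coverage = 10L),
             make_sites("chr1", 500, 0.9, coverage = 2L))
  b <- make_sites("chr1", c(100, 300, 500), c(0.1, 0.1, 0.1), coverage = 10L)
  a_f <- filter_sites(a, 3)
  dm <- call_dmrs(a_f, b, c(chr1 = 600L), "A", "B")
  expect_equal(nrow(dm), 0L)
  # at 3x it qualifies
  a2 <- rbind(make_sites("chr1", c(100, 300), c(0.9, 0.9), coverage = 10L),
              make_sites("chr1", 500, 1, coverage = 3L))
  dm2 <- call_dmrs(filter_sites(a2, 3), b, c(chr1 = 600L), "A", "B")
  expect_equal(nrow(dm2), 1L)
})

test_that("swapping groups negates deltas and preserves the flagged set", {
  st <- shared_sim()
  sa <- st$st$samples
  pa <- pool_group_calls(lapply(sa$path[sa$group == "DM"], read_cgmap))
  pb <- pool_group_calls(lapply(sa$path[sa$group == "MG"], read_cgmap))
  lens <- st$st$chrom_lengths
  ab <- call_dmrs(pa, pb, lens, "DM", "MG", delta_min = 0.05)
  ba <- call_dmrs(pb, pa, lens, "MG", "DM", delta_min = 0.05)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$start, ba$start)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
})

test_that("raising the threshold never increases the number of DMRs", {
  st <- shared_sim()
  sa <- st$st$samples
  pa <- pool_group_calls(lapply(sa$path[sa$group == "DM"], read_cgmap))
  pb <- pool_group_calls(lapply(sa$path[sa$group == "MG"], read_cgmap))
  lens <- st$st$chrom_lengths
  n_prev <- Inf
  for (th in c(0.02, 0.05, 0.1, 0.15, 0.3)) {
    n <- nrow(call_dmrs(pa, pb, lens, "DM", "MG", delta_min = th))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("self-comparison yields no DMRs and equal labels are refused", {
  st <- shared_sim()
  sa <- st$st$samples
  pa <- pool_group_calls(lapply(sa$path[sa$group == "DM"], read_cgmap))
  expect_error(call_dmrs(pa, pa, st$st$chrom_lengths, "DM", "DM"),
               "labels")
  dm <- call_dmrs(pa, pa, st$st$chrom_lengths, "DM", "DM2")
  expect_equal(nrow(dm), 0L)
})

test_that("annotation records the most specific interval relation", {
  genes <- data.table::data.table(
    gene_id = c("inner", "big"), chrom = "chr1", strand = "+",
    start = c(200L, 650L), end = c(500L, 6000L))
  dmrs <- data.table::data.table(
    chrom = "chr1", start = c(100L, 100L, 7000L), end = c(699L, 699L, 7599L),
    group_a = "A", group_b = "B", level_a = 0.8, level_b = 0.5,
    delta = 0.3, n_cg_a = 5L, n_cg_b = 5L)[c(1, 3)]
  ann <- annotate_dmrs(dmrs, genes)
  expect_equal(ann[ann$gene_id == "inner", ]$criterion, "gene_in_dmr")
  expect_equal(ann[ann$gene_id == "big", ]$criterion, "overlap")
  expect_true(is.na(ann[ann$start == 7000L, ]$gene_id))
  # identical intervals resolve to dmr_in_gene
  same <- data.table::data.table(
    chrom = "chr1", start = 200L, end = 500L, group_a = "A", group_b = "B",
    level_a = 0.8, level_b = 0.5, delta = 0.3, n_cg_a = 3L, n_cg_b = 3L)
  expect_equal(annotate_dmrs(same, genes)$criterion[1], "dmr_in_gene")
})

test_that("annotation agrees with a brute-force all-pairs interval check", {
  set.seed(17)
  genes <- data.table::data.table(
    gene_id = paste0("g", 1:30), chrom = sample(c("c1", "c2"), 30, TRUE),
    strand = "+", start = sample.int(50000, 30))
  genes[, end := start + sample.int(8000, 30)]
  starts <- sample.int(55000, 40)
  dmrs <- data.table::data.table(
    chrom = sample(c("c1", "c2"), 40, TRUE),
    start = starts, end = starts + 599L, group_a = "A", group_b = "B",
    level_a = 0.8, level_b = 0.5, delta = 0.3, n_cg_a = 3L, n_cg_b = 3L)
  ann <- annotate_dmrs(dmrs, genes)
  pairs <- ann[!is.na(ann$gene_id), ]
  brute <- list()
  for (i in seq_len(nrow(dmrs))) {
    for (j in seq_len(nrow(genes))) {
      if (dmrs$chrom[i] == genes$chrom[j] &&
          dmrs$start[i] <= genes$end[j] && dmrs$end[i] >= genes$start[j]) {
        crit <- if (dmrs$start[i] >= genes$start[j] &&
                    dmrs$end[i] <= genes$end[j]) "dmr_in_gene"
        else if (genes$start[j] >= dmrs$start[i] &&
                 genes$end[j] <= dmrs$end[i]) "gene_in_dmr"
        else "overlap"
        brute[[length(brute) + 1L]] <- data.table::data.table(
          chrom = dmrs$chrom[i], start = dmrs$start[i],
          gene_id = genes$gene_id[j], criterion = crit)
      }
    }
  }
  brute <- data.table::rbindlist(brute)
  data.table::setorder(brute, chrom, start, gene_id)
  got <- pairs[, c("chrom", "start", "gene_id", "criterion")]
  data.table::setorder(got, chrom, start, gene_id)
  expect_equal(got, brute)
})
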