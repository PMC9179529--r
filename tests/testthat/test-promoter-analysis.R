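test_that("promoter bins tile TSS +/- 2 kb with the documented orientation", {
  genes <- data.table::data.table(
    gene_id = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
    start = c(10000L, 5000L), end = c(12000L, 10000L),
    tss = c(10000L, 10000L), tes = c(12000L, 5000L))
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 5000), collapse = "")))
  grids <- promoter_grids(genes, genome, sites = NULL)
  gp <- grids[grids$gene_id == "gp", ]
  expect_equal(nrow(gp), 20L)
  expect_true(all(gp$end - gp$start + 1L == 200L))
  expect_equal(gp[gp$bin == 1L, c("start", "end")],
               data.table::data.table(start = 10000L, end = 10199L))
  expect_equal(gp[gp$bin == -1L, c("start", "end")],
               data.table::data.table(start = 9800L, end = 9999L))
  gm <- grids[grids$gene_id == "gm", ]
  expect_equal(gm[gm$bin == 1L, c("start", "end")],
               data.table::data.table(start = 9801L, end = 10000L))
  expect_equal(gm[gm$bin == -1L, c("start", "end")],
               data.table::data.table(start = 10001L, end = 10200L))
  # bins tile the promoter contiguously
  expect_equal(sort(c(gp$start, gp$end)),
               sort(c(seq(8000, 11800, 200), seq(8199, 11999, 200))))
})

test_that("CG counting handles saturated, empty and boundary-straddling cases", {
  genome <- Biostrings::DNAStringSet(c(
    cgs = paste(rep("CG", 15000), collapse = ""),
    noc = paste(rep("AT", 15000), collapse = "")))
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = c("cgs", "noc"), strand = "+",
    start = c(15000L, 15000L), end = c(16000L, 16000L),
    tss = c(15000L, 15000L), tes = c(16000L, 16000L))
  scan <- tss_scan(genes, genome)
  expect_equal(nrow(scan[scan$gene_id == "g1", ]), 100L)
  expect_true(all(scan[scan$gene_id == "g1", ]$cg_count == 100L))
  expect_true(all(scan[scan$gene_id == "g2", ]$cg_count == 0L))
  # a CG straddling a bin boundary belongs to the bin holding its C
  g3 <- Biostrings::DNAStringSet(c(chr = paste0(
    paste(rep("A", 199), collapse = ""), "CG",
    paste(rep("A", 600), collapse = ""))))
  genes3 <- data.table::data.table(
    gene_id = "g3", chrom = "chr", strand = "+", start = 1L, end = 500L,
    tss = 1L, tes = 500L)
  grid <- promoter_grids(genes3, g3, NULL, half_bp = 200L, n_bins = 2L)
  expect_equal(grid[grid$bin == 1L, ]$cg_count, 1L)   # C at position 200
  expect_equal(grid[grid$bin == -1L, ]$cg_count, 0L)
})

test_that("tss_scan refuses chromosomes missing from the FASTA", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chrX", strand = "+", start = 4L, end = 6L,
    tss = 4L, tes = 6L)
  expect_error(tss_scan(genes, genome), "chrX")
})

test_that("sequence CG counts equal a brute-force dinucleotide scan", {
  st <- shared_sim()
  grids <- promoter_grids(st$genes, st$genome, NULL)
  seq_str <- as.character(st$genome[[1]])
  set.seed(5)
  check <- grids[sample.int(nrow(grids), 40), ]
  for (i in seq_len(nrow(check))) {
    expect_equal(check$cg_count[i],
                 brute_cg_count(seq_str, check$start[i], check$end[i]))
  }
})

test_that("promoter classes cut at 8 (HCG, exclusive) and 4 (LCG, exclusive)", {
  grids <- data.table::rbindlist(lapply(1:20, function(d) {
    data.table::data.table(gene_id = paste0("g", d),
                           bin = c(-(10:1), 1:10),
                           start = 1L, end = 200L,
                           cg_count = d, truncated = FALSE)
  }))
  cls <- classify_promoters(grids)
  expect_equal(cls$mean_cg, as.numeric(1:20))
  want <- ifelse(1:20 > 8, "HCG", ifelse(1:20 < 4, "LCG", "ICG"))
  expect_equal(cls$class, want)
  expect_equal(cls$class[4], "ICG")   # exactly 4 -> ICG
  expect_equal(cls$class[8], "ICG")   # exactly 8 -> ICG
  expect_equal(cls$class[9], "HCG")
  expect_equal(cls$class[3], "LCG")
})

test_that("classification partitions the gene set of the synthetic study", {
  st <- shared_sim()
  grids <- promoter_grids(st$genes, st$genome, st$sites1)
  cls <- classify_promoters(grids)
  expect_equal(nrow(cls), nrow(st$genes))
  expect_true(all(cls$class %in% c("HCG", "ICG", "LCG")))
  # designated generator classes are recovered exactly
  truth <- st$st$genes[, c("gene_id", "promoter_class")]
  cmp <- merge(cls, truth, by = "gene_id")
  expect_equal(cmp$class, cmp$promoter_class)
})

test_that("class profiles are order-invariant and collapse to single genes", {
  st <- shared_sim()
  grids <- promoter_grids(st$genes, st$genome, st$sites1)
  cls <- classify_promoters(grids)
  p1 <- class_profiles(grids, cls)
  shuffled <- grids[sample.int(nrow(grids)), ]
  p2 <- class_profiles(shuffled, cls)
  expect_equal(p1$profile, p2$profile)
  expect_equal(p1$overall, p2$overall)
  one <- grids[grids$gene_id == st$genes$gene_id[1], ]
  pc <- suppressWarnings(class_profiles(one, cls))
  with_lvl <- one[!is.na(one$level), ]
  expect_equal(pc$profile$mean_level,
               with_lvl$level[order(with_lvl$bin)])
})
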