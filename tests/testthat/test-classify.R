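test_that("promoter calls follow the TSS-window overlap rule", {
  tss <- data.frame(gene_id = "g", chrom = "chr1", pos = 1100, strand = "+")
  cand <- data.frame(chrom = "chr1", start = 0, end = 700, group = "active")
  # window [600, 1601) overlaps [600, 700)
  expect_equal(classify_promoters(cand, tss)$class, "AP")
  tss$pos <- 1300  # window [800, 1801): no overlap
  expect_equal(nrow(classify_promoters(cand, tss)), 0)
  cand$group <- "poised"
  tss$pos <- 500
  expect_equal(classify_promoters(cand, tss)$class, "BP")
})

test_that("enhancer calls require p300 and yield to promoter precedence", {
  tss <- data.frame(gene_id = "g", chrom = "chr1", pos = 300, strand = "+")
  p300 <- data.frame(chrom = "chr1", start = c(699, 5000),
                     end = c(900, 5100))
  cand <- data.frame(chrom = "chr1",
                     start = c(0, 4800, 10000),
                     end = c(700, 5200, 11000),
                     group = c("active", "active", "poised"))
  regions <- classify_regions(cand, tss, p300)
  # candidate 1 overlaps both the TSS window and a p300 peak: promoter wins
  expect_equal(regions$class[regions$start == 0], "AP")
  # candidate 2 overlaps p300 only (1-bp overlaps count)
  expect_equal(regions$class[regions$start == 4800], "AE")
  # candidate 3 has neither: dropped
  expect_false(10000 %in% regions$start)
  # poised + p300 -> PE
  cand2 <- data.frame(chrom = "chr1", start = 4800, end = 5200,
                      group = "poised")
  expect_equal(classify_enhancers(cand2, regions[0, ], p300)$class, "PE")
})

test_that("classification matches a brute-force all-pairs oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n_c <- 200; n_t <- 100; n_p <- 100
    cand <- data.frame(chrom = sample(c("chr1", "chr2"), n_c, TRUE),
                       start = s <- sample.int(4e5, n_c),
                       end = s + sample(300:2000, n_c, TRUE),
                       group = sample(c("active", "poised"), n_c, TRUE))
    tss <- data.frame(gene_id = paste0("g", 1:n_t),
                      chrom = sample(c("chr1", "chr2"), n_t, TRUE),
                      pos = sample.int(4e5, n_t), strand = "+")
    p300 <- data.frame(chrom = sample(c("chr1", "chr2"), n_p, TRUE),
                       start = ps <- sample.int(4e5, n_p),
                       end = ps + sample(100:600, n_p, TRUE))
    got <- classify_regions(cand, tss, p300)
    # oracle: explicit loops over every candidate x TSS / peak
    exp_class <- character(0); exp_key <- character(0)
    for (i in seq_len(n_c)) {
      prom <- FALSE
      for (j in seq_len(n_t)) {
        if (brute_overlap(cand$chrom[i], cand$start[i], cand$end[i],
                          tss$chrom[j], tss$pos[j] - 500, tss$pos[j] + 501))
          prom <- TRUE
      }
      enh <- FALSE
      if (!prom) {
        for (j in seq_len(n_p)) {
          if (brute_overlap(cand$chrom[i], cand$start[i], cand$end[i],
                            p300$chrom[j], p300$start[j], p300$end[j]))
            enh <- TRUE
        }
      }
      if (prom || enh) {
        cls <- if (prom) {
          if (cand$group[i] == "active") "AP" else "BP"
        } else {
          if (cand$group[i] == "active") "AE" else "PE"
        }
        exp_class <- c(exp_class, cls)
        exp_key <- c(exp_key, paste(cand$chrom[i], cand$start[i], cand$end[i]))
      }
    }
    got_key <- paste(got$chrom, got$start, got$end)
    expect_setequal(paste(got_key, got$class), paste(exp_key, exp_class))
  }
})

test_that("gene assignment deduplicates and allows many-to-many pairs", {
  prom <- data.frame(id = "AP_1", chrom = "chr1", start = 0, end = 2000)
  tss <- data.frame(gene_id = c("g1", "g2", "g2"),
                    chrom = "chr1", pos = c(500, 1000, 1500), strand = "+")
  gm <- assign_genes_to_promoters(prom, tss)
  expect_equal(nrow(gm), 2)   # g2's two TSSs collapse to one pair
  expect_setequal(gm$gene_id, c("g1", "g2"))
  # promoter with no overlapping window yields zero pairs
  tss_far <- data.frame(gene_id = "g3", chrom = "chr1", pos = 99000,
                        strand = "+")
  expect_equal(nrow(assign_genes_to_promoters(prom, tss_far)), 0)
})

test_that("TSS distance and the 5-kb distal rule use a strict inequality", {
  regions <- data.frame(id = c("r1", "r2", "r3"), chrom = "chr1",
                        start = c(0, 0, 0), end = c(1000, 1000, 1000))
  tss <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(7000, 500, 6000), strand = "+")
  td <- tss_distance(regions[1, , drop = FALSE],
                     tss[tss$gene_id == "a", , drop = FALSE])
  expect_equal(td$distance, 6000)
  expect_true(td$distal)
  td <- tss_distance(regions[2, , drop = FALSE],
                     tss[tss$gene_id == "b", , drop = FALSE])
  expect_equal(td$distance, 0)
  # exactly 5000 bp away: not distal (strict >)
  td <- tss_distance(regions[3, , drop = FALSE],
                     tss[tss$gene_id == "c", , drop = FALSE])
  expect_equal(td$distance, 5000)
  expect_false(td$distal)
  # chromosome without TSS: undefined
  td <- tss_distance(data.frame(id = "r", chrom = "chrX", start = 0, end = 10),
                     tss)
  expect_true(is.na(td$distance))
  expect_false(td$distal)
})

test_that("intragenic/intergenic split is a partition", {
  bodies <- data.frame(chrom = "chr1", start = c(1000, 50000),
                       end = c(20000, 60000))
  set.seed(3)
  enh <- data.frame(id = paste0("AE_", 1:50), chrom = "chr1",
                    start = s <- sample.int(80000, 50), end = s + 500)
  parts <- partition_intragenic(enh, bodies)
  expect_equal(nrow(parts$intragenic) + nrow(parts$intergenic), nrow(enh))
  expect_length(intersect(parts$intragenic$id, parts$intergenic$id), 0)
  inside <- data.frame(id = "e", chrom = "chr1", start = 5000, end = 5500)
  expect_equal(nrow(partition_intragenic(inside, bodies)$intragenic), 1)
  outside <- data.frame(id = "e", chrom = "chr1", start = 30000, end = 30500)
  expect_equal(nrow(partition_intragenic(outside, bodies)$intergenic), 1)
})

test_that("classified regions keep their candidate coordinates and round-trip through BED", {
  tss <- fixture_tss(); p300 <- fixture_p300()
  cand <- merge_state_groups(fixture_track())
  regions <- classify_regions(cand, tss, p300)
  keys <- paste(regions$chrom, regions$start, regions$end)
  cand_keys <- paste(cand$chrom, cand$start, cand$end)
  expect_true(all(keys %in% cand_keys))
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions(regions, path)
  back <- read_regions(path)
  expect_setequal(paste(back$id, back$chrom, back$start, back$end, back$class),
                  paste(regions$id, regions$chrom, regions$start,
                        regions$end, regions$class))
})
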