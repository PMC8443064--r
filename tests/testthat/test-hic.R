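test_that("interaction filtering applies the top-significance thresholds", {
  ix <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 5000,
                   chrom2 = "chr1", start2 = 5e4, end2 = 5.5e4,
                   name = c("a", "b", "c"),
                   lnP = c(-150, -50, -101), FDR = c(0, 0, 0.01))
  expect_equal(filter_interactions(ix, "all"), ix)
  top <- filter_interactions(ix, "top")
  expect_equal(top$name, "a")      # b fails lnP, c fails FDR
  # top is always a subset of all
  expect_true(all(top$name %in% filter_interactions(ix, "all")$name))
})

test_that("interaction linking matches the worked single-interaction cases", {
  enh <- data.frame(id = "PE_1", chrom = "chr1", start = 100, end = 700,
                    group = "poised", class = "PE")
  prom <- data.frame(id = c("BP_1", "AP_1"), chrom = "chr1",
                     start = c(8000, 8000), end = c(9000, 9000),
                     group = c("poised", "active"), class = c("BP", "AP"))
  gm <- data.frame(promoter_id = c("BP_1", "AP_1"), gene_id = c("G1", "G2"))
  ix <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 5000,
                   chrom2 = "chr1", start2 = 5000, end2 = 10000,
                   name = "ix1", lnP = -150, FDR = 0)
  out <- link_by_interactions(enh, prom[1, ], gm, ix)
  expect_equal(out$enhancer_id, "PE_1")
  expect_equal(out$gene_id, "G1")
  expect_equal(out$class_pair, "PE-BP")
  expect_equal(out$provenance, "hic")
  # category mismatch yields no row
  expect_equal(nrow(link_by_interactions(enh, prom[2, ], gm, ix)), 0)
  # a second supporting interaction does not duplicate the row
  ix2 <- rbind(ix, ix); ix2$name <- c("ix1", "ix2")
  expect_equal(nrow(link_by_interactions(enh, prom, gm, ix2)), 1)
})

test_that("interaction linking equals the brute-force triple loop", {
  for (seed in 1:3) {
    enh <- rand_regions(120, c("AE", "PE"), seed)
    prom <- rand_regions(120, c("AP", "BP"), seed + 50)
    gm <- data.frame(promoter_id = rep(prom$id, each = 2),
                     gene_id = paste0("G", sample.int(150, 240, TRUE)))
    gm <- unique(gm)
    set.seed(seed + 99)
    n_ix <- 300
    b1 <- sample.int(400, n_ix) * 5000
    b2 <- sample.int(400, n_ix) * 5000
    ix <- data.frame(chrom1 = sample(c("chr1", "chr2"), n_ix, TRUE),
                     start1 = b1, end1 = b1 + 5000,
                     chrom2 = sample(c("chr1", "chr2"), n_ix, TRUE),
                     start2 = b2, end2 = b2 + 5000,
                     name = paste0("ix", 1:n_ix),
                     lnP = -runif(n_ix, 10, 300), FDR = 0)
    got <- link_by_interactions(enh, prom, gm, ix)
    want <- brute_link(enh, prom, gm, ix)
    expect_equal(got[, c("enhancer_id", "promoter_id", "gene_id")],
                 want, ignore_attr = TRUE)
    # every emitted pair is state-matched
    expect_true(all(got$class_pair %in% c("AE-AP", "PE-BP")))
  }
})

test_that("distance linking enforces category and the strict 1-Mb bound", {
  gm <- data.frame(promoter_id = c("AP_1", "BP_1"), gene_id = c("G1", "G2"))
  prom <- data.frame(id = c("AP_1", "BP_1"), chrom = "chr1",
                     start = c(600000, 700000), end = c(601000, 701000),
                     group = c("active", "poised"), class = c("AP", "BP"))
  enh_near <- data.frame(id = "AE_1", chrom = "chr1", start = 100000,
                         end = 101000, group = "active", class = "AE")
  out <- link_by_distance(enh_near, prom, gm)
  expect_equal(out$gene_id, "G1")   # AE links AP only, not BP
  expect_equal(out$provenance, "distance")
  # exactly 1 Mb apart: excluded (strict <)
  enh_far <- data.frame(id = "AE_2", chrom = "chr1", start = 1601000,
                        end = 1602000, group = "active", class = "AE")
  expect_equal(nrow(link_by_distance(enh_far, prom, gm)), 0)
  # just inside the bound: linked
  enh_far$start <- 1600999; enh_far$end <- 1601999
  expect_equal(nrow(link_by_distance(enh_far, prom, gm)), 1)
})

test_that("exact binomial tail matches closed forms and stays monotone in k", {
  expect_equal(binomial_enrichment(0, 10, 0.3)$p_value, 1)
  expect_equal(binomial_enrichment(3, 3, 0.5)$p_value, 0.125)
  et <- binomial_enrichment(30, 100, 0.24)
  expect_lt(abs(et$p_value - brute_binom_tail(30, 100, 0.24)), 1e-10)
  expect_equal(et$observed_prob, 0.3)
  p_prev <- 1 + 1e-12
  for (k in 0:50) {
    p_k <- binomial_enrichment(k, 50, 0.24)$p_value
    expect_lte(p_k, p_prev)
    p_prev <- p_k
  }
  expect_error(binomial_enrichment(5, 4, 0.5))
  expect_error(binomial_enrichment(2, 4, 1.2))
})

test_that("contact counting follows the dedup-per-triple rule", {
  ix <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 5000,
                   chrom2 = "chr1", start2 = 5000, end2 = 10000,
                   name = "ix1", lnP = -150, FDR = 0)
  pe <- data.frame(id = "PE_1", chrom = "chr1", start = 100, end = 700,
                   group = "poised", class = "PE")
  prom2 <- data.frame(id = c("BP_1", "AP_1"), chrom = "chr1",
                      start = c(6000, 8000), end = c(6500, 8500),
                      group = c("poised", "active"), class = c("BP", "AP"))
  cc <- count_enhancer_promoter_contacts(pe, prom2[1, ], ix, "BP")
  expect_equal(c(cc$k, cc$n), c(1L, 1L))
  cc <- count_enhancer_promoter_contacts(pe, prom2, ix, "BP")
  expect_equal(c(cc$k, cc$n), c(1L, 2L))   # BP and AP both contacted
  # no promoter-touching interactions -> n = 0
  ix_off <- ix; ix_off$start2 <- 2e6; ix_off$end2 <- 2e6 + 5000
  cc <- count_enhancer_promoter_contacts(pe, prom2, ix_off, "BP")
  expect_equal(cc$n, 0L)
})

test_that("pooled expected probability lies between the class-specific rates", {
  truth <- synth_truth(seed = 4)
  b <- gen_regions_and_interactions(truth, seed = 4)
  enh <- b$regions[b$regions$class %in% c("AE", "PE"), ]
  prom <- b$regions[b$regions$class %in% c("AP", "BP"), ]
  p0_hat <- expected_contact_prob(enh, prom, b$interactions, "BP")
  pe_rate <- with(count_enhancer_promoter_contacts(
    enh[enh$class == "PE", ], prom, b$interactions, "BP"), k / n)
  ae_rate <- with(count_enhancer_promoter_contacts(
    enh[enh$class == "AE", ], prom, b$interactions, "BP"), k / n)
  expect_gte(p0_hat, min(pe_rate, ae_rate))
  expect_lte(p0_hat, max(pe_rate, ae_rate))
})
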