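# Shared fixture builders and independent oracles used across test files.

# Random tiling segment track: consecutive segments never share a state,
# chromosomes tiled without gaps (the shape segmentation output has).
rand_track <- function(n_segments, n_states = 5, seed = 1,
                       chroms = c("chr1", "chr2")) {
  set.seed(seed)
  per <- ceiling(n_segments / length(chroms))
  out <- lapply(chroms, function(ch) {
    s <- integer(per)
    s[1] <- sample.int(n_states, 1)
    for (t in seq_len(per - 1))
      s[t + 1] <- sample(setdiff(seq_len(n_states), s[t]), 1)
    len <- sample(c(200, 400, 600, 800), per, replace = TRUE)
    ends <- cumsum(len)
    data.frame(chrom = ch, start = c(0, ends[-per]), end = ends,
               state = s, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Brute-force transition counting: explicit loop over adjacent pairs.
brute_transitions <- function(track) {
  track <- track[order(track$chrom, track$start), ]
  states <- sort(unique(track$state))
  lv <- as.character(states)
  O <- matrix(0, length(states), length(states), dimnames = list(lv, lv))
  for (i in seq_len(nrow(track) - 1)) {
    if (track$chrom[i] != track$chrom[i + 1]) next
    O[as.character(track$state[i]), as.character(track$state[i + 1])] <-
      O[as.character(track$state[i]), as.character(track$state[i + 1])] + 1
  }
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  list(observed = O, expected = E, enrichment = O / E, n = n)
}

# Scalar overlap predicate written independently of the package's
# half-open arithmetic (inclusive-coordinate formulation).
brute_overlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(FALSE)
  lo <- max(s1, s2)
  hi <- min(e1 - 1, e2 - 1)
  hi >= lo
}

# Brute-force Hi-C linker: explicit loop over interactions, enhancers and
# promoters, both anchor orderings, category matching, gene expansion.
brute_link <- function(enhancers, promoters, gene_map, interactions) {
  rows <- list()
  for (i in seq_len(nrow(interactions))) {
    for (ord in 1:2) {
      es <- if (ord == 1) 1 else 2
      ps <- if (ord == 1) 2 else 1
      ec <- interactions[[paste0("chrom", es)]][i]
      e1 <- interactions[[paste0("start", es)]][i]
      e2 <- interactions[[paste0("end", es)]][i]
      pc <- interactions[[paste0("chrom", ps)]][i]
      p1 <- interactions[[paste0("start", ps)]][i]
      p2 <- interactions[[paste0("end", ps)]][i]
      e_hit <- which(enhancers$chrom == ec & enhancers$start < e2 &
                       e1 < enhancers$end)
      p_hit <- which(promoters$chrom == pc & promoters$start < p2 &
                       p1 < promoters$end)
      for (e in e_hit) for (p in p_hit) {
        if (enhancers$group[e] != promoters$group[p]) next
        genes <- gene_map$gene_id[gene_map$promoter_id == promoters$id[p]]
        for (g in genes) {
          rows[[length(rows) + 1]] <- c(enhancers$id[e], promoters$id[p], g)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(enhancer_id = character(0), promoter_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  m <- unique(do.call(rbind, rows))
  df <- data.frame(enhancer_id = m[, 1], promoter_id = m[, 2],
                   gene_id = m[, 3], stringsAsFactors = FALSE)
  df[order(df$enhancer_id, df$promoter_id, df$gene_id), ]
}

# Direct binomial upper-tail sum from exact log binomial coefficients,
# independent of pbinom.
brute_binom_tail <- function(k, n, p0) {
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

# Random classified region set for linking tests.
rand_regions <- function(n, classes, seed, chroms = c("chr1", "chr2"),
                         span = 2e6) {
  set.seed(seed)
  start <- sample.int(span, n)
  width <- sample(200:2000, n, replace = TRUE)
  class <- sample(classes, n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + width,
                   class = class,
                   group = ifelse(class %in% c("AP", "AE"), "active",
                                  "poised"),
                   stringsAsFactors = FALSE)
  df$id <- paste0(df$class, "_", seq_len(n))
  df
}

# Per-row OLS slope of log2 values against context index (vectorized).
row_slopes <- function(x) {
  L <- log2(x)
  t_ <- seq_len(ncol(L)) - 1
  tc <- t_ - mean(t_)
  as.numeric(L %*% tc) / sum(tc^2)
}

# Hand-built 30-segment two-chromosome track with fully known expected
# post-processing output (used by region-pipeline tests).
fixture_track <- function() {
  seg <- function(chrom, start, end, state)
    data.frame(chrom = chrom, start = start, end = end, state = state,
               stringsAsFactors = FALSE)
  rbind(
    seg("chr1", 0, 400, 2), seg("chr1", 400, 900, 3),        # A1 active run
    seg("chr1", 900, 2000, 9),
    seg("chr1", 2000, 2300, 6), seg("chr1", 2300, 2700, 7),  # P1 poised run
    seg("chr1", 2700, 4000, 9),
    seg("chr1", 4000, 4400, 1),                              # 400 bp, dropped
    seg("chr1", 4400, 6000, 9),
    seg("chr1", 6000, 6700, 4),                              # touches poised ->
    seg("chr1", 6700, 7400, 6),                              # ambiguous pair
    seg("chr1", 7400, 9000, 9),
    seg("chr1", 9000, 9500, 7),                              # 500 bp, dropped
    seg("chr1", 9500, 10000, 5),
    seg("chr1", 10000, 10800, 6),                            # P3
    seg("chr1", 10800, 11200, 5),
    seg("chr1", 11200, 11600, 2), seg("chr1", 11600, 12000, 1), # A3
    seg("chr1", 12000, 13000, 9),
    seg("chr1", 13000, 13400, 3),                            # 400 bp, dropped
    seg("chr1", 13400, 14000, 8),                            # breaks the run
    seg("chr1", 14000, 14600, 4),                            # A4, exactly 600
    seg("chr1", 14600, 16000, 9),
    seg("chr1", 16000, 16800, 7),                            # P4 (no p300)
    seg("chr1", 16800, 18000, 9),
    seg("chr1", 18000, 18700, 1),                            # A5
    seg("chr1", 18700, 20000, 9),
    seg("chr2", 0, 700, 1),                                  # A6
    seg("chr2", 700, 1500, 9),
    seg("chr2", 1500, 2200, 6),                              # P5
    seg("chr2", 2200, 3000, 9))
}

fixture_tss <- function() {
  data.frame(gene_id = c("g1", "g2", "g3", "g4"),
             chrom = c("chr1", "chr1", "chr1", "chr2"),
             pos = c(1300, 2650, 12600, 350),
             strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE)
}

fixture_p300 <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
             start = c(11500, 10100, 18690, 1600, 100),
             end = c(11700, 10300, 18800, 1700, 200),
             stringsAsFactors = FALSE)
}

# Expected surviving candidates and classes for the fixture above.
fixture_expected_candidates <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr1",
              "chr2", "chr2"),
    start = c(0, 2000, 10000, 11200, 14000, 16000, 18000, 0, 1500),
    end = c(900, 2700, 10800, 12000, 14600, 16800, 18700, 700, 2200),
    group = c("active", "poised", "poised", "active", "active", "poised",
              "active", "active", "poised"),
    stringsAsFactors = FALSE)
}

# Expected classified regions for the fixture: A4 (no TSS window, no p300)
# and P4 (no p300) are dropped.
fixture_expected_classes <- function() {
  data.frame(
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(0, 0, 2000, 11200, 18000, 10000, 1500),
    end = c(900, 700, 2700, 12000, 18700, 10800, 2200),
    class = c("AP", "AP", "BP", "AE", "AE", "PE", "PE"),
    stringsAsFactors = FALSE)
}
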