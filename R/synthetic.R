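# Synthetic-data generators with known ground truth for every pipeline
# stage: segmentation tracks, region classes with state-matched Hi-C
# interactions, multi-sample tables with smooth intensity-dependent biases,
# housekeeping-like vs bivalent-like expression trajectories, and
# expression generated from a known linear model on log-signals.

#' Default histone-mark panel
#'
#' The ten marks used by the expression models: activation-associated
#' (H3K4me3, H3K27ac), enhancer-associated (H3K4me1), repression-associated
#' (H3K27me3, H4K20me3), transcription-coupled (H3K36me3, H2Bub, H3K79me2)
#' and the remaining H3K27 methylation states.
#'
#' @return Character vector of mark names.
#' @export
default_marks <- function() {
  c("H3K4me3", "H3K27ac", "H3K4me1", "H3K27me3", "H3K36me3",
    "H2Bub", "H3K27me1", "H3K27me2", "H4K20me3", "H3K79me2")
}

#' Ground-truth parameter set for the synthetic generators
#'
#' Collects every parameter the generators need, so that each generated
#' fixture is a pure function of (truth, seed). Defaults encode the study
#' conditions the pipeline is evaluated under: ten marks, a linear
#' expression model with theoretical performance r* = 0.8 at n = 2000
#' genes, a planted poised-enhancer/bivalent-promoter contact preference of
#' q = 0.29 against an expected probability p0 = 0.24, and smooth
#' per-sample intensity biases of amplitude 1 (log2) for the normalization
#' stress fixtures.
#'
#' The residual scale sigma is derived from the target correlation:
#' r*^2 = Var(X beta) / (Var(X beta) + sigma^2), so
#' sigma = sqrt(beta' Sigma beta (1/r*^2 - 1)) with Sigma the log-signal
#' covariance.
#'
#' @param seed Base seed.
#' @param n_genes Number of genes per context (default 2000).
#' @param marks Mark names (default \code{\link{default_marks}}).
#' @param beta True coefficients, one per mark; default mixes activating
#'   (positive) and repressive (negative) effects with H3K27me3 strongest.
#' @param intercept True intercept (default 1).
#' @param target_r Theoretical model performance r* (default 0.8).
#' @param mark_cor Exchangeable correlation between log-mark signals
#'   (default 0.2).
#' @param anticor Optional correlation override for the pair
#'   \code{anticor_pair} (e.g. -0.9 to emulate mutually exclusive marks);
#'   NULL leaves the exchangeable structure.
#' @param anticor_pair Mark pair for \code{anticor}
#'   (default H3K27me3 / H3K27ac).
#' @param mark_mean Mean of log2 signal (default 2).
#' @param mark_sd Standard deviation of log2 signal (default 1).
#' @param contexts Context (cell type / time point) labels.
#' @param q Probability that a poised-enhancer contact hits a bivalent
#'   promoter (default 0.29).
#' @param p0 Expected probability by chance (default 0.24); also the
#'   bivalent fraction of generated promoters.
#' @param n_interactions Interactions generated per bundle (default 1000).
#' @param bias_amplitude Amplitude (log2) of smooth per-sample biases
#'   (default 1).
#' @param genome Genome table; default two chromosomes of 10 Mb.
#' @param housekeeping_frac,trend_frac Fractions of genes flagged as
#'   housekeeping-like (stable across contexts) and bivalent-like (planted
#'   increasing trend) in trajectory fixtures (defaults 0.3 and 0.15).
#' @return List of class \code{synth_truth}.
#' @export
synth_truth <- function(seed = 1,
                        n_genes = 2000,
                        marks = default_marks(),
                        beta = NULL,
                        intercept = 1,
                        target_r = 0.8,
                        mark_cor = 0.2,
                        anticor = NULL,
                        anticor_pair = c("H3K27me3", "H3K27ac"),
                        mark_mean = 2,
                        mark_sd = 1,
                        contexts = c("ESC", "MES", "CM"),
                        q = 0.29,
                        p0 = 0.24,
                        n_interactions = 1000,
                        bias_amplitude = 1,
                        genome = data.frame(chrom = c("chr1", "chr2"),
                                            length = c(1e7, 1e7)),
                        housekeeping_frac = 0.3,
                        trend_frac = 0.15) {
  if (is.null(beta)) {
    beta <- c(0.45, 0.35, 0.15, -0.8, 0.3, 0.3, -0.15, -0.25, -0.2, 0.2)
    beta <- beta[seq_along(marks)]
  }
  stopifnot(length(beta) == length(marks), q > 0, q < 1, p0 > 0, p0 < 1)
  names(beta) <- marks
  p <- length(marks)
  Sigma <- matrix(mark_cor, p, p, dimnames = list(marks, marks))
  diag(Sigma) <- 1
  if (!is.null(anticor) && all(anticor_pair %in% marks)) {
    Sigma[anticor_pair[1], anticor_pair[2]] <- anticor
    Sigma[anticor_pair[2], anticor_pair[1]] <- anticor
    # nearest positive-definite repair in case the override breaks PD
    ev <- eigen(Sigma, symmetric = TRUE)
    if (min(ev$values) <= 1e-8) {
      v <- pmax(ev$values, 1e-6)
      Sigma <- ev$vectors %*% diag(v) %*% t(ev$vectors)
      dimnames(Sigma) <- list(marks, marks)
    }
  }
  Sigma <- Sigma * mark_sd^2
  var_xb <- drop(t(beta) %*% Sigma %*% beta)
  sigma <- sqrt(var_xb * (1 / target_r^2 - 1))
  structure(list(seed = seed, n_genes = n_genes, marks = marks, beta = beta,
                 intercept = intercept, target_r = target_r, sigma = sigma,
                 Sigma = Sigma, mark_mean = mark_mean,
                 contexts = contexts, q = q, p0 = p0,
                 n_interactions = n_interactions,
                 bias_amplitude = bias_amplitude, genome = genome,
                 housekeeping_frac = housekeeping_frac,
                 trend_frac = trend_frac),
            class = "synth_truth")
}

# Internal: derive a 32-bit sub-seed from a base seed and a stream label.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stream))) %% 2147483647L
}

#' Generate a chromatin-state segmentation track
#'
#' Seeded Markov-style alternation over 9 state labels: consecutive
#' segments never share a state, with transitions enriched within the
#' active (1-4) and poised (6-7) groups and frequent returns to the
#' unmarked state, mirroring how segmentations alternate regulatory runs
#' with unmarked spacers. Segment lengths are 200 bp times a geometric
#' number of bins (mean 3). Segments tile each chromosome without gaps.
#'
#' @param truth \code{synth_truth} object.
#' @param n_segments Approximate total segments (default 2000); the
#'   chromosomes are truncated once reached.
#' @param seed Seed (default truth's).
#' @return List: \code{track} (segment track) and \code{P} (the generating
#'   9x9 transition probability matrix, zero diagonal).
#' @export
gen_segmentation <- function(truth, n_segments = 2000, seed = truth$seed) {
  set.seed(sub_seed(seed, "segmentation"))
  scheme <- default_state_scheme()
  states <- as.integer(names(scheme))
  grp <- unname(scheme)
  P <- matrix(1, 9, 9)
  for (x in 1:9) for (y in 1:9) {
    if (x == y) { P[x, y] <- 0; next }
    w <- 1
    if (grp[x] == grp[y]) w <- 6          # within-group transitions enriched
    if (grp[y] == "unmarked") w <- 4      # unmarked spacers are common
    if (grp[x] == "unmarked" && grp[y] != "unmarked") w <- 2
    P[x, y] <- w
  }
  P <- P / rowSums(P)
  per_chrom <- ceiling(n_segments / nrow(truth$genome))
  out <- list()
  for (i in seq_len(nrow(truth$genome))) {
    len <- truth$genome$length[i]
    s <- integer(per_chrom)
    s[1] <- sample(states, 1)
    for (t in 2:per_chrom) s[t] <- sample.int(9, 1, prob = P[s[t - 1], ])
    seg_len <- 200L * (1L + stats::rgeom(per_chrom, 1 / 3))
    ends <- cumsum(as.numeric(seg_len))
    keep <- which(ends <= len)
    if (!length(keep)) keep <- 1
    starts <- c(0, ends[-length(ends)])[keep]
    out[[i]] <- data.frame(chrom = truth$genome$chrom[i],
                           start = as.integer(starts),
                           end = as.integer(ends[keep]),
                           state = s[keep], stringsAsFactors = FALSE)
  }
  list(track = do.call(rbind, out), P = P)
}

#' Generate classified regions, TSS catalogue, p300 peaks and interactions
#'
#' Places promoter and enhancer slots on a regular grid (one region per
#' 5-kb anchor bin, 20 kb apart) and constructs the inputs so that the
#' classification rules reproduce the planted classes exactly: promoters
#' contain a TSS of their target gene, enhancers contain a p300 peak and
#' lie clear of any TSS window. The bivalent fraction of promoters is
#' truth$p0. Interactions anchor one enhancer against one promoter:
#' poised-enhancer contacts hit a bivalent promoter with probability
#' truth$q (against the expected p0), active-enhancer contacts hit an
#' active promoter with probability 1 - p0 + (q - p0) (mirroring the
#' active-side enrichment); each anchor is the 5-kb bin containing the
#' region, so contact counting is unambiguous.
#'
#' @param truth \code{synth_truth} object.
#' @param n_promoters,n_enhancers Region counts (defaults 200 and 120).
#' @param seed Seed (default truth's).
#' @return List: candidates, regions (planted classes), tss, p300,
#'   gene_bodies, gene_map, interactions, truth_associations (the
#'   state-matched association table the Hi-C linker must recover) and the
#'   planted q.
#' @export
gen_regions_and_interactions <- function(truth, n_promoters = 200,
                                         n_enhancers = 120,
                                         seed = truth$seed) {
  set.seed(sub_seed(seed, "regions"))
  n_total <- n_promoters + n_enhancers
  spacing <- 20000
  genome <- truth$genome
  per_chrom <- floor(genome$length / spacing)
  capacity <- sum(per_chrom)
  if (n_total > capacity)
    stop("gen_regions_and_interactions: genome too small for region count")
  slot <- sample(capacity, n_total)   # random slot assignment
  chrom_of <- rep(genome$chrom, per_chrom)[slot]
  offset <- (slot - rep(c(0, cumsum(per_chrom))[seq_len(nrow(genome))],
                        per_chrom)[slot] - 1) * spacing
  # region of ~1.2 kb centered in the first 5-kb bin of its slot
  start <- as.integer(offset + 1900)
  end <- as.integer(offset + 3100)
  is_prom <- c(rep(TRUE, n_promoters), rep(FALSE, n_enhancers))
  n_bp <- round(truth$p0 * n_promoters)
  n_pe <- max(1, round(0.3 * n_enhancers))
  class <- c(sample(c(rep("BP", n_bp), rep("AP", n_promoters - n_bp))),
             sample(c(rep("PE", n_pe), rep("AE", n_enhancers - n_pe))))
  group <- ifelse(class %in% c("AP", "AE"), "active", "poised")
  candidates <- data.frame(chrom = chrom_of, start = start, end = end,
                           group = group, stringsAsFactors = FALSE)
  # TSS inside each promoter; p300 peak inside each enhancer
  tss <- data.frame(gene_id = paste0("G", seq_len(n_promoters)),
                    chrom = chrom_of[is_prom],
                    pos = start[is_prom] + 600L,
                    strand = sample(c("+", "-"), n_promoters, replace = TRUE),
                    stringsAsFactors = FALSE)
  p300 <- data.frame(chrom = chrom_of[!is_prom],
                     start = start[!is_prom] + 400L,
                     end = start[!is_prom] + 800L,
                     stringsAsFactors = FALSE)
  # gene bodies: ~60% of genes span 8 kb downstream of the TSS
  body_len <- ifelse(stats::runif(n_promoters) < 0.6, 8000L, 2000L)
  gene_bodies <- data.frame(chrom = tss$chrom,
                            start = tss$pos,
                            end = tss$pos + body_len,
                            name = tss$gene_id, stringsAsFactors = FALSE)
  regions <- classify_regions(candidates, tss, p300)
  stopifnot(nrow(regions) == n_total)
  gene_map <- assign_genes_to_promoters(regions[regions$class %in%
                                                  c("AP", "BP"), ], tss)
  # interactions: each pairs one enhancer bin with one promoter bin
  enh <- regions[regions$class %in% c("AE", "PE"), ]
  prom <- regions[regions$class %in% c("AP", "BP"), ]
  n_ix <- truth$n_interactions
  e_pick <- sample(nrow(enh), n_ix, replace = TRUE)
  target_bp <- ifelse(enh$class[e_pick] == "PE",
                      stats::runif(n_ix) < truth$q,
                      stats::runif(n_ix) < truth$p0 - (truth$q - truth$p0))
  p_pick <- integer(n_ix)
  bp_rows <- which(prom$class == "BP"); ap_rows <- which(prom$class == "AP")
  p_pick[target_bp] <- sample(bp_rows, sum(target_bp), replace = TRUE)
  p_pick[!target_bp] <- sample(ap_rows, sum(!target_bp), replace = TRUE)
  bin5 <- function(df) {
    b <- floor(df$start / 5000) * 5000
    data.frame(chrom = df$chrom, start = as.integer(b),
               end = as.integer(b + 5000), stringsAsFactors = FALSE)
  }
  ea <- bin5(enh[e_pick, ]); pa <- bin5(prom[p_pick, ])
  top <- stats::runif(n_ix) < 0.4
  interactions <- data.frame(
    chrom1 = ea$chrom, start1 = ea$start, end1 = ea$end,
    chrom2 = pa$chrom, start2 = pa$start, end2 = pa$end,
    name = paste0("ix", seq_len(n_ix)),
    lnP = ifelse(top, stats::runif(n_ix, -300, -100),
                 stats::runif(n_ix, -90, -7)),
    FDR = ifelse(top, 0, stats::runif(n_ix, 0.001, 0.05)),
    stringsAsFactors = FALSE)
  # ground-truth associations: state-matched pairs, expanded over genes
  matched <- enh$group[e_pick] == prom$group[p_pick]
  ta <- data.frame(enhancer_id = enh$id[e_pick[matched]],
                   promoter_id = prom$id[p_pick[matched]],
                   stringsAsFactors = FALSE)
  ta <- merge(unique(ta), gene_map, by = "promoter_id")
  cls <- function(id) sub("_.*", "", id)
  truth_assoc <- data.frame(enhancer_id = ta$enhancer_id,
                            promoter_id = ta$promoter_id,
                            gene_id = ta$gene_id,
                            class_pair = paste0(cls(ta$enhancer_id), "-",
                                                cls(ta$promoter_id)),
                            provenance = "hic", stringsAsFactors = FALSE)
  truth_assoc <- truth_assoc[order(truth_assoc$enhancer_id,
                                   truth_assoc$promoter_id,
                                   truth_assoc$gene_id), ]
  rownames(truth_assoc) <- NULL
  list(candidates = candidates, regions = regions, tss = tss, p300 = p300,
       gene_bodies = gene_bodies, gene_map = gene_map,
       interactions = interactions, truth_associations = truth_assoc,
       q = truth$q)
}

#' Generate signal matrices and expression from the known linear model
#'
#' Per context, log2 mark signal is drawn from a multivariate normal with
#' the truth's mark-mark covariance, and log2 expression is
#' y = intercept + X beta + Normal(0, sigma). Signal and FPKM tables are
#' back-transformed with the 0.1 pseudocount (FPKM = 2^y - 0.1, clipped at
#' 0, so the transform is invertible above log2(0.1)). Housekeeping genes
#' share their signal (hence expression) means across contexts; the
#' remaining genes are redrawn per context.
#'
#' @param truth \code{synth_truth} object.
#' @param n_genes Number of genes (default truth$n_genes).
#' @param contexts Context labels (default truth$contexts).
#' @param seed Seed (default truth's).
#' @return Named list per context, each with signal (matrix, regions x
#'   marks, rownames "P<i>"), expression (data.frame gene_id, fpkm),
#'   gene_map (promoter_id, gene_id), and the latent x_log / y_log.
#' @export
gen_signal_expression <- function(truth, n_genes = truth$n_genes,
                                  contexts = truth$contexts,
                                  seed = truth$seed) {
  set.seed(sub_seed(seed, "signal"))
  p <- length(truth$marks)
  genes <- paste0("G", seq_len(n_genes))
  promoters <- paste0("P", seq_len(n_genes))
  n_hk <- round(truth$housekeeping_frac * n_genes)
  hk <- seq_len(n_hk)
  base_x <- MASS::mvrnorm(n_genes, mu = rep(truth$mark_mean, p),
                          Sigma = truth$Sigma)
  colnames(base_x) <- truth$marks
  out <- list()
  for (ctx in contexts) {
    x <- MASS::mvrnorm(n_genes, mu = rep(truth$mark_mean, p),
                       Sigma = truth$Sigma)
    colnames(x) <- truth$marks
    x[hk, ] <- base_x[hk, ] +
      matrix(stats::rnorm(n_hk * p, sd = 0.05), n_hk, p)
    y <- truth$intercept + drop(x %*% truth$beta) +
      stats::rnorm(n_genes, sd = truth$sigma)
    signal <- pmax(2^x - 0.1, 0)
    rownames(signal) <- promoters
    out[[ctx]] <- list(
      signal = signal,
      expression = data.frame(gene_id = genes,
                              fpkm = pmax(2^y - 0.1, 0),
                              stringsAsFactors = FALSE),
      gene_map = data.frame(promoter_id = promoters, gene_id = genes,
                            stringsAsFactors = FALSE),
      x_log = x, y_log = y,
      housekeeping = genes[hk])
  }
  out
}

#' Generate housekeeping-like and trend expression trajectories
#'
#' A genes x contexts table in which a housekeeping subset has equal true
#' means across contexts, a bivalent-like subset has a planted monotone
#' increasing trend (log2 slope drawn from U(0.3, 0.8) per context step),
#' and the rest are stable with gene-specific means. Values are positive
#' (FPKM-like); measurement noise is N(0, 0.2) in log2.
#'
#' @param truth \code{synth_truth} object.
#' @param n_genes Number of rows (default 3000).
#' @param n_contexts Number of contexts (default 5).
#' @param seed Seed (default truth's).
#' @return List: table (positive matrix), housekeeping / trend row indices
#'   and the planted slopes.
#' @export
gen_expression_trajectories <- function(truth, n_genes = 3000,
                                        n_contexts = 5, seed = truth$seed) {
  set.seed(sub_seed(seed, "trajectories"))
  n_hk <- round(truth$housekeeping_frac * n_genes)
  n_tr <- round(truth$trend_frac * n_genes)
  hk <- seq_len(n_hk)
  tr <- seq(n_hk + 1, n_hk + n_tr)
  mu <- stats::rnorm(n_genes, mean = 4, sd = 1.5)
  slope <- rep(0, n_genes)
  slope[tr] <- stats::runif(n_tr, 0.3, 0.8)
  t_step <- 0:(n_contexts - 1)
  L <- outer(mu, rep(1, n_contexts)) + outer(slope, t_step) +
    matrix(stats::rnorm(n_genes * n_contexts, sd = 0.2), n_genes)
  tab <- 2^L
  colnames(tab) <- paste0("ctx", seq_len(n_contexts))
  rownames(tab) <- paste0("G", seq_len(n_genes))
  list(table = tab, housekeeping = hk, trend = tr, slopes = slope[tr])
}

#' Make smooth per-sample bias functions
#'
#' Returns a list of bounded smooth functions of A (log2 intensity):
#' g_s(A) = amplitude * sin(0.7 A + phase_s), with phases spread over the
#' circle, or constant offsets when \code{type = "constant"}.
#'
#' @param n_samples Number of samples.
#' @param amplitude Bias amplitude in log2 units (default 1).
#' @param type "smooth" or "constant".
#' @param seed Seed for the phases/offsets.
#' @return List of functions of A.
#' @export
make_bias_funs <- function(n_samples, amplitude = 1,
                           type = c("smooth", "constant"), seed = 1) {
  type <- match.arg(type)
  set.seed(sub_seed(seed, "bias"))
  if (type == "constant") {
    off <- stats::runif(n_samples, -amplitude, amplitude)
    return(lapply(off, function(o) { force(o); function(A) rep(o, length(A)) }))
  }
  phase <- stats::runif(n_samples, 0, 2 * pi)
  lapply(phase, function(ph) {
    force(ph)
    function(A) amplitude * sin(0.7 * A + ph)
  })
}

#' Apply per-sample biases to a base table
#'
#' sample s value = base * 2^(g_s(A)) * 2^(N(0, noise_sd)), with
#' A = log2(base). When \code{base} is a vector it is replicated across
#' samples; when it is a matrix each column keeps its own true values and
#' receives its column's bias.
#'
#' @param truth \code{synth_truth} object (carries the default amplitude).
#' @param base Positive vector or matrix of true values.
#' @param bias_funs List of bias functions (default: smooth, amplitude
#'   truth$bias_amplitude, one per sample/column).
#' @param noise_sd Log2 noise sd (default 0).
#' @param seed Seed for the noise.
#' @return Positive matrix with one column per sample; the bias functions
#'   used are attached as attribute \code{bias_funs} for recovery checks.
#' @export
gen_biased_samples <- function(truth, base, bias_funs = NULL, noise_sd = 0,
                               seed = truth$seed) {
  set.seed(sub_seed(seed, "biased"))
  if (is.matrix(base)) {
    S <- ncol(base)
    m <- base
  } else {
    if (is.null(bias_funs))
      stop("gen_biased_samples: bias_funs needed to set the sample count for a vector base")
    S <- length(bias_funs)
    m <- matrix(base, nrow = length(base), ncol = S)
  }
  if (any(m <= 0)) stop("gen_biased_samples: base must be strictly positive")
  if (is.null(bias_funs))
    bias_funs <- make_bias_funs(S, truth$bias_amplitude, seed = seed)
  stopifnot(length(bias_funs) == S)
  out <- m
  for (s in seq_len(S)) {
    A <- log2(m[, s])
    g <- bias_funs[[s]](A)
    noise <- if (noise_sd > 0) stats::rnorm(nrow(m), sd = noise_sd) else 0
    out[, s] <- m[, s] * 2^(g + noise)
  }
  if (is.null(colnames(out))) colnames(out) <- paste0("S", seq_len(S))
  attr(out, "bias_funs") <- bias_funs
  out
}

#' Write a complete synthetic input bundle
#'
#' Generates and writes every standard-format input the pipeline consumes:
#' chromosome sizes, a segmentation BED, TSS catalogue, p300 peaks, gene
#' bodies, a BEDPE of interactions, per-context signal and expression
#' tables, and a truth.json recording the planted parameters.
#'
#' @param preset "small" (fast end-to-end run), "differentiation" (five
#'   contexts) or "loess-stress" (bias-heavy multi-sample tables).
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
simulate_bundle <- function(preset = c("small", "differentiation",
                                       "loess-stress"),
                            seed = 1, outdir) {
  preset <- match.arg(preset)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- switch(preset,
    small = synth_truth(seed = seed, n_genes = 400,
                        contexts = c("ESC", "MES", "CM"),
                        n_interactions = 600),
    differentiation = synth_truth(seed = seed, n_genes = 1000,
                                  contexts = c("ESC", "MES", "CP", "CM",
                                               "NPC"),
                                  n_interactions = 1000),
    `loess-stress` = synth_truth(seed = seed, n_genes = 400,
                                 contexts = c("ESC", "MES", "CM"),
                                 bias_amplitude = 1))
  utils::write.table(truth$genome, file.path(outdir, "genome.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  seg <- gen_segmentation(truth, n_segments = 2000, seed = seed)
  seg_bed <- seg$track
  seg_bed$name <- paste0("E", seg_bed$state)
  write_bed(seg_bed[, c("chrom", "start", "end", "name")],
            file.path(outdir, "segmentation.bed"))
  bundle <- gen_regions_and_interactions(truth, seed = seed)
  utils::write.table(bundle$tss, file.path(outdir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(bundle$p300, file.path(outdir, "p300.bed"))
  write_bed(bundle$gene_bodies, file.path(outdir, "gene_bodies.bed"))
  write_bed(cbind(bundle$candidates[, c("chrom", "start", "end")],
                  name = bundle$candidates$group),
            file.path(outdir, "candidates.bed"))
  write_bedpe(bundle$interactions, file.path(outdir, "interactions.bedpe"))
  se <- gen_signal_expression(truth, seed = seed)
  for (ctx in names(se)) {
    sig <- data.frame(region_id = rownames(se[[ctx]]$signal),
                      se[[ctx]]$signal, check.names = FALSE)
    utils::write.table(sig, file.path(outdir, paste0("signal_", ctx, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(se[[ctx]]$expression,
                       file.path(outdir, paste0("expression_", ctx, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(se[[1]]$gene_map, file.path(outdir, "gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  all_expr <- data.frame(gene_id = se[[1]]$expression$gene_id,
                         sapply(se, function(e) e$expression$fpkm),
                         check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(all_expr, file.path(outdir, "expression_all.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (preset == "loess-stress") {
    traj <- gen_expression_trajectories(truth, seed = seed)
    biased <- gen_biased_samples(truth, traj$table,
                                 make_bias_funs(ncol(traj$table),
                                                truth$bias_amplitude,
                                                type = "constant",
                                                seed = seed),
                                 seed = seed)
    utils::write.table(data.frame(gene_id = rownames(traj$table), biased,
                                  check.names = FALSE),
                       file.path(outdir, "trajectories_biased.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tj <- list(preset = preset, seed = seed, marks = truth$marks,
             beta = as.list(truth$beta), intercept = truth$intercept,
             sigma = truth$sigma, target_r = truth$target_r,
             q = truth$q, p0 = truth$p0, contexts = truth$contexts,
             n_genes = truth$n_genes)
  jsonlite::write_json(tj, file.path(outdir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}
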