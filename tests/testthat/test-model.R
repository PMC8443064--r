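make_dataset <- function(n = 200, p = 3, beta = c(1, 2, -1, 0.5), sigma = 0.5,
                         seed = 1, enhancers_per_gene = 1) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n))
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  y <- beta[1] + drop(x %*% beta[-1]) + rnorm(n, sd = sigma)
  reps <- rep(seq_len(n), times = enhancers_per_gene)
  df <- data.frame(gene_id = genes[reps],
                   region_id = paste0("R", seq_along(reps)),
                   y = y[reps])
  df <- cbind(df, as.data.frame(x[reps, , drop = FALSE]))
  attr(df, "marks") <- paste0("m", 1:p)
  df
}

test_that("dataset assembly applies the 0.1 pseudocount and enhancer duplication", {
  expr <- data.frame(gene_id = c("G1", "G2"), fpkm = c(0, 3.9))
  signal <- matrix(c(0.9, 1.9, 3.9, 0, 1.9, 0.9), nrow = 3,
                   dimnames = list(c("E1", "E2", "E3"), c("mA", "mB")))
  assoc <- data.frame(enhancer_id = c("E1", "E2", "E3"),
                      gene_id = c("G1", "G1", "G2"))
  ds <- assemble_dataset(expr, signal, assoc, mode = "enhancer")
  # FPKM 0 -> y = log2(0.1)
  expect_equal(ds$y[ds$gene_id == "G1"], rep(log2(0.1), 2))
  expect_equal(ds$y[ds$gene_id == "G2"], 2)
  # gene G1 is duplicated once per associated enhancer, same y
  expect_equal(sum(ds$gene_id == "G1"), 2)
  expect_equal(ds$mA, log2(c(0.9, 1.9, 3.9) + 0.1))
  expect_equal(ds$mB[3], log2(0.9 + 0.1))
  # mark exclusion is a plain subset of columns
  ds2 <- assemble_dataset(expr, signal, assoc, marks = "mA", mode = "enhancer")
  expect_equal(attr(ds2, "marks"), "mA")
  expect_false("mB" %in% names(ds2))
  # missing signal for an associated region is an error
  assoc_bad <- rbind(assoc, data.frame(enhancer_id = "E9", gene_id = "G2"))
  expect_error(assemble_dataset(expr, signal, assoc_bad, mode = "enhancer"),
               "E9")
})

test_that("expression shuffling is a seeded permutation over all genes", {
  expr <- data.frame(gene_id = paste0("G", 1:100), fpkm = rexp(100))
  sh1 <- shuffle_expression(expr, seed = 42)
  sh2 <- shuffle_expression(expr, seed = 42)
  expect_equal(sh1, sh2)
  expect_equal(sort(sh1$fpkm), sort(expr$fpkm))
  expect_equal(sh1$gene_id, expr$gene_id)
  expect_false(all(sh1$fpkm == expr$fpkm))
})

test_that("train/test split works at gene level without leakage", {
  ds <- make_dataset(n = 10, enhancers_per_gene = 3)
  sp <- split_train_test(ds, seed = 3)
  expect_equal(length(unique(sp$train$gene_id)), 8)
  expect_equal(length(unique(sp$test$gene_id)), 2)
  expect_length(intersect(sp$train$gene_id, sp$test$gene_id), 0)
  sp2 <- split_train_test(ds, seed = 3)
  expect_equal(sp$train, sp2$train)
})

test_that("OLS coefficients match the normal-equations oracle", {
  for (seed in 1:5) {
    ds <- make_dataset(n = 200, p = 5, beta = c(0.5, 1, -2, 0, 3, -1),
                       sigma = 1, seed = seed)
    fit <- histone_lm(ds)
    X <- cbind(1, as.matrix(ds[, attr(ds, "marks")]))
    beta_hat <- solve(t(X) %*% X, t(X) %*% ds$y)
    expect_lt(max(abs(coef(fit) - drop(beta_hat))), 1e-8)
  }
})

test_that("a noiseless response is interpolated exactly with flagged t-statistics", {
  set.seed(4)
  x1 <- rnorm(50)
  ds <- data.frame(gene_id = paste0("G", 1:50), region_id = paste0("R", 1:50),
                   y = 2 + 3 * x1, m1 = x1)
  attr(ds, "marks") <- "m1"
  fit <- histone_lm(ds)
  expect_equal(unname(coef(fit)), c(2, 3), tolerance = 1e-10)
  expect_true(fit$perfect_fit)
  expect_true(all(is.infinite(fit$t)))
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  ds <- make_dataset(n = 50, p = 2, beta = c(1, 2, -1))
  ds$m2 <- 2 * ds$m1
  expect_error(histone_lm(ds), "m2")
  ds2 <- make_dataset(n = 50, p = 2, beta = c(1, 2, -1))
  ds2$m2 <- 0
  expect_error(histone_lm(ds2), "constant")
})

test_that("coefficient recovery stays within OLS sampling bounds", {
  beta <- c(0.5, 1, -2, 3)
  hits <- 0; total <- 0
  for (seed in 1:10) {
    ds <- make_dataset(n = 300, p = 3, beta = beta, sigma = 1, seed = seed)
    fit <- histone_lm(ds)
    se <- sqrt(diag(vcov(fit$fit)))
    hits <- hits + sum(abs(coef(fit) - beta) <= 3 * se)
    total <- total + length(beta)
  }
  expect_gte(hits / total, 0.95)
})

test_that("evaluation returns the Pearson r of predictions vs measurements", {
  ds <- make_dataset(n = 100, sigma = 0)
  fit <- histone_lm(ds)
  ev <- evaluate_model(fit, ds)
  expect_equal(ev$r, 1)
  flipped <- ds
  flipped$y <- -(ds$y - mean(ds$y)) + mean(ds$y)
  ev2 <- evaluate_model(fit, flipped)
  expect_equal(ev2$r, -1)
  # degenerate measurements are flagged
  const <- ds; const$y <- 1
  expect_true(evaluate_model(fit, const)$degenerate)
})

test_that("importance shares sum to one and t is invariant to y rescaling", {
  ds <- make_dataset(n = 300, p = 4, beta = c(0, 2, -1, 0.5, 0.2), seed = 9)
  fit <- histone_lm(ds)
  expect_equal(sum(fit$importance_share), 1)
  ds2 <- ds; ds2$y <- 2 * ds2$y
  fit2 <- histone_lm(ds2)
  expect_equal(unname(fit2$t), unname(fit$t), tolerance = 1e-10)
})

test_that("duplicated gene rows reproduce a weighted least-squares oracle", {
  set.seed(6)
  n <- 60; p <- 3
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  y <- 1 + drop(x %*% c(2, -1, 0.5)) + rnorm(n, sd = 0.4)
  w <- sample(1:4, n, replace = TRUE)
  reps <- rep(seq_len(n), times = w)
  ds <- data.frame(gene_id = paste0("G", reps),
                   region_id = paste0("R", seq_along(reps)),
                   y = y[reps])
  ds <- cbind(ds, as.data.frame(x[reps, , drop = FALSE]))
  attr(ds, "marks") <- paste0("m", 1:p)
  fit <- histone_lm(ds)
  X <- cbind(1, x)
  W <- diag(w)
  beta_w <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_lt(max(abs(coef(fit) - drop(beta_w))), 1e-8)
})

test_that("repeated k-fold cross-validation partitions genes per repeat", {
  ds <- make_dataset(n = 120, enhancers_per_gene = 2, seed = 2)
  cv <- cross_validate(ds, k = 10, repeats = 3, seed = 5)
  expect_equal(nrow(cv), 30)
  expect_equal(sum(cv$n), 3 * nrow(ds))  # each row tested once per repeat
  expect_true(all(is.finite(cv$r)))
  expect_named(attr(cv, "summary"), c("mean_r", "sd_r"))
})

test_that("cross-context matrices fill the off-diagonal only", {
  datasets <- list(a = make_dataset(seed = 1), b = make_dataset(seed = 2),
                   c = make_dataset(seed = 3))
  cc <- cross_context_matrix(datasets)
  expect_equal(dim(cc), c(3L, 3L))
  expect_true(all(is.na(diag(cc))))
  expect_equal(sum(!is.na(cc)), 6)
  expect_true(all(cc[!is.na(cc)] > 0.9))  # shared generating model
})

test_that("paired t-test matches the closed form and stars the thresholds", {
  # differences (0.3, 0.4, 0.5): t = dbar / (sd / sqrt(n))
  model_rs <- c(0.5, 0.6, 0.7)
  random_rs <- c(0.2, 0.2, 0.2)
  out <- paired_t_test(model_rs, random_rs)
  d <- model_rs - random_rs
  t_exp <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(out$t, t_exp, tolerance = 1e-12)
  expect_equal(out$t, 6.9282, tolerance = 1e-4)
  expect_equal(out$df, 2)
  expect_equal(out$p, 0.0202, tolerance = 1e-3)
  expect_equal(out$stars, "*")
  # degenerate when all differences equal
  expect_true(paired_t_test(c(0.5, 0.5), c(0.2, 0.2))$degenerate)
  # invariant under adding a constant to both lists
  out2 <- paired_t_test(model_rs + 1, random_rs + 1)
  expect_equal(out2$p, out$p)
})

test_that("model methods print, predict, simulate and plot coherently", {
  ds <- make_dataset(n = 150, seed = 10)
  fit <- histone_lm(ds)
  expect_output(print(fit), "histone marks")
  expect_output(print(summary(fit)), "sigma")
  expect_equal(length(predict(fit, ds)), nrow(ds))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(ds), 3L))
  expect_gt(cor(sims$sim_1, ds$y), 0.5)
  pdf(NULL)
  r <- plot(fit, ds)
  dev.off()
  expect_equal(r, evaluate_model(fit, ds)$r)
})
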