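# Linear models of gene expression from histone-modification signal:
# dataset assembly, the histone_lm fit with t-statistic variable importance,
# randomization controls, gene-level train/test splitting, repeated k-fold
# cross-validation, cross-context evaluation and the paired significance
# test.

#' Assemble a model dataset
#'
#' Joins an expression vector with region-level signal through an
#' association table. The response is y = log2(FPKM + pseudocount) and each
#' predictor x_j = log2(signal_j + pseudocount). In promoter mode there is
#' one row per (gene, promoter); in enhancer mode one row per
#' (gene, associated enhancer), so a gene enters the dataset as many times
#' as it has associated enhancers, all rows sharing its y.
#'
#' @param expression data.frame with columns gene_id and fpkm (FPKM >= 0).
#' @param signal Matrix of raw signal (regions x marks) with region ids as
#'   rownames, or a data.frame with a region_id column.
#' @param associations Association table (enhancer mode: columns
#'   enhancer_id, gene_id) or promoter-gene map (promoter mode: columns
#'   promoter_id, gene_id).
#' @param marks Character vector of predictor columns (default: all signal
#'   columns).
#' @param pseudocount Pseudocount added before log2 (default 0.1).
#' @param genes Optional gene filter (e.g. protein-coding ids); genes
#'   outside it are dropped.
#' @param mode "promoter" or "enhancer"; decides which association column
#'   names the region.
#' @return Model dataset: data.frame gene_id, region_id, y, then one column
#'   per mark (log2 scale).
#' @export
assemble_dataset <- function(expression, signal, associations, marks = NULL,
                             pseudocount = 0.1, genes = NULL,
                             mode = c("promoter", "enhancer")) {
  mode <- match.arg(mode)
  region_col <- if (mode == "promoter") "promoter_id" else "enhancer_id"
  if (!region_col %in% names(associations))
    stop("assemble_dataset: associations lack column ", region_col)
  if (is.data.frame(signal) && "region_id" %in% names(signal)) {
    rn <- signal$region_id
    signal <- as.matrix(signal[, setdiff(names(signal), "region_id"),
                               drop = FALSE])
    rownames(signal) <- rn
  }
  signal <- as.matrix(signal)
  if (is.null(marks)) marks <- colnames(signal)
  miss <- setdiff(marks, colnames(signal))
  if (length(miss))
    stop("assemble_dataset: marks absent from signal: ",
         paste(miss, collapse = ", "))
  pairs <- unique(associations[, c(region_col, "gene_id")])
  if (!is.null(genes)) pairs <- pairs[pairs$gene_id %in% genes, , drop = FALSE]
  keep <- pairs$gene_id %in% expression$gene_id
  pairs <- pairs[keep, , drop = FALSE]
  miss_reg <- setdiff(pairs[[region_col]], rownames(signal))
  if (length(miss_reg))
    stop("assemble_dataset: signal missing for region(s) ",
         paste(utils::head(miss_reg, 3), collapse = ", "))
  fpkm <- expression$fpkm[match(pairs$gene_id, expression$gene_id)]
  if (any(fpkm < 0)) stop("assemble_dataset: negative FPKM")
  out <- data.frame(gene_id = pairs$gene_id,
                    region_id = pairs[[region_col]],
                    y = log2(fpkm + pseudocount),
                    stringsAsFactors = FALSE)
  x <- log2(signal[pairs[[region_col]], marks, drop = FALSE] + pseudocount)
  out <- cbind(out, as.data.frame(x, row.names = NULL))
  attr(out, "marks") <- marks
  attr(out, "pseudocount") <- pseudocount
  rownames(out) <- NULL
  out
}

#' Shuffle expression values across genes
#'
#' Randomization control: gene ids are kept, FPKM values are permuted
#' uniformly at random over all genes (before dataset assembly), destroying
#' any relationship between histone marking and expression while preserving
#' the expression distribution.
#'
#' @param expression data.frame with gene_id, fpkm.
#' @param seed Integer seed; the permutation is deterministic given it.
#' @return Shuffled expression data.frame.
#' @export
shuffle_expression <- function(expression, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expression$fpkm <- sample(expression$fpkm)
  expression
}

#' Split a model dataset into training and test subsets
#'
#' By default the split is at gene level: all duplicated rows of a gene land
#' on one side, preventing leakage of identical y values across the split.
#' A row-level mode is retained for fidelity experiments.
#'
#' @param dataset Model dataset.
#' @param train_frac Fraction of genes (or rows) in the training subset
#'   (default 0.8).
#' @param seed Integer seed.
#' @param level "gene" (default) or "row".
#' @return List with data.frames \code{train} and \code{test}.
#' @export
split_train_test <- function(dataset, train_frac = 0.8, seed = 1,
                             level = c("gene", "row")) {
  level <- match.arg(level)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (level == "gene") {
    genes <- unique(dataset$gene_id)
    n_train <- round(train_frac * length(genes))
    train_genes <- sample(genes, n_train)
    in_train <- dataset$gene_id %in% train_genes
  } else {
    n_train <- round(train_frac * nrow(dataset))
    in_train <- seq_len(nrow(dataset)) %in% sample.int(nrow(dataset), n_train)
  }
  list(train = dataset[in_train, , drop = FALSE],
       test = dataset[!in_train, , drop = FALSE])
}

#' Fit a linear expression model on histone marks
#'
#' Ordinary least squares of y = log2(FPKM + 0.1) on the log2 mark signals:
#' y ~ beta0 + beta1 x1 + ... + betan xn + eps. Variable importance of mark
#' j is the absolute t-statistic |t_j| = |beta_j| / SE(beta_j), and the
#' importance share is |t_j| / sum |t| over the marks (intercept excluded).
#'
#' @param dataset Model dataset from \code{\link{assemble_dataset}} (or any
#'   data.frame with a y column and the mark columns).
#' @param marks Predictors to use; defaults to the dataset's marks
#'   attribute, else all non-metadata columns. Mark-exclusion models
#'   (e.g. without H3K27me3) are plain subsets of this argument.
#' @return Object of class \code{histone_lm}.
#' @export
histone_lm <- function(dataset, marks = NULL) {
  if (is.null(marks)) marks <- attr(dataset, "marks")
  if (is.null(marks))
    marks <- setdiff(names(dataset), c("gene_id", "region_id", "y"))
  if (!"y" %in% names(dataset)) stop("histone_lm: dataset lacks y")
  if (nrow(dataset) <= length(marks) + 1)
    stop("histone_lm: need more rows than predictors + 1")
  const <- marks[vapply(dataset[marks], function(v) stats::var(v) == 0,
                        logical(1))]
  if (length(const))
    stop("histone_lm: constant predictor column(s): ",
         paste(const, collapse = ", "))
  df <- dataset[, c("y", marks), drop = FALSE]
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("histone_lm: rank-deficient design; collinear column(s): ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  # a zero-residual fit is legitimate here (flagged below); silence the
  # "essentially perfect fit" warning from summary.lm
  sm <- suppressWarnings(summary(fit))
  sigma <- sm$sigma
  perfect <- sigma < 1e-10
  ct <- sm$coefficients
  tval <- ct[, "t value"]
  pval <- ct[, "Pr(>|t|)"]
  if (perfect) { tval[] <- Inf; pval[] <- 0 }
  imp <- abs(tval[marks])
  share <- if (perfect) rep(NA_real_, length(marks)) else imp / sum(imp)
  names(share) <- marks
  structure(list(coefficients = stats::coef(fit),
                 t = tval, p = pval,
                 importance = imp, importance_share = share,
                 sigma = sigma, perfect_fit = perfect,
                 marks = marks, n = nrow(df),
                 fit = fit, call = match.call()),
            class = "histone_lm")
}

#' @export
print.histone_lm <- function(x, ...) {
  cat("Linear expression model on", length(x$marks), "histone marks,",
      x$n, "rows\n")
  cat("Coefficients:\n")
  print(signif(x$coefficients, 4))
  if (x$perfect_fit)
    cat("Residual error ~ 0 (perfect fit); t-statistics flagged infinite\n")
  invisible(x)
}

#' @method summary histone_lm
#' @export
summary.histone_lm <- function(object, ...) {
  tab <- data.frame(coefficient = object$coefficients,
                    t = object$t,
                    p = object$p,
                    stringsAsFactors = FALSE)
  tab$importance <- c(NA, object$importance)[match(rownames(tab),
                                                   c("(Intercept)", object$marks))]
  tab$share <- c(NA, object$importance_share)[match(rownames(tab),
                                                    c("(Intercept)", object$marks))]
  structure(list(table = tab, sigma = object$sigma, n = object$n,
                 perfect_fit = object$perfect_fit),
            class = "summary.histone_lm")
}

#' @export
print.summary.histone_lm <- function(x, ...) {
  cat("Linear expression model (", x$n, " rows, residual sigma ",
      signif(x$sigma, 4), ")\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' @method coef histone_lm
#' @export
coef.histone_lm <- function(object, ...) object$coefficients

#' @export
predict.histone_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = newdata)
}

#' @method residuals histone_lm
#' @export
residuals.histone_lm <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.histone_lm <- function(object, ...) stats::fitted(object$fit)

#' Scatter of predicted versus measured expression
#'
#' @param x \code{histone_lm} object.
#' @param data Dataset to plot (default: the training data).
#' @param ... Passed to \code{plot}.
#' @method plot histone_lm
#' @export
plot.histone_lm <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    meas <- x$fit$model$y
    pred <- stats::fitted(x$fit)
  } else {
    meas <- data$y
    pred <- predict(x, data)
  }
  r <- stats::cor(pred, meas)
  graphics::plot(pred, meas,
                 xlab = "predicted log2 expression",
                 ylab = "measured log2 expression",
                 main = sprintf("r = %.2f", r), pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.4), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(r)
}

#' Simulate responses from a fitted model
#'
#' Draws new y vectors from the fitted linear predictor plus Gaussian noise
#' at the estimated residual scale.
#'
#' @param object \code{histone_lm} object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return data.frame with nsim columns of simulated responses.
#' @export
simulate.histone_lm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  mu <- stats::fitted(object$fit)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Evaluate a model on a dataset
#'
#' Pearson correlation r between predicted and measured y, computed over
#' rows (a gene duplicated across enhancers contributes one term per row).
#' With \code{aggregate = "gene"}, predictions and measurements are averaged
#' per gene first.
#'
#' @param model \code{histone_lm} object.
#' @param data Model dataset holding the model's predictors.
#' @param aggregate "row" (default) or "gene".
#' @return Object of class \code{epm_evaluation}: list with r, n and the
#'   per-row predictions.
#' @export
evaluate_model <- function(model, data, aggregate = c("row", "gene")) {
  aggregate <- match.arg(aggregate)
  pred <- predict(model, data)
  meas <- data$y
  if (aggregate == "gene") {
    pred <- tapply(pred, data$gene_id, mean)
    meas <- tapply(meas, data$gene_id, mean)
  }
  degenerate <- stats::sd(pred) == 0 || stats::sd(meas) == 0
  r <- if (degenerate) NA_real_ else stats::cor(pred, meas)
  structure(list(r = r, n = length(pred), degenerate = degenerate,
                 predictions = data.frame(predicted = as.numeric(pred),
                                          measured = as.numeric(meas))),
            class = "epm_evaluation")
}

#' @export
print.epm_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation on %d rows: Pearson r = %.3f\n", x$n, x$r))
  invisible(x)
}

#' Repeated k-fold cross-validation
#'
#' Gene-level fold partition (all rows of a gene stay in one fold),
#' repeated with distinct seeded shuffles. Each fold is held out once per
#' repeat; the model is fitted on the remaining folds and evaluated on it.
#'
#' @param dataset Model dataset.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeats (default 3).
#' @param seed Integer seed.
#' @param marks Predictors (defaults as in \code{\link{histone_lm}}).
#' @param level "gene" (default) or "row" fold granularity.
#' @return data.frame with columns repeat_, fold, r, n; attribute
#'   \code{summary} holds mean and sd of r.
#' @export
cross_validate <- function(dataset, k = 10, repeats = 3, seed = 1,
                           marks = NULL, level = c("gene", "row")) {
  level <- match.arg(level)
  units <- if (level == "gene") unique(dataset$gene_id)
           else seq_len(nrow(dataset))
  if (length(units) < k) stop("cross_validate: fewer units than folds")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  res <- list()
  for (rep_i in seq_len(repeats)) {
    fold_of <- sample(rep_len(seq_len(k), length(units)))
    names(fold_of) <- units
    for (fold in seq_len(k)) {
      test_units <- units[fold_of == fold]
      in_test <- if (level == "gene") dataset$gene_id %in% test_units
                 else seq_len(nrow(dataset)) %in% test_units
      model <- histone_lm(dataset[!in_test, , drop = FALSE], marks = marks)
      ev <- evaluate_model(model, dataset[in_test, , drop = FALSE])
      res[[length(res) + 1]] <- data.frame(repeat_ = rep_i, fold = fold,
                                           r = ev$r, n = ev$n)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "summary") <- c(mean_r = mean(out$r), sd_r = stats::sd(out$r))
  out
}

#' Cross-context evaluation matrix
#'
#' For each context, fits a model on all of that context's rows and
#' evaluates it on every other context's full dataset (the diagonal is left
#' empty). All contexts must share the same marks.
#'
#' @param datasets Named list of model datasets, one per context.
#' @param marks Predictors (defaults to the first dataset's marks).
#' @return Numeric matrix of r values, rows = training context, columns =
#'   evaluation context, NA diagonal.
#' @export
cross_context_matrix <- function(datasets, marks = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 2,
            !is.null(names(datasets)))
  ctx <- names(datasets)
  if (is.null(marks)) marks <- attr(datasets[[1]], "marks")
  out <- matrix(NA_real_, length(ctx), length(ctx),
                dimnames = list(train = ctx, eval = ctx))
  for (i in ctx) {
    model <- histone_lm(datasets[[i]], marks = marks)
    for (j in setdiff(ctx, i)) {
      out[i, j] <- evaluate_model(model, datasets[[j]])$r
    }
  }
  out
}

#' Paired t-test of model versus randomized performance
#'
#' Classical paired Student's t-test on the differences between model r
#' values and random-control r values aligned by evaluation set, with the
#' star code thresholds **** < 0.0001, *** < 0.001, ** < 0.01, * < 0.05.
#'
#' @param model_rs Numeric vector of model performances.
#' @param random_rs Numeric vector of paired random-model performances.
#' @return List with t, df, p (two-sided), stars and a degenerate flag (set
#'   when the differences have zero variance).
#' @export
paired_t_test <- function(model_rs, random_rs) {
  stopifnot(length(model_rs) == length(random_rs), length(model_rs) >= 2)
  d <- model_rs - random_rs
  if (stats::sd(d) < 1e-12) {
    return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                stars = "", degenerate = TRUE))
  }
  tt <- stats::t.test(model_rs, random_rs, paired = TRUE)
  p <- tt$p.value
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
           if (p < 1e-2) "**" else if (p < 0.05) "*" else ""
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       stars = stars, degenerate = FALSE)
}
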