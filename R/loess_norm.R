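# Multi-sample cyclic MA-LOESS normalization: robust local-regression
# corrections fitted pairwise on genome bins and applied, as per-sample
# functions of average log-intensity, to bins, regions or expression tables.

#' Drop rows containing zeros
#'
#' Rows with a zero in any column are removed before normalization, since a
#' zero cannot be distinguished from a sequencing dropout and the log
#' transform is undefined there.
#'
#' @param x Numeric matrix or data.frame of non-negative values.
#' @return The filtered matrix; errors when no row survives.
#' @export
drop_zero_rows <- function(x) {
  x <- as.matrix(x)
  keep <- rowSums(x == 0) == 0
  if (!any(keep)) stop("drop_zero_rows: all rows contain zeros; nothing to normalize")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("drop_zero_rows: removed ", n_drop, " row(s) containing zeros")
  x[keep, , drop = FALSE]
}

#' MA transform of two positive samples
#'
#' M = log2(x1) - log2(x2), A = (log2(x1) + log2(x2)) / 2. Defined only for
#' strictly positive values.
#'
#' @param x1,x2 Strictly positive numeric vectors.
#' @return List with components M and A.
#' @export
ma_transform <- function(x1, x2) {
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("ma_transform: values must be strictly positive")
  l1 <- log2(x1); l2 <- log2(x2)
  list(M = l1 - l2, A = (l1 + l2) / 2)
}

# Internal: clamp to range then linear interpolation (constant extrapolation).
interp_curve <- function(grid, curve, a) {
  stats::approx(grid, curve, xout = pmin(pmax(a, grid[1]), grid[length(grid)]),
                rule = 2)$y
}

#' Fit a cyclic LOESS normalization model
#'
#' Cyclic procedure over unordered sample pairs: per round, every pair's
#' M-versus-A trend is fitted by a robust (symmetric-family, degree 1) local
#' regression on a seeded random subset of rows, and half the fitted trend
#' is charged against each sample of the pair as a function of A. The
#' per-sample corrections, averaged over each sample's pairs, are applied in
#' log2 space at the end of the round; rounds repeat until the largest mean
#' absolute applied correction falls below \code{tol} or \code{max_rounds}
#' is reached. Corrections are stored as piecewise-linear curves on a fixed
#' 256-point A-grid with constant extrapolation, making the model
#' deterministic and serializable. Because the pairwise charges are
#' balanced (+/- fit/2), the corrections of one round sum to zero across
#' samples at every A, so each row's average log2 intensity is invariant and
#' round curves can be accumulated on the shared grid.
#'
#' @param x Strictly positive matrix (rows = bins/genes, columns = samples;
#'   run \code{\link{drop_zero_rows}} first). At least 2 samples, 20 rows.
#' @param span LOESS span (default 2/3).
#' @param max_rounds Maximum correction rounds (default 3).
#' @param tol Convergence threshold on mean |applied correction| in log2
#'   units (default 0.01).
#' @param subset_size Maximum rows used per pairwise fit (default 5000).
#' @param seed Seed for the row subsets (default 1).
#' @param a_method Abscissa for the pairwise fit: "mean_log" (default;
#'   average of the two log2 intensities) or "log_mean" (log2 of the average
#'   intensity).
#' @param grid_points Number of grid knots (default 256).
#' @return Object of class \code{cyclic_loess}: grid, per-sample curve
#'   matrix, the normalized input (\code{normalized}), samples, and fitting
#'   metadata.
#' @export
fit_cyclic_loess <- function(x, span = 2/3, max_rounds = 3, tol = 0.01,
                             subset_size = 5000, seed = 1,
                             a_method = c("mean_log", "log_mean"),
                             grid_points = 256) {
  a_method <- match.arg(a_method)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("fit_cyclic_loess: need at least 2 samples")
  if (nrow(x) < 20) stop("fit_cyclic_loess: need at least 20 rows")
  if (any(x <= 0)) stop("fit_cyclic_loess: values must be strictly positive")
  samples <- colnames(x)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(x)))
  L <- log2(x)
  S <- ncol(L); G <- grid_points
  grid <- seq(min(L), max(L), length.out = G)
  cum <- matrix(0, G, S, dimnames = list(NULL, samples))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rounds_run <- 0
  for (round in seq_len(max_rounds)) {
    round_curve <- matrix(0, G, S)
    for (i in seq_len(S - 1)) {
      for (j in seq((i + 1), S)) {
        idx <- if (nrow(L) > subset_size)
          sample.int(nrow(L), subset_size) else seq_len(nrow(L))
        M <- L[idx, i] - L[idx, j]
        A <- if (a_method == "mean_log") (L[idx, i] + L[idx, j]) / 2
             else log2((2^L[idx, i] + 2^L[idx, j]) / 2)
        # symmetric-family robustness breaks down when the residual spread
        # is (near) zero, e.g. a constant M; fall back to least squares
        fit <- tryCatch(
          stats::loess(M ~ A, span = span, degree = 1, family = "symmetric"),
          error = function(e)
            stats::loess(M ~ A, span = span, degree = 1, family = "gaussian"))
        pred <- stats::predict(fit, newdata = data.frame(
          A = pmin(pmax(grid, min(A)), max(A))))
        round_curve[, i] <- round_curve[, i] + pred / 2
        round_curve[, j] <- round_curve[, j] - pred / 2
      }
    }
    round_curve <- round_curve / (S - 1)
    A_row <- rowMeans(L)
    applied <- vapply(seq_len(S), function(s)
      interp_curve(grid, round_curve[, s], A_row), numeric(nrow(L)))
    L <- L - applied
    cum <- cum + round_curve
    rounds_run <- round
    if (max(colMeans(abs(applied))) < tol) break
  }
  structure(list(grid = grid, curves = cum, samples = samples,
                 normalized = 2^L,
                 span = span, a_method = a_method, tol = tol,
                 max_rounds = max_rounds, rounds_run = rounds_run,
                 subset_size = subset_size, seed = seed),
            class = "cyclic_loess")
}

#' @export
print.cyclic_loess <- function(x, ...) {
  cat("Cyclic LOESS normalization model:", length(x$samples), "samples,",
      x$rounds_run, "round(s), span", signif(x$span, 3), "\n")
  cat("  mean |correction| per sample:",
      paste(signif(colMeans(abs(x$curves)), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a fitted normalization model to a table
#'
#' For each row, A is the mean of the row's log2 values across samples; the
#' corrected value of sample s is 2^(log2 x - c_s(A)) with c_s the sample's
#' correction curve (constant extrapolation outside the fitted A-range).
#' Typical use: fit on genome bins, apply to regulatory regions.
#'
#' @param model \code{cyclic_loess} object.
#' @param x Strictly positive matrix with the model's samples as columns,
#'   in the same order.
#' @return Normalized matrix of the same shape.
#' @export
apply_cyclic_loess <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !identical(colnames(x), model$samples))
    stop("apply_cyclic_loess: sample columns do not match the model")
  if (ncol(x) != length(model$samples))
    stop("apply_cyclic_loess: wrong number of samples")
  if (any(x <= 0)) stop("apply_cyclic_loess: values must be strictly positive")
  L <- log2(x)
  A <- rowMeans(L)
  corr <- matrix(vapply(seq_along(model$samples), function(s)
    interp_curve(model$grid, model$curves[, s], A), numeric(nrow(x))),
    nrow = nrow(x))
  out <- 2^(L - corr)
  dimnames(out) <- dimnames(x)
  out
}

#' Serialize / restore a normalization model as JSON
#'
#' @param model \code{cyclic_loess} object.
#' @param path Output path.
#' @return \code{write_norm_model}: the path, invisibly.
#' @export
write_norm_model <- function(model, path) {
  obj <- model[c("grid", "samples", "span", "a_method", "tol", "max_rounds",
                 "rounds_run", "subset_size", "seed")]
  obj$curves <- unclass(as.data.frame(model$curves))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_norm_model
#' @return \code{read_norm_model}: the restored \code{cyclic_loess} object
#'   (without the \code{normalized} table).
#' @export
read_norm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- as.matrix(as.data.frame(obj$curves))
  colnames(curves) <- obj$samples
  structure(list(grid = obj$grid, curves = curves, samples = obj$samples,
                 normalized = NULL, span = obj$span, a_method = obj$a_method,
                 tol = obj$tol, max_rounds = obj$max_rounds,
                 rounds_run = obj$rounds_run, subset_size = obj$subset_size,
                 seed = obj$seed),
            class = "cyclic_loess")
}
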