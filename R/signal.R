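# Per-region and per-bin ChIP signal: library-size-normalized read counts
# averaged by region length.

#' Quantify signal over regions
#'
#' value(region) = scale * (reads overlapping the region by >= 1 bp) /
#' library_size / region length in bp. With \code{count_mode = "midpoint"} a
#' read is assigned to the region containing its midpoint instead. The
#' per-million scale keeps values order-1; any fixed scale cancels in
#' log-linear modelling up to the intercept and in MA differences.
#'
#' @param reads Interval data.frame of reads for one sample.
#' @param regions Interval data.frame of target regions.
#' @param library_size Total mapped reads of the sample (>= 1).
#' @param count_mode "overlap" (default; a read straddling two regions
#'   counts in both) or "midpoint".
#' @param scale Scaling constant (default 1e6).
#' @return Numeric vector of mean per-bp normalized counts, one per region.
#' @export
quantify <- function(reads, regions, library_size,
                     count_mode = c("overlap", "midpoint"), scale = 1e6) {
  count_mode <- match.arg(count_mode)
  if (length(library_size) != 1 || library_size < 1)
    stop("quantify: library_size must be a single integer >= 1")
  validate_intervals(regions, "regions")
  if (nrow(reads)) validate_intervals(reads, "reads")
  if (count_mode == "midpoint" && nrow(reads)) {
    mid <- floor((reads$start + reads$end) / 2)
    reads <- data.frame(chrom = reads$chrom, start = mid, end = mid + 1,
                        stringsAsFactors = FALSE)
  }
  counts <- integer(nrow(regions))
  hits <- overlap_hits(regions, reads)
  if (nrow(hits)) {
    tab <- table(hits$query)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  scale * counts / library_size / (regions$end - regions$start)
}

#' Quantify signal over genome bins
#'
#' Applies \code{\link{quantify}} to the fixed-width bins of
#' \code{\link{bin_genome}}.
#'
#' @param reads Interval data.frame of reads.
#' @param genome Genome table.
#' @param width Bin width in bp (default 2000).
#' @inheritParams quantify
#' @return Bin data.frame (chrom, start, end, name, partial) with a
#'   \code{value} column.
#' @export
quantify_bins <- function(reads, genome, width = 2000, library_size,
                          count_mode = c("overlap", "midpoint"), scale = 1e6) {
  bins <- bin_genome(genome, width)
  bins$value <- quantify(reads, bins, library_size,
                         count_mode = match.arg(count_mode), scale = scale)
  bins
}

#' Build a multi-sample signal matrix over regions
#'
#' @param reads_by_sample Named list of read interval data.frames.
#' @param regions Interval data.frame with an \code{id} column.
#' @param library_sizes Named numeric vector of library sizes, aligned with
#'   \code{reads_by_sample}.
#' @inheritParams quantify
#' @return Numeric matrix (regions x samples) with region ids as rownames.
#' @export
signal_matrix <- function(reads_by_sample, regions, library_sizes,
                          count_mode = c("overlap", "midpoint"), scale = 1e6) {
  count_mode <- match.arg(count_mode)
  stopifnot(!is.null(names(reads_by_sample)),
            all(names(reads_by_sample) %in% names(library_sizes)))
  cols <- lapply(names(reads_by_sample), function(s) {
    quantify(reads_by_sample[[s]], regions, library_sizes[[s]],
             count_mode = count_mode, scale = scale)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(reads_by_sample)
  rownames(m) <- if ("id" %in% names(regions)) regions$id else
    paste0(regions$chrom, ":", regions$start, "-", regions$end)
  m
}
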