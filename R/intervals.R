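# ---- interval data model -----------------------------------------------------
#
# Intervals are plain data.frames with columns chrom / start / end (0-based,
# half-open) plus optional name, strand and arbitrary extra columns. All
# coordinate arithmetic in the package uses this convention; 1-based dialects
# are converted at the reader boundary.

#' Construct a table of genomic intervals
#'
#' Builds and validates a BED-like data.frame of genomic intervals using
#' 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions.
#' @param name Optional identifier column.
#' @param score Optional score column (BED column 5).
#' @param strand Optional strand column ("+", "-" or ".").
#' @param ... Further columns, recycled to length.
#' @return A data.frame with class-free interval columns.
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL,
                      strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.character(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the interval invariants: non-empty chromosome names and
#' 0 <= start < end for every row.
#'
#' @param df Interval data.frame.
#' @param what Label used in error messages.
#' @return The input, invisibly.
#' @export
validate_intervals <- function(df, what = "interval table") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop(what, ": empty chromosome name")
  if (any(is.na(df$start) | is.na(df$end)))
    stop(what, ": NA coordinates")
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop(what, ": invalid coordinates (start < 0 or start >= end) at row ",
         bad[1])
  invisible(df)
}

#' Sort intervals by (chrom, start, end)
#'
#' @param df Interval data.frame.
#' @return The sorted data.frame.
#' @export
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Internal: convert 0-based half-open intervals to GRanges (1-based closed).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# Internal: all (query row, subject row) index pairs overlapping by >= 1 bp.
overlap_hits <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  h <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Test whether two intervals overlap
#'
#' Overlap means the same chromosome and an intersection of at least 1 bp
#' under half-open semantics. Vectorized over rows; shorter input recycled
#' if of length 1.
#'
#' @param a,b Interval data.frames (single- or equal-length).
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Distance between two intervals
#'
#' Returns 0 for overlapping intervals, otherwise the gap in bp between the
#' nearest ends; NA for intervals on different chromosomes.
#'
#' @param a,b Interval data.frames (single- or equal-length rows).
#' @return Numeric vector of distances (NA across chromosomes).
#' @export
interval_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  d <- pmax(a$start - b$end, b$start - a$end, 0)
  d[a$chrom != b$chrom] <- NA_real_
  as.numeric(d)
}

# ---- genome table and binning ------------------------------------------------

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path File path.
#' @return data.frame with columns chrom, length.
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"),
                          stringsAsFactors = FALSE)
  validate_genome_table(df)
  df
}

#' @rdname read_genome_table
#' @param genome Genome table to validate.
#' @export
validate_genome_table <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (any(duplicated(genome$chrom))) stop("genome table: duplicated chromosome names")
  if (any(genome$length <= 0)) stop("genome table: non-positive chromosome length")
  invisible(genome)
}

#' Tile a genome into fixed-width bins
#'
#' Produces consecutive non-overlapping bins [0, w), [w, 2w), ... for each
#' chromosome. The final partial bin is retained and flagged in the
#' \code{partial} column; downstream signal quantification uses mean-per-bp
#' values so differing bin widths do not bias signal.
#'
#' @param genome Genome table (see \code{\link{read_genome_table}}).
#' @param width Bin width in bp (default 2000).
#' @return Interval data.frame with columns chrom, start, end, name
#'   ("chrom:start-end") and logical partial.
#' @export
bin_genome <- function(genome, width = 2000) {
  validate_genome_table(genome)
  stopifnot(width > 0)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    data.frame(chrom = genome$chrom[i], start = as.integer(starts),
               end = as.integer(ends), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$name <- paste0(df$chrom, ":", df$start, "-", df$end)
  df$partial <- (df$end - df$start) < width
  df
}

# ---- readers / writers -------------------------------------------------------

#' Read a BED file
#'
#' Reads tab-separated BED (0-based half-open). Columns beyond the third are
#' kept: column 4 as \code{name}, column 5 as \code{score}, column 6 as
#' \code{strand}, further columns as \code{extra1}, \code{extra2}, ...
#'
#' @param path File path.
#' @param min_cols Minimum number of columns each line must have.
#' @return Interval data.frame in file order.
#' @export
read_bed <- function(path, min_cols = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols))
    stop("BED parse error at line ", which(nf < min_cols)[1],
         ": fewer than ", min_cols, " columns")
  ncol_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": non-integer coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": start >= end")
  df <- data.frame(chrom = mat[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  cn <- c("name", "score", "strand")
  extra_i <- 0
  for (j in seq_len(ncol_use - 3)) {
    col <- if (j <= 3) cn[j] else { extra_i <- extra_i + 1; paste0("extra", extra_i) }
    df[[col]] <- mat[, j + 3]
  }
  df
}

#' Write intervals as BED
#'
#' Emits chrom/start/end plus name, score and strand columns when present
#' (BED3/BED4/BED6 accordingly), tab-separated, no header.
#'
#' @param df Interval data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- c("chrom", "start", "end")
  for (cn in c("name", "score", "strand")) {
    if (cn %in% names(df)) cols <- c(cols, cn) else break
  }
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE interaction file
#'
#' Dialect: header line, then columns chrom1, start1, end1, chrom2, start2,
#' end2, name, lnP, FDR. \code{lnP} is the natural log of the interaction
#' p-value (<= 0) and \code{FDR} its false-discovery rate (>= 0).
#'
#' @param path File path.
#' @return data.frame of interactions.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
                      chrom2 = character(0), start2 = integer(0), end2 = integer(0),
                      name = character(0), lnP = numeric(0), FDR = numeric(0),
                      stringsAsFactors = FALSE))
  }
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "lnP", "FDR")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("BEDPE schema error: missing columns ", paste(miss, collapse = ", "))
  validate_interactions(df)
  df
}

#' @rdname read_bedpe
#' @param ix Interaction data.frame to validate.
#' @export
validate_interactions <- function(ix) {
  if (nrow(ix) == 0) return(invisible(ix))
  a1 <- data.frame(chrom = ix$chrom1, start = ix$start1, end = ix$end1)
  a2 <- data.frame(chrom = ix$chrom2, start = ix$start2, end = ix$end2)
  validate_intervals(a1, "BEDPE anchor1")
  validate_intervals(a2, "BEDPE anchor2")
  if (any(ix$lnP > 0)) stop("BEDPE: lnP must be <= 0")
  if (any(ix$FDR < 0)) stop("BEDPE: FDR must be >= 0")
  invisible(ix)
}

#' Write interactions as BEDPE
#'
#' @param ix Interaction data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedpe <- function(ix, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "lnP", "FDR")
  if (!"name" %in% names(ix)) ix$name <- paste0("ix", seq_len(nrow(ix)))
  utils::write.table(ix[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSS catalogue
#'
#' Tab-separated with header: gene_id, chrom, pos, strand, where pos is the
#' 0-based transcription start position. Each record is treated as a width-1
#' interval [pos, pos + 1).
#'
#' @param path File path.
#' @return data.frame with columns gene_id, chrom, pos, strand.
#' @export
read_tss <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TSS table: missing columns ", paste(miss, collapse = ", "))
  if (!"strand" %in% names(df)) df$strand <- "."
  df
}
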