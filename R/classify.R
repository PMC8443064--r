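# Classification of candidate regions into active/bivalent promoters and
# active/poised enhancers, promoter-gene assignment, TSS distances and the
# intragenic/intergenic enhancer partition.

# Internal: TSS windows [pos - window, pos + window + 1), clipped at 0.
tss_windows <- function(tss, window = 500) {
  data.frame(chrom = tss$chrom,
             start = pmax(0L, as.integer(tss$pos) - as.integer(window)),
             end = as.integer(tss$pos) + as.integer(window) + 1L,
             gene_id = tss$gene_id,
             stringsAsFactors = FALSE)
}

# Internal: stable candidate ids from coordinates.
candidate_ids <- function(candidates) {
  paste0(candidates$chrom, ":", candidates$start, "-", candidates$end)
}

#' Classify candidate regions as promoters
#'
#' A candidate is a promoter iff it overlaps by at least 1 bp the window
#' of +/- \code{window} bp around any TSS position (a 2*window + 1 bp
#' window). Active candidates become active promoters (AP), poised
#' candidates bivalent promoters (BP).
#'
#' @param candidates Candidate regions from \code{\link{merge_state_groups}}
#'   (columns chrom, start, end, group).
#' @param tss TSS catalogue (gene_id, chrom, pos, strand).
#' @param window Half-width of the TSS window in bp (default 500).
#' @return Regions data.frame: id, chrom, start, end, group, class.
#' @export
classify_promoters <- function(candidates, tss, window = 500) {
  validate_intervals(candidates, "candidates")
  win <- tss_windows(tss, window)
  hits <- overlap_hits(candidates, win)
  is_prom <- seq_len(nrow(candidates)) %in% hits$query
  out <- candidates[is_prom, c("chrom", "start", "end", "group"), drop = FALSE]
  out$class <- ifelse(out$group == "active", "AP", "BP")
  out <- sort_intervals(out)
  out$id <- region_ids(out$class)
  rownames(out) <- NULL
  out[, c("id", "chrom", "start", "end", "group", "class")]
}

# Internal: class-prefixed sequential ids (AP_1, AP_2, ..., BP_1, ...).
region_ids <- function(class) {
  if (length(class) == 0) return(character(0))
  k <- stats::ave(seq_along(class), class, FUN = seq_along)
  paste0(class, "_", k)
}

#' Classify candidate regions as enhancers
#'
#' Among candidates not already classified as promoters, a candidate is an
#' enhancer iff it overlaps by at least 1 bp any p300 peak. Active
#' candidates become active enhancers (AE), poised candidates poised
#' enhancers (PE). No filtering on histone-mark content is applied (H3K4me3
#' at enhancers is allowed). Candidates that are neither promoters nor
#' p300-supported are dropped.
#'
#' @param candidates Candidate regions.
#' @param promoters Promoter regions from \code{\link{classify_promoters}}.
#' @param p300_peaks Interval data.frame of p300 peaks.
#' @return Regions data.frame: id, chrom, start, end, group, class.
#' @export
classify_enhancers <- function(candidates, promoters, p300_peaks) {
  validate_intervals(candidates, "candidates")
  key <- candidate_ids(candidates)
  prom_key <- paste0(promoters$chrom, ":", promoters$start, "-", promoters$end)
  cand <- candidates[!key %in% prom_key, , drop = FALSE]
  hits <- overlap_hits(cand, p300_peaks)
  is_enh <- seq_len(nrow(cand)) %in% hits$query
  out <- cand[is_enh, c("chrom", "start", "end", "group"), drop = FALSE]
  out$class <- ifelse(out$group == "active", "AE", "PE")
  out <- sort_intervals(out)
  out$id <- region_ids(out$class)
  rownames(out) <- NULL
  out[, c("id", "chrom", "start", "end", "group", "class")]
}

#' Classify candidates into the four regulatory classes
#'
#' Convenience wrapper: promoter calls take absolute precedence, the
#' remaining candidates are tested against p300 peaks for enhancer calls.
#'
#' @inheritParams classify_promoters
#' @param p300_peaks Interval data.frame of p300 peaks.
#' @return Regions data.frame with class in {AP, BP, AE, PE}.
#' @export
classify_regions <- function(candidates, tss, p300_peaks, window = 500) {
  prom <- classify_promoters(candidates, tss, window)
  enh <- classify_enhancers(candidates, prom, p300_peaks)
  out <- rbind(prom, enh)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign promoters to their target genes
#'
#' Emits a (promoter, gene) pair for every TSS of a gene whose
#' +/- \code{window} bp window overlaps the promoter by at least 1 bp;
#' pairs are deduplicated. Promoters with no overlapping window are kept in
#' the region set but get no pair.
#'
#' @param promoters Promoter regions (id, chrom, start, end).
#' @param tss TSS catalogue.
#' @param window Half-width of the TSS window in bp (default 500).
#' @return data.frame with columns promoter_id, gene_id.
#' @export
assign_genes_to_promoters <- function(promoters, tss, window = 500) {
  win <- tss_windows(tss, window)
  hits <- overlap_hits(promoters, win)
  out <- data.frame(promoter_id = promoters$id[hits$query],
                    gene_id = win$gene_id[hits$subject],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Distance from regions to the nearest TSS
#'
#' Minimum distance (bp) between each region and any TSS point on the same
#' chromosome; 0 if a TSS falls inside the region. Regions on chromosomes
#' with no TSS get NA and are excluded from distal sets. A region is distal
#' when its distance is strictly greater than \code{distal_cutoff}.
#'
#' @param regions Regions data.frame (id, chrom, start, end).
#' @param tss TSS catalogue.
#' @param distal_cutoff Distal threshold in bp (default 5000, strict >).
#' @return data.frame: id, distance, distal.
#' @export
tss_distance <- function(regions, tss, distal_cutoff = 5000) {
  dist <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    pos <- tss$pos[tss$chrom == ch]
    if (length(pos) == 0) next
    s <- regions$start[ri]; e <- regions$end[ri]
    # distance from [s, e) to point interval [p, p + 1)
    dist[ri] <- vapply(seq_along(ri), function(j) {
      min(pmax(s[j] - (pos + 1), pos - e[j], 0))
    }, numeric(1))
  }
  data.frame(id = regions$id, distance = dist,
             distal = !is.na(dist) & dist > distal_cutoff,
             stringsAsFactors = FALSE)
}

#' Partition enhancers into intragenic and intergenic sets
#'
#' An enhancer is intragenic iff it overlaps any gene body by at least 1 bp.
#' The two sets are disjoint and exhaustive.
#'
#' @param enhancers Enhancer regions.
#' @param gene_bodies Interval data.frame of gene bodies (TSS-to-end spans,
#'   unioned per gene).
#' @return List with elements \code{intragenic} and \code{intergenic}.
#' @export
partition_intragenic <- function(enhancers, gene_bodies) {
  validate_intervals(gene_bodies, "gene bodies")
  hits <- overlap_hits(enhancers, gene_bodies)
  intra <- seq_len(nrow(enhancers)) %in% hits$query
  list(intragenic = enhancers[intra, , drop = FALSE],
       intergenic = enhancers[!intra, , drop = FALSE])
}

#' Write classified regions as BED
#'
#' Emits BED4 with "class|id" in the name column.
#'
#' @param regions Regions data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_regions <- function(regions, path) {
  df <- regions
  df$name <- paste0(df$class, "|", df$id)
  write_bed(df[, c("chrom", "start", "end", "name")], path)
}

#' Read classified regions from BED
#'
#' Inverse of \code{\link{write_regions}}.
#'
#' @param path File path.
#' @return Regions data.frame: id, chrom, start, end, group, class.
#' @export
read_regions <- function(path) {
  df <- read_bed(path, min_cols = 4)
  parts <- strsplit(df$name, "|", fixed = TRUE)
  df$class <- vapply(parts, `[`, character(1), 1)
  df$id <- vapply(parts, `[`, character(1), 2)
  df$group <- ifelse(df$class %in% c("AP", "AE"), "active", "poised")
  df[, c("id", "chrom", "start", "end", "group", "class")]
}
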