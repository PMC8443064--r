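# Chromatin-state segmentation post-processing: coalescing, the state
# transition-enrichment matrix, and merging of state groups into candidate
# active / poised regulatory regions.

#' Read a chromatin-state segmentation
#'
#' BED4 dialect: chrom, start, end, state label. Labels may be bare integers
#' ("3") or ChromHMM-style ("E3"); both are parsed to integer states.
#'
#' @param path File path.
#' @return Segment track: interval data.frame with integer \code{state}.
#' @export
read_segmentation <- function(path) {
  df <- read_bed(path, min_cols = 4)
  state <- suppressWarnings(as.integer(sub("^E", "", df$name)))
  if (any(is.na(state)))
    stop("segmentation: unparseable state label at row ", which(is.na(state))[1])
  df$state <- state
  df$name <- NULL
  sort_intervals(df)
}

#' Default 9-state grouping scheme
#'
#' Maps chromatin states to functional groups: states 1-4 carry
#' activation-associated marks, state 5 is an intermediate H3K4me1 signature,
#' states 6-7 carry the poised/bivalent combination (H3K27me3 with H3K4me3
#' and/or H3K4me1), state 8 is H3K27me3 only, and state 9 is unmarked.
#'
#' @return Named character vector mapping state label to group.
#' @export
default_state_scheme <- function() {
  c("1" = "active", "2" = "active", "3" = "active", "4" = "active",
    "5" = "intermediate", "6" = "poised", "7" = "poised",
    "8" = "repressed_only", "9" = "unmarked")
}

# Internal: check per-chromosome sorted, non-overlapping segments.
validate_track <- function(track) {
  validate_intervals(track, "segment track")
  if (!"state" %in% names(track)) stop("segment track: missing state column")
  track <- sort_intervals(track)
  same <- track$chrom[-1] == track$chrom[-nrow(track)]
  if (nrow(track) > 1 && any(same & track$start[-1] < track$end[-nrow(track)]))
    stop("segment track: overlapping segments")
  track
}

#' Merge touching same-state segments
#'
#' Adjacent segments (0-bp gap, same chromosome) with identical state are
#' merged into one. Segments separated by any gap are left untouched, so a
#' coalesced track can still contain same-state neighbours across gaps.
#'
#' @param track Segment track.
#' @return Coalesced segment track.
#' @export
coalesce_track <- function(track) {
  track <- validate_track(track)
  if (nrow(track) <= 1) return(track)
  new_run <- c(TRUE,
               track$chrom[-1] != track$chrom[-nrow(track)] |
               track$start[-1] != track$end[-nrow(track)] |
               track$state[-1] != track$state[-nrow(track)])
  run <- cumsum(new_run)
  data.frame(chrom = tapply(track$chrom, run, `[`, 1),
             start = as.integer(tapply(track$start, run, min)),
             end = as.integer(tapply(track$end, run, max)),
             state = as.integer(tapply(track$state, run, `[`, 1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' State transition-enrichment matrix
#'
#' Counts, for every ordered pair of states (x, y), the number of times a
#' segment of state y immediately follows a segment of state x left-to-right
#' along each chromosome (chromosome boundaries contribute no transitions).
#' Expected counts assume independence of origin and destination:
#' E(x, y) = out(x) * in(y) / N, with out/in the row/column marginals of the
#' observed matrix and N the total number of transitions. The enrichment is
#' R = O / E (NaN where E = 0).
#'
#' @param track Segment track.
#' @param coalesce Coalesce touching same-state segments first (default TRUE).
#' @return Object of class \code{transition_matrix}: list with matrices
#'   \code{observed}, \code{expected}, \code{enrichment}, total \code{n} and
#'   the state labels.
#' @export
transition_matrix <- function(track, coalesce = TRUE) {
  track <- if (coalesce) coalesce_track(track) else validate_track(track)
  states <- sort(unique(track$state))
  lv <- as.character(states)
  if (nrow(track) < 2) {
    z <- matrix(0, length(states), length(states), dimnames = list(lv, lv))
    return(structure(list(observed = z, expected = z, enrichment = z * NaN,
                          n = 0L, states = states),
                     class = "transition_matrix"))
  }
  keep <- track$chrom[-1] == track$chrom[-nrow(track)]
  from <- factor(track$state[-nrow(track)][keep], levels = states)
  to <- factor(track$state[-1][keep], levels = states)
  O <- table(from, to)
  O <- matrix(as.numeric(O), nrow = length(states), dimnames = list(lv, lv))
  n <- sum(O)
  if (n == 0) {
    z <- O
    return(structure(list(observed = O, expected = z, enrichment = z * NaN,
                          n = 0L, states = states),
                     class = "transition_matrix"))
  }
  E <- outer(rowSums(O), colSums(O)) / n
  R <- O / E
  structure(list(observed = O, expected = E, enrichment = R,
                 n = as.integer(n), states = states),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("State transition matrix:", x$n, "transitions,",
      length(x$states), "states\n")
  cat("Enrichment (observed / expected):\n")
  print(round(x$enrichment, 3))
  invisible(x)
}

#' Write a transition matrix as TSV
#'
#' Three blocks (observed, expected, enrichment), rows = origin state,
#' columns = destination state.
#'
#' @param x \code{transition_matrix} object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_transition_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (block in c("observed", "expected", "enrichment")) {
    writeLines(paste0("#", block), con)
    utils::write.table(x[[block]], con, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' Merge state groups into candidate regulatory regions
#'
#' Maximal runs of touching segments whose states map to the same group
#' (active or poised) are merged into one candidate region. Runs are broken
#' by any gap, by a group change, or by intermediate / repressed-only /
#' unmarked segments, which are never emitted. Regions shorter than
#' \code{min_length} are discarded as background, and any surviving active
#' region touching (0-bp gap) a surviving poised region is discarded together
#' with it as ambiguous.
#'
#' @param track Segment track.
#' @param scheme Named vector mapping state label to group
#'   (default \code{\link{default_state_scheme}}).
#' @param min_length Minimum region length in bp (default 600).
#' @param coalesce Coalesce the track first (default TRUE).
#' @return Candidate regions: data.frame chrom, start, end, group, states
#'   (comma-separated source state labels).
#' @export
merge_state_groups <- function(track, scheme = default_state_scheme(),
                               min_length = 600, coalesce = TRUE) {
  track <- if (coalesce) coalesce_track(track) else validate_track(track)
  if (any(!as.character(track$state) %in% names(scheme)))
    stop("merge_state_groups: state label missing from scheme")
  grp <- unname(scheme[as.character(track$state)])
  n <- nrow(track)
  if (n == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), group = character(0),
                      states = character(0), stringsAsFactors = FALSE))
  new_run <- c(TRUE,
               track$chrom[-1] != track$chrom[-n] |
               track$start[-1] != track$end[-n] |
               grp[-1] != grp[-n])
  run <- cumsum(new_run)
  keep <- grp %in% c("active", "poised")
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), group = character(0),
                      states = character(0), stringsAsFactors = FALSE))
  }
  t2 <- track[keep, , drop = FALSE]
  r2 <- run[keep]
  g2 <- grp[keep]
  regions <- data.frame(
    chrom = tapply(t2$chrom, r2, `[`, 1),
    start = as.integer(tapply(t2$start, r2, min)),
    end = as.integer(tapply(t2$end, r2, max)),
    group = tapply(g2, r2, `[`, 1),
    states = tapply(t2$state, r2, function(s) paste(s, collapse = ",")),
    row.names = NULL, stringsAsFactors = FALSE)
  # length filter before the ambiguity check
  regions <- regions[(regions$end - regions$start) >= min_length, , drop = FALSE]
  regions <- sort_intervals(regions)
  if (nrow(regions) > 1) {
    m <- nrow(regions)
    touch <- regions$chrom[-1] == regions$chrom[-m] &
      regions$start[-1] == regions$end[-m] &
      regions$group[-1] != regions$group[-m]
    drop <- rep(FALSE, m)
    drop[which(touch)] <- TRUE
    drop[which(touch) + 1] <- TRUE
    regions <- regions[!drop, , drop = FALSE]
  }
  rownames(regions) <- NULL
  regions
}
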