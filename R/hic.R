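# State-matched enhancer-promoter-gene association through Hi-C significant
# interactions or genomic distance, and the exact binomial contact
# enrichment test.

#' Filter Hi-C significant interactions
#'
#' \code{mode = "all"} returns the caller-significant set unchanged;
#' \code{mode = "top"} keeps interactions with FDR <= \code{fdr_max} and
#' lnP <= \code{lnp_max} (defaults FDR = 0 and ln p-value <= -100).
#'
#' @param interactions Interaction data.frame (see \code{\link{read_bedpe}}).
#' @param mode "all" or "top".
#' @param fdr_max Maximum FDR for mode "top" (default 0).
#' @param lnp_max Maximum natural-log p-value for mode "top" (default -100).
#' @return Filtered interaction data.frame.
#' @export
filter_interactions <- function(interactions, mode = c("all", "top"),
                                fdr_max = 0, lnp_max = -100) {
  mode <- match.arg(mode)
  if (mode == "all") return(interactions)
  interactions[interactions$FDR <= fdr_max & interactions$lnP <= lnp_max, ,
               drop = FALSE]
}

# Internal: split regions df by class group.
split_by_group <- function(regions) split(regions, regions$group)

# Internal: anchor interval tables of an interaction set.
anchor_df <- function(ix, side) {
  data.frame(chrom = ix[[paste0("chrom", side)]],
             start = ix[[paste0("start", side)]],
             end = ix[[paste0("end", side)]],
             stringsAsFactors = FALSE)
}

#' Link enhancers to genes through Hi-C interactions
#'
#' For every interaction, emits a row (enhancer, promoter, gene) for each
#' enhancer overlapping one anchor by >= 1 bp and each promoter of the
#' matching chromatin category (active-active or poised-poised) overlapping
#' the other anchor, expanded over the genes assigned to that promoter.
#' Both anchor orderings are tried; rows are deduplicated on
#' (enhancer, promoter, gene).
#'
#' @param enhancers Enhancer regions (id, chrom, start, end, group, class).
#' @param promoters Promoter regions.
#' @param gene_map Promoter-gene map (promoter_id, gene_id).
#' @param interactions Filtered interaction data.frame.
#' @return Association table: enhancer_id, promoter_id, gene_id, class_pair,
#'   provenance = "hic".
#' @export
link_by_interactions <- function(enhancers, promoters, gene_map, interactions) {
  pairs_for <- function(e_side, p_side) {
    he <- overlap_hits(enhancers, anchor_df(interactions, e_side))
    hp <- overlap_hits(promoters, anchor_df(interactions, p_side))
    if (nrow(he) == 0 || nrow(hp) == 0)
      return(data.frame(e = integer(0), p = integer(0)))
    merged <- merge(data.frame(ix = he$subject, e = he$query),
                    data.frame(ix = hp$subject, p = hp$query), by = "ix")
    merged[, c("e", "p"), drop = FALSE]
  }
  empty <- data.frame(enhancer_id = character(0), promoter_id = character(0),
                      gene_id = character(0), class_pair = character(0),
                      provenance = character(0), stringsAsFactors = FALSE)
  ep <- rbind(pairs_for(1, 2), pairs_for(2, 1))
  ep <- ep[enhancers$group[ep$e] == promoters$group[ep$p], , drop = FALSE]
  ep <- unique(ep)
  if (nrow(ep) == 0) return(empty)
  out <- data.frame(enhancer_id = enhancers$id[ep$e],
                    promoter_id = promoters$id[ep$p],
                    class_pair = paste0(enhancers$class[ep$e], "-",
                                        promoters$class[ep$p]),
                    stringsAsFactors = FALSE)
  out <- merge(out, gene_map, by = "promoter_id")
  if (nrow(out) == 0) return(empty)
  out <- unique(out[, c("enhancer_id", "promoter_id", "gene_id", "class_pair")])
  out$provenance <- "hic"
  out <- out[order(out$enhancer_id, out$promoter_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link enhancers to genes by genomic distance
#'
#' Emits (enhancer, promoter, gene) rows for same-category pairs on the same
#' chromosome whose distance (0 for overlapping) is strictly less than
#' \code{max_gap}.
#'
#' @inheritParams link_by_interactions
#' @param max_gap Maximum distance in bp, exclusive (default 1e6, the 1-Mb
#'   model).
#' @return Association table with provenance = "distance".
#' @export
link_by_distance <- function(enhancers, promoters, gene_map, max_gap = 1e6) {
  rows <- list()
  for (ch in intersect(unique(enhancers$chrom), unique(promoters$chrom))) {
    e <- which(enhancers$chrom == ch)
    p <- which(promoters$chrom == ch)
    if (!length(e) || !length(p)) next
    # gap[i, j] = distance between enhancer e[i] and promoter p[j]
    d1 <- outer(enhancers$start[e], promoters$end[p], `-`)
    d2 <- outer(promoters$start[p], enhancers$end[e], `-`)
    gap <- pmax(d1, t(d2), 0)
    hit <- which(gap < max_gap &
                 outer(enhancers$group[e], promoters$group[p], `==`),
                 arr.ind = TRUE)
    if (nrow(hit) == 0) next
    rows[[ch]] <- data.frame(
      enhancer_id = enhancers$id[e[hit[, 1]]],
      promoter_id = promoters$id[p[hit[, 2]]],
      class_pair = paste0(enhancers$class[e[hit[, 1]]], "-",
                          promoters$class[p[hit[, 2]]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(enhancer_id = character(0), promoter_id = character(0),
                      gene_id = character(0), class_pair = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- merge(out, gene_map, by = "promoter_id")
  out <- unique(out[, c("enhancer_id", "promoter_id", "gene_id", "class_pair")])
  out$provenance <- if (nrow(out)) "distance" else character(0)
  out <- out[order(out$enhancer_id, out$promoter_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count enhancer-promoter contact triples
#'
#' Over all (interaction, enhancer-anchor, promoter-anchor) triples in which
#' one of the supplied enhancers overlaps one anchor and any promoter
#' overlaps the other (deduplicated per interaction-enhancer-promoter),
#' counts n = all such triples and k = those whose promoter class equals
#' \code{target_class}.
#'
#' @param enhancers Enhancer regions of the class under test (e.g. all PEs).
#' @param promoters All promoter regions (APs and BPs).
#' @param interactions Interaction data.frame.
#' @param target_class Promoter class counted as success ("BP" or "AP").
#' @return List with integers k and n (n = 0 when no triples exist).
#' @export
count_enhancer_promoter_contacts <- function(enhancers, promoters,
                                             interactions, target_class) {
  triples_for <- function(e_side, p_side) {
    he <- overlap_hits(enhancers, anchor_df(interactions, e_side))
    hp <- overlap_hits(promoters, anchor_df(interactions, p_side))
    if (nrow(he) == 0 || nrow(hp) == 0)
      return(data.frame(ix = integer(0), e = integer(0), p = integer(0)))
    merge(data.frame(ix = he$subject, e = he$query),
          data.frame(ix = hp$subject, p = hp$query), by = "ix")
  }
  tr <- unique(rbind(triples_for(1, 2), triples_for(2, 1)))
  n <- nrow(tr)
  k <- sum(promoters$class[tr$p] == target_class)
  list(k = as.integer(k), n = as.integer(n))
}

#' Expected contact probability under the pooled null
#'
#' Marginal frequency of the target promoter class among all
#' promoter-overlapping anchor instances across all enhancer-anchored
#' interactions, pooling both enhancer classes. This is the default null
#' probability p0 for \code{\link{binomial_enrichment}} and can be replaced
#' with any externally supplied value.
#'
#' @param enhancers All enhancer regions (AEs and PEs pooled).
#' @param promoters All promoter regions.
#' @param interactions Interaction data.frame.
#' @param target_class Promoter class of interest.
#' @return Scalar probability, or NA when no contacts exist.
#' @export
expected_contact_prob <- function(enhancers, promoters, interactions,
                                  target_class) {
  cc <- count_enhancer_promoter_contacts(enhancers, promoters, interactions,
                                         target_class)
  if (cc$n == 0) return(NA_real_)
  cc$k / cc$n
}

#' One-sided exact binomial enrichment test
#'
#' Tests whether k successes in n trials exceed what a success probability
#' p0 would produce: p = P(X >= k) for X ~ Binomial(n, p0) (one-sided,
#' greater).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability (0 < p0 < 1).
#' @return Object of class \code{enrichment_test}: list with k, n, p0,
#'   observed_prob = k/n and p_value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (n < 1 || k < 0 || k > n) stop("binomial_enrichment: need 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("binomial_enrichment: need 0 < p0 < 1")
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  structure(list(k = as.integer(k), n = as.integer(n), p0 = p0,
                 observed_prob = k / n, p_value = p),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf(
    "Exact binomial enrichment: k = %d, n = %d\n  observed probability %.3f vs expected %.3f, one-sided p = %.3g\n",
    x$k, x$n, x$observed_prob, x$p0, x$p_value))
  invisible(x)
}

#' Write an association table as TSV
#'
#' @param assoc Association table.
#' @param regions Regions data.frame used to attach coordinates.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_associations <- function(assoc, regions, path) {
  coord <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  names(coord) <- regions$id
  out <- data.frame(enhancer_id = assoc$enhancer_id,
                    enh_coords = unname(coord[assoc$enhancer_id]),
                    promoter_id = assoc$promoter_id,
                    prom_coords = unname(coord[assoc$promoter_id]),
                    gene_id = assoc$gene_id,
                    class_pair = assoc$class_pair,
                    provenance = assoc$provenance,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
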