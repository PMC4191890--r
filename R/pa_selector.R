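# Selection of unambiguous polyadenylation-site anchors: read-count cutoff,
# same-strand single-linkage clustering, dominance-ratio resolution, top-N
# ranking.

#' Parameters for pA-site anchor selection
#'
#' Defaults follow the published procedure: a hard cutoff of 200 raw
#' reads, clustering of sites within 200 bp of each other, a 0.4
#' second-to-first read-ratio threshold, and the top 500 sites.
#'
#' @param min_reads Hard raw-read cutoff.
#' @param cluster_dist Single-linkage clustering distance (nt).
#' @param dominance_ratio Ratio threshold (second-highest / highest reads)
#'   below which a cluster has a clear dominant site; in (0, 1).
#' @param top_n Number of anchors to return.
#' @return An object of class `pa_selector_params`.
#' @export
pa_selector_params <- function(min_reads = 200, cluster_dist = 200L,
                               dominance_ratio = 0.4, top_n = 500L) {
  if (!is_number(min_reads) || min_reads <= 0) {
    stop("'min_reads' must be positive", call. = FALSE)
  }
  if (!is_count(cluster_dist) || !is_count(top_n)) {
    stop("'cluster_dist' and 'top_n' must be positive integers",
         call. = FALSE)
  }
  if (!is_number(dominance_ratio) || dominance_ratio <= 0 ||
      dominance_ratio >= 1) {
    stop("'dominance_ratio' must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(min_reads = min_reads,
                 cluster_dist = as.integer(cluster_dist),
                 dominance_ratio = dominance_ratio,
                 top_n = as.integer(top_n)),
            class = "pa_selector_params")
}

#' Select the top pA-site anchors
#'
#' Applies, in order: (1) the hard read cutoff; (2) same-strand
#' single-linkage clustering at `cluster_dist` (sites on opposite strands
#' never cluster); (3) within each multi-site cluster the ratio of the
#' second-highest to the highest read count decides the outcome — below
#' `dominance_ratio` the dominant site is kept and the rest dropped, at or
#' above it the whole cluster is discarded as ambiguous (no unambiguous
#' major 3' end); (4) the survivors are ranked by raw reads, descending,
#' and the top `top_n` returned. Ties everywhere break by
#' (chrom, pos, strand).
#'
#' `ambiguous_action = "keep_dominant"` selects the alternative reading in
#' which ambiguous clusters retain their dominant site instead of being
#' dropped.
#'
#' @param records Data frame with columns `chrom`, `pos`, `strand`,
#'   `raw_reads` (non-negative integers).
#' @param params A [pa_selector_params()].
#' @param ambiguous_action What to do with clusters whose ratio is at or
#'   above `dominance_ratio`: `"drop_cluster"` (default) or
#'   `"keep_dominant"`.
#' @return The selected anchor rows, ranked by `raw_reads` descending.
#' @examples
#' recs <- data.frame(chrom = "chrI", pos = c(100, 150), strand = "+",
#'                    raw_reads = c(1000, 300))
#' select_top_pa(recs)  # clear dominant: the 1000-read site is kept
#' @export
select_top_pa <- function(records, params = pa_selector_params(),
                          ambiguous_action = c("drop_cluster",
                                               "keep_dominant")) {
  ambiguous_action <- match.arg(ambiguous_action)
  stopifnot(inherits(params, "pa_selector_params"))
  need <- c("chrom", "pos", "strand", "raw_reads")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) && any(records$raw_reads < 0)) {
    stop("raw_reads must be non-negative", call. = FALSE)
  }
  check_strand(records$strand)

  # (1) hard cutoff
  rec <- records[records$raw_reads >= params$min_reads, , drop = FALSE]
  if (nrow(rec) == 0L) {
    rec <- rec[order(rec$raw_reads), , drop = FALSE]
    rownames(rec) <- NULL
    return(rec)
  }

  # (2) single-linkage clusters per chrom + strand
  rec <- rec[order(rec$chrom, rec$strand, rec$pos), , drop = FALSE]
  grp <- paste(rec$chrom, rec$strand)
  cluster <- integer(nrow(rec))
  cl <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cl <- cl + 1L
    cluster[idx[1]] <- cl
    if (length(idx) > 1L) {
      for (k in 2:length(idx)) {
        if (rec$pos[idx[k]] - rec$pos[idx[k - 1L]] > params$cluster_dist) {
          cl <- cl + 1L
        }
        cluster[idx[k]] <- cl
      }
    }
  }

  # (3) dominance resolution
  keep <- logical(nrow(rec))
  for (c_id in unique(cluster)) {
    idx <- which(cluster == c_id)
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
      next
    }
    o <- idx[order(-rec$raw_reads[idx], rec$chrom[idx], rec$pos[idx],
                   rec$strand[idx])]
    ratio <- rec$raw_reads[o[2]] / rec$raw_reads[o[1]]
    if (ratio < params$dominance_ratio ||
        ambiguous_action == "keep_dominant") {
      keep[o[1]] <- TRUE
    }
  }
  rec <- rec[keep, , drop = FALSE]

  # (4) rank and truncate
  rec <- rec[order(-rec$raw_reads, rec$chrom, rec$pos, rec$strand), ,
             drop = FALSE]
  rec <- utils::head(rec, params$top_n)
  rownames(rec) <- NULL
  rec
}
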