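# Anchor-centered metagene matrices (10-bp bins, transcription oriented) and
# per-terminator percent-readthrough rankings.

#' Anchor-centered occupancy matrix
#'
#' Extracts, for every anchor, the oriented window
#' `[pos - flank, pos + flank]` (minus-strand windows reversed so
#' transcription runs left to right) and averages it in `bin`-nt bins. A
#' trailing partial bin is averaged over its actual base count. Anchors
#' whose window leaves the chromosome are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param track A `coverage_track`.
#' @param anchors Data frame with columns `chrom`, `pos`, `strand` and
#'   optionally `id`.
#' @param flank Flank (nt) on each side of the anchor.
#' @param bin Bin width (nt).
#' @return An object of class `metagene_matrix`: list with `values`
#'   (anchors x bins matrix), `anchors`, `flank`, `bin`, `bin_offsets`
#'   (transcription offset of each bin start).
#' @export
anchor_matrix <- function(track, anchors, flank = 1000L, bin = 10L) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.data.frame(anchors) || nrow(anchors) == 0L) {
    stop("anchor list is empty", call. = FALSE)
  }
  check_strand(anchors$strand)
  if (is.null(anchors$id)) {
    anchors$id <- paste0("anchor_", seq_len(nrow(anchors)))
  }
  width <- 2L * flank + 1L
  nbins <- ceiling(width / bin)
  groups <- factor(rep(seq_len(nbins), each = bin)[seq_len(width)],
                   levels = seq_len(nbins))
  lens <- track_lengths(track)
  rows <- list()
  keep_ids <- character(0)
  excluded <- character(0)
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]
    pos <- anchors$pos[i]
    L <- lens[[chrom]]
    if (is.na(L) || pos - flank < 0 || pos + flank > L - 1) {
      excluded <- c(excluded, anchors$id[i])
      next
    }
    v <- track$values[[chrom]][[anchors$strand[i]]]
    win <- v[(pos - flank):(pos + flank) + 1L]
    if (anchors$strand[i] == "-") win <- rev(win)
    rows[[length(rows) + 1L]] <-
      as.numeric(tapply(win, groups, mean))
    keep_ids <- c(keep_ids, anchors$id[i])
  }
  if (!length(rows)) stop("all anchor windows are out of bounds",
                          call. = FALSE)
  values <- do.call(rbind, rows)
  rownames(values) <- keep_ids
  out <- structure(
    list(values = values,
         anchors = anchors[anchors$id %in% keep_ids, , drop = FALSE],
         flank = as.integer(flank), bin = as.integer(bin),
         bin_offsets = -flank + (seq_len(nbins) - 1L) * bin),
    class = "metagene_matrix")
  attr(out, "excluded") <- excluded
  out
}

#' Mean metagene profile
#'
#' Unweighted column means across anchors, with per-bin standard errors.
#'
#' @param matrix A [anchor_matrix()] result.
#' @return Data frame with `offset` (transcription offset of the bin
#'   start), `mean`, `se`.
#' @export
mean_profile <- function(matrix) {
  stopifnot(inherits(matrix, "metagene_matrix"))
  v <- matrix$values
  n <- nrow(v)
  data.frame(offset = matrix$bin_offsets,
             mean = colMeans(v),
             se = if (n > 1) apply(v, 2, stats::sd) / sqrt(n) else
               rep(NA_real_, ncol(v)))
}

#' @export
plot.metagene_matrix <- function(x, ...) {
  pr <- mean_profile(x)
  graphics::plot(pr$offset, pr$mean, type = "l",
                 xlab = "offset from anchor (nt)",
                 ylab = "mean occupancy", ...)
  graphics::abline(v = 0, lty = 2, col = "grey")
  invisible(pr)
}

#' Per-terminator percent readthrough, ranked
#'
#' For every terminator, 100 x (treated minus control readthrough
#' fraction) computed with [window_sums()] at the refined termination
#' point, sorted descending, with each site's rank expressed as a fraction
#' of the total. Sites too close to a chromosome end (or with an empty
#' window in either sample) are excluded and reported in the `"excluded"`
#' attribute.
#'
#' @param terminators Data frame with columns `chrom`, `pos`, `strand` and
#'   optionally `id`.
#' @param control,treated `coverage_track`s.
#' @param window Flanking window (nt).
#' @return Data frame (`id`, `chrom`, `pos`, `strand`,
#'   `percent_readthrough`, `rank`, `rank_fraction`) sorted by
#'   `percent_readthrough`, descending.
#' @export
percent_readthrough_ranking <- function(terminators, control, treated,
                                        window = 500L) {
  check_tracks_compatible(control, treated)
  if (!is.data.frame(terminators) || nrow(terminators) == 0L) {
    stop("terminator list is empty", call. = FALSE)
  }
  if (is.null(terminators$id)) {
    terminators$id <- paste0("site_", seq_len(nrow(terminators)))
  }
  pct <- rep(NA_real_, nrow(terminators))
  for (i in seq_len(nrow(terminators))) {
    wc <- window_sums(control, terminators$chrom[i], terminators$pos[i],
                      terminators$strand[i], window)
    wt <- window_sums(treated, terminators$chrom[i], terminators$pos[i],
                      terminators$strand[i], window)
    fc <- readthrough_fraction(wc[["up"]], wc[["down"]])
    ft <- readthrough_fraction(wt[["up"]], wt[["down"]])
    pct[i] <- 100 * readthrough_index(ft, fc)
  }
  ok <- !is.na(pct)
  res <- data.frame(id = terminators$id[ok],
                    chrom = terminators$chrom[ok],
                    pos = terminators$pos[ok],
                    strand = terminators$strand[ok],
                    percent_readthrough = pct[ok],
                    stringsAsFactors = FALSE)
  res <- res[order(-res$percent_readthrough, res$chrom, res$pos,
                   res$strand), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$rank_fraction <- res$rank / nrow(res)
  rownames(res) <- NULL
  attr(res, "excluded") <- terminators$id[!ok]
  res
}
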