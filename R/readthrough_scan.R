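# Genome-wide Readthrough Index: occupancy fractions in 500-bp flanking
# windows, treated minus control, with the occupancy and index filters.

#' Scan thresholds for the Readthrough Index
#'
#' Defaults follow the published procedure: a Readthrough Index above 10%,
#' at least 1000 summed reads in either sample over the combined 1-kb
#' span, and more reads in the treated than in the control sample.
#'
#' @param window Flanking window width (nt).
#' @param min_index Minimum Readthrough Index (treated minus control
#'   fraction) for a point to pass.
#' @param min_reads Minimum summed track value (up + down) required in at
#'   least one sample.
#' @param require_treated_gt_control Require total treated signal over the
#'   span to exceed the control total.
#' @param min_separation Minimum distance (nt) between selected
#'   non-overlapping candidates (see [select_candidates()]).
#' @return An object of class `scan_thresholds`.
#' @export
scan_thresholds <- function(window = 500L, min_index = 0.10,
                            min_reads = 1000, require_treated_gt_control = TRUE,
                            min_separation = 1000L) {
  if (!is_count(window)) stop("'window' must be a positive integer",
                              call. = FALSE)
  if (!is_number(min_index) || min_index < 0 || min_index > 1) {
    stop("'min_index' must be in [0, 1]", call. = FALSE)
  }
  structure(list(window = as.integer(window), min_index = min_index,
                 min_reads = min_reads,
                 require_treated_gt_control = isTRUE(require_treated_gt_control),
                 min_separation = as.integer(min_separation)),
            class = "scan_thresholds")
}

#' Occupancy sums in the flanking windows of a position
#'
#' On the plus strand the upstream window is `[pos - window, pos)` and the
#' downstream window `[pos, pos + window)`; minus-strand windows are the
#' mirror image (downstream runs toward decreasing coordinates, the focal
#' position falling in the upstream window). Together the two windows
#' partition the `2 * window` span around `pos`.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param pos 0-based position.
#' @param strand `"+"` or `"-"`.
#' @param window Window width (nt).
#' @return Named numeric `c(up = , down = )`, or `c(up = NA, down = NA)`
#'   when the position is closer than `window` to a chromosome end.
#' @export
window_sums <- function(track, chrom, pos, strand, window = 500L) {
  v <- track_values(track, chrom, strand)
  L <- length(v)
  if (pos - window < 0 || pos + window > L) {
    return(c(up = NA_real_, down = NA_real_))
  }
  left <- sum(v[(pos - window + 1L):pos])        # [pos - w, pos)
  right <- sum(v[(pos + 1L):(pos + window)])     # [pos, pos + w)
  if (strand == "+") c(up = left, down = right) else c(up = right, down = left)
}

#' Readthrough fraction
#'
#' `down / (up + down)`; `NA` (missing) when both windows are empty.
#'
#' @param up,down Non-negative window sums.
#' @return Fraction in `[0, 1]` or `NA`.
#' @export
readthrough_fraction <- function(up, down) {
  if (any(c(up, down) < 0, na.rm = TRUE)) {
    stop("window sums must be non-negative", call. = FALSE)
  }
  tot <- up + down
  ifelse(is.na(tot) | tot == 0, NA_real_, down / tot)
}

#' Readthrough Index
#'
#' Treated-minus-control readthrough fraction; missing when either
#' fraction is missing. Always lies in `[-1, 1]`.
#'
#' @param frac_treated,frac_control Readthrough fractions.
#' @return The index, or `NA`.
#' @export
readthrough_index <- function(frac_treated, frac_control) {
  ifelse(is.na(frac_treated) | is.na(frac_control), NA_real_,
         frac_treated - frac_control)
}

#' Genome-wide Readthrough Index scan
#'
#' Computes, for every position on both strands, the readthrough fraction
#' in control and treated tracks and their difference (the Readthrough
#' Index), then returns every position passing all filters: index above
#' `min_index`, combined window sum of at least `min_reads` in either
#' sample, and (optionally) more treated than control signal over the
#' span. The result is sorted by index, descending; ties break by
#' (chrom, pos, strand).
#'
#' @param control,treated `coverage_track`s over the same genome.
#' @param thresholds A [scan_thresholds()].
#' @param stride Evaluate every `stride`-th position (default 1 = every
#'   point in the genome).
#' @return Data frame with columns `chrom`, `pos`, `strand`,
#'   `up_control`, `down_control`, `up_treated`, `down_treated`,
#'   `frac_control`, `frac_treated`, `index`.
#' @export
global_scan <- function(control, treated, thresholds = scan_thresholds(),
                        stride = 1L) {
  check_tracks_compatible(control, treated)
  stopifnot(inherits(thresholds, "scan_thresholds"))
  w <- thresholds$window
  out <- list()
  for (chrom in track_chromosomes(control)) {
    L <- length(control$values[[chrom]][["+"]])
    if (L < 2L * w) next
    pos <- seq(w, L - w, by = stride)
    for (s in c("+", "-")) {
      vc <- control$values[[chrom]][[s]]
      vt <- treated$values[[chrom]][[s]]
      Cc <- c(0, cumsum(vc))
      Ct <- c(0, cumsum(vt))
      left_c <- Cc[pos + 1L] - Cc[pos - w + 1L]
      right_c <- Cc[pos + w + 1L] - Cc[pos + 1L]
      left_t <- Ct[pos + 1L] - Ct[pos - w + 1L]
      right_t <- Ct[pos + w + 1L] - Ct[pos + 1L]
      if (s == "+") {
        up_c <- left_c; down_c <- right_c; up_t <- left_t; down_t <- right_t
      } else {
        up_c <- right_c; down_c <- left_c; up_t <- right_t; down_t <- left_t
      }
      tot_c <- up_c + down_c
      tot_t <- up_t + down_t
      frac_c <- ifelse(tot_c == 0, NA_real_, down_c / tot_c)
      frac_t <- ifelse(tot_t == 0, NA_real_, down_t / tot_t)
      index <- frac_t - frac_c
      pass <- !is.na(index) & index > thresholds$min_index &
        (tot_c >= thresholds$min_reads | tot_t >= thresholds$min_reads)
      if (thresholds$require_treated_gt_control) {
        pass <- pass & tot_t > tot_c
      }
      if (any(pass)) {
        out[[paste(chrom, s)]] <- data.frame(
          chrom = chrom, pos = pos[pass], strand = s,
          up_control = up_c[pass], down_control = down_c[pass],
          up_treated = up_t[pass], down_treated = down_t[pass],
          frac_control = frac_c[pass], frac_treated = frac_t[pass],
          index = index[pass], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), up_control = numeric(0),
                      down_control = numeric(0), up_treated = numeric(0),
                      down_treated = numeric(0), frac_control = numeric(0),
                      frac_treated = numeric(0), index = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(-res$index, res$chrom, res$pos, res$strand), , drop = FALSE]
}

#' Greedy selection of non-overlapping candidate termination regions
#'
#' Walks the scan results in decreasing index order (ties broken by
#' chrom, pos, strand) and keeps a point unless an already-kept point on
#' the same chromosome and strand lies within `min_separation` nt.
#' Opposite-strand points never exclude each other.
#'
#' @param points Data frame from [global_scan()].
#' @param min_separation Minimum distance (nt) between kept same-strand
#'   points.
#' @return The kept rows, in decreasing index order.
#' @export
select_candidates <- function(points, min_separation = 1000L) {
  if (nrow(points) == 0L) return(points)
  o <- order(-points$index, points$chrom, points$pos, points$strand)
  points <- points[o, , drop = FALSE]
  kept <- logical(nrow(points))
  kept_pos <- list()
  for (i in seq_len(nrow(points))) {
    key <- paste(points$chrom[i], points$strand[i])
    ps <- kept_pos[[key]]
    if (is.null(ps) || all(abs(ps - points$pos[i]) >= min_separation)) {
      kept[i] <- TRUE
      kept_pos[[key]] <- c(ps, points$pos[i])
    }
  }
  res <- points[kept, , drop = FALSE]
  rownames(res) <- NULL
  res
}
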