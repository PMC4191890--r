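# Refinement of candidate regions to single termination points: the
# control-minus-depleted difference profile is smoothed, fitted with a cubic
# smoothing spline, and the positive-to-negative zero crossing with maximal
# flanking amplitude is taken as the termination point.

#' Control-minus-treated difference profile around a position
#'
#' Per-base `control - treated` values over `center +/- halfwidth`,
#' oriented so transcription runs left to right (minus-strand profiles are
#' reversed). Element `i` corresponds to transcription offset
#' `i - halfwidth - 1` from the center.
#'
#' @param control,treated `coverage_track`s over the same genome.
#' @param chrom Chromosome name.
#' @param center 0-based center position.
#' @param strand `"+"` or `"-"`.
#' @param halfwidth Half-width of the profile (nt); the profile spans
#'   `2 * halfwidth + 1` bases ("2 kb around" with the default 1000).
#' @return An object of class `difference_profile` with fields `chrom`,
#'   `center`, `strand`, `halfwidth`, `values`, `offsets`.
#' @export
difference_profile <- function(control, treated, chrom, center, strand,
                               halfwidth = 1000L) {
  check_tracks_compatible(control, treated)
  check_strand(strand)
  vc <- track_values(control, chrom, strand)
  vt <- track_values(treated, chrom, strand)
  L <- length(vc)
  if (center - halfwidth < 0 || center + halfwidth > L - 1) {
    stop("center ", center, " is closer than halfwidth (", halfwidth,
         ") to an end of ", chrom, call. = FALSE)
  }
  idx <- (center - halfwidth):(center + halfwidth) + 1L
  d <- vc[idx] - vt[idx]
  if (strand == "-") d <- rev(d)
  structure(list(chrom = chrom, center = center, strand = strand,
                 halfwidth = as.integer(halfwidth), values = d,
                 offsets = seq(-halfwidth, halfwidth)),
            class = "difference_profile")
}

# Genomic position of a transcription offset of a profile.
profile_offset_to_pos <- function(profile, offset) {
  if (profile$strand == "+") profile$center + offset else
    profile$center - offset
}

#' Locate the termination point on a difference profile
#'
#' The profile is pre-smoothed with a centered moving average of width
#' `smooth_window`, fitted with a cubic smoothing spline (smoothing chosen
#' by generalized cross-validation), and scanned for zero crossings where
#' the fit passes from positive to negative in the transcription
#' direction. Each crossing is scored by its crossing amplitude: the mean
#' smoothed difference over `amp_flank` nt upstream minus the mean over
#' `amp_flank` nt downstream. The crossing with maximal amplitude, subject
#' to a positive upstream and negative downstream mean, is returned;
#' `NULL` if no crossing qualifies. Sub-nucleotide crossing positions are
#' rounded to the nearest base, ties toward the upstream side.
#'
#' @param profile A [difference_profile()].
#' @param smooth_window Moving-average width (nt).
#' @param amp_flank Flank (nt) used for the crossing amplitude.
#' @param region_halfwidth Half-width (nt) of the reported release region.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; default `NULL` uses generalized
#'   cross-validation.
#' @return A list (`chrom`, `pos`, `strand`, `region_halfwidth`,
#'   `crossing_amplitude`) of class `termination_site`, or `NULL`.
#' @export
locate_termination <- function(profile, smooth_window = 25L, amp_flank = 100L,
                               region_halfwidth = 25L, spar = NULL) {
  stopifnot(inherits(profile, "difference_profile"))
  n <- length(profile$values)
  if (n < smooth_window) {
    stop("profile shorter than the smoothing window", call. = FALSE)
  }
  sm <- as.numeric(stats::filter(profile$values,
                                 rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  valid <- which(!is.na(sm))
  x <- profile$offsets[valid]
  y <- sm[valid]
  if (length(unique(y)) < 4L) return(NULL)  # flat profile, no crossing
  fit <- if (is.null(spar)) {
    stats::smooth.spline(x, y, cv = FALSE)
  } else {
    stats::smooth.spline(x, y, spar = spar)
  }
  pred <- stats::predict(fit, x)$y

  # positive -> negative sign changes (zeros between count as part of the
  # transition)
  nz <- which(pred != 0)
  if (length(nz) < 2L) return(NULL)
  sgn <- sign(pred[nz])
  trans <- which(sgn[-length(sgn)] > 0 & sgn[-1] < 0)
  if (!length(trans)) return(NULL)

  best <- NULL
  for (t in trans) {
    i <- nz[t]; j <- nz[t + 1L]
    # linear interpolation of the crossing between x[i] and x[j]
    x0 <- x[i] + pred[i] * (x[j] - x[i]) / (pred[i] - pred[j])
    k <- as.integer(ceiling(x0 - 0.5))  # ties toward the upstream side
    ki <- match(k, x)
    if (is.na(ki)) next
    up_idx <- valid_range(ki - amp_flank, ki - 1L, length(x))
    down_idx <- valid_range(ki + 1L, ki + amp_flank, length(x))
    if (!length(up_idx) || !length(down_idx)) next
    up_mean <- mean(y[up_idx])
    down_mean <- mean(y[down_idx])
    if (up_mean <= 0 || down_mean >= 0) next
    amp <- up_mean - down_mean
    if (is.null(best) || amp > best$amp) {
      best <- list(k = k, amp = amp)
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(chrom = profile$chrom,
                 pos = profile_offset_to_pos(profile, best$k),
                 strand = profile$strand,
                 region_halfwidth = as.integer(region_halfwidth),
                 crossing_amplitude = best$amp),
            class = "termination_site")
}

valid_range <- function(from, to, n) {
  from <- max(1L, from)
  to <- min(n, to)
  if (from > to) integer(0) else from:to
}

#' Refine all candidate regions to termination points
#'
#' Builds the difference profile around each candidate, locates its
#' termination point, deduplicates same-strand sites within
#' `min_separation` nt (keeping the largest crossing amplitude) and sorts
#' by crossing amplitude. Candidates whose profile is out of bounds or has
#' no qualifying crossing are dropped; the reasons are returned in the
#' `"dropped"` attribute.
#'
#' @param candidates Data frame with columns `chrom`, `pos`, `strand`
#'   (e.g. from [select_candidates()]).
#' @param control,treated `coverage_track`s.
#' @param halfwidth,smooth_window,amp_flank,region_halfwidth,spar See
#'   [difference_profile()] and [locate_termination()].
#' @param min_separation Deduplication distance (nt) between same-strand
#'   sites.
#' @return Data frame (`chrom`, `pos`, `strand`, `crossing_amplitude`,
#'   `source_pos`) sorted by decreasing amplitude, with attribute
#'   `"dropped"`.
#' @export
refine_all <- function(candidates, control, treated, halfwidth = 1000L,
                       smooth_window = 25L, amp_flank = 100L,
                       region_halfwidth = 25L, spar = NULL,
                       min_separation = 1000L) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), crossing_amplitude = numeric(0),
                      source_pos = integer(0))
  if (nrow(candidates) == 0L) {
    attr(empty, "dropped") <- data.frame(chrom = character(0),
                                         pos = integer(0),
                                         strand = character(0),
                                         reason = character(0))
    return(empty)
  }
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(candidates))) {
    chrom <- candidates$chrom[i]
    pos <- candidates$pos[i]
    strand <- candidates$strand[i]
    prof <- tryCatch(
      difference_profile(control, treated, chrom, pos, strand, halfwidth),
      error = function(e) NULL)
    if (is.null(prof)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(chrom = chrom, pos = pos, strand = strand,
                   reason = "profile out of bounds")
      next
    }
    site <- locate_termination(prof, smooth_window = smooth_window,
                               amp_flank = amp_flank,
                               region_halfwidth = region_halfwidth,
                               spar = spar)
    if (is.null(site)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(chrom = chrom, pos = pos, strand = strand,
                   reason = "no qualifying crossing")
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = site$chrom, pos = site$pos, strand = site$strand,
                 crossing_amplitude = site$crossing_amplitude,
                 source_pos = pos, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(res)) {
    res <- res[order(-res$crossing_amplitude, res$chrom, res$pos,
                     res$strand), , drop = FALSE]
    keep <- logical(nrow(res))
    kept_pos <- list()
    for (i in seq_len(nrow(res))) {
      key <- paste(res$chrom[i], res$strand[i])
      ps <- kept_pos[[key]]
      if (is.null(ps) || all(abs(ps - res$pos[i]) >= min_separation)) {
        keep[i] <- TRUE
        kept_pos[[key]] <- c(ps, res$pos[i])
      } else {
        dropped[[length(dropped) + 1L]] <-
          data.frame(chrom = res$chrom[i], pos = res$pos[i],
                     strand = res$strand[i], reason = "duplicate site")
      }
    }
    res <- res[keep, , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               reason = character(0))
  res
}
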