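#' Strand-specific per-base coverage track
#'
#' A `coverage_track` stores, for each chromosome, one dense numeric vector
#' of non-negative occupancy values per strand, together with library
#' metadata (`total_aligned`, `normalization_factor`). Values are one per
#' base; position `p` (0-based) of chromosome `chrom` on strand `s` is
#' `track$values[[chrom]][[s]][p + 1]`.
#'
#' @param values Named list, one element per chromosome; each element is a
#'   list with components `"+"` and `"-"`, numeric vectors of equal length
#'   (the chromosome length) and non-negative values.
#' @param total_aligned Number of aligned reads the track was built from
#'   (`NA` for simulated or derived tracks).
#' @param normalization_factor Multiplier already applied to the raw
#'   per-base read counts (1 for raw counts).
#' @return An object of class `coverage_track`.
#' @examples
#' tr <- coverage_track(list(chrI = list("+" = rep(1, 100), "-" = rep(0, 100))))
#' track_lengths(tr)
#' @export
coverage_track <- function(values, total_aligned = NA_real_,
                           normalization_factor = 1) {
  if (!is.list(values) || is.null(names(values)) || !all(nzchar(names(values)))) {
    stop("'values' must be a named list of chromosomes", call. = FALSE)
  }
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.list(v) || !all(c("+", "-") %in% names(v))) {
      stop("chromosome '", chrom, "' must have both '+' and '-' strands",
           call. = FALSE)
    }
    for (s in c("+", "-")) {
      if (!is.numeric(v[[s]])) {
        stop("values for ", chrom, " strand ", s, " must be numeric",
             call. = FALSE)
      }
      if (any(v[[s]] < 0, na.rm = TRUE) || anyNA(v[[s]])) {
        stop("coverage values must be non-negative and non-missing (", chrom,
             " strand ", s, ")", call. = FALSE)
      }
    }
    if (length(v[["+"]]) != length(v[["-"]])) {
      stop("strand vectors for '", chrom, "' differ in length", call. = FALSE)
    }
  }
  structure(
    list(values = values,
         total_aligned = total_aligned,
         normalization_factor = normalization_factor),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  len <- track_lengths(x)
  cat("coverage_track:", length(len), "chromosome(s),",
      format(sum(len), big.mark = ","), "bases/strand\n")
  cat("  total signal:", format(track_total(x)), "\n")
  if (!is.na(x$total_aligned)) {
    cat("  total_aligned:", x$total_aligned,
        " normalization_factor:", x$normalization_factor, "\n")
  }
  invisible(x)
}

#' @rdname coverage_track
#' @param track A `coverage_track`.
#' @export
track_lengths <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  vapply(track$values, function(v) length(v[["+"]]), numeric(1))
}

#' @rdname coverage_track
#' @export
track_chromosomes <- function(track) names(track$values)

#' @rdname coverage_track
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @export
track_values <- function(track, chrom, strand) {
  stopifnot(inherits(track, "coverage_track"))
  if (!chrom %in% names(track$values)) {
    stop("unknown chromosome '", chrom, "'", call. = FALSE)
  }
  check_strand(strand)
  track$values[[chrom]][[strand]]
}

#' @rdname coverage_track
#' @export
track_total <- function(track) {
  sum(vapply(track$values, function(v) sum(v[["+"]]) + sum(v[["-"]]), numeric(1)))
}

#' An all-zero track over the given chromosomes
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A `coverage_track` of zeros.
#' @export
empty_track <- function(chrom_lengths) {
  validate_chrom_lengths(chrom_lengths)
  vals <- lapply(chrom_lengths, function(L) {
    list("+" = numeric(L), "-" = numeric(L))
  })
  coverage_track(vals)
}

# Error unless two tracks share chromosome names and lengths.
check_tracks_compatible <- function(a, b) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"))
  la <- track_lengths(a)
  lb <- track_lengths(b)
  if (!identical(sort(names(la)), sort(names(lb))) ||
      !identical(la[sort(names(la))], lb[sort(names(lb))])) {
    stop("tracks have mismatched chromosome sets or lengths", call. = FALSE)
  }
  invisible(TRUE)
}
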