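# Read preprocessing and coverage-track I/O: adapter trimming, exact-sequence
# condensing, exclusion-interval filtering, per-1e7 normalization, and
# bedGraph / fixed-step wiggle round-trips.

#' Trim a 3' adapter from read sequences
#'
#' Removes the longest suffix of each read that matches a prefix of the
#' adapter with at least `min_overlap` bases and a mismatch rate of at
#' most `max_mismatch_rate`. Reads without a qualifying match are returned
#' unchanged (no-match is a valid outcome).
#'
#' @param reads Character vector of read sequences.
#' @param adapter Non-empty adapter sequence.
#' @param min_overlap Minimum suffix/prefix overlap (nt).
#' @param max_mismatch_rate Maximum allowed fraction of mismatching bases
#'   in the overlap.
#' @return Character vector of trimmed reads.
#' @examples
#' trim_adapter(c("ACGTACGTAGATCG"), "AGATCGGAAGAGC")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L,
                         max_mismatch_rate = 0.1) {
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter)) {
    stop("'adapter' must be a non-empty sequence", call. = FALSE)
  }
  avec <- strsplit(adapter, "")[[1]]
  vapply(reads, function(r) {
    n <- nchar(r)
    max_l <- min(n, length(avec))
    if (max_l < min_overlap) return(r)
    rv <- strsplit(r, "")[[1]]
    for (L in max_l:min_overlap) {
      mm <- sum(rv[(n - L + 1L):n] != avec[seq_len(L)])
      if (mm <= floor(max_mismatch_rate * L)) {
        return(substr(r, 1L, n - L))
      }
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

#' Condense reads to unique sequences
#'
#' Keeps each distinct sequence exactly once (no more than one of the same
#' exact sequence), preserving first-seen order; removes PCR duplicates.
#' Idempotent.
#'
#' @param reads Character vector of read sequences.
#' @return Character vector of unique sequences in first-seen order.
#' @export
condense_reads <- function(reads) {
  reads[!duplicated(reads)]
}

#' Remove reads overlapping exclusion intervals
#'
#' Drops any aligned read overlapping an exclusion interval (e.g. tRNA
#' genes) by >= 1 bp. By default overlap is required on the same strand; a
#' strand-agnostic mode is available.
#'
#' @param reads Data frame of aligned reads (`chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param exclusion Data frame with the same columns, or a
#'   [GenomicRanges::GRanges].
#' @param same_strand If `TRUE` (default) a read is removed only by
#'   exclusion intervals on its own strand.
#' @return The surviving reads, same columns and order.
#' @export
filter_excluded <- function(reads, exclusion, same_strand = TRUE) {
  reads_gr <- aligned_to_granges(reads)
  excl_gr <- if (inherits(exclusion, "GRanges")) exclusion else
    aligned_to_granges(exclusion, what = "exclusion intervals")
  hit <- IRanges::overlapsAny(reads_gr, excl_gr,
                              ignore.strand = !same_strand)
  reads[!hit, , drop = FALSE]
}

# Validate and convert a 0-based half-open interval data frame to GRanges.
aligned_to_granges <- function(x, what = "aligned reads") {
  need <- c("chrom", "start", "end", "strand")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(what, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) > 0) {
    check_strand(x$strand)
    bad <- x$start < 0 | x$start >= x$end
    if (any(bad)) {
      stop("malformed ", what, ": need 0 <= start < end (rows ",
           paste(utils::head(which(bad), 5), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x$strand)
}

#' Build a normalized coverage track from aligned reads
#'
#' The value at base `b` on strand `s` is the number of kept reads
#' covering `b` on `s`, multiplied by `norm_per / total_aligned`
#' (the per-10^7-aligned-reads normalization). A 5'-end mode counts only
#' each read's 5' base.
#'
#' @inheritParams filter_excluded
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param total_aligned Total number of aligned reads in the library
#'   (> 0); the denominator of the normalization factor.
#' @param norm_per Normalization scale (default `1e7`).
#' @param mode `"coverage"` (full-read) or `"fiveprime"`.
#' @return A `coverage_track` with `normalization_factor =
#'   norm_per / total_aligned`.
#' @examples
#' reads <- data.frame(chrom = "chrI", start = 10, end = 40, strand = "+")
#' tr <- build_track(reads, c(chrI = 100), total_aligned = 1e7)
#' track_values(tr, "chrI", "+")[11]  # 1.0
#' @export
build_track <- function(reads, chrom_lengths, total_aligned,
                        norm_per = 1e7, mode = c("coverage", "fiveprime")) {
  mode <- match.arg(mode)
  validate_chrom_lengths(chrom_lengths)
  if (!is_number(total_aligned) || total_aligned <= 0) {
    stop("'total_aligned' must be > 0", call. = FALSE)
  }
  aligned_to_granges(reads)  # validation only
  if (nrow(reads) > 0 && !all(reads$chrom %in% names(chrom_lengths))) {
    stop("reads on chromosomes absent from chrom_lengths", call. = FALSE)
  }
  factor <- norm_per / total_aligned
  vals <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    out <- list()
    for (s in c("+", "-")) {
      sel <- reads$chrom == chrom & reads$strand == s
      delta <- numeric(L + 1L)
      if (any(sel)) {
        st <- reads$start[sel]
        en <- reads$end[sel]
        if (any(en > L) || any(st >= L)) {
          stop("read extends past chromosome ", chrom, call. = FALSE)
        }
        if (mode == "fiveprime") {
          five <- if (s == "+") st else en - 1L
          st <- five
          en <- five + 1L
        }
        for (i in seq_along(st)) {
          delta[st[i] + 1L] <- delta[st[i] + 1L] + 1
          delta[en[i] + 1L] <- delta[en[i] + 1L] - 1
        }
      }
      out[[s]] <- cumsum(delta[seq_len(L)]) * factor
    }
    out
  })
  names(vals) <- names(chrom_lengths)
  coverage_track(vals, total_aligned = total_aligned,
                 normalization_factor = factor)
}

#' Pipeline read-count bookkeeping
#'
#' Records read counts at the successive preprocessing stages. Counts must
#' be monotonically non-increasing along the pipeline.
#'
#' @param raw_read_count,post_trim_count,condensed_count,aligned_count,post_trna_count
#'   Read counts after each stage.
#' @return An object of class `library_stats`.
#' @export
library_stats <- function(raw_read_count, post_trim_count, condensed_count,
                          aligned_count, post_trna_count) {
  counts <- c(raw_read_count = raw_read_count,
              post_trim_count = post_trim_count,
              condensed_count = condensed_count,
              aligned_count = aligned_count,
              post_trna_count = post_trna_count)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(diff(counts) > 0)) {
    stop("library stage counts must be non-increasing: ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  structure(as.list(counts), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat("library_stats:\n")
  for (n in names(x)) cat(" ", n, "=", x[[n]], "\n")
  invisible(x)
}

# ---- on-disk formats ------------------------------------------------------

#' Write a coverage track as per-strand bedGraph or fixed-step wiggle
#'
#' One file per strand. Values are written with full double precision so
#' that a write/read round-trip is value-exact. Zero runs are omitted
#' (absent positions read back as 0).
#'
#' @param track A `coverage_track`.
#' @param plus_path,minus_path Output paths for the two strands.
#' @param format `"bedGraph"` (0-based half-open intervals) or `"wig"`
#'   (1-based fixedStep, step 1).
#' @return Invisibly, `c(plus_path, minus_path)`.
#' @export
write_track <- function(track, plus_path, minus_path,
                        format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  stopifnot(inherits(track, "coverage_track"))
  paths <- c("+" = plus_path, "-" = minus_path)
  for (s in c("+", "-")) {
    con <- file(paths[[s]], "w")
    for (chrom in track_chromosomes(track)) {
      v <- track$values[[chrom]][[s]]
      r <- rle(v)
      ends <- cumsum(r$lengths)        # 0-based exclusive ends
      starts <- ends - r$lengths       # 0-based starts
      keep <- r$values != 0
      if (!any(keep)) next
      if (format == "bedGraph") {
        writeLines(paste(chrom, fmt_int(starts[keep]), fmt_int(ends[keep]),
                         fmt_value(r$values[keep]), sep = "\t"), con)
      } else {
        for (k in which(keep)) {
          writeLines(sprintf("fixedStep chrom=%s start=%d step=1 span=1",
                             chrom, starts[k] + 1L), con)
          writeLines(rep(fmt_value(r$values[k]), r$lengths[k]), con)
        }
      }
    }
    close(con)
  }
  invisible(c(plus_path, minus_path))
}

#' Read per-strand bedGraph or wiggle files into a coverage track
#'
#' Positions absent from the files are 0. Unknown chromosomes, negative
#' values and overlapping intervals are rejected with the offending
#' interval named.
#'
#' @param plus_path,minus_path Input paths for the two strands.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param format `"bedGraph"` or `"wig"`.
#' @return A `coverage_track`.
#' @export
read_track <- function(plus_path, minus_path, chrom_lengths,
                       format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  validate_chrom_lengths(chrom_lengths)
  vals <- lapply(chrom_lengths, function(L) {
    list("+" = numeric(L), "-" = numeric(L))
  })
  paths <- c("+" = plus_path, "-" = minus_path)
  for (s in c("+", "-")) {
    path <- paths[[s]]
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    if (length(readLines(path, n = 1L)) == 0L) next  # empty = all zero
    gr <- rtracklayer::import(path, format = format)
    if (length(gr) == 0L) next
    chroms <- as.character(GenomicRanges::seqnames(gr))
    bad_chrom <- !chroms %in% names(chrom_lengths)
    if (any(bad_chrom)) {
      stop("interval ", which(bad_chrom)[1], " in ", basename(path),
           ": unknown chromosome '", chroms[which(bad_chrom)[1]], "'",
           call. = FALSE)
    }
    score <- S4Vectors::mcols(gr)$score
    if (any(score < 0)) {
      stop("interval ", which(score < 0)[1], " in ", basename(path),
           ": negative value", call. = FALSE)
    }
    self_hits <- GenomicRanges::countOverlaps(gr, gr)
    if (any(self_hits > 1L)) {
      stop("interval ", which(self_hits > 1L)[1], " in ", basename(path),
           ": overlapping intervals", call. = FALSE)
    }
    st <- GenomicRanges::start(gr)  # 1-based
    en <- GenomicRanges::end(gr)
    over <- en > chrom_lengths[chroms]
    if (any(over)) {
      stop("interval ", which(over)[1], " in ", basename(path),
           ": extends past end of ", chroms[which(over)[1]], call. = FALSE)
    }
    for (i in seq_along(gr)) {
      vals[[chroms[i]]][[s]][st[i]:en[i]] <- score[i]
    }
  }
  coverage_track(vals)
}
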