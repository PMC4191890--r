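# Sequence analysis of termination regions: RNA-sense window extraction,
# degenerate motif scanning (overlaps counted), maximal U-run statistics and
# dinucleotide-shuffle motif enrichment.

#' Extract RNA-sense sequence upstream of termination sites
#'
#' On the plus strand the 0-based window `[pos - length, pos)` is read
#' forward; on the minus strand the window `(pos, pos + length]` is
#' reverse-complemented. DNA is transliterated to RNA (T to U). Windows
#' clipped at a chromosome end are returned shorter and flagged in the
#' `"clipped"` attribute.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param sites Data frame with columns `chrom`, `pos`, `strand` and
#'   optionally `id`.
#' @param length Window length (nt).
#' @return Named character vector of RNA-sense sequences (names = site
#'   ids), with attribute `"clipped"`.
#' @export
extract_upstream <- function(genome, sites, length = 150L) {
  if (!is.data.frame(sites) || nrow(sites) == 0L) {
    stop("site list is empty", call. = FALSE)
  }
  check_strand(sites$strand)
  if (is.null(sites$id)) sites$id <- paste0("site_", seq_len(nrow(sites)))
  glens <- Biostrings::width(genome)
  names(glens) <- names(genome)
  out <- character(nrow(sites))
  clipped <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("site ", sites$id[i], ": unknown chromosome '", chrom, "'",
           call. = FALSE)
    }
    L <- glens[[chrom]]
    pos <- sites$pos[i]
    if (pos < 0 || pos > L - 1) {
      stop("site ", sites$id[i], " lies off the genome", call. = FALSE)
    }
    if (sites$strand[i] == "+") {
      from <- max(0L, pos - length)           # 0-based [from, pos)
      clipped[i] <- from > pos - length
      if (from >= pos) { out[i] <- ""; next }
      s <- as.character(Biostrings::subseq(genome[[chrom]], from + 1L, pos))
    } else {
      to <- min(L - 1L, pos + length)         # 0-based (pos, to]
      clipped[i] <- to < pos + length
      if (to <= pos) { out[i] <- ""; next }
      s <- as.character(Biostrings::subseq(genome[[chrom]], pos + 2L,
                                           to + 1L))
      s <- reverse_complement(s)
    }
    out[i] <- dna_to_rna(s)
  }
  names(out) <- sites$id
  attr(out, "clipped") <- sites$id[clipped]
  out
}

#' Extract the RNA-sense sequence around a termination point
#'
#' Window of `upstream` nt before and `downstream` nt after each site in
#' transcription orientation (the focal base included on the downstream
#' side), for U-run analysis of the release region.
#'
#' @inheritParams extract_upstream
#' @param upstream,downstream Extent (nt) on each side.
#' @return Named character vector of RNA-sense sequences.
#' @export
terminator_window_seq <- function(genome, sites, upstream = 50L,
                                  downstream = 50L) {
  if (!is.data.frame(sites) || nrow(sites) == 0L) {
    stop("site list is empty", call. = FALSE)
  }
  if (is.null(sites$id)) sites$id <- paste0("site_", seq_len(nrow(sites)))
  glens <- Biostrings::width(genome)
  names(glens) <- names(genome)
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    L <- glens[[chrom]]
    pos <- sites$pos[i]
    if (sites$strand[i] == "+") {
      from <- max(0L, pos - upstream)
      to <- min(L - 1L, pos + downstream)
      s <- as.character(Biostrings::subseq(genome[[chrom]], from + 1L,
                                           to + 1L))
    } else {
      from <- max(0L, pos - downstream)
      to <- min(L - 1L, pos + upstream)
      s <- reverse_complement(
        as.character(Biostrings::subseq(genome[[chrom]], from + 1L, to + 1L)))
    }
    out[i] <- dna_to_rna(s)
  }
  names(out) <- sites$id
  out
}

# Validate a degenerate RNA pattern (ACGU with [..] alternatives) and
# return the corresponding regular expression.
pattern_to_regex <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop("pattern must be a non-empty string", call. = FALSE)
  }
  if (!grepl("^([ACGU]|\\[[ACGU]+\\])+$", pattern)) {
    stop("invalid pattern '", pattern,
         "': alphabet is A/C/G/U with [..] alternatives", call. = FALSE)
  }
  pattern
}

#' Scan a sequence for a degenerate motif
#'
#' Counts all matches of the pattern, including overlapping ones.
#' Patterns use the RNA alphabet with bracketed alternatives, e.g.
#' `"GUA[AG]"` (a Nrd1 binding site) or `"UCUUG"` (a Nab3 site).
#'
#' @param seq RNA-sense sequence (alphabet A/C/G/U).
#' @param pattern Degenerate pattern.
#' @return List with `count` and `positions` (0-based match starts).
#' @examples
#' scan_motif("GUAGUAA", "GUA[AG]")  # two overlapping matches
#' @export
scan_motif <- function(seq, pattern) {
  rx <- pattern_to_regex(pattern)
  if (!grepl("^[ACGU]*$", seq)) {
    stop("sequence contains characters outside A/C/G/U", call. = FALSE)
  }
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    list(count = 0L, positions = integer(0))
  } else {
    list(count = length(m), positions = as.integer(m) - 1L)
  }
}

# Vectorized overlapping match counts over several sequences.
count_motif <- function(seqs, pattern) {
  rx <- paste0("(?=", pattern_to_regex(pattern), ")")
  vapply(seqs, function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Maximal U-run statistics
#'
#' Maximal (non-extendable) runs of U of at least `min_len` nt, optionally
#' restricted to runs overlapping a window of 0-based positions within the
#' sequence.
#'
#' @param seq RNA-sense sequence.
#' @param min_len Minimum run length (>= 2).
#' @param window Optional `c(start, end)` 0-based half-open window; runs
#'   overlapping it by >= 1 nt are reported.
#' @return List with `starts` (0-based), `lengths`, `count`.
#' @examples
#' u_run_stats("UUUUAUUU", min_len = 3)  # runs of length 4 and 3
#' @export
u_run_stats <- function(seq, min_len = 3L, window = NULL) {
  if (min_len < 2) stop("'min_len' must be >= 2", call. = FALSE)
  m <- gregexpr("U+", seq)[[1]]
  if (m[1] == -1L) {
    starts <- integer(0); lens <- integer(0)
  } else {
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
  }
  keep <- lens >= min_len
  starts <- starts[keep]; lens <- lens[keep]
  if (!is.null(window)) {
    keep <- starts < window[2] & (starts + lens) > window[1]
    starts <- starts[keep]; lens <- lens[keep]
  }
  list(starts = starts, lengths = lens, count = length(starts))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: the returned sequence has
#' exactly the same dinucleotide (and hence mononucleotide) counts as the
#' input, with first and last characters fixed.
#'
#' @param seq A sequence (any alphabet).
#' @return A shuffled sequence.
#' @export
dinucleotide_shuffle <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  if (n <= 3L) return(seq)
  verts <- unique(x)
  xi <- match(x, verts)
  k <- length(verts)
  from <- xi[-n]
  to <- xi[-1]
  adj <- split(to, factor(from, levels = seq_len(k)))
  f <- xi[n]
  has_out <- vapply(adj, length, integer(1)) > 0L

  # pick a random last out-edge per non-final vertex until the chosen last
  # edges form an arborescence converging on the final vertex
  repeat {
    last <- rep(NA_integer_, k)
    for (v in seq_len(k)) {
      if (v == f || !has_out[v]) next
      a <- adj[[v]]
      last[v] <- a[sample.int(length(a), 1L)]
    }
    ok <- TRUE
    for (v in seq_len(k)) {
      if (v == f || !has_out[v]) next
      cur <- v
      steps <- 0L
      while (cur != f && steps <= k) {
        cur <- last[cur]
        steps <- steps + 1L
        if (is.na(cur)) break
      }
      if (is.na(cur) || cur != f) { ok <- FALSE; break }
    }
    if (ok) break
  }

  # permute each vertex's remaining out-edges; its chosen last edge goes last
  ordered <- vector("list", k)
  for (v in seq_len(k)) {
    a <- adj[[v]]
    if (!length(a)) next
    if (v != f) {
      drop_i <- which(a == last[v])[1]
      rest <- a[-drop_i]
      ordered[[v]] <- c(if (length(rest)) rest[sample.int(length(rest))],
                        last[v])
    } else {
      ordered[[v]] <- a[sample.int(length(a))]
    }
  }

  # walk the Eulerian path
  ptr <- integer(k)
  res <- integer(n)
  res[1] <- xi[1]
  cur <- xi[1]
  for (i in 2:n) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- ordered[[cur]][ptr[cur]]
    res[i] <- nxt
    cur <- nxt
  }
  paste(verts[res], collapse = "")
}

#' Empirical motif enrichment against dinucleotide-shuffled sequences
#'
#' Compares the observed total motif count across the sequences with its
#' distribution under per-sequence dinucleotide-preserving shuffles
#' (which preserve the AT-richness and dinucleotide composition of
#' terminator-proximal sequence). The p-value is
#' `(1 + #{shuffled totals >= observed}) / (1 + n_shuffles)`.
#'
#' @param seqs Character vector of >= 2 RNA-sense sequences.
#' @param pattern Degenerate motif pattern (see [scan_motif()]).
#' @param n_shuffles Number of shuffle rounds (a warning is logged below
#'   100).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return List with `observed`, `null_mean`, `fold_enrichment`,
#'   `p_value`, `n_shuffles`.
#' @export
motif_enrichment <- function(seqs, pattern, n_shuffles = 1000L, seed = 1L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (n_shuffles < 100L) {
    warning("n_shuffles < 100 gives a coarse p-value", call. = FALSE)
  }
  observed <- sum(count_motif(seqs, pattern))
  with_seed(seed, {
    null_tot <- vapply(seq_len(n_shuffles), function(b) {
      sum(count_motif(vapply(seqs, dinucleotide_shuffle, character(1),
                             USE.NAMES = FALSE), pattern))
    }, numeric(1))
    null_mean <- mean(null_tot)
    list(observed = observed,
         null_mean = null_mean,
         fold_enrichment = if (observed == 0) 0 else
           if (null_mean == 0) Inf else observed / null_mean,
         p_value = (1 + sum(null_tot >= observed)) / (1 + n_shuffles),
         n_shuffles = as.integer(n_shuffles))
  })
}
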