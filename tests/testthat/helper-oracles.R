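# Independent brute-force oracles, deliberately written without reusing the
# package's computation paths.

# Naive per-position readthrough scan over dense vectors.
oracle_global_scan <- function(control, treated, window, min_index,
                               min_reads, require_gt) {
  rows <- list()
  for (chrom in names(control$values)) {
    L <- length(control$values[[chrom]][["+"]])
    for (s in c("+", "-")) {
      vc <- control$values[[chrom]][[s]]
      vt <- treated$values[[chrom]][[s]]
      for (pos in window:(L - window)) {
        left_c <- sum(vc[(pos - window + 1):pos])
        right_c <- sum(vc[(pos + 1):(pos + window)])
        left_t <- sum(vt[(pos - window + 1):pos])
        right_t <- sum(vt[(pos + 1):(pos + window)])
        if (s == "+") {
          up_c <- left_c; down_c <- right_c
          up_t <- left_t; down_t <- right_t
        } else {
          up_c <- right_c; down_c <- left_c
          up_t <- right_t; down_t <- left_t
        }
        tc <- up_c + down_c; tt <- up_t + down_t
        if (tc == 0 || tt == 0) next
        idx <- down_t / tt - down_c / tc
        if (!(idx > min_index)) next
        if (!(tc >= min_reads || tt >= min_reads)) next
        if (require_gt && !(tt > tc)) next
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = pos, strand = s,
          up_control = up_c, down_control = down_c,
          up_treated = up_t, down_treated = down_t,
          frac_control = down_c / tc, frac_treated = down_t / tt,
          index = idx, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Literal cutoff -> cluster -> ratio -> rank pA selection.
oracle_select_pa <- function(records, min_reads = 200, cluster_dist = 200,
                             dominance_ratio = 0.4, top_n = 500) {
  rec <- records[records$raw_reads >= min_reads, , drop = FALSE]
  kept <- list()
  for (key in unique(paste(rec$chrom, rec$strand))) {
    sub <- rec[paste(rec$chrom, rec$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (!nrow(sub)) next
    cl_id <- cumsum(c(1, diff(sub$pos) > cluster_dist))
    for (cid in unique(cl_id)) {
      cl <- sub[cl_id == cid, , drop = FALSE]
      if (nrow(cl) == 1) {
        kept[[length(kept) + 1]] <- cl
      } else {
        srt <- cl[order(-cl$raw_reads, cl$chrom, cl$pos, cl$strand), ,
                  drop = FALSE]
        if (srt$raw_reads[2] / srt$raw_reads[1] < dominance_ratio) {
          kept[[length(kept) + 1]] <- srt[1, , drop = FALSE]
        }
        # else: ambiguous cluster dropped entirely
      }
    }
  }
  if (!length(kept)) {
    out <- records[0, c("chrom", "pos", "strand", "raw_reads")]
    rownames(out) <- NULL
    return(out)
  }
  out <- do.call(rbind, kept)
  out <- out[order(-out$raw_reads, out$chrom, out$pos, out$strand), ,
             drop = FALSE]
  out <- head(out, top_n)
  rownames(out) <- NULL
  out[, c("chrom", "pos", "strand", "raw_reads")]
}

# Per-read, per-base coverage accumulation.
oracle_coverage <- function(reads, chrom_lengths, total_aligned,
                            norm_per = 1e7) {
  vals <- lapply(chrom_lengths, function(L) {
    list("+" = numeric(L), "-" = numeric(L))
  })
  for (i in seq_len(nrow(reads))) {
    for (b in (reads$start[i] + 1):reads$end[i]) {
      vals[[reads$chrom[i]]][[reads$strand[i]]][b] <-
        vals[[reads$chrom[i]]][[reads$strand[i]]][b] + 1
    }
  }
  lapply(vals, function(v) lapply(v, function(x) x * norm_per / total_aligned))
}

# Expand a degenerate pattern and compare substrings position by position.
oracle_motif_count <- function(seq, pattern) {
  alts <- list("")
  i <- 1
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      set <- character(0)
      while (chars[j] != "]") { set <- c(set, chars[j]); j <- j + 1 }
      alts <- unlist(lapply(alts, function(a) paste0(a, set)))
      i <- j + 1
    } else {
      alts <- unlist(lapply(alts, function(a) paste0(a, chars[i])))
      i <- i + 1
    }
  }
  m <- nchar(alts[1])
  n <- nchar(seq)
  if (n < m) return(list(count = 0L, positions = integer(0)))
  hits <- which(vapply(1:(n - m + 1), function(p) {
    substr(seq, p, p + m - 1) %in% alts
  }, logical(1)))
  list(count = length(hits), positions = hits - 1L)
}

# Maximal U-runs via run-length encoding of the character vector.
oracle_u_runs <- function(seq, min_len = 3) {
  r <- rle(strsplit(seq, "")[[1]] == "U")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based
  keep <- r$values & r$lengths >= min_len
  list(starts = starts[keep], lengths = r$lengths[keep],
       count = sum(keep))
}

# Exhaustive longest suffix-prefix adapter match.
oracle_trim <- function(read, adapter, min_overlap = 5,
                        max_mismatch_rate = 0.1) {
  n <- nchar(read)
  for (L in rev(seq_len(min(n, nchar(adapter))))) {
    if (L < min_overlap) break
    suf <- strsplit(substr(read, n - L + 1, n), "")[[1]]
    pre <- strsplit(substr(adapter, 1, L), "")[[1]]
    if (sum(suf != pre) <= floor(max_mismatch_rate * L)) {
      return(substr(read, 1, n - L))
    }
  }
  read
}

# Exhaustive greedy non-overlap selection.
oracle_greedy_select <- function(points, min_separation) {
  pts <- points[order(-points$index, points$chrom, points$pos,
                      points$strand), , drop = FALSE]
  kept <- pts[0, , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    same <- kept$chrom == pts$chrom[i] & kept$strand == pts$strand[i]
    if (!any(same & abs(kept$pos - pts$pos[i]) < min_separation)) {
      kept <- rbind(kept, pts[i, , drop = FALSE])
    }
  }
  rownames(kept) <- NULL
  kept
}

dinuc_counts <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  if (length(v) < 2) return(table(character(0)))
  table(paste0(v[-length(v)], v[-1]))
}
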