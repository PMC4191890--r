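# Synthetic genomes, occupancy tracks, pA tables and raw reads with planted
# ground truth, emulating the occupancy structure of Pol II termination-factor
# depletion experiments.

#' Occupancy rate model for simulated Pol II tracks
#'
#' Parameterizes the expected per-base occupancy around a transcription
#' unit. In the control condition a locus contributes a uniform gene-body
#' plateau on `[tss, term_point]`, a Gaussian pre-termination pause bump
#' centered `pause_offset` nt upstream of the termination point, and a
#' short exponential decay tail downstream (polymerase release). Under
#' depletion of a factor targeting the locus class, a fraction
#' `readthrough_alpha` of polymerases fails to terminate and sustains the
#' body rate over `readthrough_len` nt before decaying, while the
#' remaining `1 - readthrough_alpha` still terminate with the control
#' decay; the pause bump is eliminated (Nrd1/Sen1 classes) or enlarged
#' into a confined downstream pileup (Ysh1 class).
#'
#' @param pause_amp Pause bump amplitude as a multiple of `body_rate`.
#' @param pause_sigma Pause bump standard deviation (nt).
#' @param pause_offset Distance of the bump center upstream of the
#'   termination point (nt). Default `3 * pause_sigma`, placing essentially
#'   all pause mass upstream of the release point.
#' @param decay_tau_control Exponential decay constant (nt) of occupancy
#'   past the termination point in the control.
#' @param readthrough_alpha Fraction of `body_rate` sustained downstream
#'   under depletion, in `[0, 1]`.
#' @param readthrough_len Processive extent (nt) of depletion readthrough.
#' @param background_rate Expected background events per base.
#' @return An object of class `occupancy_model`.
#' @seealso [preset_model()] for the factor-class presets.
#' @export
occupancy_model <- function(pause_amp = 2, pause_sigma = 25,
                            pause_offset = 3 * pause_sigma,
                            decay_tau_control = 15,
                            readthrough_alpha = 0.5,
                            readthrough_len = 1500,
                            background_rate = 0.05) {
  m <- list(pause_amp = pause_amp, pause_sigma = pause_sigma,
            pause_offset = pause_offset,
            decay_tau_control = decay_tau_control,
            readthrough_alpha = readthrough_alpha,
            readthrough_len = readthrough_len,
            background_rate = background_rate)
  for (f in c("pause_amp", "pause_sigma", "pause_offset", "decay_tau_control",
              "readthrough_len", "background_rate")) {
    if (!is_number(m[[f]]) || m[[f]] < 0) {
      stop("'", f, "' must be a non-negative number", call. = FALSE)
    }
  }
  if (!is_number(readthrough_alpha) || readthrough_alpha < 0 ||
      readthrough_alpha > 1) {
    stop("'readthrough_alpha' must be in [0, 1]", call. = FALSE)
  }
  structure(m, class = "occupancy_model")
}

#' Factor-class preset occupancy models
#'
#' `Nrd1`: long processive readthrough (>= 1 kb). `Sen1`: short readthrough
#' of a few hundred nt. `Ysh1`: pileup confined within 200 nt of the pA
#' site, no extended readthrough.
#'
#' @param factor_class One of `"Nrd1"`, `"Sen1"`, `"Ysh1"`.
#' @param ... Overrides passed to [occupancy_model()].
#' @return An `occupancy_model`.
#' @export
preset_model <- function(factor_class = c("Nrd1", "Sen1", "Ysh1"), ...) {
  factor_class <- match.arg(factor_class)
  defaults <- switch(factor_class,
    Nrd1 = list(readthrough_len = 1500),
    Sen1 = list(readthrough_len = 250),
    Ysh1 = list(readthrough_len = 150))
  args <- utils::modifyList(defaults, list(...))
  do.call(occupancy_model, args)
}

# Locus classes gaining readthrough under depletion of each factor.
factor_target_classes <- function(factor_class) {
  switch(factor_class,
    Nrd1 = c("snoRNA", "CUT", "antisenseCUT"),
    Sen1 = c("snoRNA", "CUT", "antisenseCUT"),
    Ysh1 = "mRNA",
    stop("unknown factor_class '", factor_class, "'", call. = FALSE))
}

LOCUS_CLASSES <- c("mRNA", "snoRNA", "CUT", "antisenseCUT")

#' Validate a locus table
#'
#' A locus table is a data frame with columns `id`, `chrom`, `strand`
#' (`+`/`-`), `tss`, `term_point` (0-based base positions), `locus_class`
#' (one of `mRNA`, `snoRNA`, `CUT`, `antisenseCUT`) and `body_rate`
#' (expected occupancy events per base, >= 0). The TSS must lie strictly
#' upstream of the termination point in the transcription direction, every
#' locus needs >= 1 kb of flanking chromosome on both sides, and loci on
#' the same strand must be separated by >= 2 kb.
#'
#' @param loci Locus data frame.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param min_flank Required flank (nt) between a locus and the chromosome
#'   ends.
#' @param min_separation Required gap (nt) between same-strand loci.
#' @return `loci`, invisibly, after validation.
#' @export
validate_loci <- function(loci, chrom_lengths, min_flank = 1000,
                          min_separation = 2000) {
  validate_chrom_lengths(chrom_lengths)
  need <- c("id", "chrom", "strand", "tss", "term_point", "locus_class",
            "body_rate")
  if (!is.data.frame(loci) || !all(need %in% names(loci))) {
    stop("loci must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(loci) == 0L) return(invisible(loci))
  check_strand(loci$strand)
  if (!all(loci$locus_class %in% LOCUS_CLASSES)) {
    stop("locus_class must be one of ", paste(LOCUS_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  if (any(loci$body_rate < 0)) stop("body_rate must be >= 0", call. = FALSE)
  if (!all(loci$chrom %in% names(chrom_lengths))) {
    stop("loci on chromosomes absent from chrom_lengths", call. = FALSE)
  }
  fwd <- loci$strand == "+"
  bad_dir <- (fwd & loci$tss >= loci$term_point) |
    (!fwd & loci$tss <= loci$term_point)
  if (any(bad_dir)) {
    stop("tss must be strictly upstream of term_point in the transcription ",
         "direction: ", paste(loci$id[bad_dir], collapse = ", "),
         call. = FALSE)
  }
  lo <- pmin(loci$tss, loci$term_point)
  hi <- pmax(loci$tss, loci$term_point)
  L <- chrom_lengths[loci$chrom]
  off <- lo - min_flank < 0 | hi + min_flank > L - 1
  if (any(off)) {
    stop("loci need >= ", min_flank, " nt flanks within their chromosome: ",
         paste(loci$id[off], collapse = ", "), call. = FALSE)
  }
  sp <- split(seq_len(nrow(loci)), paste(loci$chrom, loci$strand))
  for (idx in sp) {
    if (length(idx) < 2L) next
    o <- idx[order(lo[idx])]
    gap <- lo[o][-1] - hi[o][-length(o)]
    viol <- which(gap < min_separation)
    if (length(viol)) {
      stop("same-strand loci closer than ", min_separation, " nt: ",
           loci$id[o[viol[1]]], " / ", loci$id[o[viol[1] + 1L]],
           call. = FALSE)
    }
  }
  invisible(loci)
}

#' Expected occupancy rate tracks for a locus set
#'
#' The closed-form per-base rate function the Poisson simulator draws
#' from. Useful as an analytic oracle: window sums of the rate equal the
#' expected window sums of simulated counts.
#'
#' @inheritParams validate_loci
#' @param model An [occupancy_model()].
#' @param condition `"control"` or `"depleted"`.
#' @param factor_class `"Nrd1"`, `"Sen1"` or `"Ysh1"`; only loci of the
#'   classes targeted by that factor change between conditions.
#' @return A `coverage_track` of expected rates (events/base).
#' @export
rate_tracks <- function(loci, model, condition = c("control", "depleted"),
                        factor_class = c("Nrd1", "Sen1", "Ysh1"),
                        chrom_lengths) {
  condition <- match.arg(condition)
  factor_class <- match.arg(factor_class)
  stopifnot(inherits(model, "occupancy_model"))
  validate_loci(loci, chrom_lengths)
  targets <- factor_target_classes(factor_class)

  vals <- lapply(chrom_lengths, function(L) {
    list("+" = rep(model$background_rate, L),
         "-" = rep(model$background_rate, L))
  })

  add_at <- function(v, pos0, amount) {
    # pos0: 0-based genomic positions; out-of-range entries dropped
    keep <- pos0 >= 0 & pos0 < length(v)
    idx <- pos0[keep] + 1L
    v[idx] <- v[idx] + amount[keep]
    v
  }

  tau <- model$decay_tau_control
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    strand <- loci$strand[i]
    term <- loci$term_point[i]
    body <- loci$body_rate[i]
    dir <- if (strand == "+") 1L else -1L
    v <- vals[[chrom]][[strand]]

    # gene body plateau [tss, term_point] inclusive
    lo <- min(loci$tss[i], term)
    hi <- max(loci$tss[i], term)
    v <- add_at(v, lo:hi, rep(body, hi - lo + 1L))

    depleted_target <- condition == "depleted" &&
      loci$locus_class[i] %in% targets

    bump <- function(center_u, amp) {
      # Gaussian bump in transcription coordinates u (0 at term_point)
      span <- ceiling(4 * model$pause_sigma)
      u <- (center_u - span):(center_u + span)
      a <- amp * body * exp(-(u - center_u)^2 / (2 * model$pause_sigma^2))
      list(pos = term + dir * u, amount = a)
    }

    # control decay tail past term_point
    tail_d <- seq_len(max(1L, ceiling(12 * tau)))
    control_tail <- body * exp(-tail_d / tau)

    if (!depleted_target) {
      # control shape: pause bump + decay tail
      b <- bump(-model$pause_offset, model$pause_amp)
      v <- add_at(v, b$pos, b$amount)
      v <- add_at(v, term + dir * tail_d, control_tail)
    } else if (factor_class %in% c("Nrd1", "Sen1")) {
      # pause eliminated; alpha of polymerases read through over
      # readthrough_len then decay, (1 - alpha) terminate as in control
      alpha <- model$readthrough_alpha
      rl <- model$readthrough_len
      d <- seq_len(ceiling(rl + 12 * tau))
      rt <- ifelse(d <= rl, alpha * body,
                   alpha * body * exp(-(d - rl) / tau))
      resid <- (1 - alpha) * body * exp(-d / tau)
      v <- add_at(v, term + dir * d, rt + resid)
    } else {
      # Ysh1: control bump retained, extra pileup just downstream of the
      # pA site, plus confined readthrough
      b <- bump(-model$pause_offset, model$pause_amp)
      v <- add_at(v, b$pos, b$amount)
      p <- bump(50, model$pause_amp)
      v <- add_at(v, p$pos, p$amount)
      alpha <- model$readthrough_alpha
      rl <- model$readthrough_len
      d <- seq_len(ceiling(rl + 12 * tau))
      rt <- ifelse(d <= rl, alpha * body,
                   alpha * body * exp(-(d - rl) / tau))
      resid <- (1 - alpha) * body * exp(-d / tau)
      v <- add_at(v, term + dir * d, rt + resid)
    }
    vals[[chrom]][[strand]] <- v
  }
  coverage_track(vals)
}

#' Simulate a per-base occupancy track
#'
#' Draws independent Poisson counts at every base from the closed-form
#' rate function of [rate_tracks()]. Identical seeds give byte-identical
#' tracks.
#'
#' @inheritParams rate_tracks
#' @param seed Integer seed for the Poisson draws.
#' @return A `coverage_track` of counts (`normalization_factor = 1`).
#' @examples
#' loci <- data.frame(id = "s1", chrom = "chrI", strand = "+", tss = 2000,
#'                    term_point = 2400, locus_class = "snoRNA",
#'                    body_rate = 5)
#' tr <- simulate_occupancy(loci, preset_model("Nrd1"), "depleted", "Nrd1",
#'                          c(chrI = 10000), seed = 1)
#' @export
simulate_occupancy <- function(loci, model,
                               condition = c("control", "depleted"),
                               factor_class = c("Nrd1", "Sen1", "Ysh1"),
                               chrom_lengths, seed) {
  condition <- match.arg(condition)
  factor_class <- match.arg(factor_class)
  rates <- rate_tracks(loci, model, condition, factor_class, chrom_lengths)
  with_seed(seed, {
    vals <- lapply(names(rates$values), function(chrom) {
      list("+" = as.numeric(rpois(length(rates$values[[chrom]][["+"]]),
                                  rates$values[[chrom]][["+"]])),
           "-" = as.numeric(rpois(length(rates$values[[chrom]][["-"]]),
                                  rates$values[[chrom]][["-"]])))
    })
    names(vals) <- names(rates$values)
    coverage_track(vals, total_aligned = NA_real_, normalization_factor = 1)
  })
}

#' Sequence composition specification for simulated genomes
#'
#' @param gc_intergenic,gc_genic GC fractions in (0, 1) for intergenic and
#'   genic sequence.
#' @param motif_inserts Data frame with columns `pattern` (RNA-sense, may
#'   not contain brackets), `count`, `win_start`, `win_end` (window in
#'   transcription coordinates relative to the termination point; upstream
#'   is negative) and `classes` (pipe-separated locus classes the insert
#'   applies to, `NA` = all non-mRNA loci).
#' @param u_run_inserts Data frame with columns `run_len`, `count`,
#'   `win_start`, `win_end`, `classes` for planted U-runs.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(gc_intergenic = 0.32, gc_genic = 0.40,
                          motif_inserts = default_motif_inserts(),
                          u_run_inserts = default_u_run_inserts()) {
  for (gc in c(gc_intergenic, gc_genic)) {
    if (!is_number(gc) || gc <= 0 || gc >= 1) {
      stop("GC fractions must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  structure(list(gc_intergenic = gc_intergenic, gc_genic = gc_genic,
                 motif_inserts = motif_inserts,
                 u_run_inserts = u_run_inserts),
            class = "sequence_spec")
}

#' @rdname sequence_spec
#' @export
default_motif_inserts <- function() {
  data.frame(
    pattern = c("GUAA", "UCUUG", "UCUUG"),
    count = c(2L, 2L, 3L),
    win_start = -150L, win_end = 0L,
    classes = c("snoRNA", "snoRNA", "CUT|antisenseCUT"),
    stringsAsFactors = FALSE
  )
}

#' @rdname sequence_spec
#' @export
default_u_run_inserts <- function() {
  data.frame(
    run_len = 5L, count = 2L, win_start = -50L, win_end = 50L,
    classes = NA_character_,
    stringsAsFactors = FALSE
  )
}

insert_applies <- function(classes_field, locus_class) {
  if (is.na(classes_field)) return(locus_class != "mRNA")
  locus_class %in% strsplit(classes_field, "|", fixed = TRUE)[[1]]
}

#' Simulate a genome with planted terminator sequence features
#'
#' Draws intergenic and genic sequence at the requested GC compositions,
#' then writes the declared motif and U-run inserts into each applicable
#' locus's window (transcription-strand sense, relative to the planted
#' termination point). Same spec + loci + seed gives a byte-identical
#' genome.
#'
#' @inheritParams validate_loci
#' @param spec A [sequence_spec()].
#' @param seed Integer seed.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]),
#'   `annotation` (a [GenomicRanges::GRanges] of locus spans, `name` =
#'   locus id, `score` = class code 1..4) and `inserts` (data frame of
#'   realized insert positions, transcription coordinates).
#' @export
simulate_genome <- function(spec, loci, chrom_lengths, seed) {
  stopifnot(inherits(spec, "sequence_spec"))
  validate_chrom_lengths(chrom_lengths)
  validate_loci(loci, chrom_lengths)

  with_seed(seed, {
    probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                            G = gc / 2, T = (1 - gc) / 2)
    seqs <- lapply(chrom_lengths, function(L) {
      sample(c("A", "C", "G", "T"), L, replace = TRUE,
             prob = probs(spec$gc_intergenic))
    })
    # resample genic spans at genic GC
    for (i in seq_len(nrow(loci))) {
      lo <- min(loci$tss[i], loci$term_point[i])
      hi <- max(loci$tss[i], loci$term_point[i])
      n <- hi - lo + 1L
      seqs[[loci$chrom[i]]][(lo:hi) + 1L] <-
        sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = probs(spec$gc_genic))
    }

    # planted inserts, tracked per locus to avoid overlaps in u-space
    realized <- list()
    ins <- rbind(
      if (nrow(spec$motif_inserts)) {
        data.frame(what = spec$motif_inserts$pattern,
                   len = nchar(spec$motif_inserts$pattern),
                   count = spec$motif_inserts$count,
                   win_start = spec$motif_inserts$win_start,
                   win_end = spec$motif_inserts$win_end,
                   classes = spec$motif_inserts$classes,
                   stringsAsFactors = FALSE)
      },
      if (!is.null(spec$u_run_inserts) && nrow(spec$u_run_inserts)) {
        data.frame(what = vapply(spec$u_run_inserts$run_len, function(k) {
                     paste(rep("U", k), collapse = "")
                   }, character(1)),
                   len = spec$u_run_inserts$run_len,
                   count = spec$u_run_inserts$count,
                   win_start = spec$u_run_inserts$win_start,
                   win_end = spec$u_run_inserts$win_end,
                   classes = spec$u_run_inserts$classes,
                   stringsAsFactors = FALSE)
      })
    for (i in seq_len(nrow(loci))) {
      if (is.null(ins) || nrow(ins) == 0L) break
      occupied <- integer(0)  # occupied u positions for this locus
      term <- loci$term_point[i]
      strand <- loci$strand[i]
      chrom <- loci$chrom[i]
      L <- chrom_lengths[[chrom]]
      for (j in seq_len(nrow(ins))) {
        if (!insert_applies(ins$classes[j], loci$locus_class[i])) next
        m <- ins$len[j]
        u_cand <- ins$win_start[j]:(ins$win_end[j] - m)
        # windows must map inside the chromosome
        g_of_u <- function(u) if (strand == "+") term + u else term - u
        ok_bounds <- vapply(u_cand, function(u) {
          g <- sort(c(g_of_u(u), g_of_u(u + m - 1L)))
          g[1] >= 0 && g[2] <= L - 1
        }, logical(1))
        u_cand <- u_cand[ok_bounds]
        placed <- 0L
        tries <- 0L
        while (placed < ins$count[j] && tries < 200L && length(u_cand)) {
          tries <- tries + 1L
          u <- u_cand[sample.int(length(u_cand), 1L)]
          if (any((u:(u + m - 1L)) %in% occupied)) next
          occupied <- c(occupied, u:(u + m - 1L))
          dna <- rna_to_dna(ins$what[j])
          if (strand == "+") {
            seqs[[chrom]][(term + u):(term + u + m - 1L) + 1L] <-
              strsplit(dna, "")[[1]]
          } else {
            rc <- reverse_complement(dna)
            seqs[[chrom]][(term - u - m + 1L):(term - u) + 1L] <-
              strsplit(rc, "")[[1]]
          }
          realized[[length(realized) + 1L]] <- data.frame(
            locus_id = loci$id[i], pattern = ins$what[j], u = u,
            stringsAsFactors = FALSE)
          placed <- placed + 1L
        }
        if (placed < ins$count[j]) {
          stop("could not place ", ins$count[j], " copies of '", ins$what[j],
               "' in window [", ins$win_start[j], ",", ins$win_end[j],
               ") of locus ", loci$id[i], call. = FALSE)
        }
      }
    }

    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                              collapse = ""))
    names(genome) <- names(chrom_lengths)
    class_code <- match(loci$locus_class, LOCUS_CLASSES)
    annotation <- GenomicRanges::GRanges(
      seqnames = loci$chrom,
      ranges = IRanges::IRanges(start = pmin(loci$tss, loci$term_point) + 1L,
                                end = pmax(loci$tss, loci$term_point) + 1L),
      strand = loci$strand,
      name = loci$id, score = class_code)
    inserts <- if (length(realized)) do.call(rbind, realized) else
      data.frame(locus_id = character(0), pattern = character(0),
                 u = integer(0))
    list(genome = genome, annotation = annotation, inserts = inserts)
  })
}

#' Simulate a polyadenylation-site table
#'
#' Every `mRNA` locus receives one pA site at its planted termination
#' point with a Poisson-drawn read count; optional uniformly placed decoy
#' sites get low counts, and caller-supplied competitor sites can be
#' appended verbatim (e.g. to build clustered dominant/minor pairs).
#'
#' @inheritParams validate_loci
#' @param seed Integer seed.
#' @param noise_sites Number of low-count decoy sites to scatter.
#' @param site_mean_reads Poisson mean for true pA-site read counts.
#' @param noise_mean_reads Poisson mean for decoy read counts.
#' @param extra_sites Optional data frame (`chrom`, `pos`, `strand`,
#'   `raw_reads`) appended to the table.
#' @return Data frame with columns `chrom`, `pos`, `strand`, `raw_reads`.
#' @export
simulate_pa_table <- function(loci, chrom_lengths, seed, noise_sites = 0,
                              site_mean_reads = 2000, noise_mean_reads = 50,
                              extra_sites = NULL) {
  validate_loci(loci, chrom_lengths)
  with_seed(seed, {
    m <- loci[loci$locus_class == "mRNA", , drop = FALSE]
    tab <- data.frame(chrom = m$chrom, pos = m$term_point, strand = m$strand,
                      raw_reads = rpois(nrow(m), site_mean_reads),
                      stringsAsFactors = FALSE)
    if (noise_sites > 0) {
      chroms <- sample(names(chrom_lengths), noise_sites, replace = TRUE)
      pos <- vapply(chroms, function(ch) {
        sample.int(chrom_lengths[[ch]], 1L) - 1L
      }, integer(1))
      noise <- data.frame(chrom = chroms, pos = pos,
                          strand = sample(c("+", "-"), noise_sites,
                                          replace = TRUE),
                          raw_reads = rpois(noise_sites, noise_mean_reads),
                          stringsAsFactors = FALSE)
      tab <- rbind(tab, noise)
    }
    if (!is.null(extra_sites)) {
      tab <- rbind(tab, extra_sites[, c("chrom", "pos", "strand",
                                        "raw_reads")])
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Simulate raw reads from an occupancy track
#'
#' Read 5' ends are sampled proportional to the per-base track value; each
#' read sequence is the genomic substring (reverse-complemented on the
#' minus strand) with a prefix of the 3' adapter appended. True alignment
#' intervals are returned for oracle tests.
#'
#' @param track A `coverage_track` of sampling weights.
#' @param genome A [Biostrings::DNAStringSet] covering the track.
#' @param read_len Insert length (nt).
#' @param adapter 3' adapter sequence (DNA).
#' @param n_reads Number of reads (> 0).
#' @param adapter_overlap How many adapter bases to append (default: all).
#' @param seed Integer seed.
#' @return List with `sequences` (character vector) and `alignments`
#'   (data frame `chrom`, `start`, `end`, `strand`; 0-based half-open).
#' @export
simulate_reads <- function(track, genome, read_len = 30,
                           adapter = "AGATCGGAAGAGCACACGTCT",
                           n_reads, adapter_overlap = nchar(adapter), seed) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is_count(n_reads)) stop("n_reads must be a positive integer",
                               call. = FALSE)
  lens <- track_lengths(track)
  if (any(read_len >= lens)) {
    stop("read_len must be shorter than every chromosome", call. = FALSE)
  }
  # flatten weights; zero out positions where a full read does not fit
  chroms <- track_chromosomes(track)
  keys <- list(); wts <- list()
  for (chrom in chroms) {
    L <- lens[[chrom]]
    for (s in c("+", "-")) {
      w <- track$values[[chrom]][[s]]
      if (s == "+") {
        if (L >= read_len) w[(L - read_len + 2L):L] <- 0 else w[] <- 0
      } else {
        w[seq_len(min(read_len - 1L, L))] <- 0
      }
      keys[[paste(chrom, s)]] <- list(chrom = chrom, strand = s)
      wts[[paste(chrom, s)]] <- w
    }
  }
  flat <- unlist(wts, use.names = FALSE)
  tot <- sum(flat)
  if (tot <= 0) stop("track has no usable signal to sample reads from",
                     call. = FALSE)
  cum <- cumsum(flat)
  bounds <- cumsum(vapply(wts, length, numeric(1)))
  with_seed(seed, {
    u <- runif(n_reads) * tot
    flat_idx <- findInterval(u, cum, left.open = TRUE) + 1L
    grp <- findInterval(flat_idx - 1L, bounds, left.open = TRUE) + 1L
    offset <- flat_idx - c(0, bounds)[grp]  # 1-based within group
    chrom <- vapply(keys, `[[`, character(1), "chrom")[grp]
    strand <- vapply(keys, `[[`, character(1), "strand")[grp]
    pos <- offset - 1L  # 0-based 5' end
    start <- ifelse(strand == "+", pos, pos - read_len + 1L)
    end <- start + read_len
    seq_chr <- lapply(genome, as.character)
    insert <- vapply(seq_len(n_reads), function(i) {
      substr(seq_chr[[chrom[i]]], start[i] + 1L, end[i])
    }, character(1))
    neg <- strand == "-"
    if (any(neg)) insert[neg] <- reverse_complement(insert[neg])
    adapt <- substr(adapter, 1L, adapter_overlap)
    list(sequences = paste0(insert, adapt),
         alignments = data.frame(chrom = chrom, start = start, end = end,
                                 strand = strand, stringsAsFactors = FALSE))
  })
}
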